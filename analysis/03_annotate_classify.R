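#!/usr/bin/env Rscript
# Step 3 — annotate and classify the variants.
#
# Maps each distinct called variant onto the tRNA cloverleaf, evaluates
# Watson-Crick pair disruption, scores the 44-species conservation index,
# and classifies each variant as known / putative / polymorphism under
# the default rules (CI >= 70% or deletion, control carrier frequency
# <= 1%; catalog mutations are known).

suppressPackageStartupMessages(library(mttscreen))

model <- load_gene_model()
catalog <- load_known_mutations()
calls <- read.delim("results/calls.tsv")
alignment <- Biostrings::readDNAStringSet("results/cohort/alignment.fa")

annotations <- annotate_variants(calls, model, alignment,
                                 n_cases = 352L, n_controls = 376L)
classified <- classify_table(annotations, catalog, rule_config())
write.table(classified, "results/classified.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts <- attr(classified, "class_counts")
message("classified ", nrow(classified), " distinct variants: ",
        counts[["known"]], " known, ", counts[["putative"]], " putative, ",
        counts[["polymorphism"]], " polymorphism")
message("variants disrupting a Watson-Crick pair: ",
        sum(classified$wc_disrupted))
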