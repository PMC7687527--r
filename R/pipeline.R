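#' Pipeline run configuration
#'
#' Bundles every input of the end-to-end analysis. All paths default to
#' the reference data shipped with the package, and the cohort and
#' alignment default to the shipped study specification, so
#' `run_pipeline(run_config(out_dir))` reproduces the whole screen
#' offline.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; stage seeds are derived from it.
#' @param cohort Cohort specification ([cohort_spec()]); defaults to the
#'   shipped study cohort.
#' @param alignment Alignment specification ([alignment_spec()]); defaults
#'   to the shipped 44-vertebrate conservation spec.
#' @param rules Classification rules ([rule_config()]).
#' @param gene_model_path,tree_path,catalog_path Reference file paths.
#' @param carrier_haplogroups data.frame with columns `variant_label` and
#'   `haplogroup` driving full-mtDNA profile simulation for case-arm
#'   carriers; `NULL` loads the shipped assignment.
#' @param n_private Private variants per simulated full-mtDNA profile.
#' @param normalize Deletion normalization mode for variant calling.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = NULL, alignment = NULL,
                       rules = rule_config(),
                       gene_model_path = ref_file("mt_tt_gene_model.yaml"),
                       tree_path = ref_file("haplogroup_tree.tsv"),
                       catalog_path = ref_file("known_mutations.tsv"),
                       carrier_haplogroups = NULL, n_private = 5L,
                       normalize = c("5prime", "3prime")) {
  seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- lhon_cohort_spec(seed = seed)
  if (is.null(alignment)) {
    alignment <- lhon_alignment_spec(seed = (seed + 1L) %% .Machine$integer.max)
  }
  if (is.null(carrier_haplogroups)) {
    carrier_haplogroups <- read.delim(ref_file("carrier_haplogroups.tsv"),
                                      stringsAsFactors = FALSE,
                                      comment.char = "#")
  }
  for (p in c(gene_model_path, tree_path, catalog_path)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = seed, cohort = cohort,
                 alignment = alignment, rules = rules,
                 gene_model_path = gene_model_path, tree_path = tree_path,
                 catalog_path = catalog_path,
                 carrier_haplogroups = carrier_haplogroups,
                 n_private = as.integer(n_private),
                 normalize = match.arg(normalize)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full screening pipeline
#'
#' Simulates (or accepts) a cohort, calls MT-TT variants against the
#' reference, annotates structure and conservation, classifies each
#' variant, computes the aggregate carrier statistics, simulates
#' full-mtDNA profiles for the case-arm carriers, assigns haplogroups and
#' tabulates their frequencies, and writes the whole report bundle as
#' plain-text tables. Re-running with an identical configuration
#' reproduces byte-identical tabular outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with `calls`, `classified`, `report`,
#'   `haplogroup_calls`, `haplogroup_freq`, `truth`, `profiles` and
#'   `paths` (the files written).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  model <- load_gene_model(config$gene_model_path)
  tree <- load_haplogroup_tree(config$tree_path)
  catalog <- load_known_mutations(config$catalog_path)

  say("simulating cohort: ", config$cohort$n_cases, " cases / ",
      config$cohort$n_controls, " controls")
  cohort <- generate_cohort(config$cohort, model)
  paths <- write_cohort(cohort, config$out_dir)

  say("calling variants against ", model$gene, " (rCRS ", model$start, "-",
      model$end, ")")
  calls <- call_cohort(cohort, model, normalize = config$normalize)
  calls_path <- file.path(config$out_dir, "calls.tsv")
  write_tsv(calls, calls_path)

  say("scoring conservation on a ", config$alignment$n_species,
      "-species alignment")
  alignment <- generate_alignment(config$alignment, model)
  aln_path <- file.path(config$out_dir, "alignment.fa")
  Biostrings::writeXStringSet(alignment, aln_path)

  annotations <- annotate_variants(calls, model, alignment,
                                   config$cohort$n_cases,
                                   config$cohort$n_controls)
  classified <- classify_table(annotations, catalog, config$rules)
  counts <- attr(classified, "class_counts")
  say("classified ", nrow(classified), " distinct variants: ",
      counts[["known"]], " known / ", counts[["putative"]], " putative / ",
      counts[["polymorphism"]], " polymorphism")
  classified_path <- file.path(config$out_dir, "classified.tsv")
  write_tsv(classified, classified_path)

  report <- aggregate_report(calls, config$cohort$n_cases,
                             config$cohort$n_controls, classified)
  stats_path <- file.path(config$out_dir, "stats.json")
  jsonlite::write_json(report, stats_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  say("simulating full-mtDNA profiles for case-arm carriers")
  hap <- pipeline_haplogroups(calls, classified, tree, config)
  hap_calls_path <- file.path(config$out_dir, "haplogroup_calls.tsv")
  hap_freq_path <- file.path(config$out_dir, "haplogroup_freq.tsv")
  write_tsv(hap$calls, hap_calls_path)
  write_tsv(hap$freq, hap_freq_path)

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    paste0("package: mttscreen ",
           as.character(utils::packageVersion("mttscreen"))),
    paste0("seed: ", config$seed),
    paste0("normalize: ", config$normalize),
    paste0("rules: preset=", config$rules$preset,
           " ci_threshold=", config$rules$ci_threshold,
           " control_freq_cap=", config$rules$control_freq_cap),
    paste0("cohort: n_cases=", config$cohort$n_cases,
           " n_controls=", config$cohort$n_controls,
           " implants=", nrow(config$cohort$implants)),
    paste0("alignment: n_species=", config$alignment$n_species),
    paste0("config_hash: ", config_hash(config))
  ), log_path)

  invisible(list(calls = calls, classified = classified, report = report,
                 haplogroup_calls = hap$calls, haplogroup_freq = hap$freq,
                 truth = cohort$truth, profiles = hap$profiles,
                 paths = c(paths, calls_path, aln_path, classified_path,
                           stats_path, hap_calls_path, hap_freq_path,
                           log_path)))
}

config_hash <- function(config) {
  slim <- config
  slim$out_dir <- NULL
  raw <- serialize(slim, NULL, version = 2)
  # Compact content fingerprint; md5 is used only for run-log provenance.
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

# Simulate full-mtDNA profiles for the case-arm carriers and tabulate
# haplogroup frequencies for the carrier subgroups of interest.
pipeline_haplogroups <- function(calls, classified, tree, config) {
  case_calls <- calls[calls$arm == "case", , drop = FALSE]
  if (nrow(case_calls) == 0L) {
    empty_calls <- data.frame(subject_id = character(0), node = character(0),
                              matched = integer(0), missing = integer(0),
                              score = integer(0), stringsAsFactors = FALSE)
    return(list(calls = empty_calls,
                freq = data.frame(subgroup = character(0), n = integer(0)),
                profiles = NULL))
  }
  case_calls <- case_calls[order(match(case_calls$label,
                                       config$cohort$implants$label),
                                 case_calls$subject_id), , drop = FALSE]
  assignment <- config$carrier_haplogroups
  profiles <- list()
  hg_of <- character(0)
  pool <- assignment
  for (i in seq_len(nrow(case_calls))) {
    lab <- case_calls$label[i]
    j <- which(pool$variant_label == lab)[1L]
    if (is.na(j)) {
      stop("no haplogroup assignment left for carrier of ", lab,
           call. = FALSE)
    }
    hg <- pool$haplogroup[j]
    pool <- pool[-j, , drop = FALSE]
    prof <- generate_profile(tree, hg, n_private = config$n_private,
                             seed = (config$seed + 100L + i) %%
                               .Machine$integer.max)
    # The carrier's own MT-TT variant is part of its full-mtDNA profile.
    prof <- rbind(prof, case_calls[i, c("label", "position", "ref", "alt",
                                        "vtype")])
    prof$subject_id <- case_calls$subject_id[i]
    profiles[[i]] <- prof
    hg_of[case_calls$subject_id[i]] <- hg
  }
  profiles <- do.call(rbind, profiles)
  hap_calls <- assign_haplogroups(profiles, tree)

  putative_labels <- classified$label[classified$class == "putative"]
  grouping <- rbind(
    data.frame(subject_id = case_calls$subject_id,
               subgroup = "all_mt_tt_carriers", stringsAsFactors = FALSE),
    data.frame(subject_id =
                 case_calls$subject_id[case_calls$label == "m.15951A>G"],
               subgroup = "m.15951A>G_carriers", stringsAsFactors = FALSE),
    data.frame(subject_id =
                 case_calls$subject_id[case_calls$label == "m.15927G>A"],
               subgroup = "m.15927G>A_carriers", stringsAsFactors = FALSE),
    data.frame(subject_id =
                 case_calls$subject_id[case_calls$label %in% putative_labels],
               subgroup = "putative_carriers", stringsAsFactors = FALSE))
  freq <- haplogroup_frequency_table(hap_calls, grouping, tree)
  list(calls = hap_calls, freq = freq, profiles = profiles)
}
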