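# Shared fixtures: the shipped reference model and the annotated variant
# table of the study, rebuilt from the shipped specifications.

test_model <- function() load_gene_model()

test_tree <- function() load_haplogroup_tree()

test_catalog <- function() load_known_mutations()

# The 15 variant sites with their printed structural/conservation/count
# facts, used to parameterise reference-model and classification tests.
variant_site_facts <- function() {
  read.delim(text = "label	position	trnadb_pos	element	ci	case_count	control_count
m.15927G>A	15927	42	anticodon stem	75.00	8	0
m.15951A>G	15951	71	acceptor stem	70.45	4	0
m.15900T>C	15900	13	DHU loop	72.73	1	1
m.15901A>G	15901	14	DHU loop	100.00	1	0
m.15908T>C	15908	23	DHU stem	93.18	1	1
m.15924A>G	15924	39	anticodon stem	90.91	9	3
m.15928G>A	15928	43	anticodon stem	77.27	3	2
m.15931A>C	15931	46	variable loop	97.73	1	0
m.15940DelT	15940	56	T-loop	22.73	1	0
m.15943T>C	15943	63	T-stem	79.55	2	1
m.15949G>A	15949	69	acceptor stem	88.64	1	0
m.15907A>G	15907	22	DHU loop	65.91	1	0
m.15930G>A	15930	45	variable loop	25.00	2	13
m.15938C>T	15938	54	T-loop	40.91	1	0
m.15941T>C	15941	61	T-loop	47.73	5	2",
             stringsAsFactors = FALSE)
}

# End-to-end classified table for the shipped cohort spec, computed once
# per test run and cached.
classified_fixture <- local({
  cache <- NULL
  function(seed = 42L) {
    if (!is.null(cache)) return(cache)
    model <- test_model()
    cohort <- generate_cohort(lhon_cohort_spec(seed = seed), model)
    calls <- call_cohort(cohort, model)
    alignment <- generate_alignment(lhon_alignment_spec(seed = seed), model)
    annotations <- annotate_variants(calls, model, alignment, 352L, 376L)
    cache <<- list(
      cohort = cohort, calls = calls, alignment = alignment,
      classified = classify_table(annotations, test_catalog(), rule_config()))
    cache
  }
})
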