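test_that("generated cohort realises carrier counts exactly", {
  model <- test_model()
  spec <- lhon_cohort_spec(seed = 7L)
  cohort <- generate_cohort(spec, model)
  expect_length(cohort$cases, 352L)
  expect_length(cohort$controls, 376L)
  ref <- model$sequence
  n_mutant_cases <- sum(as.character(cohort$cases) != ref)
  expect_identical(n_mutant_cases, 41L)
  expect_identical(sum(as.character(cohort$controls) != ref), 23L)
  # truth-table per-variant counts equal the spec exactly
  truth <- cohort$truth
  for (i in seq_len(nrow(spec$implants))) {
    lab <- spec$implants$label[i]
    expect_identical(sum(truth$variant == lab & truth$arm == "case"),
                     spec$implants$case_carriers[i], label = lab)
    expect_identical(sum(truth$variant == lab & truth$arm == "control"),
                     spec$implants$control_carriers[i], label = lab)
  }
  # each carrier differs from the reference by exactly its variant
  carriers <- truth[truth$variant != "" & truth$arm == "case", ]
  seqs <- as.character(cohort$cases)
  for (i in seq_len(nrow(carriers))) {
    v <- parse_variant_label(carriers$variant[i])
    expect_identical(unname(seqs[carriers$subject_id[i]]),
                     apply_variants(ref, model$start, v))
  }
})

test_that("cohort generation is deterministic and validates implants", {
  model <- test_model()
  c1 <- generate_cohort(lhon_cohort_spec(seed = 3L), model)
  c2 <- generate_cohort(lhon_cohort_spec(seed = 3L), model)
  expect_identical(as.character(c1$cases), as.character(c2$cases))
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(lhon_cohort_spec(seed = 4L), model)
  expect_false(identical(c1$truth$variant, c3$truth$variant))

  empty <- cohort_spec(5L, 5L, lhon_cohort_spec()$implants[0, ], seed = 1L)
  cohort <- generate_cohort(empty, model)
  expect_true(all(as.character(cohort$cases) == model$sequence))

  bad <- lhon_cohort_spec()$implants
  bad$ref[1] <- "A"  # true base at 15927 is G
  expect_error(generate_cohort(cohort_spec(352L, 376L, bad), model),
               "15927")
  expect_error(cohort_spec(10L, 376L, lhon_cohort_spec()$implants),
               "exceed arm size")
})

test_that("written cohort FASTA files are byte-identical across reruns", {
  model <- test_model()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(lhon_cohort_spec(seed = 11L), model), d1)
  write_cohort(generate_cohort(lhon_cohort_spec(seed = 11L), model), d2)
  for (f in c("cases.fa", "controls.fa", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated alignments realise per-position match counts", {
  model <- test_model()
  spec <- lhon_alignment_spec(seed = 5L)
  aln <- generate_alignment(spec, model)
  expect_length(aln, 44L)
  expect_identical(as.character(aln[[1]]), model$sequence)
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  for (i in seq_len(nrow(spec$match_counts))) {
    site <- spec$match_counts$trnadb_pos[i]
    col <- model$site_map[[as.character(site)]] - model$start + 1L
    expect_identical(sum(mat[, col] == mat[1L, col]),
                     spec$match_counts$n_match[i],
                     label = paste("site", site))
  }
  # unspecified positions are fully conserved
  free_cols <- setdiff(seq_len(ncol(mat)),
                       unname(model$site_map[as.character(
                         spec$match_counts$trnadb_pos)]) - model$start + 1L)
  expect_true(all(apply(mat[, free_cols], 2, function(x) all(x == x[1L]))))

  aln2 <- generate_alignment(lhon_alignment_spec(seed = 5L), model)
  expect_identical(as.character(aln), as.character(aln2))
  expect_error(alignment_spec(10L, data.frame(trnadb_pos = 14, n_match = 11)),
               "n_species")
})

test_that("generated profiles are haplogroup-faithful and deterministic", {
  tree <- test_tree()
  p1 <- generate_profile(tree, "F1a1", n_private = 5L, seed = 7L)
  p2 <- generate_profile(tree, "F1a1", n_private = 5L, seed = 7L)
  expect_identical(p1, p2)
  expect_true(all(haplogroup_path_variants(tree, "F1a1") %in% p1$label))
  expect_identical(nrow(generate_profile(tree, "rCRS", 0L, 1L)), 0L)
  expect_error(generate_profile(tree, "Q99", 0L, 1L), "unknown haplogroup")
  # private variants never collide with defining variants anywhere in tree
  defining <- unique(unlist(tree$variants))
  private <- setdiff(p1$label, haplogroup_path_variants(tree, "F1a1"))
  expect_length(private, 5L)
  def_pos <- parse_variant_label(defining)$position
  expect_false(any(parse_variant_label(private)$position %in% def_pos))
})
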