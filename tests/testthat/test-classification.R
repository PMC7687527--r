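test_that("structural annotation reports pairing context and disruption", {
  model <- test_model()
  ann <- annotate_structure(mt_variant(15927, "G", "A"), model)
  expect_identical(ann$trnadb_pos, 42L)
  expect_identical(ann$element, "anticodon stem")
  expect_identical(ann$wc_partner, 28L)
  expect_true(ann$wc_disrupted)  # A opposite C abolishes the C-G pair
  expect_identical(ann$wc_pair, "C-G")

  ann2 <- annotate_structure(mt_variant(15931, "A", "C"), model)
  expect_identical(ann2$trnadb_pos, 46L)
  expect_identical(ann2$element, "variable loop")
  expect_true(is.na(ann2$wc_partner))
  expect_false(ann2$wc_disrupted)

  # DHU-stem 12A-23U pair: U>C at 23 leaves C opposite A, no pair
  ann3 <- annotate_structure(mt_variant(15908, "T", "C"), model)
  expect_identical(ann3$wc_partner, 12L)
  expect_true(ann3$wc_disrupted)
  expect_identical(ann3$wc_pair, "U-A")

  # T-stem 51A-63U pair: U>C leaves C opposite A
  ann4 <- annotate_structure(mt_variant(15943, "T", "C"), model)
  expect_identical(ann4$wc_partner, 51L)
  expect_true(ann4$wc_disrupted)

  # deletions at paired positions always disrupt
  del <- mt_variant(15943, "T", "Del")
  expect_true(annotate_structure(del, model)$wc_disrupted)
  expect_error(annotate_structure(mt_variant(200, "A", "G"), model),
               "outside")
})

test_that("default rules reproduce the published three-way grouping", {
  fx <- classified_fixture()
  classified <- fx$classified
  expect_identical(unname(attr(classified, "class_counts")),
                   c(2L, 9L, 4L))
  expected <- c(
    "m.15927G>A" = "known", "m.15951A>G" = "known",
    "m.15900T>C" = "putative", "m.15901A>G" = "putative",
    "m.15908T>C" = "putative", "m.15924A>G" = "putative",
    "m.15928G>A" = "putative", "m.15931A>C" = "putative",
    "m.15940DelT" = "putative", "m.15943T>C" = "putative",
    "m.15949G>A" = "putative",
    "m.15907A>G" = "polymorphism", "m.15930G>A" = "polymorphism",
    "m.15938C>T" = "polymorphism", "m.15941T>C" = "polymorphism")
  got <- setNames(classified$class, classified$label)
  expect_identical(got[names(expected)], expected)
})

test_that("classification is pure and its trace records every test", {
  catalog <- test_catalog()
  ann <- list(label = "m.15924A>G", vtype = "substitution",
              ci_percent = 90.91, control_count = 3, control_freq = 0.80)
  r1 <- classify_variant(ann, catalog, rule_config())
  r2 <- classify_variant(ann, catalog, rule_config())
  expect_identical(r1, r2)
  expect_identical(r1$label, "putative")
  expect_gt(length(r1$rule_trace), 1L)

  # deletion rescue is the only route for a low-CI absent deletion
  del <- list(label = "m.15940DelT", vtype = "deletion", ci_percent = 22.73,
              control_count = 0, control_freq = 0)
  expect_identical(classify_variant(del, catalog, rule_config())$label,
                   "putative")
  no_rescue <- rule_config(deletion_rescue = FALSE)
  expect_identical(classify_variant(del, catalog, no_rescue)$label,
                   "polymorphism")
})

test_that("strict-absence preset demands complete absence from controls", {
  catalog <- test_catalog()
  rules <- rule_config(preset = "strict_absence")
  conserved_rare <- list(label = "m.15900T>C", vtype = "substitution",
                         ci_percent = 72.73, control_count = 1,
                         control_freq = 0.27)
  expect_identical(classify_variant(conserved_rare, catalog, rules)$label,
                   "polymorphism")
  conserved_absent <- list(label = "m.15901A>G", vtype = "substitution",
                           ci_percent = 100, control_count = 0,
                           control_freq = 0)
  expect_identical(classify_variant(conserved_absent, catalog, rules)$label,
                   "putative")
})

test_that("raising the CI threshold never promotes a polymorphism", {
  fx <- classified_fixture()
  catalog <- test_catalog()
  previous_putative <- NULL
  for (thr in c(0, 20, 40, 60, 70, 80, 90, 100)) {
    cls <- classify_table(fx$classified, catalog,
                          rule_config(ci_threshold = thr))
    putative <- sort(cls$label[cls$class == "putative"])
    if (!is.null(previous_putative)) {
      expect_true(all(putative %in% previous_putative),
                  label = paste("threshold", thr))
    }
    previous_putative <- putative
  }
})

test_that("classify_table handles degenerate inputs", {
  fx <- classified_fixture()
  catalog <- test_catalog()
  empty <- classify_table(fx$classified[0, ], catalog, rule_config())
  expect_identical(unname(attr(empty, "class_counts")), c(0L, 0L, 0L))
  only_known <- fx$classified[fx$classified$label %in%
                                c("m.15927G>A", "m.15951A>G"), ]
  res <- classify_table(only_known, catalog, rule_config())
  expect_true(all(res$class == "known"))
})
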