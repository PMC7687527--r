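test_that("shipped gene model pins every curated tRNAdb anchor", {
  model <- test_model()
  anchors <- c("15900" = 13, "15901" = 14, "15907" = 22, "15908" = 23,
               "15924" = 39, "15927" = 42, "15928" = 43, "15930" = 45,
               "15931" = 46, "15938" = 54, "15940" = 56, "15941" = 61,
               "15943" = 63, "15949" = 69, "15951" = 71)
  for (coord in names(anchors)) {
    expect_identical(trnadb_position(model, as.integer(coord)),
                     as.integer(anchors[[coord]]),
                     label = paste("anchor", coord))
  }
})

test_that("structural element labels match the curated cloverleaf annotation", {
  model <- test_model()
  facts <- variant_site_facts()
  for (i in seq_len(nrow(facts))) {
    expect_identical(unname(model$element_map[[as.character(facts$trnadb_pos[i])]]),
                     facts$element[i],
                     label = paste("element at site", facts$trnadb_pos[i]))
  }
})

test_that("position map is strictly monotone and invertible", {
  model <- test_model()
  sites <- unname(model$position_map)
  expect_true(all(diff(sites) > 0))
  expect_identical(anyDuplicated(sites), 0L)
  # round trip coordinate -> site -> coordinate
  coords <- as.integer(names(model$position_map))
  back <- unname(model$site_map[as.character(sites)])
  expect_identical(back, coords)
})

test_that("pairing partners follow the stem model and are symmetric", {
  model <- test_model()
  expect_identical(pairing_partner(model, 23), 12L)
  expect_identical(pairing_partner(model, 39), 31L)
  expect_true(is.na(pairing_partner(model, 46)))  # variable loop
  expect_true(is.na(pairing_partner(model, 61)))  # printed without a WC pair
  for (i in seq_len(nrow(model$pairs))) {
    p <- model$pairs[i, 1]
    q <- model$pairs[i, 2]
    expect_identical(pairing_partner(model, p), unname(q))
    expect_identical(pairing_partner(model, q), unname(p))
  }
  expect_error(pairing_partner(model, 99), "unknown tRNAdb position")
})

test_that("every paired position carries a stem label", {
  model <- test_model()
  for (site in as.vector(model$pairs)) {
    expect_match(model$element_map[[as.character(site)]], "stem",
                 label = paste("element at paired site", site))
  }
})

test_that("reference segment matches the documented alleles and pair bases", {
  model <- test_model()
  expect_identical(nchar(model$sequence), 66L)
  refs <- c("15900" = "T", "15901" = "A", "15907" = "A", "15908" = "T",
            "15924" = "A", "15927" = "G", "15928" = "G", "15930" = "G",
            "15931" = "A", "15938" = "C", "15940" = "T", "15941" = "T",
            "15943" = "T", "15949" = "G", "15951" = "A")
  for (coord in names(refs)) {
    expect_identical(ref_base(model, as.integer(coord)), unname(refs[coord]))
  }
  # every shipped pair is Watson-Crick in the reference
  for (i in seq_len(nrow(model$pairs))) {
    b1 <- ref_base(model, model$site_map[[as.character(model$pairs[i, 1])]])
    b2 <- ref_base(model, model$site_map[[as.character(model$pairs[i, 2])]])
    expect_true(paste0(b1, b2) %in% c("AT", "TA", "GC", "CG"),
                label = paste("pair", model$pairs[i, 1], "-",
                              model$pairs[i, 2]))
  }
})

test_that("malformed gene-model configurations are rejected", {
  cfg <- yaml::read_yaml(system.file("extdata", "mt_tt_gene_model.yaml",
                                     package = "mttscreen"))
  write_cfg <- function(cfg) {
    path <- withr::local_tempfile(fileext = ".yaml",
                                  .local_envir = parent.frame())
    yaml::write_yaml(cfg, path)
    path
  }
  bad <- cfg
  bad$anchors <- list("15900" = 13, "15901" = 12)
  expect_error(load_gene_model(write_cfg(bad)), "non-monotone")
  bad <- cfg
  bad$anchors <- NULL
  expect_error(load_gene_model(write_cfg(bad)), "anchors")
  bad <- cfg
  bad$sequence <- substr(cfg$sequence, 1, 10)
  expect_error(load_gene_model(write_cfg(bad)), "length")
  expect_error(suppressWarnings(load_gene_model(tempfile())), "malformed")
})

test_that("known-mutation catalog contains the expected screening sets", {
  catalog <- test_catalog()
  known <- catalog$label[catalog$category == "known_MT_TT"]
  expect_setequal(known, c("m.15927G>A", "m.15951A>G"))
  expect_identical(sum(catalog$category == "primary"), 21L)
  primaries <- catalog$label[catalog$category == "primary"]
  expect_true(all(c("m.3460G>A", "m.11778G>A", "m.14484T>C") %in% primaries))
})
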