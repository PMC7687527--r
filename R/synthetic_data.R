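#' Cohort simulation specification
#'
#' Describes a case-control cohort with variants implanted at exactly
#' specified carrier counts. Carriers are assigned, not sampled, so the
#' generated cohort reproduces the specified per-variant counts with no
#' sampling noise; by default each carrier receives exactly one variant
#' (disjoint carriers).
#'
#' @param n_cases,n_controls Arm sizes.
#' @param implants data.frame with columns `label`, `position`, `ref`,
#'   `alt`, `vtype`, `case_carriers`, `control_carriers`.
#' @param seed Integer seed controlling the shuffle that assigns carriers
#'   to subject identifiers.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, implants, seed = 1L) {
  needed <- c("label", "position", "ref", "alt", "vtype",
              "case_carriers", "control_carriers")
  if (!all(needed %in% names(implants))) {
    stop("implants must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (sum(implants$case_carriers) > n_cases ||
      sum(implants$control_carriers) > n_controls) {
    stop("total carrier counts exceed arm size", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 implants = implants, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The shipped LHON study cohort specification
#'
#' The study conditions emulated by the simulator: 352 case probands and
#' 376 controls, with the 15 observed MT-TT variants implanted at their
#' observed per-arm carrier counts (41 case carriers and 23 control
#' carriers in total, one variant per carrier).
#'
#' @param seed Integer seed passed through to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
lhon_cohort_spec <- function(seed = 1L) {
  implants <- read.delim(ref_file("cohort_implants.tsv"),
                         stringsAsFactors = FALSE)
  cohort_spec(n_cases = 352L, n_controls = 376L, implants = implants,
              seed = seed)
}

assign_carriers <- function(n, counts, labels, prefix) {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  order_ids <- sample(ids)  # seeded by the caller
  assigned <- data.frame(subject_id = character(0), label = character(0),
                         stringsAsFactors = FALSE)
  cursor <- 1L
  for (i in seq_along(counts)) {
    k <- counts[i]
    if (k > 0L) {
      assigned <- rbind(assigned, data.frame(
        subject_id = order_ids[cursor:(cursor + k - 1L)],
        label = rep(labels[i], k), stringsAsFactors = FALSE))
      cursor <- cursor + k
    }
  }
  assigned
}

#' Generate a synthetic case-control cohort over the tRNA gene segment
#'
#' Every carrier's sequence differs from the reference by exactly its
#' implanted variant; non-carriers are identical to the reference segment.
#' Deterministic for a fixed spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param model A [load_gene_model()] gene model supplying the reference
#'   segment.
#' @return List with elements `cases` and `controls`
#'   ([Biostrings::DNAStringSet] of per-subject consensus sequences) and
#'   `truth` (data.frame `subject_id`, `arm`, `variant` with one row per
#'   subject; `variant` is `""` for non-carriers).
#' @export
generate_cohort <- function(spec, model) {
  stopifnot(inherits(spec, "cohort_spec"))
  implants <- spec$implants
  # Validate implants against the reference before assigning anyone.
  for (i in seq_len(nrow(implants))) {
    rb <- ref_base(model, implants$position[i])
    if (rb != implants$ref[i]) {
      stop("implant ", implants$label[i], ": reference allele at position ",
           implants$position[i], " is ", rb, ", not ", implants$ref[i],
           call. = FALSE)
    }
  }
  set.seed(spec$seed)
  case_carriers <- assign_carriers(spec$n_cases, implants$case_carriers,
                                   implants$label, "case")
  ctrl_carriers <- assign_carriers(spec$n_controls, implants$control_carriers,
                                   implants$label, "ctrl")

  build_arm <- function(n, prefix, carriers) {
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    seqs <- rep(model$sequence, n)
    truth <- data.frame(subject_id = ids,
                        arm = ifelse(prefix == "case", "case", "control"),
                        variant = "", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(carriers))) {
      j <- match(carriers$subject_id[i], ids)
      v <- implants[implants$label == carriers$label[i], , drop = FALSE]
      seqs[j] <- apply_variants(model$sequence, model$start, v)
      truth$variant[j] <- carriers$label[i]
    }
    list(seqs = Biostrings::DNAStringSet(setNames(seqs, ids)), truth = truth)
  }
  cases <- build_arm(spec$n_cases, "case", case_carriers)
  controls <- build_arm(spec$n_controls, "ctrl", ctrl_carriers)
  list(cases = cases$seqs, controls = controls$seqs,
       truth = rbind(cases$truth, controls$truth))
}

#' Write a generated cohort to FASTA and a truth table to TSV
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`cases.fa`, `controls.fa`,
#'   `truth.tsv`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cases.fa", "controls.fa", "truth.tsv"))
  Biostrings::writeXStringSet(cohort$cases, paths[1L])
  Biostrings::writeXStringSet(cohort$controls, paths[2L])
  utils::write.table(cohort$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Multi-species alignment simulation specification
#'
#' Describes a gapless multi-species alignment of the tRNA gene with an
#' exactly specified number of species matching the human base at selected
#' tRNAdb positions (the human row always matches itself). Unspecified
#' positions are fully conserved.
#'
#' @param n_species Number of rows including the human sequence.
#' @param match_counts data.frame with columns `trnadb_pos` and `n_match`
#'   (species matching the human base, human included).
#' @param seed Integer seed.
#' @return An object of class `alignment_spec`.
#' @export
alignment_spec <- function(n_species = 44L, match_counts = NULL, seed = 1L) {
  if (is.null(match_counts)) {
    match_counts <- data.frame(trnadb_pos = integer(0), n_match = integer(0))
  }
  if (any(match_counts$n_match < 1L) ||
      any(match_counts$n_match > n_species)) {
    stop("match counts must lie in 1..n_species (the human row always ",
         "matches itself)", call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 match_counts = match_counts, seed = as.integer(seed)),
            class = "alignment_spec")
}

#' The shipped cross-species conservation specification
#'
#' A 44-vertebrate alignment spec whose per-position match counts
#' reproduce the conservation indexes observed at the 15 annotated MT-TT
#' variant sites.
#'
#' @param seed Integer seed passed through to [alignment_spec()].
#' @return An `alignment_spec`.
#' @export
lhon_alignment_spec <- function(seed = 1L) {
  counts <- read.delim(ref_file("conservation_counts.tsv"),
                       stringsAsFactors = FALSE)
  alignment_spec(n_species = 44L, match_counts = counts, seed = seed)
}

#' Generate a synthetic multi-species alignment of the gene segment
#'
#' @param spec An [alignment_spec()].
#' @param model Gene model supplying the human (reference) row and the
#'   tRNAdb position map.
#' @return A [Biostrings::DNAStringSet] of `n_species` equal-length rows;
#'   the first row (`Homo_sapiens`) is the reference segment.
#' @export
generate_alignment <- function(spec, model) {
  stopifnot(inherits(spec, "alignment_spec"))
  n <- spec$n_species
  width <- nchar(model$sequence)
  human <- strsplit(model$sequence, "")[[1L]]
  mat <- matrix(rep(human, each = n), nrow = n)
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(spec$match_counts))) {
    site <- spec$match_counts$trnadb_pos[i]
    k <- spec$match_counts$n_match[i]
    key <- as.character(site)
    if (!key %in% names(model$site_map)) {
      stop("tRNAdb position ", site, " does not map into the gene",
           call. = FALSE)
    }
    col <- model$site_map[[key]] - model$start + 1L
    n_mismatch <- n - k
    if (n_mismatch > 0L) {
      rows <- sample(2:n, n_mismatch)
      mat[rows, col] <- sample(setdiff(bases, human[col]), n_mismatch,
                               replace = TRUE)
    }
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- c("Homo_sapiens",
                   sprintf("species_%02d", seq_len(n - 1L) + 1L))
  Biostrings::DNAStringSet(rows)
}

#' Generate a full-mtDNA variant profile for a haplogroup
#'
#' The profile is the union of the defining variants on the root-to-node
#' path plus `n_private` random variants at positions that collide with no
#' defining variant anywhere in the tree (collisions are redrawn), so
#' haplogroup assignment on the output recovers the input lineage.
#'
#' @param tree A [load_haplogroup_tree()] tree.
#' @param haplogroup Node name present in the tree.
#' @param n_private Number of private (non-defining) variants to add.
#' @param seed Integer seed.
#' @return data.frame with columns `label`, `position`, `ref`, `alt`,
#'   `vtype`, sorted by position.
#' @export
generate_profile <- function(tree, haplogroup, n_private = 0L, seed = 1L) {
  path <- haplogroup_path_variants(tree, haplogroup)
  profile <- parse_variant_label(path)
  set.seed(seed)
  reserved <- unique(stats::na.omit(
    parse_variant_label(all_defining_variants(tree))$position))
  bases <- c("A", "C", "G", "T")
  taken <- profile$position
  n_added <- 0L
  while (n_added < n_private) {
    pos <- sample.int(16569L, 1L)
    if (pos %in% reserved || pos %in% taken) next
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    profile <- rbind(profile, mt_variant(pos, ref, alt))
    taken <- c(taken, pos)
    n_added <- n_added + 1L
  }
  profile[order(profile$position), , drop = FALSE]
}
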