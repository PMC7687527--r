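#' Call variants in a consensus sequence against the reference segment
#'
#' Performs an exact global (Needleman-Wunsch) comparison of a subject's
#' consensus sequence with the reference gene segment and returns the
#' minimal set of substitutions and single-base deletions. Deletions
#' inside homopolymer runs are coordinate-ambiguous; they are normalized
#' to the 5'-most position of the run on the forward rCRS strand by
#' default (the convention under which the observed T-loop deletion in
#' the rCRS T-run 15940-15944 is written m.15940DelT), configurable to
#' 3'-most.
#'
#' @param subject_seq Consensus sequence over the gene segment (character
#'   or [Biostrings::DNAString]); ACGT only, IUPAC ambiguity codes are
#'   rejected.
#' @param model Gene model providing the reference segment and its rCRS
#'   coordinates.
#' @param normalize Homopolymer deletion normalization: `"5prime"`
#'   (default) or `"3prime"`.
#' @param subject_id Optional identifier used in error messages.
#' @return data.frame with columns `label`, `position`, `ref`, `alt`,
#'   `vtype`, sorted by position (zero rows for a reference-identical
#'   sequence).
#' @examples
#' model <- load_gene_model()
#' mutant <- apply_variants(model$sequence, model$start,
#'                          mt_variant(15927, "G", "A"))
#' call_variants(mutant, model)$label  # "m.15927G>A"
#' @export
call_variants <- function(subject_seq, model,
                          normalize = c("5prime", "3prime"),
                          subject_id = "subject") {
  normalize <- match.arg(normalize)
  subject_seq <- toupper(as.character(subject_seq))
  if (grepl("[^ACGT]", subject_seq)) {
    stop(subject_id, ": sequence contains non-ACGT characters ",
         "(ambiguity codes are not interpreted)", call. = FALSE)
  }
  ref <- model$sequence
  ldiff <- nchar(ref) - nchar(subject_seq)
  if (abs(ldiff) > 3L) {
    stop(subject_id, ": length differs from the reference by ", abs(ldiff),
         " (more than 3)", call. = FALSE)
  }
  if (ldiff < 0L) {
    stop(subject_id, ": sequence is longer than the reference; insertions ",
         "are not supported", call. = FALSE)
  }

  empty <- data.frame(label = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), stringsAsFactors = FALSE)
  if (subject_seq == ref) return(empty)

  if (ldiff == 0L) {
    rc <- strsplit(ref, "")[[1L]]
    sc <- strsplit(subject_seq, "")[[1L]]
    idx <- which(rc != sc)
    calls <- mt_variant(model$start + idx - 1L, rc[idx], sc[idx])
  } else {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(subject_seq),
      subject = Biostrings::DNAString(ref),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 4, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    refa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    if (any(refa == "-")) {
      stop(subject_id, ": unresolvable alignment (insertion relative to ",
           "the reference)", call. = FALSE)
    }
    coord <- model$start + seq_along(refa) - 1L
    dele <- pat == "-"
    mism <- !dele & pat != refa
    calls <- empty
    if (any(mism)) {
      calls <- rbind(calls, mt_variant(coord[mism], refa[mism], pat[mism]))
    }
    if (any(dele)) {
      del_pos <- normalize_deletions(ref, model$start, coord[dele], normalize)
      calls <- rbind(calls, mt_variant(del_pos,
                                       substring(ref, del_pos - model$start + 1L,
                                                 del_pos - model$start + 1L),
                                       "Del"))
    }
  }
  calls <- calls[order(calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  if (anyDuplicated(calls$position)) {
    stop(subject_id, ": unresolvable alignment (duplicate positions)",
         call. = FALSE)
  }
  calls
}

# Shift each deleted coordinate to the 5'- or 3'-most position of the
# homopolymer run containing it; multiple deletions in one run take
# consecutive coordinates from the run end chosen.
normalize_deletions <- function(ref, start, del_coords, normalize) {
  rc <- strsplit(ref, "")[[1L]]
  out <- integer(0)
  for (pos in sort(del_coords)) {
    i <- pos - start + 1L
    b <- rc[i]
    lo <- i
    while (lo > 1L && rc[lo - 1L] == b) lo <- lo - 1L
    hi <- i
    while (hi < length(rc) && rc[hi + 1L] == b) hi <- hi + 1L
    run <- (start + lo - 1L):(start + hi - 1L)
    cand <- if (normalize == "5prime") run else rev(run)
    out <- c(out, cand[!(cand %in% out)][1L])
  }
  sort(out)
}

#' Call variants for every subject of a generated or loaded cohort
#'
#' @param cohort Either the result of [generate_cohort()] or a list with
#'   elements `cases` and `controls` ([Biostrings::DNAStringSet], e.g.
#'   read with [Biostrings::readDNAStringSet()]).
#' @inheritParams call_variants
#' @return data.frame with columns `subject_id`, `arm`, `label`,
#'   `position`, `ref`, `alt`, `vtype`; one row per called variant.
#' @export
call_cohort <- function(cohort, model, normalize = c("5prime", "3prime")) {
  normalize <- match.arg(normalize)
  one_arm <- function(seqs, arm) {
    ids <- names(seqs)
    chr <- as.character(seqs)
    out <- vector("list", length(chr))
    for (i in seq_along(chr)) {
      if (chr[i] == model$sequence) next  # reference-identical: no calls
      calls <- call_variants(chr[i], model, normalize, subject_id = ids[i])
      if (nrow(calls) > 0L) {
        out[[i]] <- cbind(data.frame(subject_id = ids[i], arm = arm,
                                     stringsAsFactors = FALSE), calls)
      }
    }
    do.call(rbind, out)
  }
  res <- rbind(one_arm(cohort$cases, "case"),
               one_arm(cohort$controls, "control"))
  if (is.null(res)) {
    res <- data.frame(subject_id = character(0), arm = character(0),
                      label = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Screen a full-mtDNA variant profile against the known-mutation catalog
#'
#' @param profile data.frame with a `label` column (or columns `position`,
#'   `ref`, `alt` from which labels are derived).
#' @param catalog Catalog from [load_known_mutations()].
#' @return data.frame of matched catalog entries (`gene`, `label`,
#'   `aa_change`, `category`); zero rows when nothing matches.
#' @export
screen_known <- function(profile, catalog = load_known_mutations()) {
  if (!"label" %in% names(profile)) {
    profile$label <- variant_label(profile$position, profile$ref,
                                   profile$alt)
  }
  catalog[catalog$label %in% profile$label, , drop = FALSE]
}
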