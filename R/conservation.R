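#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up (0.125 -> 0.13 at two
#' digits), matching how percentages are conventionally rendered in
#' variant tables; base R's `round()` rounds ties to even.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAStringSet") ||
      inherits(alignment, "XStringSet")) {
    rows <- as.character(alignment)
  } else {
    rows <- as.character(alignment)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment has ragged rows (widths ",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  do.call(rbind, strsplit(toupper(rows), ""))
}

#' Conservation index of a tRNA position
#'
#' The conservation index (CI) of a site is the percentage of species in a
#' multi-species alignment whose base matches the human base, the human
#' row included. By convention the first alignment row is the human
#' sequence.
#'
#' @param alignment Aligned sequences ([Biostrings::DNAStringSet] or
#'   character vector), equal-length rows, human row first.
#' @param model Gene model mapping tRNAdb positions to alignment columns
#'   (column = rCRS coordinate - segment start + 1).
#' @param trnadb_pos tRNAdb position to score.
#' @param gaps `"mismatch"` (default) counts gapped rows as non-matching;
#'   `"exclude"` drops them from the denominator.
#' @return CI as a percentage rounded half-up to two decimals.
#' @examples
#' model <- load_gene_model()
#' aln <- generate_alignment(lhon_alignment_spec(seed = 1), model)
#' conservation_index(aln, model, 39)  # 90.91
#' @export
conservation_index <- function(alignment, model, trnadb_pos,
                               gaps = c("mismatch", "exclude")) {
  gaps <- match.arg(gaps)
  key <- as.character(as.integer(trnadb_pos))
  if (!key %in% names(model$site_map)) {
    stop("tRNAdb position ", trnadb_pos, " does not map into the ",
         model$gene, " gene", call. = FALSE)
  }
  mat <- as_alignment_matrix(alignment)
  col <- mat[, model$site_map[[key]] - model$start + 1L]
  human <- col[1L]
  if (gaps == "exclude") col <- col[col != "-"]
  round_half_up(100 * sum(col == human) / length(col), 2L)
}

#' Per-position conservation profile of the whole gene
#'
#' @inheritParams conservation_index
#' @return data.frame with one row per tRNAdb position in the gene:
#'   `trnadb_pos`, `position` (rCRS), `n_total`, `n_match`, `ci_percent`.
#' @export
conservation_profile <- function(alignment, model,
                                 gaps = c("mismatch", "exclude")) {
  gaps <- match.arg(gaps)
  mat <- as_alignment_matrix(alignment)
  sites <- unname(model$position_map)
  coords <- as.integer(names(model$position_map))
  out <- data.frame(trnadb_pos = sites, position = coords,
                    n_total = NA_integer_, n_match = NA_integer_,
                    ci_percent = NA_real_)
  for (i in seq_along(sites)) {
    col <- mat[, coords[i] - model$start + 1L]
    human <- col[1L]
    if (gaps == "exclude") col <- col[col != "-"]
    out$n_total[i] <- length(col)
    out$n_match[i] <- sum(col == human)
    out$ci_percent[i] <- round_half_up(100 * out$n_match[i] / out$n_total[i],
                                       2L)
  }
  out
}

#' Conservation threshold flag
#'
#' Inclusive comparison: a site is flagged as conserved when its CI
#' reaches the threshold (default 70 percent).
#'
#' @param ci_percent CI value(s).
#' @param threshold Threshold in percent.
#' @return Logical vector.
#' @export
ci_threshold_flag <- function(ci_percent, threshold = 70) {
  ci_percent >= threshold
}
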