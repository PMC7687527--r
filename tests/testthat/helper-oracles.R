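# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: string edits are enumerated by brute force and
# the chi-square tail comes from the regularized incomplete gamma function.

# All sequences reachable from `ref` by exactly one substitution, with the
# edit that produced them.
enumerate_substitutions <- function(ref, start) {
  chars <- strsplit(ref, "")[[1L]]
  out <- list()
  for (i in seq_along(chars)) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[i])) {
      mutant <- chars
      mutant[i] <- alt
      out[[length(out) + 1L]] <- list(
        seq = paste(mutant, collapse = ""),
        position = start + i - 1L, ref = chars[i], alt = alt)
    }
  }
  out
}

# For a sequence one base shorter than `ref`, every deletion coordinate
# that explains it exactly (homopolymer runs give several).
explaining_deletions <- function(ref, start, subject) {
  chars <- strsplit(ref, "")[[1L]]
  hits <- integer(0)
  for (i in seq_along(chars)) {
    if (paste(chars[-i], collapse = "") == subject) {
      hits <- c(hits, start + i - 1L)
    }
  }
  hits
}

# Upper-tail probability of chi-square with 1 df via the regularized
# upper incomplete gamma function Q(1/2, x/2).
chisq_upper_tail_oracle <- function(x) {
  pracma::gammainc(x / 2, 1 / 2)[["uppinc"]] / gamma(1 / 2)
}

# Pearson statistic recomputed through stats::chisq.test.
chisq_stat_oracle <- function(a, b, c, d) {
  unname(suppressWarnings(
    stats::chisq.test(rbind(c(a, b), c(c, d)), correct = FALSE))$statistic)
}
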