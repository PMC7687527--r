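#' Carrier frequency as a printed percentage
#'
#' @param count Carrier count(s).
#' @param total Arm size.
#' @return `100 * count / total` rounded half-up to two decimals.
#' @export
variant_frequency <- function(count, total) {
  if (any(total <= 0)) stop("arm size must be positive", call. = FALSE)
  round_half_up(100 * count / total, 2L)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Computes the uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on the table
#' `rbind(c(a, b), c(c, d))` and the two-sided p-value as the upper tail
#' of the chi-square distribution with one degree of freedom. The Yates
#' continuity correction is available but off by default.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d).
#' @param correct Apply the Yates continuity correction?
#' @return List with `chi2`, `df` (always 1) and `p_value`.
#' @examples
#' chi_square_2x2(41, 311, 23, 353)  # p ~ 0.0085
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("zero row or column margin: chi-square is undefined",
         call. = FALSE)
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  chi2 <- n * dev^2 / prod(margins)
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Aggregate cohort report
#'
#' Summarizes a cohort call set: distinct variants and carrier counts per
#' arm, variant-free subject counts, the combined carrier frequency of the
#' known disease-associated mutations, and the Pearson chi-square
#' comparison of carrier prevalence between arms.
#'
#' @param calls Cohort calls from [call_cohort()].
#' @param n_cases,n_controls Arm sizes.
#' @param classified Optional classified table from [classify_table()];
#'   when given, per-class carrier counts and frequencies are included.
#' @param correct Passed to [chi_square_2x2()].
#' @return List with components `n_cases`, `n_controls`,
#'   `case_variants`, `control_variants` (distinct variant counts),
#'   `case_carriers`, `control_carriers`, `variant_free_cases`,
#'   `variant_free_controls`, `chi2`, `p_value`, and (with `classified`)
#'   `known_case_carriers`, `known_case_freq`, `putative_case_carriers`,
#'   `putative_case_freq`.
#' @export
aggregate_report <- function(calls, n_cases, n_controls, classified = NULL,
                             correct = FALSE) {
  case_calls <- calls[calls$arm == "case", , drop = FALSE]
  ctrl_calls <- calls[calls$arm == "control", , drop = FALSE]
  case_carriers <- length(unique(case_calls$subject_id))
  ctrl_carriers <- length(unique(ctrl_calls$subject_id))
  report <- list(
    n_cases = n_cases, n_controls = n_controls,
    case_variants = length(unique(case_calls$label)),
    control_variants = length(unique(ctrl_calls$label)),
    case_carriers = case_carriers,
    control_carriers = ctrl_carriers,
    variant_free_cases = n_cases - case_carriers,
    variant_free_controls = n_controls - ctrl_carriers)
  if (case_carriers + ctrl_carriers > 0 &&
      case_carriers < n_cases + n_controls) {
    test <- chi_square_2x2(case_carriers, n_cases - case_carriers,
                           ctrl_carriers, n_controls - ctrl_carriers,
                           correct = correct)
    report$chi2 <- test$chi2
    report$p_value <- test$p_value
  } else {
    report$chi2 <- NA_real_
    report$p_value <- NA_real_
  }
  if (!is.null(classified)) {
    for (cl in c("known", "putative")) {
      labels <- classified$label[classified$class == cl]
      carriers <- length(unique(
        case_calls$subject_id[case_calls$label %in% labels]))
      report[[paste0(cl, "_case_carriers")]] <- carriers
      report[[paste0(cl, "_case_freq")]] <- variant_frequency(carriers,
                                                              n_cases)
    }
  }
  report
}
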