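#' Structural annotation of a tRNA gene variant
#'
#' Maps the variant onto the tRNA cloverleaf: its tRNAdb position, the
#' structural element, the Watson-Crick pairing partner (if the position
#' sits in a stem) and whether the change disrupts the pair. A
#' substitution disrupts the pair when the new base no longer forms A-U or
#' G-C with the partner's reference base; a deletion at a paired position
#' always disrupts it.
#'
#' @param variant One-row data.frame from [mt_variant()] (columns
#'   `position`, `ref`, `alt`, `vtype`).
#' @param model Gene model.
#' @return List with `trnadb_pos`, `element`, `wc_partner` (integer or
#'   `NA`), `wc_disrupted` (logical) and `wc_pair` (display string such as
#'   `"C-G"` in RNA alphabet, `NA` for unpaired positions).
#' @examples
#' model <- load_gene_model()
#' annotate_structure(mt_variant(15927, "G", "A"), model)
#' @export
annotate_structure <- function(variant, model) {
  site <- trnadb_position(model, variant$position)
  element <- unname(model$element_map[[as.character(site)]])
  partner <- pairing_partner(model, site)
  if (is.na(partner)) {
    return(list(trnadb_pos = site, element = element,
                wc_partner = NA_integer_, wc_disrupted = FALSE,
                wc_pair = NA_character_))
  }
  partner_base <- ref_base(model, model$site_map[[as.character(partner)]])
  disrupted <- if (variant$vtype == "deletion") {
    TRUE
  } else {
    !is_wc_pair(variant$alt, partner_base)
  }
  # display convention: pyrimidine first ("U-A", "C-G"), RNA alphabet
  rna <- function(b) sub("T", "U", b)
  pp <- c(rna(variant$ref), rna(partner_base))
  pair_lab <- paste(pp[order(!pp %in% c("C", "U"), pp)], collapse = "-")
  list(trnadb_pos = site, element = element, wc_partner = partner,
       wc_disrupted = disrupted, wc_pair = pair_lab)
}

is_wc_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG")
}

#' Classification rule configuration
#'
#' Two presets are available. `"default"` reproduces the published
#' variant table: a non-catalog variant is putative when it is highly
#' conserved (CI at or above `ci_threshold`) or is a deletion, and its
#' control carrier frequency does not exceed `control_freq_cap`.
#' `"strict_absence"` is the stricter prose rule (CI strictly above the
#' threshold and complete absence from controls).
#'
#' @param preset `"default"` or `"strict_absence"`.
#' @param ci_threshold Conservation threshold in percent.
#' @param control_freq_cap Maximum control carrier frequency in percent
#'   for a putative call (default rule only).
#' @param deletion_rescue Should deletions qualify as structure-disrupting
#'   regardless of CI (default rule only)?
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(preset = c("default", "strict_absence"),
                        ci_threshold = 70, control_freq_cap = 1,
                        deletion_rescue = TRUE) {
  preset <- match.arg(preset)
  structure(list(preset = preset, ci_threshold = ci_threshold,
                 control_freq_cap = control_freq_cap,
                 deletion_rescue = deletion_rescue),
            class = "rule_config")
}

#' Classify one annotated variant
#'
#' Assigns `known` (present in the known disease-associated tRNA-Thr
#' catalog), `putative` or `polymorphism` according to the rule
#' configuration, and records every test fired.
#'
#' @param annotation List or one-row data.frame with at least `label`,
#'   `vtype`, `ci_percent`, `control_count` and `control_freq` (percent).
#' @param catalog Catalog from [load_known_mutations()].
#' @param rules A [rule_config()].
#' @return List with `label` (the class) and `rule_trace` (character
#'   vector of fired criteria).
#' @export
classify_variant <- function(annotation, catalog = load_known_mutations(),
                             rules = rule_config()) {
  known_set <- catalog$label[catalog$category == "known_MT_TT"]
  trace <- character(0)
  in_catalog <- annotation$label %in% known_set
  trace <- c(trace, paste0("known_catalog=", in_catalog))
  if (in_catalog) {
    return(list(label = "known", rule_trace = trace))
  }
  ci <- annotation$ci_percent
  if (rules$preset == "strict_absence") {
    conserved <- ci > rules$ci_threshold
    absent <- annotation$control_count == 0
    trace <- c(trace, paste0("ci>", rules$ci_threshold, "=", conserved),
               paste0("absent_in_controls=", absent))
    label <- if (conserved && absent) "putative" else "polymorphism"
    return(list(label = label, rule_trace = trace))
  }
  conserved <- ci_threshold_flag(ci, rules$ci_threshold)
  is_del <- identical(annotation$vtype, "deletion")
  rescued <- rules$deletion_rescue && is_del
  rare <- annotation$control_freq <= rules$control_freq_cap
  trace <- c(trace, paste0("ci>=", rules$ci_threshold, "=", conserved),
             paste0("deletion=", rescued),
             paste0("control_freq<=", rules$control_freq_cap, "=", rare))
  label <- if ((conserved || rescued) && rare) "putative" else "polymorphism"
  list(label = label, rule_trace = trace)
}

#' Annotate and tabulate the distinct variants of a cohort call set
#'
#' Builds the per-variant evaluation table: structural context,
#' Watson-Crick effect, conservation index, per-arm carrier counts and
#' frequencies.
#'
#' @param calls Cohort calls from [call_cohort()].
#' @param model Gene model.
#' @param alignment Multi-species alignment for the conservation index.
#' @param n_cases,n_controls Arm sizes (frequency denominators).
#' @return data.frame with one row per distinct variant, sorted by
#'   position: `label`, `position`, `ref`, `alt`, `vtype`, `trnadb_pos`,
#'   `element`, `wc_partner`, `wc_pair`, `wc_disrupted`, `ci_percent`,
#'   `case_count`, `case_freq`, `control_count`, `control_freq`.
#' @export
annotate_variants <- function(calls, model, alignment, n_cases, n_controls) {
  distinct <- unique(calls[, c("label", "position", "ref", "alt", "vtype")])
  distinct <- distinct[order(distinct$position), , drop = FALSE]
  if (nrow(distinct) == 0L) {
    return(data.frame(
      label = character(0), position = integer(0), ref = character(0),
      alt = character(0), vtype = character(0), trnadb_pos = integer(0),
      element = character(0), wc_partner = integer(0),
      wc_pair = character(0), wc_disrupted = logical(0),
      ci_percent = numeric(0), case_count = integer(0),
      case_freq = numeric(0), control_count = integer(0),
      control_freq = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(distinct))
  for (i in seq_len(nrow(distinct))) {
    v <- distinct[i, , drop = FALSE]
    ann <- annotate_structure(v, model)
    case_count <- sum(calls$label == v$label & calls$arm == "case")
    control_count <- sum(calls$label == v$label & calls$arm == "control")
    rows[[i]] <- data.frame(
      v,
      trnadb_pos = ann$trnadb_pos, element = ann$element,
      wc_partner = ann$wc_partner, wc_pair = ann$wc_pair,
      wc_disrupted = ann$wc_disrupted,
      ci_percent = conservation_index(alignment, model, ann$trnadb_pos),
      case_count = case_count,
      case_freq = round_half_up(100 * case_count / n_cases, 2L),
      control_count = control_count,
      control_freq = round_half_up(100 * control_count / n_controls, 2L),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify an annotated variant table
#'
#' @param annotations Table from [annotate_variants()].
#' @param catalog Catalog from [load_known_mutations()].
#' @param rules A [rule_config()].
#' @return The input table with added columns `class` and `rule_trace`
#'   (criteria joined by `"; "`), plus an attribute `class_counts` (named
#'   vector over known/putative/polymorphism).
#' @examples
#' \dontrun{
#' tbl <- classify_table(annotations)
#' attr(tbl, "class_counts")
#' }
#' @export
classify_table <- function(annotations, catalog = load_known_mutations(),
                           rules = rule_config()) {
  cls <- character(nrow(annotations))
  trace <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    res <- classify_variant(annotations[i, , drop = FALSE], catalog, rules)
    cls[i] <- res$label
    trace[i] <- paste(res$rule_trace, collapse = "; ")
  }
  annotations$class <- cls
  annotations$rule_trace <- trace
  counts <- c(known = sum(cls == "known"),
              putative = sum(cls == "putative"),
              polymorphism = sum(cls == "polymorphism"))
  # Present groups in report order: known, putative, polymorphism.
  ord <- order(match(cls, c("known", "putative", "polymorphism")),
               annotations$position)
  annotations <- annotations[ord, , drop = FALSE]
  rownames(annotations) <- NULL
  attr(annotations, "class_counts") <- counts
  annotations
}
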