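#' Canonical label for an mtDNA variant
#'
#' Substitutions render as `m.<pos><ref>><alt>` (e.g. `m.15927G>A`),
#' single-base deletions as `m.<pos>Del<ref>` (e.g. `m.15940DelT`), the
#' notation used throughout the mt-tRNA literature.
#'
#' @param position 1-based rCRS coordinate.
#' @param ref Reference base.
#' @param alt Alternate base, or `"Del"` for a single-base deletion.
#' @return Character label.
#' @export
variant_label <- function(position, ref, alt) {
  ifelse(alt == "Del",
         paste0("m.", position, "Del", ref),
         paste0("m.", position, ref, ">", alt))
}

#' Construct an mtDNA variant record
#'
#' @inheritParams variant_label
#' @return One-row data.frame with columns `label`, `position`, `ref`,
#'   `alt`, `vtype`.
#' @export
mt_variant <- function(position, ref, alt) {
  position <- as.integer(position)
  ref <- toupper(ref)
  alt <- ifelse(toupper(alt) == "DEL", "Del", toupper(alt))
  vtype <- ifelse(alt == "Del", "deletion", "substitution")
  if (any(vtype == "substitution" & ref == alt)) {
    stop("substitution must change the base", call. = FALSE)
  }
  data.frame(label = variant_label(position, ref, alt),
             position = position, ref = ref, alt = alt, vtype = vtype,
             stringsAsFactors = FALSE)
}

#' Parse a variant label back into its fields
#'
#' @param label Labels such as `"m.15927G>A"` or `"m.15940DelT"`.
#' @return data.frame with columns `label`, `position`, `ref`, `alt`,
#'   `vtype`. Labels that match neither form (e.g. multi-base deletions in
#'   haplogroup tree files) are kept with `NA` fields apart from `label`
#'   and `position` where recoverable.
#' @export
parse_variant_label <- function(label) {
  if (length(label) == 0L) {
    return(data.frame(label = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), stringsAsFactors = FALSE))
  }
  sub_m <- regmatches(label, regexec("^m\\.(\\d+)([ACGT])>([ACGT])$", label))
  del_m <- regmatches(label, regexec("^m\\.(\\d+)Del([ACGT])$", label))
  out <- data.frame(label = label, position = NA_integer_,
                    ref = NA_character_, alt = NA_character_,
                    vtype = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(label)) {
    if (length(sub_m[[i]]) == 4L) {
      out$position[i] <- as.integer(sub_m[[i]][2L])
      out$ref[i] <- sub_m[[i]][3L]
      out$alt[i] <- sub_m[[i]][4L]
      out$vtype[i] <- "substitution"
    } else if (length(del_m[[i]]) == 3L) {
      out$position[i] <- as.integer(del_m[[i]][2L])
      out$ref[i] <- del_m[[i]][3L]
      out$alt[i] <- "Del"
      out$vtype[i] <- "deletion"
    } else {
      pos <- regmatches(label[i], regexec("^m\\.(\\d+)", label[i]))[[1L]]
      if (length(pos) == 2L) out$position[i] <- as.integer(pos[2L])
    }
  }
  out
}

#' Apply variants to a reference segment
#'
#' Used by the cohort simulator and by round-trip checks: substitutions
#' replace the reference base, single-base deletions drop it.
#'
#' @param sequence Reference segment (character string, ACGT).
#' @param start rCRS coordinate of the first base of `sequence`.
#' @param variants data.frame with columns `position`, `ref`, `alt`,
#'   `vtype` (as from [mt_variant()]).
#' @return The edited sequence as a character string.
#' @export
apply_variants <- function(sequence, start, variants) {
  chars <- strsplit(sequence, "")[[1L]]
  if (nrow(variants) == 0L) return(sequence)
  idx <- variants$position - start + 1L
  if (any(idx < 1L | idx > length(chars))) {
    stop("variant position outside the segment", call. = FALSE)
  }
  if (any(chars[idx] != variants$ref)) {
    bad <- variants$position[chars[idx] != variants$ref][1L]
    stop("reference allele mismatch at position ", bad, call. = FALSE)
  }
  drop <- logical(length(chars))
  for (i in seq_len(nrow(variants))) {
    if (variants$vtype[i] == "deletion") {
      drop[idx[i]] <- TRUE
    } else {
      chars[idx[i]] <- variants$alt[i]
    }
  }
  paste(chars[!drop], collapse = "")
}
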