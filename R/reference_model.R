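#' @importFrom utils read.delim
#' @importFrom stats setNames
NULL

#' Path to a reference data file shipped with the package
#'
#' @param file File name under `extdata`, or `""` to list the directory.
#' @return Absolute path to the file.
#' @keywords internal
ref_file <- function(file = "") {
  system.file("extdata", file, package = "mttscreen", mustWork = (file != ""))
}

#' Load a mitochondrial tRNA gene model
#'
#' Reads a YAML gene-model configuration (rCRS segment, tRNAdb position
#' anchors, structural element ranges, and Watson-Crick stem pairs) and
#' builds the full rCRS-coordinate-to-tRNAdb-position map by monotone
#' left-aligned interpolation between anchors. Mitochondrial tRNAs are
#' shorter than the canonical 76-position body, so the map skips canonical
#' positions that have no genomic base.
#'
#' @param path Path to a gene-model YAML file. Defaults to the MT-TT
#'   (tRNA-Thr, rCRS m.15888-15953) model shipped with the package.
#' @return An object of class `trna_gene_model`: a list with elements
#'   `gene`, `start`, `end`, `sequence`, `position_map` (named integer
#'   vector, names are rCRS coordinates, values tRNAdb positions),
#'   `site_map` (the inverse), `element_map` (named character vector keyed
#'   by tRNAdb position) and `pairs` (two-column integer matrix of
#'   Watson-Crick paired tRNAdb positions).
#' @examples
#' model <- load_gene_model()
#' model$position_map[["15927"]]  # tRNAdb position 42, anticodon stem
#' @export
load_gene_model <- function(path = ref_file("mt_tt_gene_model.yaml")) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed gene model file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  for (field in c("gene", "start", "end", "sequence", "anchors",
                  "elements", "pairs")) {
    if (is.null(cfg[[field]])) {
      stop("gene model file is missing required entry '", field, "'",
           call. = FALSE)
    }
  }
  start <- as.integer(cfg$start)
  end <- as.integer(cfg$end)
  sequence <- toupper(cfg$sequence)
  if (nchar(sequence) != end - start + 1L) {
    stop("gene model sequence length (", nchar(sequence),
         ") does not match coordinates ", start, "-", end, call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("gene model sequence contains non-ACGT characters", call. = FALSE)
  }

  anchors <- unlist(cfg$anchors)
  if (length(anchors) == 0L) {
    stop("gene model has no position anchors", call. = FALSE)
  }
  anchor_coord <- as.integer(names(anchors))
  anchor_site <- as.integer(anchors)
  if (anyNA(anchor_coord) || anyNA(anchor_site)) {
    stop("gene model anchors must map integer coordinates to integer ",
         "tRNAdb positions", call. = FALSE)
  }
  ord <- order(anchor_coord)
  anchor_coord <- anchor_coord[ord]
  anchor_site <- anchor_site[ord]
  if (any(anchor_coord < start) || any(anchor_coord > end)) {
    bad <- anchor_coord[anchor_coord < start | anchor_coord > end][1L]
    stop("anchor coordinate ", bad, " lies outside the gene segment ",
         start, "-", end, call. = FALSE)
  }
  if (any(diff(anchor_site) <= 0L)) {
    i <- which(diff(anchor_site) <= 0L)[1L]
    stop("non-monotone anchor map: ", anchor_coord[i], "->", anchor_site[i],
         " followed by ", anchor_coord[i + 1L], "->", anchor_site[i + 1L],
         call. = FALSE)
  }
  # Interpolate: before the first anchor and between anchors, coordinates
  # take consecutive tRNAdb positions continuing from the anchor on their
  # left (left-aligned fill); the jump to the next anchor absorbs any
  # skipped canonical positions.
  coords <- start:end
  sites <- integer(length(coords))
  first_c <- anchor_coord[1L]
  first_s <- anchor_site[1L]
  if (first_s - (first_c - start) < 1L) {
    stop("anchor ", first_c, "->", first_s,
         " leaves no room for upstream positions", call. = FALSE)
  }
  for (i in seq_along(coords)) {
    c_i <- coords[i]
    k <- findInterval(c_i, anchor_coord)
    if (k == 0L) {
      sites[i] <- first_s - (first_c - c_i)
    } else {
      sites[i] <- anchor_site[k] + (c_i - anchor_coord[k])
    }
  }
  # Left-aligned fill must not run into (or past) the next anchor.
  for (k in seq_len(length(anchor_coord) - 1L)) {
    span <- anchor_coord[k + 1L] - anchor_coord[k]
    if (anchor_site[k] + span > anchor_site[k + 1L]) {
      stop("anchors ", anchor_coord[k], "->", anchor_site[k], " and ",
           anchor_coord[k + 1L], "->", anchor_site[k + 1L],
           " are closer in tRNAdb numbering than in rCRS coordinates",
           call. = FALSE)
    }
  }
  if (any(duplicated(sites)) || any(diff(sites) <= 0L)) {
    stop("interpolated position map is not strictly increasing", call. = FALSE)
  }

  position_map <- setNames(sites, coords)
  site_map <- setNames(coords, sites)

  elements <- cfg$elements
  element_map <- character(0)
  for (rng in elements) {
    if (is.null(rng$from) || is.null(rng$to) || is.null(rng$element)) {
      stop("malformed element range entry in gene model", call. = FALSE)
    }
    span <- as.integer(rng$from):as.integer(rng$to)
    element_map[as.character(span)] <- rng$element
  }
  missing_el <- setdiff(as.character(sites), names(element_map))
  if (length(missing_el) > 0L) {
    stop("no structural element label for tRNAdb position(s) ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }

  pairs <- do.call(rbind, lapply(cfg$pairs, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || anyNA(p)) {
      stop("malformed pairing entry in gene model", call. = FALSE)
    }
    sort(p)
  }))
  colnames(pairs) <- c("pos5", "pos3")

  structure(
    list(gene = cfg$gene, start = start, end = end, sequence = sequence,
         position_map = position_map, site_map = site_map,
         element_map = element_map, pairs = pairs),
    class = "trna_gene_model"
  )
}

#' @export
print.trna_gene_model <- function(x, ...) {
  cat("tRNA gene model:", x$gene, "\n")
  cat("  rCRS segment: ", x$start, "-", x$end, " (", nchar(x$sequence),
      " nt)\n", sep = "")
  cat("  tRNAdb positions:", min(x$position_map), "-", max(x$position_map),
      "\n")
  cat("  Watson-Crick pairs:", nrow(x$pairs), "\n")
  invisible(x)
}

#' Reference base at an rCRS coordinate
#'
#' @param model A `trna_gene_model`.
#' @param position rCRS coordinate inside the gene segment.
#' @return Single reference base.
#' @export
ref_base <- function(model, position) {
  position <- as.integer(position)
  if (position < model$start || position > model$end) {
    stop("position ", position, " is outside the ", model$gene, " segment ",
         model$start, "-", model$end, call. = FALSE)
  }
  substr(model$sequence, position - model$start + 1L,
         position - model$start + 1L)
}

#' tRNAdb position of an rCRS coordinate
#'
#' @inheritParams ref_base
#' @return Integer tRNAdb position.
#' @export
trnadb_position <- function(model, position) {
  key <- as.character(as.integer(position))
  if (!key %in% names(model$position_map)) {
    stop("position ", position, " is outside the ", model$gene, " segment",
         call. = FALSE)
  }
  unname(model$position_map[[key]])
}

#' Watson-Crick pairing partner of a tRNAdb position
#'
#' @param model A `trna_gene_model`.
#' @param trnadb_pos tRNAdb position (must exist in the model).
#' @return The paired tRNAdb position, or `NA_integer_` for unpaired
#'   (loop) positions.
#' @examples
#' model <- load_gene_model()
#' pairing_partner(model, 23)  # 12: the DHU-stem 12-23 pair
#' @export
pairing_partner <- function(model, trnadb_pos) {
  trnadb_pos <- as.integer(trnadb_pos)
  if (!as.character(trnadb_pos) %in% names(model$element_map)) {
    stop("unknown tRNAdb position ", trnadb_pos, call. = FALSE)
  }
  hit5 <- model$pairs[, "pos5"] == trnadb_pos
  hit3 <- model$pairs[, "pos3"] == trnadb_pos
  if (any(hit5)) return(unname(model$pairs[hit5, "pos3"][1L]))
  if (any(hit3)) return(unname(model$pairs[hit3, "pos5"][1L]))
  NA_integer_
}

#' Load the catalog of known disease-associated mtDNA mutations
#'
#' The shipped catalog covers the primary LHON mutations (including the
#' three classical screening mutations m.3460G>A, m.11778G>A and
#' m.14484T>C), candidate LHON mutations, and the two known
#' LHON-associated MT-TT mutations m.15927G>A and m.15951A>G.
#'
#' @param path Path to a TSV with columns `gene`, `label`, `aa_change`,
#'   `category` (`primary`, `candidate` or `known_MT_TT`).
#' @return A data.frame with those columns.
#' @export
load_known_mutations <- function(path = ref_file("known_mutations.tsv")) {
  cat_levels <- c("primary", "candidate", "known_MT_TT")
  catalog <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "label", "aa_change", "category")
  if (!all(needed %in% names(catalog))) {
    stop("known-mutation catalog must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!all(catalog$category %in% cat_levels)) {
    stop("unknown catalog category: ",
         paste(setdiff(catalog$category, cat_levels), collapse = ", "),
         call. = FALSE)
  }
  catalog
}
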