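#' Load a haplogroup defining-variant tree
#'
#' The tree file is a TSV with columns `node`, `parent` and
#' `defining_variants` (variant labels separated by `;`); the root (named
#' `rCRS` in the shipped tree) has an empty parent and no defining
#' variants. A lineage carries the union of the defining variants on its
#' root-to-node path.
#'
#' @param path Path to a tree TSV. Defaults to the curated minimal
#'   East-Asian tree shipped with the package.
#' @return An object of class `haplogroup_tree`: list with `nodes`
#'   (data.frame `node`, `parent`, `depth`), `variants` (named list of
#'   per-node defining-variant labels) and `root`.
#' @export
load_haplogroup_tree <- function(path = ref_file("haplogroup_tree.tsv")) {
  raw <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    na.strings = NULL)
  needed <- c("node", "parent", "defining_variants")
  if (!all(needed %in% names(raw))) {
    stop("haplogroup tree must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  raw$parent[is.na(raw$parent)] <- ""
  raw$defining_variants[is.na(raw$defining_variants)] <- ""
  roots <- raw$node[raw$parent == ""]
  if (length(roots) != 1L) {
    stop("haplogroup tree must have exactly one root", call. = FALSE)
  }
  if (anyDuplicated(raw$node)) {
    stop("duplicate node names in haplogroup tree", call. = FALSE)
  }
  unknown_parent <- setdiff(raw$parent[raw$parent != ""], raw$node)
  if (length(unknown_parent) > 0L) {
    stop("parent node(s) not defined: ",
         paste(unknown_parent, collapse = ", "), call. = FALSE)
  }
  variants <- lapply(strsplit(raw$defining_variants, ";", fixed = TRUE),
                     function(v) v[nzchar(v)])
  names(variants) <- raw$node
  depth <- setNames(rep(NA_integer_, nrow(raw)), raw$node)
  depth[roots] <- 0L
  # Iterate until all depths resolve; guards against cycles.
  for (pass in seq_len(nrow(raw))) {
    todo <- is.na(depth)
    if (!any(todo)) break
    for (nd in raw$node[todo]) {
      p <- raw$parent[raw$node == nd]
      if (!is.na(depth[p])) depth[nd] <- depth[p] + 1L
    }
  }
  if (anyNA(depth)) {
    stop("haplogroup tree contains nodes unreachable from the root: ",
         paste(names(depth)[is.na(depth)], collapse = ", "), call. = FALSE)
  }
  nodes <- data.frame(node = raw$node, parent = raw$parent,
                      depth = unname(depth[raw$node]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, variants = variants, root = roots),
            class = "haplogroup_tree")
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("Haplogroup tree:", nrow(x$nodes), "nodes, root", x$root, "\n")
  invisible(x)
}

#' Defining variants on the root-to-node path
#'
#' @param tree A `haplogroup_tree`.
#' @param node Node name.
#' @return Character vector of variant labels (empty for the root).
#' @export
haplogroup_path_variants <- function(tree, node) {
  if (!node %in% tree$nodes$node) {
    stop("unknown haplogroup '", node, "'", call. = FALSE)
  }
  labels <- character(0)
  nd <- node
  while (nd != "") {
    labels <- c(tree$variants[[nd]], labels)
    nd <- tree$nodes$parent[tree$nodes$node == nd]
  }
  labels
}

all_defining_variants <- function(tree) {
  unique(unlist(tree$variants, use.names = FALSE))
}

#' Assign an mtDNA haplogroup to a full-genome variant profile
#'
#' Deepest-consistent-node search over the defining-variant tree: each
#' node is scored as (defining variants present on its root-to-node path)
#' minus (defining variants absent); the maximum-score node wins, ties
#' broken by fewer missing variants, then greater depth, then node name.
#' An empty profile is assigned to the root.
#'
#' @param profile data.frame with a `label` column (or `position`, `ref`,
#'   `alt` columns from which labels are derived).
#' @param tree A [load_haplogroup_tree()] tree.
#' @return List with `best_node`, `matched`, `missing`, `score`, `depth`.
#' @export
assign_haplogroup <- function(profile, tree) {
  if (!"label" %in% names(profile)) {
    profile$label <- variant_label(profile$position, profile$ref,
                                   profile$alt)
  }
  have <- unique(profile$label)
  nodes <- tree$nodes$node
  matched <- missing <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    path <- haplogroup_path_variants(tree, nodes[i])
    matched[i] <- sum(path %in% have)
    missing[i] <- length(path) - matched[i]
  }
  score <- matched - missing
  ord <- order(-score, missing, -tree$nodes$depth, nodes)
  best <- ord[1L]
  list(best_node = nodes[best], matched = matched[best],
       missing = missing[best], score = score[best],
       depth = tree$nodes$depth[best])
}

#' Assign haplogroups to a set of subject profiles
#'
#' @param profiles data.frame with columns `subject_id` and `label` (or
#'   `position`, `ref`, `alt`).
#' @param tree A `haplogroup_tree`.
#' @return data.frame with one row per subject: `subject_id`, `node`,
#'   `matched`, `missing`, `score`.
#' @export
assign_haplogroups <- function(profiles, tree) {
  ids <- unique(profiles$subject_id)
  rows <- lapply(ids, function(id) {
    call <- assign_haplogroup(
      profiles[profiles$subject_id == id, , drop = FALSE], tree)
    data.frame(subject_id = id, node = call$best_node,
               matched = call$matched, missing = call$missing,
               score = call$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Macro-haplogroup of a tree node
#'
#' Walks from the node toward the root and returns the first name found in
#' `macros`, or `"other"` when none of the ancestors is a macro-haplogroup.
#'
#' @param tree A `haplogroup_tree`.
#' @param node Node name.
#' @param macros Macro-haplogroup names (the default covers the columns of
#'   the study's frequency table).
#' @return Single macro-haplogroup name.
#' @export
macro_haplogroup <- function(tree, node,
                             macros = c("D", "G", "M7", "M8", "A", "B",
                                        "N", "H2", "F")) {
  if (!node %in% tree$nodes$node) {
    stop("unknown haplogroup '", node, "'", call. = FALSE)
  }
  nd <- node
  while (nd != "") {
    if (nd %in% macros) return(nd)
    nd <- tree$nodes$parent[tree$nodes$node == nd]
  }
  "other"
}

#' Haplogroup frequency table by subject subgroup
#'
#' Tabulates, for each subgroup of subjects, the percentage falling in
#' each macro-haplogroup (one decimal, half-up rounding). Subjects may
#' belong to several subgroups (e.g. a variant-specific subgroup and an
#' "all carriers" row).
#'
#' @param calls data.frame from [assign_haplogroups()] (columns
#'   `subject_id`, `node`).
#' @param grouping data.frame with columns `subject_id` and `subgroup`;
#'   repeated subject ids place a subject in several rows.
#' @param tree A `haplogroup_tree`.
#' @param macros Macro-haplogroup column set.
#' @return data.frame with one row per subgroup: `subgroup`, `n`, one
#'   column per macro-haplogroup and `other`. Subgroups with no members
#'   are dropped with a warning.
#' @export
haplogroup_frequency_table <- function(calls, grouping, tree,
                                       macros = c("D", "G", "M7", "M8", "A",
                                                  "B", "N", "H2", "F")) {
  calls$macro <- vapply(calls$node, function(nd) {
    macro_haplogroup(tree, nd, macros)
  }, character(1))
  subgroups <- unique(grouping$subgroup)
  rows <- list()
  for (sg in subgroups) {
    ids <- grouping$subject_id[grouping$subgroup == sg]
    members <- calls[calls$subject_id %in% ids, , drop = FALSE]
    if (nrow(members) == 0L) {
      warning("subgroup '", sg, "' has no members; row omitted",
              call. = FALSE)
      next
    }
    pct <- vapply(c(macros, "other"), function(m) {
      round_half_up(100 * sum(members$macro == m) / nrow(members), 1L)
    }, numeric(1))
    rows[[sg]] <- data.frame(subgroup = sg, n = nrow(members),
                             as.list(pct), check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subgroup = character(0), n = integer(0))
  }
  rownames(out) <- NULL
  out
}
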