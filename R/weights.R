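#' Gerstein-Sonnhammer-Chothia sequence weights
#'
#' Classic GSC weighting on a rooted guide tree with branch lengths:
#' each branch's length is divided equally among the leaves beneath it,
#' and a leaf's weight is the sum of its shares over all branches on
#' its root path.  Weights are normalised to sum to 1.  A tree of zero
#' total length yields uniform weights.
#'
#' @param alignment `rna_alignment`.
#' @param guide_tree `phylo` tree whose tip labels are the alignment
#'   row names; defaults to the tree attached by [progressive_align()].
#' @return Object of class `weighted_alignment`: list with
#'   `alignment`, `weights` (named, positive, summing to 1) and
#'   `guide_tree`.
#' @export
gsc_weights <- function(alignment, guide_tree = NULL) {
  tree <- guide_tree %||% alignment$guide_tree
  ids <- names(alignment$rows)
  if (is.null(tree)) {
    if (length(ids) == 1L) {
      w <- setNames(1, ids)
      return(structure(list(alignment = alignment, weights = w,
                            guide_tree = NULL),
                       class = "weighted_alignment"))
    }
    stop("no guide tree supplied or attached to the alignment")
  }
  if (!setequal(tree$tip.label, ids)) {
    stop("guide tree tips do not match alignment rows")
  }
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length %||% rep(0, nrow(edge))

  # leaves under each node, by postorder accumulation
  nnode <- ntip + tree$Nnode
  under <- vector("list", nnode)
  for (t in seq_len(ntip)) under[[t]] <- t
  po <- ape::reorder.phylo(tree, "postorder")
  pe <- po$edge
  for (k in seq_len(nrow(pe))) {
    par <- pe[k, 1L]; chd <- pe[k, 2L]
    under[[par]] <- c(under[[par]], under[[chd]])
  }

  w <- setNames(rep(0, ntip), tree$tip.label)
  for (k in seq_len(nrow(edge))) {
    leaves <- under[[edge[k, 2L]]]
    w[leaves] <- w[leaves] + elen[k] / length(leaves)
  }
  if (sum(w) <= 0) {
    w[] <- 1 / ntip
  } else {
    w <- w / sum(w)
  }
  w <- w[ids]
  structure(list(alignment = alignment, weights = w, guide_tree = tree),
            class = "weighted_alignment")
}

#' Construct a weighted alignment with explicit weights
#'
#' Convenience constructor used by tests and by profile rebuilding;
#' weights are normalised to sum to 1.
#'
#' @param alignment `rna_alignment`.
#' @param weights positive numeric vector, one per row (default
#'   uniform).
#' @return `weighted_alignment`.
#' @export
weighted_alignment <- function(alignment,
                               weights = NULL) {
  n <- length(alignment$rows)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("weights must be positive, one per alignment row")
  }
  w <- setNames(weights / sum(weights), names(alignment$rows))
  structure(list(alignment = alignment, weights = w, guide_tree = NULL),
            class = "weighted_alignment")
}

#' @export
print.weighted_alignment <- function(x, ...) {
  cat("<weighted_alignment> ", length(x$weights), " rows x ",
      nchar(x$alignment$rows[[1L]]), " columns; weight range [",
      signif(min(x$weights), 3), ", ", signif(max(x$weights), 3), "]\n",
      sep = "")
  invisible(x)
}
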