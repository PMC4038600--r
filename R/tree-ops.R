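# Phylogeny handling: Newick I/O, patristic distances, pruning, rescaling,
# and the path-incidence structure used by least-squares branch fitting.
#
# Trees are plain ape "phylo" objects. Branch (edge) identity is the row index
# of `tree$edge` in ape's cladewise order, which is deterministic for a given
# Newick string, so per-branch outputs are reproducible across runs.

#' Read a phylogeny from a Newick string or file
#'
#' Wraps [ape::read.tree()] and validates the result: tip labels must be
#' unique and non-empty, and all branch lengths present and non-negative.
#' Internal node labels (e.g. support values) are preserved verbatim.
#'
#' @param text a Newick string (containing "(" or ";"), or a path to a file.
#' @return An object of class `phylo`.
#' @seealso [write_newick()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- if (grepl("[(;]", text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stopf("Newick parse error: %s", conditionMessage(e)))
  } else {
    tryCatch(ape::read.tree(file = text),
             error = function(e) stopf("Newick parse error in '%s': %s", text,
                                       conditionMessage(e)))
  }
  if (is.null(tr)) stopf("Newick parse error: input could not be read as a tree")
  validate_phylogeny(tr)
  tr
}

#' Write a phylogeny to a Newick string or file
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths (default 15, enough for
#'   lossless round-trips at double precision).
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Validate a phylogeny
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' tip labels and non-negative branch lengths on every edge.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stopf("empty tip label at position %d", which(!nzchar(labs))[1])
  dup <- labs[duplicated(labs)]
  if (length(dup)) stopf("duplicate tip label(s): %s", paste(unique(dup), collapse = ", "))
  if (length(labs) > 1L) {
    if (is.null(tree$edge.length)) stopf("branch lengths are required but absent")
    if (anyNA(tree$edge.length)) stopf("missing branch length on edge %d",
                                       which(is.na(tree$edge.length))[1])
    if (any(tree$edge.length < 0)) stopf("negative branch length on edge %d",
                                         which(tree$edge.length < 0)[1])
  }
  invisible(tree)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' computed with the cophenetic distances of the tree.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return A symmetric matrix with zero diagonal, rows/columns in
#'   `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (n == 1L) {
    m <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Prune a phylogeny to a subset of tips
#'
#' Drops all tips not in `keep`; resulting degree-2 nodes are suppressed with
#' their branch lengths summed, so patristic distances among kept tips are
#' unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (non-empty).
#' @return The induced subtree as a `phylo` object.
#' @export
prune_tips <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (!length(keep)) stopf("'keep' must name at least one tip")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stopf("unknown tip label(s): %s", paste(unknown, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Tip depths (root-to-tip path lengths), in tip order.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_along(tree$tip.label)]
}

#' Root height of an ultrametric tree, with tolerance check
#'
#' @param tree a `phylo` object.
#' @param tol maximum allowed relative spread of tip depths (default `1e-6`).
#' @return The common root-to-tip depth.
#' @keywords internal
ultrametric_height <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  h <- max(d)
  if (h <= 0) stopf("tree has zero height")
  spread <- (h - min(d)) / h
  if (spread > tol) {
    stopf("tree is not ultrametric: relative tip-depth spread %.3g exceeds %.1g",
          spread, tol)
  }
  h
}

#' Rescale an ultrametric tree to a target root age
#'
#' Multiplies every branch length by `target / height` so that all tips lie at
#' depth `target` (the analyses use a root age of 1).
#'
#' @param tree an ultrametric `phylo` object (relative tip-depth spread below
#'   `tol`).
#' @param target positive target root age (default 1).
#' @param tol ultrametricity tolerance, relative (default `1e-6`).
#' @return The rescaled `phylo` object.
#' @export
rescale_root_age <- function(tree, target = 1, tol = 1e-6) {
  stopifnot(is.numeric(target), target > 0)
  h <- ultrametric_height(tree, tol)
  tree$edge.length <- tree$edge.length * (target / h)
  tree
}

#' Per-branch bookkeeping table
#'
#' One row per edge of the tree, in the deterministic edge order used by all
#' branch-indexed outputs.
#'
#' @param tree a `phylo` object.
#' @return A data frame with columns `branch` (edge index), `parent`, `child`
#'   (node ids), `length`, and `class` (`"terminal"` for edges ending in a
#'   tip, else `"internal"`).
#' @export
branch_table <- function(tree) {
  n_tip <- length(tree$tip.label)
  data.frame(
    branch = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1L],
    child  = tree$edge[, 2L],
    length = tree$edge.length,
    class  = ifelse(tree$edge[, 2L] <= n_tip, "terminal", "internal"),
    stringsAsFactors = FALSE
  )
}

#' Path-incidence matrix of a phylogeny
#'
#' Binary matrix with one row per unordered tip pair and one column per edge;
#' entry 1 when the edge lies on the path between the pair. By additivity,
#' `A %*% tree$edge.length` equals the vectorized patristic distances exactly.
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @return A 0/1 matrix; rows named `"tipA|tipB"` following
#'   `combn(tip.label, 2)` order, columns indexed by edge.
#' @export
path_incidence <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 2L) stopf("path incidence requires at least 2 tips")
  n_edge <- nrow(tree$edge)
  # tips below each edge, by postorder accumulation
  below <- matrix(FALSE, n_edge, n)
  po <- ape::reorder.phylo(tree, "postorder")
  idx <- match(paste(po$edge[, 1], po$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  child_sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) child_sets[[i]] <- i
  for (k in seq_len(n_edge)) {
    par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[idx[k], child_sets[[ch]]] <- TRUE
    child_sets[[par]] <- c(child_sets[[par]], child_sets[[ch]])
  }
  pairs <- utils::combn(n, 2L)
  A <- matrix(0L, ncol(pairs), n_edge)
  for (e in seq_len(n_edge)) {
    b <- below[e, ]
    A[, e] <- as.integer(xor(b[pairs[1L, ]], b[pairs[2L, ]]))
  }
  rownames(A) <- paste(tree$tip.label[pairs[1L, ]], tree$tip.label[pairs[2L, ]],
                       sep = "|")
  A
}

#' Resolve polytomies and zero-length branches for contrast-based methods
#'
#' Multifurcations are resolved into arbitrary binary nodes with zero-length
#' branches, and any zero-length branch is then set to a small fraction of the
#' tree height so that contrast denominators are positive.
#'
#' @param tree a `phylo` object.
#' @param eps fraction of the maximum tip depth assigned to zero branches
#'   (default `1e-8`).
#' @return A binary `phylo` object with strictly positive branch lengths.
#' @export
resolve_polytomies <- function(tree, eps = 1e-8) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (is.null(tree$edge.length)) stopf("branch lengths are required")
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length[tree$edge.length <= 0] <- eps * h
  tree
}
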