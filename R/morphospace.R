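# Ordination of the (corrected) measurement space and maximum-likelihood
# ancestral positions for phylomorphospace projection.

#' Principal component ordination of a measurement table
#'
#' Covariance-matrix PCA of the column-centered data (no rescaling: the log10
#' transform already gives traits a similar dimension of variance).
#' Components are ordered by decreasing eigenvalue; the sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making score plots reproducible.
#'
#' @param table a `measurement_table` (any state except `raw_mm`), or a
#'   numeric matrix with specimen rownames.
#' @param retain_threshold cumulative variance fraction defining the retained
#'   leading components (default 0.95).
#' @return An object of class `ordination`: list with `scores`
#'   (specimens x components), `loadings` (traits x components, orthonormal
#'   columns), `variance_fractions`, `eigenvalues`, `retained` (count of
#'   leading components first reaching the threshold), and `center`.
#' @export
morpho_pca <- function(table, retain_threshold = 0.95) {
  x <- if (inherits(table, "measurement_table")) {
    require_state(table, c("log10", "size_corrected_bbpm",
                           "size_corrected_regression"))
    table$values
  } else as.matrix(table)
  if (nrow(x) < 3) stopf("PCA needs at least 3 specimens")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  cv <- crossprod(xc) / (nrow(x) - 1)
  total <- sum(diag(cv))
  if (total < 1e-14) stopf("constant table: zero total variance")
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- xc %*% load
  frac <- ev / sum(ev)
  retained <- which(cumsum(frac) >= retain_threshold - 1e-12)[1L]
  structure(list(scores = scores, loadings = load, eigenvalues = ev,
                 variance_fractions = frac, retained = retained,
                 center = ctr, threshold = retain_threshold),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d specimens, %d components; PC1 %.1f%%, %d retained (>=%.0f%%)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$variance_fractions[1],
              x$retained, 100 * x$threshold))
  invisible(x)
}

#' Indices of the components retained at the variance threshold
#'
#' The smallest leading set of components whose cumulative variance fraction
#' reaches the threshold (default 95%), used by all downstream group tests to
#' discard measurement noise.
#'
#' @param ordination an `ordination` object.
#' @param threshold cumulative variance fraction (default the ordination's).
#' @return Integer vector `1:k`.
#' @export
retain_95 <- function(ordination, threshold = NULL) {
  threshold <- threshold %||% ordination$threshold
  k <- which(cumsum(ordination$variance_fractions) >= threshold - 1e-12)[1L]
  seq_len(k)
}

#' Retained PC scores
#'
#' @param ordination an `ordination` object.
#' @param threshold optional cumulative variance threshold.
#' @return Score matrix restricted to the retained components.
#' @export
retained_scores <- function(ordination, threshold = NULL) {
  ordination$scores[, retain_95(ordination, threshold), drop = FALSE]
}

#' Maximum-likelihood ancestral states of a continuous trait
#'
#' Brownian-motion ML estimates at every internal node (equivalently the GLS
#' phylogenetic mean of the tree re-rooted at each node); computed with
#' [phytools::fastAnc()]. Polytomies and zero-length branches are resolved
#' to near-zero-length binary branches first.
#'
#' @param tree a `phylo` object.
#' @param tip_values named numeric vector, names exactly the tip labels.
#' @return Named numeric vector of estimates for internal node ids of the
#'   original tree (`ntip+1 ... ntip+Nnode`).
#' @export
ancestral_states <- function(tree, tip_values) {
  miss <- setdiff(tree$tip.label, names(tip_values))
  extra <- setdiff(names(tip_values), tree$tip.label)
  if (length(miss) || length(extra)) {
    stopf("tip/value label mismatch; missing values for: %s; unknown labels: %s",
          paste(miss, collapse = ", ") %||% "-",
          paste(extra, collapse = ", ") %||% "-")
  }
  x <- tip_values[tree$tip.label]
  binary <- ape::is.binary(tree) && all(tree$edge.length > 0)
  if (!binary) {
    res <- resolve_polytomies(tree)
    anc <- phytools::fastAnc(res, x[res$tip.label])
    # map resolved internal nodes back to original ones by shared tip sets
    orig_parts <- lapply(seq_len(tree$Nnode) + length(tree$tip.label),
                         function(nd) sort(node_tips(tree, nd)))
    res_parts <- lapply(seq_len(res$Nnode) + length(res$tip.label),
                        function(nd) sort(node_tips(res, nd)))
    idx <- match(vapply(orig_parts, paste, "", collapse = "\r"),
                 vapply(res_parts, paste, "", collapse = "\r"))
    out <- as.numeric(anc)[idx]
  } else {
    out <- as.numeric(phytools::fastAnc(tree, x))
  }
  stats::setNames(out, seq_len(tree$Nnode) + length(tree$tip.label))
}

#' Project a phylogeny into morphospace
#'
#' Tip coordinates are the PC scores on the chosen axes; internal-node
#' coordinates are ML ancestral states per axis; the edge list connects them
#' for plotting.
#'
#' @param tree a `phylo` whose tips match the ordination's specimens.
#' @param ordination an `ordination` object with tip-labeled scores.
#' @param axes pair of component indices (default `c(1, 2)`).
#' @return A list with `nodes` (data frame: `node`, `label`, `type`, one
#'   column per axis) and `edges` (parent/child node ids).
#' @export
phylomorphospace <- function(tree, ordination, axes = c(1, 2)) {
  if (any(axes < 1) || any(axes > ncol(ordination$scores)))
    stopf("axis out of range (1..%d)", ncol(ordination$scores))
  sc <- ordination$scores
  miss <- setdiff(tree$tip.label, rownames(sc))
  if (length(miss)) stopf("scores missing for tip(s): %s",
                          paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  coords <- matrix(NA_real_, n_tip + tree$Nnode, length(axes))
  colnames(coords) <- colnames(sc)[axes]
  coords[seq_len(n_tip), ] <- sc[tree$tip.label, axes]
  for (j in seq_along(axes)) {
    coords[n_tip + seq_len(tree$Nnode), j] <-
      ancestral_states(tree, stats::setNames(sc[tree$tip.label, axes[j]],
                                             tree$tip.label))
  }
  nodes <- data.frame(
    node = seq_len(n_tip + tree$Nnode),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    type = rep(c("tip", "ancestor"), c(n_tip, tree$Nnode)),
    coords, check.names = FALSE, stringsAsFactors = FALSE)
  list(nodes = nodes,
       edges = data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L]))
}
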