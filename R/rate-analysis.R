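# Decoupling of morphological from molecular rates: least-squares branch
# lengths fitted to morphometric distance matrices on the fixed topology,
# percentile screening of morphological/molecular branch-length ratios, and
# multivariate standardized independent contrasts as branch-rate estimates.

#' Least-squares branch lengths from a tip distance matrix
#'
#' Minimizes `||A b - d||^2` where `A` is the path-incidence matrix of the
#' topology and `d` the vectorized tip distances, via the singular-value
#' pseudo-inverse (minimum-norm solution when the system is rank-deficient,
#' which on a rooted tree always affects the two root-child edges: only
#' their sum is identifiable from distances). Negative fitted lengths are
#' then clamped to zero, once.
#'
#' @param tree a `phylo` supplying the topology (its branch lengths are
#'   ignored).
#' @param dist symmetric matrix of tip distances with zero diagonal, labels
#'   matching the tips.
#' @return A list of class `ls_branch_fit`: `lengths` (clamped, per edge),
#'   `raw` (unclamped), `rank_deficient` flag, `fitted` (distances implied by
#'   `raw`), `objective` (residual sum of squares of the clamped solution),
#'   and `tree` (the topology with `lengths` installed).
#' @export
ls_branch_lengths <- function(tree, dist) {
  dist <- as.matrix(dist)
  miss <- setdiff(tree$tip.label, rownames(dist))
  if (length(miss)) stopf("distance matrix missing tip(s): %s",
                          paste(miss, collapse = ", "))
  dist <- dist[tree$tip.label, tree$tip.label]
  stopifnot(isSymmetric(unname(dist), tol = 1e-8),
            max(abs(diag(dist))) < 1e-10)
  A <- path_incidence(tree)
  pairs <- utils::combn(length(tree$tip.label), 2L)
  d <- dist[cbind(pairs[1L, ], pairs[2L, ])]
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  raw <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], d)) / sv$d[pos])
  raw <- as.numeric(raw)
  lengths <- pmax(raw, 0)
  fit_tree <- tree
  fit_tree$edge.length <- lengths
  structure(list(lengths = lengths, raw = raw,
                 rank_deficient = sum(pos) < ncol(A),
                 fitted = as.numeric(A %*% raw),
                 objective = sum((as.numeric(A %*% lengths) - d)^2),
                 tree = fit_tree),
            class = "ls_branch_fit")
}

#' Flag branches whose morphological/molecular length ratio is extreme
#'
#' Per-branch ratio of morphometric to molecular branch length, screened
#' against the central 95% of the empirical ratio distribution — separately
#' for internal branches and tips, whose lengths differ systematically.
#' Ratios at zero molecular length are reported as undefined and excluded
#' from the screen; classes with too few defined ratios are skipped (their
#' percentiles would be unstable).
#'
#' @param morph_lengths fitted morphometric branch lengths, in edge order.
#' @param mol_lengths molecular branch lengths, same edge order.
#' @param tree the `phylo` object defining the edges.
#' @param method `"percentile"` (empirical 2.5/97.5 percentiles, default) or
#'   `"normal"` (mean +/- 1.96 SD).
#' @param min_class minimum number of ratio-defined branches per class
#'   (default 20).
#' @return A data frame (one row per edge): `branch`, `parent`, `child`,
#'   `class`, `mol_length`, `morph_length`, `ratio` (NA when undefined),
#'   `outlier` (`"none"`, `"high"`, `"low"`).
#' @export
rate_ratio_outliers <- function(morph_lengths, mol_lengths, tree,
                                method = c("percentile", "normal"),
                                min_class = 20) {
  method <- match.arg(method)
  bt <- branch_table(tree)
  stopifnot(length(morph_lengths) == nrow(bt),
            length(mol_lengths) == nrow(bt))
  ratio <- ifelse(mol_lengths > 0, morph_lengths / mol_lengths, NA_real_)
  outlier <- rep("none", nrow(bt))
  for (cl in c("internal", "terminal")) {
    idx <- which(bt$class == cl & !is.na(ratio))
    if (length(idx) < min_class) {
      message(sprintf("branch class '%s': only %d defined ratio(s) (< %d), screen skipped",
                      cl, length(idx), min_class))
      next
    }
    r <- ratio[idx]
    if (method == "percentile") {
      lo <- stats::quantile(r, 0.025, names = FALSE)
      hi <- stats::quantile(r, 0.975, names = FALSE)
    } else {
      lo <- mean(r) - 1.96 * stats::sd(r)
      hi <- mean(r) + 1.96 * stats::sd(r)
    }
    outlier[idx[r > hi]] <- "high"
    outlier[idx[r < lo]] <- "low"
  }
  data.frame(bt[, c("branch", "parent", "child", "class")],
             mol_length = mol_lengths, morph_length = morph_lengths,
             ratio = ratio, outlier = outlier, stringsAsFactors = FALSE)
}

#' Standardized phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node joining subtree
#' values `x_a, x_b` over adjusted branch lengths `v_a, v_b`, the contrast is
#' `(x_a - x_b) / sqrt(v_a + v_b)`, the node value the precision-weighted
#' average, and the parent branch is inflated by `v_a v_b / (v_a + v_b)`.
#' Contrasts are i.i.d. N(0, sigma^2) under Brownian motion. Polytomies are
#' resolved into near-zero-length binary branches first.
#'
#' @param tree a `phylo` object with positive branch lengths.
#' @param trait named numeric vector over the tips.
#' @return Numeric vector of standardized contrasts named by internal node
#'   id (of the resolved tree), with the resolved tree as attribute
#'   `"tree"` and node values as attribute `"node_values"`.
#' @export
independent_contrasts <- function(tree, trait) {
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stopf("trait values missing for tip(s): %s",
                          paste(miss, collapse = ", "))
  if (!ape::is.binary(tree) || any(tree$edge.length <= 0))
    tree <- resolve_polytomies(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  val <- c(as.numeric(trait[tree$tip.label]), rep(NA_real_, tree$Nnode))
  extra <- numeric(n_node)
  contrast <- stats::setNames(rep(NA_real_, tree$Nnode),
                              n_tip + seq_len(tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  # internal nodes in completion order: children always precede their parent
  node_order <- rev(unique(rev(po$edge[, 1L])))
  for (node in node_order) {
    ke <- which(tree$edge[, 1L] == node)
    ch <- tree$edge[ke, 2L]
    v <- tree$edge.length[ke] + extra[ch]
    if (sum(v) <= 0) stopf("zero combined branch length at node %d", node)
    contrast[as.character(node)] <- (val[ch[1]] - val[ch[2]]) / sqrt(sum(v))
    val[node] <- (val[ch[1]] / v[1] + val[ch[2]] / v[2]) / (1 / v[1] + 1 / v[2])
    extra[node] <- v[1] * v[2] / sum(v)
  }
  structure(contrast, tree = tree,
            node_values = val[n_tip + seq_len(tree$Nnode)])
}

#' Multivariate standardized contrast rates
#'
#' Per-trait standardized independent contrasts on the ultrametric tree
#' (rescaled to root age 1), combined per internal node into a multivariate
#' rate: the Euclidean norm of the node's contrast vector across traits.
#' Node depths (time before present) are returned for plotting rates over
#' the tree.
#'
#' @param tree an ultrametric `phylo`; rescaled internally to root age 1.
#' @param table a `measurement_table` (log10 or size-corrected) whose
#'   specimens are the tips.
#' @return A list of class `contrast_set`: `rates` (data frame: `node`,
#'   `depth` = time before present, `rate`), `contrasts` (internal nodes x
#'   traits matrix), `tree` (the rescaled, resolved tree).
#' @export
multivariate_rates <- function(tree, table) {
  stopifnot(inherits(table, "measurement_table"))
  tree <- rescale_root_age(tree, 1)
  miss <- setdiff(tree$tip.label, rownames(table$values))
  if (length(miss)) stopf("measurements missing for tip(s): %s",
                          paste(miss, collapse = ", "))
  vals <- table$values[tree$tip.label, , drop = FALSE]
  first <- independent_contrasts(tree, stats::setNames(vals[, 1], tree$tip.label))
  res_tree <- attr(first, "tree")
  cm <- matrix(NA_real_, res_tree$Nnode, ncol(vals),
               dimnames = list(names(first), colnames(vals)))
  cm[, 1] <- as.numeric(first)
  if (ncol(vals) > 1) {
    for (j in 2:ncol(vals)) {
      cm[, j] <- as.numeric(independent_contrasts(
        res_tree, stats::setNames(vals[, j], res_tree$tip.label)))
    }
  }
  n_tip <- length(res_tree$tip.label)
  node_depth <- ape::node.depth.edgelength(res_tree)
  h <- max(node_depth[seq_len(n_tip)])
  rates <- data.frame(node = as.integer(names(first)),
                      depth = h - node_depth[n_tip + seq_len(res_tree$Nnode)],
                      rate = sqrt(rowSums(cm^2)))
  structure(list(rates = rates, contrasts = cm, tree = res_tree),
            class = "contrast_set")
}

#' Full morphological-vs-molecular rate comparison
#'
#' Runs, for both the uncorrected (log10) and the BBPM size-corrected data
#' state: least-squares branch-length fitting of the Euclidean morphometric
#' distances on the molecular topology, ratio-outlier screening against the
#' molecular branch lengths, and multivariate contrast rates on the
#' ultrametric time tree — enabling the size-vs-shape divergence comparison
#' per branch.
#'
#' @param tree_mol the molecular tree (topology + molecular branch lengths).
#' @param tree_time an ultrametric tree on the same tips (root rescaled to 1
#'   internally).
#' @param table a `measurement_table` in `raw_mm` or `log10` state.
#' @param method passed to [rate_ratio_outliers()].
#' @return A list of class `rate_pipeline` with elements `uncorrected` and
#'   `corrected`, each holding `fit` (an `ls_branch_fit`), `profile` (ratio
#'   outlier data frame) and `rates` (a `contrast_set`).
#' @export
rate_pipeline <- function(tree_mol, tree_time, table,
                          method = c("percentile", "normal")) {
  method <- match.arg(method)
  if (table$state == "raw_mm") table <- log_transform(table)
  require_state(table, "log10")
  states <- list(uncorrected = table, corrected = bbpm_correct(table))
  out <- lapply(names(states), function(nm) {
    tab <- states[[nm]]
    dmat <- as.matrix(stats::dist(tab$values))
    fit <- ls_branch_lengths(tree_mol, dmat)
    profile <- rate_ratio_outliers(fit$lengths, tree_mol$edge.length,
                                   tree_mol, method = method)
    list(fit = fit, profile = profile,
         rates = multivariate_rates(tree_time, tab))
  })
  names(out) <- names(states)
  structure(out, class = "rate_pipeline")
}
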