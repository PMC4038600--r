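# Phylogenetically explicit statistics: Blomberg's K with permutation
# significance and clade-subsampling sensitivity, PGLS of morphospace on
# feeding types with ML Pagel's lambda, and Mantel tests between molecular
# and morphometric distance matrices.

# BM covariance among tips (shared root-to-MRCA path lengths), tip order
bm_covariance <- function(tree) {
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label]
}

# all n! permutations of 1..n (exact Mantel null); n must stay small
permutations_all <- function(n, limit = 5040) {
  if (factorial(n) > limit) stopf("%d! permutations exceed the limit", n)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L, limit = Inf)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

#' Blomberg's K phylogenetic signal statistic
#'
#' Ratio of the observed to the Brownian-expected similarity of relatives:
#' with `V` the BM covariance of the tree and `a` the GLS phylogenetic mean,
#' `K = (MSE0/MSE) / ((tr(V) - n/sum(V^-1)) / (n-1))` where
#' `MSE0 = (x-a)'(x-a)/(n-1)` and `MSE = (x-a)'V^-1(x-a)/(n-1)`. `K = 1`
#' is the BM expectation; `K > 1` means closer relatives are more similar
#' than BM predicts. Significance comes from permuting trait values across
#' tips and counting permutations with `MSE <=` the observed (+1 convention).
#'
#' @param tree a `phylo` object; polytomies are fine, but zero-length
#'   branches are resolved to near-zero positive ones to keep the
#'   covariance nonsingular.
#' @param trait named numeric vector over the tips.
#' @param n_perm permutations for the p-value (default 999; 0 skips it).
#' @param seed integer seed.
#' @return A list of class `blomberg_k`: `K`, `p_value`, `n_tips`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stopf("trait values missing for tip(s): %s",
                          paste(miss, collapse = ", "))
  x <- as.numeric(trait[tree$tip.label])
  n <- length(x)
  if (any(tree$edge.length <= 0)) tree <- resolve_polytomies(tree)
  V <- bm_covariance(tree)
  Vi <- tryCatch(solve(V), error = function(e) stopf("singular BM covariance"))
  denom <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  k_of <- function(x) {
    ahat <- sum(Vi %*% x) / sum(Vi)
    r <- x - ahat
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(crossprod(r, Vi %*% r)) / (n - 1)
    c(K = (mse0 / mse) / denom, mse = mse)
  }
  obs <- k_of(x)
  p <- NA_real_
  if (n_perm > 0) {
    hits <- with_seed(seed, sum(vapply(seq_len(n_perm), function(i)
      k_of(sample(x))["mse"] <= obs["mse"] + 1e-12, logical(1))))
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(K = unname(obs["K"]), p_value = p, n_tips = n,
                 n_perm = n_perm), class = "blomberg_k")
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4g (n = %d), p = %.4g (%d permutations)\n",
              x$K, x$n_tips, x$p_value, x$n_perm))
  invisible(x)
}

# lambda transform: off-diagonal BM covariances scaled by lambda
lambda_cov <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# ML GLS fit of y on X under V(lambda); returns coefficients, sigma2, logLik
gls_fit <- function(y, X, Vl) {
  L <- chol(Vl)
  z <- backsolve(L, y, transpose = TRUE)
  W <- backsolve(L, X, transpose = TRUE)
  qrW <- qr(W)
  beta <- qr.coef(qrW, z)
  res <- z - W %*% beta
  n <- length(y)
  rss <- sum(res^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(L))) + n)
  list(beta = beta, sigma2 = sigma2, log_lik = ll, rss = rss, L = L,
       z = z, W = W)
}

#' PGLS of morphospace components on feeding types
#'
#' For every retained principal component, a generalized least squares
#' regression with feeding type as the (dummy-coded, alphabetical reference)
#' predictor and residual covariance `V(lambda)` — the BM covariance with
#' off-diagonal entries multiplied by Pagel's lambda, estimated by maximum
#' likelihood on a grid over `[0, 1]` with local refinement; kappa and delta
#' are fixed at 1. The pooled summary is the variance-fraction-weighted mean
#' adjusted r-squared across components (per-component values are always
#' reported alongside).
#'
#' @param tree a `phylo` object.
#' @param scores tip-labeled score matrix, or an `ordination` (its retained
#'   components and eigenvalue weights are then used).
#' @param feeding named character vector of feeding types per tip.
#' @param weights optional per-component weights for the pooled summary
#'   (defaults to the ordination's variance fractions, else equal).
#' @return A list of class `pgls_feeding`: `fits` (data frame per component:
#'   `component`, `lambda_hat`, `adjusted_r2`, `log_likelihood`),
#'   `coefficients` (list per component), `pooled_adjusted_r2`, `kappa`,
#'   `delta`.
#' @export
pgls_feeding <- function(tree, scores, feeding, weights = NULL) {
  if (inherits(scores, "ordination")) {
    keep <- retain_95(scores)
    weights <- weights %||% scores$variance_fractions[keep]
    scores <- scores$scores[, keep, drop = FALSE]
  }
  scores <- as.matrix(scores)
  miss <- setdiff(tree$tip.label, rownames(scores))
  if (length(miss)) stopf("scores missing for tip(s): %s",
                          paste(miss, collapse = ", "))
  miss <- setdiff(tree$tip.label, names(feeding))
  if (length(miss)) stopf("feeding labels missing for tip(s): %s",
                          paste(miss, collapse = ", "))
  y_all <- scores[tree$tip.label, , drop = FALSE]
  f <- factor(feeding[tree$tip.label])
  if (nlevels(f) < 2) stopf("need at least 2 feeding levels, got '%s'",
                            levels(f))
  X <- stats::model.matrix(~ f)
  n <- length(tree$tip.label)
  V <- bm_covariance(tree)
  weights <- weights %||% rep(1, ncol(y_all))
  grid <- seq(0, 1, length.out = 101)
  fit_one <- function(y) {
    ll_of <- function(lam) gls_fit(y, X, lambda_cov(V, lam))$log_lik
    ll_grid <- vapply(grid, ll_of, numeric(1))
    i <- which.max(ll_grid)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(ll_of, c(lo, hi), maximum = TRUE, tol = 1e-6)
    lam <- if (opt$objective >= ll_grid[i]) opt$maximum else grid[i]
    fit <- gls_fit(y, X, lambda_cov(V, lam))
    # r2 in the whitened space, against the GLS intercept-only fit
    null <- gls_fit(y, X[, 1, drop = FALSE], lambda_cov(V, lam))
    r2 <- 1 - fit$rss / null$rss
    p <- ncol(X) - 1
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    list(lambda_hat = lam, coefficients = stats::setNames(as.numeric(fit$beta),
                                                          colnames(X)),
         adjusted_r2 = adj, log_likelihood = fit$log_lik)
  }
  fits <- lapply(seq_len(ncol(y_all)), function(j) fit_one(y_all[, j]))
  comp_names <- colnames(y_all) %||% paste0("PC", seq_len(ncol(y_all)))
  tab <- data.frame(component = comp_names,
                    lambda_hat = vapply(fits, `[[`, 0, "lambda_hat"),
                    adjusted_r2 = vapply(fits, `[[`, 0, "adjusted_r2"),
                    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
                    stringsAsFactors = FALSE)
  w <- weights / sum(weights)
  structure(list(fits = tab,
                 coefficients = stats::setNames(lapply(fits, `[[`, "coefficients"),
                                                comp_names),
                 pooled_adjusted_r2 = sum(w * tab$adjusted_r2),
                 kappa = 1, delta = 1, reference_level = levels(f)[1]),
            class = "pgls_feeding")
}

#' @export
print.pgls_feeding <- function(x, ...) {
  cat(sprintf("PGLS on feeding types (%d components, kappa = delta = 1)\n",
              nrow(x$fits)))
  print(x$fits, row.names = FALSE)
  cat(sprintf("pooled adjusted r^2 = %.4g\n", x$pooled_adjusted_r2))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strict lower triangles; one-sided
#' significance (greater) from jointly permuting rows and columns of the
#' second matrix, with the +1 convention, or from complete enumeration of
#' all label permutations when `exact = TRUE`.
#'
#' @param d1,d2 symmetric matrices with zero diagonal and matching labels
#'   (when dimnames are present `d2` is aligned to `d1`).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param exact enumerate all `n!` permutations (small matrices only).
#' @return A list of class `mantel`: `r`, `p_value`, `n`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000, seed = NULL, exact = FALSE) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    miss <- setdiff(rownames(d1), rownames(d2))
    if (length(miss)) stopf("labels missing from second matrix: %s",
                            paste(miss, collapse = ", "))
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  n <- nrow(d1)
  stopifnot(nrow(d2) == n, isSymmetric(unname(d1), tol = 1e-8),
            isSymmetric(unname(d2), tol = 1e-8))
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (stats::sd(v1) < 1e-14 || stats::sd(d2[lt]) < 1e-14)
    stopf("constant off-diagonal distances: Mantel correlation undefined")
  r_obs <- stats::cor(v1, d2[lt])
  if (exact) {
    perms <- permutations_all(n)
    r_perm <- apply(perms, 1L, function(pm) stats::cor(v1, d2[pm, pm][lt]))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    hits <- with_seed(seed, sum(vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      stats::cor(v1, d2[pm, pm][lt]) >= r_obs - 1e-12
    }, logical(1))))
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p_value = p, n = n, n_perm = n_perm),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4g (n = %d), one-sided p = %.4g (%d permutations)\n",
              x$r, x$n, x$p_value, x$n_perm))
  invisible(x)
}

#' Per-trait K under stepwise subsampling of a focal clade
#'
#' Emulates the sensitivity analysis for sampling bias: for each target size,
#' a random subset of that many focal-clade tips is retained (all other tips
#' kept), tree and table are pruned, and Blomberg's K recomputed for every
#' trait; the focal trait's rank among all traits (1 = highest K) is
#' reported per target size.
#'
#' @param tree a `phylo` object.
#' @param table a size-corrected (or log10) `measurement_table` whose
#'   specimens are the tips.
#' @param focal_tips tip labels of the focal clade.
#' @param target_sizes integer vector of focal-clade sizes to retain.
#' @param focal_trait trait whose rank is tracked (default `"MCL"`).
#' @param seed integer seed for the subsampling draws.
#' @param n_perm permutations for per-trait p-values (default 0 = none).
#' @return A list: `k_table` (long data frame `target_size`, `trait`, `K`)
#'   and `focal_rank` (data frame `target_size`, `rank`).
#' @export
k_subsampling <- function(tree, table, focal_tips, target_sizes,
                          focal_trait = "MCL", seed = 1L, n_perm = 0) {
  stopifnot(inherits(table, "measurement_table"))
  focal_tips <- intersect(focal_tips, tree$tip.label)
  if (any(target_sizes > length(focal_tips)))
    stopf("target size %d exceeds focal clade size %d",
          max(target_sizes), length(focal_tips))
  if (!focal_trait %in% colnames(table$values))
    stopf("focal trait '%s' not in table", focal_trait)
  others <- setdiff(tree$tip.label, focal_tips)
  rows <- list(); ranks <- list()
  for (ts in target_sizes) {
    sub <- if (ts == length(focal_tips)) focal_tips else
      with_seed(derive_seed(seed, paste0("ksub", ts)), sample(focal_tips, ts))
    keep <- c(others, sub)
    tr <- prune_tips(tree, keep)
    vals <- table$values[keep, , drop = FALSE]
    ks <- vapply(colnames(vals), function(trait)
      blomberg_k(tr, stats::setNames(vals[, trait], keep), n_perm = n_perm,
                 seed = derive_seed(seed, paste0("kperm", ts, trait)))$K,
      numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(target_size = ts,
                                            trait = names(ks), K = unname(ks),
                                            stringsAsFactors = FALSE)
    ranks[[length(ranks) + 1L]] <- data.frame(
      target_size = ts, rank = rank(-ks, ties.method = "min")[focal_trait],
      K_focal = unname(ks[focal_trait]))
  }
  list(k_table = do.call(rbind, rows), focal_rank = do.call(rbind, ranks))
}

#' Mantel tests within feeding types
#'
#' For every feeding type with at least `min_n` members, the Mantel test
#' between the patristic submatrix of the molecular tree and the Euclidean
#' distance submatrix of the (size-corrected) measurements, plus the
#' complete-sampling row. Types with fewer members are skipped with a notice.
#'
#' @param tree the molecular `phylo` object.
#' @param table a `measurement_table` (size-corrected or log10).
#' @param feeding named character vector of feeding types per tip.
#' @param n_perm Mantel permutations (default 10000).
#' @param seed integer seed.
#' @param min_n minimum members per type (default 3).
#' @return Data frame: `feeding`, `n`, `r`, `p_value` (first row =
#'   `"complete"`).
#' @export
mantel_by_feeding <- function(tree, table, feeding, n_perm = 10000,
                              seed = 1L, min_n = 3) {
  stopifnot(inherits(table, "measurement_table"))
  dmol <- patristic_distances(tree)
  dmorph <- as.matrix(stats::dist(table$values[tree$tip.label, , drop = FALSE]))
  full <- mantel_test(dmol, dmorph, n_perm = n_perm,
                      seed = derive_seed(seed, "mantel:complete"))
  out <- data.frame(feeding = "complete", n = full$n, r = full$r,
                    p_value = full$p_value, stringsAsFactors = FALSE)
  for (tp in sort(unique(feeding[tree$tip.label]))) {
    members <- intersect(tree$tip.label, names(feeding)[feeding == tp])
    if (length(members) < min_n) {
      message(sprintf("feeding type '%s' has %d member(s) (< %d): skipped",
                      tp, length(members), min_n))
      next
    }
    mt <- mantel_test(dmol[members, members], dmorph[members, members],
                      n_perm = n_perm,
                      seed = derive_seed(seed, paste0("mantel:", tp)))
    out <- rbind(out, data.frame(feeding = tp, n = mt$n, r = mt$r,
                                 p_value = mt$p_value, stringsAsFactors = FALSE))
  }
  out
}
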