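test_that("PCA matches a direct eigendecomposition of the covariance", {
  # two traits with exact sample covariance diag(8/3, 2/3): fractions 0.8/0.2
  m <- matrix(c(2, -2, 0, 0, 0, 0, 1, -1), 4, 2,
              dimnames = list(paste0("s", 1:4), c("a", "b")))
  ord <- morpho_pca(log_table(m))
  expect_equal(ord$variance_fractions, c(0.8, 0.2), tolerance = 1e-12)

  set.seed(11)
  x <- matrix(rnorm(300 * 6), 300, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  dimnames(x) <- list(paste0("s", 1:300), paste0("tr", 1:6))
  ord2 <- morpho_pca(log_table(x))
  expect_equal(ord2$eigenvalues, eigen(cov(x), symmetric = TRUE)$values,
               tolerance = 1e-9)
})

test_that("PCA components are orthonormal and reconstruct centered data", {
  lg <- log_transform(random_raw_table(30, 20, seed = 12))
  ord <- morpho_pca(lg)
  expect_equal(crossprod(ord$loadings), diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  centered <- sweep(lg$values, 2, colMeans(lg$values))
  expect_equal(ord$scores %*% t(ord$loadings), centered, tolerance = 1e-8,
               ignore_attr = TRUE)
  # total variance conserved
  expect_equal(sum(ord$eigenvalues), sum(diag(cov(lg$values))),
               tolerance = 1e-10)
  # deterministic sign convention: dominant loading positive
  for (j in 1:20) {
    expect_gt(ord$loadings[which.max(abs(ord$loadings[, j])), j], 0)
  }
})

test_that("data on a line collapses to one retained component", {
  s <- rnorm(10)
  m <- outer(s, c(1, 2, -1)) + 5
  dimnames(m) <- list(paste0("s", 1:10), c("a", "b", "c"))
  ord <- morpho_pca(log_table(m))
  expect_equal(ord$retained, 1L)
  expect_equal(ord$variance_fractions[1], 1, tolerance = 1e-12)
  expect_error(morpho_pca(log_table(m * 0)), "zero total variance")
})

test_that("component retention follows the cumulative 95% rule", {
  fake <- function(fr) structure(list(variance_fractions = fr,
                                      threshold = 0.95), class = "ordination")
  expect_equal(retain_95(fake(c(0.96, 0.04))), 1L)
  expect_equal(retain_95(fake(c(0.5, 0.3, 0.15, 0.05))), 1:3)
  expect_equal(retain_95(fake(rep(1 / 20, 20))), 1:19)
})

test_that("PCA of BBPM output is confined to the shape subspace", {
  bb <- bbpm_correct(log_transform(random_raw_table(40, 8, seed = 5)))
  ord <- morpho_pca(bb)
  expect_lt(min(ord$eigenvalues), 1e-12)  # the isometric direction is gone
  a <- rep(1, 8) / sqrt(8)
  nonzero <- ord$eigenvalues > 1e-10
  expect_lt(max(abs(crossprod(a, ord$loadings[, nonzero]))), 1e-8)
})

test_that("ancestral states: cherry closed form and constant data", {
  tr <- read_newick("(A:2,B:0.5);")
  est <- ancestral_states(tr, c(A = 3, B = 1))
  expect_equal(unname(est), (3 / 2 + 1 / 0.5) / (1 / 2 + 1 / 0.5))
  tree <- fixture_dataset(12, seed = 6)$tree
  const <- setNames(rep(4.2, 12), tree$tip.label)
  expect_equal(unname(ancestral_states(tree, const)), rep(4.2, tree$Nnode),
               tolerance = 1e-9)
  expect_error(ancestral_states(tree, const[-1]), "mismatch")
})

test_that("ancestral states match the dense re-rooted GLS solve", {
  ds <- fixture_dataset(12, seed = 6)
  tree <- ds$tree
  x <- setNames(log10(ds$table$values[tree$tip.label, "MCL"]), tree$tip.label)
  est <- ancestral_states(tree, x)
  # oracle: for every internal node, root the covariance at that node via
  # node-to-tip path lengths and take the GLS mean
  dn <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  for (node in n + seq_len(tree$Nnode)) {
    dv <- dn[node, seq_len(n)]
    V <- outer(dv, dv, `+`) - dn[seq_len(n), seq_len(n)]
    V <- V / 2
    diag(V) <- dv
    Vi <- solve(V)
    ahat <- sum(Vi %*% x[tree$tip.label]) / sum(Vi)
    expect_equal(unname(est[as.character(node)]), unname(ahat),
                 tolerance = 1e-8)
  }
})

test_that("ancestral states are shift-equivariant", {
  ds <- fixture_dataset(12, seed = 6)
  x <- setNames(rnorm(12), ds$tree$tip.label)
  expect_equal(ancestral_states(ds$tree, x + 7),
               ancestral_states(ds$tree, x) + 7, tolerance = 1e-9)
})

test_that("phylomorphospace passes tip scores through and places the root", {
  # star tree: single ancestor at the GLS mean (= arithmetic mean here)
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  sc <- matrix(rnorm(12), 6, 2,
               dimnames = list(c("A", "B", "C", "D", "E", "F"), c("PC1", "PC2")))
  ord <- structure(list(scores = sc, variance_fractions = c(0.6, 0.4),
                        threshold = 0.95), class = "ordination")
  pm <- phylomorphospace(star, ord, axes = c(1, 2))
  tips <- pm$nodes[pm$nodes$type == "tip", ]
  expect_equal(as.matrix(tips[, c("PC1", "PC2")]),
               sc[tips$label, ], ignore_attr = TRUE)
  anc <- pm$nodes[pm$nodes$type == "ancestor", c("PC1", "PC2")]
  expect_equal(as.numeric(anc), colMeans(sc), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(phylomorphospace(star, ord, axes = c(1, 9)), "range")
})
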