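test_that("Mantel r is exact on identical and affine-related matrices", {
  d <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  expect_equal(mantel_test(d, d, n_perm = 9, seed = 1)$r, 1, tolerance = 1e-12)
  expect_equal(mantel_test(d, 2 * d + 3, n_perm = 9, seed = 1)$r, 1,
               tolerance = 1e-12)
  const <- d * 0 + 1; diag(const) <- 0
  expect_error(mantel_test(d, const, n_perm = 9), "constant")
})

test_that("exact Mantel p equals exhaustive permutation enumeration", {
  set.seed(31)
  d1 <- as.matrix(dist(rnorm(5)))
  d2 <- as.matrix(dist(rnorm(5)))
  res <- mantel_test(d1, d2, exact = TRUE)
  expect_equal(res$n_perm, 120L)
  # oracle: independent loop over all permutations of 1..5
  lt <- lower.tri(d1)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  r_all <- apply(perms, 1, function(p) cor(d1[lt], d2[p, p][lt]))
  r_obs <- cor(d1[lt], d2[lt])
  expect_equal(res$r, r_obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(r_all >= r_obs - 1e-12), tolerance = 1e-12)
})

test_that("Mantel statistic agrees with vegan and is symmetric", {
  skip_if_not_installed("vegan")
  set.seed(32)
  d1 <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  mine <- mantel_test(d1, d2, n_perm = 99, seed = 3)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mantel_test(d2, d1, n_perm = 9, seed = 1)$r, mine$r,
               tolerance = 1e-12)
})

test_that("Blomberg's K is exactly one on an equal-branch star tree", {
  star <- read_newick("(A:1.5,B:1.5,C:1.5,D:1.5,E:1.5,F:1.5,G:1.5,H:1.5);")
  set.seed(33)
  for (i in 1:3) {
    x <- setNames(rnorm(8), star$tip.label)
    expect_equal(blomberg_k(star, x, n_perm = 0)$K, 1, tolerance = 1e-12)
  }
})

test_that("Blomberg's K is invariant to affine trait transforms", {
  ds <- fixture_dataset(40, seed = 14)
  x <- trait_vec(bbpm_correct(log_transform(ds$table)), "MCL")
  k1 <- blomberg_k(ds$mol_tree, x, n_perm = 0)$K
  k2 <- blomberg_k(ds$mol_tree, 3.7 * x + 11, n_perm = 0)$K
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("Blomberg's K matches picante on the same data", {
  skip_if_not_installed("picante")
  ds <- fixture_dataset(40, seed = 14)
  tree <- ape::multi2di(ds$mol_tree)
  x <- trait_vec(log_transform(ds$table), "EL")
  mine <- blomberg_k(tree, x, n_perm = 0)$K
  ref <- picante::Kcalc(x[tree$tip.label], tree)
  expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
})

test_that("a deep clade split yields strong phylogenetic signal", {
  left <- paste0("(", paste0("L", 1:8, ":0.2", collapse = ","), ")")
  right <- paste0("(", paste0("R", 1:8, ":0.2", collapse = ","), ")")
  tree <- read_newick(paste0("(", left, ":5,", right, ":5);"))
  x <- setNames(rep(c(0, 1), each = 8), tree$tip.label)
  res <- blomberg_k(tree, x, n_perm = 199, seed = 4)
  expect_gt(res$K, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("PGLS reduces to OLS when the covariance is proportional to I", {
  star <- read_newick(paste0("(", paste0("t", 1:24, ":1", collapse = ","), ");"))
  set.seed(35)
  feeding <- setNames(rep(c("ANT", "HERB", "SAP"), 8), star$tip.label)
  y <- rnorm(24) + ifelse(feeding == "HERB", 1.5, 0)
  sc <- matrix(y, 24, 1, dimnames = list(star$tip.label, "PC1"))
  fit <- pgls_feeding(star, sc, feeding)
  ols <- lm(y ~ factor(feeding[star$tip.label]))
  expect_equal(unname(fit$coefficients$PC1), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$fits$adjusted_r2, summary(ols)$adj.r.squared,
               tolerance = 1e-6)
})

test_that("PGLS lambda estimate tracks phytools on BM-like data", {
  skip_if_not_installed("phytools")
  ds <- fixture_dataset(80, seed = 15)
  tree <- ds$tree
  x <- trait_vec(log_transform(ds$table), "MCL")
  # two-level dummy with no effect: the lambda profile is driven by x alone
  feeding <- setNames(rep(c("ANT", "HERB"), 40), tree$tip.label)
  sc <- matrix(x[tree$tip.label], ncol = 1,
               dimnames = list(tree$tip.label, "PC1"))
  fit <- pgls_feeding(tree, sc, feeding)
  ref <- phytools::phylosig(tree, x[tree$tip.label], method = "lambda")
  expect_equal(fit$fits$lambda_hat, ref$lambda, tolerance = 0.15)
})

test_that("PGLS validates its label inputs", {
  ds <- fixture_dataset(40, seed = 14)
  sc <- matrix(rnorm(40), 40, 1, dimnames = list(ds$tree$tip.label, "PC1"))
  one_level <- setNames(rep("ANT", 40), ds$tree$tip.label)
  expect_error(pgls_feeding(ds$tree, sc, one_level), "2 feeding levels")
  expect_error(pgls_feeding(ds$tree, sc[1:10, , drop = FALSE],
                            one_level), "missing")
})

test_that("subsampling at full clade size reproduces the unpruned K values", {
  ds <- fixture_dataset(60, seed = 7)
  bb <- bbpm_correct(log_transform(ds$table))
  focal <- ds$clades[[1]]
  res <- k_subsampling(ds$mol_tree, bb, focal, length(focal), seed = 2)
  full <- vapply(colnames(bb$values), function(tr)
    blomberg_k(ds$mol_tree, trait_vec(bb, tr), n_perm = 0)$K, numeric(1))
  got <- setNames(res$k_table$K, res$k_table$trait)
  expect_equal(got[names(full)], full, tolerance = 1e-9)
  expect_error(k_subsampling(ds$mol_tree, bb, focal, length(focal) + 1),
               "exceeds")
})

test_that("Mantel-by-feeding reports the complete row and skips tiny types", {
  ds <- fixture_dataset(60, seed = 7)
  bb <- bbpm_correct(log_transform(ds$table))
  feeding <- setNames(rep("HERB", 60), names(ds$feeding))
  feeding[1:2] <- "ANT"  # a type below the minimum membership
  expect_message(
    res <- mantel_by_feeding(ds$mol_tree, bb, feeding, n_perm = 99, seed = 3),
    "skipped")
  expect_equal(res$feeding[1], "complete")
  expect_equal(res$n[1], 60)
  expect_setequal(res$feeding, c("complete", "HERB"))
  expect_true(all(res$n[-1] >= 3))
})
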