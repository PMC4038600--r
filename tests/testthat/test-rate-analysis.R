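test_that("LS branch fitting recovers additive distances exactly", {
  ds <- fixture_dataset(12, seed = 6)
  tree <- ds$mol_tree
  d <- patristic_distances(tree)
  fit <- ls_branch_lengths(tree, d)
  bt <- branch_table(tree)
  root <- length(tree$tip.label) + 1L
  non_root <- bt$parent != root
  # all identifiable edges recovered; the two root-child edges are confounded
  # (only their sum enters any tip distance), so compare their sum
  expect_equal(fit$lengths[non_root], tree$edge.length[non_root],
               tolerance = 1e-8)
  expect_equal(sum(fit$lengths[!non_root]), sum(tree$edge.length[!non_root]),
               tolerance = 1e-8)
  expect_true(fit$rank_deficient)
  # fitted distances reproduce the input exactly
  pairs <- t(utils::combn(tree$tip.label, 2))
  expect_equal(fit$fitted, unname(d[pairs]), tolerance = 1e-8)
})

test_that("three-point star distances solve in closed form", {
  star <- read_newick("(A:9,B:9,C:9);")
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 5
  fit <- ls_branch_lengths(star, d)
  got <- setNames(fit$lengths, star$tip.label[star$edge[, 2]])
  expect_equal(got[c("A", "B", "C")], c(A = 1, B = 2, C = 3),
               tolerance = 1e-10)
  expect_false(fit$rank_deficient)
})

test_that("LS objective matches an independent least-squares solver", {
  ds <- fixture_dataset(15, seed = 8)
  tree <- ds$tree
  # a non-additive distance matrix: Euclidean distances between trait rows
  tab <- log_transform(ds$table)
  d <- as.matrix(dist(tab$values))
  fit <- ls_branch_lengths(tree, d)
  A <- path_incidence(tree)
  pairs <- t(utils::combn(tree$tip.label, 2))
  dv <- d[pairs]
  ref <- lm.fit(A, dv)
  rss_mine <- sum((A %*% fit$raw - dv)^2)
  expect_equal(rss_mine, sum(ref$residuals^2), tolerance = 1e-6)
  # clamping never reduces the attained objective
  expect_gte(fit$objective + 1e-12, rss_mine)
  expect_true(all(fit$lengths >= 0))
})

test_that("ratio outliers flag only extreme branches, per class", {
  ds <- fixture_dataset(42, seed = 10)
  tree <- ds$tree
  mol <- tree$edge.length
  # all ratios equal: nothing flagged
  prof <- rate_ratio_outliers(2 * mol, mol, tree)
  expect_true(all(prof$outlier == "none"))
  expect_equal(prof$ratio, rep(2, nrow(prof)), tolerance = 1e-12)
  # one internal branch at 100x the others is flagged high
  internal <- which(branch_table(tree)$class == "internal")
  morph <- 2 * mol
  morph[internal[5]] <- 200 * mol[internal[5]]
  set.seed(1)
  morph <- morph * exp(rnorm(length(morph), 0, 0.01))
  prof2 <- rate_ratio_outliers(morph, mol, tree)
  expect_equal(prof2$outlier[internal[5]], "high")
  # zero molecular length: undefined ratio, never flagged
  mol0 <- mol; mol0[internal[1]] <- 0
  prof3 <- rate_ratio_outliers(morph, mol0, tree)
  expect_true(is.na(prof3$ratio[internal[1]]))
  expect_equal(prof3$outlier[internal[1]], "none")
})

test_that("small branch classes are skipped with a notice", {
  tree <- simulate_tree(simulation_spec(n_tips = 8, seed = 3))
  expect_message(rate_ratio_outliers(tree$edge.length, tree$edge.length, tree),
                 "skipped")
})

test_that("independent contrasts follow the pruning recursion", {
  cherry <- read_newick("(A:1,B:1);")
  pic <- independent_contrasts(cherry, c(A = 3, B = 1))
  expect_equal(abs(unname(as.numeric(pic))), sqrt(2), tolerance = 1e-12)

  ds <- fixture_dataset(20, seed = 9)
  const <- setNames(rep(2, 20), ds$tree$tip.label)
  expect_equal(unname(as.numeric(independent_contrasts(ds$tree, const))),
               rep(0, 19), tolerance = 1e-12)
})

test_that("contrasts agree with ape::pic node by node", {
  ds <- fixture_dataset(25, seed = 12)
  tree <- ds$tree
  x <- trait_vec(log_transform(ds$table), "PTL")
  mine <- independent_contrasts(tree, x)
  ref <- ape::pic(x[tree$tip.label], tree)
  expect_equal(abs(as.numeric(mine[names(ref)])), abs(as.numeric(ref)),
               tolerance = 1e-8)
})

test_that("contrast sets are invariant to tip order and trait shifts", {
  ds <- fixture_dataset(18, seed = 11)
  tree <- ds$tree
  x <- trait_vec(log_transform(ds$table), "EH")
  c1 <- independent_contrasts(tree, x)
  c2 <- independent_contrasts(tree, x[sample(names(x))])
  expect_equal(as.numeric(c1), as.numeric(c2), tolerance = 1e-12)
  c3 <- independent_contrasts(tree, x + 5)
  expect_equal(as.numeric(c1), as.numeric(c3), tolerance = 1e-10)
})

test_that("multivariate rates are contrast-vector norms with node depths", {
  ds <- fixture_dataset(16, seed = 13)
  tree <- ds$tree
  tab <- log_transform(ds$table)
  one <- tab; one$values <- tab$values[, "MCL", drop = FALSE]
  rates1 <- multivariate_rates(tree, one)
  pic1 <- independent_contrasts(rescale_root_age(tree, 1),
                                trait_vec(tab, "MCL"))
  expect_equal(rates1$rates$rate, abs(as.numeric(pic1)), tolerance = 1e-10)
  # duplicated trait: rate scales by sqrt(2)
  two <- tab; two$values <- cbind(MCL = tab$values[, "MCL"],
                                  MCL2 = tab$values[, "MCL"])
  rownames(two$values) <- rownames(tab$values)
  rates2 <- multivariate_rates(tree, two)
  expect_equal(rates2$rates$rate, sqrt(2) * rates1$rates$rate,
               tolerance = 1e-10)
  # depths are times before present in [0, 1]
  expect_true(all(rates1$rates$depth >= -1e-9 & rates1$rates$depth <= 1 + 1e-9))
})

test_that("size-only divergence collapses after correction", {
  spec <- simulation_spec(n_tips = 40, seed = 19, size_sd = 0.5,
                          shape_rate = 1e-6, measurement_error_sd = 0,
                          rate_shifts = list(), focal_shift = NULL)
  tree <- simulate_tree(spec)
  tab <- log_transform(simulate_traits(tree, spec)$table)
  rp <- rate_pipeline(tree, tree, tab)
  total_uncorr <- sum(rp$uncorrected$fit$lengths)
  total_corr <- sum(rp$corrected$fit$lengths)
  expect_lt(total_corr, 0.2 * total_uncorr)
})
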