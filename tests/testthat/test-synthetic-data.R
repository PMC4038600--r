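test_that("tree simulation is deterministic and ultrametric at height 1", {
  spec <- simulation_spec(n_tips = 30, seed = 5)
  t1 <- simulate_tree(spec)
  t2 <- simulate_tree(spec)
  expect_identical(write_newick(t1), write_newick(t2))
  depths <- ape::node.depth.edgelength(t1)[1:30]
  expect_equal(unname(depths), rep(1, 30), tolerance = 1e-9)
  expect_equal(t1$Nnode, 29L)  # binary pure-birth: n - 1 internal nodes

  cherry <- simulate_tree(simulation_spec(n_tips = 2, seed = 1))
  expect_equal(sort(cherry$edge.length), c(1, 1))
})

test_that("error-free reported measurements equal the latent values", {
  spec <- simulation_spec(n_tips = 12, seed = 3, measurement_error_sd = 0)
  tree <- simulate_tree(spec)
  tr <- simulate_traits(tree, spec, clades = list(focal = tree$tip.label[1:4]))
  expect_equal(log10(tr$table$values), tr$latent, tolerance = 1e-12)
})

test_that("replicate averaging shrinks measurement error as 1/sqrt(repeats)", {
  spec1 <- simulation_spec(n_tips = 80, seed = 4, measurement_error_sd = 0.2,
                           n_repeats = 1, rate_shifts = list(),
                           focal_shift = NULL)
  spec5 <- simulation_spec(n_tips = 80, seed = 4, measurement_error_sd = 0.2,
                           n_repeats = 25, rate_shifts = list(),
                           focal_shift = NULL)
  tree <- simulate_tree(spec1)
  r1 <- simulate_traits(tree, spec1)
  r5 <- simulate_traits(tree, spec5)
  e1 <- log10(r1$table$values) - r1$latent
  e5 <- log10(r5$table$values) - r5$latent
  expect_lt(abs(sd(e1) - 0.2), 0.02)
  expect_lt(abs(sd(e5) - 0.2 / 5), 0.01)
})

test_that("a dominant size factor drives PC1 of the uncorrected data", {
  spec <- simulation_spec(n_tips = 60, seed = 8, size_sd = 0.5,
                          shape_rate = 1e-4, rate_shifts = list(),
                          focal_shift = NULL)
  tree <- simulate_tree(spec)
  tab <- log_transform(simulate_traits(tree, spec)$table)
  expect_gt(impact_of_size(tab), 0.95)
})

test_that("the focal jump shifts the focal trait by the stated offset", {
  spec <- simulation_spec(n_tips = 50, seed = 9, size_sd = 0,
                          shape_rate = 1e-8, measurement_error_sd = 0,
                          rate_shifts = list(),
                          focal_shift = list(clade = "focal", trait = "MCL",
                                             offset = 0.3))
  tree <- simulate_tree(spec)
  clades <- pick_clades(tree, 3)
  clades$focal <- clades[[1]]
  tr <- simulate_traits(tree, spec, clades = clades)
  inside <- rownames(tr$latent) %in% clades$focal
  gap <- mean(tr$latent[inside, "MCL"]) - mean(tr$latent[!inside, "MCL"])
  expect_equal(gap, 0.3, tolerance = 0.01)
  # other traits unaffected
  gap_other <- mean(tr$latent[inside, "EL"]) - mean(tr$latent[!inside, "EL"])
  expect_lt(abs(gap_other), 0.01)
})

test_that("unknown clade references are rejected", {
  spec <- simulation_spec(n_tips = 10, seed = 1,
                          rate_shifts = list(list(clade = "nope", mult = 2)),
                          focal_shift = NULL)
  tree <- simulate_tree(spec)
  expect_error(simulate_traits(tree, spec), "nope")
})

test_that("molecular-tree noise has the configured log-scale SD", {
  spec0 <- simulation_spec(n_tips = 40, seed = 2, molecular_noise_sd = 0)
  tree <- simulate_tree(spec0)
  expect_identical(write_newick(simulate_molecular_tree(tree, spec0)),
                   write_newick(tree))
  spec <- simulation_spec(n_tips = 500, seed = 2, molecular_noise_sd = 0.5)
  big <- simulate_tree(spec)
  mol <- simulate_molecular_tree(big, spec)
  lr <- log(mol$edge.length / big$edge.length)
  expect_lt(abs(sd(lr) - 0.5), 0.06)
  # additivity still holds on the perturbed lengths
  A <- path_incidence(mol)
  pairs <- t(utils::combn(mol$tip.label, 2))
  expect_equal(as.numeric(A %*% mol$edge.length),
               patristic_distances(mol)[pairs], tolerance = 1e-9)
})

test_that("labels cover every tip and track clades up to the convergence knob", {
  ds <- fixture_dataset(60, seed = 7)
  tree <- ds$tree
  clades <- ds$clades
  labs0 <- assign_labels(tree, clades, convergent_fraction = 0, seed = 1)
  expect_setequal(names(labs0$group), tree$tip.label)
  expect_false(anyNA(labs0$feeding))
  # zero convergence: feeding constant within every clade
  for (nm in names(clades)) {
    expect_equal(length(unique(labs0$feeding[clades[[nm]]])), 1L)
  }
  # full convergence: feeding independent of clade
  spec <- simulation_spec(n_tips = 300, seed = 21)
  big <- simulate_tree(spec)
  big_clades <- pick_clades(big, 5)
  labs1 <- assign_labels(big, big_clades, convergent_fraction = 1, seed = 2)
  tab <- table(labs1$group, labs1$feeding)
  suppressWarnings(p <- chisq.test(tab)$p.value)
  expect_gt(p, 1e-4)
  # overlapping clades rejected
  expect_error(assign_labels(tree, list(a = clades[[1]], b = clades[[1]][1])),
               "overlap")
})

test_that("pure-BM contrasts are standard normal at the simulated rate", {
  spec <- simulation_spec(n_tips = 150, seed = 13, size_sd = 0,
                          shape_rate = 1, measurement_error_sd = 0,
                          rate_shifts = list(), focal_shift = NULL)
  tree <- simulate_tree(spec)
  tr <- simulate_traits(tree, spec)
  pics <- independent_contrasts(tree, trait_vec(tr$table, "MCL") |> log10())
  expect_equal(mean(pics^2), 1, tolerance = 0.35)
  expect_gt(shapiro.test(as.numeric(pics))$p.value, 0.01)
})
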