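# Synthetic-data generator: pure-birth trees, multivariate Brownian trait
# evolution with a dominant isometric size factor, clade rate shifts, a
# directional jump on one focal trait, replicated measurement error, and
# clade-aligned group/feeding labels with a convergence knob.
#
# The defaults emulate the study conditions of the chafer body-shape data:
# 182 specimens, 20 traits, measurements repeated 5 times and averaged, a
# size factor dominant enough that PC1 of the uncorrected log10 data explains
# roughly 82-90% of variance, and a focal-clade increase of metacoxal length
# (MCL) with a moderately elevated shape rate inside that clade.

# plausible adult-chafer dimensions (mm) used as the log-scale baseline
default_baseline_mm <- function(traits) {
  base <- c(BH = 6, EH = 5.5, EL = 12, Eld = 10, Elmb = 8, EW = 8, Ewb = 7,
            PL = 4.5, PW = 7, ED = 1.5, HW = 4, IOD = 2.5, MCL = 3, MFL = 4,
            MFW = 1.2, MTL = 5, MTW = 1.1, PFL = 3.5, PFW = 1, PTL = 4)
  out <- base[traits]
  out[is.na(out)] <- 5
  names(out) <- traits
  out
}

#' Specify a synthetic morphometric data set
#'
#' Bundles every parameter of the generator: tree shape, the shared isometric
#' size factor, the shape rate matrix with optional clade-specific
#' multipliers, an optional directional jump of one focal trait on one
#' branch, the replicated measurement-error model, and the molecular-rate
#' noise that decouples the "molecular" tree from the time tree.
#'
#' @param n_tips number of tips / specimens (default 182).
#' @param birth_rate pure-birth speciation rate (default 1; the tree is
#'   rescaled to root age 1, so this only matters jointly with `n_tips`).
#' @param trait_names trait panel (default [chafer_traits()]).
#' @param baseline_mm named vector of per-trait baseline sizes in mm at the
#'   root (default: plausible chafer dimensions; synthetic stand-ins, the
#'   real specimen means are not available).
#' @param size_sd standard deviation, at root age 1, of the shared isometric
#'   size Brownian factor on the log10 scale (default 0.35).
#' @param shape_rate either a scalar per-trait Brownian variance at root age
#'   1 for log10 shape deviations (default 0.011), or a symmetric
#'   positive-semidefinite rate matrix of dimension `length(trait_names)`.
#' @param rate_shifts list of `list(clade = , mult = )` entries; `mult > 0`
#'   scales the shape rate matrix on every branch inside the (crown) clade.
#'   `clade` is a vector of tip labels (the clade is their MRCA subtree), an
#'   internal node number, or the keyword `"focal"` resolved by
#'   [simulate_dataset()].
#' @param focal_shift `NULL` or `list(clade = , trait = , offset = )`: adds
#'   `offset` (log10 units) to one trait on the stem branch of the clade, so
#'   every descendant inherits the jump — the metacoxal-length analogue.
#' @param measurement_error_sd per-repeat additive log10 measurement error SD
#'   (default 0.01).
#' @param n_repeats number of replicate measurements averaged per specimen
#'   (default 5).
#' @param molecular_noise_sd SD of the log-normal multiplicative perturbation
#'   applied per branch to build the molecular tree (default 0.3).
#' @param convergent_fraction fraction of tips whose feeding type is
#'   reassigned away from their clade's type (default 0.15).
#' @param seed integer master seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_tips = 182, birth_rate = 1,
                            trait_names = chafer_traits(),
                            baseline_mm = default_baseline_mm(trait_names),
                            size_sd = 0.35, shape_rate = 0.011,
                            rate_shifts = list(list(clade = "focal", mult = 3)),
                            focal_shift = list(clade = "focal", trait = "MCL",
                                               offset = 0.5),
                            measurement_error_sd = 0.01, n_repeats = 5,
                            molecular_noise_sd = 0.3,
                            convergent_fraction = 0.15, seed = 1L) {
  stopifnot(n_tips >= 2, birth_rate > 0, n_repeats >= 1,
            measurement_error_sd >= 0, molecular_noise_sd >= 0,
            size_sd >= 0, convergent_fraction >= 0, convergent_fraction <= 1)
  p <- length(trait_names)
  if (is.matrix(shape_rate)) {
    if (!isSymmetric(unname(shape_rate)) || nrow(shape_rate) != p)
      stopf("shape_rate matrix must be symmetric %d x %d", p, p)
    if (min(eigen(shape_rate, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stopf("shape_rate matrix must be positive semidefinite")
  } else {
    stopifnot(length(shape_rate) == 1L, shape_rate >= 0)
  }
  for (sh in rate_shifts) {
    if (is.null(sh$clade) || is.null(sh$mult) || sh$mult <= 0)
      stopf("each rate shift needs a clade and a positive mult")
  }
  if (!is.null(focal_shift)) {
    stopifnot(!is.null(focal_shift$clade), is.character(focal_shift$trait),
              is.numeric(focal_shift$offset))
    if (!focal_shift$trait %in% trait_names)
      stopf("focal trait '%s' is not in the trait panel", focal_shift$trait)
  }
  baseline_mm <- baseline_mm[trait_names]
  if (anyNA(baseline_mm) || any(baseline_mm <= 0))
    stopf("baseline_mm must be positive for every trait")
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 trait_names = trait_names, baseline_mm = baseline_mm,
                 size_sd = size_sd, shape_rate = shape_rate,
                 rate_shifts = rate_shifts, focal_shift = focal_shift,
                 measurement_error_sd = measurement_error_sd,
                 n_repeats = as.integer(n_repeats),
                 molecular_noise_sd = molecular_noise_sd,
                 convergent_fraction = convergent_fraction,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0("<simulation_spec> %d tips, %d traits, size_sd=%g, ",
                     "error_sd=%g x %d repeats, seed=%d\n"),
              x$n_tips, length(x$trait_names), x$size_sd,
              x$measurement_error_sd, x$n_repeats, x$seed))
  invisible(x)
}

#' Simulate a pure-birth (Yule) time tree
#'
#' Conditioned on the number of tips and rescaled to root age 1, so tips are
#' specimens `t1..tN` at depth exactly 1.
#'
#' @param spec a `simulation_spec`.
#' @param seed optional seed overriding `spec$seed`.
#' @return An ultrametric `phylo` object of height 1.
#' @export
simulate_tree <- function(spec, seed = NULL) {
  seed <- seed %||% derive_seed(spec$seed, "tree")
  tr <- with_seed(seed, ape::rphylo(spec$n_tips, birth = spec$birth_rate,
                                    death = 0))
  tr$tip.label <- paste0("t", seq_len(spec$n_tips))
  rescale_root_age(tr, 1)
}

# resolve a clade reference (tip-label vector, node number, or name into
# `clades`) to the MRCA node number
clade_node <- function(tree, ref, clades = NULL) {
  if (is.numeric(ref)) {
    node <- as.integer(ref)
    n_tip <- length(tree$tip.label)
    if (node < 1 || node > n_tip + tree$Nnode)
      stopf("clade node %d not found in tree", node)
    return(node)
  }
  ref <- as.character(ref)
  if (length(ref) == 1L && !ref %in% tree$tip.label) {
    if (is.null(clades) || is.null(clades[[ref]]))
      stopf("clade identifier '%s' not found in tree", ref)
    ref <- clades[[ref]]
  }
  unknown <- setdiff(ref, tree$tip.label)
  if (length(unknown))
    stopf("clade tip label(s) not in tree: %s", paste(unknown, collapse = ", "))
  if (length(ref) == 1L) return(match(ref, tree$tip.label))
  ape::getMRCA(tree, ref)
}

# tip labels descending from a node (the node itself when it is a tip)
node_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tree$tip.label[ape::prop.part(tree)[[node - n_tip]]]
}

#' All descendant node ids of a node
#'
#' Tips and internal nodes below `node`, excluding the node itself.
#'
#' @param tree a `phylo` object.
#' @param node internal node id (or tip id, giving an empty result).
#' @return Integer vector of node ids.
#' @export
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1L] == node, 2L]
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, nd)
    stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
  }
  out
}

#' Edges belonging to a clade
#'
#' Logical over the tree's edges: `TRUE` for crown branches of the clade
#' rooted at `node` (optionally including its stem branch). This is the
#' membership used by clade rate shifts.
#'
#' @param tree a `phylo` object.
#' @param node the clade's MRCA node id.
#' @param include_stem also mark the branch subtending the clade.
#' @return Logical vector over edge indices.
#' @export
edges_in_clade <- function(tree, node, include_stem = FALSE) {
  inside <- tree$edge[, 2L] %in% descendant_nodes(tree, node)
  if (include_stem) inside <- inside | tree$edge[, 2L] == node
  inside
}

shape_rate_matrix <- function(spec) {
  p <- length(spec$trait_names)
  if (is.matrix(spec$shape_rate)) spec$shape_rate else diag(spec$shape_rate, p)
}

#' Simulate trait measurements on a tree
#'
#' Each tip's log10 trait vector is `baseline + s * 1 + shape (+ focal
#' jump)`, with `s` a univariate Brownian size factor and `shape` a
#' multivariate Brownian realization whose rate matrix is scaled by the clade
#' multipliers of `spec$rate_shifts`. The reported table averages
#' `n_repeats` noisy log10 replicates per cell and back-transforms to mm; the
#' error-free latent values are returned for oracle checks.
#'
#' @param tree an ultrametric `phylo` (tips are the specimens).
#' @param spec a `simulation_spec`.
#' @param clades optional named list of tip-label vectors used to resolve
#'   named clade references in `rate_shifts` / `focal_shift`.
#' @param seed optional seed overriding the spec-derived stream.
#' @return A list with `table` (a raw-mm `measurement_table`), `latent`
#'   (error-free log10 matrix), and `size` (the per-tip size factor).
#' @export
simulate_traits <- function(tree, spec, clades = NULL, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  ultrametric_height(tree, tol = 1e-6)
  seed <- seed %||% derive_seed(spec$seed, "traits")
  p <- length(spec$trait_names)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  R <- shape_rate_matrix(spec)
  eg <- eigen(R, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p)  # R = L L'

  mult <- rep(1, nrow(tree$edge))
  for (sh in spec$rate_shifts) {
    node <- clade_node(tree, sh$clade, clades)
    mult[edges_in_clade(tree, node)] <- mult[edges_in_clade(tree, node)] * sh$mult
  }
  jump <- rep(0, nrow(tree$edge))
  focal_trait_idx <- NA_integer_
  if (!is.null(spec$focal_shift)) {
    node <- clade_node(tree, spec$focal_shift$clade, clades)
    stem <- which(tree$edge[, 2L] == node)
    if (!length(stem)) stopf("focal branch not found (clade node is the root)")
    jump[stem] <- spec$focal_shift$offset
    focal_trait_idx <- match(spec$focal_shift$trait, spec$trait_names)
  }

  pre <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  with_seed(seed, {
    s <- numeric(n_node)
    shp <- matrix(0, n_node, p)
    for (k in seq_len(nrow(pre$edge))) {
      e <- ord[k]
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      s[ch] <- s[par] + stats::rnorm(1, 0, spec$size_sd * sqrt(len))
      shp[ch, ] <- shp[par, ] + sqrt(len * mult[e]) * as.numeric(L %*% stats::rnorm(p))
      if (jump[e] != 0) shp[ch, focal_trait_idx] <- shp[ch, focal_trait_idx] + jump[e]
    }
    latent <- sweep(shp[seq_len(n_tip), , drop = FALSE] + s[seq_len(n_tip)],
                    2L, log10(spec$baseline_mm), `+`)
    dimnames(latent) <- list(tree$tip.label, spec$trait_names)
    reported <- latent
    if (spec$measurement_error_sd > 0) {
      err <- matrix(stats::rnorm(n_tip * p, 0,
                                 spec$measurement_error_sd / sqrt(spec$n_repeats)),
                    n_tip, p)
      reported <- latent + err
    }
    list(table = measurement_table(10^reported, "raw_mm"),
         latent = latent,
         size = stats::setNames(s[seq_len(n_tip)], tree$tip.label))
  })
}

#' Perturb branch lengths to form a "molecular" tree
#'
#' Multiplies every branch length by an independent log-normal factor
#' `exp(N(0, molecular_noise_sd^2))`, decoupling molecular rates from time
#' while keeping the topology (and hence additivity) intact.
#'
#' @param tree a `phylo` object.
#' @param spec a `simulation_spec`.
#' @param seed optional seed.
#' @return A `phylo` object with perturbed branch lengths.
#' @export
simulate_molecular_tree <- function(tree, spec, seed = NULL) {
  seed <- seed %||% derive_seed(spec$seed, "molecular")
  if (spec$molecular_noise_sd == 0) return(tree)
  with_seed(seed, {
    tree$edge.length <- tree$edge.length *
      exp(stats::rnorm(length(tree$edge.length), 0, spec$molecular_noise_sd))
    tree
  })
}

#' Choose disjoint reference clades on a tree
#'
#' Greedy deterministic selection of non-overlapping clades (largest first,
#' capped at a fraction of the tips) used to define lineage groups; the first
#' (largest) clade is the focal, species-rich lineage analogue.
#'
#' @param tree a `phylo` object.
#' @param n_clades maximum number of clades (default 6).
#' @param min_size smallest acceptable clade (default 3 tips).
#' @param max_frac largest acceptable clade as a fraction of tips (default 0.4).
#' @return Named list (`clade1` the largest, ...) of tip-label vectors.
#' @export
pick_clades <- function(tree, n_clades = 6, min_size = 3, max_frac = 0.4) {
  n_tip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  ord <- order(sizes, decreasing = TRUE)
  chosen <- list()
  used <- integer(0)
  for (i in ord) {
    if (length(chosen) >= n_clades) break
    if (sizes[i] < min_size || sizes[i] > max_frac * n_tip) next
    if (length(intersect(parts[[i]], used))) next
    chosen[[length(chosen) + 1L]] <- tree$tip.label[parts[[i]]]
    used <- c(used, parts[[i]])
  }
  if (!length(chosen)) stopf("no clade satisfies the size constraints")
  names(chosen) <- paste0("clade", seq_along(chosen))
  chosen
}

#' Feeding-type levels
#'
#' ANT anthophilous, COP coprophagous, HERB herbivorous, SFU sap/fluid
#' utilizers, NF non-feeding, SAP saprophagous.
#'
#' @return Character vector of the six feeding types.
#' @export
feeding_types <- function() c("ANT", "COP", "HERB", "SFU", "NF", "SAP")

#' Assign lineage groups and feeding types to tips
#'
#' Each tip's group is its containing clade (or `"other"`); feeding types are
#' assigned per clade by cycling through the six levels, then a stated
#' fraction of tips is reassigned to a type drawn uniformly at random
#' (possibly its own) — the convergence knob emulating repeated independent
#' origins of feeding habits: at 1 the labels are independent of the clades.
#'
#' @param tree a `phylo` object.
#' @param clades named list of disjoint tip-label vectors
#'   (see [pick_clades()]).
#' @param convergent_fraction fraction of tips reassigned (0 = feeding
#'   perfectly nested in clades, 1 = independent of clade).
#' @param seed integer seed for the reassignment draw.
#' @return A list with named character vectors `group` and `feeding`
#'   (one entry per tip).
#' @export
assign_labels <- function(tree, clades, convergent_fraction = 0, seed = 1L) {
  tips <- tree$tip.label
  all_members <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- all_members[duplicated(all_members)][1]
    stopf("clades overlap (tip '%s' occurs in more than one)", dup)
  }
  unknown <- setdiff(all_members, tips)
  if (length(unknown)) stopf("clade tip(s) not in tree: %s",
                             paste(unknown, collapse = ", "))
  group <- stats::setNames(rep("other", length(tips)), tips)
  for (nm in names(clades)) group[clades[[nm]]] <- nm
  types <- feeding_types()
  clade_type <- stats::setNames(types[(seq_along(clades) - 1L) %% length(types) + 1L],
                                names(clades))
  feeding <- ifelse(group == "other", types[length(clades) %% length(types) + 1L],
                    clade_type[group])
  names(feeding) <- tips
  if (convergent_fraction > 0) {
    feeding <- with_seed(seed, {
      k <- round(convergent_fraction * length(tips))
      if (k > 0) {
        switchers <- sample(tips, k)
        feeding[switchers] <- sample(types, k, replace = TRUE)
      }
      feeding
    })
  }
  list(group = group, feeding = feeding)
}

#' Simulate a complete analysis-ready data set
#'
#' Runs the whole generator under one master seed: time tree, reference
#' clades (resolving `"focal"` references to the largest clade), trait
#' table, molecular tree, and group/feeding labels.
#'
#' @param spec a `simulation_spec`.
#' @param n_clades,min_size,max_frac passed to [pick_clades()].
#' @return A list: `spec`, `tree` (ultrametric, height 1), `mol_tree`,
#'   `table` (raw mm), `latent`, `size`, `clades`, `focal_clade` (name),
#'   `group`, `feeding`.
#' @export
simulate_dataset <- function(spec = simulation_spec(), n_clades = 6,
                             min_size = 3, max_frac = 0.4) {
  tree <- simulate_tree(spec)
  clades <- pick_clades(tree, n_clades, min_size, max_frac)
  clades[["focal"]] <- clades[[1L]]
  tr <- simulate_traits(tree, spec, clades = clades)
  mol <- simulate_molecular_tree(tree, spec)
  labs <- assign_labels(tree, clades[names(clades) != "focal"],
                        convergent_fraction = spec$convergent_fraction,
                        seed = derive_seed(spec$seed, "labels"))
  list(spec = spec, tree = tree, mol_tree = mol, table = tr$table,
       latent = tr$latent, size = tr$size,
       clades = clades[names(clades) != "focal"], focal_clade = "clade1",
       group = labs$group, feeding = labs$feeding)
}
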