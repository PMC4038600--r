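# Shared fixtures, built in code. Trees come from the package's own
# generator; tables are constructed per test where exact values matter.

# small ultrametric tree + traits, memoized per (n_tips, seed) so several
# tests can share one simulation without re-running it
.fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function(n_tips = 60, seed = 7, ...) {
  key <- paste(n_tips, seed, length(list(...)), sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    spec <- simulation_spec(n_tips = n_tips, seed = seed, ...)
    # relax clade-size constraints on small trees so clades always exist
    .fixture_cache[[key]] <- simulate_dataset(
      spec, min_size = if (n_tips < 30) 2 else 3,
      max_frac = if (n_tips < 30) 0.6 else 0.4)
  }
  .fixture_cache[[key]]
}

# a tip-labeled trait vector from a table column
trait_vec <- function(table, trait) {
  stats::setNames(table$values[, trait], rownames(table$values))
}

# wrap an arbitrary numeric matrix as a log10-state table
log_table <- function(m) {
  tab <- measurement_table(matrix(1, nrow(m), ncol(m), dimnames = dimnames(m)),
                           "raw_mm")
  tab$values <- m
  tab$state <- "log10"
  tab
}

# random raw-mm table, n specimens x p traits (log-uniform spread)
random_raw_table <- function(n, p = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(10^runif(n * p, -0.5, 1.5), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("tr", seq_len(p))))
  measurement_table(m, "raw_mm")
}

# brute-force patristic distance between two tips: enumerate the root-to-tip
# edge paths and symmetric-difference their lengths (independent of the
# implementation's cophenetic route)
brute_patristic <- function(tree) {
  n <- length(tree$tip.label)
  parent_of <- function(node) {
    k <- which(tree$edge[, 2] == node)
    if (length(k)) tree$edge[k, 1] else NA_integer_
  }
  path_edges <- function(tip) {
    out <- integer(0); node <- tip
    repeat {
      k <- which(tree$edge[, 2] == node)
      if (!length(k)) break
      out <- c(out, k); node <- tree$edge[k, 1]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- intersect(paths[[i]], paths[[j]])
    d[i, j] <- d[j, i] <- sum(tree$edge.length[setdiff(paths[[i]], shared)]) +
      sum(tree$edge.length[setdiff(paths[[j]], shared)])
  }
  d
}
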