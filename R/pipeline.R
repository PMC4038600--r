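# End-to-end driver: one configuration in, every table of the analysis out,
# fully deterministic under the master seed.

#' Build a run configuration
#'
#' Either supply file paths (`tree_file`, `mol_tree_file`,
#' `measurements_file`, optional `groups_file` / `feeding_file` as 2-column
#' CSVs) or a [simulation_spec()] from which a synthetic data set is
#' generated. All analysis thresholds live here with their conventional
#' defaults.
#'
#' @param out_dir output directory (created if absent).
#' @param spec a `simulation_spec`, or `NULL` when files are given.
#' @param tree_file,mol_tree_file,measurements_file,groups_file,feeding_file
#'   input paths (ignored when `spec` is given).
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param n_perm_permanova,n_perm_mantel,n_perm_k permutation counts
#'   (defaults 9999, 10000, 999).
#' @param retain_threshold cumulative variance retained (default 0.95).
#' @param alpha significance level (default 0.05).
#' @param focal_trait trait tracked in subsampling and reconstruction
#'   (default `"MCL"`).
#' @param subsample_sizes focal-clade sizes for the K sensitivity analysis;
#'   `NULL` picks a decreasing ladder down to 3.
#' @param outlier_method `"percentile"` or `"normal"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, spec = NULL, tree_file = NULL,
                       mol_tree_file = NULL, measurements_file = NULL,
                       groups_file = NULL, feeding_file = NULL, seed = 1L,
                       n_perm_permanova = 9999, n_perm_mantel = 10000,
                       n_perm_k = 999, retain_threshold = 0.95, alpha = 0.05,
                       focal_trait = "MCL", subsample_sizes = NULL,
                       outlier_method = c("percentile", "normal")) {
  if (is.null(spec) && (is.null(tree_file) || is.null(measurements_file)))
    stopf("either a simulation spec or tree + measurement files are required")
  structure(list(out_dir = out_dir, spec = spec, tree_file = tree_file,
                 mol_tree_file = mol_tree_file,
                 measurements_file = measurements_file,
                 groups_file = groups_file, feeding_file = feeding_file,
                 seed = as.integer(seed), n_perm_permanova = n_perm_permanova,
                 n_perm_mantel = n_perm_mantel, n_perm_k = n_perm_k,
                 retain_threshold = retain_threshold, alpha = alpha,
                 focal_trait = focal_trait, subsample_sizes = subsample_sizes,
                 outlier_method = match.arg(outlier_method)),
            class = "run_config")
}

write_csv_out <- function(df, dir, name, log) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(log, path)
}

read_label_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Run the complete analysis
#'
#' Executes every stage on the configured inputs: log transform, both size
#' corrections, PCA with 95% retention and impact of size, phylomorphospace,
#' global and pairwise PERMANOVA per data state, LDA with leave-one-out CV,
#' PGLS of retained components on feeding types, Mantel tests (complete and
#' within feeding types), per-trait Blomberg's K with focal-clade
#' subsampling, least-squares morphometric branch lengths with ratio-outlier
#' screening, multivariate contrast rates, and ML ancestral reconstruction
#' of the focal trait. Writes all result tables as CSV (plus Newick trees)
#' into `out_dir`, with a manifest recording seed, exclusions and file
#' hashes; reruns with the same configuration are byte-identical.
#'
#' Lineages with a single member are excluded from PERMANOVA and LDA (with a
#' logged notice); stages needing feeding labels are skipped when none are
#' configured.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every intermediate result.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  notices <- character(0)
  note <- function(msg) {
    message(msg)
    notices <<- c(notices, msg)
    invisible(NULL)
  }

  ## ---- inputs ----
  if (!is.null(config$spec)) {
    ds <- simulate_dataset(config$spec)
    tree_time <- ds$tree; tree_mol <- ds$mol_tree
    table_raw <- ds$table; group <- ds$group; feeding <- ds$feeding
    focal_tips <- ds$clades[[ds$focal_clade]]
    write_newick(tree_time, file.path(config$out_dir, "tree_time.nwk"))
    write_newick(tree_mol, file.path(config$out_dir, "tree_molecular.nwk"))
    write_measurements(table_raw, file.path(config$out_dir, "measurements_raw.csv"))
    files <- c(files, file.path(config$out_dir,
                                c("tree_time.nwk", "tree_molecular.nwk",
                                  "measurements_raw.csv")))
    files <- write_csv_out(data.frame(specimen = names(group), group = group),
                           config$out_dir, "groups.csv", files)
    files <- write_csv_out(data.frame(specimen = names(feeding), feeding = feeding),
                           config$out_dir, "feeding.csv", files)
  } else {
    tree_time <- read_newick(config$tree_file)
    tree_mol <- if (!is.null(config$mol_tree_file))
      read_newick(config$mol_tree_file) else tree_time
    table_raw <- read_measurements(config$measurements_file)
    group <- if (!is.null(config$groups_file)) read_label_csv(config$groups_file)
             else NULL
    feeding <- if (!is.null(config$feeding_file)) read_label_csv(config$feeding_file)
               else NULL
    focal_tips <- NULL
  }
  ids <- rownames(table_raw$values)
  mism <- c(setdiff(tree_time$tip.label, ids), setdiff(ids, tree_time$tip.label))
  if (length(mism)) stopf("specimen ids differ between tree and table: %s",
                          paste(unique(mism), collapse = ", "))

  ## ---- transforms and corrections ----
  tab_log <- log_transform(table_raw)
  states <- list(uncorrected = tab_log, corrected_bbpm = bbpm_correct(tab_log),
                 corrected_regression = regression_correct(tab_log))
  for (nm in names(states)) {
    f <- file.path(config$out_dir, paste0("measurements_", nm, ".csv"))
    write_measurements(states[[nm]], f)
    files <- c(files, f)
  }
  size_impact <- impact_of_size(tab_log)

  ## ---- ordination ----
  ords <- lapply(states, morpho_pca, retain_threshold = config$retain_threshold)
  for (nm in names(ords)) {
    o <- ords[[nm]]
    files <- write_csv_out(data.frame(specimen = rownames(o$scores),
                                      o$scores, check.names = FALSE),
                           config$out_dir, paste0("pca_scores_", nm, ".csv"), files)
    files <- write_csv_out(data.frame(trait = rownames(o$loadings), o$loadings,
                                      check.names = FALSE),
                           config$out_dir, paste0("pca_loadings_", nm, ".csv"), files)
    files <- write_csv_out(data.frame(component = seq_along(o$variance_fractions),
                                      variance_fraction = o$variance_fractions,
                                      retained = seq_along(o$variance_fractions)
                                      <= o$retained),
                           config$out_dir, paste0("pca_variance_", nm, ".csv"), files)
  }

  ## ---- phylomorphospace (BBPM state, PCs 1-2) ----
  pms <- phylomorphospace(tree_mol, ords$corrected_bbpm, axes = c(1, 2))
  files <- write_csv_out(pms$nodes, config$out_dir,
                         "phylomorphospace_nodes.csv", files)

  ## ---- group tests ----
  perma <- list(); pairwise <- list(); lda <- list()
  if (!is.null(group)) {
    sizes <- table(group[ids])
    singletons <- names(sizes)[sizes < 2]
    if (length(singletons))
      note(sprintf("singleton group(s) excluded from PERMANOVA/LDA: %s",
                   paste(singletons, collapse = ", ")))
    keep <- ids[!group[ids] %in% singletons]
    for (nm in c("uncorrected", "corrected_bbpm", "corrected_regression")) {
      sc <- retained_scores(ords[[nm]])[keep, , drop = FALSE]
      g <- group[keep]
      perma[[nm]] <- permanova(sc, g, n_perm = config$n_perm_permanova,
                               seed = derive_seed(config$seed,
                                                  paste0("permanova:", nm)))
      pairwise[[nm]] <- pairwise_permanova(sc, g,
                                           n_perm = config$n_perm_permanova,
                                           seed = derive_seed(config$seed,
                                                              paste0("pair:", nm)),
                                           alpha = config$alpha)
      files <- write_csv_out(pairwise[[nm]], config$out_dir,
                             paste0("permanova_pairwise_", nm, ".csv"), files)
      k_use <- min(ncol(sc), nrow(sc) - length(unique(g)) - 1L)
      if (k_use < ncol(sc))
        note(sprintf("LDA (%s): retained components reduced from %d to %d",
                     nm, ncol(sc), k_use))
      lda[[nm]] <- lda_loocv(sc[, seq_len(k_use), drop = FALSE], g)
      files <- write_csv_out(lda[[nm]]$assignments, config$out_dir,
                             paste0("lda_loocv_", nm, ".csv"), files)
    }
    files <- write_csv_out(
      data.frame(state = names(perma),
                 pseudo_F = vapply(perma, `[[`, 0, "pseudo_F"),
                 p_value = vapply(perma, `[[`, 0, "p_value"),
                 lda_percent_correct = vapply(lda, `[[`, 0, "percent_correct")),
      config$out_dir, "group_tests_summary.csv", files)
  } else note("no group labels configured: PERMANOVA/LDA skipped")

  ## ---- feeding-type analyses ----
  pgls <- NULL; mantel_feed <- NULL
  if (!is.null(feeding)) {
    pgls <- lapply(list(uncorrected = ords$uncorrected,
                        corrected_bbpm = ords$corrected_bbpm),
                   function(o) pgls_feeding(tree_mol, o, feeding))
    files <- write_csv_out(
      do.call(rbind, lapply(names(pgls), function(nm)
        data.frame(state = nm, pgls[[nm]]$fits,
                   pooled_adjusted_r2 = pgls[[nm]]$pooled_adjusted_r2))),
      config$out_dir, "pgls_feeding.csv", files)
    mantel_feed <- mantel_by_feeding(tree_mol, states$corrected_bbpm, feeding,
                                     n_perm = config$n_perm_mantel,
                                     seed = derive_seed(config$seed, "mantel"))
    files <- write_csv_out(mantel_feed, config$out_dir,
                           "mantel_by_feeding.csv", files)
  } else note("no feeding labels configured: PGLS and Mantel-by-feeding skipped")

  ## ---- phylogenetic signal ----
  kt <- lapply(colnames(states$corrected_bbpm$values), function(trait)
    blomberg_k(tree_mol,
               stats::setNames(states$corrected_bbpm$values[, trait], ids),
               n_perm = config$n_perm_k,
               seed = derive_seed(config$seed, paste0("K:", trait))))
  k_table <- data.frame(trait = colnames(states$corrected_bbpm$values),
                        K = vapply(kt, `[[`, 0, "K"),
                        p_value = vapply(kt, `[[`, 0, "p_value"))
  files <- write_csv_out(k_table, config$out_dir, "blomberg_k.csv", files)

  ksub <- NULL
  if (!is.null(focal_tips) && length(focal_tips) >= 3 &&
      config$focal_trait %in% colnames(states$corrected_bbpm$values)) {
    sizes <- config$subsample_sizes %||%
      unique(pmax(3, round(length(focal_tips) * c(1, 0.5, 0.25, 0.1, 0))))
    sizes <- sort(unique(pmin(sizes, length(focal_tips))), decreasing = TRUE)
    ksub <- k_subsampling(tree_mol, states$corrected_bbpm, focal_tips,
                          sizes, focal_trait = config$focal_trait,
                          seed = derive_seed(config$seed, "ksub"))
    files <- write_csv_out(ksub$k_table, config$out_dir,
                           "k_subsampling.csv", files)
    files <- write_csv_out(ksub$focal_rank, config$out_dir,
                           "k_subsampling_focal_rank.csv", files)
  } else note("no focal clade configured: K subsampling skipped")

  ## ---- rates ----
  rp <- rate_pipeline(tree_mol, tree_time, tab_log,
                      method = config$outlier_method)
  for (nm in names(rp)) {
    files <- write_csv_out(rp[[nm]]$profile, config$out_dir,
                           paste0("rate_profile_", nm, ".csv"), files)
    files <- write_csv_out(rp[[nm]]$rates$rates, config$out_dir,
                           paste0("contrast_rates_", nm, ".csv"), files)
    f <- file.path(config$out_dir, paste0("tree_morph_", nm, ".nwk"))
    write_newick(rp[[nm]]$fit$tree, f)
    files <- c(files, f)
  }

  ## ---- ancestral reconstruction of the focal trait ----
  anc <- NULL
  if (config$focal_trait %in% colnames(states$corrected_bbpm$values)) {
    anc <- ancestral_states(tree_mol,
                            stats::setNames(states$corrected_bbpm$values[, config$focal_trait],
                                            ids))
    files <- write_csv_out(data.frame(node = as.integer(names(anc)),
                                      estimate = as.numeric(anc)),
                           config$out_dir,
                           paste0("ancestral_", config$focal_trait, ".csv"),
                           files)
  }

  ## ---- manifest ----
  summary_df <- data.frame(quantity = c("impact_of_size_pc1",
                                        "retained_components_bbpm"),
                           value = c(size_impact, ords$corrected_bbpm$retained))
  files <- write_csv_out(summary_df, config$out_dir, "summary.csv", files)
  manifest <- c(sprintf("package: morphorates %s",
                        as.character(utils::packageVersion("morphorates"))),
                sprintf("seed: %d", config$seed),
                sprintf("notices: %s",
                        if (length(notices)) paste(notices, collapse = " | ")
                        else "none"),
                "files:",
                sprintf("  %s %s", tools::md5sum(sort(files)),
                        basename(sort(files))))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

  invisible(list(tree_time = tree_time, tree_mol = tree_mol,
                 table_raw = table_raw, states = states, ordinations = ords,
                 impact_of_size = size_impact, phylomorphospace = pms,
                 permanova = perma, pairwise = pairwise, lda = lda,
                 pgls = pgls, mantel_by_feeding = mantel_feed,
                 blomberg_k = k_table, k_subsampling = ksub,
                 rates = rp, ancestral = anc, notices = notices,
                 files = sort(files)))
}
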