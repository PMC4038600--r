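# Permutation-based multivariate group tests on retained PC scores, and
# discriminant reassignment with leave-one-out cross-validation.

# all distinct label arrangements of a multiset (exact permutation null)
multiset_permutations <- function(labels, limit = 2e5) {
  labels <- as.character(labels)
  counts <- table(labels)
  n_arr <- factorial(length(labels)) / prod(factorial(counts))
  if (n_arr > limit) stopf("%.0f distinct arrangements exceed the limit", n_arr)
  lev <- names(counts)
  rec <- function(cnt, acc) {
    if (all(cnt == 0)) return(list(acc))
    out <- list()
    for (i in seq_along(cnt)) {
      if (cnt[i] > 0) {
        cnt2 <- cnt; cnt2[i] <- cnt2[i] - 1L
        out <- c(out, rec(cnt2, c(acc, lev[i])))
      }
    }
    out
  }
  do.call(rbind, rec(as.integer(counts), character(0)))
}

permanova_ss <- function(D2, M, n_g) {
  # within-group sum of squared distances / group size, via indicator algebra
  sum(diag(crossprod(M, D2 %*% M)) / (2 * n_g))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Euclidean-distance one-factor PERMANOVA: with `SS_total` the sum of all
#' squared pairwise distances divided by N and `SS_within` the analogous
#' within-group sums divided by group sizes,
#' `pseudo-F = (SS_between/(g-1)) / (SS_within/(N-g))`. Significance comes
#' from random relabelings with the +1 convention, or from complete
#' enumeration of all distinct relabelings when `exact = TRUE`.
#'
#' @param scores numeric matrix (specimens x retained components).
#' @param groups group labels, one per row of `scores`.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all distinct relabelings instead of sampling
#'   (feasible for small samples only).
#' @return A list of class `permanova`: `pseudo_F`, `p_value`, `n_perm`,
#'   `ss_between`, `ss_within`, `df` and group sizes.
#' @export
permanova <- function(scores, groups, n_perm = 9999, seed = NULL,
                      exact = FALSE) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(scores))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) stopf("group(s) with fewer than 2 members: %s",
                           paste(small, collapse = ", "))
  if (length(sizes) < 2) stopf("need at least 2 groups")
  n <- nrow(scores); g <- length(sizes)
  D2 <- as.matrix(stats::dist(scores))^2
  ss_total <- sum(D2) / (2 * n)
  M0 <- stats::model.matrix(~ groups - 1)
  n_g <- as.numeric(sizes[sub("^groups", "", colnames(M0))])
  ss_w <- permanova_ss(D2, M0, n_g)
  ss_b <- ss_total - ss_w
  f_obs <- (ss_b / (g - 1)) / (ss_w / (n - g))
  eps <- 1e-12 * max(1, abs(f_obs))
  if (exact) {
    arr <- multiset_permutations(groups)
    f_perm <- apply(arr, 1L, function(lb) {
      M <- stats::model.matrix(~ lb - 1)
      ssw <- permanova_ss(D2, M, as.numeric(table(lb)[sub("^lb", "", colnames(M))]))
      ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
    })
    p <- mean(f_perm >= f_obs - eps)
    n_perm <- nrow(arr)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      M <- M0[sample.int(n), , drop = FALSE]
      ssw <- permanova_ss(D2, M, n_g)
      ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
    }, numeric(1)))
    p <- (sum(f_perm >= f_obs - eps) + 1) / (n_perm + 1)
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_perm = n_perm,
                 ss_between = ss_b, ss_within = ss_w, ss_total = ss_total,
                 df = c(between = g - 1, within = n - g), sizes = sizes),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA with sequential Bonferroni (Holm) correction
#'
#' PERMANOVA for every unordered pair of groups; the Holm step-down
#' correction is applied to the full vector of raw p-values, and both raw
#' and corrected significance flags are reported (as in triangular
#' F-value tables that footnote "significant without sequential Bonferroni").
#' Each pair draws its permutations from a stream hashed from the master
#' seed and the pair name, so results do not depend on pair order.
#'
#' @inheritParams permanova
#' @param alpha significance level for the flags (default 0.05).
#' @return A data frame: `group1`, `group2`, `n1`, `n2`, `pseudo_F`, `p_raw`,
#'   `p_holm`, `sig_raw`, `sig_holm`.
#' @export
pairwise_permanova <- function(scores, groups, n_perm = 9999, seed = 1L,
                               alpha = 0.05) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) stopf("need at least 2 groups")
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    sel <- groups %in% c(g1, g2)
    fit <- permanova(scores[sel, , drop = FALSE], groups[sel], n_perm = n_perm,
                     seed = derive_seed(seed, paste("permanova", g1, g2, sep = "|")))
    data.frame(group1 = g1, group2 = g2,
               n1 = sum(groups == g1), n2 = sum(groups == g2),
               pseudo_F = fit$pseudo_F, p_raw = fit$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out$sig_raw <- out$p_raw < alpha
  out$sig_holm <- out$p_holm < alpha
  out
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Group reassignment on retained PC scores via [MASS::lda()]: for each
#' specimen, the discriminant model fitted on all others yields posterior
#' class probabilities; reported are the assigned class, its posterior, and
#' the overall percentage correctly reassigned.
#'
#' @param scores numeric matrix (specimens x retained components).
#' @param groups group labels, one per row; every group needs >= 2 members.
#' @param prior `"proportional"` (to group sizes, the default of the
#'   implementation the field uses) or `"equal"`.
#' @return A list: `assignments` (data frame with `specimen`, `group`,
#'   `assigned`, `posterior`, `correct`) and `percent_correct`.
#' @export
lda_loocv <- function(scores, groups, prior = c("proportional", "equal")) {
  prior <- match.arg(prior)
  scores <- as.matrix(scores)
  groups <- factor(groups)
  stopifnot(length(groups) == nrow(scores))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) stopf("group(s) with fewer than 2 members: %s",
                           paste(small, collapse = ", "))
  if (ncol(scores) >= nrow(scores) - length(sizes))
    stopf("too many components (%d) for %d specimens in %d groups; reduce the retained set",
          ncol(scores), nrow(scores), length(sizes))
  args <- list(x = scores, grouping = groups, CV = TRUE)
  if (prior == "equal") args$prior <- rep(1 / nlevels(groups), nlevels(groups))
  fit <- tryCatch(do.call(MASS::lda, args), error = function(e)
    stopf("LDA failed (%s); consider fewer retained components",
          conditionMessage(e)))
  post <- apply(fit$posterior, 1L, max)
  assigned <- as.character(fit$class)
  correct <- assigned == as.character(groups)
  list(assignments = data.frame(
         specimen = rownames(scores) %||% seq_len(nrow(scores)),
         group = as.character(groups), assigned = assigned,
         posterior = as.numeric(post), correct = correct,
         stringsAsFactors = FALSE),
       percent_correct = 100 * mean(correct))
}
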