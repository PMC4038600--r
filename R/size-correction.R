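# Isometric size removal from log-scale linear measurements, by the two
# methods compared downstream: Burnaby back projection (BBPM) and residuals
# of a regression on a body-size proxy.

#' Log-transform raw measurements
#'
#' Element-wise log10 of a raw-mm table; the log scale renders relations
#' among linear measurements more nearly linear and gives traits a similar
#' dimension of variance.
#'
#' @param table a `measurement_table` in state `raw_mm`.
#' @return A `measurement_table` in state `log10`.
#' @export
log_transform <- function(table) {
  require_state(table, "raw_mm")
  if (any(table$values <= 0)) {
    ij <- which(table$values <= 0, arr.ind = TRUE)[1L, ]
    stopf("non-positive value for specimen '%s', trait '%s'",
          rownames(table$values)[ij[1]], colnames(table$values)[ij[2]])
  }
  measurement_table(log10(table$values), "log10")
}

#' Burnaby back projection (BBPM) size correction
#'
#' Removes isometric size by projecting each log10 trait vector onto the
#' orthogonal complement of the isometric vector `a = (1,...,1)/sqrt(p)` and
#' returning it to the original coordinate system: `x <- x (I - a a')`.
#' Output rows are exactly orthogonal to `a`; the operator is idempotent.
#'
#' @param table a `measurement_table` in state `log10`.
#' @return A `measurement_table` in state `size_corrected_bbpm`.
#' @export
bbpm_correct <- function(table) {
  require_state(table, "log10")
  p <- ncol(table$values)
  if (p < 2) stopf("BBPM needs at least 2 traits")
  x <- table$values
  # x (I - a a') with a = 1/sqrt(p): subtract the row mean from every entry
  corrected <- x - rowMeans(x)
  out <- measurement_table(corrected, "size_corrected_bbpm")
  out
}

#' Regression-residual size correction
#'
#' Replaces each log10 trait column by the residuals of its ordinary
#' least-squares regression (with intercept) on a body-size proxy, the
#' logarithm of the summed pronotal and elytral lengths, `log10(PL + EL)`
#' computed on the mm scale.
#'
#' @param table a `measurement_table` in state `log10`.
#' @param size_traits the two trait names summed into the proxy
#'   (default `c("PL", "EL")`).
#' @return A `measurement_table` in state `size_corrected_regression`, with
#'   the proxy attached as attribute `"size_proxy"`.
#' @export
regression_correct <- function(table, size_traits = c("PL", "EL")) {
  require_state(table, "log10")
  missing_tr <- setdiff(size_traits, colnames(table$values))
  if (length(missing_tr)) stopf("size trait(s) absent: %s",
                                paste(missing_tr, collapse = ", "))
  # back-transform the two columns to mm, sum, log10 (= log10(PL_mm + EL_mm))
  proxy <- log10(rowSums(10^table$values[, size_traits, drop = FALSE]))
  if (stats::sd(proxy) < 1e-12) stopf("size proxy has zero variance")
  X <- cbind(1, proxy)
  coefs <- solve(crossprod(X), crossprod(X, table$values))
  resid <- table$values - X %*% coefs
  out <- measurement_table(resid, "size_corrected_regression")
  attr(out, "size_proxy") <- proxy
  out
}

#' Impact of size
#'
#' Fraction of total variance explained by the first principal component of
#' the uncorrected log10 table — the working measure of how much of the
#' morphometric variation is size alone.
#'
#' @param table a `measurement_table` in state `log10`.
#' @return A single number in `[0, 1]`.
#' @export
impact_of_size <- function(table) {
  require_state(table, "log10")
  if (nrow(table$values) < 3) stopf("impact of size needs at least 3 specimens")
  morpho_pca(table)$variance_fractions[1L]
}
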