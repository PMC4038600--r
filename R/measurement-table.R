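# MeasurementTable: specimens x traits with an explicit transform state.

#' Standard trait panel of linear body measurements
#'
#' The 20 linear distances of the chafer body-shape panel: body and elytral
#' heights/lengths/widths, pronotal dimensions, head and eye measures, and
#' leg segments including metacoxal length (MCL), the focal trait of the
#' key-innovation analyses.
#'
#' @return Character vector of 20 trait names.
#' @export
chafer_traits <- function() {
  c("BH", "EH", "EL", "Eld", "Elmb", "EW", "Ewb", "PL", "PW", "ED",
    "HW", "IOD", "MCL", "MFL", "MFW", "MTL", "MTW", "PFL", "PFW", "PTL")
}

#' Construct a measurement table
#'
#' A specimens-by-traits numeric matrix carrying its transform state so that
#' stages cannot be chained out of order (e.g. size correction on raw mm).
#'
#' @param values numeric matrix, rownames = specimen ids, colnames = traits.
#' @param state one of `"raw_mm"`, `"log10"`, `"size_corrected_bbpm"`,
#'   `"size_corrected_regression"`.
#' @return An object of class `measurement_table`.
#' @export
measurement_table <- function(values, state = "raw_mm") {
  state <- match.arg(state, c("raw_mm", "log10", "size_corrected_bbpm",
                              "size_corrected_regression"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stopf("specimen ids (rownames) are required")
  if (is.null(colnames(values))) stopf("trait names (colnames) are required")
  if (anyDuplicated(rownames(values))) stopf("duplicate specimen ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate trait names")
  if (anyNA(values)) {
    ij <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stopf("missing value for specimen '%s', trait '%s'",
          rownames(values)[ij[1]], colnames(values)[ij[2]])
  }
  if (state == "raw_mm" && any(values <= 0)) {
    ij <- which(values <= 0, arr.ind = TRUE)[1L, ]
    stopf("non-positive raw measurement for specimen '%s', trait '%s'",
          rownames(values)[ij[1]], colnames(values)[ij[2]])
  }
  structure(list(values = values, state = state), class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d specimens x %d traits, state: %s\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.measurement_table <- function(x) dim(x$values)

#' @export
as.matrix.measurement_table <- function(x, ...) x$values

#' Write a measurement table to CSV
#'
#' The transform state is recorded in a `# state:` comment on the first line
#' so that [read_measurements()] restores it.
#'
#' @param table a `measurement_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_measurements <- function(table, file) {
  stopifnot(inherits(table, "measurement_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", table$state), con)
  df <- data.frame(specimen = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Read a measurement table from CSV
#'
#' @param file path written by [write_measurements()], or any CSV with a
#'   `specimen` id column and one column per trait.
#' @param state transform state to assume when the file carries no
#'   `# state:` header (default `"raw_mm"`).
#' @return A `measurement_table`.
#' @export
read_measurements <- function(file, state = "raw_mm") {
  first <- readLines(file, n = 1L)
  if (grepl("^# state:", first)) state <- trimws(sub("^# state:", "", first))
  df <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  measurement_table(m, state)
}

require_state <- function(table, state) {
  stopifnot(inherits(table, "measurement_table"))
  if (!table$state %in% state) {
    stopf("measurement table is in state '%s'; expected %s",
          table$state, paste(sprintf("'%s'", state), collapse = " or "))
  }
  invisible(table)
}
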