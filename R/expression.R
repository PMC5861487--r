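#' Time-course expression matrix
#'
#' Container for a proteins x samples expression table with its sampling
#' design. Columns are time-major (all replicates of time point 1, then time
#' point 2, ...). Values must be finite: the dynamic model has no missing-data
#' mechanism, so incomplete rows have to be dropped before construction.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns. Row
#'   names are taken as protein identifiers unless `protein_ids` is given.
#' @param design A [time_design()]; `ncol(values)` must equal
#'   [n_samples()] of the design.
#' @param protein_ids Optional character vector of unique protein identifiers.
#' @param condition Free-text condition label (e.g. the organ name).
#'
#' @return An object of class `expression_matrix` with elements `values`
#'   (named numeric matrix), `design` and `condition`.
#' @export
expression_matrix <- function(values, design, protein_ids = rownames(values),
                              condition = "") {
  stopifnot(inherits(design, "time_design"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(protein_ids)) {
    stop_regennet("protein identifiers are required (row names or protein_ids)",
                  "regennet_format_error")
  }
  protein_ids <- as.character(protein_ids)
  if (length(protein_ids) != nrow(values)) {
    stop_regennet("protein_ids length must match the number of rows",
                  "regennet_format_error")
  }
  if (anyDuplicated(protein_ids)) {
    dup <- unique(protein_ids[duplicated(protein_ids)])
    stop_regennet(paste0("duplicate protein identifiers: ",
                         paste(utils::head(dup, 5), collapse = ", ")),
                  "regennet_format_error")
  }
  if (ncol(values) != n_samples(design)) {
    stop_regennet(sprintf(
      "expression matrix has %d sample columns but the design implies %d",
      ncol(values), n_samples(design)), "regennet_format_error")
  }
  if (any(!is.finite(values))) {
    bad <- protein_ids[apply(!is.finite(values), 1, any)]
    stop_regennet(paste0("non-finite expression values for: ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "regennet_format_error")
  }
  rownames(values) <- protein_ids
  colnames(values) <- design_sample_names(design)
  structure(
    list(values = values, design = design, condition = as.character(condition)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "Expression matrix '%s': %d proteins x %d samples (%d time points)\n",
    x$condition, nrow(x$values), ncol(x$values), length(x$design$time_points)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a wide expression TSV
#'
#' Expects a tab-separated table whose first column holds the protein
#' identifier and whose remaining columns are sample measurements laid out
#' time-major per `design`. Lines starting with `#` are ignored. `NA` cells are
#' rejected: the downstream model cannot represent missing values.
#'
#' @param path Path to the TSV file.
#' @param design The [time_design()] the columns must match.
#' @param condition Condition label stored on the result.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, design, condition = "") {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character(0))
  if (ncol(df) < 2) {
    stop_regennet("expression table needs an id column and sample columns",
                  "regennet_format_error")
  }
  if (ncol(df) - 1L != n_samples(design)) {
    stop_regennet(sprintf(
      "file promises %d sample columns but the design implies %d",
      ncol(df) - 1L, n_samples(design)), "regennet_format_error")
  }
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  na_token <- toupper(trimws(raw)) %in% c("NA", "NAN", "")
  if (any(na_token)) {
    bad <- unique(ids[apply(matrix(na_token, nrow = nrow(raw)), 1, any)])
    stop_regennet(paste0("missing values are not representable; offending proteins: ",
                         paste(utils::head(bad, 10), collapse = ", ")),
                  "regennet_format_error")
  }
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (any(is.na(num))) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_regennet(sprintf(
      "non-numeric cell at row %d (protein %s), sample column %d",
      idx[1], ids[idx[1]], idx[2]), "regennet_format_error")
  }
  expression_matrix(num, design, protein_ids = ids, condition = condition)
}

#' Write an expression matrix as a TSV readable by [read_expression_table()]
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  header <- paste(c("protein_id", colnames(matrix$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix$values)), function(i) {
    paste(c(rownames(matrix$values)[i], fmt_num(matrix$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), con = path)
  invisible(path)
}
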