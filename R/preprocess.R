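# Sample normalization and differential-expression filtering.
#
# The inference model only needs presence/absence-comparable trajectories, so
# preprocessing is deliberately light: per-sample upper-quartile scaling and a
# one-way ANOVA screen across time points. Platform-specific raw-array
# pipelines (GCRMA and vendor software) are upstream concerns; matrices from
# such platforms must arrive pre-normalized.

#' Percentile (upper-quartile) normalization
#'
#' Divides every sample column by its own q-th percentile so that all columns
#' share percentile 1 afterwards. The percentile uses linear interpolation
#' between closest ranks (rank position (n-1)*q/100, R's default type-7
#' quantile), recorded in the `percentile` attribute of the result.
#'
#' @param matrix An [expression_matrix()].
#' @param q Percentile in (0, 100]; default 75 (upper quartile).
#' @return A normalized [expression_matrix()].
#' @export
percentile_normalize <- function(matrix, q = 75) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 100) {
    stop_regennet("q must lie in (0, 100]", "regennet_parameter_error")
  }
  scale <- apply(matrix$values, 2, stats::quantile, probs = q / 100,
                 names = FALSE, type = 7)
  bad <- which(scale <= 0)
  if (length(bad) > 0) {
    stop_regennet(paste0("degenerate sample column(s) with non-positive ",
                         q, "th percentile: ",
                         paste(colnames(matrix$values)[bad], collapse = ", ")),
                  "regennet_degenerate_sample_error")
  }
  out <- expression_matrix(sweep(matrix$values, 2, scale, "/"), matrix$design,
                           condition = matrix$condition)
  attr(out, "percentile") <- q
  out
}

#' Shifted log2 transform
#'
#' Elementwise `log2(value + offset)`.
#'
#' @param matrix An [expression_matrix()].
#' @param offset Nonnegative shift, default 1.
#' @return A transformed [expression_matrix()].
#' @export
log2_transform <- function(matrix, offset = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0) {
    stop_regennet("offset must be a nonnegative number", "regennet_parameter_error")
  }
  if (any(matrix$values <= -offset)) {
    stop_regennet("values <= -offset: log2 transform undefined",
                  "regennet_domain_error")
  }
  expression_matrix(log2(matrix$values + offset), matrix$design,
                    condition = matrix$condition)
}

#' Differential-expression screen by one-way ANOVA with Bonferroni correction
#'
#' Per protein, a fixed-effects one-way ANOVA across time-point groups
#' (replicates are the observations) tests whether mean expression changes over
#' the time course. A protein enters the pool iff its raw p-value is below
#' `alpha / n_tests`. Proteins with zero total variance (flat probes) get
#' p = 1 and are excluded, never an error.
#'
#' @param matrix An [expression_matrix()]; every time point needs >= 2
#'   replicates.
#' @param alpha Family-wise significance level, default 0.05.
#' @param correction Only `"bonferroni"` (the comparison logic of the study
#'   this implements needs family-wise control, not FDR).
#' @param n_tests Bonferroni family size; defaults to the number of proteins in
#'   `matrix` (a per-condition family).
#' @return An object of class `protein_pool`: list with `protein_ids` (retained
#'   ids), `p_values` (named raw p-values for all tested proteins), `alpha`,
#'   `n_tests`.
#' @export
anova_filter <- function(matrix, alpha = 0.05, correction = "bonferroni",
                         n_tests = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  correction <- match.arg(correction, "bonferroni")
  design <- matrix$design
  if (length(design$time_points) < 2) {
    stop_regennet("ANOVA needs at least two time points", "regennet_design_error")
  }
  if (any(design$replicates < 2)) {
    stop_regennet("every time point needs >= 2 replicates for ANOVA",
                  "regennet_design_error")
  }
  if (is.null(n_tests)) n_tests <- nrow(matrix$values)
  if (n_tests < 1) {
    stop_regennet("n_tests must be >= 1", "regennet_parameter_error")
  }
  groups <- factor(design_groups(design))
  vals <- matrix$values
  p <- vapply(seq_len(nrow(vals)), function(i) {
    y <- vals[i, ]
    if (stats::var(y) == 0) return(1)
    stats::oneway.test(y ~ groups, var.equal = TRUE)$p.value
  }, numeric(1))
  # zero within-group variance with differing means gives F = Inf, p = 0; a
  # NaN can only arise from constant rows, already mapped to p = 1
  p[is.na(p)] <- 1
  names(p) <- rownames(vals)
  n_flat <- sum(p == 1 & apply(vals, 1, stats::var) == 0)
  if (n_flat > 0) {
    message(sprintf("anova_filter: %d zero-variance protein(s) assigned p = 1",
                    n_flat))
  }
  retained <- names(p)[p < alpha / n_tests]
  structure(
    list(protein_ids = retained, p_values = p, alpha = alpha,
         n_tests = n_tests),
    class = "protein_pool"
  )
}

#' @export
print.protein_pool <- function(x, ...) {
  cat(sprintf(
    "Protein pool: %d of %d proteins with p < %g/%d (Bonferroni)\n",
    length(x$protein_ids), length(x$p_values), x$alpha, x$n_tests))
  invisible(x)
}

#' Collapse duplicate identifiers to their most significant row
#'
#' Microarray tables often carry several probes per gene symbol. Among rows
#' sharing an identifier, the row with the smallest ANOVA p-value is kept; ties
#' break to the first occurrence.
#'
#' Because [expression_matrix()] forbids duplicate identifiers, this function
#' takes the raw pieces and returns a valid matrix.
#'
#' @param values Numeric matrix with (possibly duplicated) row identifiers.
#' @param ids Character identifiers, one per row of `values`.
#' @param p_values Numeric vector, one raw p-value per row.
#' @param design,condition Passed to [expression_matrix()] for the result.
#' @return An [expression_matrix()] with unique identifiers.
#' @export
collapse_duplicates <- function(values, ids, p_values, design, condition = "") {
  values <- as.matrix(values)
  ids <- as.character(ids)
  stopifnot(length(ids) == nrow(values), length(p_values) == nrow(values))
  # stable min-p per id: order by p then original position, keep first per id
  ord <- order(p_values, seq_along(ids), method = "radix")
  keep_ord <- ord[!duplicated(ids[ord])]
  keep <- sort(keep_ord)
  expression_matrix(values[keep, , drop = FALSE], design,
                    protein_ids = ids[keep], condition = condition)
}

#' Write a protein pool as a TSV
#'
#' Columns: protein_id, p_raw, p_bonferroni (capped at 1), retained.
#' @param pool A `protein_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_pool <- function(pool, path) {
  stopifnot(inherits(pool, "protein_pool"))
  ids <- names(pool$p_values)
  p_adj <- pmin(pool$p_values * pool$n_tests, 1)
  retained <- ids %in% pool$protein_ids
  lines <- c("protein_id\tp_raw\tp_bonferroni\tretained",
             paste(ids, fmt_num(pool$p_values), fmt_num(p_adj),
                   ifelse(retained, "TRUE", "FALSE"), sep = "\t"))
  writeLines(lines, con = path)
  invisible(path)
}

#' Read a protein pool TSV written by [write_protein_pool()]
#' @param path Path to the TSV.
#' @param alpha,n_tests Family parameters recorded on the result; defaults
#'   reconstruct retention from the `retained` column.
#' @return A `protein_pool`.
#' @export
read_protein_pool <- function(path, alpha = 0.05, n_tests = NULL) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein_id", "p_raw", "retained")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0) {
    stop_regennet(paste0("pool table lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "regennet_format_error")
  }
  p <- as.numeric(df$p_raw)
  names(p) <- as.character(df$protein_id)
  if (is.null(n_tests)) n_tests <- length(p)
  structure(
    list(protein_ids = as.character(df$protein_id)[as.logical(df$retained)],
         p_values = p, alpha = alpha, n_tests = n_tests),
    class = "protein_pool"
  )
}
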