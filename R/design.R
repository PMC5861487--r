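#' Time-course sampling design
#'
#' Describes when a regeneration time course was sampled (in days post injury,
#' dpi) and how many biological replicates exist per time point. Sample columns
#' of an [expression_matrix()] are laid out time-major: all replicates of the
#' first time point, then all replicates of the second, and so on.
#'
#' @param time_points Strictly increasing numeric vector of sampling times
#'   (dpi); at least two.
#' @param replicates Positive integer replicate count per time point; either a
#'   single value recycled to all time points or one value per time point.
#'
#' @return An object of class `time_design` with elements `time_points` and
#'   `replicates`.
#'
#' @examples
#' time_design(c(0, 0.25, 1, 3), replicates = 2)
#' @export
time_design <- function(time_points, replicates = 2L) {
  time_points <- as.numeric(time_points)
  if (length(time_points) < 2) {
    stop_regennet("a time design needs at least two time points", "regennet_design_error")
  }
  if (any(!is.finite(time_points)) || any(diff(time_points) <= 0)) {
    stop_regennet("time points must be finite and strictly increasing", "regennet_design_error")
  }
  replicates <- as.integer(replicates)
  if (length(replicates) == 1L) replicates <- rep(replicates, length(time_points))
  if (length(replicates) != length(time_points) || any(is.na(replicates)) ||
      any(replicates < 1L)) {
    stop_regennet("replicates must be >= 1, one per time point", "regennet_design_error")
  }
  structure(
    list(time_points = time_points, replicates = replicates),
    class = "time_design"
  )
}

#' @export
print.time_design <- function(x, ...) {
  cat("Time design:", length(x$time_points), "time points (dpi):",
      paste(x$time_points, collapse = ", "), "\n")
  cat("Replicates per time point:", paste(x$replicates, collapse = ", "), "\n")
  invisible(x)
}

#' Number of sample columns implied by a design
#' @param design A [time_design()].
#' @return Integer, the total replicate count.
#' @export
n_samples <- function(design) {
  stopifnot(inherits(design, "time_design"))
  sum(design$replicates)
}

#' Time-major sample column labels for a design
#' @noRd
design_sample_names <- function(design) {
  unlist(mapply(
    function(t, r) sprintf("t%g_r%d", t, seq_len(r)),
    design$time_points, design$replicates,
    SIMPLIFY = FALSE
  ), use.names = FALSE)
}

#' Time-point group index of each sample column (time-major order)
#' @noRd
design_groups <- function(design) {
  rep(seq_along(design$time_points), design$replicates)
}
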