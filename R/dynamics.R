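# Per-target dynamic model identification and AIC pruning.
#
# The model for target protein i with candidate interactors j = 1..N_i is the
# discrete-time linear update
#
#   x_i[t+1] = x_i[t] + sum_j a_ij x_j[t] - lambda_i x_i[t] + k_i + eps_i[t]
#
# where a_ij is the interaction ability of j on i, lambda_i in [0,1] the
# degradation effect and k_i >= 0 the basal level. Written as a regression,
# each dense-grid step contributes one equation
#
#   x_i[t+1] = (x_1[t] ... x_N[t]  x_i[t]  1) (a_i1 ... a_iN  1-lambda_i  k_i)'
#
# stacked over t = t_1 .. t_{M-1}. Short time courses are densified to M
# uniform grid points by a natural cubic spline through the per-time-point
# replicate means before stacking.

#' Densify a time course by natural cubic splines
#'
#' Replicates are averaged per time point, a natural cubic spline is fitted
#' through the averaged knots per protein, and evaluated on a uniform grid of
#' `m_points` times spanning exactly the observed interval. With exactly two
#' observed time points the interpolant falls back to linear (a message is
#' emitted).
#'
#' @param matrix An [expression_matrix()].
#' @param m_points Number of grid points, at least the number of observed time
#'   points.
#' @return An object of class `dense_trajectory`: list with `grid` (length-M
#'   numeric) and `values` (proteins x M matrix).
#' @export
spline_densify <- function(matrix, m_points) {
  stopifnot(inherits(matrix, "expression_matrix"))
  design <- matrix$design
  times <- design$time_points
  m_points <- as.integer(m_points)
  if (m_points < length(times)) {
    stop_regennet(sprintf(
      "m_points (%d) must be >= the number of observed time points (%d)",
      m_points, length(times)), "regennet_parameter_error")
  }
  groups <- design_groups(design)
  # per-protein, per-time-point replicate means (proteins x time points)
  means <- t(apply(matrix$values, 1, function(y) tapply(y, groups, mean)))
  if (nrow(matrix$values) == 1L) means <- matrix(means, nrow = 1)
  grid <- seq(times[1], times[length(times)], length.out = m_points)
  if (length(times) == 2L) {
    message("spline_densify: only two observed time points, using linear interpolation")
    vals <- t(apply(means, 1, function(y) {
      stats::approx(times, y, xout = grid)$y
    }))
  } else {
    vals <- t(apply(means, 1, function(y) {
      stats::spline(times, y, xout = grid, method = "natural")$y
    }))
  }
  if (nrow(matrix$values) == 1L) vals <- matrix(vals, nrow = 1)
  rownames(vals) <- rownames(matrix$values)
  structure(list(grid = grid, values = vals), class = "dense_trajectory")
}

#' @export
print.dense_trajectory <- function(x, ...) {
  cat(sprintf("Dense trajectory: %d proteins on %d grid points over [%g, %g]\n",
              nrow(x$values), length(x$grid), x$grid[1], x$grid[length(x$grid)]))
  invisible(x)
}

#' Assemble the stacked per-target regression
#'
#' Builds the response `X_i = (x_i(t_2), ..., x_i(t_M))` and the design matrix
#' whose row for step t is `(x_1(t), ..., x_N(t), x_i(t), 1)`, for
#' `t = t_1 .. t_(M-1)`. The identifiability margin M-1 >= N_i + 2 is enforced
#' here.
#'
#' @param target Target protein id.
#' @param interactors Ordered character vector of candidate interactor ids
#'   (may be empty); must not contain the target.
#' @param dense A [spline_densify()] result containing the target and all
#'   interactors.
#' @return An object of class `regression_problem`: list with `target`,
#'   `interactors`, `response` (length M-1), `design` ((M-1) x (N_i+2) matrix),
#'   `n_equations`.
#' @export
assemble_regression <- function(target, interactors, dense) {
  stopifnot(inherits(dense, "dense_trajectory"))
  interactors <- as.character(interactors)
  if (target %in% interactors) {
    stop_regennet("target must not be listed among its own interactors",
                  "regennet_contract_error")
  }
  missing_ids <- setdiff(c(target, interactors), rownames(dense$values))
  if (length(missing_ids) > 0) {
    stop_regennet(paste0("not in dense trajectory: ",
                         paste(missing_ids, collapse = ", ")),
                  "regennet_lookup_error")
  }
  m <- length(dense$grid)
  n_eq <- m - 1L
  n_int <- length(interactors)
  if (n_eq < n_int + 2L) {
    stop_regennet(sprintf(
      "only %d equations for %d interactors + 2 self parameters; densify further",
      n_eq, n_int), "regennet_identifiability_error")
  }
  x_target <- dense$values[target, ]
  design <- cbind(
    if (n_int > 0) t(dense$values[interactors, 1:n_eq, drop = FALSE]) else NULL,
    x_target[1:n_eq],
    rep(1, n_eq)
  )
  colnames(design) <- c(interactors, ".self", ".const")
  structure(
    list(target = target, interactors = interactors,
         response = unname(x_target[2:m]), design = unname(design),
         n_equations = n_eq),
    class = "regression_problem"
  )
}

# Minimum-norm least squares via SVD; returns list(theta, rank).
min_norm_ls <- function(X, y) {
  if (ncol(X) == 0) return(list(theta = numeric(0), rank = 0L))
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank == 0) return(list(theta = rep(0, ncol(X)), rank = 0L))
  theta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  list(theta = drop(theta), rank = rank)
}

#' Fit the dynamic model by box-constrained least squares
#'
#' Minimizes the residual sum of squares of the stacked regression over the
#' parameters of a chosen interactor subset, subject to the physical bounds
#' `1 - lambda in [0, 1]` (degradation effect between 0 and 1) and basal level
#' `k >= 0`; interaction abilities are unconstrained. Because only two
#' coordinates are bounded, the convex problem is solved exactly by enumerating
#' the six possible active sets, solving each equality-restricted least-squares
#' problem (minimum-norm via SVD when rank deficient) and keeping the feasible
#' solution with the smallest residual sum of squares.
#'
#' @param problem A [assemble_regression()] result.
#' @param subset Character vector, a subset of `problem$interactors` to keep in
#'   the model; all others get interaction ability 0. Defaults to all.
#' @return An object of class `parameter_estimate`: list with
#'   `interaction_abilities` (named over all problem interactors, zeros off the
#'   subset), `degradation` (lambda), `basal` (k), `residuals`, `fitted`,
#'   `rss`, `degenerate` (TRUE if the active design was rank deficient and the
#'   minimum-norm rule applied).
#' @export
fit_constrained_ls <- function(problem, subset = problem$interactors) {
  stopifnot(inherits(problem, "regression_problem"))
  subset <- as.character(subset)
  if (length(setdiff(subset, problem$interactors)) > 0) {
    stop_regennet("subset contains ids that are not problem interactors",
                  "regennet_contract_error")
  }
  keep <- problem$interactors %in% subset
  n_keep <- sum(keep)
  p <- n_keep + 2L
  if (problem$n_equations < p) {
    stop_regennet("fewer equations than parameters in the requested subset",
                  "regennet_identifiability_error")
  }
  X <- problem$design[, c(which(keep), length(problem$interactors) + 1:2),
                      drop = FALSE]
  y <- problem$response
  i_b <- p - 1L  # column of 1 - lambda
  i_k <- p       # column of k
  tol <- 1e-9

  # active sets: (value of b if fixed, value of k if fixed), NA = free
  active_sets <- list(
    c(NA, NA), c(0, NA), c(1, NA), c(NA, 0), c(0, 0), c(1, 0)
  )
  best <- NULL
  for (act in active_sets) {
    fixed_idx <- integer(0)
    fixed_val <- numeric(0)
    if (!is.na(act[1])) { fixed_idx <- c(fixed_idx, i_b); fixed_val <- c(fixed_val, act[1]) }
    if (!is.na(act[2])) { fixed_idx <- c(fixed_idx, i_k); fixed_val <- c(fixed_val, act[2]) }
    free_idx <- setdiff(seq_len(p), fixed_idx)
    y_adj <- y - if (length(fixed_idx) > 0) {
      X[, fixed_idx, drop = FALSE] %*% fixed_val
    } else 0
    fit <- min_norm_ls(X[, free_idx, drop = FALSE], drop(y_adj))
    theta <- numeric(p)
    theta[fixed_idx] <- fixed_val
    theta[free_idx] <- fit$theta
    # feasibility of the bounded coordinates
    if (theta[i_b] < -tol || theta[i_b] > 1 + tol || theta[i_k] < -tol) next
    theta[i_b] <- min(max(theta[i_b], 0), 1)
    theta[i_k] <- max(theta[i_k], 0)
    fitted <- drop(X %*% theta)
    rss <- sum((y - fitted)^2)
    degen <- fit$rank < length(free_idx)
    # ties keep the earlier candidate, i.e. the one with fewer active
    # constraints: on flat optima that is the minimum-norm solution
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(theta = theta, rss = rss, fitted = fitted, degenerate = degen)
    }
  }
  if (is.null(best)) {
    # pathological rank-deficient case where every min-norm candidate landed
    # outside the box: fall back to a bounded quasi-Newton solve
    obj <- function(th) sum((y - X %*% th)^2)
    gr <- function(th) drop(-2 * crossprod(X, y - X %*% th))
    lower <- c(rep(-Inf, p - 2L), 0, 0)
    upper <- c(rep(Inf, p - 2L), 1, Inf)
    opt <- stats::optim(rep(0, p), obj, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    fitted <- drop(X %*% opt$par)
    best <- list(theta = opt$par, rss = sum((y - fitted)^2), fitted = fitted,
                 degenerate = TRUE)
  }
  a_full <- stats::setNames(rep(0, length(problem$interactors)),
                            problem$interactors)
  if (n_keep > 0) a_full[which(keep)] <- best$theta[seq_len(n_keep)]
  structure(
    list(target = problem$target,
         interaction_abilities = a_full,
         degradation = 1 - best$theta[i_b],
         basal = best$theta[i_k],
         residuals = y - best$fitted,
         fitted = best$fitted,
         rss = best$rss,
         subset = problem$interactors[keep],
         degenerate = best$degenerate),
    class = "parameter_estimate"
  )
}

#' @export
print.parameter_estimate <- function(x, ...) {
  cat(sprintf(
    "Dynamic model fit for %s: %d interactor(s), lambda = %.4g, k = %.4g, RSS = %.4g%s\n",
    x$target, length(x$subset), x$degradation, x$basal, x$rss,
    if (x$degenerate) " (degenerate: minimum-norm)" else ""))
  invisible(x)
}

#' Akaike information criterion of a fitted dynamic model
#'
#' `K = log(max(RSS / n_equations, 1e-12)) + 2 * n_params / n_equations`
#' (natural log). The floor keeps noiseless perfect fits finite. `n_params`
#' counts the retained interactions plus 2 (the self/degradation term and the
#' basal level).
#'
#' @param estimate A `parameter_estimate`, or a numeric residual vector.
#' @param n_params Number of identified parameters.
#' @param n_equations Number of stacked equations; defaults to the residual
#'   length.
#' @return The criterion value (numeric scalar).
#' @export
aic_score <- function(estimate, n_params, n_equations = NULL) {
  resid <- if (inherits(estimate, "parameter_estimate")) {
    estimate$residuals
  } else {
    as.numeric(estimate)
  }
  if (is.null(n_equations)) n_equations <- length(resid)
  if (n_equations < 1) {
    stop_regennet("n_equations must be >= 1", "regennet_parameter_error")
  }
  rss <- sum(resid^2)
  log(max(rss / n_equations, 1e-12)) + 2 * n_params / n_equations
}

#' Prune candidate interactions of one target by AIC over model order
#'
#' Fits the full candidate model, ranks interactors by the magnitude of their
#' fitted interaction ability (ties broken by id), then refits nested
#' top-n subsets for n = 0..N_i, scoring each with [aic_score()] at
#' `n_params = n + 2`. The smallest n attaining the minimal criterion wins.
#'
#' @param problem A [assemble_regression()] result.
#' @return An object of class `aic_selection`: list with `target`,
#'   `retained_interactors`, `selected_order`, `aic_trace` (length N_i + 1,
#'   entry n+1 is the criterion of the top-n model), `ranking` (interactors in
#'   scan order) and `estimate` (the refit `parameter_estimate` on the retained
#'   subset).
#' @export
prune_by_aic <- function(problem) {
  stopifnot(inherits(problem, "regression_problem"))
  n_int <- length(problem$interactors)
  full <- fit_constrained_ls(problem)
  ranking <- problem$interactors[order(-abs(full$interaction_abilities),
                                       problem$interactors, method = "radix")]
  trace <- numeric(n_int + 1L)
  fits <- vector("list", n_int + 1L)
  for (n in 0:n_int) {
    est <- if (n == n_int) full else fit_constrained_ls(problem, ranking[seq_len(n)])
    fits[[n + 1L]] <- est
    trace[n + 1L] <- aic_score(est, n + 2L, problem$n_equations)
  }
  sel <- which.min(trace) - 1L  # first minimum = smallest order on ties
  structure(
    list(target = problem$target,
         retained_interactors = ranking[seq_len(sel)],
         selected_order = sel,
         aic_trace = trace,
         ranking = ranking,
         estimate = fits[[sel + 1L]]),
    class = "aic_selection"
  )
}

#' @export
print.aic_selection <- function(x, ...) {
  cat(sprintf(
    "AIC selection for %s: order %d of %d candidates (K = %.4g)\n",
    x$target, x$selected_order, length(x$ranking),
    x$aic_trace[x$selected_order + 1]))
  if (x$selected_order > 0) {
    cat("Retained:", paste(x$retained_interactors, collapse = ", "), "\n")
  }
  invisible(x)
}
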