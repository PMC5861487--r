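# Synthetic benchmark generator: ground-truth networks, dynamic-model
# trajectories with noise and replicates, spiked false-positive candidate
# edges, and edge-recovery scoring.

#' Default synthetic sampling design
#'
#' The regeneration time courses this package emulates sample few, irregular
#' time points; the default mirrors the heart/cerebellum grid (0, 0.25, 1 and
#' 3 days post injury) with two biological replicates per time point.
#'
#' @param time_points Sampling times in dpi.
#' @param replicates Replicates per time point.
#' @return A [time_design()].
#' @export
regen_design <- function(time_points = c(0, 0.25, 1, 3), replicates = 2L) {
  time_design(time_points, replicates)
}

#' Generate a ground-truth dynamic PPI model
#'
#' Samples an Erdos-Renyi undirected edge set, independent per-direction
#' interaction abilities with random sign, and per-node degradation, basal and
#' initial levels. Models whose linear update matrix `I + A - diag(lambda)` has
#' spectral radius above `stability_limit` are resampled (up to 100 attempts)
#' so simulated trajectories cannot explode over the short horizons this
#' package works with. The default limit 1.35 caps worst-case growth over a
#' 15-step horizon at roughly 90-fold -- a strong induction response -- while
#' remaining satisfiable at the default density and ability range; tighten it
#' for sparser or weaker-coupling models.
#'
#' @param n_nodes Number of proteins.
#' @param edge_density Pair-wise edge probability in (0, 1].
#' @param a_range Magnitude range of interaction abilities (sign is random).
#' @param lambda_range Degradation-effect range, within \[0, 1\].
#' @param k_range Basal-level range, nonnegative.
#' @param x0_range Initial expression range, nonnegative. The default starts
#'   trajectories away from their steady states, emulating the perturbed state
#'   right after injury.
#' @param noise_sigma Gaussian noise standard deviation used by
#'   [simulate_expression()] for both process and measurement noise.
#' @param stability_limit Upper bound on the update-matrix spectral radius.
#' @param seed Integer RNG seed (the model is fully reproducible from it).
#' @return An object of class `ground_truth_model`: list with `nodes`,
#'   `edges` (two-column character matrix of true undirected edges), `a`
#'   (matrix, `a[i, j]` is the ability of j on i; zero off the edge set),
#'   `lambda`, `k`, `x0` (named numeric vectors), `noise_sigma`, `seed`.
#' @export
generate_ground_truth <- function(n_nodes = 20, edge_density = 0.15,
                                  a_range = c(0.1, 0.5),
                                  lambda_range = c(0, 0.3),
                                  k_range = c(0, 1),
                                  x0_range = c(0.5, 1.5),
                                  noise_sigma = 0.05, stability_limit = 1.35,
                                  seed = 1) {
  if (edge_density <= 0 || edge_density > 1) {
    stop_regennet("edge_density must lie in (0, 1]", "regennet_parameter_error")
  }
  if (min(a_range) < 0 || min(lambda_range) < 0 || max(lambda_range) > 1 ||
      min(k_range) < 0 || min(x0_range) < 0) {
    stop_regennet("parameter ranges violate the model bounds",
                  "regennet_parameter_error")
  }
  nodes <- sprintf("p%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  with_seed(seed, {
    for (attempt in seq_len(100)) {
      sel <- stats::runif(nrow(pairs)) < edge_density
      edges <- pairs[sel, , drop = FALSE]
      colnames(edges) <- c("a", "b")
      A <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
      if (nrow(edges) > 0) {
        for (e in seq_len(nrow(edges))) {
          u <- edges[e, 1]; v <- edges[e, 2]
          A[u, v] <- stats::runif(1, a_range[1], a_range[2]) * sample(c(-1, 1), 1)
          A[v, u] <- stats::runif(1, a_range[1], a_range[2]) * sample(c(-1, 1), 1)
        }
      }
      lambda <- stats::setNames(
        stats::runif(n_nodes, lambda_range[1], lambda_range[2]), nodes)
      k <- stats::setNames(stats::runif(n_nodes, k_range[1], k_range[2]), nodes)
      x0 <- stats::setNames(stats::runif(n_nodes, x0_range[1], x0_range[2]), nodes)
      update <- diag(n_nodes) + A - diag(lambda)
      rho <- max(Mod(eigen(update, only.values = TRUE)$values))
      if (rho <= stability_limit) {
        return(structure(
          list(nodes = nodes, edges = edges, a = A, lambda = lambda, k = k,
               x0 = x0, noise_sigma = noise_sigma, seed = seed,
               spectral_radius = rho, attempts = attempt),
          class = "ground_truth_model"))
      }
    }
    stop_regennet(
      "could not satisfy the stability guard in 100 attempts; shrink a_range",
      "regennet_generation_error")
  })
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf(
    "Ground-truth dynamic model: %d proteins, %d true interactions (rho = %.3f, sigma = %g)\n",
    length(x$nodes), nrow(x$edges), x$spectral_radius, x$noise_sigma))
  invisible(x)
}

#' Simulate time-course expression from a ground-truth model
#'
#' Iterates the dynamic update on a uniform internal grid of `dense_steps`
#' times spanning the design interval, adding i.i.d. Gaussian process noise
#' (sd `model$noise_sigma`) per node and step. Each design time point is read
#' off the nearest internal grid point and each replicate receives independent
#' Gaussian measurement noise of the same sd. Expression is not clipped at
#' zero (the model is linear; set `clip = TRUE` for display purposes only).
#'
#' @param model A [generate_ground_truth()] model.
#' @param design A [time_design()]; defaults to [regen_design()].
#' @param dense_steps Internal grid size, at least the number of design time
#'   points; default 16.
#' @param seed Integer RNG seed for the noise draws.
#' @param clip Clip simulated values at 0 (off by default).
#' @return An [expression_matrix()] (condition label `"synthetic"`).
#' @export
simulate_expression <- function(model, design = regen_design(),
                                dense_steps = 16, seed = 1, clip = FALSE) {
  stopifnot(inherits(model, "ground_truth_model"), inherits(design, "time_design"))
  dense_steps <- as.integer(dense_steps)
  if (dense_steps < length(design$time_points)) {
    stop_regennet("dense_steps must be >= the number of design time points",
                  "regennet_parameter_error")
  }
  n <- length(model$nodes)
  times <- design$time_points
  grid <- seq(times[1], times[length(times)], length.out = dense_steps)
  sigma <- model$noise_sigma
  with_seed(seed, {
    traj <- matrix(0, n, dense_steps, dimnames = list(model$nodes, NULL))
    traj[, 1] <- model$x0
    for (s in seq_len(dense_steps - 1)) {
      eps <- if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
      traj[, s + 1] <- traj[, s] + model$a %*% traj[, s] -
        model$lambda * traj[, s] + model$k + eps
    }
    # sample each design time at the nearest internal grid point
    idx <- vapply(times, function(t) which.min(abs(grid - t)), integer(1))
    cols <- vector("list", length(times))
    for (ti in seq_along(times)) {
      reps <- design$replicates[ti]
      base_col <- traj[, idx[ti]]
      cols[[ti]] <- vapply(seq_len(reps), function(r) {
        base_col + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
      }, numeric(n))
    }
    vals <- do.call(cbind, cols)
    if (clip) vals[vals < 0] <- 0
    expression_matrix(vals, design, protein_ids = model$nodes,
                      condition = "synthetic")
  })
}

#' Spike false-positive edges into a candidate network
#'
#' Builds the pruning task the AIC stage must solve: the true edge set plus
#' `round(fp_ratio * n_true)` uniformly sampled absent pairs (their true
#' interaction ability is zero by construction).
#'
#' @param model A [generate_ground_truth()] model.
#' @param fp_ratio Nonnegative ratio of spiked to true edges.
#' @param seed Integer RNG seed.
#' @return A [candidate_network()]; the spiked pairs are recorded in attribute
#'   `spiked` (two-column character matrix).
#' @export
spike_false_positives <- function(model, fp_ratio = 1, seed = 1) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (fp_ratio < 0) {
    stop_regennet("fp_ratio must be nonnegative", "regennet_parameter_error")
  }
  n_spike <- round(fp_ratio * nrow(model$edges))
  pairs <- t(utils::combn(model$nodes, 2))
  true_keys <- pair_key(model$edges[, 1], model$edges[, 2])
  absent <- pairs[!pair_key(pairs[, 1], pairs[, 2]) %in% true_keys, ,
                  drop = FALSE]
  if (n_spike > nrow(absent)) {
    stop_regennet(sprintf(
      "requested %d spiked edges but only %d absent pairs exist",
      n_spike, nrow(absent)), "regennet_parameter_error")
  }
  spiked <- with_seed(seed, {
    absent[sample.int(nrow(absent), n_spike), , drop = FALSE]
  })
  out <- candidate_network(c(model$edges[, 1], spiked[, 1]),
                           c(model$edges[, 2], spiked[, 2]))
  colnames(spiked) <- c("a", "b")
  attr(out, "spiked") <- spiked
  out
}

#' Score edge recovery against the ground truth
#'
#' Confusion counts on undirected edge sets. Conventions: precision is 1 when
#' nothing was predicted, recall is 1 when there was nothing to recover, and F1
#' is 0 when undefined.
#'
#' @param refined A `refined_network` (or any object [write_network()]
#'   accepts).
#' @param model A [generate_ground_truth()] model (or a two-column character
#'   matrix of true edges).
#' @return An object of class `recovery_metrics`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_recovery <- function(refined, model) {
  pred_ed <- network_edges(refined)
  true_ed <- if (inherits(model, "ground_truth_model")) model$edges else model
  pred <- unique(pair_key(pred_ed[, "a"], pred_ed[, "b"]))
  truth <- unique(pair_key(true_ed[, 1], true_ed[, 2]))
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1),
    class = "recovery_metrics"
  )
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    "Edge recovery: TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F1 %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}
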