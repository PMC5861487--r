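# Whole-network inference: run the per-target dynamic fit and AIC pruning over
# every node of a candidate network and assemble the refined network.

#' Inference configuration
#'
#' @param m_points `"auto"` or a positive integer. `"auto"` fits on the
#'   observed grid (`T_obs` points) unless the largest candidate degree
#'   `N_max` demands more equations, in which case the spline grid grows to
#'   `N_max + 6` points so every target has at least `N_i + 2` equations plus
#'   a margin of 4. Interpolated points beyond that carry no new information
#'   and blunt the model-order selection, so the rule never oversamples an
#'   already sufficient grid.
#' @param merge `"both"` (default: an interaction is kept only when both
#'   endpoint regressions retain it, which is what keeps false-positive
#'   candidates in check) or `"union"` (either regression suffices).
#' @return A list of class `infer_control`.
#' @export
infer_control <- function(m_points = "auto", merge = c("both", "union")) {
  merge <- match.arg(merge)
  if (!identical(m_points, "auto")) {
    m_points <- as.integer(m_points)
    if (is.na(m_points) || m_points < 2) {
      stop_regennet("m_points must be 'auto' or an integer >= 2",
                    "regennet_parameter_error")
    }
  }
  structure(list(m_points = m_points, merge = merge),
            class = "infer_control")
}

resolve_m_points <- function(control, n_obs_times, n_max_degree) {
  if (identical(control$m_points, "auto")) {
    max(n_obs_times, n_max_degree + 2L + 4L)
  } else {
    control$m_points
  }
}

#' Fit dynamic PPI models over a candidate network
#'
#' The model-fitting entry point of the package. For every node of the
#' candidate network, its expression trajectory is regressed on its candidate
#' interactors under the discrete-time dynamic model (see [prune_by_aic()]);
#' the per-target AIC scans decide which candidate interactions carry
#' identifiable interaction ability. An undirected edge survives if it is
#' retained by both of its endpoint regressions (default) or by at least one
#' (`merge = "union"`).
#'
#' The whole procedure is deterministic: ties are broken lexicographically and
#' no randomness is involved.
#'
#' @param candidate A [candidate_network()].
#' @param matrix An [expression_matrix()] containing every candidate node.
#' @param control An [infer_control()].
#' @return An object of class `refined_network`: list with `nodes`, `edges`
#'   (data.frame `a`, `b`, `a_ab`, `a_ba`: `a_ab` is the fitted ability of b in
#'   a's regression when retained there, else `NA`), `selections` (named list
#'   of [prune_by_aic()] results per target), `dense` (the shared
#'   [spline_densify()] grid), `control`, `condition` and `call`. Supports
#'   `print`, `summary`, `coef`, `residuals`, `fitted`, `predict`, `plot` and
#'   `simulate`.
#' @seealso [prune_by_aic()], [compare_networks()], [evaluate_recovery()]
#' @export
infer_network <- function(candidate, matrix, control = infer_control()) {
  stopifnot(inherits(candidate, "candidate_network"),
            inherits(matrix, "expression_matrix"),
            inherits(control, "infer_control"))
  cl <- match.call()
  missing_nodes <- setdiff(candidate$nodes, rownames(matrix$values))
  if (length(missing_nodes) > 0) {
    stop_regennet(paste0("candidate nodes missing from the expression matrix: ",
                         paste(missing_nodes, collapse = ", ")),
                  "regennet_lookup_error")
  }
  nodes <- candidate$nodes
  nbrs <- lapply(stats::setNames(nodes, nodes),
                 function(v) neighborhood(candidate, v))
  n_max <- if (length(nbrs) > 0) max(lengths(nbrs)) else 0L
  m_points <- resolve_m_points(control, length(matrix$design$time_points), n_max)
  dense <- spline_densify(matrix, m_points)

  selections <- vector("list", length(nodes))
  names(selections) <- nodes
  for (v in nodes) {
    problem <- assemble_regression(v, nbrs[[v]], dense)
    selections[[v]] <- prune_by_aic(problem)
  }

  # directed retention: ability[target -> source] where retained
  retained_in <- function(target, source) {
    sel <- selections[[target]]
    if (is.null(sel) || !source %in% sel$retained_interactors) return(NA_real_)
    sel$estimate$interaction_abilities[[source]]
  }
  keep_a <- character(0); keep_b <- character(0)
  ab <- numeric(0); ba <- numeric(0)
  if (nrow(candidate$edges) > 0) {
    for (e in seq_len(nrow(candidate$edges))) {
      u <- candidate$edges[e, "a"]
      v <- candidate$edges[e, "b"]
      a_uv <- retained_in(u, v)  # effect of v on u
      a_vu <- retained_in(v, u)
      keep_edge <- if (control$merge == "union") {
        !is.na(a_uv) || !is.na(a_vu)
      } else {
        !is.na(a_uv) && !is.na(a_vu)
      }
      if (keep_edge) {
        keep_a <- c(keep_a, u); keep_b <- c(keep_b, v)
        ab <- c(ab, a_uv); ba <- c(ba, a_vu)
      }
    }
  }
  edges <- data.frame(a = keep_a, b = keep_b, a_ab = ab, a_ba = ba,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort(unique(c(edges$a, edges$b))),
         edges = edges,
         selections = selections,
         dense = dense,
         control = control,
         condition = matrix$condition,
         call = cl),
    class = "refined_network"
  )
}

#' Read a network TSV written by [write_network()] as a refined network
#'
#' Reconstructs the node/edge structure and the per-direction abilities;
#' per-target fit details (`selections`, `dense`) are not stored on disk and
#' are absent from the result.
#'
#' @param path Path to the TSV.
#' @return A `refined_network` (structure-only).
#' @export
read_refined_network <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b")
  if (length(setdiff(need, colnames(df))) > 0) {
    stop_regennet("network TSV lacks protein_a/protein_b columns",
                  "regennet_format_error")
  }
  edges <- data.frame(
    a = as.character(df$protein_a), b = as.character(df$protein_b),
    a_ab = if ("a_ab" %in% colnames(df)) as.numeric(df$a_ab) else NA_real_,
    a_ba = if ("a_ba" %in% colnames(df)) as.numeric(df$a_ba) else NA_real_,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
         selections = NULL, dense = NULL, control = NULL, condition = "",
         call = NULL),
    class = "refined_network"
  )
}

#' @export
print.refined_network <- function(x, ...) {
  cat(sprintf("Refined PPI network%s: %d proteins, %d interactions\n",
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else "",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
summary.refined_network <- function(object, ...) {
  deg <- table(factor(c(object$edges$a, object$edges$b), levels = object$nodes))
  orders <- if (!is.null(object$selections)) {
    vapply(object$selections, function(s) s$selected_order, integer(1))
  } else {
    integer(0)
  }
  out <- list(
    condition = object$condition,
    n_nodes = length(object$nodes),
    n_edges = nrow(object$edges),
    degree_summary = if (length(deg) > 0) summary(as.integer(deg)) else NULL,
    mean_selected_order = if (length(orders) > 0) mean(orders) else NA_real_,
    n_bidirectional = sum(!is.na(object$edges$a_ab) & !is.na(object$edges$a_ba))
  )
  class(out) <- "summary.refined_network"
  out
}

#' @export
print.summary.refined_network <- function(x, ...) {
  cat(sprintf("Refined PPI network%s\n",
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else ""))
  cat(sprintf("  proteins: %d, interactions: %d (%d retained in both directions)\n",
              x$n_nodes, x$n_edges, x$n_bidirectional))
  if (!is.null(x$degree_summary)) {
    cat("  degree distribution:\n")
    print(x$degree_summary)
  }
  if (!is.na(x$mean_selected_order)) {
    cat(sprintf("  mean selected model order: %.2f\n", x$mean_selected_order))
  }
  invisible(x)
}

#' Fitted parameters of a refined network
#'
#' @param object A `refined_network` from [infer_network()].
#' @param what `"interactions"` for the directed interaction abilities (one row
#'   per retained direction: target, interactor, ability) or `"self"` for the
#'   per-target degradation effect and basal level.
#' @param ... Ignored.
#' @return A data.frame.
#' @export
coef.refined_network <- function(object, what = c("interactions", "self"), ...) {
  what <- match.arg(what)
  if (is.null(object$selections)) {
    stop_regennet("this network carries no fit details (read from disk?)",
                  "regennet_contract_error")
  }
  if (what == "self") {
    return(data.frame(
      target = names(object$selections),
      lambda = vapply(object$selections, function(s) s$estimate$degradation,
                      numeric(1)),
      basal = vapply(object$selections, function(s) s$estimate$basal, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE))
  }
  rows <- lapply(object$selections, function(s) {
    if (s$selected_order == 0) return(NULL)
    data.frame(target = s$target, interactor = s$retained_interactors,
               ability = unname(
                 s$estimate$interaction_abilities[s$retained_interactors]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target = character(), interactor = character(),
                      ability = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
residuals.refined_network <- function(object, ...) {
  if (is.null(object$selections)) return(NULL)
  lapply(object$selections, function(s) s$estimate$residuals)
}

#' @export
fitted.refined_network <- function(object, ...) {
  if (is.null(object$selections)) return(NULL)
  lapply(object$selections, function(s) s$estimate$fitted)
}

#' One-step-ahead predictions from the fitted dynamic models
#'
#' For each target, predicts the next-step expression from current levels under
#' the fitted model. With `newdata = NULL` this reproduces the in-sample fitted
#' values.
#'
#' @param object A `refined_network` with fit details.
#' @param newdata Optional proteins x times numeric matrix of current levels
#'   (row names must cover each target and its retained interactors).
#' @param ... Ignored.
#' @return A named list of numeric vectors, one per target.
#' @export
predict.refined_network <- function(object, newdata = NULL, ...) {
  if (is.null(object$selections)) {
    stop_regennet("this network carries no fit details (read from disk?)",
                  "regennet_contract_error")
  }
  if (is.null(newdata)) return(fitted(object))
  lapply(object$selections, function(s) {
    est <- s$estimate
    ids <- c(s$retained_interactors, s$target)
    missing_ids <- setdiff(ids, rownames(newdata))
    if (length(missing_ids) > 0) {
      stop_regennet(paste0("newdata lacks rows: ",
                           paste(missing_ids, collapse = ", ")),
                    "regennet_lookup_error")
    }
    x_t <- newdata[s$target, ]
    drive <- if (s$selected_order > 0) {
      drop(est$interaction_abilities[s$retained_interactors] %*%
             newdata[s$retained_interactors, , drop = FALSE])
    } else 0
    x_t + drive - est$degradation * x_t + est$basal
  })
}

#' Simulate trajectories from a fitted refined network
#'
#' Iterates the fitted dynamic model (retained interaction abilities,
#' degradation and basal terms) from the first dense-grid expression state,
#' optionally adding Gaussian noise.
#'
#' @param object A `refined_network` with fit details.
#' @param nsim Number of simulated trajectory sets.
#' @param seed Optional RNG seed (restored afterwards).
#' @param sigma Gaussian noise standard deviation per node and step, default 0.
#' @param ... Ignored.
#' @return A list of `nsim` matrices (proteins x grid points).
#' @export
simulate.refined_network <- function(object, nsim = 1, seed = NULL, sigma = 0,
                                     ...) {
  if (is.null(object$selections) || is.null(object$dense)) {
    stop_regennet("this network carries no fit details (read from disk?)",
                  "regennet_contract_error")
  }
  run <- function() {
    vals <- object$dense$values
    targets <- names(object$selections)
    m <- length(object$dense$grid)
    out <- matrix(0, nrow = length(targets), ncol = m,
                  dimnames = list(targets, NULL))
    out[, 1] <- vals[targets, 1]
    for (s_idx in seq_len(m - 1)) {
      cur <- out[, s_idx]
      for (v in targets) {
        sel <- object$selections[[v]]
        est <- sel$estimate
        drive <- if (sel$selected_order > 0) {
          sum(est$interaction_abilities[sel$retained_interactors] *
                cur[sel$retained_interactors])
        } else 0
        out[v, s_idx + 1] <- cur[v] + drive - est$degradation * cur[v] +
          est$basal + if (sigma > 0) stats::rnorm(1, 0, sigma) else 0
      }
    }
    out
  }
  sims <- if (is.null(seed)) {
    replicate(nsim, run(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, run(), simplify = FALSE))
  }
  sims
}

#' Plot a refined network
#'
#' Draws the undirected network with igraph; edge width scales with the largest
#' absolute fitted interaction ability of the edge.
#'
#' @param x A `refined_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return The igraph object, invisibly.
#' @export
plot.refined_network <- function(x, ...) {
  if (nrow(x$edges) == 0) {
    warning("empty network: nothing to plot")
    return(invisible(NULL))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = x$edges$a, to = x$edges$b, stringsAsFactors = FALSE),
    directed = FALSE)
  w <- pmax(abs(ifelse(is.na(x$edges$a_ab), 0, x$edges$a_ab)),
            abs(ifelse(is.na(x$edges$a_ba), 0, x$edges$a_ba)))
  width <- if (max(w) > 0) 0.5 + 2.5 * w / max(w) else 1
  igraph::plot.igraph(g, edge.width = width, vertex.size = 6,
                      vertex.label.cex = 0.7, ...)
  invisible(g)
}
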