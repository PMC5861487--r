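# Independent oracles, implemented from first principles so they share no code
# with the package internals they check.

# Natural cubic interpolating spline via the textbook tridiagonal system for
# the knot second derivatives (M_1 = M_n = 0), evaluated piecewise.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  h <- diff(x)
  # interior equations: h[i-1] M[i-1] + 2(h[i-1]+h[i]) M[i] + h[i] M[i+1] = rhs
  n_int <- n - 2
  A <- matrix(0, n_int, n_int)
  rhs <- numeric(n_int)
  for (r in seq_len(n_int)) {
    i <- r + 1  # knot index 2..n-1
    if (r > 1) A[r, r - 1] <- h[i - 1]
    A[r, r] <- 2 * (h[i - 1] + h[i])
    if (r < n_int) A[r, r + 1] <- h[i]
    rhs[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- c(0, solve(A, rhs), 0)
  vapply(xout, function(xx) {
    i <- findInterval(xx, x, rightmost.closed = TRUE)
    i <- min(max(i, 1), n - 1)
    hi <- h[i]
    t1 <- x[i + 1] - xx
    t2 <- xx - x[i]
    M[i] * t1^3 / (6 * hi) + M[i + 1] * t2^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * t1 +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * t2
  }, numeric(1))
}

# One-way fixed-effects ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }))
  ss_within <- sum(unlist(lapply(split(values, groups), function(g) {
    (g - mean(g))^2
  })))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss_between = ss_between, ss_within = ss_within)
}

# Linear-interpolation percentile at rank position (n-1) * q / 100.
oracle_percentile <- function(v, q) {
  v <- sort(unname(v))
  pos <- (length(v) - 1) * q / 100
  lo <- floor(pos)
  frac <- pos - lo
  if (lo + 2 > length(v)) return(v[length(v)])
  v[lo + 1] * (1 - frac) + v[lo + 2] * frac
}

# Orientation-insensitive pair normalization by explicit sort + unique.
oracle_normalize_pairs <- function(a, b) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  unique(paste(lo, hi, sep = "|"))
}

# Exhaustive AIC model-order selection: fit every interactor subset.
oracle_exhaustive_aic <- function(problem) {
  ids <- problem$interactors
  n <- length(ids)
  best_k <- Inf
  best_subset <- character(0)
  for (mask in 0:(2^n - 1)) {
    subset <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    est <- fit_constrained_ls(problem, subset)
    k <- aic_score(est, length(subset) + 2, problem$n_equations)
    if (k < best_k) {
      best_k <- k
      best_subset <- subset
    }
  }
  list(k = best_k, subset = sort(best_subset))
}

# Brute-force confusion counts on undirected edge key sets.
oracle_confusion <- function(pred_keys, true_keys) {
  tp <- sum(pred_keys %in% true_keys)
  list(tp = tp, fp = length(pred_keys) - tp,
       fn = sum(!true_keys %in% pred_keys))
}

edge_keys <- function(net) {
  ed <- if (inherits(net, "refined_network")) cbind(net$edges$a, net$edges$b)
        else if (inherits(net, "candidate_network")) net$edges
        else net
  if (nrow(ed) == 0) return(character(0))
  paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]), sep = "|")
}
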