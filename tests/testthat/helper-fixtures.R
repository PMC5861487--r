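# Programmatic fixtures shared by the suite.

# The dense benchmark design used wherever edge recovery is measured: a
# 0.1-dpi uniform sampling of the 0-3 dpi window with duplicate arrays,
# matched step-for-step by the simulator grid so the discrete model holds
# exactly on the fitted grid.
bench_design <- function() time_design(seq(0, 3, by = 0.1), replicates = 2L)
bench_steps <- function() length(seq(0, 3, by = 0.1))

# n random id pairs without self-pairs (duplicates allowed; edge_list dedups)
normalize_random_pairs <- function(ids, n) {
  a <- sample(ids, n, replace = TRUE)
  b <- sample(ids, n, replace = TRUE)
  keep <- a != b
  cbind(a[keep], b[keep])
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_expression <- function(n_proteins, design, seed) {
  set.seed(seed)
  vals <- matrix(stats::runif(n_proteins * n_samples(design), 0.5, 4),
                 nrow = n_proteins)
  expression_matrix(vals, design,
                    protein_ids = sprintf("pr%02d", seq_len(n_proteins)))
}

# Dense trajectories with smooth, well-conditioned curves for regression tests.
random_dense <- function(ids, m, seed, span = c(0, 3)) {
  set.seed(seed)
  grid <- seq(span[1], span[2], length.out = m)
  vals <- t(vapply(ids, function(id) {
    a <- stats::runif(3, -1, 1)
    1.5 + a[1] * grid + a[2] * sin(grid * stats::runif(1, 1, 3)) +
      a[3] * cos(grid * stats::runif(1, 0.5, 2))
  }, numeric(m)))
  rownames(vals) <- ids
  structure(list(grid = grid, values = vals), class = "dense_trajectory")
}

# Simulate target data that satisfies the dynamic update exactly on the grid:
# x_i[t+1] = x_i[t] + sum_j a_j x_j[t] - lambda x_i[t] + k.
make_target_problem <- function(dense, a, lambda, k, target = ".target",
                                extra_interactors = character(0)) {
  drivers <- names(a)
  m <- length(dense$grid)
  x <- numeric(m)
  x[1] <- 1
  for (s in seq_len(m - 1)) {
    x[s + 1] <- x[s] + sum(a * dense$values[drivers, s]) - lambda * x[s] + k
  }
  vals <- rbind(dense$values, x)
  rownames(vals) <- c(rownames(dense$values), target)
  dense2 <- structure(list(grid = dense$grid, values = vals),
                      class = "dense_trajectory")
  assemble_regression(target, sort(c(drivers, extra_interactors)), dense2)
}
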