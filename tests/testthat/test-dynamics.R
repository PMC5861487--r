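test_that("spline densification reproduces linear trajectories exactly", {
  design <- time_design(c(0, 0.25, 1, 3), replicates = 2)
  times <- rep(design$time_points, each = 2)
  vals <- rbind(2 + 3 * times, 1 - 0.5 * times)
  m <- expression_matrix(vals, design, protein_ids = c("up", "down"))
  dense <- spline_densify(m, 13)
  expect_equal(dense$values["up", ], 2 + 3 * dense$grid, tolerance = 1e-10)
  expect_equal(dense$values["down", ], 1 - 0.5 * dense$grid, tolerance = 1e-10)
})

test_that("grid points at knots return the replicate means", {
  design <- time_design(c(0, 1, 2, 3), replicates = 2)
  m <- random_expression(3, design, seed = 77)
  dense <- spline_densify(m, 7)  # grid 0, .5, 1, ... hits every knot
  groups <- rep(1:4, each = 2)
  for (i in 1:3) {
    means <- tapply(m$values[i, ], groups, mean)
    knot_cols <- match(design$time_points, dense$grid)
    expect_equal(unname(dense$values[i, knot_cols]), as.numeric(means),
                 tolerance = 1e-9)
  }
})

test_that("densified values match the tridiagonal natural-spline oracle", {
  design <- time_design(c(0, 0.25, 1, 3), replicates = 1)
  set.seed(8)
  vals <- matrix(runif(8, 0, 5), nrow = 2)
  m <- expression_matrix(vals, design, protein_ids = c("a", "b"))
  dense <- spline_densify(m, 13)
  for (i in 1:2) {
    expect_equal(dense$values[i, ],
                 oracle_natural_spline(design$time_points, vals[i, ], dense$grid),
                 tolerance = 1e-9)
  }
})

test_that("densification validates m_points and falls back to linear at 2 knots", {
  design <- time_design(c(0, 0.25, 1, 3), replicates = 1)
  m <- random_expression(2, design, seed = 1)
  expect_error(spline_densify(m, 3), class = "regennet_parameter_error")
  d2 <- time_design(c(0, 3), replicates = 1)
  m2 <- expression_matrix(rbind(c(0, 3), c(1, 4)), d2, protein_ids = c("a", "b"))
  expect_message(dense <- spline_densify(m2, 4), "linear")
  expect_equal(unname(dense$values["a", ]), dense$grid, tolerance = 1e-12)
})

test_that("regression assembly lays out response and design as the model dictates", {
  ids <- c("i1", "i2", "tg")
  dense <- random_dense(ids, 11, seed = 2)
  # no interactors, M = 4
  d4 <- structure(list(grid = dense$grid[1:4],
                       values = dense$values[, 1:4]),
                  class = "dense_trajectory")
  p0 <- assemble_regression("tg", character(0), d4)
  expect_equal(dim(p0$design), c(3, 2))
  expect_equal(p0$design[, 1], unname(dense$values["tg", 1:3]))
  expect_equal(p0$design[, 2], rep(1, 3))
  # 2 interactors, M = 11
  p2 <- assemble_regression("tg", c("i1", "i2"), dense)
  expect_equal(dim(p2$design), c(10, 4))
  expect_equal(p2$design[1, ],
               unname(c(dense$values["i1", 1], dense$values["i2", 1],
                        dense$values["tg", 1], 1)))
  expect_equal(p2$response[1], unname(dense$values["tg", 2]))
  expect_equal(p2$n_equations, 10)
  # entries equal direct indexing of the dense values everywhere
  for (r in sample(1:10, 4)) {
    expect_equal(p2$design[r, 1:2], unname(dense$values[c("i1", "i2"), r]))
    expect_equal(p2$response[r], unname(dense$values["tg", r + 1]))
  }
  expect_error(assemble_regression("tg", c("tg", "i1"), dense),
               class = "regennet_contract_error")
  expect_error(assemble_regression("zz", "i1", dense),
               class = "regennet_lookup_error")
})

test_that("assembly enforces the identifiability margin", {
  ids <- c("i1", "i2", "i3", "tg")
  d4 <- random_dense(ids, 4, seed = 3)  # 3 equations < 3 + 2
  expect_error(assemble_regression("tg", c("i1", "i2", "i3"), d4),
               class = "regennet_identifiability_error")
})

test_that("constrained least squares recovers noiseless dynamics exactly", {
  drivers <- random_dense(c("j1", "j2"), 12, seed = 4)
  prob <- make_target_problem(drivers, c(j1 = 0.3, j2 = -0.2),
                              lambda = 0.1, k = 0.5)
  est <- fit_constrained_ls(prob)
  expect_equal(unname(est$interaction_abilities[c("j1", "j2")]), c(0.3, -0.2),
               tolerance = 1e-6)
  expect_equal(est$degradation, 0.1, tolerance = 1e-6)
  expect_equal(est$basal, 0.5, tolerance = 1e-6)
  expect_lt(sqrt(est$rss), 1e-9)
})

test_that("the all-zero degenerate problem resolves by the minimum-norm rule", {
  dense <- structure(list(grid = 0:5,
                          values = matrix(0, 1, 6, dimnames = list("tg", NULL))),
                     class = "dense_trajectory")
  prob <- assemble_regression("tg", character(0), dense)
  est <- fit_constrained_ls(prob)
  expect_equal(est$basal, 0)
  expect_equal(est$rss, 0)
  expect_true(est$degenerate)
  # minimum-norm drives the self coefficient 1 - lambda to 0
  expect_equal(est$degradation, 1)
})

test_that("no feasible parameter vector beats the constrained optimum", {
  drivers <- random_dense(c("j1", "j2", "j3"), 10, seed = 6)
  prob <- make_target_problem(drivers, c(j1 = 0.4, j2 = -0.3, j3 = 0.05),
                              lambda = 0.25, k = 0.1)
  # add noise so the optimum is interiorish but nontrivial
  set.seed(61)
  prob$response <- prob$response + rnorm(length(prob$response), 0, 0.2)
  est <- fit_constrained_ls(prob)
  X <- prob$design
  for (draw in 1:100) {
    theta <- c(runif(3, -1, 1), runif(1, 0, 1), runif(1, 0, 2))
    rss_rand <- sum((prob$response - X %*% theta)^2)
    expect_gte(rss_rand, est$rss - 1e-9)
  }
})

test_that("bound constraints are honored when the unconstrained fit violates them", {
  # build data whose unconstrained self coefficient exceeds 1 (growth > 1)
  dense <- structure(list(
    grid = 0:7,
    values = matrix(2^(0:7), 1, 8, dimnames = list("tg", NULL))),
    class = "dense_trajectory")
  prob <- assemble_regression("tg", character(0), dense)
  est <- fit_constrained_ls(prob)
  expect_gte(est$degradation, 0)
  expect_lte(est$degradation, 1)
  expect_gte(est$basal, 0)
  # and the fit is still the best feasible one
  X <- prob$design
  for (draw in 1:50) {
    theta <- c(runif(1, 0, 1), runif(1, 0, 5))
    expect_gte(sum((prob$response - X %*% theta)^2), est$rss - 1e-9)
  }
})

test_that("the information criterion reproduces its defining arithmetic", {
  expect_identical(aic_score(rep(1, 4), n_params = 2), 1.0)
  expect_equal(aic_score(rep(0, 4), n_params = 2), log(1e-12) + 1)
  set.seed(71)
  for (rep in 1:20) {
    r <- rnorm(sample(3:12, 1))
    np <- sample(1:5, 1)
    expect_equal(aic_score(r, np),
                 log(max(sum(r^2) / length(r), 1e-12)) + 2 * np / length(r),
                 tolerance = 1e-12)
  }
})

test_that("at fixed residual error the criterion strictly increases with order", {
  r <- rnorm(10)
  ks <- vapply(1:6, function(np) aic_score(r, np), numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("AIC pruning handles the trivial and the planted-singleton cases", {
  # no candidates: trace has the self-only model only
  dense <- random_dense("tg", 8, seed = 81)
  p0 <- assemble_regression("tg", character(0), dense)
  sel0 <- prune_by_aic(p0)
  expect_equal(sel0$selected_order, 0)
  expect_length(sel0$aic_trace, 1)

  # exactly one of four candidates truly drives the target
  drivers <- random_dense(c("j1", "j2", "j3", "j4"), 14, seed = 82)
  prob <- make_target_problem(drivers, c(j2 = 0.5), lambda = 0.15, k = 0.3,
                              extra_interactors = c("j1", "j3", "j4"))
  sel <- prune_by_aic(prob)
  expect_identical(sel$retained_interactors, "j2")
  ex <- oracle_exhaustive_aic(prob)
  expect_identical(ex$subset, "j2")
  expect_equal(min(sel$aic_trace), ex$k, tolerance = 1e-9)
})

test_that("the selected criterion never exceeds the full or empty model", {
  set.seed(91)
  for (rep in 1:8) {
    drivers <- random_dense(paste0("j", 1:3), 12, seed = 910 + rep)
    prob <- make_target_problem(drivers, c(j1 = 0.2, j3 = -0.3),
                                lambda = 0.2, k = 0.4,
                                extra_interactors = "j2")
    prob$response <- prob$response + rnorm(length(prob$response), 0, 0.05)
    sel <- prune_by_aic(prob)
    kmin <- min(sel$aic_trace)
    expect_lte(kmin, sel$aic_trace[1])                      # empty model
    expect_lte(kmin, sel$aic_trace[length(sel$aic_trace)])  # full model
    expect_equal(sel$aic_trace[sel$selected_order + 1], kmin)
  }
})

test_that("nested-scan selection is bounded below by the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:10) {
    drivers <- random_dense(paste0("j", 1:5), 14, seed = 1010 + rep)
    prob <- make_target_problem(drivers, c(j1 = 0.3, j4 = -0.25),
                                lambda = 0.1, k = 0.2,
                                extra_interactors = c("j2", "j3", "j5"))
    noisy <- rep %% 2 == 0
    if (noisy) {
      prob$response <- prob$response + rnorm(length(prob$response), 0, 0.1)
    }
    sel <- prune_by_aic(prob)
    ex <- oracle_exhaustive_aic(prob)
    expect_gte(min(sel$aic_trace), ex$k - 1e-9)
    if (!noisy) {
      expect_equal(min(sel$aic_trace), ex$k, tolerance = 1e-9)
      expect_identical(sort(sel$retained_interactors), ex$subset)
    }
  }
})

test_that("parameter error shrinks as observation noise shrinks", {
  sigmas <- c(0.5, 0.1, 0.02)
  mean_err <- vapply(sigmas, function(sg) {
    errs <- vapply(1:30, function(rep) {
      drivers <- random_dense(c("j1", "j2"), 12, seed = 3000 + rep)
      prob <- make_target_problem(drivers, c(j1 = 0.35, j2 = -0.25),
                                  lambda = 0.2, k = 0.5)
      set.seed(4000 + rep)
      prob$response <- prob$response + rnorm(length(prob$response), 0, sg)
      est <- fit_constrained_ls(prob)
      mean(abs(est$interaction_abilities[c("j1", "j2")] - c(0.35, -0.25)))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("relabeling interactor order never changes the retained set", {
  drivers <- random_dense(paste0("j", 1:4), 13, seed = 111)
  base <- make_target_problem(drivers, c(j1 = 0.3, j3 = -0.2),
                              lambda = 0.1, k = 0.3,
                              extra_interactors = c("j2", "j4"))
  set.seed(112)
  base$response <- base$response + rnorm(length(base$response), 0, 0.05)
  sel_ref <- sort(prune_by_aic(base)$retained_interactors)
  for (perm in 1:5) {
    ord <- sample(4)
    prob <- base
    prob$interactors <- base$interactors[ord]
    prob$design <- base$design[, c(ord, 5, 6)]
    expect_identical(sort(prune_by_aic(prob)$retained_interactors), sel_ref)
  }
})
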