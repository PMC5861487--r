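test_that("percentile normalization matches the closest-ranks oracle and is idempotent", {
  design <- time_design(c(0, 1), replicates = 2)
  m <- expression_matrix(rbind(c(1, 10, 2, 5), c(2, 20, 4, 10),
                               c(3, 30, 6, 20), c(4, 40, 8, 40)),
                         design, protein_ids = letters[1:4])
  out <- percentile_normalize(m, q = 75)
  for (j in 1:4) {
    expect_equal(out$values[, j], m$values[, j] / oracle_percentile(m$values[, j], 75))
    expect_equal(oracle_percentile(out$values[, j], 75), 1, tolerance = 1e-12)
  }
  # a column whose 75th percentile is already 1 is a fixed point
  fixed <- expression_matrix(
    rbind(c(0.25, 0.1), c(0.5, 0.2), c(1, 0.5), c(1, 1)),
    time_design(c(0, 1), replicates = 1), protein_ids = letters[1:4])
  expect_equal(percentile_normalize(fixed)$values[, 1], fixed$values[, 1])
  # idempotence
  twice <- percentile_normalize(out, q = 75)
  expect_equal(twice$values, out$values, tolerance = 1e-12)
})

test_that("percentile normalization is scale invariant per column", {
  design <- time_design(c(0, 1, 2), replicates = 2)
  m <- random_expression(6, design, seed = 9)
  scaled <- m
  scaled$values <- sweep(m$values, 2, c(2, 0.5, 10, 1, 3, 7), "*")
  expect_equal(percentile_normalize(scaled)$values,
               percentile_normalize(m)$values, tolerance = 1e-12)
})

test_that("a degenerate sample column is reported by name", {
  design <- time_design(c(0, 1), replicates = 1)
  m <- expression_matrix(rbind(c(0, 1), c(0, 2)), design,
                         protein_ids = c("a", "b"))
  expect_error(percentile_normalize(m), "t0_r1",
               class = "regennet_degenerate_sample_error")
})

test_that("log2 transform is the documented bijection", {
  design <- time_design(c(0, 1), replicates = 1)
  m <- expression_matrix(rbind(c(1, 0), c(3, 7)), design,
                         protein_ids = c("a", "b"))
  out <- log2_transform(m, offset = 1)
  expect_equal(out$values["a", ], c(t0_r1 = 1, t1_r1 = 0))
  inv <- 2^out$values - 1
  expect_equal(inv, m$values, tolerance = 1e-12)
  neg <- expression_matrix(matrix(c(-2, 1), 1), design, protein_ids = "a")
  expect_error(log2_transform(neg), class = "regennet_domain_error")
})

test_that("ANOVA F and p match a hand-computed sums-of-squares oracle", {
  design <- time_design(c(0, 1, 3), replicates = 2)
  vals <- rbind(c(1.0, 1.2, 2.9, 3.1, 5.0, 5.4),
                c(2.0, 2.1, 2.0, 2.2, 2.1, 1.9))
  m <- expression_matrix(vals, design, protein_ids = c("sig", "null"))
  pool <- anova_filter(m, alpha = 0.05, n_tests = 2)
  groups <- rep(1:3, each = 2)
  for (i in 1:2) {
    expect_equal(unname(pool$p_values[i]), oracle_anova(vals[i, ], groups)$p,
                 tolerance = 1e-12)
  }
  expect_identical(pool$protein_ids, "sig")
})

test_that("null proteins are excluded and extreme signal retained", {
  design <- time_design(c(0, 1), replicates = 2)
  m <- expression_matrix(rbind(c(5.01, 4.99, 5.02, 4.98),
                               c(0.001, -0.001, 10.001, 9.999)),
                         design, protein_ids = c("flatish", "jump"))
  pool <- anova_filter(m, alpha = 0.05, n_tests = 2)
  expect_false("flatish" %in% pool$protein_ids)
  expect_true("jump" %in% pool$protein_ids)
})

test_that("zero-variance proteins get p = 1 without an error", {
  design <- time_design(c(0, 1), replicates = 2)
  m <- expression_matrix(rbind(c(3, 3, 3, 3), c(0, 1, 5, 6)), design,
                         protein_ids = c("flat", "var"))
  expect_message(pool <- anova_filter(m, n_tests = 2), "zero-variance")
  expect_equal(unname(pool$p_values["flat"]), 1)
})

test_that("the ANOVA screen needs two replicates everywhere", {
  design <- time_design(c(0, 1), replicates = c(2, 1))
  m <- expression_matrix(matrix(1:3, 1), design, protein_ids = "a")
  expect_error(anova_filter(m), class = "regennet_design_error")
})

test_that("the screen is invariant to replicate and row order", {
  design <- time_design(c(0, 1, 2), replicates = 2)
  m <- random_expression(8, design, seed = 5)
  pool <- suppressMessages(anova_filter(m))
  # swap replicates within each time point
  perm <- c(2, 1, 4, 3, 6, 5)
  m2 <- expression_matrix(m$values[, perm], design,
                          protein_ids = rownames(m$values))
  pool2 <- suppressMessages(anova_filter(m2))
  expect_equal(pool$p_values, pool2$p_values, tolerance = 1e-12)
  # permute protein rows
  rp <- sample(nrow(m$values))
  m3 <- expression_matrix(m$values[rp, ], design,
                          protein_ids = rownames(m$values)[rp])
  pool3 <- suppressMessages(anova_filter(m3))
  expect_equal(pool$p_values[names(pool3$p_values)], pool3$p_values,
               tolerance = 1e-12)
})

test_that("shrinking alpha or growing the family never grows the pool", {
  design <- time_design(c(0, 0.25, 1, 3), replicates = 2)
  m <- random_expression(40, design, seed = 11)
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.001), function(al) {
    length(suppressMessages(anova_filter(m, alpha = al))$protein_ids)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  sizes_n <- vapply(c(10, 40, 400, 4000), function(nt) {
    length(suppressMessages(anova_filter(m, n_tests = nt))$protein_ids)
  }, integer(1))
  expect_true(all(diff(sizes_n) <= 0))
})

test_that("duplicate identifiers collapse to the most significant row", {
  design <- time_design(c(0, 1), replicates = 1)
  vals <- rbind(c(1, 2), c(3, 4), c(5, 6))
  # unique ids: identity
  out <- collapse_duplicates(vals, c("a", "b", "c"), c(0.5, 0.2, 0.9), design)
  expect_equal(nrow(out$values), 3)
  # keep the smaller p
  out2 <- collapse_duplicates(vals, c("A", "A", "b"), c(0.2, 0.01, 0.5), design)
  expect_equal(unname(out2$values["A", ]), c(3, 4))
  # ties break to first occurrence
  out3 <- collapse_duplicates(vals, c("A", "A", "b"), c(0.3, 0.3, 0.5), design)
  expect_equal(unname(out3$values["A", ]), c(1, 2))
})

test_that("random duplicated tables equal brute-force group-by-min", {
  design <- time_design(c(0, 1), replicates = 1)
  set.seed(13)
  for (rep in 1:5) {
    n <- 20
    ids <- sample(letters[1:6], n, replace = TRUE)
    vals <- matrix(rnorm(n * 2), n)
    p <- runif(n)
    out <- collapse_duplicates(vals, ids, p, design)
    for (id in unique(ids)) {
      rows <- which(ids == id)
      best <- rows[which.min(p[rows])]
      expect_equal(unname(out$values[id, ]), unname(vals[best, ]))
    }
  }
})

test_that("protein pools round-trip through their TSV form", {
  design <- time_design(c(0, 1, 2), replicates = 2)
  m <- random_expression(10, design, seed = 3)
  pool <- suppressMessages(anova_filter(m, alpha = 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_pool(pool, path)
  back <- read_protein_pool(path, alpha = pool$alpha)
  expect_identical(back$protein_ids, pool$protein_ids)
  expect_equal(back$p_values, pool$p_values, tolerance = 1e-12)
})
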