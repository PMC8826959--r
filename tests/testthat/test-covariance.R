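test_that("multiplicity rescales counts by relative gene target size", {
  x <- mutation_count_matrix(rbind(gA = c(3L, 0L), gB = c(1L, 2L)),
                             population_ids = c("p1", "p2"))
  # equal sizes: multiplicity equals counts
  ann_eq <- gene_annotation(c("gA", "gB"), c(250, 250))
  expect_equal(multiplicity_matrix(x, ann_eq), x$counts + 0)

  # a gene half the mean size doubles its counts; zeros stay zero
  ann <- gene_annotation(c("gA", "gB", "gC"), c(100, 300, 200))  # Lbar = 200
  m <- multiplicity_matrix(x, ann)
  expect_equal(m["gA", ], c(p1 = 6, p2 = 0))
  expect_equal(m["gB", ], c(p1 = 2 / 3, p2 = 4 / 3))
  expect_true(all((m == 0) == (x$counts == 0)))
})

test_that("normalized eigenvalues sum to M and a rank-1 matrix takes it all", {
  A <- outer(c(1, 2, 3), c(1, 0, 2, 1))
  res <- normalized_largest_eigenvalue(A, center = FALSE)
  expect_equal(sum(res$e), res$M, tolerance = 1e-9)
  expect_equal(res$e[1], 4)  # single nonzero eigenvalue captures all variance

  sim <- simulate_counts(covariance_null_config(1, m = 10))
  mm <- multiplicity_matrix(sim$matrix, sim$annotation)
  res2 <- normalized_largest_eigenvalue(mm)
  expect_equal(sum(res2$e), res2$M, tolerance = 1e-9)

  expect_error(normalized_largest_eigenvalue(matrix(1, 2, 1)), "2 populations")
  expect_error(normalized_largest_eigenvalue(matrix(0, 3, 4)), "2 genes")
})

test_that("Tracy-Widom centering and scaling take their closed-form values", {
  expect_equal(pardiv:::tw_center(1, 2), 2)
  expect_equal(pardiv:::tw_center(4, 5), (sqrt(4) + sqrt(4))^2 / 5)
  expect_equal(pardiv:::tw_scale(4, 5), (4 / 5) * (1 / 2 + 1 / 2)^(1 / 3))
})

test_that("the null statistic for white noise sits at the Tracy-Widom bulk", {
  set.seed(90210)
  stats <- replicate(200, {
    A <- matrix(rnorm(500 * 50), nrow = 500)
    normalized_largest_eigenvalue(A, center = FALSE)$stat
  })
  expect_lt(abs(mean(stats) - TW1_MEAN), 0.5)
})

test_that("fixed-margin randomization preserves margins and forced tables", {
  sim <- simulate_counts(covariance_null_config(7, m = 8))
  x <- sim$matrix
  y <- fixed_margin_randomize(x, seed = 3)
  expect_identical(rowSums(y$counts), rowSums(x$counts))
  expect_identical(colSums(y$counts), colSums(x$counts))
  expect_identical(x$counts, simulate_counts(covariance_null_config(7, m = 8))$matrix$counts)

  # a single nonzero row is forced by its margins
  forced <- matrix(c(2L, 0L, 0L, 0L, 0L, 0L, 3L, 0L, 0L), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("p", "q", "r")))
  out <- fixed_margin_randomize(forced, seed = 1)
  expect_identical(out, forced)

  expect_error(fixed_margin_randomize(matrix(0L, 2, 2,
    dimnames = list(c("a", "b"), c("p", "q")))), "no mutations")
})

test_that("covariance test P values obey permutation bounds and reproduce", {
  sim <- simulate_counts(covariance_null_config(21, m = 12))
  ct <- covariance_test(sim$matrix, sim$annotation, permutations = 19, seed = 4)
  expect_gte(ct$p_value, 1 / 20)
  expect_lte(ct$p_value, 1)
  expect_length(ct$null_stats, 19)
  ct2 <- covariance_test(sim$matrix, sim$annotation, permutations = 19, seed = 4)
  expect_identical(ct$observed_stat, ct2$observed_stat)
  expect_identical(ct$null_stats, ct2$null_stats)

  # a single permutation with null >= observed gives the add-one maximum P = 1
  ct1 <- covariance_test(sim$matrix, sim$annotation, permutations = 1, seed = 8)
  expect_true(ct1$p_value %in% c(0.5, 1))
})

test_that("detection-vs-replication tables are deterministic given the seed", {
  sim <- simulate_counts(covariance_null_config(5, m = 20))
  t1 <- detection_vs_replication(sim$matrix, sim$annotation,
                                 sizes = c(5, 10), reps = 10, seed = 77)
  t2 <- detection_vs_replication(sim$matrix, sim$annotation,
                                 sizes = c(5, 10), reps = 10, seed = 77)
  expect_identical(t1, t2)
  expect_error(detection_vs_replication(sim$matrix, sim$annotation,
                                        sizes = 50, reps = 2, seed = 1),
               "\\[2, M")
})
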