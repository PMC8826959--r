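test_that("pooled gene probabilities normalize, pool and ignore column order", {
  m <- mutation_count_matrix(matrix(c(3L, 0L, 1L, 0L), nrow = 2,
                                    dimnames = list(c("g1", "g2"), c("p1", "p2"))))
  expect_equal(unname(pooled_gene_probabilities(m)), c(1, 0))

  m2 <- mutation_count_matrix(diag(2) * 1L,
                              gene_ids = c("g1", "g2"),
                              population_ids = c("p1", "p2"))
  expect_equal(unname(pooled_gene_probabilities(m2)), c(0.5, 0.5))

  sim <- simulate_counts(occupancy_config(10, seed = 3))$matrix
  perm <- sample(ncol(sim$counts))
  shuffled <- mutation_count_matrix(sim$counts[, perm],
                                    treatments = sim$treatments[perm])
  expect_equal(pooled_gene_probabilities(shuffled), pooled_gene_probabilities(sim))
  expect_equal(sum(pooled_gene_probabilities(sim)), 1)

  zero <- mutation_count_matrix(matrix(0L, 1, 1, dimnames = list("g", "p")))
  expect_error(pooled_gene_probabilities(zero), "no mutations")
})

test_that("observed occupancy is the fraction of populations hit", {
  counts <- rbind(gA = c(2L, 0L, 1L), gB = c(0L, 0L, 0L), gC = c(1L, 3L, 2L))
  colnames(counts) <- paste0("p", 1:3)
  o <- observed_occupancy(mutation_count_matrix(counts))
  expect_equal(unname(o), c(2 / 3, 0, 1))
})

test_that("Poisson prediction matches brute-force enumeration of the sampling law", {
  counts <- matrix(c(3L, 1L, 0L, 2L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("p1", "p2")))
  x <- mutation_count_matrix(counts)
  p <- pooled_gene_probabilities(x)
  ntot <- population_totals(x)
  # enumerate the per-population binomial allocation over the two genes
  brute <- sapply(seq_along(p), function(i) {
    absent <- sapply(ntot, function(n) {
      sum(dbinom(0:n, n, p[i]) * (0:n == 0))
    })
    1 - mean(absent)
  })
  expect_equal(unname(predicted_occupancy_poisson(x)), brute, tolerance = 1e-12)
})

test_that("degenerate occupancy cases hit their closed-form values", {
  # all mutations in one gene, M = 1: certain occupancy
  one <- mutation_count_matrix(matrix(c(3L, 0L), ncol = 1,
                                      dimnames = list(c("g1", "g2"), "p1")))
  expect_equal(unname(predicted_occupancy_poisson(one)), c(1, 0))
  expect_equal(unname(predicted_occupancy_geometric(one))[2], 0)

  # mu = 1 with a single population: geometric occupancy is 1/2
  half <- mutation_count_matrix(matrix(c(1L, 1L), ncol = 1,
                                       dimnames = list(c("g1", "g2"), "p1")))
  expect_equal(unname(predicted_occupancy_geometric(half)), c(0.5, 0.5))

  # predictions always live in [0, 1]
  sim <- simulate_counts(occupancy_config(20, seed = 5))$matrix
  for (o in list(predicted_occupancy_poisson(sim),
                 predicted_occupancy_geometric(sim),
                 observed_occupancy(sim))) {
    expect_true(all(o >= 0 & o <= 1))
  }
})

test_that("occupancy_error averages absolute errors and excludes ties", {
  obs <- c(a = 0.5, b = 0.5)
  poi <- c(a = 0.6, b = 0.2)
  geo <- c(a = 0.7, b = 0.1)
  err <- occupancy_error(obs, poi, geo)
  expect_equal(err$mae_poisson, 0.2)
  expect_equal(err$mae_geometric, 0.3)
  expect_equal(err$fraction_poisson_better, 1)
  expect_equal(err$n_ties, 0)

  perfect <- occupancy_error(obs, obs, obs)
  expect_equal(perfect$mae_poisson, 0)
  expect_equal(perfect$n_ties, 2)
  expect_true(is.na(perfect$fraction_poisson_better))

  expect_error(occupancy_error(obs, poi[2:1], geo), "different gene sets")
})

test_that("Poisson beats the geometric alternative on model-generated data", {
  fit <- occupancy_fit(simulate_counts(occupancy_config(200, seed = 8))$matrix)
  expect_gt(fit$fraction_poisson_better, 0.5)
  expect_lt(fit$mae_poisson, fit$mae_geometric)
})

test_that("subsample error curve is deterministic and exact at the full size", {
  x <- simulate_counts(occupancy_config(12, seed = 2))$matrix
  full <- occupancy_fit(x)$mae_poisson
  tab <- subsample_error_curve(x, sizes = c(4, 12), reps = 5, seed = 99)
  expect_equal(tab$mean_mae[tab$m == 12], full)
  expect_equal(tab$sd_mae[tab$m == 12], 0)
  tab2 <- subsample_error_curve(x, sizes = c(4, 12), reps = 5, seed = 99)
  expect_identical(tab, tab2)
  expect_error(subsample_error_curve(x, sizes = 13, reps = 2, seed = 1),
               "\\[2, M")
})
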