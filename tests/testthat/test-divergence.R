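test_that("identical treatments yield no tested genes and no critical level", {
  n <- c(gA = 3, gB = 0, gC = 7)
  pair <- treatment_pair("A", "B", n, n)
  rep <- divergence_test(pair, n_genes = 100)
  expect_true(all(rep$genes$abs_delta_n == 0))
  expect_true(all(rep$genes$direction == "none"))
  expect_equal(rep$n_tested, 0)
  expect_true(is.na(rep$p_star))
  expect_false(any(rep$genes$significant))
})

test_that("swapping treatment labels flips directions and nothing else", {
  sim <- simulate_counts(divergence_power_config(17))
  pair <- collapse_by_treatment(sim$matrix)[[1]]
  fwd <- divergence_test(pair, alpha = 0.05, n_min = 1)

  # relabeling the environments flips every direction and changes nothing else
  relabeled <- treatment_pair(pair$label_2, pair$label_1, pair$n_1, pair$n_2)
  rev <- divergence_test(relabeled, alpha = 0.05, n_min = 1)
  expect_equal(fwd$genes$p_value, rev$genes$p_value)
  expect_equal(fwd$genes$abs_delta_n, rev$genes$abs_delta_n)
  expect_equal(fwd$genes$significant, rev$genes$significant)
  moved <- fwd$genes$direction != "none"
  expect_true(all(fwd$genes$direction[moved] != rev$genes$direction[moved]))
  expect_true(all(rev$genes$direction[!moved] == "none"))

  # the folded null is symmetric in the two rates: reversing the data order
  # leaves P values and significance untouched
  reversed <- treatment_pair(pair$label_2, pair$label_1, pair$n_2, pair$n_1)
  bwd <- divergence_test(reversed, alpha = 0.05, n_min = 1)
  expect_equal(fwd$genes$p_value, bwd$genes$p_value)
  expect_equal(fwd$genes$significant, bwd$genes$significant)
})

test_that("an all-zero comparison is rejected and null rates are the totals spread", {
  z <- c(g = 0)
  expect_error(divergence_test(treatment_pair("A", "B", z, z)),
               "no mutations in either treatment")
  pair <- treatment_pair("A", "B", c(g1 = 4, g2 = 0), c(g1 = 1, g2 = 1))
  rep <- divergence_test(pair, n_genes = 50)
  expect_equal(rep$null$lambda_1, 4 / 50)
  expect_equal(rep$null$lambda_2, 2 / 50)
})

test_that("P values in a report are non-increasing in the count difference", {
  sim <- simulate_counts(divergence_power_config(23))
  rep <- divergence_test(collapse_by_treatment(sim$matrix)[[1]], n_min = 1)
  g <- rep$genes[!is.na(rep$genes$p_value), ]
  ord <- order(g$abs_delta_n)
  expect_true(all(diff(g$p_value[ord]) <= 0))
})

test_that("consistent enrichment requires significance toward one treatment in every pair", {
  # gene0001 enriched in A only; B and C share the base rates
  cfg <- sim_config(n_genes = 200, m_per_treatment = 6,
                    treatments = c("A", "B", "C"),
                    rate_concentration = Inf,
                    total_law = list(law = "poisson", mean = 100),
                    enrichment = data.frame(gene = 1, treatment = "A", fold = 10),
                    seed = 31)
  reports <- divergence_test_all_pairs(simulate_counts(cfg)$matrix)
  sets <- consistent_enrichment(reports)
  expect_true("gene0001" %in% sets$A)
  expect_false("gene0001" %in% c(sets$B, sets$C))

  # dropping one comparison is an error naming the gap
  expect_error(consistent_enrichment(reports[-2]), "missing pairwise")

  # a gene significant toward a treatment in only some pairs is not assigned:
  # force significance of gene0001 toward B in the B-C pair only
  bc <- reports[["B|C"]]
  bc$genes$significant[bc$genes$gene_id == "gene0001"] <- TRUE
  bc$genes$direction[bc$genes$gene_id == "gene0001"] <- "B"
  sets2 <- consistent_enrichment(list(reports[["A|B"]], reports[["A|C"]], bc))
  expect_false("gene0001" %in% sets2$B)
})

test_that("two treatments reduce consistency to the single report's directed set", {
  sim <- simulate_counts(divergence_power_config(53))
  reports <- divergence_test_all_pairs(sim$matrix)
  sets <- consistent_enrichment(reports)
  g <- reports[[1]]$genes
  expect_setequal(sets$A, g$gene_id[g$significant & g$direction == "A"])
  expect_setequal(sets$B, g$gene_id[g$significant & g$direction == "B"])
})
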