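# Independent oracles and frozen simulation configs shared across tests.

# Brute-force folded difference of two independent Poisson laws, by direct
# convolution on a truncated support (independent of the package's Bessel
# evaluation).
conv_abs_pmf <- function(k, lambda_1, lambda_2, trunc = 400) {
  p1 <- dpois(0:trunc, lambda_1)
  p2 <- dpois(0:trunc, lambda_2)
  d <- abs(outer(0:trunc, 0:trunc, `-`))
  joint <- outer(p1, p2)
  vapply(k, function(kk) sum(joint[d == kk]), numeric(1))
}

conv_abs_upper_tail <- function(k_obs, lambda_1, lambda_2, trunc = 400) {
  if (k_obs == 0) return(1)
  1 - sum(conv_abs_pmf(0:(k_obs - 1), lambda_1, lambda_2, trunc = trunc))
}

# Enumerate all nonnegative integer tables with the given margins, with their
# probabilities under the conditional independence (Fisher) model.
enumerate_margin_tables <- function(r, c) {
  compositions <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (v in 0:min(total, caps[1])) {
      for (rest in compositions(total - v, caps[-1])) {
        out[[length(out) + 1]] <- c(v, rest)
      }
    }
    out
  }
  recurse <- function(rows_left, cols_remaining) {
    if (length(rows_left) == 1) {
      if (all(cols_remaining >= 0)) return(list(matrix(cols_remaining, nrow = 1)))
      return(list())
    }
    out <- list()
    for (row in compositions(rows_left[1], cols_remaining)) {
      for (sub in recurse(rows_left[-1], cols_remaining - row)) {
        out[[length(out) + 1]] <- rbind(row, sub, deparse.level = 0)
      }
    }
    out
  }
  tables <- recurse(r, c)
  n <- sum(r)
  logp <- vapply(tables, function(tab) {
    sum(lfactorial(r)) + sum(lfactorial(c)) - lfactorial(n) -
      sum(lfactorial(tab))
  }, numeric(1))
  list(tables = tables, prob = exp(logp))
}

table_key <- function(tab) paste(as.vector(tab), collapse = ",")

# Frozen study conditions used by the calibration/power checks. The effect
# sizes were fixed by pilot simulation before the assertions were written.
null_pair_config <- function(seed) {
  sim_config(n_genes = 500, m_per_treatment = 6, treatments = c("A", "B"),
             rate_concentration = Inf,
             total_law = list(law = "poisson", mean = 50), seed = seed)
}

divergence_power_config <- function(seed) {
  sim_config(n_genes = 200, m_per_treatment = 6, treatments = c("A", "B"),
             rate_concentration = Inf,
             total_law = list(law = "poisson", mean = 100),
             enrichment = data.frame(gene = 1, treatment = "A", fold = 10),
             seed = seed)
}

covariance_null_config <- function(seed, m = 50) {
  sim_config(n_genes = 300, m_per_treatment = m, rate_concentration = 1,
             total_law = list(law = "poisson", mean = 20), seed = seed)
}

covariance_power_config <- function(seed, sigma = 2) {
  sim_config(n_genes = 300, m_per_treatment = 100, rate_concentration = 1,
             total_law = list(law = "poisson", mean = 50),
             covariance = list(list(genes = 1:20, sigma = sigma)),
             seed = seed)
}

occupancy_config <- function(m, seed) {
  sim_config(n_genes = 100, m_per_treatment = m, rate_concentration = 1,
             total_law = list(law = "poisson", mean = 20), seed = seed)
}

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}

# small literal count matrix for I/O and arithmetic checks
tiny_matrix <- function() {
  mutation_count_matrix(matrix(c(1L, 0L, 0L, 2L), nrow = 2,
                               dimnames = list(c("gA", "gB"), c("p1", "p2"))))
}

# published mean of the Tracy-Widom beta = 1 law (numerical quadrature value)
TW1_MEAN <- -1.2065335745820
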