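#' Configuration for the synthetic count-matrix generator
#'
#' The generator mirrors the sampling frame the framework assumes: each
#' population draws its total mutation count, then allocates it multinomially
#' over genes according to a (possibly treatment- and population-specific)
#' relative rate vector. Structured departures from independence are injected
#' on top: treatment-specific enrichment (a fold change on chosen genes'
#' rates, renormalized) and gene-set covariance (a shared log-normal latent
#' multiplier per population on each set, renormalized).
#'
#' @param n_genes number of genes
#' @param m_per_treatment replicate populations per treatment
#' @param treatments character vector of treatment labels
#' @param rate_concentration symmetric Dirichlet concentration for the
#'   per-gene relative rates; `Inf` gives exactly uniform rates. Default 1
#'   (flat Dirichlet) gives the heterogeneous, sparse-count regime typical of
#'   evolve-and-resequence data.
#' @param total_law per-population total mutation count: either
#'   `list(law = "fixed", value = n)` or `list(law = "poisson", mean = mu)`
#' @param enrichment data.frame with columns `gene` (index or id), `treatment`,
#'   `fold` (> 0), or NULL
#' @param covariance list of `list(genes = indices, sigma = strength >= 0)`,
#'   or NULL; sigma is the standard deviation of the shared log-normal latent
#'   factor
#' @param length_meanlog,length_sdlog log-normal law for per-gene
#'   nonsynonymous site counts L (defaults: median ~700 sites, sdlog 0.5)
#' @param seed integer seed
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_genes, m_per_treatment, treatments = "default",
                       rate_concentration = 1,
                       total_law = list(law = "poisson", mean = 20),
                       enrichment = NULL, covariance = NULL,
                       length_meanlog = log(700), length_sdlog = 0.5,
                       seed = 1L) {
  rate_concentration <- as.numeric(rate_concentration)  # "Inf" from YAML
  stopifnot(n_genes >= 1, m_per_treatment >= 1, length(treatments) >= 1,
            rate_concentration > 0)
  if (!total_law$law %in% c("fixed", "poisson")) {
    stop_pardiv("total_law$law must be 'fixed' or 'poisson'",
                class = "pardiv_validation")
  }
  if (!is.null(enrichment)) {
    stopifnot(is.data.frame(enrichment),
              all(c("gene", "treatment", "fold") %in% colnames(enrichment)))
    if (any(enrichment$fold <= 0)) {
      stop_pardiv("enrichment fold changes must be > 0", class = "pardiv_validation")
    }
    if (!all(enrichment$treatment %in% treatments)) {
      stop_pardiv("enrichment names an unknown treatment", class = "pardiv_validation")
    }
  }
  if (!is.null(covariance)) {
    ok <- all(vapply(covariance, function(cv) {
      length(cv$genes) >= 2 && cv$sigma >= 0
    }, logical(1)))
    if (!ok) {
      stop_pardiv("covariance specs need >= 2 genes and sigma >= 0",
                  class = "pardiv_validation")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 m_per_treatment = as.integer(m_per_treatment),
                 treatments = as.character(treatments),
                 rate_concentration = rate_concentration,
                 total_law = total_law,
                 enrichment = enrichment, covariance = covariance,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a mutation count matrix with known ground truth
#'
#' @param config a [sim_config()]
#' @return list with `matrix` (a `count_matrix`), `annotation`
#'   (a `gene_annotation`), and `truth` (base rates, per-treatment rates,
#'   enriched and covarying gene ids, drawn totals)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    gene_ids <- sprintf("gene%04d", seq_len(G))
    # base relative rates shared across treatments
    base <- if (is.infinite(config$rate_concentration)) {
      rep(1 / G, G)
    } else {
      g <- stats::rgamma(G, shape = config$rate_concentration, rate = 1)
      if (sum(g) == 0) g <- rep(1, G)
      g / sum(g)
    }
    names(base) <- gene_ids
    # treatment-specific rates after enrichment
    rates <- lapply(config$treatments, function(t) {
      r <- base
      if (!is.null(config$enrichment)) {
        e <- config$enrichment[config$enrichment$treatment == t, , drop = FALSE]
        for (i in seq_len(nrow(e))) {
          gi <- resolve_gene(e$gene[i], gene_ids)
          r[gi] <- r[gi] * e$fold[i]
        }
      }
      r / sum(r)
    })
    names(rates) <- config$treatments
    Tn <- length(config$treatments)
    Mt <- config$m_per_treatment
    M <- Tn * Mt
    pop_ids <- sprintf("pop%03d", seq_len(M))
    treat_of <- rep(config$treatments, each = Mt)
    names(treat_of) <- pop_ids
    totals <- switch(config$total_law$law,
      fixed = rep(as.integer(config$total_law$value), M),
      poisson = stats::rpois(M, config$total_law$mean))
    counts <- matrix(0L, nrow = G, ncol = M,
                     dimnames = list(gene_ids, pop_ids))
    for (j in seq_len(M)) {
      r <- rates[[treat_of[j]]]
      if (!is.null(config$covariance)) {
        for (cv in config$covariance) {
          gi <- resolve_gene(cv$genes, gene_ids)
          r[gi] <- r[gi] * exp(cv$sigma * stats::rnorm(1))
        }
        r <- r / sum(r)
      }
      if (totals[j] > 0) {
        counts[, j] <- stats::rmultinom(1, totals[j], r)
      }
    }
    L <- stats::rlnorm(G, config$length_meanlog, config$length_sdlog)
    annotation <- gene_annotation(gene_ids, L)
    truth <- list(base_rates = base, treatment_rates = rates,
                  enriched_genes = if (is.null(config$enrichment)) character(0)
                                   else gene_ids[resolve_gene(config$enrichment$gene, gene_ids)],
                  covarying_genes = if (is.null(config$covariance)) list()
                                    else lapply(config$covariance, function(cv)
                                      gene_ids[resolve_gene(cv$genes, gene_ids)]),
                  totals = stats::setNames(totals, pop_ids))
    list(matrix = mutation_count_matrix(counts, treatments = treat_of),
         annotation = annotation, truth = truth)
  })
}

resolve_gene <- function(g, gene_ids) {
  if (is.numeric(g)) {
    gi <- as.integer(g)
    if (any(gi < 1 | gi > length(gene_ids))) {
      stop_pardiv("gene index out of range", class = "pardiv_validation")
    }
    gi
  } else {
    gi <- match(as.character(g), gene_ids)
    if (anyNA(gi)) {
      stop_pardiv("unknown gene id '%s' in spec", g[which(is.na(gi))[1]],
                  class = "pardiv_validation")
    }
    gi
  }
}

#' Simulate a null treatment pair (no divergence)
#'
#' Both treatments draw from the identical rate vector; useful for false
#' discovery calibration of the divergence test.
#'
#' @param config a two-treatment [sim_config()] without enrichment
#' @return a single [treatment_pair()]
#' @export
simulate_null_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$treatments) != 2) {
    stop_pardiv("null pair needs exactly two treatments", class = "pardiv_validation")
  }
  if (!is.null(config$enrichment) && nrow(config$enrichment) > 0) {
    stop_pardiv("null pair must have no enrichment", class = "pardiv_validation")
  }
  sim <- simulate_counts(config)
  collapse_by_treatment(sim$matrix)[[1]]
}
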