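#' Pooled per-gene mutation probabilities
#'
#' Each population is modelled as allocating its total mutation count over
#' genes i.i.d. with per-gene probability p_i; the zero-free-parameter
#' estimate pools counts over all M replicate populations:
#' p_i = (sum_j n_ij) / (sum_j n_tot_j). The vector sums to one.
#'
#' @param x a `count_matrix`
#' @return named numeric vector of per-gene probabilities summing to 1
#' @export
pooled_gene_probabilities <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  tot <- sum(x$counts)
  if (tot == 0) {
    stop_pardiv("no mutations to estimate rates (all counts zero)",
                class = "pardiv_validation")
  }
  rowSums(x$counts) / tot
}

#' Observed per-gene occupancy
#'
#' Occupancy is the fraction of replicate populations carrying at least one
#' mutation in the gene.
#'
#' @param x a `count_matrix`
#' @return named numeric vector in \[0, 1\]
#' @export
observed_occupancy <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  rowMeans(x$counts >= 1L)
}

#' Predicted occupancy under the Poisson/binomial sampling model
#'
#' With pooled probabilities p_i, a population with total n_tot_j leaves gene i
#' untouched with probability (1 - p_i)^(n_tot_j); predicted occupancy averages
#' the hit probability over the M populations:
#' o_i = 1 - (1/M) * sum_j (1 - p_i)^(n_tot_j).
#' A population with n_tot_j = 0 contributes absence deterministically
#' (empty product).
#'
#' @param x a `count_matrix`
#' @param p optional probability vector (defaults to
#'   [pooled_gene_probabilities()])
#' @return named numeric vector in \[0, 1\]
#' @export
predicted_occupancy_poisson <- function(x, p = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  p <- p %||% pooled_gene_probabilities(x)
  ntot <- population_totals(x)
  # genes x populations matrix of absence probabilities
  absent <- outer(1 - p, ntot, `^`)
  stats::setNames(1 - rowMeans(absent), rownames(x$counts))
}

#' Predicted occupancy under a mean-matched geometric alternative
#'
#' The alternative model lets each population's count in a gene follow a
#' geometric distribution on \{0, 1, 2, ...\} matched to the Poisson model's
#' per-population mean mu_ij = p_i * n_tot_j, giving absence probability
#' 1 / (1 + mu_ij). Predicted occupancy again averages over populations.
#'
#' @inheritParams predicted_occupancy_poisson
#' @return named numeric vector in \[0, 1\]
#' @export
predicted_occupancy_geometric <- function(x, p = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  p <- p %||% pooled_gene_probabilities(x)
  ntot <- population_totals(x)
  absent <- 1 / (1 + outer(p, ntot))
  stats::setNames(1 - rowMeans(absent), rownames(x$counts))
}

#' Occupancy prediction errors and model comparison
#'
#' @param observed,poisson,geometric same-length named occupancy vectors over
#'   an identical gene set
#' @return list with `mae_poisson`, `mae_geometric`,
#'   `fraction_poisson_better` (ties in absolute error excluded from numerator
#'   and denominator), and `n_ties`
#' @export
occupancy_error <- function(observed, poisson, geometric) {
  if (!identical(names(observed), names(poisson)) ||
      !identical(names(observed), names(geometric))) {
    stop_pardiv("occupancy vectors cover different gene sets",
                class = "pardiv_validation")
  }
  ep <- abs(poisson - observed)
  eg <- abs(geometric - observed)
  tie <- ep == eg
  list(mae_poisson = mean(ep),
       mae_geometric = mean(eg),
       fraction_poisson_better = if (all(tie)) NA_real_ else mean(ep[!tie] < eg[!tie]),
       n_ties = sum(tie))
}

#' Fit the occupancy prediction model to a count matrix
#'
#' Computes observed occupancy, the Poisson and geometric predictions, per-gene
#' absolute errors and summary error statistics. By default only genes with at
#' least one pooled mutation enter the error summaries (zero-count genes are
#' predicted and observed at exactly 0 by construction); set
#' `include_zero_genes = TRUE` to keep them.
#'
#' @param x a `count_matrix`
#' @param include_zero_genes include genes with zero pooled mutations in the
#'   error summaries (default FALSE)
#' @return an object of class `occupancy_fit` with a per-gene data.frame
#'   (`$genes`) and summary statistics
#' @export
occupancy_fit <- function(x, include_zero_genes = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  p <- pooled_gene_probabilities(x)
  obs <- observed_occupancy(x)
  op <- predicted_occupancy_poisson(x, p)
  og <- predicted_occupancy_geometric(x, p)
  genes <- data.frame(gene_id = rownames(x$counts),
                      pooled_probability = p,
                      observed = obs,
                      predicted_poisson = op,
                      predicted_geometric = og,
                      abs_err_poisson = abs(op - obs),
                      abs_err_geometric = abs(og - obs),
                      stringsAsFactors = FALSE, row.names = NULL)
  keep <- if (include_zero_genes) rep(TRUE, nrow(genes)) else p > 0
  err <- occupancy_error(obs[keep], op[keep], og[keep])
  structure(c(list(genes = genes, M = ncol(x$counts),
                   n_genes = nrow(genes), n_genes_summarized = sum(keep),
                   include_zero_genes = include_zero_genes), err),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Occupancy prediction over M = %d populations, %d genes (%d summarized)\n",
              x$M, x$n_genes, x$n_genes_summarized))
  cat(sprintf("  MAE (Poisson):   %.5f\n", x$mae_poisson))
  cat(sprintf("  MAE (geometric): %.5f\n", x$mae_geometric))
  if (is.na(x$fraction_poisson_better)) {
    cat("  Poisson vs geometric: all genes tied\n")
  } else {
    cat(sprintf("  Poisson better on %.1f%% of genes (%d ties excluded)\n",
                100 * x$fraction_poisson_better, x$n_ties))
  }
  invisible(x)
}

#' @export
summary.occupancy_fit <- function(object, ...) {
  print(object)
  invisible(object[c("mae_poisson", "mae_geometric",
                     "fraction_poisson_better", "n_ties")])
}

#' @export
plot.occupancy_fit <- function(x, ...) {
  g <- x$genes
  graphics::plot(g$observed, g$predicted_poisson,
                 xlab = "Observed occupancy", ylab = "Predicted occupancy",
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::points(g$observed, g$predicted_geometric, pch = 1, col = "tomato")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("Poisson", "geometric"),
                   pch = c(16, 1), col = c("steelblue", "tomato"), bty = "n")
  invisible(x)
}

#' Prediction error as a function of the number of replicate populations
#'
#' Subsamples populations without replacement and recomputes the whole fit
#' (pooled probabilities, predictions, observed occupancy, MAE) within each
#' subset, tracing how error shrinks as replication grows.
#'
#' @param x a `count_matrix`
#' @param sizes integer vector of subsample sizes, each in \[2, M\]
#' @param reps subsamples per size
#' @param seed integer seed; identical seeds give identical tables
#' @param include_zero_genes passed to [occupancy_fit()]
#' @return data.frame with columns `m`, `mean_mae`, `sd_mae` (Poisson MAE)
#' @export
subsample_error_curve <- function(x, sizes, reps, seed,
                                  include_zero_genes = FALSE) {
  stopifnot(inherits(x, "count_matrix"), reps >= 1)
  M <- ncol(x$counts)
  sizes <- as.integer(sizes)
  if (any(sizes < 2L) || any(sizes > M)) {
    stop_pardiv("subsample sizes must lie in [2, M = %d]", M,
                class = "pardiv_validation")
  }
  res <- with_seed(seed, {
    lapply(sizes, function(m) {
      maes <- vapply(seq_len(reps), function(r) {
        cols <- sample.int(M, m)
        sub <- mutation_count_matrix(x$counts[, cols, drop = FALSE],
                                     treatments = x$treatments[cols])
        occupancy_fit(sub, include_zero_genes = include_zero_genes)$mae_poisson
      }, numeric(1))
      c(mean_mae = mean(maes), sd_mae = stats::sd(maes))
    })
  })
  data.frame(m = sizes,
             mean_mae = vapply(res, `[[`, numeric(1), "mean_mae"),
             sd_mae = vapply(res, `[[`, numeric(1), "sd_mae"))
}
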