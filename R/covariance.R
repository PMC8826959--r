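#' Multiplicity matrix (gene-size-corrected mutation counts)
#'
#' Rescales each gene's counts by its nonsynonymous target size so genes are
#' comparable: m_ij = n_ij * Lbar / L_i, with Lbar the mean target size over
#' all genes in the annotation (the genome), not just mutated genes.
#'
#' @param x a `count_matrix`
#' @param annotation a `gene_annotation` covering every gene in `x`
#' @return numeric matrix with the same dimnames as `x$counts`
#' @export
multiplicity_matrix <- function(x, annotation) {
  stopifnot(inherits(x, "count_matrix"))
  L <- lookup_target_sizes(annotation, rownames(x$counts))
  Lbar <- mean_target_size(annotation)
  x$counts * (Lbar / L)
}

# Tracy-Widom centering and scaling for the normalized largest eigenvalue of
# an M-population, N-gene covariance spectrum (Johnstone-type constants on the
# e = M*E/sum(E) scale, i.e. divided by N)
tw_center <- function(M, N) (sqrt(N - 1) + sqrt(M))^2 / N
tw_scale  <- function(M, N) {
  ((sqrt(N - 1) + sqrt(M)) / N) * (1 / sqrt(N - 1) + 1 / sqrt(M))^(1 / 3)
}

#' Normalized largest eigenvalue of a multiplicity matrix
#'
#' Summarizes global gene-gene covariance by the largest eigenvalue of the
#' population-level Gram spectrum of the (by default gene-centered)
#' multiplicity matrix. Eigenvalues are normalized to sum to M
#' (e_m = M * E_m / sum(E)), and the largest is centered and scaled by the
#' Tracy-Widom constants mu(M, N) = (sqrt(N-1) + sqrt(M))^2 / N and
#' sigma(M, N) = ((sqrt(N-1) + sqrt(M)) / N) * (1/sqrt(N-1) + 1/sqrt(M))^(1/3),
#' under which the statistic for independent genes approaches the Tracy-Widom
#' law as M and N grow.
#'
#' @param mult numeric genes-x-populations matrix (e.g. from
#'   [multiplicity_matrix()]); rows that are identically zero are dropped
#' @param center subtract each gene's mean across populations first (default)
#' @return list with `stat` (the centered, scaled largest eigenvalue), `e`
#'   (normalized eigenvalues summing to M), `M`, `n_genes` (genes retained)
#' @export
normalized_largest_eigenvalue <- function(mult, center = TRUE) {
  mult <- as.matrix(mult)
  keep <- rowSums(mult != 0) > 0
  A <- mult[keep, , drop = FALSE]
  M <- ncol(A)
  N <- nrow(A)
  if (M < 2) stop_pardiv("need at least 2 populations", class = "pardiv_validation")
  if (N < 2) stop_pardiv("need at least 2 genes with mutations", class = "pardiv_validation")
  if (center) A <- A - rowMeans(A)
  E <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
  E <- pmax(E, 0)
  if (sum(E) <= 0) {
    stop_pardiv("multiplicity matrix has rank 0 after centering",
                class = "pardiv_validation")
  }
  e <- M * E / sum(E)
  list(stat = (e[1] - tw_center(M, N)) / tw_scale(M, N),
       e = e, M = M, n_genes = N)
}

#' Randomize a count matrix preserving all margins
#'
#' Draws a random integer table with exactly the input's row sums (per-gene
#' totals) and column sums (per-population totals), uniform over tables under
#' the conditional independence model, using Patefield's algorithm
#' ([stats::r2dtable]). The input is not modified.
#'
#' @param x a `count_matrix` or plain nonnegative integer matrix
#' @param seed optional integer seed (local to this call)
#' @return object of the same kind as the input with identical margins
#' @export
fixed_margin_randomize <- function(x, seed = NULL) {
  cm <- inherits(x, "count_matrix")
  counts <- if (cm) x$counts else as.matrix(x)
  if (sum(counts) == 0) {
    stop_pardiv("matrix has no mutations to shuffle", class = "pardiv_validation")
  }
  tab <- with_seed(seed, r2dtable_checked(counts))
  dimnames(tab) <- dimnames(counts)
  if (cm) mutation_count_matrix(tab, treatments = x$treatments) else tab
}

r2dtable_checked <- function(counts) {
  stats::r2dtable(1, rowSums(counts), colSums(counts))[[1]]
}

#' Randomization test for a global signal of gene-gene covariance
#'
#' The observed statistic is the normalized largest eigenvalue of the
#' multiplicity matrix. The null distribution is generated by repeatedly
#' randomizing the raw counts with fixed gene and population margins
#' (randomize first, then apply the multiplicity correction), and the one-sided
#' upper-tail P value uses the add-one permutation estimator
#' (1 + #\{null >= observed\}) / (1 + permutations), which is never zero.
#'
#' @param x a `count_matrix`
#' @param annotation a `gene_annotation` covering the matrix's genes
#' @param permutations number of fixed-margin null tables (>= 1)
#' @param seed integer seed; the whole test is reproducible given it
#' @param center passed to [normalized_largest_eigenvalue()]
#' @return object of class `covariance_test` with `observed_stat`,
#'   `null_stats`, `p_value`, `permutations`, `seed`, `M`, `n_genes`,
#'   `n_zero_genes`
#' @export
covariance_test <- function(x, annotation, permutations = 1000, seed = NULL,
                            center = TRUE) {
  stopifnot(inherits(x, "count_matrix"), permutations >= 1)
  mult <- multiplicity_matrix(x, annotation)
  nonzero <- rowSums(x$counts) > 0
  counts <- x$counts[nonzero, , drop = FALSE]
  Lfac <- (mean_target_size(annotation) /
             lookup_target_sizes(annotation, rownames(counts)))
  obs <- normalized_largest_eigenvalue(mult[nonzero, , drop = FALSE],
                                       center = center)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  null_stats <- with_seed(seed, {
    tabs <- stats::r2dtable(permutations, rs, cs)
    vapply(tabs, function(tab) {
      normalized_largest_eigenvalue(tab * Lfac, center = center)$stat
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= obs$stat)) / (1 + permutations)
  structure(list(observed_stat = obs$stat, null_stats = null_stats,
                 p_value = p, permutations = as.integer(permutations),
                 seed = seed, M = obs$M, n_genes = obs$n_genes,
                 n_zero_genes = sum(!nonzero), center = center),
            class = "covariance_test")
}

#' @export
print.covariance_test <- function(x, ...) {
  cat("Gene-gene covariance randomization test\n")
  cat(sprintf("  M = %d populations, %d mutated genes (%d zero-count genes dropped)\n",
              x$M, x$n_genes, x$n_zero_genes))
  cat(sprintf("  Observed normalized largest eigenvalue: %.4f\n", x$observed_stat))
  cat(sprintf("  P = %.4g (%d fixed-margin randomizations%s)\n",
              x$p_value, x$permutations,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' @export
plot.covariance_test <- function(x, ...) {
  graphics::hist(x$null_stats, breaks = 30, col = "grey85", border = "white",
                 main = "Fixed-margin null of the largest eigenvalue",
                 xlab = "normalized largest eigenvalue",
                 xlim = range(c(x$null_stats, x$observed_stat)), ...)
  graphics::abline(v = x$observed_stat, lwd = 2, lty = 2)
  invisible(x)
}

#' Covariance detectability as a function of replication
#'
#' For each subsample size, repeatedly subsamples populations, computes the
#' observed statistic and one fixed-margin null draw, and reports the fraction
#' of repetitions where the observed statistic exceeds its null. Near 0.5 for
#' independent genes; grows with replication when genes covary.
#'
#' @param x a `count_matrix`
#' @param annotation a `gene_annotation`
#' @param sizes subsample sizes, each in \[2, M\]
#' @param reps repetitions per size
#' @param seed integer seed
#' @param center passed to [normalized_largest_eigenvalue()]
#' @return data.frame with columns `m`, `fraction_observed_greater`
#' @export
detection_vs_replication <- function(x, annotation, sizes, reps, seed,
                                     center = TRUE) {
  stopifnot(inherits(x, "count_matrix"), reps >= 1)
  M <- ncol(x$counts)
  sizes <- as.integer(sizes)
  if (any(sizes < 2L) || any(sizes > M)) {
    stop_pardiv("sizes must lie in [2, M = %d]", M, class = "pardiv_validation")
  }
  Lbar <- mean_target_size(annotation)
  Lall <- lookup_target_sizes(annotation, rownames(x$counts))
  frac <- with_seed(seed, {
    vapply(sizes, function(m) {
      wins <- vapply(seq_len(reps), function(r) {
        cols <- sample.int(M, m)
        sub <- x$counts[, cols, drop = FALSE]
        keep <- rowSums(sub) > 0
        sub <- sub[keep, , drop = FALSE]
        if (nrow(sub) < 2 || sum(sub) == 0) return(NA)
        fac <- Lbar / Lall[keep]
        obs <- normalized_largest_eigenvalue(sub * fac, center = center)$stat
        tab <- r2dtable_checked(sub)
        nul <- normalized_largest_eigenvalue(tab * fac, center = center)$stat
        obs > nul
      }, logical(1))
      mean(wins, na.rm = TRUE)
    }, numeric(1))
  })
  data.frame(m = sizes, fraction_observed_greater = frac)
}
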