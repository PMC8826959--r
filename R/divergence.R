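#' Test a treatment pair for gene-level divergent evolution
#'
#' For every gene, the absolute difference in summed mutation counts between
#' the two environments is referred to a folded Skellam null whose rates are
#' the treatment totals spread uniformly over the gene universe. Genes with
#' |difference| >= n_min get a discrete upper-tail P value; the critical level
#' P* is chosen by the expected-discoveries FDR rule.
#'
#' @param pair a [treatment_pair()]
#' @param n_genes gene-universe size for the null rates; defaults to the
#'   number of genes in `annotation` if given, else the number of genes in the
#'   pair (typically the mutated-gene matrix rows)
#' @param alpha target false discovery rate in (0, 1)
#' @param n_min minimum |difference| at which a gene is tested (>= 1)
#' @param annotation optional `gene_annotation` defining the genome-wide gene
#'   universe
#' @return object of class `divergence_report`: per-gene data.frame (`$genes`)
#'   with counts, |difference|, direction, P value and significance flag, plus
#'   `p_star`, `k_star`, `null`, `alpha`, `n_min`, `n_tested`
#' @export
divergence_test <- function(pair, n_genes = NULL, alpha = 0.05, n_min = 1,
                            annotation = NULL) {
  stopifnot(inherits(pair, "treatment_pair"), alpha > 0, alpha < 1, n_min >= 1)
  if (pair$n_tot_1 == 0 && pair$n_tot_2 == 0) {
    stop_pardiv("no mutations in either treatment", class = "pardiv_validation")
  }
  if (is.null(n_genes)) {
    n_genes <- if (!is.null(annotation)) nrow(annotation) else length(pair$n_1)
  }
  null <- skellam_null(pair$n_tot_1, pair$n_tot_2, n_genes)
  k <- abs(pair$n_1 - pair$n_2)
  direction <- ifelse(pair$n_1 > pair$n_2, pair$label_1,
                      ifelse(pair$n_2 > pair$n_1, pair$label_2, "none"))
  tested <- k >= n_min
  p <- rep(NA_real_, length(k))
  if (any(tested)) {
    uk <- sort(unique(k[tested]))
    pu <- divergence_p_value(uk, null)
    p[tested] <- pu[match(k[tested], uk)]
  }
  crit <- critical_p_value(stats::setNames(k, names(pair$n_1)), null,
                           alpha = alpha, n_min = n_min)
  genes <- data.frame(gene_id = names(pair$n_1),
                      n_1 = as.integer(pair$n_1),
                      n_2 = as.integer(pair$n_2),
                      abs_delta_n = as.integer(k),
                      direction = direction,
                      p_value = p,
                      significant = names(pair$n_1) %in% crit$significant,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(genes = genes,
                 label_1 = pair$label_1, label_2 = pair$label_2,
                 null = null, alpha = alpha, n_min = n_min,
                 n_tested = sum(tested),
                 p_star = crit$p_star, k_star = crit$k_star),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("Divergence test: %s vs %s\n", x$label_1, x$label_2))
  cat(sprintf("  Null rates: lambda_1 = %.4g, lambda_2 = %.4g (N_genes = %d)\n",
              x$null$lambda_1, x$null$lambda_2, x$null$n_genes))
  cat(sprintf("  Tested %d genes with |delta n| >= %d at FDR alpha = %g\n",
              x$n_tested, x$n_min, x$alpha))
  if (is.na(x$p_star)) {
    cat("  No critical P value qualifies; no significant genes\n")
  } else {
    sig <- x$genes[x$genes$significant, , drop = FALSE]
    cat(sprintf("  P* = %.3g (|delta n| >= %d): %d significant gene(s)\n",
                x$p_star, x$k_star, nrow(sig)))
    if (nrow(sig) > 0 && nrow(sig) <= 20) {
      cat(paste0("    ", sig$gene_id, " (", sig$direction,
                 ", |delta n| = ", sig$abs_delta_n, ")", collapse = "\n"), "\n")
    }
  }
  invisible(x)
}

#' @export
summary.divergence_report <- function(object, ...) {
  print(object)
  invisible(object$genes[object$genes$significant, , drop = FALSE])
}

#' Run divergence tests over every pair of treatments
#'
#' @param x a `count_matrix` with >= 2 treatments
#' @inheritParams divergence_test
#' @return named list of `divergence_report`s, one per unordered pair
#' @export
divergence_test_all_pairs <- function(x, n_genes = NULL, alpha = 0.05,
                                      n_min = 1, annotation = NULL) {
  pairs <- collapse_by_treatment(x)
  lapply(pairs, divergence_test, n_genes = n_genes, alpha = alpha,
         n_min = n_min, annotation = annotation)
}

#' Genes consistently enriched within one treatment across all comparisons
#'
#' A gene is a treatment-specific candidate of adaptation only if it is
#' significant, with the enrichment pointing at that treatment, in every
#' pairwise comparison involving the treatment. A gene can therefore be
#' assigned to at most one treatment.
#'
#' @param reports list of `divergence_report`s covering all unordered pairs of
#'   the treatment set
#' @return named list: for each treatment, the character vector of assigned
#'   genes
#' @export
consistent_enrichment <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "divergence_report")))
  labs <- sort(unique(unlist(lapply(reports, function(r) c(r$label_1, r$label_2)))))
  want <- utils::combn(labs, 2, simplify = FALSE)
  have <- lapply(reports, function(r) sort(c(r$label_1, r$label_2)))
  missing <- want[!vapply(want, function(p) {
    any(vapply(have, identical, logical(1), p))
  }, logical(1))]
  if (length(missing) > 0) {
    stop_pardiv("missing pairwise comparison(s): %s",
                paste(vapply(missing, paste, character(1), collapse = " vs "),
                      collapse = "; "),
                class = "pardiv_validation")
  }
  out <- lapply(labs, function(t) {
    rel <- Filter(function(r) t %in% c(r$label_1, r$label_2), reports)
    sets <- lapply(rel, function(r) {
      g <- r$genes
      g$gene_id[g$significant & g$direction == t]
    })
    Reduce(intersect, sets)
  })
  names(out) <- labs
  out
}

#' Write a divergence report to TSV
#' @param report a `divergence_report`
#' @param path output path
#' @param params extra metadata for the commented header
#' @return `path`, invisibly
#' @export
write_divergence_report <- function(report, path, params = list()) {
  stopifnot(inherits(report, "divergence_report"))
  meta <- list(comparison = paste(report$label_1, "vs", report$label_2),
               lambda_1 = report$null$lambda_1,
               lambda_2 = report$null$lambda_2,
               n_genes = report$null$n_genes,
               alpha = report$alpha, n_min = report$n_min,
               p_star = if (is.na(report$p_star)) "none" else report$p_star)
  write_tsv_with_header(report$genes, path, c(params, meta))
}
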