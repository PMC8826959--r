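#' Skellam null for between-treatment divergence
#'
#' Under the null, every gene acquires mutations at the same rate within a
#' treatment, so the per-gene rates are the treatment totals spread uniformly
#' over the gene universe: lambda_k = n_tot^(k) / N_genes. Gene target size is
#' deliberately not used here.
#'
#' @param n_tot_1,n_tot_2 treatment-wide mutation totals
#' @param n_genes size of the gene universe the totals are spread over
#' @return object of class `skellam_null` with fields `lambda_1`, `lambda_2`,
#'   `n_genes`
#' @export
skellam_null <- function(n_tot_1, n_tot_2, n_genes) {
  stopifnot(n_tot_1 >= 0, n_tot_2 >= 0, n_genes >= 1)
  structure(list(lambda_1 = n_tot_1 / n_genes,
                 lambda_2 = n_tot_2 / n_genes,
                 n_genes = as.integer(n_genes)),
            class = "skellam_null")
}

#' Folded Skellam probability mass function
#'
#' The difference of two independent Poisson counts n1 - n2 with rates
#' (lambda1, lambda2) is Skellam distributed; folding onto k = |n1 - n2| >= 0
#' gives, for k > 0,
#' Pr\[k\] = exp(-(l1+l2)) * I_k(2*sqrt(l1*l2)) * ((l1/l2)^(k/2) + (l2/l1)^(k/2))
#' (using I_k = I_-k for integer order) and for k = 0
#' Pr\[0\] = exp(-(l1+l2)) * I_0(2*sqrt(l1*l2)),
#' with I_k the modified Bessel function of the first kind. Evaluated in log
#' space with exponentially scaled Bessel values for stability. When one rate
#' is zero the fold degenerates to a pure Poisson law on k; when both are zero
#' it is a point mass at 0.
#'
#' @param k vector of nonnegative integers
#' @param null a [skellam_null()] (or pass `lambda_1`/`lambda_2` directly)
#' @param lambda_1,lambda_2 nonnegative rates, read from `null` when given
#' @return Pr\[|difference| = k\], same length as `k`
#' @export
skellam_abs_pmf <- function(k, null = NULL, lambda_1 = NULL, lambda_2 = NULL) {
  if (!is.null(null)) {
    stopifnot(inherits(null, "skellam_null"))
    lambda_1 <- null$lambda_1
    lambda_2 <- null$lambda_2
  }
  if (is.null(lambda_1) || is.null(lambda_2) || lambda_1 < 0 || lambda_2 < 0) {
    stop_pardiv("rates must be nonnegative", class = "pardiv_validation")
  }
  if (anyNA(k) || any(k < 0) || any(k != round(k))) {
    stop_pardiv("k must be nonnegative integers", class = "pardiv_validation")
  }
  k <- as.numeric(k)
  if (lambda_1 == 0 && lambda_2 == 0) return(as.numeric(k == 0))
  if (lambda_1 == 0 || lambda_2 == 0) {
    return(stats::dpois(k, lambda_1 + lambda_2))
  }
  x <- 2 * sqrt(lambda_1 * lambda_2)
  logI <- log_bessel_i(x, k)
  r <- 0.5 * k * (log(lambda_1) - log(lambda_2))
  # log((l1/l2)^(k/2) + (l2/l1)^(k/2)) = |r| + log1p(exp(-2|r|)); 0 at k = 0
  fold <- ifelse(k == 0, 0, abs(r) + log1p(exp(-2 * abs(r))))
  exp(-(lambda_1 + lambda_2) + logI + fold)
}

# log I_k(x) for integer k >= 0, x > 0, without underflow: the exponentially
# scaled Bessel is accurate while the order stays below the argument; beyond
# that (where besselI underflows) the ascending series
# I_k(x) = sum_m (x/2)^(2m+k) / (m! (m+k)!) is summed in log space.
log_bessel_i <- function(x, k) {
  k <- as.numeric(k)
  out <- numeric(length(k))
  direct <- k <= x
  if (any(direct)) {
    out[direct] <- log(besselI(x, k[direct], expon.scaled = TRUE)) + x
  }
  if (any(!direct)) {
    out[!direct] <- vapply(k[!direct], function(kk) {
      lx <- log(x / 2)
      m <- 0
      lt <- kk * lx - lgamma(kk + 1)
      lmax <- lt
      acc <- 0   # sum of exp(lt_m - lmax), rescaled as lmax moves
      repeat {
        acc <- acc + exp(lt - lmax)
        m <- m + 1
        lt_next <- (2 * m + kk) * lx - lgamma(m + 1) - lgamma(m + kk + 1)
        if (lt_next > lmax) {
          acc <- acc * exp(lmax - lt_next)
          lmax <- lt_next
        }
        if (lt_next < lmax - 40 && lt_next < lt) break
        lt <- lt_next
      }
      lmax + log(acc)
    }, numeric(1))
  }
  out
}

#' Upper-tail P value for an observed absolute count difference
#'
#' P(k_obs) = sum over k >= k_obs of the folded Skellam pmf, summed directly in
#' the tail until the remaining mass is provably below ~1e-15 (once the
#' term ratio drops under 1/2, a geometric majorant bounds the remainder by
#' twice the current term).
#'
#' @param k_obs vector of nonnegative integers
#' @param null a [skellam_null()]
#' @param lambda_1,lambda_2 alternative to `null`
#' @return P values in (0, 1\]; exactly 1 at k_obs = 0
#' @export
divergence_p_value <- function(k_obs, null = NULL,
                               lambda_1 = NULL, lambda_2 = NULL) {
  if (!is.null(null)) {
    stopifnot(inherits(null, "skellam_null"))
    lambda_1 <- null$lambda_1
    lambda_2 <- null$lambda_2
  }
  if (anyNA(k_obs) || any(k_obs < 0) || any(k_obs != round(k_obs))) {
    stop_pardiv("k_obs must be nonnegative integers", class = "pardiv_validation")
  }
  one <- function(k0) {
    if (k0 == 0) return(1)
    total <- 0
    k <- k0
    prev <- skellam_abs_pmf(k, lambda_1 = lambda_1, lambda_2 = lambda_2)
    repeat {
      total <- total + prev
      nxt <- skellam_abs_pmf(k + 1, lambda_1 = lambda_1, lambda_2 = lambda_2)
      if (prev == 0 ||
          (nxt < 0.5 * prev && nxt < 1e-15 * max(total, .Machine$double.xmin))) {
        # geometric majorant: remaining tail < nxt / (1 - 1/2) = 2 * nxt
        total <- total + 2 * nxt
        break
      }
      prev <- nxt
      k <- k + 1
    }
    min(total, 1)
  }
  vapply(as.numeric(k_obs), one, numeric(1))
}

#' Expected number of genes reaching a P-value level
#'
#' Expected count, under the null, of genes with |difference| >= n_min and
#' P value <= P. Because the P value depends on the gene only through its
#' |difference| k and is strictly decreasing in k, the Heaviside sum collapses
#' to a tail: N_bar(P) = N_genes * Pvalue(max(k*(P), n_min)) where k*(P) is
#' the smallest k whose P value is <= P.
#'
#' @param P level in (0, 1\]
#' @param null a [skellam_null()]
#' @param n_min smallest tested |difference|
#' @return expected count
#' @export
expected_significant <- function(P, null, n_min = 1) {
  stopifnot(inherits(null, "skellam_null"), P > 0, P <= 1, n_min >= 0)
  k_star <- smallest_k_at_level(P, null)
  if (is.na(k_star)) return(0)
  null$n_genes * divergence_p_value(max(k_star, n_min), null)
}

# smallest k with P(k) <= P; NA if no k within a generous search bound reaches P
smallest_k_at_level <- function(P, null) {
  if (P >= 1) return(0)
  mu <- null$lambda_1 + null$lambda_2
  kmax <- ceiling(mu + 20 * sqrt(mu + 1) + 200)
  k <- 1
  while (k <= kmax) {
    if (divergence_p_value(k, null) <= P) return(k)
    k <- k + 1
  }
  NA_integer_
}

#' Critical P value for a target false discovery rate
#'
#' Scans the achievable discrete P-value levels (one per observed |difference|
#' k >= n_min) and returns the largest level P* at which the ratio of the
#' expected to the observed number of qualifying genes is at most alpha.
#'
#' @param observed_k named vector of per-gene absolute count differences
#' @param null a [skellam_null()]
#' @param alpha target FDR in (0, 1)
#' @param n_min genes with |difference| below this are never tested
#' @return list with `p_star` (NA if no level qualifies), `k_star`, and
#'   `significant` (character vector of qualifying gene names)
#' @export
critical_p_value <- function(observed_k, null, alpha = 0.05, n_min = 1) {
  stopifnot(inherits(null, "skellam_null"), alpha > 0, alpha < 1, n_min >= 1)
  if (length(observed_k) == 0) {
    stop_pardiv("no observed counts supplied", class = "pardiv_validation")
  }
  tested <- observed_k[observed_k >= n_min]
  if (length(tested) == 0) {
    return(list(p_star = NA_real_, k_star = NA_integer_,
                significant = character(0)))
  }
  ks <- sort(unique(tested))          # candidate levels, P(k) decreasing in k
  best <- NA_integer_
  for (kc in ks) {                    # smallest qualifying k = largest P*
    p_c <- divergence_p_value(kc, null)
    n_bar <- null$n_genes * p_c       # kc >= n_min so the threshold is kc itself
    n_obs <- sum(tested >= kc)        # P_i <= P(kc) iff k_i >= kc
    if (n_bar / n_obs <= alpha) {
      best <- kc
      break
    }
  }
  if (is.na(best)) {
    return(list(p_star = NA_real_, k_star = NA_integer_,
                significant = character(0)))
  }
  list(p_star = divergence_p_value(best, null), k_star = best,
       significant = names(tested)[tested >= best])
}
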