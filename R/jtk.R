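#' Reference ordering of a cosine at a given period and lag
#'
#' Ranks of `cos(2*pi*(t - lag)/period)` on the sampling grid, with average
#' ranks for ties. Grid points one full period apart, and points symmetric
#' about the cosine peak, fall into tie groups; the tie structure is
#' recorded because the exact null distribution of the concordance statistic
#' depends on it.
#'
#' @param period Reference period in hours; must be a positive multiple of
#'   the sampling interval and lie in `[20, 28]`.
#' @param lag Reference lag (peak time) in hours.
#' @param timepoints Sampling grid in ZT hours (evenly spaced).
#' @return A `reference_ordering`: list with `period`, `lag`, `ranks`
#'   (average ranks), `values` (the reference cosine), and `tie_sizes`
#'   (sizes of the tie groups in reference order).
#' @export
reference_ordering <- function(period, lag, timepoints) {
  interval <- diff(timepoints)[1L]
  if (period < 20 || period > 28) stop("period must lie in [20, 28] hours")
  if (abs(period / interval - round(period / interval)) > 1e-9) {
    stop("period ", period, " is not a multiple of the ", interval,
         " h sampling interval")
  }
  ref <- cos(2 * pi * (timepoints - lag) / period)
  ref <- round(ref, 9)  # collapse numerically-equal symmetric values into ties
  r <- rank(ref, ties.method = "average")
  structure(list(period = period, lag = lag %% period, ranks = r,
                 values = ref,
                 tie_sizes = as.integer(table(ref))),
            class = "reference_ordering")
}

#' Kendall S concordance of a series with a reference ordering
#'
#' `S = sum over pairs i<j of sign(y_j - y_i) * sign(ref_j - ref_i)`; pairs
#' tied in either vector contribute 0. S is positive when y tends to rise
#' and fall with the reference, negative in antiphase.
#'
#' @param y Expression vector.
#' @param ref A [reference_ordering()] (or a numeric vector of reference
#'   values) of the same length.
#' @return Integer S.
#' @export
kendall_s <- function(y, ref) {
  rv <- if (inherits(ref, "reference_ordering")) ref$values else ref
  stopifnot(length(y) == length(rv))
  sy <- sign(outer(y, y, "-"))
  sr <- sign(outer(rv, rv, "-"))
  as.integer(sum((sy * sr)[upper.tri(sy)]))
}

#' Exact null distribution of Kendall S for a tied reference
#'
#' Under the null, the observed series is an exchangeable (tie-free) random
#' ordering; S then equals `M - 2k`, where M is the number of
#' reference-untied pairs and k the number of "inversions" of a random
#' multiset permutation with the reference's tie-group sizes. The inversion
#' distribution is computed exactly by Gaussian-binomial polynomial
#' convolution (the generating-function form of the Jonckheere-Terpstra /
#' Mann-Kendall null), so p-values are exact, not asymptotic.
#'
#' @param tie_sizes Integer sizes of the reference tie groups (sum = n).
#' @return List with `s` (support, from -M to M in steps of 2) and `p`
#'   (probabilities summing to 1). Guarded to n <= 60.
#' @export
exact_null <- function(tie_sizes) {
  tie_sizes <- as.integer(tie_sizes)
  n <- sum(tie_sizes)
  stopifnot(all(tie_sizes >= 1L), n >= 2L, n <= 60L)
  # polynomial in q for the number of inversions: product of Gaussian
  # binomials [N_i choose n_i]_q over successive groups
  poly <- 1
  cum <- 0L
  for (g in tie_sizes) {
    poly <- poly_mult(poly, gaussian_binomial(cum + g, g))
    cum <- cum + g
  }
  m_untied <- (n * (n - 1L)) %/% 2L - sum(tie_sizes * (tie_sizes - 1L)) %/% 2L
  stopifnot(length(poly) == m_untied + 1L)
  p <- poly / sum(poly)
  # inversions k -> S = M - 2k; reverse so support is increasing in S
  list(s = m_untied - 2 * (length(p) - 1L):0, p = rev(p))
}

# Coefficients of the Gaussian binomial [m choose k]_q via the Pascal
# recurrence [m k]_q = [m-1 k-1]_q + q^k [m-1 k]_q. Exact in doubles for the
# sizes used here (counts <= n! for n <= 60 groups of interest are not
# reached; coefficients stay below 2^53 for n <= 20, ample for a 12-point
# grid).
gaussian_binomial <- function(m, k) {
  if (k == 0L || k == m) return(1)
  # rows[[kk + 1]] holds the polynomial for [mm choose kk]_q as mm grows
  rows <- c(list(1), rep(list(numeric(0)), k))
  for (mm in 1:m) {
    for (kk in min(k, mm):1) {
      a <- rows[[kk]]                                  # [mm-1 choose kk-1]
      b <- rows[[kk + 1L]]                             # [mm-1 choose kk]
      bq <- if (length(b)) c(numeric(kk), b) else numeric(0)
      rows[[kk + 1L]] <- poly_add(a, bq)
    }
  }
  rows[[k + 1L]]
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric(0))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  a + b
}

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Two-sided exact p-value P(|S| >= |s_obs|) from an exact_null pmf.
exact_p_two_sided <- function(null, s_obs) {
  p <- sum(null$p[abs(null$s) >= abs(s_obs) - 1e-9])
  min(1, max(p, .Machine$double.xmin))
}

# All (period, lag) reference orderings for a grid: periods restricted to
# multiples of the interval within [period_min, period_max]; one lag per
# timepoint step within each period.
jtk_reference_set <- function(timepoints, period_min = 20, period_max = 28) {
  interval <- diff(timepoints)[1L]
  periods <- seq(ceiling(period_min / interval) * interval,
                 floor(period_max / interval) * interval, by = interval)
  refs <- list()
  for (per in periods) {
    for (lag in seq(0, per - interval, by = interval)) {
      refs[[length(refs) + 1L]] <- reference_ordering(per, lag, timepoints)
    }
  }
  refs
}

#' Call rhythmic genes with the nonparametric concordance test
#'
#' For every gene, Kendall's S is computed against cosine reference
#' orderings over all grid-representable periods in `[period_min,
#' period_max]` and all lags; the (period, lag) combination maximising |S|
#' wins (ties to the earlier combination in period-then-lag order). The
#' two-sided exact p-value of the best S is Bonferroni-adjusted by the
#' number of combinations tested, and genes with adjusted p below `alpha`
#' are called. The test is rank-based, so calls are invariant under
#' per-gene monotone increasing transforms.
#'
#' @param tc A [timecourse].
#' @param period_min,period_max Period search bounds in hours.
#' @param alpha Significance level on the adjusted p-value.
#' @return A `rhythm_calls` data frame (method `"jtk"`): `phase` = best lag
#'   mod 24, `period` = best period, `score` = best S, `p_value` = adjusted
#'   p. Attribute `results` carries the per-gene table for all genes.
#' @export
call_rhythmic_jtk <- function(tc, period_min = 20, period_max = 28,
                              alpha = 0.05) {
  stopifnot(inherits(tc, "timecourse"))
  refs <- jtk_reference_set(tc$timepoints, period_min, period_max)
  n_comb <- length(refs)
  if (n_comb == 0L) stop("no grid-representable period in the requested range")
  # cache exact nulls by tie structure
  nulls <- list()
  null_for <- function(tie_sizes) {
    key <- paste(sort(tie_sizes), collapse = ",")
    if (is.null(nulls[[key]])) nulls[[key]] <<- exact_null(tie_sizes)
    nulls[[key]]
  }
  ng <- nrow(tc$values)
  ntp <- ncol(tc$values)
  ut <- upper.tri(matrix(0, ntp, ntp))
  # S for all genes x references in one product of pairwise sign matrices
  sign_pairs <- function(v) sign(outer(v, v, "-"))[ut]
  sy <- t(apply(tc$values, 1L, sign_pairs))          # genes x pairs
  sr <- vapply(refs, function(rf) sign_pairs(rf$values),
               numeric(sum(ut)))                     # pairs x refs
  smat <- round(sy %*% sr)
  best_ref <- max.col(abs(smat), ties.method = "first")
  best_s <- smat[cbind(seq_len(ng), best_ref)]
  p_raw <- vapply(seq_len(ng), function(i) {
    exact_p_two_sided(null_for(refs[[best_ref[i]]]$tie_sizes), best_s[i])
  }, numeric(1))
  p_adj <- pmin(1, p_raw * n_comb)
  best_period <- vapply(refs, `[[`, numeric(1), "period")[best_ref]
  best_lag <- vapply(refs, `[[`, numeric(1), "lag")[best_ref]
  # a negative best S is a rhythm in antiphase to the reference: the peak
  # sits half a period away from the reference lag
  best_lag <- ifelse(best_s < 0, best_lag + best_period / 2, best_lag)
  res <- data.frame(
    id = tc$ids,
    period = best_period,
    phase = phase_mod24(best_lag),
    s = best_s, p = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
  called <- res$p_adj < alpha
  out <- rhythm_calls(id = res$id[called], method = "jtk",
                      phase = res$phase[called], period = res$period[called],
                      shape = NA_character_, score = res$s[called],
                      p_value = res$p_adj[called])
  structure(out, results = res, n_combinations = n_comb)
}
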