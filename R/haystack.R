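#' Build the model-pattern library for waveform matching
#'
#' One candidate pattern per (shape, integer phase 0-23) combination at a
#' fixed 24 h period, evaluated on the sampling grid via [make_waveform()].
#' Patterns that are constant on the grid (possible for a spike whose phase
#' falls between samples, though every integer phase snaps to the nearest
#' grid residue) are dropped with a warning, since a constant regressor has
#' no defined correlation.
#'
#' @param timepoints Sampling grid (ZT hours, >= 4 points).
#' @param shapes Waveform families to include.
#' @param period Model period in hours.
#' @return A `model_library`: list with `patterns` (data frame `shape`,
#'   `phase`) and `values` (matrix, one row per pattern).
#' @export
build_model_library <- function(timepoints,
                                shapes = waveform_shapes,
                                period = 24) {
  stopifnot(length(timepoints) >= 4L)
  stopifnot(all(shapes %in% waveform_shapes))
  grid <- expand.grid(phase = 0:23, shape = shapes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$shape, shapes), grid$phase), c("shape", "phase")]
  vals <- t(vapply(seq_len(nrow(grid)),
                   function(i) make_waveform(grid$shape[i], period,
                                             grid$phase[i], timepoints),
                   numeric(length(timepoints))))
  keep <- apply(vals, 1L, function(v) max(v) - min(v) > 1e-12)
  if (any(!keep)) {
    warning(sum(!keep), " constant pattern(s) dropped from model library")
  }
  structure(list(patterns = grid[keep, , drop = FALSE],
                 values = vals[keep, , drop = FALSE],
                 period = period, timepoints = timepoints),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat("<model_library> ", nrow(x$patterns), " patterns (",
      paste(unique(x$patterns$shape), collapse = ", "), ") x period ",
      x$period, " h\n", sep = "")
  invisible(x)
}

#' Score one gene against one model pattern
#'
#' Ordinary least-squares regression of the expression series on the pattern
#' values; the reported `r` is the signed Pearson correlation (so only
#' positively matching fits, `r > 0`, are eligible as rhythmic hits).
#' A constant expression series has no defined correlation; `r` is set to 0
#' and the fit flagged.
#'
#' @param y Expression vector.
#' @param pattern_values Model pattern on the same grid.
#' @return List with `r`, `slope`, `intercept`, `constant` (flag).
#' @export
score_gene <- function(y, pattern_values) {
  stopifnot(length(y) == length(pattern_values))
  if (stats::sd(y) == 0) {
    return(list(r = 0, slope = 0, intercept = mean(y), constant = TRUE))
  }
  sxx <- stats::var(pattern_values)
  sxy <- stats::cov(pattern_values, y)
  slope <- sxy / sxx
  list(r = stats::cor(y, pattern_values), slope = slope,
       intercept = mean(y) - slope * mean(pattern_values), constant = FALSE)
}

# Correlation of every row of `values` (genes x time) with every pattern:
# returns genes x patterns matrix. Rows with zero variance get correlation 0.
pattern_correlations <- function(values, library_values) {
  zs <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2))
    sweep(m - mu, 1L, pmax(s, .Machine$double.eps), "/") *
      (s > 1e-12)  # zero out constant rows
  }
  zs(values) %*% t(zs(library_values))
}

# Per-gene best pattern: index, r. Ties broken by library order (shape
# order, then lower phase).
best_pattern_fit <- function(values, lib) {
  r <- pattern_correlations(values, lib$values)
  idx <- max.col(r, ties.method = "first")
  list(index = idx, r = r[cbind(seq_len(nrow(r)), idx)])
}

#' Permutation-derived correlation threshold for pattern matching
#'
#' For each of `n_perm` permutations, the time labels of every row are
#' independently shuffled and the best-pattern correlation recomputed; the
#' threshold is the `100 - q` percentile of the pooled null best
#' correlations, so roughly the top `q`% of genes on comparable noise exceed
#' it. Seeded and reproducible; invariant to the row order of the input.
#'
#' @param tc A [timecourse].
#' @param lib A [build_model_library()] result on the same grid.
#' @param n_perm Number of permutation rounds (>= 100).
#' @param q Target top percentile (default 5).
#' @param seed Integer seed.
#' @return Correlation threshold (scalar).
#' @export
permutation_threshold <- function(tc, lib, n_perm = 200, q = 5, seed = 1L) {
  stopifnot(inherits(tc, "timecourse"), n_perm >= 100)
  ntp <- ncol(tc$values)
  n <- nrow(tc$values)
  set.seed(seed)
  null_best <- numeric(n_perm * n)
  for (p in seq_len(n_perm)) {
    perm <- t(vapply(seq_len(n),
                     function(i) tc$values[i, sample.int(ntp)],
                     numeric(ntp)))
    r <- pattern_correlations(perm, lib$values)
    null_best[((p - 1L) * n + 1L):(p * n)] <- apply(r, 1L, max)
  }
  unname(stats::quantile(null_best, probs = 1 - q / 100, type = 7))
}

#' Call rhythmic genes by model-pattern matching
#'
#' Each gene is fitted against the full model library; it is called rhythmic
#' when its best correlation passes the detection rule. The default rule
#' (`mode = "conjunction"`) requires the best r to clear both the fixed
#' correlation cutoff (0.81) and the permutation-calibrated top-`q`%
#' threshold — the stricter reading of combining a printed cutoff with a
#' permutation top-percentile rule. `mode = "cutoff"` uses the fixed cutoff
#' alone; `mode = "top_fraction"` instead keeps the top `q`% of genes ranked
#' by best correlation (still requiring r >= cutoff when combined via
#' conjunction is off).
#'
#' @param tc A [timecourse].
#' @param cutoff Correlation cutoff (default 0.81).
#' @param top_percent Top percentile for the permutation rule.
#' @param n_perm Permutation rounds.
#' @param seed Seed for the permutation null.
#' @param shapes Waveform families for the library.
#' @param mode `"conjunction"`, `"cutoff"`, `"permutation"`, or
#'   `"top_fraction"`.
#' @param min_fold Optional minimum (max - min) expression range per gene;
#'   `0` disables the filter (default).
#' @return A `rhythm_calls` data frame (method `"haystack"`) with one row
#'   per called gene: `phase` and `shape` of the best pattern, `period` of
#'   the library, `score` = best r. The threshold actually applied is
#'   attached as attribute `threshold`.
#' @export
call_rhythmic_haystack <- function(tc, cutoff = 0.81, top_percent = 5,
                                   n_perm = 200, seed = 1L,
                                   shapes = waveform_shapes,
                                   mode = c("conjunction", "cutoff",
                                            "permutation", "top_fraction"),
                                   min_fold = 0) {
  stopifnot(inherits(tc, "timecourse"))
  mode <- match.arg(mode)
  lib <- build_model_library(tc$timepoints, shapes = shapes)
  fit <- best_pattern_fit(tc$values, lib)
  thr <- switch(mode,
    cutoff = cutoff,
    permutation = permutation_threshold(tc, lib, n_perm, top_percent, seed),
    conjunction = max(cutoff,
                      permutation_threshold(tc, lib, n_perm, top_percent,
                                            seed)),
    top_fraction = {
      k <- max(1L, floor(nrow(tc$values) * top_percent / 100))
      max(cutoff, sort(fit$r, decreasing = TRUE)[k])
    })
  called <- fit$r >= thr & fit$r > 0
  if (min_fold > 0) {
    rng <- apply(tc$values, 1L, function(v) max(v) - min(v))
    called <- called & rng >= min_fold
  }
  out <- rhythm_calls(id = tc$ids[called],
                      method = "haystack",
                      phase = lib$patterns$phase[fit$index[called]],
                      period = lib$period,
                      shape = lib$patterns$shape[fit$index[called]],
                      score = fit$r[called],
                      p_value = NA_real_)
  structure(out, threshold = thr)
}
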