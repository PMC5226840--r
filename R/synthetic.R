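#' Evaluate a unit-amplitude model waveform on a sampling grid
#'
#' The five waveform families cover the shape vocabulary of diurnal
#' transcriptome profiles: a smooth cosine, a one-timepoint spike, a
#' half-period box, and rising/falling ramps.
#'
#' Conventions (all arithmetic mod `period` on the circular time axis):
#' \itemize{
#'   \item `cosine`: `cos(2*pi*(t - phase)/period)`; continuous maximum at
#'     `t == phase (mod period)`.
#'   \item `spike`: 1 at the single grid residue nearest `phase` in each
#'     cycle (ties toward the earlier residue), 0 elsewhere.
#'   \item `box`: 1 on the half-open half-period `[phase, phase + period/2)`,
#'     0 elsewhere.
#'   \item `ramp_up`: rises linearly 0 to 1 over one period, resetting at
#'     `phase`.
#'   \item `ramp_down`: falls linearly 1 to 0 over one period, resetting at
#'     `phase`.
#' }
#'
#' @param shape One of `"cosine"`, `"spike"`, `"box"`, `"ramp_up"`,
#'   `"ramp_down"`.
#' @param period Cycle length in hours (> 0).
#' @param phase Peak/anchor time in ZT hours, in `[0, 24)`.
#' @param timepoints Numeric vector of ZT hours.
#' @return Numeric vector of the waveform at `timepoints`.
#' @export
make_waveform <- function(shape, period, phase, timepoints) {
  stopifnot(period > 0, phase >= 0, phase < 24)
  t_rel <- (timepoints - phase) %% period
  switch(shape,
    cosine = cos(2 * pi * t_rel / period),
    spike = {
      res <- sort(unique(timepoints %% period))
      d <- pmin((res - phase) %% period, (phase - res) %% period)
      hit <- res[which.min(d)]  # which.min ties toward the earlier residue
      as.numeric(abs((timepoints %% period) - hit) < 1e-9)
    },
    box = as.numeric(t_rel < period / 2),
    ramp_up = t_rel / period,
    ramp_down = 1 - t_rel / period,
    stop("unknown waveform shape: ", shape)
  )
}

waveform_shapes <- c("cosine", "spike", "box", "ramp_up", "ramp_down")

#' Specify a synthetic diurnal expression dataset
#'
#' Defaults emulate a liver-style diurnal profiling experiment: a 48 h time
#' course sampled every 4 h (12 timepoints, ZT0-ZT44), roughly one gene in
#' ten rhythmic, 24 h periods dominating, phases spread over the whole day,
#' and i.i.d. Gaussian measurement noise at 20% of the oscillation amplitude.
#'
#' @param n_genes Number of features to simulate.
#' @param frac_rhythmic Fraction of genes that carry a rhythm, in `[0,1]`.
#' @param shapes Named numeric vector of waveform-family weights (normalised
#'   internally; names from [make_waveform()]'s shape vocabulary).
#' @param period_choices Periods (hours) sampled uniformly for rhythmic
#'   genes; must lie in `[20, 28]`.
#' @param phase_dist Either `"uniform"` (phases uniform on `[0,24)`) or a
#'   data frame with columns `mean`, `sd`, `weight` describing a mixture of
#'   wrapped-normal clusters (ZT hours).
#' @param amplitude Oscillation amplitude (expression units).
#' @param baseline Baseline expression level.
#' @param noise_sd SD of the additive Gaussian noise per cell.
#' @param timepoints Sampling grid in ZT hours.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 1000,
                           frac_rhythmic = 0.11,
                           shapes = c(cosine = 0.55, spike = 0.15, box = 0.15,
                                      ramp_up = 0.075, ramp_down = 0.075),
                           period_choices = c(20, 24, 28),
                           phase_dist = "uniform",
                           amplitude = 1,
                           baseline = 8,
                           noise_sd = 0.2,
                           timepoints = seq(0, 44, by = 4),
                           seed = 1L) {
  stopifnot(n_genes >= 1, frac_rhythmic >= 0, frac_rhythmic <= 1,
            all(period_choices >= 20), all(period_choices <= 28),
            amplitude > 0, noise_sd >= 0)
  if (is.null(names(shapes)) || !all(names(shapes) %in% waveform_shapes)) {
    stop("shape weights must be named with known waveform shapes")
  }
  if (any(shapes < 0) || sum(shapes) <= 0) stop("invalid shape weights")
  shapes <- shapes / sum(shapes)
  if (is.data.frame(phase_dist)) {
    stopifnot(all(c("mean", "sd", "weight") %in% names(phase_dist)))
  } else {
    stopifnot(identical(phase_dist, "uniform"))
  }
  structure(list(n_genes = as.integer(n_genes), frac_rhythmic = frac_rhythmic,
                 shapes = shapes, period_choices = period_choices,
                 phase_dist = phase_dist, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 timepoints = timepoints, seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_phases <- function(n, phase_dist) {
  if (identical(phase_dist, "uniform")) return(stats::runif(n, 0, 24))
  comp <- sample.int(nrow(phase_dist), n, replace = TRUE,
                     prob = phase_dist$weight)
  (stats::rnorm(n, phase_dist$mean[comp], phase_dist$sd[comp])) %% 24
}

# Draw per-gene truth (shape/period/phase) and build the noiseless signal
# matrix for `n` rhythmic genes. Returns list(truth, signal).
resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

draw_rhythmic <- function(n, spec, phases = NULL) {
  shp <- resample(names(spec$shapes), n, prob = spec$shapes)
  per <- resample(spec$period_choices, n)
  if (is.null(phases)) phases <- draw_phases(n, spec$phase_dist)
  sig <- matrix(0, n, length(spec$timepoints))
  for (i in seq_len(n)) {
    sig[i, ] <- make_waveform(shp[i], per[i], phases[i], spec$timepoints)
  }
  list(shape = shp, period = per, phase = phases, signal = sig)
}

#' Generate a synthetic time course with known ground truth
#'
#' Rhythmic genes are `baseline + amplitude * waveform + N(0, noise_sd)`;
#' arrhythmic genes are `baseline + N(0, noise_sd)`. The number of rhythmic
#' genes is `round(frac_rhythmic * n_genes)`. Identical seeds give
#' bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `tc` (a [timecourse]) and `truth` (data frame with
#'   columns `id`, `is_rhythmic`, `shape`, `period`, `phase`, `amplitude`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  n_rhy <- round(spec$frac_rhythmic * n)
  ids <- sprintf("gene%0*d", max(4L, nchar(n)), seq_len(n))
  ntp <- length(spec$timepoints)
  signal <- matrix(0, n, ntp)
  truth <- data.frame(id = ids, is_rhythmic = seq_len(n) <= n_rhy,
                      shape = NA_character_, period = NA_real_,
                      phase = NA_real_, amplitude = NA_real_,
                      stringsAsFactors = FALSE)
  if (n_rhy > 0) {
    rhy <- draw_rhythmic(n_rhy, spec)
    truth$shape[seq_len(n_rhy)] <- rhy$shape
    truth$period[seq_len(n_rhy)] <- rhy$period
    truth$phase[seq_len(n_rhy)] <- rhy$phase
    truth$amplitude[seq_len(n_rhy)] <- spec$amplitude
    signal[seq_len(n_rhy), ] <- spec$amplitude * rhy$signal
  }
  noise <- matrix(stats::rnorm(n * ntp, 0, spec$noise_sd), n, ntp)
  tc <- timecourse(ids, spec$timepoints, spec$baseline + signal + noise)
  list(tc = tc, truth = truth)
}

#' Generate a pair of datasets with controlled overlap and phase shift
#'
#' Builds two time courses sharing `n_shared` rhythmic genes whose dataset-B
#' phase equals the dataset-A phase plus `phase_shift` (mod 24); `n_only_a`
#' and `n_only_b` further genes are rhythmic in exactly one dataset and flat
#' (baseline + noise) in the other. Shared genes keep their shape and period
#' across datasets. Used to emulate cross-dataset comparisons with known
#' Venn partition and known per-gene phase relations.
#'
#' @param n_shared,n_only_a,n_only_b Non-negative gene counts of the Venn
#'   partition of the two rhythmic sets.
#' @param phase_shift Hours added to shared genes' phases in dataset B.
#' @param spec A [synthetic_spec()]; its `n_genes`/`frac_rhythmic` are
#'   ignored in favour of the explicit counts, plus `n_arrhythmic` flat genes
#'   present in both.
#' @param n_arrhythmic Genes rhythmic in neither dataset.
#' @return List with `tc_a`, `tc_b` ([timecourse]s over the same ids) and
#'   `truth` (data frame: `id`, `rhythmic_a`, `rhythmic_b`, `shape`,
#'   `period`, `phase_a`, `phase_b`).
#' @export
generate_comparative_scenario <- function(n_shared, n_only_a, n_only_b,
                                          phase_shift = 0,
                                          spec = synthetic_spec(),
                                          n_arrhythmic = 0) {
  stopifnot(n_shared >= 0, n_only_a >= 0, n_only_b >= 0, n_arrhythmic >= 0)
  set.seed(spec$seed)
  n <- n_shared + n_only_a + n_only_b + n_arrhythmic
  ids <- sprintf("gene%0*d", max(4L, nchar(n)), seq_len(n))
  grp <- rep(c("shared", "a_only", "b_only", "none"),
             c(n_shared, n_only_a, n_only_b, n_arrhythmic))
  ntp <- length(spec$timepoints)
  truth <- data.frame(id = ids, rhythmic_a = grp %in% c("shared", "a_only"),
                      rhythmic_b = grp %in% c("shared", "b_only"),
                      shape = NA_character_, period = NA_real_,
                      phase_a = NA_real_, phase_b = NA_real_,
                      stringsAsFactors = FALSE)
  sig_a <- matrix(0, n, ntp)
  sig_b <- matrix(0, n, ntp)
  n_rhy <- n_shared + n_only_a + n_only_b
  if (n_rhy > 0) {
    rhy <- draw_rhythmic(n_rhy, spec)
    idx <- seq_len(n_rhy)
    truth$shape[idx] <- rhy$shape
    truth$period[idx] <- rhy$period
    truth$phase_a[idx] <- ifelse(truth$rhythmic_a[idx], rhy$phase, NA)
    in_b <- truth$rhythmic_b[idx]
    phase_b <- ifelse(grp[idx] == "shared", (rhy$phase + phase_shift) %% 24,
                      rhy$phase)
    truth$phase_b[idx] <- ifelse(in_b, phase_b, NA)
    for (i in idx) {
      if (truth$rhythmic_a[i]) sig_a[i, ] <- spec$amplitude * rhy$signal[i, ]
      if (truth$rhythmic_b[i]) {
        sig_b[i, ] <- spec$amplitude *
          make_waveform(rhy$shape[i], rhy$period[i], phase_b[i],
                        spec$timepoints)
      }
    }
  }
  noise_a <- matrix(stats::rnorm(n * ntp, 0, spec$noise_sd), n, ntp)
  noise_b <- matrix(stats::rnorm(n * ntp, 0, spec$noise_sd), n, ntp)
  list(tc_a = timecourse(ids, spec$timepoints, spec$baseline + sig_a + noise_a),
       tc_b = timecourse(ids, spec$timepoints, spec$baseline + sig_b + noise_b),
       truth = truth)
}
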