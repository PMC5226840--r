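#' Normalize bead-plex transcript readings
#'
#' Processing follows the assay's stated order exactly: technical replicates
#' are averaged first, the background is subtracted from the technical mean,
#' and the result is divided by the same-sample (timepoint x biological
#' replicate) value of the reference gene. Negative post-subtraction values
#' are floored at 0 (count reported); a reference value that is not positive
#' after subtraction invalidates the whole sample and is an error. Because
#' every gene in a sample is divided by the same reference value, the result
#' is invariant to rescaling all raw intensities of that sample.
#'
#' @param readings Long-format data frame with columns `gene`, `zt`,
#'   `bio_rep`, `tech_rep`, `intensity` (>= 0).
#' @param reference_gene Gene id used as the normalizer; must be present at
#'   every (zt, bio_rep).
#' @param background Scalar background intensity, or a data frame
#'   `gene`, `background` for per-gene backgrounds.
#' @return List with `per_rep` (one [timecourse] per biological replicate),
#'   `mean` and `sd` ([timecourse]-shaped matrices across biological
#'   replicates, as data frames gene x ZT), and `n_floored`.
#' @export
normalize_plex <- function(readings, reference_gene, background = 0) {
  need <- c("gene", "zt", "bio_rep", "tech_rep", "intensity")
  stopifnot(all(need %in% names(readings)))
  if (!reference_gene %in% readings$gene) {
    stop("reference gene '", reference_gene, "' absent from readings")
  }
  if (any(readings$intensity < 0)) stop("raw intensities must be >= 0")
  # 1) average technical replicates
  tech_mean <- stats::aggregate(intensity ~ gene + zt + bio_rep,
                                data = readings, FUN = mean)
  # 2) subtract background
  if (is.data.frame(background)) {
    stopifnot(all(c("gene", "background") %in% names(background)))
    bg <- background$background[match(tech_mean$gene, background$gene)]
    if (anyNA(bg)) stop("missing background for some gene(s)")
  } else {
    bg <- background
  }
  tech_mean$net <- tech_mean$intensity - bg
  n_floored <- sum(tech_mean$net < 0)
  if (n_floored > 0) {
    message(n_floored, " negative background-subtracted value(s) floored at 0")
  }
  tech_mean$net <- pmax(tech_mean$net, 0)
  # 3) divide by the same-sample reference value
  is_ref <- tech_mean$gene == reference_gene
  refs <- tech_mean[is_ref, c("zt", "bio_rep", "net")]
  key <- function(df) paste(df$zt, df$bio_rep, sep = "/")
  ref_net <- refs$net[match(key(tech_mean), key(refs))]
  if (anyNA(ref_net)) {
    miss <- unique(key(tech_mean)[is.na(ref_net)])
    stop("reference gene missing for sample(s): ", paste(miss, collapse = ", "))
  }
  bad <- ref_net <= 0
  if (any(bad)) {
    stop("reference value <= 0 after background subtraction in sample(s): ",
         paste(unique(key(tech_mean)[bad]), collapse = ", "))
  }
  tech_mean$norm <- tech_mean$net / ref_net

  genes <- unique(readings$gene)
  zts <- sort(unique(tech_mean$zt))
  reps <- sort(unique(tech_mean$bio_rep))
  per_rep <- lapply(reps, function(b) {
    sub <- tech_mean[tech_mean$bio_rep == b, ]
    m <- matrix(NA_real_, length(genes), length(zts),
                dimnames = list(genes, NULL))
    m[cbind(match(sub$gene, genes), match(sub$zt, zts))] <- sub$norm
    if (anyNA(m)) stop("incomplete series for biological replicate ", b)
    timecourse(genes, zts, m)
  })
  names(per_rep) <- paste0("bio_rep_", reps)
  arr <- simplify2array(lapply(per_rep, function(tc) tc$values))
  mean_mat <- apply(arr, c(1, 2), mean)
  sd_mat <- apply(arr, c(1, 2), stats::sd)
  list(per_rep = per_rep,
       mean = timecourse(genes, zts, mean_mat),
       sd = as.data.frame(sd_mat),
       n_floored = n_floored)
}

#' Two-sample test between trough and acrophase measurements
#'
#' Welch's (unequal-variance) two-sided t-test between the replicate
#' measurements pooled over the trough timepoints and those pooled over the
#' acrophase timepoints. The caller supplies the two timepoint sets
#' explicitly. Degenerate inputs (zero variance in both groups) return p = 1
#' when the means are equal, p = 0 otherwise, by convention.
#'
#' @param values_a,values_b Numeric vectors of >= 2 measurements each.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
trough_acrophase_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    return(if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 1 else 0)
  }
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}
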