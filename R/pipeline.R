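#' Default analysis configuration
#'
#' Detection and comparison settings: pattern-matching correlation cutoff
#' 0.81 with the permutation top-5% rule, concordance-test periods 20-28 h
#' at alpha 0.05, a 4 h phase-agreement window, and presence threshold 4 for
#' the "common gene" class.
#'
#' @param ... Overrides for any default field.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(cutoff = 0.81, top_percent = 5, n_perm = 200,
              haystack_mode = "conjunction", period_min = 20,
              period_max = 28, alpha = 0.05, window = 4, contour_bin = 2,
              common_threshold = 4, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# Percent of total, half-up to 1 decimal.
percent_of <- function(count, total) round_half_up(100 * count / total, 1)

#' Run both rhythm detectors and merge their calls
#'
#' Runs pattern matching and the nonparametric concordance test on the same
#' time course, merges the two hit lists into their union (for genes called
#' by both, the merged record keeps the pattern-matching phase/shape and the
#' concordance-test p-value), and assembles a run report with per-detector
#' counts, fractions of the interrogated features, union/intersection
#' counts, and the phase histogram of the merged calls.
#'
#' @param tc A [timecourse].
#' @param config See [default_config()].
#' @return List with `calls` (merged `rhythm_calls`), `haystack`, `jtk`
#'   (per-detector calls), and `report`.
#' @export
run_detection <- function(tc, config = default_config()) {
  hay <- call_rhythmic_haystack(tc, cutoff = config$cutoff,
                                top_percent = config$top_percent,
                                n_perm = config$n_perm, seed = config$seed,
                                mode = config$haystack_mode)
  jtk <- call_rhythmic_jtk(tc, period_min = config$period_min,
                           period_max = config$period_max,
                           alpha = config$alpha)
  merged <- merge_detector_calls(hay, jtk)
  total <- length(tc$ids)
  both <- intersect(hay$id, jtk$id)
  report <- list(
    total_features = total,
    haystack = list(n = nrow(hay), percent = percent_of(nrow(hay), total)),
    jtk = list(n = nrow(jtk), percent = percent_of(nrow(jtk), total)),
    common = length(both),
    union = list(n = nrow(merged),
                 percent = percent_of(nrow(merged), total)),
    phase_histogram = as.list(phase_histogram(merged$phase,
                                              config$contour_bin)),
    config = config
  )
  stopifnot(report$union$n ==
              (nrow(hay) - length(both)) + length(both) +
              (nrow(jtk) - length(both)))
  list(calls = merged, haystack = hay, jtk = jtk, report = report)
}

# Union of two call tables keyed by id. For ids present in both, phase,
# shape, period and score come from the first (pattern-matching) table and
# the p-value from the second; method records the provenance.
merge_detector_calls <- function(a, b) {
  both <- intersect(a$id, b$id)
  a_df <- as.data.frame(a); b_df <- as.data.frame(b)
  rows <- rbind(
    a_df[!(a_df$id %in% both), , drop = FALSE],
    if (length(both)) {
      m <- a_df[a_df$id %in% both, , drop = FALSE]
      m$method <- paste(a_df$method[1], b_df$method[1], sep = "+")
      m$p_value <- b_df$p_value[match(m$id, b_df$id)]
      m
    },
    b_df[!(b_df$id %in% both), , drop = FALSE]
  )
  rows <- rows[order(rows$id), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("rhythm_calls", "data.frame")
  rows
}

#' Compare two rhythm-call tables
#'
#' Optionally maps the first table's ids through an ortholog table, then
#' computes the Venn partition and Tanimoto-Jaccard index of the two hit
#' sets and, on the intersection, the phase-agreement fraction at the
#' sampling window, the 2-D phase contour grid, and the dawn-adjusted R^2.
#'
#' @param calls_a,calls_b `rhythm_calls` tables (non-empty).
#' @param ortholog_mapping Optional [id_mapping()] applied to `calls_a` ids.
#' @param config See [default_config()].
#' @return Report list with `venn`, `jaccard100`, and (when the
#'   intersection is non-empty) `agreement_fraction`, `contour_grid`,
#'   `adjusted_r_squared`.
#' @export
run_comparison <- function(calls_a, calls_b, ortholog_mapping = NULL,
                           config = default_config()) {
  stopifnot(nrow(calls_a) > 0, nrow(calls_b) > 0)
  a_df <- as.data.frame(calls_a)
  if (!is.null(ortholog_mapping)) {
    mapped <- merge(a_df, as.data.frame(ortholog_mapping),
                    by.x = "id", by.y = "source")
    # a query gene with several orthologs contributes each target once;
    # targets hit via several query genes keep the circular-mean phase
    phases <- tapply(mapped$phase, mapped$target,
                     function(p) as.numeric(circular_mean(p)))
    a_df <- data.frame(id = names(phases), phase = as.numeric(phases),
                       stringsAsFactors = FALSE)
  }
  set_a <- gene_set("a", unique(a_df$id))
  set_b <- gene_set("b", unique(calls_b$id))
  venn <- venn_counts(set_a, set_b)
  report <- list(venn = as.list(venn),
                 jaccard100 = jaccard100(set_a, set_b))
  common <- intersect(set_a$members, set_b$members)
  if (length(common) == 0L) {
    report$agreement_fraction <- NA
    report$note <- "empty intersection: phase comparison undefined"
    return(report)
  }
  pairs <- phase_pairs(common,
                       a_df$phase[match(common, a_df$id)],
                       calls_b$phase[match(common, calls_b$id)])
  report$agreement_fraction <- agreement_fraction(pairs, config$window)
  report$contour_grid <- contour_grid(pairs, config$contour_bin)
  report$adjusted_r_squared <- if (length(common) >= 3L) {
    as.numeric(adjusted_r_squared(pairs))
  } else NA_real_
  report
}

#' Write a run report as JSON
#'
#' @param report A report list from [run_detection()] or [run_comparison()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
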