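#' Reduce hours onto the 24 h circle
#'
#' @param hours Numeric vector of hours.
#' @return `hours %% 24`, in `[0, 24)`.
#' @export
phase_mod24 <- function(hours) hours %% 24

#' Circular mean of phases on a 24 h clock
#'
#' Phases are mapped to unit vectors at angle `2*pi*h/24`, averaged, and the
#' mean direction mapped back to hours. This automates the dawn correction a
#' naive arithmetic mean gets wrong: the average of ZT2 and ZT22 is ZT0, not
#' ZT12. When the resultant vector has (numerically) zero length the mean
#' direction is undefined (a perfectly antipodal set); the smaller input
#' phase is returned with attribute `tie = TRUE`.
#'
#' @param phases Numeric vector of ZT hours (reduced mod 24).
#' @return Mean phase in `[0, 24)`; attribute `tie` flags the antipodal case.
#' @export
circular_mean <- function(phases) {
  if (length(phases) == 0L) stop("circular_mean of empty phase list")
  phases <- phase_mod24(phases)
  ang <- phases * pi / 12
  s <- mean(sin(ang)); c <- mean(cos(ang))
  if (sqrt(s^2 + c^2) < 1e-9) {
    return(structure(min(phases), tie = TRUE))
  }
  h <- phase_mod24(atan2(s, c) * 12 / pi)
  if (h > 24 - 1e-9) h <- 0  # guard against 24 - epsilon wrap
  structure(h, tie = FALSE)
}

#' Adjust a phase pair for linear correlation across the dawn boundary
#'
#' Pairs whose raw difference exceeds 12 h straddle the day boundary; 24 h is
#' added to the smaller member, extending the scale past 24 so that e.g.
#' (ZT23, ZT1) becomes (23, 25) and correlates as a 2 h difference rather
#' than a 22 h one. Pairs at most 12 h apart are returned unchanged.
#'
#' @param a,b Phases in ZT hours.
#' @return Numeric vector `c(a, b)` after adjustment (values may exceed 24).
#' @export
adjust_pair <- function(a, b) {
  if (abs(a - b) > 12) {
    if (a < b) a <- a + 24 else b <- b + 24
  }
  c(a, b)
}

#' Circular distance between two phases
#'
#' @param a,b Phases in ZT hours.
#' @return Shorter arc in hours, in `[0, 12]`; the complementary interval
#'   (`24 -` shorter arc) is attached as attribute `complement`.
#' @export
phase_distance <- function(a, b) {
  d <- abs(a - b) %% 24
  d <- min(d, 24 - d)
  structure(d, complement = 24 - d)
}

# Vectorised circular distance without the complement attribute.
phase_distance_vec <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

#' Assemble a table of matched phase pairs
#'
#' @param id Unique identifiers.
#' @param phase_a,phase_b Phases (ZT hours) of each id in two datasets;
#'   reduced mod 24.
#' @return A `phase_pairs` data frame.
#' @export
phase_pairs <- function(id, phase_a, phase_b) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate ids in phase pair table")
  df <- data.frame(id = id, phase_a = phase_mod24(as.numeric(phase_a)),
                   phase_b = phase_mod24(as.numeric(phase_b)),
                   stringsAsFactors = FALSE)
  class(df) <- c("phase_pairs", "data.frame")
  df
}

#' Fraction of pairs with similar phases
#'
#' The share of genes whose two phases lie within `window` hours of each
#' other on the circle — the cross-dataset agreement statistic, typically
#' evaluated at the sampling interval (4 h).
#'
#' @param pairs A [phase_pairs()] table.
#' @param window Agreement window in hours (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
agreement_fraction <- function(pairs, window = 4) {
  stopifnot(window > 0)
  if (nrow(pairs) == 0L) stop("empty phase pair table")
  mean(phase_distance_vec(pairs$phase_a, pairs$phase_b) <= window)
}

#' Two-dimensional phase histogram (contour grid)
#'
#' Counts pairs in `bin`-hour phase bins of dataset A against dataset B;
#' bins are half-open `[lo, lo + bin)` and labelled by their lower edge.
#' Marginal sums reproduce the one-dimensional phase histograms.
#'
#' @param pairs A [phase_pairs()] table.
#' @param bin Bin width in hours; must divide 24.
#' @return Integer matrix, rows = phase-A bins, columns = phase-B bins.
#' @export
contour_grid <- function(pairs, bin = 2) {
  stopifnot(bin > 0, abs(24 / bin - round(24 / bin)) < 1e-9)
  edges <- seq(0, 24 - bin, by = bin)
  ia <- findInterval(pairs$phase_a, edges)
  ib <- findInterval(pairs$phase_b, edges)
  g <- matrix(0L, length(edges), length(edges),
              dimnames = list(paste0("ZT", edges), paste0("ZT", edges)))
  for (k in seq_len(nrow(pairs))) g[ia[k], ib[k]] <- g[ia[k], ib[k]] + 1L
  g
}

#' One-dimensional phase histogram
#'
#' @param phases ZT hours (reduced mod 24).
#' @param bin Bin width in hours; must divide 24.
#' @return Named integer vector of counts, bins half-open, labelled by
#'   lower edge.
#' @export
phase_histogram <- function(phases, bin = 2) {
  stopifnot(bin > 0, abs(24 / bin - round(24 / bin)) < 1e-9)
  edges <- seq(0, 24 - bin, by = bin)
  idx <- findInterval(phase_mod24(phases), edges)
  counts <- tabulate(idx, nbins = length(edges))
  names(counts) <- paste0("ZT", edges)
  counts
}

#' Squared correlation of dawn-adjusted phase pairs
#'
#' Applies [adjust_pair()] to every row (so dawn-straddling pairs are
#' compared on an extended scale) and returns the squared Pearson
#' correlation of the adjusted phases — the R^2 reported for cross-method
#' and cross-dataset phase scatter plots.
#'
#' @param pairs A [phase_pairs()] table with at least 3 rows.
#' @return R^2 in `[0, 1]`, or `NA` with attribute `degenerate = TRUE` when
#'   either adjusted column has zero variance.
#' @export
adjusted_r_squared <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need >=3 phase pairs")
  adj <- t(mapply(adjust_pair, pairs$phase_a, pairs$phase_b))
  if (stats::sd(adj[, 1]) == 0 || stats::sd(adj[, 2]) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(adj[, 1], adj[, 2])^2
}
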