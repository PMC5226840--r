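#' Venn partition counts of two gene sets
#'
#' @param a,b [gene_set()] objects.
#' @return Named integer vector `a_only`, `common`, `b_only`; the three
#'   counts sum to the size of the union.
#' @export
venn_counts <- function(a, b) {
  common <- length(intersect(a$members, b$members))
  c(a_only = length(a$members) - common, common = common,
    b_only = length(b$members) - common)
}

#' Tanimoto-Jaccard set-similarity index, scaled to 100
#'
#' `100 * |A n B| / |A u B|`: 100 for identical sets, 0 for disjoint ones.
#' Accepts either two gene sets or the three printed sizes `(|A|, |B|,
#' |A n B|)`, so similarity can be computed from reported set sizes when
#' membership lists are unavailable. Reported half-up to 1 decimal.
#'
#' @param a A [gene_set()], or `|A|` when called with `sizes = TRUE` syntax
#'   (see `n_common`).
#' @param b A [gene_set()], or `|B|`.
#' @param n_common Intersection size; supplying it switches to the
#'   size-based form.
#' @return Index in `[0, 100]`, rounded half-up to 1 decimal.
#' @export
jaccard100 <- function(a, b, n_common = NULL) {
  if (is.null(n_common)) {
    stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
    n_common <- length(intersect(a$members, b$members))
    na <- length(a$members); nb <- length(b$members)
  } else {
    na <- a; nb <- b
    stopifnot(n_common <= min(na, nb))
  }
  union <- na + nb - n_common
  if (union <= 0) stop("empty union: Jaccard index undefined")
  round_half_up(100 * n_common / union, 1)
}

# round() uses banker's rounding; printed indexes use conventional half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Rank a panel of gene sets by similarity to a query set
#'
#' @param query A [gene_set()].
#' @param panel Named list of [gene_set()]s.
#' @return Data frame `name`, `jaccard100`, sorted descending by index with
#'   alphabetical tie-break.
#' @export
rank_similarity <- function(query, panel) {
  stopifnot(length(panel) > 0)
  nm <- names(panel)
  if (is.null(nm)) nm <- vapply(panel, `[[`, character(1), "name")
  idx <- vapply(panel, function(s) jaccard100(query, s), numeric(1))
  out <- data.frame(name = nm, jaccard100 = unname(idx),
                    stringsAsFactors = FALSE)
  out[order(-out$jaccard100, out$name), , drop = FALSE]
}

#' Bin genes by how many datasets they appear in
#'
#' Classifies every gene by its presence count (number of datasets
#' containing it) into classes 1, 2, 3, and "common" (`>= common_threshold`
#' datasets — with 12 tissue datasets and the default threshold, "present in
#' 4 to 12 tissues"), then tallies the classes within each dataset's member
#' genes.
#'
#' @param m A [presence_matrix()].
#' @param common_threshold Minimum presence count of the "common" class
#'   (>= 2).
#' @return List with `counts` (dataset x class integer matrix) and
#'   `proportions` (rows sum to 1).
#' @export
presence_bins <- function(m, common_threshold = 4) {
  stopifnot(inherits(m, "presence_matrix"), common_threshold >= 2)
  n_present <- rowSums(m)
  cls_levels <- c(as.character(seq_len(common_threshold - 1L)),
                  paste0(">=", common_threshold))
  cls <- ifelse(n_present >= common_threshold,
                paste0(">=", common_threshold), as.character(n_present))
  counts <- t(vapply(colnames(m), function(d) {
    tab <- table(factor(cls[m[, d]], levels = cls_levels))
    as.integer(tab)
  }, integer(length(cls_levels))))
  colnames(counts) <- cls_levels
  list(counts = counts, proportions = counts / rowSums(counts))
}

#' Genes specific to one dataset
#'
#' @param m A [presence_matrix()].
#' @param dataset Dataset (column) name.
#' @param k Maximum total presence count; `k = 1` gives strictly
#'   dataset-specific genes.
#' @return A [gene_set()] of genes present in `dataset` and in at most `k`
#'   datasets overall.
#' @export
specific_subset <- function(m, dataset, k = 1) {
  if (!dataset %in% colnames(m)) stop("unknown dataset: ", dataset)
  sel <- m[, dataset] & rowSums(m) <= k
  gene_set(paste0(dataset, "_k", k), rownames(m)[sel])
}
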