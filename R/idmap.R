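#' Collapse transcript-level rhythm calls to gene level
#'
#' Each transcript contributes to every gene it maps to (many-to-many
#' mappings fan out), and the transcripts of one gene merge into a single
#' record whose phase is the circular mean of the member phases — so a gene
#' with transcripts peaking at ZT2 and ZT22 gets phase ZT0, not ZT12.
#' Transcripts absent from the mapping are dropped and counted. When merged
#' transcripts disagree on period or shape the gene record takes the modal
#' value, with ties resolved toward a pattern-matching ("haystack") entry
#' and then the lower period.
#'
#' @param calls A `rhythm_calls` data frame keyed by transcript id.
#' @param mapping An [id_mapping()] with transcript sources and gene targets.
#' @return List with `calls` (gene-level `rhythm_calls`, method
#'   `"merged"`) and `report` (input/output/multi-mapped/unmapped counts).
#' @export
collapse_transcripts_to_genes <- function(calls, mapping) {
  stopifnot(all(c("id", "phase", "period") %in% names(calls)))
  hit <- calls$id %in% mapping$source
  if (!any(hit)) stop("mapping covers none of the calls")
  n_unmapped <- sum(!hit)
  mapped <- merge(as.data.frame(calls)[hit, , drop = FALSE],
                  as.data.frame(mapping),
                  by.x = "id", by.y = "source")
  n_multi <- sum(table(mapped$id) > 1L)
  genes <- sort(unique(mapped$target))
  rows <- lapply(genes, function(g) {
    sub <- mapped[mapped$target == g, , drop = FALSE]
    data.frame(id = g,
               method = paste(sort(unique(sub$method)), collapse = "+"),
               phase = as.numeric(circular_mean(sub$phase)),
               period = modal_value(sub$period, sub$method),
               shape = modal_value(sub$shape, sub$method),
               score = max(sub$score),
               p_value = suppressWarnings(min(sub$p_value, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value[!is.finite(out$p_value)] <- NA_real_
  class(out) <- c("rhythm_calls", "data.frame")
  list(calls = out,
       report = list(input = nrow(calls), output = nrow(out),
                     multi_mapped = n_multi, unmapped = n_unmapped))
}

# Modal value of x; ties broken toward entries whose method mentions
# "haystack", then toward the smaller value.
modal_value <- function(x, method) {
  x <- as.character(x)
  keep <- !is.na(x)
  if (!any(keep)) return(NA)
  x <- x[keep]; method <- method[keep]
  tab <- table(x)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1L) {
    hay <- unique(x[grepl("haystack", method)])
    pref <- intersect(cand, hay)
    cand <- if (length(pref)) pref else cand
    cand <- sort(cand)[1L]  # numeric strings sort lower-period first
  }
  num <- suppressWarnings(as.numeric(cand))
  if (!is.na(num)) num else cand
}

#' Map a gene set to its non-redundant ortholog targets
#'
#' The output is the deduplicated union of all targets of the mapped genes;
#' genes absent from the mapping are counted as unmapped.
#'
#' @param genes A [gene_set()].
#' @param orthologs An [id_mapping()] (source = query species gene, target =
#'   ortholog gene); many-to-many allowed.
#' @return List with `set` (non-redundant target [gene_set()]) and `report`.
#' @export
map_orthologs <- function(genes, orthologs) {
  stopifnot(inherits(genes, "gene_set"))
  hit <- genes$members %in% orthologs$source
  targets <- unique(orthologs$target[orthologs$source %in% genes$members])
  list(set = gene_set(paste0(genes$name, "_orthologs"), targets),
       report = list(input = length(genes$members),
                     output = length(targets),
                     multi_mapped = sum(table(
                       orthologs$source[orthologs$source %in% genes$members]
                     ) > 1L),
                     unmapped = sum(!hit)))
}
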