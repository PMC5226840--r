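#' Construct a validated expression time course
#'
#' A `timecourse` holds an expression matrix (one row per feature, one column
#' per sample time) together with its sampling grid in Zeitgeber Time (ZT)
#' hours. The grid must be strictly increasing and evenly spaced; both rhythm
#' detectors rely on a complete, regular grid.
#'
#' @param ids Character vector of unique, non-empty feature identifiers
#'   (probesets, transcripts, or genes).
#' @param timepoints Numeric vector of ZT hours, strictly increasing, evenly
#'   spaced.
#' @param values Numeric matrix, `length(ids)` rows by `length(timepoints)`
#'   columns. No missing values are permitted.
#' @param interval Sampling interval in hours; inferred from `timepoints`
#'   when `NULL`.
#' @return An object of class `timecourse` with fields `ids`, `timepoints`,
#'   `values`, `interval`.
#' @export
timecourse <- function(ids, timepoints, values, interval = NULL) {
  ids <- as.character(ids)
  timepoints <- as.numeric(timepoints)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(ids) == 0L) stop("timecourse needs at least one feature")
  if (anyNA(ids) || any(!nzchar(ids))) stop("ids must be non-empty strings")
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyNA(timepoints) || any(timepoints < 0)) {
    stop("timepoints must be non-negative ZT hours")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (length(timepoints) >= 2L) {
    steps <- diff(timepoints)
    if (max(steps) - min(steps) > 1e-8) {
      stop("timepoints must be evenly spaced; got intervals ",
           paste(signif(unique(steps), 6), collapse = ", "))
    }
    inferred <- steps[1L]
  } else {
    inferred <- NA_real_
  }
  if (is.null(interval)) interval <- inferred
  if (!is.na(inferred) && abs(interval - inferred) > 1e-8) {
    stop("declared interval ", interval, " does not match grid spacing ", inferred)
  }
  if (nrow(values) != length(ids)) stop("values must have one row per id")
  if (ncol(values) != length(timepoints)) {
    stop("values must have one column per timepoint")
  }
  if (anyNA(values)) stop("missing values are not permitted")
  dimnames(values) <- list(ids, paste0("ZT", timepoints))
  structure(
    list(ids = ids, timepoints = timepoints, values = values,
         interval = as.numeric(interval)),
    class = "timecourse"
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse> ", length(x$ids), " features x ", length(x$timepoints),
      " timepoints (ZT", x$timepoints[1], "-ZT",
      x$timepoints[length(x$timepoints)], ", every ", x$interval, " h)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.timecourse <- function(x) dim(x$values)

# Parse a vector of timepoint labels. Accepts "ZT<h>", bare numbers, and
# "LD<h>" labels. LD labels are hours since lights-on of the first recorded
# day of the experiment; they are converted to ZT by subtracting `ld_start`
# (the LD hour at which sampling began, e.g. LD24 -> ZT0 with ld_start = 24).
# When ld_start is NULL the smallest LD label is used, anchoring the series
# at ZT0.
parse_timepoint_labels <- function(labels, ld_start = NULL) {
  labels <- trimws(labels)
  is_ld <- grepl("^LD", labels, ignore.case = TRUE)
  num <- sub("^(ZT|LD)", "", labels, ignore.case = TRUE)
  hours <- suppressWarnings(as.numeric(num))
  if (anyNA(hours)) {
    stop("cannot parse timepoint label(s): ",
         paste(labels[is.na(hours)], collapse = ", "))
  }
  if (any(is_ld)) {
    if (any(!is_ld)) stop("cannot mix LD labels with ZT/numeric labels")
    if (is.null(ld_start)) ld_start <- min(hours)
    hours <- hours - ld_start
  }
  hours
}

#' Read an expression time course from delimited text
#'
#' Expects a tab-separated table whose header row is `id` followed by
#' timepoint labels (`ZT0`, `4`, or the lights-on dialect `LD24`; see
#' Details), and whose body rows are a feature id followed by numeric
#' intensities. Row order is preserved.
#'
#' @details `LD<h>` labels count hours since lights-on at the start of the
#' experiment and are converted to ZT by subtracting `ld_start` (so `LD24`
#' becomes `ZT0` when `ld_start = 24`). If `ld_start` is `NULL` the smallest
#' LD label anchors the series at ZT0.
#'
#' @param path Path to a TSV file, or a character vector of lines.
#' @param interval_hint Expected sampling interval in hours (optional; a
#'   mismatch is an error).
#' @param ld_start Offset for LD-style labels; see Details.
#' @return A [timecourse].
#' @export
read_timecourse <- function(path, interval_hint = NULL, ld_start = NULL) {
  lines <- read_text_lines(path)
  if (length(lines) < 2L) stop("time course needs a header and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ntp <- length(header) - 1L
  if (ntp < 1L) stop("header must list at least one timepoint")
  tp <- parse_timepoint_labels(header[-1L], ld_start = ld_start)
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != ntp + 1L)) {
    bad <- which(widths != ntp + 1L)[1L]
    stop("ragged row ", bad + 1L, ": expected ", ntp + 1L, " fields, got ",
         widths[bad])
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(ntp))
  )
  if (anyNA(vals)) {
    bad <- which(apply(is.na(rbind(vals)), 2L, any))[1L]
    stop("non-numeric expression value in row ", bad + 1L, " (id ", ids[bad], ")")
  }
  vals <- matrix(t(rbind(vals)), nrow = length(ids), ncol = ntp)
  timecourse(ids, tp, vals, interval = interval_hint)
}

#' Write a time course as TSV
#'
#' Inverse of [read_timecourse()]; `read_timecourse(write_timecourse(tc, f))`
#' reproduces `tc` up to printed precision of the values.
#'
#' @param tc A [timecourse].
#' @param path Destination file path.
#' @param digits Significant digits for the values.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, digits = 10) {
  stopifnot(inherits(tc, "timecourse"))
  header <- paste(c("id", paste0("ZT", tc$timepoints)), collapse = "\t")
  rows <- vapply(seq_along(tc$ids), function(i) {
    paste(c(tc$ids[i], formatC(tc$values[i, ], digits = digits, format = "g")),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a gene set from a one-id-per-line text file
#'
#' Blank lines and duplicates are dropped; the number of duplicates dropped
#' is reported via a message and stored in the `n_duplicates` attribute.
#'
#' @param path Path to a text file, or a character vector of lines.
#' @param name Label for the set (defaults to the file name).
#' @return A `gene_set`: list with `name` and unique, non-empty `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- trimws(read_text_lines(path))
  if (is.null(name)) {
    name <- if (length(path) == 1L && file.exists(path)) basename(path) else "gene_set"
  }
  lines <- lines[nzchar(lines)]
  ndup <- sum(duplicated(lines))
  if (ndup > 0) message(ndup, " duplicate id(s) dropped from gene set '", name, "'")
  gene_set(name, unique(lines), n_duplicates = ndup)
}

#' Construct a gene set
#'
#' @param name Label.
#' @param members Character vector of identifiers; duplicates and empty
#'   strings are rejected.
#' @param n_duplicates Optional count of duplicates dropped upstream.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members, n_duplicates = 0L) {
  members <- as.character(members)
  if (any(!nzchar(members)) || anyNA(members)) stop("empty member id")
  if (anyDuplicated(members)) stop("duplicate member id")
  structure(list(name = name, members = members),
            n_duplicates = n_duplicates, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> '", x$name, "': ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Read a transcript-to-gene or gene-to-ortholog mapping table
#'
#' Two-column TSV (source id, target id); a header row is detected by
#' non-identifier-looking first line only when `header = NA`. Many-to-many
#' mappings are allowed; exact duplicate pairs are an error.
#'
#' @param path Path to a TSV file, or a character vector of lines.
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect a `source<TAB>target`
#'   header.
#' @return An `id_mapping`: data frame with columns `source`, `target`.
#' @export
read_id_mapping <- function(path, header = NA) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mapping table")
  if (is.na(header)) {
    header <- grepl("^(source|from|transcript|gene)\\b", lines[1L],
                    ignore.case = TRUE)
  }
  if (header) lines <- lines[-1L]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 2L)) {
    bad <- which(lengths(cells) != 2L)[1L]
    stop("mapping row ", bad, " does not have exactly 2 fields")
  }
  id_mapping(vapply(cells, `[[`, character(1), 1L),
             vapply(cells, `[[`, character(1), 2L))
}

#' Construct an identifier mapping
#'
#' @param source,target Character vectors of equal length; pairs must be
#'   unique and both sides non-empty. Many-to-many relations are permitted.
#' @return An `id_mapping` data frame.
#' @export
id_mapping <- function(source, target) {
  source <- as.character(source); target <- as.character(target)
  stopifnot(length(source) == length(target))
  if (any(!nzchar(source)) || any(!nzchar(target))) {
    stop("mapping ids must be non-empty")
  }
  if (anyDuplicated(paste0(source, "\r", target))) stop("duplicated mapping pair")
  structure(data.frame(source = source, target = target,
                       stringsAsFactors = FALSE),
            class = c("id_mapping", "data.frame"))
}

rhythm_call_columns <- c("id", "method", "phase", "period", "shape",
                         "score", "p_value")

#' Assemble a rhythm-call table
#'
#' One row per (feature, method) detection record: `phase` is the peak time in
#' ZT hours, `period` the cycle length in hours, `shape` the best-matching
#' waveform family (pattern matching only), `score` the method's statistic
#' (correlation r, or Kendall S), and `p_value` the adjusted p where the
#' method produces one.
#'
#' @param id,method Character vectors.
#' @param phase,period,score,p_value Numeric vectors.
#' @param shape Character vector (`NA` allowed).
#' @return A `rhythm_calls` data frame.
#' @export
rhythm_calls <- function(id, method, phase, period, shape = NA_character_,
                         score = NA_real_, p_value = NA_real_) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   method = rep_len(as.character(method), n),
                   phase = rep_len(as.numeric(phase), n),
                   period = rep_len(as.numeric(period), n),
                   shape = rep_len(as.character(shape), n),
                   score = rep_len(as.numeric(score), n),
                   p_value = rep_len(as.numeric(p_value), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("rhythm_calls", "data.frame")
  df
}

empty_rhythm_calls <- function() {
  rhythm_calls(character(0), character(0), numeric(0), numeric(0),
               character(0), numeric(0), numeric(0))
}

#' Write rhythm calls as TSV
#'
#' Columns `id, method, phase, period, shape, score, p_value`, ordered by id
#' then method so output is stable across runs.
#'
#' @param calls A `rhythm_calls` data frame (see [rhythm_calls()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_rhythm_calls <- function(calls, path) {
  stopifnot(all(rhythm_call_columns %in% names(calls)))
  calls <- calls[order(calls$id, calls$method), rhythm_call_columns]
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read rhythm calls written by [write_rhythm_calls()]
#'
#' @param path TSV path.
#' @return A `rhythm_calls` data frame.
#' @export
read_rhythm_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(id = "character", method = "character",
                                         shape = "character"))
  stopifnot(identical(names(df), rhythm_call_columns))
  class(df) <- c("rhythm_calls", "data.frame")
  df
}

#' Read a gene-by-dataset binary presence matrix
#'
#' TSV with header `id<TAB><dataset names...>` and 0/1 entries; used for
#' tissue-specificity binning.
#'
#' @param path TSV path or character vector of lines.
#' @return A `presence_matrix`: logical matrix, genes in rows, datasets in
#'   columns.
#' @export
read_presence_matrix <- function(path) {
  lines <- read_text_lines(path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]][-1L]
  body <- cells[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- vapply(body, function(r) as.numeric(r[-1L]), numeric(length(header)))
  presence_matrix(matrix(t(rbind(vals)) > 0, nrow = length(ids),
                         dimnames = list(ids, header)))
}

#' Construct/validate a presence matrix
#'
#' @param m Logical (or 0/1) matrix with gene row names and dataset column
#'   names; every gene must be present in at least one dataset.
#' @return A `presence_matrix` object.
#' @export
presence_matrix <- function(m) {
  m <- as.matrix(m) > 0
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("presence matrix needs gene row names and dataset column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in presence matrix")
  if (any(rowSums(m) == 0)) stop("every gene must be present in >=1 dataset")
  structure(m, class = c("presence_matrix", class(m)))
}

# Accept either a file path or a character vector of already-split lines.
read_text_lines <- function(path) {
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, encoding = "UTF-8")
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
}
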