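# Shared helpers for the test suite.

zt_grid <- seq(0, 44, by = 4)

# All permutations of a vector (for brute-force null enumeration, n <= 6).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Vectorised circular distance in hours on the 24 h clock.
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# A tiny 3-gene time course as TSV lines.
tiny_tc_lines <- function() {
  vals <- rbind(8 + make_waveform("cosine", 24, 8, zt_grid),
                6 + 2 * make_waveform("box", 24, 0, zt_grid),
                rep(5, 12))
  c(paste(c("id", paste0("ZT", zt_grid)), collapse = "\t"),
    vapply(1:3, function(i) {
      paste(c(paste0("g", i), format(vals[i, ], digits = 10)), collapse = "\t")
    }, character(1)))
}
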