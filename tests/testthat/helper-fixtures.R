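# Shared fixtures: hand-built tetrads with known event signatures, and small
# simulation configs used across test files.

# a 10-marker chromosome at 1 kb spacing; rows given as strings of A/B/N
toy_tetrad <- function(..., id = "toy", chrom = "c1",
                       pos = seq(1000L, 10000L, by = 1000L)) {
  rows <- list(...)
  stopifnot(length(rows) == 4L)
  calls <- do.call(rbind, lapply(rows, function(s) {
    v <- strsplit(s, "")[[1]]
    stopifnot(length(v) == length(pos))
    match(ifelse(v == "N", NA, v), c("A", "B"))
  }))
  tetrad_seg(id, stats::setNames(list(list(pos = pos, calls = calls)), chrom))
}

toy_layout <- function(length = 12000, chrom = "c1",
                       pos = seq(1000L, 10000L, by = 1000L)) {
  genome_layout(chrom, length, round(length / 2),
                stats::setNames(list(as.integer(pos)), chrom))
}

# dense-marker layout for caller-fidelity simulations
dense_layout <- function(n_chrom = 4, len = 5e5, spacing = 500) {
  kl_layout(lengths = rep(len, n_chrom), marker_density = 1 / spacing,
            spacing_shape = 1)
}

# recall: fraction of detectable truth COs covered by a called CO span
# (+/- slack); undetectable events have no signature in the marker data
co_recall <- function(events, truth, slack = 5000) {
  co <- events[events$kind == "CO", , drop = FALSE]
  tr <- truth[truth$kind == "CO" & truth$detectable, , drop = FALSE]
  hits <- mapply(function(tt, cc, pp) {
    any(co$tetrad == tt & co$chrom == cc &
          co$max_start - slack <= pp & co$max_end + slack >= pp)
  }, tr$tetrad, tr$chrom, tr$pos)
  mean(hits)
}

co_precision <- function(events, truth, slack = 5000) {
  co <- events[events$kind == "CO", , drop = FALSE]
  tr <- truth[truth$kind == "CO", , drop = FALSE]
  hits <- mapply(function(tt, cc, s, e) {
    any(tr$tetrad == tt & tr$chrom == cc &
          tr$pos >= s - slack & tr$pos <= e + slack)
  }, co$tetrad, co$chrom, co$max_start, co$max_end)
  mean(hits)
}

# events data.frame built directly from positions (for statistics modules)
make_events <- function(tetrad, chrom, midpoint, kind = "CO",
                        chromatids = "") {
  n <- max(length(tetrad), length(chrom), length(midpoint))
  ev <- data.frame(
    tetrad = rep_len(as.character(tetrad), n),
    chrom = rep_len(as.character(chrom), n),
    kind = rep_len(kind, n),
    class = ifelse(rep_len(kind, n) == "CO", 0L, NA_integer_),
    chromatids = rep_len(chromatids, n),
    midpoint = rep_len(midpoint, n),
    min_start = rep_len(midpoint, n), min_end = rep_len(midpoint, n),
    max_start = rep_len(midpoint, n), max_end = rep_len(midpoint, n),
    discontinuous = FALSE, loh_40 = FALSE, tract_lengths = "",
    stringsAsFactors = FALSE)
  class(ev) <- c("recomb_events", "data.frame")
  ev
}

# hard-core CO process: successive positions at least `core` apart
hardcore_events <- function(n_meioses, chrom_len, core = 60000,
                            mean_extra = 30000, chrom = "c1") {
  out <- list()
  for (i in seq_len(n_meioses)) {
    pos <- numeric(0)
    cur <- stats::runif(1, 0, core + mean_extra)
    while (cur < chrom_len) {
      pos <- c(pos, cur)
      cur <- cur + core + stats::rexp(1, 1 / mean_extra)
    }
    if (length(pos)) {
      out[[length(out) + 1L]] <-
        make_events(paste0("t", i), chrom, pos)
    }
  }
  ev <- do.call(rbind, out)
  class(ev) <- c("recomb_events", "data.frame")
  ev
}
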