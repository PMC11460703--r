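# Permutation-based CO hotspot/coldspot detection, synteny-based conservation
# across species, and gene-set association.

#' Window counts of CO midpoints
#'
#' Chromosomes are partitioned into non-overlapping windows anchored at
#' position 1; the final partial window is kept and flagged.
#'
#' @param events a `recomb_events` data.frame (CO rows are used).
#' @param layout a [genome_layout()].
#' @param window window size in bp.
#' @return A data.frame with columns chrom, start, end (1-based inclusive),
#'   count, partial.
#' @export
window_counts <- function(events, layout, window) {
  stopifnot(inherits(layout, "genome_layout"), window > 0)
  co <- events[events$kind == "CO", , drop = FALSE]
  rows <- lapply(seq_len(nrow(layout$chrom)), function(i) {
    cn <- layout$chrom$chrom[i]
    L <- layout$chrom$length[i]
    nw <- ceiling(L / window)
    start <- (seq_len(nw) - 1) * window + 1
    end <- pmin(seq_len(nw) * window, L)
    mid <- co$midpoint[co$chrom == cn]
    b <- pmin(nw, floor((mid - 1) / window) + 1L)
    data.frame(chrom = cn, start = start, end = end,
               count = as.numeric(tabulate(b, nbins = nw)),
               partial = end - start + 1 < window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation threshold for hotspot/coldspot calling
#'
#' Drops `n_events` events into `n_windows` windows with equal probability
#' (multinomial) `n_perm` times, records the per-permutation extreme (max or
#' min) window count, and returns the `rank`-th largest (max mode) or smallest
#' (min mode) of these extremes. Deterministic given `seed`.
#'
#' @param n_events number of events to permute (> 0 in max mode).
#' @param n_windows number of windows.
#' @param n_perm number of permutations (default 1e5; must be >= `rank`).
#' @param rank extreme rank defining the threshold (default 2000, i.e. a 2%
#'   tail with the default `n_perm`).
#' @param mode "max" (hotspots) or "min" (coldspots).
#' @param seed optional integer seed (RNG state restored on exit).
#' @return Integer threshold.
#' @export
permutation_threshold <- function(n_events, n_windows, n_perm = 1e5,
                                  rank = 2000, mode = c("max", "min"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < rank) stop("n_perm must be >= rank")
  if (mode == "max" && n_events == 0) {
    stop("n_events must be > 0 in max mode")
  }
  if (n_events == 0) return(0L)  # min mode, trivially
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  prob <- rep(1 / n_windows, n_windows)
  extremes <- numeric(n_perm)
  chunk <- max(1L, min(n_perm, floor(2e6 / n_windows)))
  done <- 0L
  fun <- if (mode == "max") max else min
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    m <- stats::rmultinom(nb, n_events, prob)
    extremes[done + seq_len(nb)] <- apply(m, 2, fun)
    done <- done + nb
  }
  s <- sort(extremes, decreasing = (mode == "max"))
  as.integer(s[rank])
}

#' Call CO hotspots / coldspots
#'
#' Hotspots are windows whose CO count is strictly above the max-mode
#' permutation threshold; coldspots are windows at or below the min-mode
#' threshold (with the default parameters the coldspot threshold is 0, i.e.
#' windows devoid of COs). Adjacent qualifying windows are reported
#' individually and as merged intervals.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @param window window size (5 kb default for hotspots, 20 kb for coldspots).
#' @param n_perm,rank,seed passed to [permutation_threshold()].
#' @param strict use strict inequality (count > threshold) for hotspots; if
#'   FALSE, count >= threshold. The min mode comparison is always
#'   count <= threshold.
#' @return A list with `threshold`, `windows` (qualifying windows), `merged`
#'   (merged intervals) and `all_windows` (the full count table).
#' @export
call_hotspots <- function(events, layout, window = 5000, n_perm = 1e5,
                          rank = 2000, seed = NULL, strict = TRUE) {
  wc <- window_counts(events, layout, window)
  n_events <- sum(wc$count)
  thr <- permutation_threshold(n_events, nrow(wc), n_perm, rank,
                               mode = "max", seed = seed)
  hit <- if (strict) wc$count > thr else wc$count >= thr
  list(threshold = thr, windows = wc[hit, , drop = FALSE],
       merged = merge_windows(wc[hit, , drop = FALSE]), all_windows = wc)
}

#' @rdname call_hotspots
#' @export
call_coldspots <- function(events, layout, window = 20000, n_perm = 1e5,
                           rank = 2000, seed = NULL) {
  wc <- window_counts(events, layout, window)
  n_events <- sum(wc$count)
  thr <- permutation_threshold(n_events, nrow(wc), n_perm, rank,
                               mode = "min", seed = seed)
  hit <- wc$count <= thr
  list(threshold = thr, windows = wc[hit, , drop = FALSE],
       merged = merge_windows(wc[hit, , drop = FALSE]), all_windows = wc)
}

merge_windows <- function(w) {
  if (nrow(w) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0)))
  }
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  out <- list()
  cur <- w[1, c("chrom", "start", "end")]
  cur$n_windows <- 1L
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && w$start[i] == cur$end + 1) {
      cur$end <- w$end[i]
      cur$n_windows <- cur$n_windows + 1L
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- w[i, c("chrom", "start", "end")]
      cur$n_windows <- 1L
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

interval_gap <- function(s1, e1, s2, e2) {
  # gap between two intervals; 0 if they overlap or touch
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Cross-species hotspot conservation by synteny
#'
#' For every hotspot in species A the `n_genes` nearest genes are identified;
#' their orthologs are mapped into species B; if at least `min_orthologs`
#' orthologs co-locate within `synteny_dist` of each other on one B
#' chromosome, the region is considered syntenic and the hotspot testable. A
#' testable hotspot is conserved iff a B hotspot lies within `conserved_dist`
#' of the syntenic block. Hotspots whose neighbourhood cannot be mapped are
#' marked untestable, not non-conserved.
#'
#' @param hotspots_a,hotspots_b data.frames with chrom, start, end.
#' @param genes_a,genes_b gene tables: gene, chrom, start, end.
#' @param orthologs data.frame with columns gene_a, gene_b.
#' @param n_genes nearest genes to consider (default 5).
#' @param min_orthologs minimum co-locating orthologs for synteny (default 2).
#' @param synteny_dist maximum span between co-locating orthologs (10 kb).
#' @param conserved_dist maximum hotspot-to-block distance (5 kb).
#' @return A data.frame: one row per A hotspot with `status` in
#'   {"conserved", "not_conserved", "untestable"} and the syntenic block
#'   coordinates when defined.
#' @export
conservation <- function(hotspots_a, hotspots_b, genes_a, genes_b, orthologs,
                         n_genes = 5, min_orthologs = 2,
                         synteny_dist = 10000, conserved_dist = 5000) {
  rows <- lapply(seq_len(nrow(hotspots_a)), function(i) {
    h <- hotspots_a[i, ]
    res <- data.frame(chrom = h$chrom, start = h$start, end = h$end,
                      status = "untestable", block_chrom = NA_character_,
                      block_start = NA_real_, block_end = NA_real_,
                      stringsAsFactors = FALSE)
    ga <- genes_a[genes_a$chrom == h$chrom, , drop = FALSE]
    if (nrow(ga) == 0L) return(res)
    d <- interval_gap(h$start, h$end, ga$start, ga$end)
    near <- ga$gene[order(d)][seq_len(min(n_genes, nrow(ga)))]
    ob <- orthologs$gene_b[orthologs$gene_a %in% near]
    gb <- genes_b[genes_b$gene %in% ob, , drop = FALSE]
    if (nrow(gb) < min_orthologs) return(res)
    # cluster ortholog midpoints per B chromosome within synteny_dist
    for (cn in unique(gb$chrom)) {
      mids <- sort((gb$start[gb$chrom == cn] + gb$end[gb$chrom == cn]) / 2)
      if (length(mids) < min_orthologs) next
      # sliding cluster: any window of min_orthologs consecutive midpoints
      # spanning <= synteny_dist
      for (j in seq_len(length(mids) - min_orthologs + 1)) {
        jj <- j + min_orthologs - 1
        if (mids[jj] - mids[j] <= synteny_dist) {
          b_start <- mids[j]; b_end <- mids[jj]
          res$status <- "not_conserved"
          res$block_chrom <- cn
          res$block_start <- b_start; res$block_end <- b_end
          hb <- hotspots_b[hotspots_b$chrom == cn, , drop = FALSE]
          if (nrow(hb) &&
              any(interval_gap(b_start, b_end, hb$start, hb$end) <=
                  conserved_dist)) {
            res$status <- "conserved"
          }
          break
        }
      }
      if (res$status != "untestable") break
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-set association with called windows
#'
#' Tests whether a gene set is over-represented among the genes overlapping a
#' set of called windows (e.g. coldspots), by the hypergeometric upper tail
#' with the full annotated gene table as the universe.
#'
#' @param windows data.frame with chrom, start, end (1-based inclusive).
#' @param gene_set character vector of gene identifiers (non-empty).
#' @param genes gene table: gene, chrom, start, end (the universe).
#' @return A list with `p`, `overlap`, `n_in_windows`, `set_size`, `universe`.
#' @export
geneset_association <- function(windows, gene_set, genes) {
  if (length(gene_set) == 0L) stop("empty gene set")
  in_win <- vapply(seq_len(nrow(genes)), function(i) {
    w <- windows[windows$chrom == genes$chrom[i], , drop = FALSE]
    nrow(w) > 0 && any(genes$start[i] <= w$end & genes$end[i] >= w$start)
  }, logical(1))
  N <- nrow(genes)
  K <- sum(genes$gene %in% gene_set)
  n <- sum(in_win)
  q <- sum(in_win & genes$gene %in% gene_set)
  p <- stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, overlap = q, n_in_windows = n, set_size = K, universe = N)
}
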