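# CO/NCO event calling and classification from tetrad segregation matrices.
#
# The caller detects two kinds of per-chromosome features: (i) phase switches
# on individual chromatids (maximal runs of constant parental origin, missing
# calls skipped) and (ii) conversion tracts (maximal runs of complete marker
# columns deviating from 2:2). Features whose midpoints fall within
# `merge_dist` of each other are grouped by single linkage; each group becomes
# one event. A group is a CO iff >= 2 chromatids reciprocally exchange their
# flanking phase across the group, otherwise an NCO.

#' Find phase switches on one chromatid
#'
#' @param calls vector of parental-origin calls for one chromatid (1/2 or
#'   "A"/"B"; NA or "N" = missing), in marker order.
#' @return A list with `runs` (data.frame: value, first, last marker index of
#'   each maximal constant-origin run, missing skipped) and `switches`
#'   (data.frame: left, right marker indices flanking each phase switch; the
#'   switch lies in the inter-marker interval spanning any skipped missing
#'   markers). An all-missing row yields empty results with a warning.
#' @examples
#' find_breakpoints(c(1, 1, 1, 2, 2))$switches  # one switch between 3 and 4
#' @export
find_breakpoints <- function(calls) {
  if (is.character(calls)) {
    calls <- match(ifelse(calls == "N", NA, calls), c("A", "B"))
  }
  idx <- which(!is.na(calls))
  if (length(idx) == 0L) {
    warning("all calls missing on this chromatid")
    return(list(
      runs = data.frame(value = integer(0), first = integer(0),
                        last = integer(0)),
      switches = data.frame(left = integer(0), right = integer(0))))
  }
  r <- rle(as.integer(calls[idx]))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- data.frame(value = r$values, first = idx[starts], last = idx[ends])
  k <- nrow(runs)
  switches <- if (k > 1L) {
    data.frame(left = runs$last[-k], right = runs$first[-1L])
  } else data.frame(left = integer(0), right = integer(0))
  list(runs = runs, switches = switches)
}

# column status of a 4 x M call matrix: -1 = has missing, otherwise the count
# of parent-A alleles (0..4)
column_status <- function(calls) {
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  nmiss <- colSums(is.na(calls))
  ifelse(nmiss > 0L, -1L, n1)
}

# running maximum of the previous elements (for single-linkage on intervals):
# cummax_shift(x)[i] = max(x[1..i-1]), with x[1] for i = 1
cummax_shift <- function(x) {
  if (length(x) <= 1L) return(x)
  c(x[1], cummax(x)[-length(x)])
}

# maximal runs of TRUE in a logical vector -> data.frame(first, last)
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- r$values
  data.frame(first = starts[keep], last = ends[keep])
}

#' Call recombination events in a tetrad
#'
#' Re-implementation of the classic tetrad event-calling step: per-chromatid
#' phase switches and 3:1/4:0 conversion tracts are detected, features with
#' midpoints within `merge_dist` are single-linkage grouped into events, each
#' group is typed CO (reciprocal flanking-phase exchange on >= 2 chromatids)
#' or NCO, and COs are classified on the Anderson scheme (see
#' [classify_event()]). Ambiguous groups are emitted with class 8 rather than
#' dropped.
#'
#' @param seg a [tetrad_seg()] or a list of them.
#' @param merge_dist grouping distance on feature midpoints in bp
#'   (default 5000).
#' @param layout optional [genome_layout()]; provides chromosome lengths for
#'   maximal spans of events at chromosome ends (otherwise the last marker is
#'   used).
#' @return A `recomb_events` data.frame with columns tetrad, chrom, kind
#'   (CO/NCO), class (0/1/2/3/4/8 for COs, NA for NCOs), chromatids
#'   (comma-joined), midpoint, min_start/min_end (first to last affected
#'   marker), max_start/max_end (flanking unconverted markers), discontinuous,
#'   loh_40 (standalone 4:0 tract, candidate LOH), tract_lengths
#'   (comma-joined mid-convention conversion tract lengths in bp).
#' @export
call_events <- function(seg, merge_dist = 5000, layout = NULL) {
  if (inherits(seg, "tetrad_seg")) seg <- list(seg)
  out <- lapply(seg, function(tt) {
    rows <- lapply(names(tt$chroms), function(cn) {
      el <- tt$chroms[[cn]]
      L <- if (!is.null(layout)) {
        layout$chrom$length[match(cn, layout$chrom$chrom)]
      } else NA_real_
      call_chromosome(tt$id, cn, el$pos, el$calls, merge_dist, L)
    })
    do.call(rbind, rows)
  })
  ev <- do.call(rbind, out)
  if (is.null(ev) || nrow(ev) == 0L) return(empty_events())
  rownames(ev) <- NULL
  class(ev) <- c("recomb_events", "data.frame")
  ev
}

call_chromosome <- function(tid, cn, pos, calls, merge_dist, chrom_len) {
  M <- length(pos)
  if (M < 2L) return(NULL)

  # per-chromatid run structure
  bp <- lapply(1:4, function(r) suppressWarnings(find_breakpoints(calls[r, ])))

  feats <- list()
  for (r in 1:4) {
    sw <- bp[[r]]$switches
    if (nrow(sw)) {
      feats[[length(feats) + 1L]] <- data.frame(
        type = "switch", chromatid = r, first = sw$left, last = sw$right,
        mid = (pos[sw$left] + pos[sw$right]) / 2)
    }
  }
  st <- column_status(calls)
  non22 <- st >= 0L & st != 2L
  tr <- logical_runs(non22)
  if (nrow(tr)) {
    feats[[length(feats) + 1L]] <- data.frame(
      type = "tract", chromatid = NA_integer_, first = tr$first,
      last = tr$last, mid = (pos[tr$first] + pos[tr$last]) / 2)
  }
  if (length(feats) == 0L) return(NULL)
  f <- do.call(rbind, feats)
  f$start_bp <- pos[f$first]
  f$end_bp <- pos[f$last]
  f <- f[order(f$start_bp, f$end_bp), , drop = FALSE]

  # single-linkage grouping on feature extents: a feature joins the current
  # group when it starts within merge_dist of the group's running end. This
  # keeps a crossover chained to its own conversion tract (which physically
  # touches the offset switch) even when the tract is long, while distinct
  # events separated by > merge_dist of clean 2:2 markers stay apart.
  run_end <- cummax_shift(f$end_bp)
  grp <- cumsum(c(1, (f$start_bp[-1] - run_end[-1]) > merge_dist))

  rows <- lapply(split(seq_len(nrow(f)), grp), function(ii) {
    build_event(tid, cn, pos, calls, f[ii, , drop = FALSE], bp, st, chrom_len)
  })
  do.call(rbind, rows)
}

# internal (phase-revert) runs of a chromatid: rle runs that are neither the
# first nor the last run -> converted markers on that chromatid
internal_runs <- function(bp_r) {
  runs <- bp_r$runs
  k <- nrow(runs)
  if (k < 3L) return(runs[0, , drop = FALSE])
  runs[2:(k - 1L), , drop = FALSE]
}

build_event <- function(tid, cn, pos, calls, f, bp, st, chrom_len) {
  M <- length(pos)
  is_sw <- f$type == "switch"
  # flanking (unconverted) marker indices around the whole group
  flank_left <- min(ifelse(is_sw, f$first, f$first - 1L))
  flank_right <- max(ifelse(is_sw, f$last, f$last + 1L))

  before <- after <- rep(NA_integer_, 4L)
  for (r in 1:4) {
    if (flank_left >= 1L) {
      v <- calls[r, seq_len(min(flank_left, M))]
      nz <- which(!is.na(v))
      if (length(nz)) before[r] <- v[nz[length(nz)]]
    }
    if (flank_right <= M) {
      v <- calls[r, flank_right:M]
      nz <- which(!is.na(v))
      if (length(nz)) after[r] <- v[nz[1]]
    }
  }
  known <- !is.na(before) & !is.na(after)
  changed <- which(known & before != after)
  n_ab <- sum(before[changed] == 1L)
  n_ba <- sum(before[changed] == 2L)
  is_co <- length(changed) >= 2L && n_ab == n_ba

  # conversion tract runs inside the group (marker index ranges)
  tr <- f[!is_sw, , drop = FALSE]
  n_tracts <- nrow(tr)
  has40 <- n_tracts > 0 && any(unlist(lapply(seq_len(n_tracts), function(j) {
    s <- st[tr$first[j]:tr$last[j]]; s == 0L | s == 4L
  })))

  # carriers: chromatids whose internal (revert) runs overlap a tract run
  carrier_keys <- character(0)
  all_carriers <- integer(0)
  gc_inv <- FALSE; gc_non <- FALSE
  tract_lens <- numeric(0)
  if (n_tracts) {
    ir <- lapply(1:4, function(r) internal_runs(bp[[r]]))
    # a chromatid carries the tract iff one of its phase-revert runs is
    # contained in the converted-column run (2-marker slack for columns
    # masked by missing calls); mere overlap would also catch the long
    # span between two distant switches of a double-CO chromatid
    carriers_of <- function(a, b) {
      which(vapply(1:4, function(r) {
        any(ir[[r]]$first >= a - 2L & ir[[r]]$last <= b + 2L &
              ir[[r]]$first <= b & ir[[r]]$last >= a)
      }, logical(1)))
    }
    for (j in seq_len(n_tracts)) {
      a <- tr$first[j]; b <- tr$last[j]
      carriers <- carriers_of(a, b)
      if (length(carriers) == 0L) {
        if (is_co) {
          gc_inv <- TRUE
          carrier_keys <- c(carrier_keys, "involved")
        } else {
          # e.g. tract running to a chromosome end: the carrier is the
          # chromatid whose calls inside the run contradict its flank phase
          carriers <- which(vapply(1:4, function(r) {
            ref <- if (!is.na(before[r])) before[r] else after[r]
            if (is.na(ref)) return(FALSE)
            v <- calls[r, a:b]
            v <- v[!is.na(v)]
            length(v) > 0 && mean(v != ref) > 0.5
          }, logical(1)))
          carrier_keys <- c(carrier_keys, paste(carriers, collapse = "+"))
        }
      } else {
        if (any(carriers %in% changed)) gc_inv <- TRUE
        if (any(!(carriers %in% changed))) gc_non <- TRUE
        # tracts on involved chromatids share one key so that an interrupted
        # tract around the exchange point reads as discontinuous
        key <- if (is_co && all(carriers %in% changed)) "involved" else
          paste(sort(carriers), collapse = "+")
        carrier_keys <- c(carrier_keys, key)
      }
      all_carriers <- c(all_carriers, carriers)
      # mid-convention tract length: average of minimal (first-last converted
      # marker) and maximal (flanking unconverted markers) extents
      min_len <- pos[b] - pos[a] + 1
      lo <- if (a > 1L) pos[a - 1L] else 1
      hi <- if (b < M) pos[b + 1L] else (if (is.na(chrom_len)) pos[M] else chrom_len)
      max_len <- hi - lo - 1
      tract_lens <- c(tract_lens, (min_len + max_len) / 2)
    }
  }
  discontinuous <- n_tracts > 1L && anyDuplicated(carrier_keys) > 0L

  if (is_co) {
    kind <- "CO"
    cls <- classify_event(length(changed), gc_inv, gc_non, discontinuous)
    chromatids <- paste(sort(changed), collapse = ",")
  } else if (n_tracts > 0L) {
    kind <- "NCO"
    cls <- NA_integer_
    carr <- sort(unique(c(changed, all_carriers)))
    chromatids <- paste(carr, collapse = ",")
  } else {
    # switch features without net phase change or tract evidence (e.g. an
    # apparent tight double CO): ambiguous composite
    kind <- "CO"
    cls <- 8L
    chromatids <- paste(sort(changed), collapse = ",")
  }

  max_start <- if (flank_left >= 1L) pos[flank_left] else 1
  max_end <- if (flank_right <= M) pos[flank_right] else {
    if (is.na(chrom_len)) pos[M] else chrom_len
  }
  # minimal span: first to last converted marker; for conversion-free groups
  # (pure switches), the markers flanking the switch interval(s)
  if (n_tracts > 0L) {
    min_start <- min(pos[tr$first])
    min_end <- max(pos[tr$last])
  } else {
    min_start <- min(pos[f$first])
    min_end <- max(pos[f$last])
  }

  data.frame(
    tetrad = tid, chrom = cn, kind = kind, class = cls,
    chromatids = chromatids, midpoint = (max_start + max_end) / 2,
    min_start = min_start, min_end = min_end,
    max_start = max_start, max_end = max_end,
    discontinuous = discontinuous,
    loh_40 = has40 && !is_co,
    tract_lengths = paste(round(tract_lens, 1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Classify a crossover on the Anderson scheme
#'
#' Class labels: 0 = simple CO without gene conversion; 1 = CO with a GC tract
#' on an involved chromatid; 2 = CO with a GC tract on a chromatid not
#' involved in the exchange; 3 = GC tracts on both involved and non-involved
#' chromatids; 4 = discontinuous (interrupted) GC; 8 = any other composite
#' (e.g. more than two exchanged chromatids). Classes 0 and 1 are "simple",
#' 2/3/4/8 "complex".
#'
#' @param n_involved number of chromatids whose flanking phase changed.
#' @param gc_involved any conversion tract on an involved chromatid?
#' @param gc_noninvolved any conversion tract on a non-involved chromatid?
#' @param discontinuous any carrier with an interrupted tract?
#' @return Integer class label.
#' @export
classify_event <- function(n_involved, gc_involved, gc_noninvolved,
                           discontinuous) {
  if (n_involved > 2L) return(8L)
  if (gc_involved && gc_noninvolved) return(3L)
  if (discontinuous) return(4L)
  if (gc_involved) return(1L)
  if (gc_noninvolved) return(2L)
  0L
}

#' Summarize called events
#'
#' Dataset-level statistics: per-meiosis CO and NCO counts (median and mean;
#' tetrads without events count as zero), per-chromosome means, events per Mb
#' (dataset total / genome Mb, and per-meiosis rate), per-tetrad CO:NCO
#' ratios, fraction of COs with a detectable conversion tract, median tract
#' lengths (mid convention), fraction of complex CO classes, and Pearson /
#' Spearman correlations of per-chromosome mean counts and densities versus
#' chromosome length. Standalone 4:0 tracts (`loh_40`) are excluded from NCO
#' counts.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @param n_meioses number of meioses in the dataset (must be >= 1).
#' @return An object of class `recomb_summary` (a list).
#' @export
summarize_events <- function(events, layout, n_meioses) {
  stopifnot(inherits(layout, "genome_layout"))
  if (n_meioses < 1) stop("n_meioses must be >= 1")
  ev <- events[!(events$kind == "NCO" & events$loh_40), , drop = FALSE]
  G_mb <- genome_size(layout) / 1e6
  k <- nrow(layout$chrom)

  tids <- unique(ev$tetrad)
  count_per <- function(kind) {
    tab <- table(factor(ev$tetrad[ev$kind == kind], levels = tids))
    c(as.numeric(tab), rep(0, n_meioses - length(tids)))
  }
  co_n <- count_per("CO")
  nco_n <- count_per("NCO")

  co <- ev[ev$kind == "CO", , drop = FALSE]
  nco <- ev[ev$kind == "NCO", , drop = FALSE]
  has_gc <- nzchar(co$tract_lengths)
  parse_lens <- function(s) {
    as.numeric(unlist(strsplit(s[nzchar(s)], ",", fixed = TRUE)))
  }

  per_chrom <- data.frame(
    chrom = layout$chrom$chrom, length = layout$chrom$length,
    mean_co = as.numeric(table(factor(co$chrom,
      levels = layout$chrom$chrom))) / n_meioses,
    mean_nco = as.numeric(table(factor(nco$chrom,
      levels = layout$chrom$chrom))) / n_meioses)
  per_chrom$co_density <- per_chrom$mean_co / (per_chrom$length / 1e6)

  safe_cor <- function(x, y, method = "pearson") {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = method)
  }
  cors <- list(
    pearson_co_vs_length = safe_cor(per_chrom$mean_co, per_chrom$length),
    spearman_co_vs_length = safe_cor(per_chrom$mean_co, per_chrom$length,
                                     "spearman"),
    pearson_density_vs_length = safe_cor(per_chrom$co_density,
                                         per_chrom$length),
    spearman_density_vs_length = safe_cor(per_chrom$co_density,
                                          per_chrom$length, "spearman"))

  ratio_ok <- nco_n > 0
  structure(list(
    n_meioses = n_meioses,
    n_chromosomes = k,
    total_co = nrow(co), total_nco = nrow(nco),
    median_co = stats::median(co_n), mean_co = mean(co_n),
    median_nco = stats::median(nco_n), mean_nco = mean(nco_n),
    co_per_chromosome = stats::median(co_n) / k,
    nco_per_chromosome = stats::median(nco_n) / k,
    co_per_mb_total = nrow(co) / G_mb,
    co_per_mb_per_meiosis = mean(co_n) / G_mb,
    nco_per_mb_per_meiosis = mean(nco_n) / G_mb,
    mean_co_nco_ratio = if (any(ratio_ok)) {
      mean(co_n[ratio_ok] / nco_n[ratio_ok])
    } else NA_real_,
    frac_co_with_gc = if (nrow(co)) mean(has_gc) else NA_real_,
    median_co_tract = stats::median(parse_lens(co$tract_lengths)),
    median_nco_tract = stats::median(parse_lens(nco$tract_lengths)),
    frac_complex_co = if (nrow(co)) {
      mean(co$class %in% c(2L, 3L, 4L, 8L))
    } else NA_real_,
    per_chromosome = per_chrom,
    correlations = cors,
    co_counts = co_n, nco_counts = nco_n
  ), class = "recomb_summary")
}

#' @export
print.recomb_summary <- function(x, ...) {
  cat("<recomb_summary> ", x$n_meioses, " meioses, ", x$n_chromosomes,
      " chromosomes\n", sep = "")
  cat(sprintf("  CO : total %d, median/meiosis %.0f (%.1f per chromosome), %.0f per Mb (dataset)\n",
              x$total_co, x$median_co, x$co_per_chromosome, x$co_per_mb_total))
  cat(sprintf("  NCO: total %d, median/meiosis %.0f (%.1f per chromosome)\n",
              x$total_nco, x$median_nco, x$nco_per_chromosome))
  cat(sprintf("  mean CO:NCO ratio %.2f | %.0f%% of COs with GC | complex CO %.0f%%\n",
              x$mean_co_nco_ratio, 100 * x$frac_co_with_gc,
              100 * x$frac_complex_co))
  cat(sprintf("  median tract (mid) CO %.0f bp, NCO %.0f bp\n",
              x$median_co_tract, x$median_nco_tract))
  invisible(x)
}

#' Positional statistics of events
#'
#' Distances of event midpoints to the centromere and to the nearer chromosome
#' end.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @return A data.frame with per-event `dist_centromere` and `dist_end` (bp)
#'   plus the input identification columns; attribute `medians` holds the
#'   per-kind medians.
#' @export
positional_stats <- function(events, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  i <- match(events$chrom, layout$chrom$chrom)
  cen <- layout$chrom$centromere[i]
  len <- layout$chrom$length[i]
  out <- data.frame(
    tetrad = events$tetrad, chrom = events$chrom, kind = events$kind,
    midpoint = events$midpoint,
    dist_centromere = abs(events$midpoint - cen),
    dist_end = pmin(events$midpoint - 1, len - events$midpoint),
    stringsAsFactors = FALSE)
  med <- do.call(rbind, lapply(split(out, out$kind), function(d) {
    data.frame(kind = d$kind[1],
               median_dist_centromere = stats::median(d$dist_centromere),
               median_dist_end = stats::median(d$dist_end))
  }))
  rownames(med) <- NULL
  attr(out, "medians") <- med
  out
}
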