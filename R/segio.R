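# Segregation data model and TSV/BED IO.
#
# Internal genotype coding: integer 1 = parent A, 2 = parent B, NA = missing.
# File coding: A / B / N. Positions are 1-based inclusive internally; all BED
# output is 0-based half-open.

#' Tetrad segregation object
#'
#' Per-tetrad container of parental-origin calls: for each chromosome a 4 x M
#' integer matrix (rows = spores 1..4, columns = ordered markers; values 1 =
#' parent A, 2 = parent B, NA = missing) plus the marker positions.
#'
#' @param id tetrad identifier (character scalar).
#' @param chroms named list; each element is a list with `pos` (strictly
#'   increasing integer positions) and `calls` (4 x M matrix of 1/2/NA).
#' @return An object of class `tetrad_seg`.
#' @export
tetrad_seg <- function(id, chroms) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, is.list(chroms), !is.null(names(chroms)))
  for (cn in names(chroms)) {
    el <- chroms[[cn]]
    if (!is.list(el) || !all(c("pos", "calls") %in% names(el))) {
      stop("each chromosome element needs fields pos and calls")
    }
    calls <- el$calls
    if (!is.matrix(calls) || nrow(calls) != 4L) {
      stop("tetrad ", id, ", ", cn, ": calls must be a 4-row matrix ",
           "(exactly four spores)")
    }
    if (ncol(calls) != length(el$pos)) {
      stop("tetrad ", id, ", ", cn,
           ": matrix width must equal the number of markers")
    }
    if (length(el$pos) && is.unsorted(el$pos, strictly = TRUE)) {
      stop("tetrad ", id, ", ", cn, ": markers out of order")
    }
    ok <- is.na(calls) | calls == 1L | calls == 2L
    if (!all(ok)) stop("tetrad ", id, ", ", cn, ": calls must be 1, 2 or NA")
  }
  structure(list(id = id, chroms = chroms), class = "tetrad_seg")
}

#' @export
print.tetrad_seg <- function(x, ...) {
  nm <- vapply(x$chroms, function(e) length(e$pos), integer(1))
  cat("<tetrad_seg> ", x$id, ": ", length(x$chroms), " chromosomes, ",
      sum(nm), " markers\n", sep = "")
  invisible(x)
}

.code_chr <- c("A", "B")

#' Read a segregation TSV
#'
#' The segregation dialect is a UTF-8 tab-separated file with a header and
#' columns `tetrad`, `chrom`, `pos`, `spore1`..`spore4`. Calls are coded
#' `A` / `B` (parental origin) or `N` (missing). Rows are grouped by tetrad and
#' chromosome; marker positions must be strictly increasing within each group.
#'
#' @param path path to the TSV file.
#' @return A named list of [tetrad_seg()] objects (one per tetrad).
#' @seealso [write_segregation()]
#' @export
read_segregation <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tetrad", "chrom", "pos", paste0("spore", 1:4))
  if (!all(need %in% names(d))) {
    stop("segregation file must have columns: ", paste(need, collapse = ", "))
  }
  sp <- as.matrix(d[, paste0("spore", 1:4)])
  bad <- !(sp %in% c("A", "B", "N"))
  if (any(bad)) {
    ln <- which(rowSums(matrix(bad, nrow = nrow(d))) > 0)[1] + 1L
    stop("parse error at line ", ln, ": unknown call code '",
         sp[bad][1], "' (expected A, B or N)")
  }
  pos <- suppressWarnings(as.integer(d$pos))
  if (anyNA(pos)) {
    ln <- which(is.na(pos))[1] + 1L
    stop("parse error at line ", ln, ": non-integer position '",
         d$pos[is.na(pos)][1], "'")
  }
  num <- matrix(match(sp, .code_chr), nrow = nrow(d))  # N -> NA
  out <- list()
  for (tid in unique(d$tetrad)) {
    rows_t <- d$tetrad == tid
    chroms <- list()
    for (cn in unique(d$chrom[rows_t])) {
      i <- which(rows_t & d$chrom == cn)
      p <- pos[i]
      if (is.unsorted(p, strictly = TRUE)) {
        stop("validation error: tetrad ", tid, ", ", cn,
             ": markers out of order")
      }
      chroms[[cn]] <- list(pos = p, calls = t(num[i, , drop = FALSE]))
    }
    out[[tid]] <- tetrad_seg(tid, chroms)
  }
  out
}

#' Write segregation data
#'
#' Inverse of [read_segregation()]: writes one row per marker per tetrad, in
#' the documented TSV dialect.
#'
#' @param tetrads a list of [tetrad_seg()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segregation <- function(tetrads, path) {
  if (inherits(tetrads, "tetrad_seg")) tetrads <- list(tetrads)
  blocks <- lapply(tetrads, function(tt) {
    do.call(rbind, lapply(names(tt$chroms), function(cn) {
      el <- tt$chroms[[cn]]
      m <- matrix(.code_chr[el$calls], nrow = 4)
      m[is.na(m)] <- "N"
      data.frame(tetrad = tt$id, chrom = cn, pos = el$pos,
                 spore1 = m[1, ], spore2 = m[2, ], spore3 = m[3, ],
                 spore4 = m[4, ], stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a tetrad's segregation matrix
#'
#' Report-only check of marker-column allele balance. Columns with no missing
#' call must segregate 2:2 (Mendelian), 3:1 (conversion on one chromatid; both
#' directions counted symmetrically) or 4:0 (conversion on two chromatids, or
#' a loss-of-heterozygosity / aneuploidy scar when chromosome-wide).
#'
#' @param seg a [tetrad_seg()].
#' @param loh_threshold chromosomes whose 4:0 column fraction exceeds this
#'   value are flagged as candidate LOH/aneuploidy scars (default 0.5).
#' @return A data.frame with one row per chromosome: fractions of 2:2, 3:1,
#'   4:0 and missing-containing columns, and a logical `flagged` column.
#' @export
validate_tetrad <- function(seg, loh_threshold = 0.5) {
  stopifnot(inherits(seg, "tetrad_seg"))
  rows <- lapply(names(seg$chroms), function(cn) {
    calls <- seg$chroms[[cn]]$calls
    M <- ncol(calls)
    if (M == 0L) {
      return(data.frame(chrom = cn, n_markers = 0L, frac_22 = NA_real_,
                        frac_31 = NA_real_, frac_40 = NA_real_,
                        frac_missing = NA_real_, flagged = FALSE))
    }
    n1 <- colSums(calls == 1L, na.rm = TRUE)
    nmiss <- colSums(is.na(calls))
    full <- nmiss == 0L
    f22 <- sum(full & n1 == 2L)
    f31 <- sum(full & (n1 == 1L | n1 == 3L))
    f40 <- sum(full & (n1 == 0L | n1 == 4L))
    data.frame(chrom = cn, n_markers = M,
               frac_22 = f22 / M, frac_31 = f31 / M, frac_40 = f40 / M,
               frac_missing = mean(nmiss > 0L),
               flagged = (f40 / M) > loh_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write recombination events as a BED-like TSV
#'
#' Intervals are the events' maximal spans, converted to 0-based half-open
#' coordinates, sorted by chromosome then start, with deterministic column
#' order. `read_events()` is the inverse.
#'
#' @param events a `recomb_events` data.frame (see [call_events()]).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("chrom", "start", "end", "tetrad", "kind", "class", "chromatids",
            "midpoint", "min_start", "min_end", "discontinuous", "loh_40",
            "tract_lengths")
  if (nrow(events) == 0L) {
    empty <- stats::setNames(
      data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
    utils::write.table(empty, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = events$chrom,
    start = as.integer(events$max_start) - 1L,  # 0-based half-open
    end = as.integer(events$max_end),
    tetrad = events$tetrad,
    kind = events$kind,
    class = events$class,
    chromatids = events$chromatids,
    midpoint = events$midpoint,
    min_start = events$min_start,
    min_end = events$min_end,
    discontinuous = events$discontinuous,
    loh_40 = events$loh_40,
    tract_lengths = ifelse(nzchar(events$tract_lengths),
                           events$tract_lengths, "."),
    stringsAsFactors = FALSE
  )
  bed <- bed[order(bed$chrom, bed$start, bed$end, bed$tetrad), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(empty_events())
  ev <- data.frame(
    tetrad = as.character(d$tetrad), chrom = as.character(d$chrom),
    kind = d$kind, class = as.integer(d$class),
    chromatids = as.character(d$chromatids),
    midpoint = as.numeric(d$midpoint),
    min_start = as.numeric(d$min_start), min_end = as.numeric(d$min_end),
    max_start = as.numeric(d$start) + 1, max_end = as.numeric(d$end),
    discontinuous = as.logical(d$discontinuous),
    loh_40 = as.logical(d$loh_40),
    tract_lengths = ifelse(d$tract_lengths == ".", "",
                           as.character(d$tract_lengths)),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("recomb_events", "data.frame")
  ev
}

#' Write window calls (hotspots/coldspots) as BED
#'
#' @param windows data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and any extra columns; written 0-based half-open, sorted.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_windows <- function(windows, path) {
  w <- windows
  if (nrow(w)) {
    w$start <- as.integer(w$start) - 1L
    w <- w[order(w$chrom, w$start), , drop = FALSE]
  }
  utils::write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

empty_events <- function() {
  ev <- data.frame(
    tetrad = character(0), chrom = character(0), kind = character(0),
    class = integer(0), chromatids = character(0), midpoint = numeric(0),
    min_start = numeric(0), min_end = numeric(0), max_start = numeric(0),
    max_end = numeric(0), discontinuous = logical(0), loh_40 = logical(0),
    tract_lengths = character(0),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("recomb_events", "data.frame")
  ev
}
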