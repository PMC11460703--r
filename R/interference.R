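# Crossover interference statistics: genetic-distance conversion, gamma
# fitting of inter-CO distances, coefficient-of-coincidence curves, and
# chromatid interference.

#' Convert physical to genetic distance
#'
#' Uses the tetrad mapping relation 1 Morgan = genome size (bp) x 2 / mean
#' crossovers per meiosis, i.e. `cM = 100 * bp * mean_co / (2 * G)`. Linear
#' and invertible.
#'
#' @param bp physical distance(s) in bp.
#' @param genome_size total genome size G in bp (> 0).
#' @param mean_co mean crossover count per meiosis (> 0).
#' @return Genetic distance(s) in centiMorgans.
#' @examples
#' to_genetic_distance(250000, 1e6, 2)  # 25 cM
#' @export
to_genetic_distance <- function(bp, genome_size, mean_co) {
  if (mean_co <= 0) stop("mean_co must be > 0")
  if (genome_size <= 0) stop("genome_size must be > 0")
  100 * bp * mean_co / (2 * genome_size)
}

#' Inter-crossover distances
#'
#' Distances between successive CO midpoints within the same tetrad and
#' chromosome, pooled across the dataset. Chromosomes with fewer than two COs
#' contribute nothing. Optionally converted to genetic distance.
#'
#' @param events a `recomb_events` data.frame (only rows with kind == "CO"
#'   are used).
#' @param scale "bp" (default) or "cM".
#' @param genome_size,mean_co required when `scale = "cM"` (see
#'   [to_genetic_distance()]).
#' @return Numeric vector of pooled inter-CO distances.
#' @export
inter_co_distances <- function(events, scale = c("bp", "cM"),
                               genome_size = NULL, mean_co = NULL) {
  scale <- match.arg(scale)
  co <- events[events$kind == "CO", , drop = FALSE]
  if (nrow(co) == 0L) return(numeric(0))
  d <- unlist(lapply(split(co$midpoint, list(co$tetrad, co$chrom),
                           drop = TRUE),
                     function(p) if (length(p) >= 2L) diff(sort(p)) else NULL),
              use.names = FALSE)
  if (is.null(d)) d <- numeric(0)
  if (scale == "cM") {
    if (is.null(genome_size) || is.null(mean_co)) {
      stop("genome_size and mean_co required for cM scale")
    }
    d <- to_genetic_distance(d, genome_size, mean_co)
  }
  d
}

#' Fit a gamma distribution to inter-CO distances
#'
#' Maximum-likelihood gamma fit: the shape is the root of the profile score
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))`, solved by
#' Newton iteration to a tolerance of 1e-8; the scale is `mean(x) / shape`.
#' Interference is then assessed by a Kolmogorov-Smirnov test of the sample
#' against a shape-1 gamma (i.e. an exponential, no interference) whose scale
#' is fixed to the sample mean.
#'
#' @param distances positive inter-CO distances (n >= 30).
#' @return An object of class `gamma_interference` with elements `shape`,
#'   `scale`, `ks_p` (p-value vs the shape-1 null), `median`, `mean`, `n`.
#'   `coef()` returns c(shape, scale).
#' @export
fit_gamma <- function(distances) {
  x <- as.numeric(distances)
  if (length(x) < 30L) stop("need at least 30 distances")
  if (any(x <= 0)) stop("all distances must be positive")
  m <- mean(x)
  if (stats::var(x) == 0) stop("degenerate zero-variance sample")
  s <- log(m) - mean(log(x))          # always > 0 for non-degenerate samples
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # starting value
  for (i in 1:100) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / fp
    shape_new <- shape - step
    if (shape_new <= 0) shape_new <- shape / 2
    if (abs(shape_new - shape) < 1e-8 * max(1, shape)) {
      shape <- shape_new
      break
    }
    shape <- shape_new
  }
  ks <- suppressWarnings(
    stats::ks.test(x, "pgamma", shape = 1, scale = m))
  structure(list(shape = shape, scale = m / shape, ks_p = ks$p.value,
                 median = stats::median(x), mean = m, n = length(x)),
            class = "gamma_interference")
}

#' @export
print.gamma_interference <- function(x, ...) {
  cat("<gamma_interference> n =", x$n, "\n")
  cat(sprintf("  shape (gamma) = %.3f, scale = %.3f, median = %.2f\n",
              x$shape, x$scale, x$median))
  cat(sprintf("  KS vs shape-1 gamma (scale = sample mean): p = %.3g\n",
              x$ks_p))
  invisible(x)
}

#' @export
coef.gamma_interference <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' Coefficient-of-coincidence curve
#'
#' The genome is partitioned into fixed, non-overlapping bins anchored at
#' position 1 of each chromosome. For bin i, `f_i` is the fraction of meioses
#' with at least one event in the bin. For every same-chromosome bin pair
#' (i, j), the observed double frequency `f_ij` is compared with the expected
#' `f_i * f_j`; the CoC at an inter-interval distance d is the mean of
#' `f_ij / (f_i * f_j)` over all pairs with non-zero expected frequency whose
#' bin starts are d apart. Interference is `1 - CoC`.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @param n_meioses number of meioses in the dataset.
#' @param bin bin width in bp (default 25000).
#' @param event_set one of "CO", "NCO", "all".
#' @return A data.frame with columns `distance` (bp between bin starts),
#'   `coc`, `interference` (1 - CoC) and `n_pairs`; distance classes with no
#'   valid pair are omitted.
#' @export
coc_curve <- function(events, layout, n_meioses, bin = 25000,
                      event_set = c("CO", "NCO", "all")) {
  event_set <- match.arg(event_set)
  stopifnot(inherits(layout, "genome_layout"))
  ev <- switch(event_set,
               CO = events[events$kind == "CO", , drop = FALSE],
               NCO = events[events$kind == "NCO", , drop = FALSE],
               all = events)
  tids <- unique(ev$tetrad)
  if (length(tids) < n_meioses) {
    tids <- c(tids, paste0(".empty", seq_len(n_meioses - length(tids))))
  }
  num <- list(); den <- list()
  for (ci in seq_len(nrow(layout$chrom))) {
    cn <- layout$chrom$chrom[ci]
    nb <- ceiling(layout$chrom$length[ci] / bin)
    if (nb < 2L) next
    e <- ev[ev$chrom == cn, , drop = FALSE]
    occ <- matrix(FALSE, n_meioses, nb)
    if (nrow(e)) {
      b <- pmin(nb, floor((e$midpoint - 1) / bin) + 1L)
      ti <- match(e$tetrad, tids)
      occ[cbind(ti, b)] <- TRUE
    }
    f <- colMeans(occ)
    # cross-products give observed double frequencies for all bin pairs
    dbl <- crossprod(occ) / n_meioses
    for (d in 1:(nb - 1L)) {
      i <- seq_len(nb - d)
      j <- i + d
      expd <- f[i] * f[j]
      ok <- expd > 0
      if (!any(ok)) next
      ratio <- dbl[cbind(i[ok], j[ok])] / expd[ok]
      key <- as.character(d * bin)
      num[[key]] <- c(num[[key]], sum(ratio))
      den[[key]] <- c(den[[key]], length(ratio))
    }
  }
  if (length(num) == 0L) {
    return(data.frame(distance = numeric(0), coc = numeric(0),
                      interference = numeric(0), n_pairs = integer(0)))
  }
  dist <- as.numeric(names(num))
  coc <- vapply(names(num), function(k) sum(num[[k]]) / sum(den[[k]]),
                numeric(1))
  np <- vapply(names(num), function(k) sum(den[[k]]), numeric(1))
  o <- order(dist)
  data.frame(distance = dist[o], coc = as.numeric(coc[o]),
             interference = 1 - as.numeric(coc[o]),
             n_pairs = as.integer(np[o]))
}

#' Chromatid interference test
#'
#' Adjacent same-chromosome CO pairs within a tetrad are classified by the
#' number of chromatids they share: 2 shared = 2-strand, 1 = 3-strand, 0 =
#' 4-strand double crossovers. Without chromatid interference these occur
#' 1:2:1; the observed counts are tested by chi-square.
#'
#' @param events a `recomb_events` data.frame whose CO rows carry chromatid
#'   assignments ("a,b" strings).
#' @return A list with `counts` (named: two_strand, three_strand,
#'   four_strand), `p` (chi-square p vs 1:2:1) and `n_pairs`. Fewer than 20
#'   pairs triggers a warning (p still returned).
#' @export
chromatid_interference <- function(events) {
  co <- events[events$kind == "CO" & nzchar(events$chromatids), , drop = FALSE]
  cnt <- c(two_strand = 0L, three_strand = 0L, four_strand = 0L)
  for (grp in split(co, list(co$tetrad, co$chrom), drop = TRUE)) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$midpoint), , drop = FALSE]
    chl <- lapply(strsplit(grp$chromatids, ",", fixed = TRUE), as.integer)
    for (i in seq_len(nrow(grp) - 1L)) {
      a <- chl[[i]]; b <- chl[[i + 1L]]
      if (length(a) != 2L || length(b) != 2L) next  # complex COs skipped
      shared <- length(intersect(a, b))
      cnt[3L - shared] <- cnt[3L - shared] + 1L
    }
  }
  n <- sum(cnt)
  if (n < 20L) warning("fewer than 20 adjacent CO pairs; p-value unreliable")
  p <- if (n > 0L) {
    suppressWarnings(stats::chisq.test(cnt, p = c(0.25, 0.5, 0.25))$p.value)
  } else NA_real_
  list(counts = cnt, p = p, n_pairs = n)
}
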