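# Crossover control statistics: homeostasis, detectability-corrected NCO
# counts, dispersion of per-chromosome CO counts, and non-exchange (E0)
# chromosome inventories with Poisson expectations.

#' Per-tetrad CO and NCO counts
#'
#' @param events a `recomb_events` data.frame.
#' @param n_meioses total meioses (tetrads without events count as zero).
#' @return A data.frame with columns tetrad, co, nco (loh_40 NCOs excluded).
#' @export
tetrad_counts <- function(events, n_meioses) {
  ev <- events[!(events$kind == "NCO" & events$loh_40), , drop = FALSE]
  tids <- unique(ev$tetrad)
  if (length(tids) < n_meioses) {
    tids <- c(tids, paste0(".empty", seq_len(n_meioses - length(tids))))
  }
  data.frame(
    tetrad = tids,
    co = as.numeric(table(factor(ev$tetrad[ev$kind == "CO"], levels = tids))),
    nco = as.numeric(table(factor(ev$tetrad[ev$kind == "NCO"],
                                  levels = tids))),
    stringsAsFactors = FALSE)
}

#' Crossover homeostasis test
#'
#' Homeostasis maintains CO numbers at the expense of NCOs when initiating
#' events are limiting; it manifests as a negative Pearson correlation between
#' the per-tetrad CO:NCO ratio and the total event count (CO + NCO). Tetrads
#' with zero NCOs are skipped with a warning. If either variable has zero
#' variance (e.g. perfectly proportional counts), r = 0 and p = 1 are returned
#' with a warning.
#'
#' @param counts data.frame with columns `co` and `nco` (one row per tetrad;
#'   see [tetrad_counts()]), >= 10 usable tetrads required.
#' @param corrected if TRUE, NCO counts are divided by `detectability` first.
#' @param detectability NCO detection probability from [nco_detectability()];
#'   required when `corrected = TRUE`.
#' @return A list with `r`, `p`, `n` and `corrected`.
#' @export
homeostasis <- function(counts, corrected = FALSE, detectability = NULL) {
  nco <- counts$nco
  if (corrected) {
    if (is.null(detectability)) {
      stop("detectability required when corrected = TRUE")
    }
    nco <- nco / detectability
  }
  ok <- nco > 0
  if (any(!ok)) {
    warning(sum(!ok), " tetrad(s) with zero NCOs skipped")
  }
  co <- counts$co[ok]; nco <- nco[ok]
  if (length(co) < 10L) stop("need >= 10 tetrads with NCO > 0")
  ratio <- co / nco
  total <- co + nco
  if (stats::sd(ratio) == 0 || stats::sd(total) == 0) {
    warning("zero variance; returning r = 0")
    return(list(r = 0, p = 1, n = length(co), corrected = corrected))
  }
  ct <- stats::cor.test(ratio, total)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(co),
       corrected = corrected)
}

#' NCO detectability from marker coverage
#'
#' Probability that a conversion tract of random length, placed uniformly on
#' the genome, covers at least one marker — the Mancera-style correction
#' factor. With inter-marker gaps `g_k` and a tract of length `t`, the tract
#' is missed only when it falls strictly inside a gap, so
#' `D(t) = 1 - sum_k max(g_k - t, 0) / sum_k g_k`; `D` is the expectation of
#' `D(t)` under the tract-length distribution (closed form for constant and
#' exponential tracts).
#'
#' @param layout a [genome_layout()] carrying the marker map.
#' @param tract_median median tract length in bp.
#' @param tract_dist "exponential" or "constant".
#' @return Detection probability in (0, 1]. An error is raised below 0.05
#'   (marker map too sparse for a meaningful correction).
#' @export
nco_detectability <- function(layout, tract_median = 1200,
                              tract_dist = c("exponential", "constant")) {
  tract_dist <- match.arg(tract_dist)
  stopifnot(inherits(layout, "genome_layout"))
  gaps <- unlist(lapply(seq_len(nrow(layout$chrom)), function(i) {
    pos <- layout$markers[[layout$chrom$chrom[i]]]
    L <- layout$chrom$length[i]
    diff(c(0, pos, L))  # terminal gaps included: tracts there miss markers
  }))
  total <- sum(gaps)
  miss <- if (tract_dist == "constant") {
    sum(pmax(gaps - tract_median, 0))
  } else {
    m <- tract_median / log(2)  # mean of the exponential
    # E[max(g - t, 0)] for t ~ Exp(mean m)
    sum(gaps - m * (1 - exp(-gaps / m)))
  }
  D <- 1 - miss / total
  if (D < 0.05) stop("detectability underflow (< 0.05): marker map too sparse")
  D
}

#' Detectability-corrected NCO counts
#'
#' @param nco_counts observed NCO counts (scalar or vector).
#' @param layout a [genome_layout()].
#' @param tract_median,tract_dist tract-length model passed to
#'   [nco_detectability()].
#' @return A list with `corrected` counts (observed / D) and `detectability`.
#' @export
corrected_nco <- function(nco_counts, layout, tract_median = 1200,
                          tract_dist = c("exponential", "constant")) {
  D <- nco_detectability(layout, tract_median, match.arg(tract_dist))
  list(corrected = nco_counts / D, detectability = D)
}

#' Index-of-dispersion test for per-chromosome CO counts
#'
#' Under a Poisson model (independent COs) the variance of per-meiosis CO
#' counts equals the mean; the index of dispersion `(n - 1) s^2 / xbar` is
#' referred to a chi-square with n - 1 degrees of freedom. The p-value is
#' two-sided; under-dispersion (s^2 < xbar) with p < 0.05 indicates
#' interference-like count regularization.
#'
#' @param counts per-meiosis CO counts for one chromosome (n >= 20
#'   recommended).
#' @return A list with `variance`, `mean`, `statistic`, `df`, `p`,
#'   `underdispersed` (logical).
#' @export
dispersion_test <- function(counts) {
  x <- as.numeric(counts)
  n <- length(x)
  m <- mean(x)
  if (m == 0) stop("mean count is zero")
  v <- stats::var(x)
  stat <- (n - 1) * v / m
  p_lo <- stats::pchisq(stat, df = n - 1)
  p <- min(1, 2 * min(p_lo, 1 - p_lo))
  list(variance = v, mean = m, statistic = stat, df = n - 1, p = p,
       underdispersed = (v < m) && p < 0.05)
}

#' Per-chromosome dispersion report
#'
#' Applies [dispersion_test()] to every chromosome and combines the
#' per-chromosome p-values by Fisher's method.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @param n_meioses number of meioses.
#' @return A list with `table` (per-chromosome variance, mean, p,
#'   underdispersed) and `fisher_p`.
#' @export
dispersion_report <- function(events, layout, n_meioses) {
  co <- events[events$kind == "CO", , drop = FALSE]
  tids <- unique(events$tetrad)
  if (length(tids) < n_meioses) {
    tids <- c(tids, paste0(".empty", seq_len(n_meioses - length(tids))))
  }
  rows <- lapply(layout$chrom$chrom, function(cn) {
    cnt <- as.numeric(table(factor(co$tetrad[co$chrom == cn], levels = tids)))
    dt <- dispersion_test(cnt)
    data.frame(chrom = cn, mean = dt$mean, variance = dt$variance,
               p = dt$p, underdispersed = dt$underdispersed)
  })
  tab <- do.call(rbind, rows)
  stat <- -2 * sum(log(pmax(tab$p, .Machine$double.xmin)))
  fisher_p <- stats::pchisq(stat, df = 2 * nrow(tab), lower.tail = FALSE)
  list(table = tab, fisher_p = fisher_p)
}

#' Non-exchange (E0) chromosome inventory
#'
#' A chromosome is E0 in a tetrad iff zero COs were called on it. Each E0 is
#' annotated with the presence of gene conversion (NCO) events, which tells
#' whether the homolog pair engaged in any detectable interhomolog
#' interaction.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @param n_meioses number of meioses.
#' @return A list with `inventory` (data.frame: tetrad, chrom, has_nco),
#'   `pct_ge1` (% of meioses with >= 1 E0 chromosome), `pct_gt1` (% with
#'   more than one) and `frac_e0_without_nco`.
#' @export
detect_E0 <- function(events, layout, n_meioses) {
  tids <- unique(events$tetrad)
  if (length(tids) < n_meioses) {
    tids <- c(tids, paste0(".empty", seq_len(n_meioses - length(tids))))
  }
  co <- events[events$kind == "CO", , drop = FALSE]
  nco <- events[events$kind == "NCO" & !events$loh_40, , drop = FALSE]
  chroms <- layout$chrom$chrom
  co_tab <- table(factor(co$tetrad, levels = tids),
                  factor(co$chrom, levels = chroms))
  nco_tab <- table(factor(nco$tetrad, levels = tids),
                   factor(nco$chrom, levels = chroms))
  e0 <- which(co_tab == 0L, arr.ind = TRUE)
  inventory <- data.frame(
    tetrad = tids[e0[, 1]], chrom = chroms[e0[, 2]],
    has_nco = nco_tab[e0] > 0L, stringsAsFactors = FALSE)
  per_tetrad <- rowSums(co_tab == 0L)
  list(inventory = inventory,
       pct_ge1 = 100 * mean(per_tetrad >= 1L),
       pct_gt1 = 100 * mean(per_tetrad > 1L),
       frac_e0_without_nco = if (nrow(inventory)) {
         mean(!inventory$has_nco)
       } else NA_real_)
}

#' Expected non-exchange frequency under a Poisson model
#'
#' If the CO count of chromosome c is Poisson with mean `lambda_c`, the
#' probability that a meiosis has at least one E0 chromosome is
#' `1 - prod_c (1 - exp(-lambda_c))`. The uniform curve variant distributes a
#' total of m COs evenly over k chromosomes (`lambda_c = m / k`).
#'
#' @param lambda per-chromosome mean CO counts (non-empty, >= 0).
#' @return Expected percentage of meioses with >= 1 E0 chromosome.
#' @examples
#' expected_E0_poisson(rep(23 / 6, 6))  # 12.3
#' @export
expected_E0_poisson <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (length(lambda) == 0L) stop("empty lambda vector")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  100 * (1 - prod(1 - exp(-lambda)))
}

#' @rdname expected_E0_poisson
#' @param m total mean CO count per meiosis.
#' @param k number of chromosomes.
#' @param m_grid grid of total CO counts for the curve.
#' @return `expected_E0_curve()` returns a data.frame with columns `m` and
#'   `p_no_e0` (probability of observing no E0 chromosome when m COs are
#'   distributed uniformly over k chromosomes).
#' @export
expected_E0_curve <- function(k, m_grid = seq(1, 60, by = 0.5)) {
  data.frame(m = m_grid,
             p_no_e0 = (1 - exp(-m_grid / k))^k)
}

#' Full crossover-control report
#'
#' Bundles the homeostasis, dispersion and E0 statistics of a dataset.
#'
#' @param events a `recomb_events` data.frame.
#' @param layout a [genome_layout()].
#' @param n_meioses number of meioses.
#' @param nco_tract_median tract median (bp) for the detectability correction.
#' @return An object of class `control_report`.
#' @export
control_report <- function(events, layout, n_meioses,
                           nco_tract_median = 1200) {
  counts <- tetrad_counts(events, n_meioses)
  D <- tryCatch(nco_detectability(layout, nco_tract_median), error = function(e) NA)
  hom <- tryCatch(suppressWarnings(homeostasis(counts)),
                  error = function(e) list(r = NA, p = NA, n = NA,
                                           corrected = FALSE))
  hom_c <- if (!is.na(D)) {
    tryCatch(suppressWarnings(homeostasis(counts, corrected = TRUE,
                                          detectability = D)),
             error = function(e) list(r = NA, p = NA))
  } else list(r = NA, p = NA)
  disp <- dispersion_report(events, layout, n_meioses)
  e0 <- detect_E0(events, layout, n_meioses)
  co <- events[events$kind == "CO", , drop = FALSE]
  lambda_c <- as.numeric(table(factor(co$chrom,
                                      levels = layout$chrom$chrom))) /
    n_meioses
  structure(list(
    counts = counts,
    homeostasis = hom, homeostasis_corrected = hom_c,
    nco_detectability = D,
    dispersion = disp,
    e0 = e0,
    lambda_c = stats::setNames(lambda_c, layout$chrom$chrom),
    expected_e0_pct = expected_E0_poisson(lambda_c),
    expected_e0_pct_uniform = expected_E0_poisson(
      rep(sum(lambda_c) / length(lambda_c), length(lambda_c)))
  ), class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat("<control_report>\n")
  cat(sprintf("  homeostasis: r = %.3f (p = %.3g); corrected r = %.3f\n",
              x$homeostasis$r, x$homeostasis$p, x$homeostasis_corrected$r))
  cat(sprintf("  dispersion (Fisher combined p) = %.3g; %d/%d chromosomes underdispersed\n",
              x$dispersion$fisher_p, sum(x$dispersion$table$underdispersed),
              nrow(x$dispersion$table)))
  cat(sprintf("  E0: observed %.1f%% of meioses (>1: %.1f%%); expected %.1f%% (per-chromosome) / %.1f%% (uniform)\n",
              x$e0$pct_ge1, x$e0$pct_gt1, x$expected_e0_pct,
              x$expected_e0_pct_uniform))
  invisible(x)
}
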