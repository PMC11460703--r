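# Gamma-renewal meiosis simulator.
#
# Crossovers are placed by a stationary gamma renewal process in genetic
# distance (interference shape nu; nu = 1 is a Poisson process, i.e. no
# interference), mapped to bp through the genome layout. Each CO exchanges the
# distal segments of one uniformly chosen non-sister chromatid pair (so there
# is no chromatid interference by construction). NCOs are uniform 3:1
# conversion tracts. Ground truth is recorded for every event.

#' Simulation configuration
#'
#' Bundles the generative parameters of the tetrad simulator. Defaults are the
#' study conditions of a K. lactis-like cross: six chromosomes totalling
#' ~10.7 Mb, ~0.28% marker density with a median inter-marker gap of ~187 bp,
#' 23 expected COs and 21 expected NCOs per meiosis, interference shape 1.29,
#' 78% of COs carrying a conversion tract, exponential tract lengths with
#' underlying medians 1.3 kb (CO) and 0.78 kb (NCO), and an 8% chance that a
#' CO deposits an extra tract on a chromatid not involved in the exchange.
#' The NCO rate, CO-tract probability and tract medians are underlying (true)
#' values: marker-coverage and event-merging losses on the default map, and
#' the detection conditioning that favours long tracts, turn them into the
#' post-detection values such a cross exhibits — about 14 detected NCOs per
#' meiosis, ~65% of COs with a detectable tract, and measured median tract
#' lengths of ~1.8 kb (CO) and ~1.2 kb (NCO).
#'
#' @param layout a [genome_layout()]; default [kl_layout()].
#' @param nu interference shape of the inter-CO gamma renewal process
#'   (dimensionless, >= 0.01; 1 = no interference).
#' @param lambda_co expected CO count per meiosis (genome-wide).
#' @param lambda_nco expected NCO count per meiosis (genome-wide).
#' @param co_gc_frac probability that a CO carries a conversion tract on an
#'   involved chromatid (the "detectable fraction" of CO-associated GC).
#' @param co_tract_median,nco_tract_median median tract lengths in bp; tracts
#'   are drawn from the distribution named by `tract_dist`.
#' @param tract_dist "exponential" (default) or "constant".
#' @param epsilon probability that a CO acquires an additional conversion
#'   tract on a chromatid not involved in the exchange (complex events).
#' @param obligate_co if TRUE, chromosomes with zero COs are redrawn.
#' @param homeostasis "none" (CO and NCO numbers independent) or "quota"
#'   (per-meiosis precursor pool N ~ Poisson(lambda_co + lambda_nco); exactly
#'   min(Q, N) precursors become COs by count-matched systematic thinning,
#'   which preserves an interference-like spacing; the rest become NCOs).
#' @param quota CO quota Q used when `homeostasis = "quota"` (must be > 0).
#' @param missing_rate per-call probability of a missing genotype.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(layout = kl_layout(),
                       nu = 1.29,
                       lambda_co = 23,
                       lambda_nco = 21,
                       co_gc_frac = 0.78,
                       co_tract_median = 1300,
                       nco_tract_median = 780,
                       tract_dist = c("exponential", "constant"),
                       epsilon = 0.08,
                       obligate_co = FALSE,
                       homeostasis = c("none", "quota"),
                       quota = NULL,
                       missing_rate = 0) {
  tract_dist <- match.arg(tract_dist)
  homeostasis <- match.arg(homeostasis)
  stopifnot(inherits(layout, "genome_layout"))
  if (nu < 0.01) stop("nu must be >= 0.01")
  if (lambda_co < 0 || lambda_nco < 0) stop("rates must be >= 0")
  if (co_gc_frac < 0 || co_gc_frac > 1) {
    stop("co_gc_frac must be in [0, 1]")
  }
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]")
  }
  if (homeostasis == "quota") {
    if (is.null(quota) || quota <= 0) {
      stop("quota > 0 required in quota mode")
    }
  }
  structure(list(layout = layout, nu = nu, lambda_co = lambda_co,
                 lambda_nco = lambda_nco, co_gc_frac = co_gc_frac,
                 co_tract_median = co_tract_median,
                 nco_tract_median = nco_tract_median,
                 tract_dist = tract_dist, epsilon = epsilon,
                 obligate_co = obligate_co, homeostasis = homeostasis,
                 quota = quota, missing_rate = missing_rate),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$layout$chrom), " chromosomes / ",
      format(genome_size(x$layout), big.mark = ","), " bp\n",
      "  nu = ", x$nu, ", lambda_CO = ", x$lambda_co,
      ", lambda_NCO = ", x$lambda_nco,
      ", homeostasis = ", x$homeostasis,
      if (x$homeostasis == "quota") paste0(" (Q = ", x$quota, ")"),
      ", obligate CO = ", x$obligate_co, "\n", sep = "")
  invisible(x)
}

draw_tract <- function(n, median_bp, dist) {
  if (dist == "constant") rep(median_bp, n)
  else stats::rexp(n, rate = log(2) / median_bp)
}

#' Place crossovers on one chromosome by a gamma renewal process
#'
#' Inter-CO distances are gamma draws with shape `nu` and mean spacing
#' `L / lambda_c` (so the expected CO count on the chromosome is `lambda_c`).
#' Stationarity is reached by starting the renewal a burn-in of at least ten
#' mean spacings before the chromosome and clipping to `[1, L]`. Each CO is
#' independently assigned one of the four non-sister chromatid pairs, chosen
#' uniformly (no chromatid interference by construction).
#'
#' @param length_bp chromosome length in bp.
#' @param lambda_c expected number of COs on the chromosome.
#' @param nu gamma shape (>= 0.01).
#' @return A data.frame with columns `pos` (numeric bp, sorted) and
#'   `chromatid_a`, `chromatid_b` (the exchanged chromatids; 1,2 = parent A
#'   copies, 3,4 = parent B copies).
#' @export
place_crossovers <- function(length_bp, lambda_c, nu) {
  if (nu <= 0) stop("nu must be > 0")
  if (lambda_c < 0) stop("lambda_c must be >= 0")
  if (lambda_c == 0) {
    return(data.frame(pos = numeric(0), chromatid_a = integer(0),
                      chromatid_b = integer(0)))
  }
  mu <- length_bp / lambda_c              # mean inter-CO spacing, bp
  start <- -10 * mu                        # burn-in >= 10 mean spacings
  # draw in blocks until we pass the chromosome end
  pos <- numeric(0)
  cur <- start
  repeat {
    n_blk <- max(16L, ceiling((length_bp - cur) / mu * 1.5))
    gaps <- stats::rgamma(n_blk, shape = nu, scale = mu / nu)
    pts <- cur + cumsum(gaps)
    pos <- c(pos, pts)
    cur <- pts[length(pts)]
    if (cur > length_bp) break
  }
  pos <- pos[pos >= 1 & pos <= length_bp]
  n <- length(pos)
  pair <- sample.int(4L, n, replace = TRUE)  # four non-sister pairs, uniform
  pairs <- matrix(c(1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L), ncol = 2, byrow = TRUE)
  data.frame(pos = pos, chromatid_a = pairs[pair, 1],
             chromatid_b = pairs[pair, 2])
}

# Apply one meiosis' events to marker matrices and read off genotypes.
#
# Chromatid bookkeeping: `chromatid_a` in {1,2} and `chromatid_b` in {3,4}
# label the parental DNA molecules joined at each exchange point (every CO
# joins a parent-A segment to a parent-B segment at its locus, so it is
# always a visible reciprocal switch). Because earlier exchanges re-route
# molecules onto different output strands, COs are processed left to right
# while a carrier permutation tracks which spore (matrix row) carries each
# molecule's DNA at the current position. The spores actually exchanged at
# each CO (`row_a`, `row_b`) are recorded for the truth table.
render_meiosis <- function(config, id, cos, ncos) {
  layout <- config$layout
  chroms <- list()
  cos$row_a <- rep(NA_integer_, nrow(cos))
  cos$row_b <- rep(NA_integer_, nrow(cos))
  ord <- order(cos$chrom, cos$pos)
  cos <- cos[ord, , drop = FALSE]
  for (i in seq_len(nrow(layout$chrom))) {
    cn <- layout$chrom$chrom[i]
    pos <- layout$markers[[cn]]
    M <- length(pos)
    calls <- matrix(rep(c(1L, 1L, 2L, 2L), M), nrow = 4)
    jj <- which(cos$chrom == cn)
    carrier <- 1:4  # carrier[molecule] = spore row holding it at current pos
    for (j in jj) {
      x <- cos$pos[j]
      ra <- carrier[cos$chromatid_a[j]]
      rb <- carrier[cos$chromatid_b[j]]
      distal <- pos > x
      if (any(distal)) {
        tmp <- calls[ra, distal]
        calls[ra, distal] <- calls[rb, distal]
        calls[rb, distal] <- tmp
      }
      cos$row_a[j] <- ra; cos$row_b[j] <- rb
      # beyond x the two molecules flow into each other's former spores
      carrier[c(cos$chromatid_a[j], cos$chromatid_b[j])] <- c(rb, ra)
      # conversion tract on an involved spore, adjacent to the exchange
      if (!is.na(cos$tract_start[j])) {
        left_side <- cos$tract_end[j] <= x + 1e-9
        on_a <- cos$tract_chromatid[j] == cos$chromatid_a[j]
        # proximal side of x: molecule still on its pre-exchange row;
        # distal side: rerouted onto the partner's row
        trow <- if (left_side) (if (on_a) ra else rb) else
          (if (on_a) rb else ra)
        sel <- pos >= cos$tract_start[j] & pos <= cos$tract_end[j]
        if (any(sel)) calls[trow, sel] <- 3L - calls[trow, sel]
      }
      # extra tract on a non-involved molecule (complex events)
      if (!is.na(cos$extra_start[j])) {
        erow <- carrier[cos$extra_chromatid[j]]
        sel <- pos >= cos$extra_start[j] & pos <= cos$extra_end[j]
        if (any(sel)) calls[erow, sel] <- 3L - calls[erow, sel]
      }
    }
    nco_c <- ncos[ncos$chrom == cn, , drop = FALSE]
    if (nrow(nco_c)) {
      for (j in seq_len(nrow(nco_c))) {
        sel <- pos >= nco_c$tract_start[j] & pos <= nco_c$tract_end[j]
        if (any(sel)) {
          ch <- nco_c$chromatid[j]
          calls[ch, sel] <- 3L - calls[ch, sel]
        }
      }
    }
    if (config$missing_rate > 0 && M > 0) {
      drop <- stats::runif(4L * M) < config$missing_rate
      calls[drop] <- NA_integer_
    }
    chroms[[cn]] <- list(pos = pos, calls = calls)
  }
  list(seg = tetrad_seg(id, chroms), cos = cos)
}

other_chromatid <- function(a, b) {
  # a molecule not involved in the (a, b) exchange, uniformly
  sample(setdiff(1:4, c(a, b)), 1L)
}

overlaps_marker <- function(pos, s, e) {
  if (length(pos) == 0L) return(FALSE)
  i <- findInterval(e, pos)
  i >= 1 && pos[i] >= s
}

#' Simulate one meiosis
#'
#' Generates a four-spore tetrad under a [sim_config()]: COs placed by the
#' gamma renewal process per chromosome (expected counts proportional to
#' physical length), reciprocal exchange applied distal to each CO on its two
#' chromatids, CO-associated conversion tracts on an involved chromatid with
#' probability `co_gc_frac` and on a non-involved chromatid with probability
#' `epsilon`, NCO tracts placed uniformly, genotypes read off at the marker
#' positions, and missing calls injected at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param id tetrad identifier.
#' @return A list with elements `seg` (a [tetrad_seg()]) and `truth` (a
#'   data.frame of true events: tetrad, chrom, kind, pos, chromatids,
#'   tract_start/end, detectable).
#' @export
simulate_meiosis <- function(config, id = "t1") {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  G <- genome_size(layout)
  k <- nrow(layout$chrom)

  if (config$homeostasis == "quota") {
    ev <- draw_quota_events(config)
    cos <- ev$cos; ncos <- ev$ncos
  } else {
    cos_l <- list()
    for (i in seq_len(k)) {
      cn <- layout$chrom$chrom[i]
      L <- layout$chrom$length[i]
      lam_c <- config$lambda_co * L / G
      repeat {
        cc <- place_crossovers(L, lam_c, config$nu)
        if (!config$obligate_co || nrow(cc) > 0 || lam_c == 0) break
      }
      if (nrow(cc)) cc$chrom <- cn
      cos_l[[i]] <- cc
    }
    cos <- do.call(rbind, cos_l[vapply(cos_l, nrow, 1L) > 0])
    if (is.null(cos)) {
      cos <- data.frame(pos = numeric(0), chromatid_a = integer(0),
                        chromatid_b = integer(0), chrom = character(0))
    }
    n_nco <- stats::rpois(1, config$lambda_nco)
    ncos <- draw_uniform_ncos(config, n_nco)
  }

  cos <- decorate_cos(cos, config)
  rend <- render_meiosis(config, id, cos, ncos)
  out <- assemble_truth(config, id, rend$cos, ncos)
  list(seg = rend$seg, truth = out$truth)
}

# attach GC tracts to COs
decorate_cos <- function(cos, config) {
  n <- nrow(cos)
  cos$tract_start <- rep(NA_real_, n); cos$tract_end <- rep(NA_real_, n)
  cos$tract_chromatid <- rep(NA_integer_, n)
  cos$extra_start <- rep(NA_real_, n); cos$extra_end <- rep(NA_real_, n)
  cos$extra_chromatid <- rep(NA_integer_, n)
  if (n == 0L) return(cos)
  has_gc <- stats::runif(n) < config$co_gc_frac
  if (any(has_gc)) {
    t <- draw_tract(sum(has_gc), config$co_tract_median, config$tract_dist)
    # one-sided tract abutting the exchange point: in the final product the
    # involved chromatid's switch is offset from its partner's by the tract
    # length, with 3:1 columns in between (the classic CO-GC signature)
    left_side <- stats::runif(sum(has_gc)) < 0.5
    cos$tract_start[has_gc] <- ifelse(left_side, cos$pos[has_gc] - t,
                                      cos$pos[has_gc])
    cos$tract_end[has_gc] <- ifelse(left_side, cos$pos[has_gc],
                                    cos$pos[has_gc] + t)
    pick_a <- stats::runif(sum(has_gc)) < 0.5
    cos$tract_chromatid[has_gc] <-
      ifelse(pick_a, cos$chromatid_a[has_gc], cos$chromatid_b[has_gc])
  }
  has_extra <- stats::runif(n) < config$epsilon
  if (any(has_extra)) {
    t <- draw_tract(sum(has_extra), config$co_tract_median, config$tract_dist)
    off <- stats::runif(sum(has_extra))
    cos$extra_start[has_extra] <- cos$pos[has_extra] - off * t
    cos$extra_end[has_extra] <- cos$pos[has_extra] + (1 - off) * t
    idx <- which(has_extra)
    cos$extra_chromatid[idx] <- vapply(
      idx, function(j) other_chromatid(cos$chromatid_a[j], cos$chromatid_b[j]),
      integer(1))
  }
  cos
}

draw_uniform_ncos <- function(config, n_nco, positions = NULL) {
  layout <- config$layout
  G <- genome_size(layout)
  if (n_nco == 0L) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      chromatid = integer(0), tract_start = numeric(0),
                      tract_end = numeric(0)))
  }
  if (is.null(positions)) positions <- stats::runif(n_nco, 0, G)
  cum <- cumsum(layout$chrom$length)
  idx <- findInterval(positions, c(0, cum), rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(layout$chrom))
  offset <- positions - c(0, cum)[idx]
  t <- draw_tract(n_nco, config$nco_tract_median, config$tract_dist)
  off <- stats::runif(n_nco)
  data.frame(chrom = layout$chrom$chrom[idx],
             pos = offset,
             chromatid = sample.int(4L, n_nco, replace = TRUE),
             tract_start = offset - off * t,
             tract_end = offset + (1 - off) * t,
             stringsAsFactors = FALSE)
}

# quota homeostasis: N ~ Poisson(lambda_co + lambda_nco) precursors placed by
# a genome-wide gamma renewal; min(Q, N) become COs via systematic
# (count-matched) thinning, preserving interference; the rest become NCOs.
draw_quota_events <- function(config) {
  layout <- config$layout
  G <- genome_size(layout)
  n_prec <- stats::rpois(1, config$lambda_co + config$lambda_nco)
  n_co <- min(config$quota, n_prec)
  # precursor positions: gamma renewal over the concatenated genome
  if (n_prec > 0) {
    prec <- sort(stats::runif(n_prec, 0, G))
  } else prec <- numeric(0)
  co_sel <- rep(FALSE, n_prec)
  if (n_co > 0) {
    # systematic thinning: evenly spaced ranks with a random phase
    step <- n_prec / n_co
    ranks <- unique(pmin(n_prec, ceiling(stats::runif(1, 0, step) +
                                           step * (seq_len(n_co) - 1))))
    co_sel[ranks] <- TRUE
    # top up in case of collisions after rounding
    while (sum(co_sel) < n_co) {
      co_sel[sample(which(!co_sel), 1L)] <- TRUE
    }
  }
  cum <- cumsum(layout$chrom$length)
  to_chrom <- function(gpos) {
    idx <- findInterval(gpos, c(0, cum), rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), nrow(layout$chrom))
    list(chrom = layout$chrom$chrom[idx], pos = gpos - c(0, cum)[idx])
  }
  co_pos <- prec[co_sel]
  mapped <- to_chrom(co_pos)
  pairs <- matrix(c(1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, length(co_pos), replace = TRUE)
  cos <- data.frame(pos = mapped$pos, chromatid_a = pairs[pick, 1],
                    chromatid_b = pairs[pick, 2], chrom = mapped$chrom,
                    stringsAsFactors = FALSE)
  ncos <- draw_uniform_ncos(config, sum(!co_sel), positions = prec[!co_sel])
  list(cos = cos, ncos = ncos)
}

assemble_truth <- function(config, id, cos, ncos) {
  layout <- config$layout
  rows <- list()
  if (nrow(cos)) {
    det <- vapply(seq_len(nrow(cos)), function(j) {
      pos <- layout$markers[[cos$chrom[j]]]
      # a CO is detectable iff markers flank it on both sides, outside its
      # own conversion tract (the tract erases the flanking phase there)
      lo <- min(cos$pos[j], cos$tract_start[j], na.rm = TRUE)
      hi <- max(cos$pos[j], cos$tract_end[j], na.rm = TRUE)
      any(pos < lo) && any(pos > hi)
    }, logical(1))
    ra <- if (!is.null(cos$row_a) && !anyNA(cos$row_a)) cos$row_a else
      cos$chromatid_a
    rb <- if (!is.null(cos$row_b) && !anyNA(cos$row_b)) cos$row_b else
      cos$chromatid_b
    rows$co <- data.frame(
      tetrad = id, chrom = cos$chrom, kind = "CO", pos = cos$pos,
      chromatids = paste(pmin(ra, rb), pmax(ra, rb), sep = ","),
      tract_start = cos$tract_start, tract_end = cos$tract_end,
      detectable = det, stringsAsFactors = FALSE)
  }
  if (nrow(ncos)) {
    det <- vapply(seq_len(nrow(ncos)), function(j) {
      pos <- layout$markers[[ncos$chrom[j]]]
      overlaps_marker(pos, ncos$tract_start[j], ncos$tract_end[j])
    }, logical(1))
    rows$nco <- data.frame(
      tetrad = id, chrom = ncos$chrom, kind = "NCO", pos = ncos$pos,
      chromatids = as.character(ncos$chromatid),
      tract_start = ncos$tract_start, tract_end = ncos$tract_end,
      detectable = det, stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else data.frame(
    tetrad = character(0), chrom = character(0), kind = character(0),
    pos = numeric(0), chromatids = character(0), tract_start = numeric(0),
    tract_end = numeric(0), detectable = logical(0))
  rownames(truth) <- NULL
  list(cos = cos, ncos = ncos, truth = truth)
}

#' Simulate a population of meioses
#'
#' @param config a [sim_config()].
#' @param n number of meioses.
#' @param seed optional integer seed; when given, results are reproducible
#'   (the RNG state is restored on exit).
#' @return A list with `tetrads` (named list of [tetrad_seg()]) and `truth`
#'   (row-bound truth table with per-meiosis entries; tetrad ids `t1..tn`).
#' @export
simulate_population <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  tetrads <- list(); truths <- vector("list", n)
  for (i in seq_len(n)) {
    id <- paste0("t", i)
    m <- simulate_meiosis(config, id)
    tetrads[[id]] <- m$seg
    truths[[i]] <- m$truth
  }
  truth <- if (n > 0) do.call(rbind, truths) else
    assemble_truth(config, "t0",
                   data.frame(pos = numeric(0), chromatid_a = integer(0),
                              chromatid_b = integer(0), chrom = character(0)),
                   draw_uniform_ncos(config, 0L))$truth
  rownames(truth) <- NULL
  list(tetrads = tetrads, truth = truth)
}

#' Convert a truth table to a recomb_events data.frame
#'
#' Useful for feeding simulator ground truth directly into the statistics
#' modules (interference, CO control, hotspots) without marker rendering.
#'
#' @param truth the `truth` element of [simulate_population()].
#' @param detectable_only drop events whose tract covers no marker.
#' @return A `recomb_events` data.frame.
#' @export
truth_as_events <- function(truth, detectable_only = FALSE) {
  t <- truth
  if (detectable_only) t <- t[t$detectable, , drop = FALSE]
  if (nrow(t) == 0L) return(empty_events())
  ev <- data.frame(
    tetrad = t$tetrad, chrom = t$chrom, kind = t$kind,
    class = ifelse(t$kind == "CO", 0L, NA_integer_),
    chromatids = t$chromatids, midpoint = t$pos,
    min_start = ifelse(is.na(t$tract_start), t$pos, t$tract_start),
    min_end = ifelse(is.na(t$tract_end), t$pos, t$tract_end),
    max_start = ifelse(is.na(t$tract_start), t$pos, t$tract_start),
    max_end = ifelse(is.na(t$tract_end), t$pos, t$tract_end),
    discontinuous = FALSE, loh_40 = FALSE,
    tract_lengths = ifelse(is.na(t$tract_start), "",
                           as.character(round(t$tract_end - t$tract_start, 1))),
    stringsAsFactors = FALSE)
  class(ev) <- c("recomb_events", "data.frame")
  ev
}
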