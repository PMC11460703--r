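# Event calling: breakpoints, grouping, classification, summaries.

test_that("find_breakpoints localizes switches and skips missing calls", {
  r <- find_breakpoints(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2))
  expect_equal(nrow(r$switches), 1L)
  expect_equal(r$switches$left, 5L)
  expect_equal(r$switches$right, 6L)

  expect_equal(nrow(find_breakpoints(rep(1, 10))$switches), 0L)

  # switch spanning a missing marker: interval widens to flanking calls
  r2 <- find_breakpoints(c("A", "A", "N", "B", "B", "B"))
  expect_equal(r2$switches$left, 2L)
  expect_equal(r2$switches$right, 4L)

  expect_warning(r3 <- find_breakpoints(rep(NA, 5)), "missing")
  expect_equal(nrow(r3$switches), 0L)
})

test_that("simple CO and simple NCO are called with correct spans", {
  # reciprocal switch on spores 2,3 between markers 5 and 6
  tt <- toy_tetrad("AAAAAAAAAA", "AAAAABBBBB", "BBBBBAAAAA", "BBBBBBBBBB")
  ev <- call_events(tt, layout = toy_layout())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "CO")
  expect_equal(ev$class, 0L)
  expect_equal(ev$chromatids, "2,3")
  expect_equal(ev$max_start, 5000)
  expect_equal(ev$max_end, 6000)
  expect_equal(ev$midpoint, 5500)

  # 2-marker 3:1 tract on spore 1, no switch
  tt2 <- toy_tetrad("AAABBAAAAA", "AAAAAAAAAA", "BBBBBBBBBB", "BBBBBBBBBB")
  ev2 <- call_events(tt2, layout = toy_layout())
  expect_equal(ev2$kind, "NCO")
  expect_equal(ev2$chromatids, "1")
  expect_equal(ev2$min_start, 4000)
  expect_equal(ev2$min_end, 5000)
  expect_equal(ev2$max_start, 3000)
  expect_equal(ev2$max_end, 6000)
  expect_false(ev2$discontinuous)
})

test_that("CO classes follow the Anderson scheme definitions", {
  lay <- toy_layout()
  # class 1: CO (2,3) with adjacent 3:1 tract on involved spore 2
  ev <- call_events(
    toy_tetrad("AAAAAAAAAA", "AAABBBBBBB", "BBBBBAAAAA", "BBBBBBBBBB"),
    layout = lay)
  expect_equal(ev$kind, "CO")
  expect_equal(ev$class, 1L)
  expect_equal(ev$chromatids, "2,3")

  # class 2: CO (2,3) + tract on non-involved spore 4
  ev2 <- call_events(
    toy_tetrad("AAAAAAAAAA", "AAAAABBBBB", "BBBBBAAAAA", "BBBAABBBBB"),
    layout = lay)
  expect_equal(ev2$class, 2L)

  # class 3: tracts on involved spore 2 (markers 4-5) and on non-involved
  # spore 4 (markers 7-8, distal of the exchange)
  ev3 <- call_events(
    toy_tetrad("AAAAAAAAAA", "AAABBBBBBB", "BBBBBAAAAA", "BBBBBBAABB"),
    layout = lay)
  expect_equal(ev3$class, 3L)

  # class 4: conversion tract interrupted by one unconverted marker
  ev4 <- call_events(
    toy_tetrad("AAAAAAAAAA", "AAABABBBBB", "BBBBBBAAAA", "BBBBBBBBBB"),
    layout = lay)
  expect_equal(ev4$kind, "CO")
  expect_equal(ev4$class, 4L)
  expect_true(ev4$discontinuous)

  # class 8: four spores exchanged within one group
  ev8 <- call_events(
    toy_tetrad("AAABBBBBBB", "AAAAAAABBB", "BBBAAAAAAA", "BBBBBBBAAA"),
    layout = lay)
  expect_equal(ev8$kind, "CO")
  expect_equal(ev8$class, 8L)
  expect_equal(ev8$chromatids, "1,2,3,4")

  # classify_event unit rules
  expect_equal(classify_event(2, FALSE, FALSE, FALSE), 0L)
  expect_equal(classify_event(2, TRUE, FALSE, FALSE), 1L)
  expect_equal(classify_event(2, FALSE, TRUE, FALSE), 2L)
  expect_equal(classify_event(2, TRUE, TRUE, FALSE), 3L)
  expect_equal(classify_event(2, TRUE, FALSE, TRUE), 4L)
  expect_equal(classify_event(4, TRUE, TRUE, FALSE), 8L)
})

test_that("NCO variants: discontinuous flag, end tract, standalone 4:0", {
  lay <- toy_layout()
  # discontinuous NCO on spore 1
  evd <- call_events(
    toy_tetrad("AABABAAAAA", "AAAAAAAAAA", "BBBBBBBBBB", "BBBBBBBBBB"),
    layout = lay)
  expect_equal(evd$kind, "NCO")
  expect_true(evd$discontinuous)

  # tract running to the chromosome end: still an NCO (single spore changed)
  eve <- call_events(
    toy_tetrad("AAAAAAABBB", "AAAAAAAAAA", "BBBBBBBBBB", "BBBBBBBBBB"),
    layout = lay)
  expect_equal(eve$kind, "NCO")
  expect_equal(eve$chromatids, "1")

  # standalone 4:0 run flagged as candidate LOH and excluded from counts
  ev40 <- call_events(
    toy_tetrad("AAAAAAAAAA", "AAAAAAAAAA", "BBAABBBBBB", "BBAABBBBBB"),
    layout = lay)
  expect_equal(ev40$kind, "NCO")
  expect_true(ev40$loh_40)
  s <- summarize_events(ev40, lay, 1)
  expect_equal(s$total_nco, 0L)
})

test_that("calling is invariant under parent relabeling and spore order", {
  gl <- dense_layout(2, 1e5, 1000)
  cfg <- sim_config(layout = gl, lambda_co = 5, lambda_nco = 3,
                    co_gc_frac = 0.7, epsilon = 0.1)
  pop <- simulate_population(cfg, 12, seed = 301)
  ev <- call_events(pop$tetrads, layout = gl)
  key <- function(e) {
    e <- e[order(e$tetrad, e$chrom, e$midpoint), ]
    e[, c("tetrad", "chrom", "kind", "class", "midpoint", "discontinuous")]
  }
  # swap parent labels 1 <-> 2 everywhere
  flipped <- lapply(pop$tetrads, function(tt) {
    tt$chroms <- lapply(tt$chroms, function(el) {
      el$calls <- 3L - el$calls
      el
    })
    tetrad_seg(tt$id, tt$chroms)
  })
  expect_equal(key(call_events(flipped, layout = gl)), key(ev),
               ignore_attr = TRUE)
  # permute spore order
  perm <- c(3L, 1L, 4L, 2L)
  shuffled <- lapply(pop$tetrads, function(tt) {
    tt$chroms <- lapply(tt$chroms, function(el) {
      el$calls <- el$calls[perm, , drop = FALSE]
      el
    })
    tetrad_seg(tt$id, tt$chroms)
  })
  expect_equal(key(call_events(shuffled, layout = gl)), key(ev),
               ignore_attr = TRUE)
})

test_that("every called CO shows an odd number of switches on >= 2 spores", {
  gl <- dense_layout(2, 2e5, 500)
  cfg <- sim_config(layout = gl, lambda_co = 6, lambda_nco = 2)
  pop <- simulate_population(cfg, 10, seed = 302)
  ev <- call_events(pop$tetrads, layout = gl)
  co <- ev[ev$kind == "CO" & ev$class != 8L, ]
  ok_n <- 0L
  for (i in seq_len(nrow(co))) {
    el <- pop$tetrads[[co$tetrad[i]]]$chroms[[co$chrom[i]]]
    ch <- as.integer(strsplit(co$chromatids[i], ",")[[1]])
    expect_gte(length(ch), 2L)
    for (r in ch) {
      sw <- find_breakpoints(el$calls[r, ])$switches
      inside <- sum(el$pos[sw$left] >= co$max_start[i] &
                      el$pos[sw$right] <= co$max_end[i])
      ok_n <- ok_n + (inside %% 2L == 1L)
    }
  }
  expect_equal(ok_n, sum(nchar(co$chromatids) - nchar(gsub(",", "",
                                                           co$chromatids))) +
                 nrow(co))
})

test_that("summaries and positional statistics are computed correctly", {
  lay <- genome_layout("c1", 1e6, 5e5,
                       list(c1 = as.integer(seq(1000, 999000, 1000))))
  set.seed(303)
  ev <- make_events("t1", "c1", runif(4000, 1, 1e6))
  ps <- positional_stats(ev, lay)
  # uniform events on a 1 Mb chromosome: median distance to nearer end ~ 250 kb
  expect_lt(abs(stats::median(ps$dist_end) - 250000), 15000)
  # exact cases
  ps2 <- positional_stats(make_events("t1", "c1", c(5e5, 1)), lay)
  expect_equal(ps2$dist_centromere[1], 0)
  expect_equal(ps2$dist_end[2], 0)

  expect_error(summarize_events(ev, lay, 0), "n_meioses")
})
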