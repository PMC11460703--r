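# Hotspot/coldspot permutation calling, conservation, gene-set association.

test_that("window counts partition chromosomes and conserve totals", {
  lay <- genome_layout(c("c1", "c2"), c(23000, 12000), c(10000, 6000),
                       list(c1 = integer(0), c2 = integer(0)))
  ev <- make_events("t1", c("c1", "c1", "c1", "c2"),
                    c(1200, 1700, 4900, 11900))
  wc <- window_counts(ev, lay, 5000)
  expect_equal(nrow(wc), ceiling(23000 / 5000) + ceiling(12000 / 5000))
  expect_equal(sum(wc$count), 4)
  expect_equal(wc$count[wc$chrom == "c1" & wc$start == 1], 3)
  # final partial window kept and flagged
  expect_true(wc$partial[wc$chrom == "c1" & wc$start == 20001])
  expect_equal(wc$end[wc$chrom == "c2" & wc$start == 10001], 12000)
})

test_that("permutation threshold matches a brute-force re-simulation", {
  thr <- permutation_threshold(100, 10, n_perm = 4000, rank = 80,
                               mode = "max", seed = 601)
  # independent oracle: re-simulate the max of a multinomial(100, uniform-10)
  set.seed(9001)
  maxes <- replicate(4000, max(tabulate(sample.int(10, 100, replace = TRUE),
                                        nbins = 10)))
  oracle <- sort(maxes, decreasing = TRUE)[80]
  expect_lte(abs(thr - oracle), 1)

  expect_equal(permutation_threshold(0, 10, 100, 10, mode = "min"), 0L)
  expect_error(permutation_threshold(0, 10, 100, 10, mode = "max"),
               "n_events")
  expect_error(permutation_threshold(10, 10, n_perm = 5, rank = 10), "rank")
  # determinism given seed
  expect_identical(
    permutation_threshold(500, 50, 2000, 40, seed = 11),
    permutation_threshold(500, 50, 2000, 40, seed = 11))
})

test_that("threshold is monotone in events and windows", {
  t_base <- permutation_threshold(2000, 400, 3000, 60, seed = 602)
  t_more_events <- permutation_threshold(4000, 400, 3000, 60, seed = 602)
  t_more_windows <- permutation_threshold(2000, 800, 3000, 60, seed = 602)
  expect_gte(t_more_events, t_base)
  expect_lte(t_more_windows, t_base)
})

test_that("hotspot calling is calibrated and catches spiked windows", {
  lay <- kl_layout(lengths = rep(250000, 4), marker_density = 1e-4)
  set.seed(603)
  # spike-in: 20x local excess in one 5 kb window over a uniform background
  # (chr4 left empty to probe coldspot behaviour)
  bg <- make_events("t1", sample(lay$chrom$chrom[1:3], 400, TRUE),
                    runif(400, 1, 250000))
  spike <- make_events("t1", "chr2", runif(40, 100001, 105000))
  hs <- call_hotspots(rbind(bg, spike), lay, window = 5000,
                      n_perm = 5000, rank = 100, seed = 604)
  expect_true(any(hs$windows$chrom == "chr2" &
                    hs$windows$start == 100001))

  # family-wise calibration: ~2% of uniform datasets contain >= 1 hotspot
  n_win <- sum(ceiling(lay$chrom$length / 5000))
  thr <- permutation_threshold(440, n_win, n_perm = 10000, rank = 200,
                               seed = 605)
  set.seed(606)
  hits <- replicate(800, {
    mx <- max(tabulate(sample.int(n_win, 440, replace = TRUE),
                       nbins = n_win))
    mx > thr
  })
  expect_lt(abs(mean(hits) - 0.02), 0.015)

  # chromosome devoid of events: all its 20 kb windows qualify as coldspots
  colds <- call_coldspots(rbind(bg, spike), lay, window = 20000,
                          n_perm = 2000, rank = 40, seed = 607)
  expect_true(all(colds$windows$count <= colds$threshold))
  chr4_called <- colds$windows[colds$windows$chrom == "chr4", ]
  expect_equal(nrow(chr4_called), ceiling(250000 / 20000))
  # adjacent qualifying windows merge into one interval
  expect_lte(nrow(colds$merged), nrow(colds$windows))
  expect_true(any(colds$merged$chrom == "chr4" &
                    colds$merged$n_windows == ceiling(250000 / 20000)))
})

test_that("conservation: self-comparison conserves all testable hotspots", {
  set.seed(608)
  genes <- data.frame(gene = paste0("g", 1:60), chrom = "c1",
                      start = seq(1000, by = 5000, length.out = 60),
                      end = seq(3000, by = 5000, length.out = 60))
  hots <- data.frame(chrom = "c1", start = c(50001, 150001),
                     end = c(55000, 155000))
  orth <- data.frame(gene_a = genes$gene, gene_b = genes$gene)
  res <- conservation(hots, hots, genes, genes, orth)
  expect_true(all(res$status == "conserved"))

  # hotspot with < 2 mappable orthologs is untestable, not non-conserved
  orth2 <- orth[1, , drop = FALSE]
  res2 <- conservation(hots, hots, genes, genes, orth2)
  expect_true(all(res2$status == "untestable"))

  # orthologs scattered far apart in B: syntenic block never forms
  genesB <- genes
  genesB$chrom <- "cB"
  genesB$start <- seq(1000, by = 50000, length.out = 60)
  genesB$end <- genesB$start + 2000
  res3 <- conservation(hots, hots, genes, genesB, orth)
  expect_true(all(res3$status == "untestable"))

  # syntenic block present but no nearby B hotspot -> not conserved
  hotsB_far <- data.frame(chrom = "c1", start = 250001, end = 255000)
  res4 <- conservation(hots[1, ], hotsB_far, genes, genes, orth)
  expect_equal(res4$status, "not_conserved")
})

test_that("gene-set association reproduces the exact hypergeometric tail", {
  genes <- data.frame(gene = paste0("g", 1:20), chrom = "c1",
                      start = seq(1, 19001, 1000),
                      end = seq(500, 19500, 1000))
  win <- data.frame(chrom = "c1", start = 1, end = 4600)
  r <- geneset_association(win, paste0("g", 1:5), genes)
  expect_equal(r$overlap, 5L)
  expect_equal(r$p, 1 / choose(20, 5))

  # overlap at expectation -> unremarkable p
  r2 <- geneset_association(win, paste0("g", c(1, 6, 11, 16)), genes)
  expect_gt(r2$p, 0.4)

  expect_error(geneset_association(win, character(0), genes), "empty")
})
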