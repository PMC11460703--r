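# Generative model: renewal placement, conservation invariants, determinism.

test_that("place_crossovers matches its target rate and interference shape", {
  set.seed(201)
  # law of large numbers on the expected count
  n <- replicate(10000, nrow(place_crossovers(1e6, 2, 1)))
  expect_lt(abs(mean(n) - 2) / 2, 0.02)

  # nu = 1.9: method-of-moments shape on pooled spacings
  sp <- diff(place_crossovers(5e6, 5000, 1.9)$pos)
  mom <- mean(sp)^2 / stats::var(sp)
  expect_gt(mom, 1.75)
  expect_lt(mom, 2.05)

  # nu = 1 gives exponential spacings (KS at alpha = 0.01)
  sp1 <- diff(place_crossovers(5e6, 5000, 1)$pos)
  ks <- stats::ks.test(sp1, "pexp", rate = 1 / mean(sp1))
  expect_gt(ks$p.value, 0.01)

  expect_error(place_crossovers(1e6, 2, 0), "nu")
  expect_equal(nrow(place_crossovers(1e6, 0, 1)), 0L)
})

test_that("chromatid pairs are non-sister and uniform", {
  set.seed(202)
  cc <- place_crossovers(1e7, 2000, 1)
  expect_true(all(cc$chromatid_a %in% 1:2))
  expect_true(all(cc$chromatid_b %in% 3:4))
  tab <- table(cc$chromatid_a, cc$chromatid_b)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("conservation: without conversion every marker column is 2:2", {
  gl <- dense_layout(3, 2e5, 1000)
  cfg <- sim_config(layout = gl, lambda_co = 6, lambda_nco = 0,
                    co_gc_frac = 0, epsilon = 0)
  pop <- simulate_population(cfg, 25, seed = 203)
  for (tt in pop$tetrads) {
    for (el in tt$chroms) {
      n1 <- colSums(el$calls == 1L)
      expect_true(all(n1 == 2L))
    }
  }
})

test_that("allele counts always sum to 4 and deviations are 3:1 or 4:0", {
  gl <- dense_layout(2, 2e5, 500)
  cfg <- sim_config(layout = gl, lambda_co = 5, lambda_nco = 6,
                    co_gc_frac = 0.8, epsilon = 0.2)
  pop <- simulate_population(cfg, 25, seed = 204)
  for (tt in pop$tetrads) {
    for (el in tt$chroms) {
      n1 <- colSums(el$calls == 1L)
      n2 <- colSums(el$calls == 2L)
      expect_true(all(n1 + n2 == 4L))
      expect_true(all(n1 %in% 0:4))
    }
  }
})

test_that("every truth CO is a reciprocal phase switch on two spores", {
  gl <- dense_layout(2, 3e5, 500)
  cfg <- sim_config(layout = gl, lambda_co = 6, lambda_nco = 0,
                    co_gc_frac = 0, epsilon = 0)
  pop <- simulate_population(cfg, 15, seed = 205)
  tr <- pop$truth[pop$truth$kind == "CO" & pop$truth$detectable, ]
  for (i in seq_len(nrow(tr))) {
    el <- pop$tetrads[[tr$tetrad[i]]]$chroms[[tr$chrom[i]]]
    before <- el$calls[, max(which(el$pos <= tr$pos[i]))]
    after <- el$calls[, min(which(el$pos > tr$pos[i]))]
    ch <- as.integer(strsplit(tr$chromatids[i], ",")[[1]])
    expect_setequal(which(before != after), ch)
    # reciprocal: one A->B, one B->A
    expect_setequal(before[ch], c(1L, 2L))
  }
})

test_that("simulate_population is reproducible and handles n = 0", {
  gl <- dense_layout(2, 1e5, 2000)
  cfg <- sim_config(layout = gl, lambda_co = 4, lambda_nco = 2,
                    missing_rate = 0.02)
  p1 <- simulate_population(cfg, 8, seed = 206)
  p2 <- simulate_population(cfg, 8, seed = 206)
  expect_identical(p1$truth, p2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_segregation(p1$tetrads, f1)
  write_segregation(p2$tetrads, f2)
  expect_identical(readLines(f1), readLines(f2))

  p0 <- simulate_population(cfg, 0, seed = 1)
  expect_length(p0$tetrads, 0L)
  expect_equal(nrow(p0$truth), 0L)
})

test_that("study-scale config yields the expected per-meiosis CO counts", {
  # K. lactis-like conditions; sparse markers speed up rendering without
  # affecting truth counts
  gl <- kl_layout(marker_density = 5e-5)
  cfg <- sim_config(layout = gl)
  pop <- simulate_population(cfg, 205, seed = 207)
  med <- stats::median(table(pop$truth$tetrad[pop$truth$kind == "CO"]))
  expect_gte(med, 21)
  expect_lte(med, 25)
})

test_that("obligate-CO mode leaves no chromosome without a crossover", {
  gl <- dense_layout(3, 2e5, 2000)
  cfg <- sim_config(layout = gl, lambda_co = 2, lambda_nco = 0,
                    obligate_co = TRUE, co_gc_frac = 0, epsilon = 0)
  pop <- simulate_population(cfg, 40, seed = 208)
  co <- pop$truth[pop$truth$kind == "CO", ]
  tab <- table(factor(co$tetrad, levels = unique(pop$truth$tetrad)),
               factor(co$chrom, levels = gl$chrom$chrom))
  expect_true(all(tab >= 1L))
})

test_that("NCO detectability flag matches marker coverage", {
  gl <- dense_layout(2, 2e5, 4000)
  cfg <- sim_config(layout = gl, lambda_co = 0, lambda_nco = 10,
                    tract_dist = "constant", nco_tract_median = 2000)
  pop <- simulate_population(cfg, 40, seed = 209)
  tr <- pop$truth
  for (i in seq_len(nrow(tr))) {
    pos <- gl$markers[[tr$chrom[i]]]
    covered <- any(pos >= tr$tract_start[i] & pos <= tr$tract_end[i])
    expect_equal(tr$detectable[i], covered)
  }
  # fraction detectable ~ closed form t/s for constant tract < spacing
  D_hat <- mean(tr$detectable)
  D <- nco_detectability(gl, 2000, "constant")
  expect_lt(abs(D_hat - D), 3 * sqrt(D * (1 - D) / nrow(tr)) + 0.02)
})

test_that("quota mode enforces the CO quota", {
  gl <- dense_layout(4, 2.5e5, 2000)
  cfg <- sim_config(layout = gl, lambda_co = 20, lambda_nco = 20,
                    homeostasis = "quota", quota = 15,
                    co_gc_frac = 0, epsilon = 0)
  pop <- simulate_population(cfg, 50, seed = 210)
  co_n <- table(factor(pop$truth$tetrad[pop$truth$kind == "CO"],
                       levels = unique(pop$truth$tetrad)))
  expect_true(all(co_n <= 15))
  expect_error(sim_config(layout = gl, homeostasis = "quota"), "quota")
})
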