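# Molecular evolution statistics: NG86 dN/dS, pi, Watterson's theta,
# enrichment.

test_that("pairwise dN/dS codon oracles", {
  # identical sequences
  r0 <- pairwise_dnds("AAATTT", "AAATTT")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))

  # GGG -> GGA: Gly -> Gly, one synonymous difference
  r1 <- pairwise_dnds("GGG", "GGA")
  expect_equal(r1$dN, 0)
  expect_equal(r1$S_diffs, 1)
  expect_equal(r1$N_diffs, 0)
  expect_equal(r1$ratio, 0)

  # AAA -> GAA: Lys -> Glu, one nonsynonymous difference, dS = 0
  r2 <- pairwise_dnds("AAA", "GAA")
  expect_equal(r2$dS, 0)
  expect_equal(r2$N_diffs, 1)
  expect_gt(r2$dN, 0)
  expect_true(is.na(r2$ratio))

  # codons with N or gaps are skipped
  r3 <- pairwise_dnds("AAANNNTTT", "GAANNNTTT")
  expect_equal(r3$n_codons, 2L)
  expect_error(pairwise_dnds("AAA", "AAATTT"), "mismatch")
  expect_error(pairwise_dnds("TAAAAA", "TAAAAA"), "internal stop")
})

test_that("NG86 site counts and JC correction behave correctly", {
  # TTT (Phe): only position 3 T->C is synonymous -> 1/3 syn site
  r <- pairwise_dnds("TTT", "TTT")
  expect_equal(r$S_sites, 1 / 3)
  expect_equal(r$N_sites, 3 - 1 / 3)
  # JC correction increases the distance: d >= p on a diverged pair
  set.seed(701)
  a <- paste(rep("GCT", 50), collapse = "")  # Ala codons
  bv <- strsplit(a, "")[[1]]
  idx <- seq(3, 150, by = 15)
  bv[idx] <- "C"  # synonymous third positions GCT -> GCC
  b <- paste(bv, collapse = "")
  rr <- pairwise_dnds(a, b)
  pS <- rr$S_diffs / rr$S_sites
  expect_gte(rr$dS, pS)
  expect_equal(rr$dN, 0)
  expect_equal(rr$ratio, 0)
})

test_that("pairwise dN/dS is symmetric", {
  set.seed(702)
  codons <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], NULL)
  for (i in 1:20) {
    s1 <- paste(sample(codons, 30, replace = TRUE), collapse = "")
    s2 <- paste(sample(codons, 30, replace = TRUE), collapse = "")
    a <- pairwise_dnds(s1, s2)
    b <- pairwise_dnds(s2, s1)
    expect_equal(a$dN, b$dN, tolerance = 1e-12)
    expect_equal(a$dS, b$dS, tolerance = 1e-12)
  }
})

test_that("mean pairwise dN/dS averages defined pairs only", {
  a <- "GGGAAAGAT"
  b <- "GGAAAAGAT"  # one synonymous diff vs a
  c <- "GGGGAAGAT"  # one nonsynonymous diff vs a
  aln <- codon_alignment(c(a, b, c), gene = "toy")
  m <- mean_pairwise_dnds(aln)
  p_ab <- pairwise_dnds(a, b)$ratio
  p_ac <- pairwise_dnds(a, c)$ratio
  p_bc <- pairwise_dnds(b, c)$ratio
  defined <- c(p_ab, p_ac, p_bc)
  expect_equal(m$n_pairs, 3L)
  expect_equal(m$n_undefined, sum(is.na(defined)))
  expect_equal(m$mean_ratio, mean(defined, na.rm = TRUE))

  # n = 2 equals the single pairwise value
  m2 <- mean_pairwise_dnds(codon_alignment(c(a, b)))
  expect_equal(m2$mean_ratio, p_ab)

  # all identical -> undefined with 3 undefined pairs
  m3 <- mean_pairwise_dnds(codon_alignment(c(a, a, a)))
  expect_true(is.na(m3$mean_ratio))
  expect_equal(m3$n_undefined, 3L)
})

test_that("pi and Watterson's theta match their closed forms", {
  # identical sequences
  aln0 <- codon_alignment(c("ACGACG", "ACGACG"))
  expect_equal(nucleotide_diversity(aln0), 0)
  expect_equal(watterson_theta(aln0), 0)

  # two sequences, 3 diffs over 99 sites: pi = theta_w = 3/99 (a_2 = 1)
  s1 <- paste(rep("ACA", 33), collapse = "")
  v <- strsplit(s1, "")[[1]]; v[c(4, 10, 16)] <- "G"
  aln2 <- codon_alignment(c(s1, paste(v, collapse = "")))
  expect_equal(nucleotide_diversity(aln2), 3 / 99)
  expect_equal(watterson_theta(aln2), 3 / 99)

  # n = 4, S = 11 over L = 100 full columns -> theta = 11/(1.8333*100) = 0.060
  base <- rep("ACC", 34)                      # 102 nt, no stops
  mk <- function(mut_at, to) {
    x <- strsplit(paste(base, collapse = ""), "")[[1]]
    x[mut_at] <- to
    paste(x, collapse = "")
  }
  s_a <- paste(base, collapse = "")
  s_b <- mk(c(2, 5, 8, 11), "T")              # ACC -> ATC etc., 4 sites
  s_c <- mk(c(14, 17, 20, 23), "T")           # 4 more sites
  s_d0 <- mk(c(26, 29, 32), "T")              # 3 more: S = 11 total
  # mask 2 of the untouched sites in one sequence -> L = 100
  x <- strsplit(s_d0, "")[[1]]; x[c(97, 100)] <- "N"
  s_d <- paste(x, collapse = "")
  aln4 <- codon_alignment(c(s_a, s_b, s_c, s_d))
  a_n <- 1 + 1 / 2 + 1 / 3
  expect_equal(watterson_theta(aln4), 11 / (a_n * 100))
  expect_equal(round(watterson_theta(aln4), 3), 0.060)
  expect_gte(nucleotide_diversity(aln4), 0)
})

test_that("theta_w ~ pi in expectation under the neutral frequency spectrum", {
  # under neutrality segregating sites carry i mutant copies with weight 1/i;
  # placing mutations that way makes E[pi] = E[theta_w]
  set.seed(703)
  n <- 6; L <- 300
  sfs_w <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  ratios <- replicate(60, {
    anc <- sample(c("A", "C", "G"), L, replace = TRUE)  # no T: no stop risk
    m <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
    sites <- sample.int(L, 12)
    for (s in sites) {
      i <- sample.int(n - 1, 1, prob = sfs_w)
      alt <- setdiff(c("A", "C", "G"), anc[s])[1]
      m[sample.int(n, i), s] <- alt
    }
    aln <- codon_alignment(apply(m, 1, paste, collapse = ""))
    c(watterson_theta(aln), nucleotide_diversity(aln))
  })
  expect_lt(abs(mean(ratios[1, ]) - mean(ratios[2, ])) / mean(ratios[2, ]),
            0.1)
})

test_that("median-rank enrichment excludes ties and matches phyper", {
  vals <- stats::setNames(c(1:10 / 10, rep(0.55, 0)), paste0("g", 1:10))
  # focal set entirely above the median
  r <- median_rank_enrichment(vals, paste0("g", 6:10))
  expect_equal(r$n_high, 5L)
  expect_equal(r$n_focal_high, 5L)
  expect_equal(r$p, 1 / choose(10, 5))

  # ties at the median are excluded from the universe
  vals2 <- stats::setNames(c(1, 2, 3, 3, 3, 4, 5), paste0("g", 1:7))
  r2 <- median_rank_enrichment(vals2, c("g6", "g7"))
  expect_equal(r2$universe, 4L)

  expect_error(median_rank_enrichment(vals, character(0)), "empty")

  # random focal sets give roughly uniform p-values
  set.seed(704)
  vals3 <- stats::setNames(runif(40), paste0("g", 1:40))
  ps <- replicate(300, median_rank_enrichment(
    vals3, sample(names(vals3), 8))$p)
  expect_gt(mean(ps > 0.5), 0.25)

  # rank-sum wrapper runs on the same values
  w <- group_rank_test(vals3, paste0("g", 1:8))
  expect_s3_class(w, "htest")
})

test_that("codon alignment IO validates and reads FASTA", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGGATCCA", ">s2", "ACGGATCCG"), f)
  aln <- read_codon_alignment(f)
  expect_equal(aln$n, 2L)
  expect_equal(aln$length, 9L)
  expect_error(codon_alignment(c("ACG", "ACGT")), "equal lengths")
  expect_error(codon_alignment(c("ACGT")), "divisible by 3")
  expect_error(codon_alignment("ACGTAAACG"), "stop")
  expect_error(codon_alignment("AXGTTT"), "alphabet")
})
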