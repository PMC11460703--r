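# Gene-level molecular evolution statistics: Nei-Gojobori (1986) pairwise
# dN/dS with Jukes-Cantor correction, nucleotide diversity (pi), Watterson's
# theta, and median-rank enrichment.

.me_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.me_cache$gc)) {
    g <- Biostrings::GENETIC_CODE
    .me_cache$gc <- stats::setNames(as.character(g), names(g))
  }
  .me_cache$gc
}

#' Codon alignment container
#'
#' @param seqs character vector of aligned coding sequences (upper-case,
#'   alphabet A/C/G/T/N/-), equal lengths divisible by 3. Sequences with
#'   internal stop codons are rejected.
#' @param gene optional gene identifier.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, gene = NA_character_) {
  seqs <- toupper(as.character(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal lengths")
  if (L %% 3 != 0) stop("alignment length must be divisible by 3")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("alphabet must be A/C/G/T/N/-")
  gc <- genetic_code()
  for (i in seq_along(seqs)) {
    cds <- substring(seqs[i], seq(1, L - 2, 3), seq(3, L, 3))
    internal <- cds[-length(cds)]
    known <- internal %in% names(gc)
    if (any(gc[internal[known]] == "*")) {
      stop("internal stop codon in sequence ", i)
    }
  }
  structure(list(seqs = seqs, gene = gene, n = length(seqs), length = L),
            class = "codon_alignment")
}

#' Read codon alignments from a FASTA file
#'
#' @param path FASTA file with equal-length, codon-aligned sequences.
#' @param gene gene id (defaults to the file name).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  codon_alignment(as.character(x),
                  gene = if (is.null(gene)) {
                    sub("\\.[^.]*$", "", basename(path))
                  } else gene)
}

# NG86 synonymous site count of one codon: at each position, the fraction of
# the three possible single-base changes that preserve the amino acid
# (changes to stop codons count as nonsynonymous).
syn_sites_codon <- function(codon) {
  gc <- genetic_code()
  aa <- gc[codon]
  if (is.na(aa) || aa == "*") return(NA_real_)
  bases <- c("A", "C", "G", "T")
  s <- 0
  cd <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    for (b in setdiff(bases, cd[p])) {
      alt <- cd; alt[p] <- b
      if (gc[paste(alt, collapse = "")] == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged synonymous / nonsynonymous difference counts between two
# codons (NG86): all orderings of the differing positions are averaged
# uniformly; pathways passing through stop codons are excluded (if every
# pathway is blocked, all are used).
codon_diffs <- function(c1, c2) {
  gc <- genetic_code()
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(d)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- switch(nd, list(1L), list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  paths <- list()
  for (pm in perms) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (step in pm) {
      p <- d[step]
      nxt <- cur; nxt[p] <- tgt[p]
      a1 <- gc[paste(cur, collapse = "")]
      a2 <- gc[paste(nxt, collapse = "")]
      # endpoints are never stops, so a stop here is a blocked intermediate
      if (a2 == "*" || a1 == "*") blocked <- TRUE
      if (a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(syn = syn, nonsyn = nonsyn,
                                     blocked = as.numeric(blocked))
  }
  pm <- do.call(rbind, paths)
  use <- pm[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(pm))
  c(syn = mean(pm[use, "syn"]), nonsyn = mean(pm[use, "nonsyn"]))
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("proportion of differences >= 0.75: Jukes-Cantor ",
                      "correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS (Nei-Gojobori 1986)
#'
#' Unweighted NG86 estimator: synonymous and nonsynonymous site counts are
#' averaged over the two sequences; multiple-substitution pathways between
#' differing codons are averaged uniformly (stop-containing pathways
#' excluded); proportions are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - (4/3) p)`. Codons containing N, gaps, or stops in
#' either sequence are skipped.
#'
#' @param seq1,seq2 codon-aligned sequences of equal length.
#' @return A list with `dN`, `dS`, `ratio` (NA when dS = 0), `n_codons`,
#'   and the underlying site/difference counts.
#' @examples
#' pairwise_dnds("GGG", "GGA")  # one synonymous difference: dN = 0
#' @export
pairwise_dnds <- function(seq1, seq2) {
  s1 <- toupper(seq1); s2 <- toupper(seq2)
  if (nchar(s1) != nchar(s2)) stop("length mismatch")
  L <- nchar(s1)
  if (L %% 3 != 0) stop("length must be divisible by 3")
  gc <- genetic_code()
  starts <- seq(1, L - 2, 3)
  c1 <- substring(s1, starts, starts + 2)
  c2 <- substring(s2, starts, starts + 2)
  clean <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  c1 <- c1[clean]; c2 <- c2[clean]
  stop1 <- gc[c1] == "*"; stop2 <- gc[c2] == "*"
  if (length(c1)) {
    internal <- seq_along(c1) < length(c1)
    if (any(stop1[internal]) || any(stop2[internal])) {
      stop("internal stop codon")
    }
    keep <- !stop1 & !stop2
    c1 <- c1[keep]; c2 <- c2[keep]
  }
  if (length(c1) == 0L) {
    return(list(dN = NA_real_, dS = NA_real_, ratio = NA_real_,
                n_codons = 0L, S_sites = 0, N_sites = 0,
                S_diffs = 0, N_diffs = 0))
  }
  S1 <- vapply(c1, syn_sites_codon, numeric(1))
  S2 <- vapply(c2, syn_sites_codon, numeric(1))
  S_sites <- sum((S1 + S2) / 2)
  N_sites <- 3 * length(c1) - S_sites
  diffs <- vapply(seq_along(c1),
                  function(i) codon_diffs(c1[i], c2[i]), numeric(2))
  S_d <- sum(diffs["syn", ])
  N_d <- sum(diffs["nonsyn", ])
  pS <- if (S_sites > 0) S_d / S_sites else 0
  pN <- if (N_sites > 0) N_d / N_sites else 0
  # saturated proportions (p >= 3/4) have no finite JC distance -> NA
  dS <- if (pS >= 0.75) NA_real_ else jc_correct(pS)
  dN <- if (pN >= 0.75) NA_real_ else jc_correct(pN)
  ratio <- if (!is.na(dN) && dN == 0 && S_d > 0) {
    0                              # no amino-acid divergence at all
  } else if (!is.na(dS) && dS > 0 && !is.na(dN)) {
    dN / dS
  } else {
    NA_real_                       # dS = 0 or saturated: undefined, not Inf
  }
  list(dN = dN, dS = dS, ratio = ratio,
       n_codons = length(c1), S_sites = S_sites, N_sites = N_sites,
       S_diffs = S_d, N_diffs = N_d)
}

#' Gene-level mean pairwise dN/dS
#'
#' Mean of [pairwise_dnds()] ratios over all unordered sequence pairs with a
#' defined ratio (dS > 0); the number of undefined pairs is reported.
#'
#' @param aln a [codon_alignment()].
#' @return A list with `mean_ratio` (NA if no pair is defined), `n_pairs`,
#'   `n_undefined`, `mean_dn`, `mean_ds`.
#' @export
mean_pairwise_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  n <- aln$n
  ratios <- c(); dns <- c(); dss <- c(); undef <- 0L; np <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- pairwise_dnds(aln$seqs[i], aln$seqs[j])
      np <- np + 1L
      dns <- c(dns, r$dN); dss <- c(dss, r$dS)
      if (is.na(r$ratio)) undef <- undef + 1L else ratios <- c(ratios, r$ratio)
    }
  }
  list(mean_ratio = if (length(ratios)) mean(ratios) else NA_real_,
       n_pairs = np, n_undefined = undef,
       mean_dn = mean(dns, na.rm = TRUE), mean_ds = mean(dss, na.rm = TRUE))
}

valid_site_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  list(m = m, ok = ok)
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites over all unordered sequence
#' pairs; for each pair, only sites where both sequences carry an unambiguous
#' base are compared.
#'
#' @param aln a [codon_alignment()] (any equal-length alignment works).
#' @return pi per site.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  v <- valid_site_matrix(aln)
  n <- aln$n
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- v$ok[i, ] & v$ok[j, ]
      if (!any(both)) next
      tot <- tot + mean(v$m[i, both] != v$m[j, both])
      np <- np + 1L
    }
  }
  if (np == 0L) return(NA_real_)
  tot / np
}

#' Watterson's theta
#'
#' `theta_w = S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`, S the number of
#' segregating sites and L the number of sites at which every sequence carries
#' an unambiguous base.
#'
#' @param aln a [codon_alignment()].
#' @return theta_w per site.
#' @examples
#' a <- codon_alignment(c("AAATTT", "AAATTA"))
#' watterson_theta(a)  # 1 segregating site / (1 * 6)
#' @export
watterson_theta <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  v <- valid_site_matrix(aln)
  full <- colSums(v$ok) == aln$n
  L <- sum(full)
  if (L == 0L) return(NA_real_)
  S <- sum(apply(v$m[, full, drop = FALSE], 2,
                 function(col) length(unique(col)) > 1L))
  a_n <- sum(1 / seq_len(aln$n - 1))
  S / (a_n * L)
}

#' Median-rank enrichment test
#'
#' Genes with values strictly above the genome-wide median form the "high"
#' class (genes exactly at the median are excluded); enrichment of a focal
#' gene set among high genes is tested by the hypergeometric upper tail.
#'
#' @param values named numeric vector of per-gene values (e.g. dN/dS).
#' @param focal_set character vector of focal gene names (non-empty).
#' @return A list with `p`, `n_high`, `n_focal_high`, `n_focal`, `universe`.
#' @export
median_rank_enrichment <- function(values, focal_set) {
  if (length(focal_set) == 0L) stop("empty focal set")
  values <- values[!is.na(values)]
  med <- stats::median(values)
  keep <- values != med        # ties at the median are excluded
  v <- values[keep]
  high <- names(v)[v > med]
  universe <- names(v)
  focal <- intersect(focal_set, universe)
  q <- length(intersect(focal, high))
  p <- stats::phyper(q - 1, length(focal),
                     length(universe) - length(focal), length(high),
                     lower.tail = FALSE)
  list(p = p, n_high = length(high), n_focal_high = q,
       n_focal = length(focal), universe = length(universe))
}

#' Rank-sum comparison of two gene groups
#'
#' Convenience wrapper over the Wilcoxon rank-sum test for comparing, e.g.,
#' meiosis genes against the remaining genes on a per-gene statistic.
#'
#' @param values named numeric vector.
#' @param group_set names belonging to the focal group.
#' @param alternative passed to [stats::wilcox.test()] (default "greater":
#'   focal group tends to larger values).
#' @return The `htest` object.
#' @export
group_rank_test <- function(values, group_set, alternative = "greater") {
  ing <- names(values) %in% group_set
  stats::wilcox.test(values[ing], values[!ing], alternative = alternative)
}
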