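---
title: "Models and methods behind meiorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiorec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiorec)
```

`meiorec` analyses meiotic recombination from four-spore tetrads: it calls
crossover (CO) and noncrossover (NCO) events from marker-level segregation
matrices and computes the statistics used to characterise crossover control —
interference, homeostasis, assurance — together with permutation-based
hotspot/coldspot detection and gene-level molecular-evolution summaries. A
generative tetrad simulator with full ground truth makes every stage testable
without sequencing data. This vignette explains the models, the defaults, and
the numerical choices.

## The data model

A tetrad is the set of four haploid spores from one meiosis. After genotyping
at a panel of SNP markers between two parental backgrounds, each spore carries
a parental-origin call (A, B, or missing) at every marker. Mendelian
segregation gives 2:2 allele balance at each marker column; gene conversion
produces local 3:1 (one chromatid converted) or 4:0 (two chromatids) columns.
Internally calls are coded 1/2/NA; positions are 1-based inclusive; all BED
exports are 0-based half-open. Missing calls are tolerated and skipped during
event calling, never imputed — the upstream marker filters are assumed to have
removed unreliable positions, and imputation would manufacture evidence.

## Event calling and classification

The caller detects two feature types per chromosome of a tetrad:

* **phase switches** on individual chromatids — boundaries between maximal
  runs of constant parental origin (missing calls skipped, so a switch next
  to missing markers is localised to the widened flanking interval);
* **conversion tracts** — maximal runs of complete marker columns deviating
  from 2:2.

Features are grouped into events by single linkage on their *extents*: a
feature joins a group when its interval starts within `merge_dist` (default
5 kb, the conventional midpoint-separation criterion for "simple" events) of
the group's running end. Linking on extents rather than midpoints matters for
crossovers with long conversion tracts: the tract physically touches both the
exchange point and the offset switch it produces on the involved chromatid,
so the whole signature stays one event no matter how long the tract is,
whereas midpoint linkage would split it into a spurious CO/NCO pair and
contaminate the inter-CO distance distribution with short artefacts. For
clean events separated by more than 5 kb of 2:2 markers the two rules
coincide.

A group is typed by the flanking phase of each chromatid on either side of
the group: chromatids whose phase changed are *involved*; a group with at
least two involved chromatids and balanced exchange (equal numbers of A→B and
B→A) is a **CO**, otherwise a group with converted columns is an **NCO**.
Groups with switch evidence but no net phase change and no conversion (e.g.
tight two-strand double crossovers, the classic "apparent double CO"
ambiguity) are emitted as class 8 composites rather than dropped.

CO classes follow the established tetrad scheme: 0 = no conversion tract;
1 = tract on an involved chromatid; 2 = tract on a non-involved chromatid;
3 = tracts on both; 4 = discontinuous (interrupted) tract; 8 = any other
composite, including more than two exchanged chromatids. The taxonomy leaves
the 4-vs-8 boundary underspecified; `meiorec` reads 4 as
"discontinuous conversion, single carrier category" and 8 as "everything
else", and documents that as an interpretation. Tract carriers are the
chromatids whose phase-revert runs are *contained* in the converted-column
run (with two markers of slack for missing-masked columns); containment
rather than overlap is essential because the long span between two distant
switches of a doubly-recombinant chromatid would otherwise be mistaken for a
conversion carrier. Tract lengths are reported as minimal (first–last
converted marker), maximal (flanking unconverted markers), and their average
("mid"); medians use the mid value. Standalone 4:0 runs are reported but
flagged (`loh_40`) and excluded from NCO counts, as candidate loss of
heterozygosity rather than meiotic conversion.

## The tetrad simulator

The generator's defaults are the study conditions of a *Kluyveromyces
lactis*-like intraspecific cross; they are the package's reference
conditions and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| chromosomes | 1.06–2.60 Mb, total ~10.71 Mb | six chromosomes, centromere mid-arm |
| marker density | 0.00279 per bp | ~29.8k markers; gamma-distributed gaps (shape 0.57) give a median spacing of ~187 bp |
| `lambda_co` | 23 | expected COs per meiosis, split across chromosomes in proportion to physical length |
| `lambda_nco` | 21 | expected NCOs per meiosis (underlying; ~14 detected) |
| `nu` | 1.29 | gamma shape of inter-CO distances (1 = no interference) |
| `co_gc_frac` | 0.78 | probability a CO carries a conversion tract on an involved chromatid (underlying; ~65% detected) |
| tract medians | 1.3 kb (CO), 0.78 kb (NCO) | exponential tract lengths (underlying; ~1.8/~1.2 kb as measured) |
| `epsilon` | 0.08 | probability of an extra tract on a non-involved chromatid (complex events) |
| `missing_rate` | 0 | per-call missing probability |

COs are placed by a **stationary gamma renewal process**: inter-CO distances
are gamma draws with shape `nu` and mean spacing set by the chromosome's
expected CO count; stationarity is achieved by starting the renewal at least
ten mean spacings before the chromosome and clipping. Interference is thereby
modelled in genetic distance — under the tetrad Morgan relation (below) the
genetic-to-physical map is linear, so renewal in bp with rate proportional to
physical length is equivalent. Each CO joins one parent-A DNA molecule to one
parent-B molecule, drawn uniformly from the four non-sister combinations, so
there is **no chromatid interference by construction**. Because earlier
exchanges re-route molecules onto different spores, events are applied left
to right while a carrier permutation tracks which spore holds each molecule;
this guarantees every CO is a visible reciprocal switch, and the truth table
records the actual spore pair exchanged (2-, 3- and 4-strand adjacent pairs
occur 1:2:1, which the test suite verifies).

CO-associated conversion tracts are one-sided, abutting the exchange point on
a random side of a random involved chromatid — producing the classic
offset-switch signature with 3:1 columns between the two involved chromatids'
switch positions. With probability `epsilon` an additional tract lands on a
non-involved chromatid (class 2/3 signatures). NCOs are placed uniformly on
physical coordinates — no positional model for NCOs is assumed, which is an
explicit simplification — as 3:1 tracts on one uniformly chosen chromatid.
Composite classes beyond these arise only as emergent overlaps of independent
events.

Two crossover-control regimes exist besides the default independent one:
`obligate_co` redraws chromosomes with zero COs (CO assurance), and
`homeostasis = "quota"` draws a per-meiosis precursor pool
N ~ Poisson(`lambda_co` + `lambda_nco`) and promotes exactly min(Q, N)
precursors to COs by systematic (count-matched) thinning, the remainder
becoming NCOs — producing the negative CO:NCO-vs-total correlation that
defines homeostasis, while independent pools leave it near zero.

**Underlying vs observed parameters.** The printed observables of a real
cross are post-detection quantities: an NCO is seen only if its tract covers
a marker, a CO tract only if it creates at least one 3:1 column, and measured
tract lengths are biased upward because long tracts are detected
preferentially. The defaults above are therefore *underlying* rates obtained
by dividing the target observables by the measured end-to-end detection
response on the default marker map (NCO detection ~0.66 including
event-merging losses; CO-tract detection ~0.85; tract-median inflation
~1.4×). With these defaults a 205-meiosis simulation yields, after calling,
a median of 23 COs and 14 NCOs per meiosis, ~65% of COs with detectable
conversion, and measured median tracts of ~1.8 kb (CO) and ~1.2 kb (NCO).

## Genetic distance and interference

Physical distances are converted with the tetrad mapping relation
`1 Morgan = 2 G / mean-CO-count` (G = genome size in bp), i.e.
`cM = 100 · bp · meanCO / (2G)` — linear and invertible. Inter-CO distances
are physical distances between successive CO midpoints within a tetrad and
chromosome, pooled across the dataset without end-censoring correction
(matching standard practice for these analyses). The gamma fit is maximum
likelihood: the shape solves the profile score
`log(shape) − digamma(shape) = log(mean x) − mean(log x)` by Newton iteration
to a relative tolerance of 1e-8 (the closed-form Minka approximation is the
starting value), with the scale `mean(x)/shape`. The fit agrees with
`MASS::fitdistr` to four decimals in the test suite, which keeps the
implementation and its oracle separate. Interference is tested by a
Kolmogorov–Smirnov comparison against a *fully specified* shape-1 gamma whose
scale is fixed to the sample mean — the natural moment match, since only "a
gamma with shape 1" defines the null.

The coefficient of coincidence uses fixed, non-overlapping 25 kb bins
anchored at position 1 of each chromosome (nothing suggests sliding windows
for this analysis). For bins i, j on the same chromosome, CoC =
f_ij / (f_i · f_j), averaged over all pairs with non-zero expected frequency
in each inter-interval distance class (one bin width); interference is
1 − CoC. Chromatid interference classifies adjacent same-chromosome CO pairs
by shared chromatids (2/1/0 shared = 2-/3-/4-strand) and tests the counts
against 1:2:1 by chi-square; fewer than 20 pairs triggers a warning rather
than an error.

## Crossover control statistics

*Homeostasis*: Pearson correlation between the per-tetrad CO:NCO ratio and
the total event count. Tetrads with zero NCOs are skipped with a warning; a
zero-variance ratio (perfectly proportional counts) returns r = 0, p = 1 with
a warning instead of erroring, since such data are the textbook null case.
The *corrected* variant first divides NCO counts by a detectability factor
D = P(a random tract covers ≥ 1 marker), computed in closed form from the
empirical inter-marker gap distribution for constant or exponential tract
lengths: `D(t) = 1 − Σ max(g_k − t, 0) / Σ g_k`, averaged over the tract law.
D below 0.05 raises an error (map too sparse to correct meaningfully).

*Dispersion*: per chromosome, the index of dispersion `(n−1) s²/x̄` of CO
counts across meioses referred to chi-square with n−1 df, two-sided;
under-dispersion (s² < x̄, p < 0.05) is the interference signature.
Per-chromosome p-values are also combined by Fisher's method, since how the
source analyses aggregated chromosomes into one verdict is unstated.

*Non-exchange (E0) chromosomes*: a chromosome with zero called COs in a
tetrad, annotated with the presence of NCOs (did the homolog pair interact at
all?). The Poisson expectation for the fraction of meioses with at least one
E0 is `1 − Π_c (1 − e^{−λ_c})` with per-chromosome means λ_c; the uniform
variant uses λ = m/k for Fig-5-style curves (with k = 6 and m = 23 it equals
12.3%).

## Hotspots, coldspots, conservation

CO midpoints are binned into non-overlapping windows (5 kb for hotspots,
20 kb for coldspots; the final partial window is kept and flagged). The null
drops the observed event total into the windows with *equal probability per
window* — the stated permutation scheme, taken literally rather than weighted
by marker density — 10^5 times, records each permutation's extreme window
count, and takes the 2000th most extreme as the threshold (a ~2%
family-wise-style calibration, not a Benjamini–Hochberg FDR). Hotspots are
windows strictly above the max-mode threshold (the comparison operator is a
documented option, since "> threshold" vs "≥ threshold" is ambiguous at
integer counts); coldspots are windows at or below the min-mode threshold.
Adjacent qualifying windows are reported individually and merged.

Conservation between two species maps the five genes nearest each hotspot
through an ortholog table; if at least two orthologs co-locate within 10 kb
on one chromosome of the second species the region is syntenic and the
hotspot testable, and it is conserved iff a hotspot of the second species
lies within 5 kb of the syntenic block. Hotspots without a mappable
neighbourhood are *untestable*, never "not conserved". Gene-set association
(e.g. coldspots vs DNA-repair genes) is a hypergeometric upper tail over the
annotated gene universe.

## Molecular evolution

Pairwise dN/dS uses the unweighted Nei–Gojobori (1986) estimator: per-codon
synonymous site counts averaged over the two sequences, substitution
pathways between codons differing at multiple positions averaged uniformly
with stop-containing pathways excluded, and Jukes–Cantor correction
`d = −(3/4) ln(1 − 4p/3)`. Saturated proportions (p ≥ 0.75) yield NA
distances; a pair with dN = 0 and synonymous divergence reports ratio 0, and
dS = 0 reports the ratio as missing, never infinity. Gene-level values are
means over the unordered pairs with defined ratios. Nucleotide diversity π is
the mean pairwise difference per site (pairwise-complete sites); Watterson's
θw is S/(a_n·L) over sites where every sequence has an unambiguous base.
Median-rank enrichment tests a focal gene set among genes strictly above the
genome-wide median (ties at the median excluded) by the hypergeometric upper
tail. The estimator choice is deliberately the simplest standard one — codon
model ML (branch/site models) is out of scope.

## What the simulator does and does not emulate

The generator reproduces the *statistical* structure tetrad analyses rely
on: marker density and spacing skew, per-meiosis CO/NCO counts, gamma
inter-CO spacings, tract-length scales, detectable fractions, complex-event
rates, obligate-CO and quota regimes. It deliberately does **not** model
recombination-rate heterogeneity along the genome (hotspots/coldspots,
centromere and telomere effects), DSB-level mechanism, sister-chromatid
repair, or sequence-level reads. Consequences worth knowing:

* Pooled inter-CO distances lack the many short spacings that CO clustering
  creates in real maps, so the simulated median inter-CO distance (~30 cM
  under the default conditions) exceeds what a clustered real map of the
  same mean rate shows (~22 cM).
* The gamma shape fitted to *called* events runs slightly above the
  generative `nu` (~+0.1 at `nu` = 1.29): 5 kb event merging truncates the
  shortest spacings, and chromosome-end censoring adds a little more. Fits
  on raw renewal spacings recover `nu` within ±0.1, which is what the
  parameter-recovery tests check.
* Under a uniform null the hotspot caller is *calibrated* (≈2% of datasets
  yield any call), so simulated hotspot counts are near zero by design;
  hotspot detection is validated by spike-in and threshold tests, not by
  reproducing observed hotspot counts.

Passing tests on this generator therefore demonstrate correctness of the
statistics and the caller under the stated assumptions, not that real
genomes are uniform.

## Numerical and degenerate-input choices

* Gamma MLE: Newton on the profile score, tolerance 1e-8, guarded against
  non-positive iterates; requires n ≥ 30 strictly positive distances and a
  non-degenerate sample.
* Permutation threshold: multinomial draws in chunks sized to ~2e6 cells to
  bound memory; deterministic given `seed` (RNG state restored on exit).
* CoC: distance classes with no valid pair are omitted, not reported as 0.
* Event spans at chromosome boundaries: when no flanking marker exists the
  maximal span extends to the chromosome end (or position 1), which is also
  where BED's 0-based convention is exercised.
* A truth-table CO is flagged detectable only if markers exist on both sides
  *outside its own conversion tract* — a CO whose tract swallows its last
  flanking markers leaves no recoverable signature, and caller fidelity is
  assessed against detectable events.
* Ambiguity is surfaced, not hidden: non-reciprocal or evidence-free groups
  become class 8; standalone 4:0 runs are flagged `loh_40`.

## Test problem sizes

The test suite exercises the pipeline at deliberately modest scales chosen to
make Monte-Carlo error small relative to each assertion's tolerance:
caller-fidelity runs use 200 meioses at ~500 bp marker spacing; CoC
calibration uses 1000 meioses of truth events on eight 300 kb chromosomes;
interference recovery uses 100 replicate fits on ~5000 renewal spacings per
shape; the dispersion level check uses 1000 replicate Poisson datasets; the
study-scale checks (23 CO medians, E0 rates) run 205–400 meioses on
sparse-marker layouts where marker rendering is not needed. The acceptance
script runs the full default conditions: 205 meioses, ~29.8k markers, 10^5
permutations.

## Known limitations

Uniform event intensity (no hotspot landscape); no chromatid interference or
CO-assurance mechanism beyond redraws; NCO placement uniform; no LOH or
aneuploidy simulation (the caller only flags 4:0 scars); conservation
analysis assumes ortholog tables are given; dN/dS is pairwise NG86, not a
codon model. These match the package's scope: statistics and calling, not
mechanism.
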