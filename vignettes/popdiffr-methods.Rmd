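---
title: "Methods: region-based population differentiation, delta-DAF and combined-population eQTL scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-based population differentiation, delta-DAF and combined-population eQTL scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiffr)
```

popdiffr analyses recent population differentiation from phased genotypes.
This vignette is the package's account of the statistical machinery: the
estimators, the simulator that provides the neutral reference, the scan
model, the synthetic-data generator the tests rely on, and the numerical
and design choices that were genuinely open.

## The Hudson estimator and ratio-of-averages aggregation

For one biallelic variant with alternate (or derived) allele frequencies
$p_1, p_2$ estimated from $n_1, n_2$ called alleles, the package uses the
Hudson-style components

$$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad \hat D = p_1(1-p_2) + p_2(1-p_1),$$

where the two subtracted terms correct the finite-sample bias of
$(p_1-p_2)^2$. A region estimate over variants $v$ is the *ratio of
averages* $\sum_v \hat N_v / \sum_v \hat D_v$, never the average of
per-variant ratios: rare variants contribute little to both sums instead of
injecting noisy ratios, and the estimate is defined whenever the summed
denominator is positive. Consequences the implementation embraces rather
than hides:

* corrected numerators are frequently negative for rare variants and are
  **not clamped**; window distributions therefore extend below zero,
* variants monomorphic for the same allele in both populations contribute
  $0/0$ and drop out automatically,
* a window or region whose variants are all uninformative is reported as
  flagged-undefined, and counted, rather than silently removed.

Census frequencies (simulation output, where the whole deme is observed)
use the uncorrected numerator $(p_1-p_2)^2$; there is no sampling to
correct for, and no estimate can then be negative.

Windows are `[kw, (k+1)w)` in 0-based coordinates, anchored at multiples of
the window size `w` (1,000 and 10,000 bp by default); the trailing remnant
shorter than `w` is excluded from scans, so a 25 kb chromosome holds exactly
two 10 kb windows. VCF positions stay 1-based; all internal interval
arithmetic is 0-based half-open with conversion only at I/O boundaries.

## Genome partition by gene-component priority

Every base of the genome receives exactly one of ten classes. Nine are
ranked — CDS, 5'UTR, 3'UTR, noncoding exon, intron, upstream 1 kb,
downstream 1 kb, upstream 5 kb, downstream 5 kb — and whatever no
annotation reaches is the remainder. Where annotations overlap, the
minimum-rank class wins; e.g. a base inside one gene's intron and another
gene's 5'UTR is 5'UTR. The partition is exhaustive and exclusive by
construction, so per-class coverages sum exactly to the genome length — a
property the tests assert and the region-summary pipeline reports.

Flanks are **strand-agnostic**, defined on genomic coordinates relative to
the annotated gene start (lower coordinate) and end: upstream means lower
coordinates, downstream higher, regardless of transcription direction. The
defining description of the flank classes never mentions strand, so the
neutral genomic-coordinate reading was adopted and is recorded here as an
assumption. A window or region is REPEAT if it overlaps any repeat interval
by at least one base (half-open, so a repeat starting exactly at the window
end does not count).

## Forward Wright–Fisher simulator

The neutral reference for windowed F_ST distributions is a forward
simulator of a split demography with four phases:

1. **burn-in** — `N` diploid individuals mate randomly for `8N` generations
   from a monomorphic start, long enough to reach mutation–drift
   equilibrium;
2. **split** — individuals are randomly partitioned into two demes of `N/2`;
3. **growth** — each deme gains one individual per generation for `N/2`
   generations (size at `t` generations post-split is `N/2 + t`), with no
   migration;
4. **stationary** — `4N` further generations at size `N`.

Each offspring draws two parents uniformly at random (selfing allowed — the
simplest Wright–Fisher reading; at `N >= 200` the effect is negligible) and
receives one recombinant gamete from each, with `Poisson(L rho)` crossovers
and `Poisson(L mu)` new mutations per gamete, both at uniform real-valued
positions on `[0, L)`. Because positions are continuous, every mutation is
its own site (a draw colliding with a position already on the receiving
gamete is redrawn), giving infinite-sites behaviour without a site grid.
Defaults are `mu = rho = 1e-7` per bp per generation, with presets
`N = 200, L = 2 Mb, 10 replicates` and `N = 400, L = 1 Mb, 20 replicates`.

Ploidy was an open choice: the demography is stated in individuals and the
reproduction scheme ("random mating") implies recombination between two
parental haplotypes, so diploidy is the default; a haploid mode (`N`
haplotypes, each offspring a recombinant of two uniform parents) is
provided as a flag for sensitivity analysis.

Implementation notes that matter for correctness:

* haplotypes are sparse sorted position vectors; sites lost from a deme
  simply stop appearing, while sites fixed within a deme are stripped from
  its haplotypes each generation and re-materialised at output as frequency
  1 (sites fixed in both demes contribute nothing to any component and are
  dropped). Memory stays bounded over thousands of generations.
* the deme-size schedule is asserted every generation inside the engine; a
  violation aborts the run.
* all randomness flows through R's RNG, so `set.seed()` makes runs
  bit-identical; the suite checks seed determinism, the absence of negative
  census estimates, and that divergence grows across post-split checkpoints
  at `0, N, 2N, 4N` generations after growth.
* output is the final census frequency of every site per deme;
  `summarize_windows()` then applies the uncorrected windowed estimator and
  pools windows across replicates (replicates are pooled, not
  concatenated). At these presets the pooled means come out near 0.29
  (1 kb) and 0.61 (10 kb) for the base preset — the quantities
  `scripts/acceptance.R` recomputes from scratch on every run.

## Combined-population eQTL scan

Population-specific variants are nearly fixed in one population and rare in
another, so per-population scans are underpowered for exactly the variants
of interest. The scan therefore pools all samples and fits, per
variant–feature pair,

$$y_i = \beta_0 + \beta_1 \, d_i + \boldsymbol\gamma^\top \mathbf{z}_i + \varepsilon_i,$$

where $d_i$ is the 0/1/2 allele dosage and $\mathbf{z}_i$ are population
indicators (one per population after the first, alphabetically). The
covariate absorbs population-level expression shifts, so mean expression
differences between populations are not mistaken for genotype effects; the
suite verifies that p-values are uniform under a population-shifted null
with the covariate and inflated without it. The implementation residualises
dosage and expression against the covariate design once (Frisch–Waugh) and
then evaluates every pair as a simple regression with
`df = n - (#parameters)`; it is exactly equal to per-pair OLS, which the
tests confirm against `lm()`.

Filters and classification follow the standard cis/trans scan conventions:

* **MAF** — variants with pooled minor allele frequency `> 0.05` are
  analyzed; the boundary is strict, so exactly 0.05 is removed. Pooled
  (not per-population) frequency is used, matching the combined design.
* **cis/trans** — cis iff variant and feature anchor share a chromosome and
  lie within `1e6` bp, boundary inclusive; different chromosomes are always
  trans. The feature anchor is the annotated feature start.
* **thresholds and FDR** — cis records with `p >= 0.05` and trans records
  with `p >= 0.01` are discarded; Benjamini–Hochberg runs separately per
  family with `m` equal to the family's *total* test count. That is the
  convention of the standard scan packages, whose outputs store only
  sub-cutoff records but adjust against every test performed; adjusting
  only over retained records (exposed as `m = "retained"` for diagnostics)
  is markedly anticonservative and flags near-null records wholesale.
  Significance is `fdr < 0.05`.

`hotspot_counts()` tabulates, per variant, the significant cis and trans
features; a trans-regulation hub — one cis-regulated driver whose product
controls many distant features — surfaces at the top of the trans ranking.

## DAF, delta-DAF and grouping

Polarisation requires an ancestral call: ancestral = ref gives DAF = alt
frequency, ancestral = alt gives 1 − alt frequency, and any other state
(`UNKNOWN`/`OTHER`) *excludes* the variant from every DAF analysis —
exclusion is a value, not an error, mirroring the use of only-concordant
ancestral calls. Delta-DAF is the **unsigned** difference `|DAF_A − DAF_B|`:
ranking "by decreasing delta-DAF" is only well defined unsigned, and a
signed variant is available for diagnostics.

Grouping sorts analyzed variants by delta-DAF descending (ties broken by
coordinates for determinism) and chunks them into fixed-size groups —
20,000 for coding-gene variants, 10,000 for noncoding — keeping the partial
final chunk as its own group, so the group count is `ceiling(n / size)`.
With 2,895,539 coding variants and groups of 20,000 this yields exactly 145
groups, the arithmetic anchor of the acceptance suite. Per group the
summaries report the fraction of members with significant cis (and trans)
eQTLs and the mean DAF per population; trans enrichment at the top of the
ranking flags selection specific to one population, enrichment at the
bottom — with low mean DAF in both populations of the ranking pair — flags
shared pressure. DAF histograms come in two presets: uniform 0.01-wide bins
on [0, 1], and log-spaced bins below 0.01 to resolve structure among very
rare derived alleles.

## Linkage disequilibrium

From phased haplotypes, with marginals $p_A, p_B$ and joint $p_{AB}$:
$D = p_{AB} - p_A p_B$, $D' = |D| / D_{\max}$ with the usual sign-dependent
$D_{\max}$, and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$. Haplotypes missing at
either site are dropped pairwise; a site monomorphic after filtering gives
a flagged-undefined result. Combined-population LD pools the selected
populations' haplotypes without reweighting. Unphased matrices are refused.

## Synthetic-data generator

The generator emits every input format the pipeline reads (phased VCF,
panel TSV, ancestral TSV, gene/component TSVs, repeat BED, expression and
anchor TSVs) plus truth tables, all deterministically from one seed, so
every stage is testable without downloads. It emulates:

* three populations (African-, East-Asian- and European-ancestry panels of
  504/504/503 samples by default, the sample sizes of the study data this
  pipeline targets) with Balding–Nichols-style frequency drift around
  ancestral frequencies concentrated near zero (drift 0.08/0.14/0.12 by
  default, chosen to land genome-wide differentiation in the 0.10–0.15
  range typical of continental human comparisons);
* a sweep fraction whose derived alleles are near-fixed (DAF 0.9–1.0) in
  the two out-of-Africa panels and rare elsewhere;
* block LD via a per-haplotype latent state refreshed at block boundaries
  (20 kb) and with small within-block probability — marginals stay exact
  while neighbours correlate;
* ancestral calls with a 2% mislabel rate and 5% missing rate;
* expression with planted cis effects, per-feature population shifts,
  Gaussian noise, and one trans hub: a driver variant cis-regulates a
  regulator feature, and each hub target receives an attenuated copy of the
  regulator's expression, so the driver reaches distant features only
  through the regulator.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic demographic history (drift is
cross-sectional, not genealogical; the Wright–Fisher simulator provides
the genealogical route for end-to-end realism), sequence composition,
genotyping error, expression-quantification artefacts, latent expression
confounders beyond population, and realistic gene density. Tests that
recover planted effects demonstrate correctness of the machinery, not
power on any particular real dataset.

## Numerical choices and edge cases

* Undefined results (no called alleles, zero denominators, monomorphic LD
  sites, degenerate chi-squared margins) are flagged values, never
  exceptions; errors are reserved for malformed inputs.
* Collinear dosages (constant within covariate strata) are skipped and
  counted, not fitted.
* Extreme-set selection uses `ceiling(0.01 n)` in fraction mode; ties are
  broken by coordinates so all-equal inputs select deterministically.
* Length-matched control regions use rejection sampling (uniform placement
  on the same chromosome, resampled while overlapping an exclusion, capped
  at 1,000 tries) under a mandatory seed.
* Chi-squared enrichment tests use one degree of freedom and no continuity
  correction, appropriate for the large counts this comparison is used on.
* The 2×2 haplotype, OLS, BH and F_ST paths are each cross-checked against
  brute-force oracles on small fixtures in the test suite.

## Problem sizes

The test suite runs the simulator presets at 3 replicates each and the
generator at 40–80 samples per population with hundreds of variants —
sizes chosen so the full suite completes in about a minute while leaving
every statistical check well powered. `scripts/acceptance.R` runs the full
presets (10 and 20 replicates). The generator's scientific defaults (504/
504/503 samples, 2,000 variants) are unchanged by any test.

## Known limitations

* Ancestral-state inference is consumed, not performed; mislabelled calls
  flip DAF to 1 − DAF and are only partially detectable.
* The scan supports one categorical covariate (population); latent-factor
  expression correction is out of scope.
* Transcript-isoform structure is reduced to interval unions per component;
  the transcription-ratio trait guards zero denominators by dropping the
  affected samples pairwise.
* The simulator models two demes, no migration and no selection — it is a
  neutral reference, not a demographic fit to any real population.
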