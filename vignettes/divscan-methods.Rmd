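---
title: "Methods: windowed diversity and divergence scans with divscan"
author: "divscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed diversity and divergence scans with divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

# Scope and data model

divscan implements the windowed population-genomic toolkit used to
characterise a crop genome from resequencing data: two-population
divergence scans (π, S, Tajima's D, Weir–Cockerham F_ST, ROD), an
outlier/permutation analysis for sweep candidates, a single-genotype
low-heterozygosity (autozygosity) scan, pedigree haplotype-block tracing,
and genetic-map scaffold anchoring with Marey-map recombination rates.

The central container is `GenotypeMatrix`, a
`RangedSummarizedExperiment`: rows are biallelic SNP sites (width-1
`GRanges`), columns are samples, the `GT` assay holds alternate-allele
dosages (0/1/2, `NA` for missing), and `colData$group` holds the
population label. All windows are `GRanges` in the ecosystem's 1-based,
closed-interval convention; VCF positions are used as-is on ingest. A
window printed as `[s+1, e]` here is the same set of base pairs as the
0-based half-open interval `[s, e)` used by BED-style tools, and all
boundary rules below are stated against that identity.

# Statistics

**Nucleotide diversity.** Per site with `c` alternate alleles among `k`
non-missing chromosomes the unbiased mean pairwise difference is
`2c(k−c)/(k(k−1))`; a window's π is the sum over its sites divided by the
window length in bp, so monomorphic and unobserved positions dilute the
denominator (the convention of windowed-π tools). Sites with `k < 2` are
skipped and counted.

**Tajima's D** uses the standard constants `a1 = Σ 1/i`, `a2 = Σ 1/i²`
(`i = 1..n−1`), `b1 = (n+1)/(3(n−1))`, `b2 = 2(n²+n+3)/(9n(n−1))`,
`c1 = b1 − 1/a1`, `c2 = b2 − (n+2)/(a1 n) + a2/a1²`, `e1 = c1/a1`,
`e2 = c2/(a1² + a2)`, with `D = (π̂ − S/a1)/√(e1 S + e2 S(S−1))` and is
undefined for `S = 0`. Per window, `n` is twice the sample count when the
window has no missing data; with missing data we use the modal per-site
chromosome count and flag the window (`mixed_n`). This choice is a
package decision — the windowed-D literature is silent on it — and it
reduces to the exact definition whenever data are complete.

**F_ST.** Per-site Weir–Cockerham variance components for two
populations (`a` among populations, `b` among individuals within
populations, `c` within individuals) are computed from the per-population
sample sizes, allele frequencies and heterozygote frequencies; windows
report the ratio of sums `Σa / Σ(a+b+c)` (the "weighted" estimator).
Negative estimates are preserved: truncating at zero would distort the
empirical distribution from which the outlier cutoff is taken. Sites
where one population is entirely missing are excluded from both sums.

**ROD** is `1 − π₁/π₂` with group 1 in the "diversity-reduced candidate"
slot (e.g. an Occidental gene pool against an Asian reference pool);
undefined when `π₂ = 0`.

# Outlier scan and permutation FDR

The cutoff is the interpolated empirical quantile (type 7) of the defined
window F_ST values, default 0.95, and windows with `fst ≥ cutoff` are
flagged — with ties this can flag more than 5%. The false-discovery rate
of the flagged set is estimated by permutation: individual-to-population
labels are shuffled genome-wide (group sizes preserved), windowed F_ST is
recomputed, and the FDR estimate is the mean permuted count of windows
reaching the cutoff divided by the observed count. Shuffling whole
individuals rather than per-window genotypes preserves the linkage
structure within individuals. The permutation statistic is the per-window
F_ST compared against the observed cutoff (not a genome-wide maximum);
this estimates the expected fraction of false windows in the flagged set
rather than family-wise error. Each F_ST outlier window is classified as
a sweep candidate in whichever group shows negative Tajima's D there
(both are possible), with ROD attached as evidence.

# Synthetic data: what it emulates and what it does not

`simulateTwoPopulations()` draws ancestral frequencies
`p ~ Uniform(0.05, 0.95)` — bounded away from 0/1 so that the MAF > 0.10
filter keeps its pass rate high and stable — and population frequencies
from the Balding–Nichols law `Beta(p(1−F)/F, (1−p)(1−F)/F)` (`p_k = p`
when `F = 0`), with Hardy–Weinberg `Binomial(2, p_k)` genotypes. The
defaults mirror a founder panel of 23 diploids split 11 (Western) and 12
(Eastern) at moderate divergence `F = 0.15`. Sweeps are modelled by
frequency replacement: inside a sweep window the sweep population's
frequency is replaced with probability 0.9 by a draw near fixation
(`Uniform(0.98, 1)` or `Uniform(0, 0.02)`, the side chosen by rounding
`p`). This is deliberately not a coalescent: it is cheap, and it produces
exactly the three signatures the scan keys on (low π, an excess of rare
alleles and hence negative D, elevated F_ST). Sites are unlinked, there
is no linkage disequilibrium, no ascertainment bias and no missingness
unless introduced; passing the calibration tests therefore shows the
estimators and the scan logic are correct under the stated model, not
that real resequencing data meet the model.

Randomness flows from a single integer seed per generator call; the
stream order (positions, ancestral frequencies, population 1 then 2
frequencies, sweep replacements, genotypes) is documented so outputs are
bit-reproducible.

`simulatePedigreeGenotypes()` gene-drops uniquely labelled founder
haplotypes through a validated pedigree. Crossovers per meiosis are
`Poisson(L_cM/100)` placed uniformly on the cM scale (Haldane model, no
interference — the recovery tests compare against recorded truth, which
does not depend on interference) and converted to bp through the marker
map by piecewise-linear interpolation. Haplotype 1 of every individual is
maternal. Founder alleles are either fully informative labels or
Bernoulli(0.5) biallelic states.

`simulateAnchoringFixture()` lays scaffolds on linkage groups with known
order and orientation, emits probe alignments (identity ≥ 98.5%, coverage
≥ 0.96, unique) and degrades a chosen fraction into low-identity,
low-coverage or multi-hit decoys that the filter must remove exactly.

# Autozygosity scan

Per-window heterozygous-SNP counts of a focal genotype are thresholded at
an interpolated genome-wide percentile (default 10th; fractional
thresholds such as 377.5 are therefore possible), flagged strictly below,
and runs of boundary-sharing flagged windows are merged into regions
(never across chromosomes). Partial terminal windows are excluded from
threshold estimation and flagged on rescaled counts
(`count × size/actual_length`), avoiding spurious terminal calls.

The recovery test plants identity-by-descent through inbreeding: the
focal individual's parents both descend from one founder. With parents
that are half-sibs (kinship 1/8) the expected IBD fraction, 12.5%,
exceeds the 10th-percentile flagging rule and the genome-wide threshold
degenerates to zero; the packaged scenario therefore inserts one more
generation (kinship 1/16, expected IBD 6.25%) so that the percentile
threshold remains informative, and uses a 30-cM map on 10 × 20-Mb
chromosomes so that IBD tracts are long relative to the 1-Mb windows.
Seeds whose realised IBD fraction still exceeds the percentile recover
nothing — the strict threshold behaves as designed — and the criterion is
the median per-seed coverage of true segments (≥ 0.8) over seeds with
non-empty truth.

# Haplotype blocks

Blocks are the intervals between the sorted union of crossover positions
over the chosen ancestral meioses; they partition each chromosome and
carry their markers. Tracing compares a focal haplotype's block alleles
with each parental haplotype at all mutually non-missing markers —
identity must be exact, with no mismatch tolerance, since blocks are
recombination-free by construction — and climbs the pedigree while the
match is unique, reporting `unknown` the moment zero or several
haplotypes match. Which ancestral meioses define the partition is a
parameter (the package takes crossover positions, simulated or supplied),
not a fixed rule. Ancestor identity declares a block matched when either
focal haplotype equals either ancestor haplotype, and reports per-chromosome
matched counts and bp. The module consumes phased data; pedigree-based
phasing inference is out of scope.

# Anchoring and Marey maps

Alignments are retained iff identity ≥ 98, coverage ≥ 0.95 and the probe
hits the genome once (the "filter out < 98% / < 95% / multi-hit" rule
read with inclusive boundaries). Scaffolds take the modal linkage group
of their markers only when the mode holds more than 2/3 of them
(otherwise they are left unanchored with a conflict flag), are ordered by
mean cM, and oriented by the sign of the Spearman correlation between
marker cM and scaffold bp — rank-based because marker spacing is
non-uniform; fewer than two distinct positions gives `unknown`, laid out
as `+` and flagged. Pseudomolecules concatenate scaffolds with fixed
100,000-bp gaps, emitted as known-length `N`/`contig` AGP v2.1 rows, and
the coordinate lift between scaffold and pseudomolecule coordinates is an
exact bijection on component spans (minus-strand positions map to
`offset + len − x + 1`). Marey rates are least-squares slopes of cM on Mb
over the markers of 10-Mb windows sliding by 1 Mb (windows that fit
entirely on the chromosome); windows with fewer than 2 markers, or
without two distinct positions, are undefined. Non-monotone cM within a
linkage group draws a warning, not an error, since the slope remains
defined.

# Numerical and degenerate-input choices

- Quantiles everywhere are R's type-7 interpolation; `counts 1..10` at
  the 10th percentile give 1.9.
- Undefined statistics are `NA`, never silently zero: D with `S = 0`,
  F_ST with no defined site, ROD with `π₂ = 0`.
- `filterVariants` applies MAF strictly greater than the threshold
  (a site at exactly 0.10 is removed) and missingness non-strictly.
- Multiallelic and indel VCF records are dropped (and counted), not
  decomposed: the statistics are defined on biallelic SNPs.
- Final partial windows are emitted and flagged `partial`; the outlier
  scan includes them, the autozygosity threshold excludes them.
- An empty VCF or `nSites = 0` yields an empty matrix with a warning;
  a pedigree individual with exactly one known parent is an error.

# Problem sizes used by the shipped checks

The calibration and recovery tests run: estimator recovery at 50,000
sites (one seed; the acceptance script repeats it over five seeds);
oracle equivalence on 200 random matrices (≤ 6 samples, ≤ 20 sites) plus
50 random component tables; scan calibration on 20 planted-sweep seeds
and 3 null seeds (10,000 and 8,000 sites on a 20-Mb chromosome, 200 and
100 permutations); autozygosity and haplotype-block recovery on 20 seeds
each. These sizes were chosen as the smallest at which the binomial noise
of the pass criteria (e.g. ±0.02 on F_ST, median Jaccard ≥ 0.5) is
comfortably resolved.

# Known limitations

- The Balding–Nichols generator has no linkage, mutation model or
  ascertainment; it validates estimators, not data-quality handling.
- The sweep model plants frequency distortions, not genealogies; sweep
  "width" is exactly the planted window.
- Tajima's D with heavy, uneven missingness leans on the modal-`n`
  approximation.
- The permutation FDR assumes exchangeable individuals under the null;
  family structure within a population would break that assumption.
- Haplotype-block tracing requires phased input and treats identity as
  exact; genotyping error would fragment matches rather than be absorbed.
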