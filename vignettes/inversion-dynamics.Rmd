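---
title: "Inferring chromosomal inversion frequencies from Pool-Seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosomal inversion frequencies from Pool-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolinv)
library(dplyr)
```

## The problem

Chromosomal inversions suppress recombination in heterokaryotypes and are
classic targets of selection in *Drosophila*. Pooled sequencing (Pool-Seq)
yields genome-wide allele frequencies cheaply, but destroys haplotype
information, so an inversion's frequency cannot be read off a pool
directly. The way around it is a set of *diagnostic marker SNPs*: sites at
which every chromosome carrying the inversion has one allele and every
chromosome of any other arrangement on the same arm has another. Once such
markers exist, the inversion's frequency in a pool is simply the average
frequency of the inverted alleles at the marker positions.

`poolinv` implements the full chain:

1. **Haplotype reconstruction** (`reconstruct_haplotypes()`): paternal
   haplotypes are recovered from F1 larvae of crosses between wild-karyotype
   males and females of a strain homozygous for standard arrangements, by
   contrasting F1 read counts against the reference.
2. **Marker discovery** (`find_fixed_differences()`): fixed differences
   between karyotype classes in a panel of haplotypes with known karyotype.
3. **Frequency estimation** (`estimate_inversion_frequency()`): coverage-
   filtered, marker-averaged inverted-allele frequencies per pool.
4. **Inference** (`cmh_test()`, `fet_test()`, `anova_inversion()`):
   replicate-aware tests of frequency change over time or space.
5. **Arrangement-stratified population genetics** (`window_pi()`,
   `window_fst()`, `ld_r2()`, `ld_ratio()`).
6. **A neutral null** (`wf_drift()`, `wf_empirical_p()`): Wright–Fisher
   forward simulation giving empirical p-values for observed replicated
   frequency changes.
7. **Synthetic data with known truth** (`sim_*()`) for every stage.

All user-facing functions take and return tibbles, so steps chain with the
pipe.

## Haplotype reconstruction and its filters

A larva from the cross carries one maternal chromosome that is reference at
(almost) every site, so a heterozygous F1 site reveals a non-reference
paternal allele and a homozygous-reference site a reference paternal
allele. Sequencing noise is controlled by the exclusion of reference-strain
polymorphisms (pool minor-allele frequency > 10%) and five per-site
criteria, applied in order:

* **(i)** coverage < 15 is discarded (large sampling error);
* **(ii)** coverage above the 95th percentile of that larva's arm-wide
  coverage distribution is discarded (duplications, mismapping);
* **(iii)** alleles with fewer than 20 supporting reads summed across all
  larvae are dropped;
* **(iv)** at sites with more than two surviving alleles only the two most
  frequent are kept;
* **(v)** at a two-allele larva, both counts must fall inside the central
  90% binomial interval for an expected frequency of 1/2 at that larva's
  coverage.

Three numerical choices deserve a note. The coverage percentile uses the
nearest-rank definition (`coverage_percentile()`), not interpolation, so
the threshold is always an observed integer coverage and filtering is
exactly reproducible. The criterion-(v) interval is the central equal-tailed
*exact* interval with inclusive boundaries — counts sitting exactly on the
bound are retained — and is symmetric about coverage/2 by construction
(`binom_retention_bounds()`). When the 2nd and 3rd most frequent alleles of
a multi-allelic site tie, there is no principled way to pick two alleles,
so the site is filtered rather than resolved arbitrarily.

On synthetic F1 data (`sim_f1_counts()`) the pipeline is exact in the
noiseless limit and recovers more than 99% of called paternal alleles
correctly at 30x coverage with a 1% per-read error rate; those checks run
in the test suite.

## Marker discovery

`find_fixed_differences()` scans one arm for sites where the inverted class
is fixed for one allele and *all other arrangements* — standard chromosomes
pooled with overlapping inversions on the same arm — are fixed for a
different allele. A site is only eligible when at least 80% of the
chromosomes in each class are informative (non-missing) there; this
`informative_min` is the single relaxation the scan exposes. Missing data
count against informativeness only: fixation is judged over the informative
chromosomes, and strict fixation is required (one discordant chromosome
removes a site). Fixed differences are biallelic by definition, so sites
showing three or more alleles are never markers.

Marker density along the arm is summarised in 100-kb non-overlapping
windows (`summarize_marker_distribution()`) and against user-supplied
breakpoint intervals (`tally_breakpoint_markers()`); breakpoints are
configuration read from BED (`read_breakpoints()`), converted from BED's
0-based half-open convention to the 1-based inclusive coordinates used
everywhere else (`bed_to_coords()`).

## Frequency estimation from sync files

Pool-Seq counts enter in the PoPoolation2 sync dialect (`read_sync()`): one
`A:T:C:G:N:del` column per pool. `N` and deletion counts are parsed but
excluded from every allele-frequency denominator — the estimates are SNP
allele frequencies, and treating deletions as coverage would deflate them;
this is a deliberate choice where either reading was defensible.

Per marker and pool, the inverted-allele frequency is its count over the
`A+T+C+G` coverage. Markers below the minimum coverage (default 10-fold;
3-fold is the customary preset for low-coverage data sets) or above the
95th percentile of that pool's *genome-wide* coverage distribution
(computed from all sync records, not just marker positions) are dropped,
and the pool's estimate is the unweighted arithmetic mean over the
surviving markers — unweighted because the estimator is defined as the
average of marker allele frequencies; a coverage-weighted variant sits
behind `weighted = TRUE` but is not the default. A pool in which no marker
survives yields an explicit `NA`, never a 0. Markers absent from the sync
table are dropped with a message rather than an error, so partial sync
extracts remain usable.

Simulation places the estimator's accuracy: with 40 markers at 30x
coverage and a true frequency of 0.25, the mean absolute error is below
0.02 and the bias below 0.005 over 1000 simulated pools (run in
`tests/testthat/test-acceptance.R`).

## Statistical inference on frequency change

For replicated time series, `cmh_markers()` runs a Cochran–Mantel–Haenszel
test per marker SNP, stratified by replicate population, on 2x2 tables of
inverted/other allele counts at two time points. The classical CMH
chi-square is implemented directly (hypergeometric variance, 1 df), with
the continuity correction off by default; a single stratum is allowed and
equals the `(n-1)/n`-scaled Pearson chi-square of that table. Strata with
an empty margin carry no information and are dropped with a warning.
Per-marker p-values are combined with `combine_p()`, whose default is the
arithmetic mean across markers. A mean of p-values is a *summary*, not a
calibrated combined test, and it is labelled accordingly; Fisher's method
is available behind a flag for users who want a proper combination, but
neither is asserted to be the historically published rule for clinal
comparisons, which the original descriptions leave unspecified.

Unreplicated spatial comparisons use Fisher's exact test per marker against
a baseline (lowest-latitude) pool (`fet_markers()`); a table with an empty
margin returns p = 1 and a flag.

Karyotype counts — the cytological gold standard — are analysed with the
fully factorial fixed-effects two-way ANOVA `frequency ~ inversion *
regime` (`anova_inversion()`), on exact `count/n` frequencies. In the
balanced 6 inversions x 2 regimes x 3 replicates layout the dfs are
(5, 1, 5; 24) and the sums-of-squares type is immaterial. `tidy()` and
`glance()` methods expose the table and the headline F statistics. No
multiple-testing correction is applied across inversions; raw p-values are
reported.

## Diversity and linkage disequilibrium by arrangement

Nucleotide diversity uses the unbiased site-frequency form
$\pi = \frac{1}{L}\sum_s \frac{n}{n-1}\left(1 - \sum_i \hat p_i^2\right)$,
which reduces exactly to the mean pairwise difference; the consequential
choice here is the window denominator $L$: by default it is the number of
accessible sites (positions present in the panel with at least two
non-missing alleles), so masked repeats do not deflate π, and
`denominator = "window"` restores the nominal window length for panels that
record every site. Differentiation is the π-based Hudson-style
$F_{ST} = (\pi_{total} - \bar\pi_{within})/\pi_{total}$ per 100-kb window,
undefined where $\pi_{total} = 0$; sampling noise can push the estimate
below zero, in which case it is clamped to 0 and flagged. Group sizes down
to 2 haplotypes are accepted — arrangement classes as small as three
chromosomes are a reality of karyotyped panels — with accuracy left to the
reader's judgement rather than a hard refusal.

$r^2$ between two sites is the squared allelic correlation over
pairwise-complete haplotypes. The inverted/standard LD contrast
(`ld_ratio()`) averages $r^2$ over SNP pairs inside the inversion interval
separately per arrangement and reports the ratio; because $r^2$ depends
strongly on sample size, the larger group is first subsampled to the size
of the smaller, seeded for reproducibility. One SNP set — sites polymorphic
in both matched groups — is sampled once and shared, which makes
`ld_ratio(a, b)` and `ld_ratio(b, a)` exact reciprocals at a fixed seed.
All sampled polymorphic pairs inside the interval enter the averages; no
masking-aware pair exclusion is attempted.

## The Wright–Fisher null

Observed frequency changes are compared against pure drift:
$p_{t+1} = X/n_{copies}$, $X \sim \text{Binomial}(n_{copies}, p_t)$, with
absorbing boundaries. An effective size of $N = 200$ — the scale estimated
for typical laboratory selection experiments — is read as a *diploid* size,
so $n_{copies} = 2N = 400$ chromosome copies are resampled; the haploid
reading is available via `n_copies = N`. The empirical p-value simulates
all replicates jointly (each with its own generation count, e.g. 60 for a
hot and 34 for a cold regime) from the base-population frequency and counts
iterations in which the simulated polarized change *strictly* exceeds the
observed polarized change in every replicate; with 100,000 iterations the
resolution is $10^{-5}$ and zero exceedances are reported as
`< 1/iterations`. A replicate with exactly zero observed change has no
polarity; it is flagged and contributes the condition
|simulated change| > 0. The simulator's mean (martingale) and its
closed-form variance $p_0(1-p_0)\left[1-(1-1/n_{copies})^t\right]$ are
verified against 100,000-iteration runs at $t \in \{10, 34, 60\}$ in the
test suite.

## What the synthetic generators emulate — and what they do not

`sim_haplotype_panel()` plants a known set of fixed differences (30 by
default, mirroring mid-range marker counts per inversion) inside a
configurable inversion interval on a 1-Mb arm, against 10,000 shared SNPs
(one per 100 bp) whose frequencies are independent of karyotype and drawn
from U(0.1, 0.9) — keeping shared frequencies off the boundaries makes
chance fixation between finite samples negligible, so the truth record is
exhaustive. Default class sizes (20 standard, 10 inverted) match the scale
of per-arrangement samples in combined karyotyped panels. Placement can be
uniform within the inversion or breakpoint-clustered, the two empirical
patterns seen in cosmopolitan inversions. `sim_pool_counts()` draws
Poisson coverage (negative binomial behind a flag for overdispersion
checks) and binomial inverted-allele counts; `sim_f1_counts()` uses
constant per-site coverage so threshold criteria behave deterministically;
`sim_ld_panel()` creates suppressed recombination by descent from two
founder blocks. All generators are seed-deterministic to the byte.

What passing tests on these fixtures shows is that the *algorithms* are
correct and calibrated under their stated sampling models. Real data add
mapping artefacts, correlated errors, repeat-masked gaps, linked selection
and reference bias that none of the generators emulate, so published
marker counts and frequency estimates from field data are not reproduced
here; the generators' role is planted-truth recovery, not realism.

## Problem sizes and runtime

The shipped tests run marker recovery on 100 seeded panels of ~2,030 sites
x 30 chromosomes, estimator calibration on 1,000 pools x 40 markers,
10,000 CMH null simulations, an exhaustive Fisher-exact sweep of all 2x2
tables with margins up to 12, 100,000-iteration drift checks at three
horizons, and 1,000 oracle trials each for π, F_ST and r² — sizes chosen so
the full suite completes in a few minutes on one core while keeping
Monte-Carlo bands tight.

## A worked example

```{r example}
p <- sim_haplotype_panel(n_standard = 16, n_inverted = 8, n_planted = 20,
                         n_shared = 1000, arm_length = 2e5, seed = 1)
markers <- find_fixed_differences(p$panel, "In(3R)C")
nrow(markers)

sync <- sim_pool_counts(markers, truth_freq = c(0.15, 0.16, 0.14, 0.52, 0.55, 0.49),
                        mean_coverage = 40, seed = 2)
estimate_inversion_frequency(sync, markers)

cmh <- cmh_markers(sync, markers, strata = list(c(1, 4), c(2, 5), c(3, 6)))
combine_p(cmh$p_value)

wf_empirical_p(p0 = 0.15, p_obs = c(0.52, 0.55, 0.49), generations = 60,
               iterations = 1e5, seed = 3)
```

## Known limitations

* Marker discovery assumes the karyotype labels of the panel are correct;
  a mislabelled chromosome silently erodes the marker set (by design —
  strict fixation).
* The mean-of-p summary is not a test statistic with a known null
  distribution; use Fisher's method when calibrated combination matters.
* The LD ratio is sensitive to the SNP-sampling scheme in small panels;
  the shared-SNP-set choice trades a little power for exact symmetry.
* Read mapping, repeat masking and indel handling are upstream of this
  package: inputs are assumed to be clean per-position counts.
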