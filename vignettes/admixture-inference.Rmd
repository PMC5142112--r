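---
title: "Admixture inference and its genomic consequences: models and methods"
author: "backflow package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture inference and its genomic consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backflow)
```

## The problem

Many present-day populations derive their genomes from ancient mixtures of
diverged source populations — the recurrent Holocene gene flow from Eurasia
back into African populations is a canonical example. Three questions arise
again and again: *did* a population receive gene flow (detection), *how
much* (proportion), and *when* (dating)? A fourth, subtler question is what
the mixture does to downstream analyses: admixture from a bottlenecked
source depresses heterozygosity, imports alleles that masquerade as targets
of positive selection, and carries archaic ancestry into populations that
never met the archaic source.

`backflow` implements this whole chain of reasoning as a tested R package:
f-statistics with block-jackknife errors, weighted-LD admixture dating, the
population branch statistic (PBS) with a neutral post-admixture
expectation, PCA-based local-ancestry masks, heterozygosity and ROH
summaries per ancestry-segment class, and rho-statistic Y-chromosome
dating. Because the genotype data that motivated these methods are not
generally redistributable, the package carries its own forward-time
Wright–Fisher simulator with recorded ground truth, and every method is
validated against it.

## The simulator

### Two levels of simulation

`simulate_freqs()` drifts derived-allele frequencies along a population
tree by binomial Wright–Fisher sampling (`p' ~ Binomial(2N, p) / 2N` per
generation), mixing frequencies at an admixture pulse as
`alpha * p_donor + (1 - alpha) * p_recipient` — an identity that holds
exactly and is tested exactly. It is the fast oracle for every statistic
that depends only on allele frequencies (f3/f4/D, f4-ratios, PBS).

`simulate_panel()` adds haplotypes and linkage. Populations drift at the
frequency level until a pulse recipient is founded; from the first pulse
onward the recipient is simulated as `N` diploid individuals mating at
random, each gamete recombining its parent's two haplotypes with a
Poisson(map length in Morgans) crossover count, positions uniform on the
genetic map, no interference. Each haplotype segment carries the index of
the founder haplotype it descends from, so the true ancestry tract of
every sampled haplotype is known exactly; tracts are exported in 0-based
half-open bp coordinates and tile each chromosome (asserted by test).
Pulses copy whole donor haplotypes with probability `alpha` per gamete.

### Deliberate simplifications

* **Standing variation only.** The simulator works on a fixed grid of
  segregating sites seeded at the root (ancestral derived-allele frequency
  drawn from Uniform(0.05, 0.95), configurable). No new mutations are
  injected during the simulated epochs; over the few hundred forward
  generations the package simulates, de-novo variants would contribute
  negligibly to any statistic computed here. The per-generation mutation
  rate (default 1.25e-8) is carried in the genome configuration for
  conversions and documentation.
* **No background LD in unadmixed populations.** Haplotypes of populations
  that never receive a pulse are drawn site-wise from their drifted
  frequencies. Admixture LD in the recipient therefore arises purely from
  ancestry tracts — which is exactly the signal weighted-LD dating
  measures. The simulator consequently cannot emulate ALDER's
  short-range background-LD corrections, which is why the curve's lower
  distance cutoff (0.5 cM) matters less here than on real data.
* **Ancestral alleles by construction.** The simulated root allele is the
  ancestral allele; an artificial `Chimp` outgroup sample fixed for it is
  included by default so that f4/D outgroup slots work unmodified.
* **Uniform SFS.** Uniform(0.05, 0.95) ancestral frequencies overweight
  common variants relative to a neutral site-frequency spectrum. All
  f-statistics are frequency contrasts and are insensitive to this;
  absolute heterozygosity values are not comparable to real per-kb rates
  (the simulated panels carry ~0.03 hets/kb at ~1 SNP per 10 kb density).

### The canned scenarios

Two presets compress a deep African/Eurasian history into a 1200-generation
timeline that drifts in minutes at desk scale.

`"ooa_bottleneck"`: one ancestral African population (N = 5000); the
Eurasian branch splits at generation 950 and spends its entire existence in
a bottleneck (N = 400), emulating a strong out-of-Africa founder effect at
the time of divergence. The realized donor/recipient heterozygosity ratio
is about 0.75.

`"chad_double_pulse"`: adds a large recipient population (N = 4000)
splitting from the African branch shortly before receiving an older small
Eurasian pulse (alpha = 0.1, 150 generations before sampling) and a younger
larger one (alpha = 0.2, 10 generations before sampling) — the
double-backflow structure inferred for northern-Chad populations.

The calibration of these presets deserves a note, because the two
heterozygosity properties they must exhibit pin the model into a narrow
window. Writing `r` for the donor/recipient heterozygosity ratio and
`delta` for the scaled squared frequency divergence
`E[(p_A - p_E)^2] / H_A`, the heterozygosity of a mixed genome is
`H(alpha)/H(0) = (1-alpha)^2 + alpha^2 r + 2 alpha (1-alpha) ((1+r)/2 +
delta)`. Segment ordering `H_AE >= H_AA` requires `delta >= (1-r)/2`,
while genome-wide decline at `alpha = 0.25` requires
`delta < (1-r) * 2/3` — a window of width `(1-r)/6`. The excess of `delta`
over `(1-r)/2` is, to first order, the African-branch heterozygosity loss
since the split, which fixes the African size at 5000 given the
250-generation branch. Empirical per-class segment rates reported for real
admixed Africans (1.23 / 1.19 / 0.96 hets/kb for AE / AA / EE) imply the
same near-marginality, so this narrowness is a property of the science,
not an artifact of the simulator.

## f-statistics

`f3(C; A, B)` averages `(c-a)(c-b) - c(1-c)/(n_c - 1)` over SNPs; the
subtraction unbiases the target's sampled heterozygosity, which is why the
target needs at least two chromosomes. A strongly negative value
(conventionally Z < -4) demonstrates admixture; a positive value does
*not* exclude it — post-admixture drift in small recipients overwhelms the
negative mixture term, a sensitivity loss the package reproduces on
simulated data (and the reason the LD-based test below exists).

`f4(A, B, C, D)` averages `(a-b)(c-d)`; `d_stat()` normalizes the same
numerator by `(w + x - 2wx)(y + z - 2yz)`, oriented so that
`D(W, chimp; Y, Z) > 0` iff W shares more derived alleles with Y.
`f4_ratio()` estimates a mixture proportion as a ratio of genome-wide f4
sums; it is deliberately not clamped to [0, 1], since sampling noise
legitimately pushes estimates outside. `supervised_admixture()` is the
likelihood counterpart: per individual it maximizes
`sum log Binomial(g | 2, alpha p_A + (1-alpha) p_B)` over `alpha` in
[0, 1] by bounded 1-D optimization (tolerance 1e-8), with reference
frequencies clamped to `[1e-6, 1 - 1e-6]`. On simulated individuals with
per-individual ancestry fractions the two estimators correlate above 0.98,
mirroring the near-perfect concordance reported on real data.

All genome-wide estimates are ratios of sums (not means of ratios), with
standard errors from a weighted delete-one-block jackknife (Busing's
variance formula), blocks being contiguous 5 cM windows when a genetic map
is attached and 500-SNP chunks otherwise. SNPs missing in any argument
population are deleted listwise per statistic. Only the f3 target
correction is applied; f4/D numerators carry no small-sample correction.

## Weighted-LD admixture dating

For SNP pairs at genetic distance `d` (Morgans), admixture `n` generations
ago leaves dosage covariance proportional to `exp(-n d)`. The curve
accumulates `cov(s, t) * w(s) * w(t)` with `w` the reference
allele-frequency contrast, into 0.1 cM bins between 0.5 and 30 cM
(defaults; the lower cutoff suppresses background LD, and the data-driven
cutoff selection of ALDER is intentionally out of scope). Cross-chromosome
pairs are not used; the affine offset is estimated in the fit instead of by
inter-chromosome subtraction.

`fit_decay()` fits `sum_j A_j exp(-n_j d) + c` by weighted nonlinear least
squares (weights = pair counts per bin, approximately inverse variance),
with multi-start initialization over a rate grid {5, 15, 45, 135, 400,
1200} generations. Uncertainty comes from leave-one-chromosome-out
refits — the jackknife unit is the chromosome because pairs within one are
dependent. `malder_scan()` fits k = 1..k_max and keeps the largest k whose
every amplitude is jackknife-significant (|Z| >= 2.58, two-sided p < 0.01);
k = 0 is a valid outcome and the null simulations select it. Dates convert
to years at 30 years per generation.

Two practical lessons from the package's own validation are worth
recording. First, unweighted fitting lets long-distance bins (many, nearly
flat) dominate and a two-pulse curve collapses into a single intermediate
exponential; pair-count weighting makes the true two-component solution the
global optimum. Second, resolving an old (n = 150) pulse under a young
(n = 10) one requires chromosomes long enough for the young component to
decay out within the fitted range — with 20 cM chromosomes the young
exponential is degenerate with the offset, with 50 cM chromosomes both
pulses are recovered. Multiple reference pairs are handled by running the
scan per pair and reporting each; no meta-combination across pairs is
attempted.

## PBS and the neutral post-admixture expectation

Per variant (or per window of variants, ratio-of-averages within the
window), Hudson's FST estimator is computed for the three population pairs
— numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
`p1(1-p2) + p2(1-p1)` — chosen for its robustness to unequal sample sizes.
Branch lengths are `T = -log(1 - FST)` with FST clamped into
[0, 0.999999] at the transform (negative per-SNP values are retained in
sums); `PBS = (T_fs + T_fo - T_so)/2`. A per-SNP pair with zero denominator
(both populations monomorphic) carries no differentiation and scores
FST = 0. Candidates are variants above the 95th percentile by default. An
optional normalization dividing each pairwise `T` by its genome-wide median
is available (off by default) as this package's own coarse long-term-size
adjustment; it is not the published correction, whose exact form is not
specified by the sources available here.

The interpretive half is `neutral_daf_after_admixture()`: with ancestry
fraction `alpha` from a source carrying a derived allele at `p_source`, the
expected frequency is just `alpha * p_source + (1 - alpha) * p_background`
— e.g. 0.30 x 0.13 = 3.9%. `drift_compatible()` then asks whether an
observed frequency is inside the central 95% interval of Wright–Fisher
drift (simulated forward, default 10,000 replicates) plus binomial
sampling. The acceptance suite reproduces the full logic: a donor-private
near-fixed allele introgressed at alpha = 0.3 lands above the scan's 95th
percentile while being fully explained by admixture plus drift.

## Local ancestry

Windows of 1 cM (genetic distance) are scored independently: reference
haplotypes of the two ancestries are projected onto the window's leading
two principal components, each ancestry summarized by a Gaussian
(ridge-regularized covariance), and each query haplotype assigned the
class posterior under equal priors. Only windows with posterior > 0.9 are
assigned — matching the stated collect-confident-windows usage — and a
full HMM smoother along the chromosome is an explicit non-goal. Diploid
classes (AA / AE / EE) require both haplotypes assigned; `unassigned`
windows are excluded from downstream segment-heterozygosity denominators.
On simulated admixed genomes, window-level accuracy of assigned calls
exceeds 99% and mask-implied ancestry fractions track the truth within
0.02. `apply_negative_mask()` blanks genotypes inside a chosen class —
e.g. removing Eurasian-Eurasian segments before coalescent-style analyses.

## Heterozygosity and ROH

`het_per_kb()` divides heterozygous calls by a mappable length — 2.17 Gb
by convention for real whole-genome data, the simulated length for
simulated panels. ROH are maximal runs of consecutive homozygous calls
spanning more than 2 Mb with at most 0 heterozygous interruptions
(both configurable); this run-based rule follows the simple
VCFtools-style convention rather than an HMM. `het_excluding_roh()`
removes ROH from both numerator and denominator, correcting for recent
inbreeding. `segment_het_by_ancestry()` pools hets and lengths per diploid
class across samples (length-weighted), and `het_admixture_experiment()`
runs the full simulation experiment: pulse at each `alpha`, ten
generations of random mating, mean per-individual heterozygosity. Strict
monotonicity in `alpha` is *not* expected — small admixture fractions can
transiently raise heterozygosity through between-population divergence —
but decline at `alpha >= 0.25` holds for the bottlenecked-donor preset.

## Y-chromosome dating

Under infinite sites, a binary derived-allele matrix determines a unique
perfect phylogeny; `build_perfect_phylogeny()` constructs it recursively
from nested derived tip sets and names the offending grouping when a site
pair fails the four-gamete test. This replaces maximum-likelihood tree
search, which is adequate because the rho statistic needs only topology
and branch mutation counts; for real data with recurrent mutation it is a
documented limitation. The ancestral state must be supplied (derived = 1),
e.g. by polarizing against an outgroup; there is no midpoint rooting.

`rho_age()` computes rho as the mean mutation count from a node to its
descendant tips (additive over children, asserted by test) and converts to
years as `rho / (mu L)` with the default rate 0.76e-9 per site per year
(95% CI 0.67e-9–0.86e-9). Three intervals are reported: sampling
(`SE^2 = rho / n_tips`, a star-tree approximation), rate (exact inversion
of the rate CI), and a combined interval adding relative half-widths in
quadrature. Tree-topology uncertainty is not covered. Terminal nodes date
to the present (rho = 0); their private mutation loads remain visible as
stem counts.

## Problem sizes and numerical choices

The validation suite runs entirely on synthetic data at sizes chosen to
make each signal measurable in minutes on one core: frequency-level checks
use 10–30 thousand independent SNPs with 25–50 diploids per population;
the single-pulse dating scenario uses N = 1000 diploids, 10 chromosomes of
20 Mb at 1 cM/Mb and 20,000 SNPs (decay-rate recovery within 25% at
n = 100); the double-pulse scenario uses 6 chromosomes of 50 Mb for the
reasons above; D-statistic calibration uses 100 replicates of 5000 SNPs;
rho calibration uses 200 replicates of 20-tip star trees. Optimizer
tolerances: 1e-8 for the supervised likelihood; nls.lm with up to 300
iterations and lower bounds A >= 0, n >= 1e-3 for decay fits, non-converged
starts discarded, an error raised only if every start fails.

## Limitations

Beyond the per-module notes above: QC filters apply globally (not per
population); the HWE test is the exact conditional test, a deliberate
choice in the 1e-6 tail regime where the chi-square approximation is
unreliable; merge harmonization drops strand-ambiguous A/T and C/G sites
rather than frequency-matching them; no phasing, imputation or PLINK-format
support; no coalescent machinery (MSMC-style inference is out of scope);
selection is not modeled in the simulator. Passing tests on this
simulator demonstrate correctness of the estimators under the stated
models, not robustness to artefacts real data carry (genotyping error,
phasing switch errors, background LD, ascertainment bias).
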