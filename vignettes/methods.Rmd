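---
title: "Methods: simulating and calibrating a transposable-element invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calibrating a transposable-element invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling assumptions, parameterization,
numerical choices, and limitations behind `teinvade`. The package
implements an individual-based forward simulator of a transposable-element
(TE) invasion into an experimental fly population, a multi-task
Gaussian-process (GP) surrogate for the simulator, and a calibration
pipeline that ranks parameter combinations against observed copy-number
trajectories and summarizes the inferred distribution of fitness effects
(DFE) of new insertions.

## The biological setting

A naive laboratory population is seeded from wild-collected isofemale
lines, some of which carry active TE copies. Over roughly 60 overlapping
generations the element spreads by transposition until host silencing —
modelled as the *trap model* of piRNA-cluster regulation — and purifying
selection against deleterious insertions halt the invasion, producing the
characteristic plateau in mean copy number. Two replicate invasions
("waves") differ in their founders: wave 1 founders carry few, strictly
heterozygous insertions (mean ~0.86 haploid copies); wave 2 founders carry
more, fully homozygous insertions (~6.92 copies).

## Model assumptions

**Genome.** Five chromosomes of 32.4 Mb each (162 Mb total), positions
continuous within each chromosome. A single piRNA cluster sits at the
high-coordinate end of every chromosome and occupies a fraction
`f_regulatory` of its length. Clusters are the only regulatory regions.

**Trap model.** An insertion landing in any cluster is neutral (`s = 0`)
and silences transposition of *all* copies in that individual's genome.
Silencing is genotype-based and re-evaluated every generation: offspring
are silenced if and only if they inherit at least one cluster insertion.
There is no maternal deposition or partial silencing.

**Transposition and excision.** In an unsilenced zygote, each copy
transposes with probability `u` per generation, independently; the copy
count used is the pre-transposition count (new insertions do not transpose
in the generation they arise). New sites are uniform over the genome,
resampled on collision with an occupied site. Each transposing copy is
excised from its donor site with probability `v` (0 by default).

**Fitness.** Each non-cluster insertion draws a selection coefficient
`s = -|s|` with `|s| ~ Beta(alpha, beta)`, fixed for the life of that
insertion and inherited with it. Fitness is multiplicative across loci:
a heterozygous insertion contributes `1 + h s` (default `h = 0.5`), a
homozygous one `1 + s`. Fitness is floored at `1e-9` so lethal homozygotes
do not produce zero-probability parents.

**Life cycle.** Discrete non-overlapping generations, constant census
`N = 1000`, obligate outcrossing. Each offspring draws two *distinct*
parents with probability proportional to fitness, receives one recombinant
gamete from each (crossovers Poisson with rate `4e-8` per bp per
generation; free assortment between chromosomes), and then undergoes
transposition/excision as a zygote.

**Founders.** 200 isofemale lines of 5 flies each; flies within a line are
isogenic. A line carries insertions with probability `p_carrier`; carrier
lines draw `Poisson(lambda)` insertion loci. Wave 1 places each locus on
one haplotype (heterozygous); wave 2 on both (homozygous). `lambda` is
solved so the expected population mean haploid copy number matches the
empirical initial values: `lambda = target / (p_carrier * 0.5)` for
heterozygous founders and `target / p_carrier` for homozygous ones.
Founder lines that happen to carry a cluster insertion start silenced.

## Parameters and bounds

The basic calibration space has five free parameters:

| parameter      | range        | meaning                                   |
|----------------|--------------|-------------------------------------------|
| `p_carrier`    | 0.15–0.5     | probability an isofemale line carries TEs |
| `f_regulatory` | 0.01–0.1     | genome fraction that is piRNA cluster     |
| `u`            | 0.15–0.5     | transposition probability per copy        |
| `alpha`        | 0.001–0.5    | Beta DFE shape 1                          |
| `beta`         | 10–20        | Beta DFE shape 2                          |

The extended space adds dominance `h` (0–1) and excision `v` (0–0.5).
Mean `|s|` is `alpha / (alpha + beta)`; with `beta >= 10` and small
`alpha` the DFE is strongly weighted toward weak effects.

## Efficacy classification

An insertion class is "effectively selected" when the product of the mean
selection pressure and the effective population size exceeds one. We use
the heterozygous pressure `h |s|` with `Ne = 221` (default), so the
neutrality threshold is `1 / (2 h Ne) ≈ 0.0113` on `|s|`. A parameter
combination is classified *effective* when its DFE mean `alpha/(alpha+beta)`
exceeds `1 / (2 h Ne) * ... ` — concretely, when
`mean|s| * 2 h Ne > 1`. `efficacy_config(Ne = 442)` provides the doubled-Ne
robustness setting. The *effectively neutral fraction* of a DFE is
`P(|s| < 1/(2 h Ne))`, and the mean of the selected tail conditions on
exceeding that threshold.

## Surrogate model

Running the simulator at every candidate parameter combination is too
expensive for a dense calibration grid, so we emulate the replicate-mean
copy number at the six evolved sampling generations of each wave with a
multi-task GP:

* **Inputs** are normalized to the unit cube using the design bounds.
* **Targets** are divided by a single global standard deviation (no
  centering), so the GP's zero prior mean corresponds to zero copies —
  predictions revert toward 0, not toward the data mean, away from the
  design. This deviates from per-task standardization deliberately: copy
  numbers are non-negative and anchored at 0.
* **Kernel**: product of a squared-exponential with automatic relevance
  determination over inputs and a rank-one-plus-diagonal task covariance
  `omega omega' + sigma^2 I` over the six generations, which captures the
  strong positive correlation between successive sampling times.
* **Noise model**: a learned iid observation-noise variance absorbs the
  Monte-Carlo error of the replicate-mean training targets, so the
  surrogate smooths rather than interpolates simulation noise.
* **Likelihood**: the Kronecker structure of the product kernel lets the
  exact marginal likelihood be evaluated from one eigendecomposition of the
  n-by-n input kernel and one of the 6-by-6 task kernel; the iid noise
  adds exactly to every joint eigenvalue.
* **Optimization**: Adam (learning rate 0.01) on the negative log marginal
  likelihood, gradients by central differences that reuse the input
  eigensystem for all parameters except the lengthscales. Training runs in
  rounds; after each round a snapshot is scored on a held-out validation
  set, and the snapshot with the lowest validation RMSE is kept. This
  guards against the occasional round where noisy finite-difference steps
  degrade the fit.

Training designs are Latin hypercubes (`lhs::randomLHS`) so every
one-dimensional projection is stratified.

## Calibration metric

For each wave the error of a candidate is the sum over evolved sampling
generations of the root-mean-square deviation between the surrogate
prediction and the replicate observations, normalized by the replicate
mean at that generation (NRMSE). The overall score is the sum over both
waves; candidates are ranked ascending with stable ties. Top-k ranges
(default k = 100) summarize the spread of well-fitting parameters, and
candidates are grouped by efficacy class before extracting per-group best
fits and DFE summaries.

## Synthetic data realism

`generate_pseudo_empirical()` produces observation tables with the exact
schema of the empirical data: both waves, 3 replicates, copy numbers at
the recorded generations ({0,10,20,30,40,50,60} for wave 1;
{0,10,15,20,25,30,60} for wave 2). Each replicate is an independent full
simulator run at the truth parameters — so replicate-to-replicate spread
reflects genuine drift and transposition stochasticity — plus
multiplicative Gaussian measurement noise with coefficient of variation
`cv` (default 5%), truncated at zero. Packaged anchor values
(`load_fixture()`) record the empirical initial copy numbers, plateau
height, and published DFE summaries used as test oracles.

## Desk-scale problem sizes

The package's own defaults are sized to run on one CPU core in minutes,
not hours; they are the package's choice for development and continuous
testing, and every driver accepts larger sizes for production runs:

* surrogate training: 150 design points with 8 simulator replicates each,
  50 validation points (per wave);
* calibration grid: 10,000 Latin-hypercube candidates;
* Monte-Carlo founder checks: ~100–120 initializations;
* plateau checks: 50 replicate invasions.

At these sizes a wave-1 training set takes roughly 4 minutes to simulate
and GP training a few seconds; held-out per-generation NRMSE within the
empirically relevant copy-number range (0–25 copies) is well under the
0.25 working tolerance.

## Numerical choices

* The simulator core is C++ (via Rcpp) with sorted-haplotype
  representations: fitness uses a two-pointer merge, cluster membership a
  binary search, and gamete formation copies whole chromosome segments
  between crossover breakpoints. All random numbers come from R's RNG, so
  `set.seed()` governs everything.
* Replicate and design-point seeds are drawn up front with
  `sample.int(.Machine$integer.max, ...)`, keeping each unit reproducible
  and independent of execution order.
* The GP adds `1e-6` jitter to the Kronecker eigenvalue products and
  clamps input-kernel eigenvalues at zero before combining them.
* `integrate()` with `rel.tol = 1e-6` computes the conditional mean of the
  selected DFE tail; all other DFE summaries are closed-form
  (`pbeta`/`qbeta`).

## Limitations

* The trap model is deliberately minimal: no maternal inheritance of
  silencing, no partial silencing, no cluster-specific strength, and no
  insertion-site preference outside uniform placement.
* Selection coefficients are independent across loci; no epistasis or
  ectopic-recombination cost that scales with copy number.
* The surrogate emulates the replicate *mean* only; the calibration
  treats simulator stochasticity as irreducible observation spread rather
  than modelling it explicitly.
* The GP's finite-difference gradients are slower and noisier than
  analytic ones; the snapshot/validation mechanism mitigates but does not
  eliminate this.
* Continuous insertion positions ignore chromatin context and real
  recombination-rate variation along chromosomes.
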