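---
title: "Methods: simulating and detecting seasonally fluctuating selection"
author: "flucsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting seasonally fluctuating selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flucsel)
```

# The model

`flucsel` simulates a single selected locus embedded in a recombining
neutral sequence in a diploid, randomly mating Wright--Fisher population
of constant size $N$. Time is divided into binary seasons of $g$
generations (default 10, never rescaled); generation 0 is the first
summer generation and the selected mutation enters at the beginning of
summer. Fitness at the selected locus depends on genotype and season:

| season | $\omega_{WW}$ | $\omega_{SW}$        | $\omega_{SS}$ |
|--------|---------------|----------------------|---------------|
| summer | $1$           | $1 + h_s s_s$        | $1 + s_s$     |
| winter | $1 + s_w$     | $1 + h_w s_w$        | $1$           |

where $S$ is the summer-favored (derived) allele and $W$ the
winter-favored (ancestral) allele. A dominance coefficient above one
half for the currently favored allele (reversal of dominance, e.g.
$h = 0.6$) stabilises the seasonal polymorphism. Comparison modes share
the same machinery: symmetric heterozygote advantage
($\omega = (1-s,\,1,\,1-s)$, season-independent), hard sweeps
($1,\,1+hs,\,1+s$ from a single de novo copy), soft sweeps (the same
fitness scheme fed by recurrent beneficial mutation at the selected
site), and neutrality.

The infinite-population recursion
$p' = \frac{p^2\omega_{SS} + p(1-p)\omega_{SW}}
{p^2\omega_{SS} + 2p(1-p)\omega_{SW} + (1-p)^2\omega_{WW}}$
(`deterministicUpdate()`) is used three ways: as the expectation oracle
for the stochastic engines, iterated to its limit cycle
(`limitCycle()`) to obtain deterministic amplitudes, and to define the
equilibrium frequency (0.5 in every symmetric case) used for
equilibrium detection.

# Simulation engines

Two engines share one seasonal fitness model. The **single-locus
engine** (`simulateTrajectory()`) propagates only the allele frequency:
each generation applies the deterministic selection update and samples
$2N$ gametes binomially. It is used for trajectory-level quantities
(amplitudes, hitting times, long-run means) where linked variation is
irrelevant, and makes the full $N = 10{,}000$, 100,000-generation
protocol cheap. The **sequence engine** (`runReplicate()`) is
individual-based: each offspring draws two parents with probability
proportional to fitness, each transmitted gamete receives
Poisson($rL$) crossovers at uniform positions and Poisson($\mu L$) new
neutral mutations under an infinite-sites model with continuous
coordinates on $[0, L)$, so position collisions have probability zero
and windows partition $[0, L)$ as 0-based half-open intervals.
Optional background selection adds deleterious mutations at rate
`deleteriousFraction * mu * L` per gamete with gamma-distributed
effects (mean magnitude 0.000133, shape 0.35, $h = 0.5$), composed
multiplicatively across loci.

Key procedural choices:

* **Burn-in.** A neutral forward burn-in of $10N$ generations (the
  conventional point at which neutral diversity has equilibrated to
  $4N\mu$ per bp) replaces an external coalescent burn-in, keeping the
  package self-contained; `runReplicate(initialPopulation=)` accepts an
  externally built population for users who prefer their own
  equilibrium input.
* **Restarts.** If the selected locus goes monomorphic before the end
  of the run (fluctuating selection and heterozygote advantage; loss
  only for hard sweeps), the forward phase restarts from the *stored*
  burn-in population with a fresh mutation placement, and the restart
  is counted. The cap is 1,000 restarts, after which the replicate
  aborts with a diagnostic.
* **Rescaling.** `scaleParameters()` implements the standard
  diffusion-scale rescaling (divide $N$ by $Q$; multiply $\mu$, $r$,
  $s$ by $Q$); the headline parameterisation ($N = 10^4$,
  $\mu = 10^{-7}$, $r = 10^{-6}$, $s \in \{0.1, 0.5, 1\}$) is a
  100-fold down-scaling of a *Drosophila*-like population of $10^6$.
  Season length is never scaled, since a season shorter than one
  generation cannot be represented.
* **Soft-sweep mutation rate.** The recurrent beneficial mutation rate
  at the selected site is exposed as `softSweepRate`; the default gives
  a population-scaled beneficial mutation rate
  $\theta_b = 4N \cdot \texttt{softSweepRate} = 2$, for which
  multiple-origin sweeps are the typical outcome. Fixation of the
  *trait* is declared when every individual carries beneficial alleles
  on both haplotypes while at least two origins segregate; a sweep that
  fixes from a single origin is flagged as hardened.
* **Amplitude.** The amplitude of fluctuation is the within-cycle range
  (max minus min) of the summer-allele frequency, averaged over the
  final 10 complete cycles. At the deterministic limit this equals the
  end-of-summer minus end-of-winter frequency. As a range statistic it
  carries a small ($O(1/N)$, about $10^{-3}$ at $N = 10^4$) upward
  drift bias relative to the deterministic limit cycle; this is
  invisible at the precision the amplitudes are reported to, but
  matters when comparing against the deterministic value at
  sub-$10^{-3}$ resolution.
* **Time to equilibrium.** Defined as the first generation at which the
  trajectory reaches the deterministic equilibrium frequency
  (first-hitting of 0.5 in the symmetric cases). For oscillating
  trajectories the first hit occurs on a summer upswing, so this
  definition yields systematically earlier times for fluctuating
  selection than an oscillation-stability criterion would; it is kept
  because it is parameter-free and deterministic to evaluate.

# Sampling scheme

With `equilibriumSampling = TRUE`, each replicate is sampled across one
full seasonal cycle at two timepoints: *early equilibrium*, the first
cycle boundary after the selected allele first reaches its equilibrium
frequency, and *long-term*, the final complete cycle of the run. Within
each sampled cycle, samples are taken at mid-summer, end of summer,
mid-winter and end of winter ("middle of season" is generation
$\lceil g/2 \rceil - 1$ within the season, "end" its last generation).
Neutral replicates, which have no equilibrium of their own, use a fixed
early pseudo-timepoint (generation 160, matching the average time
fluctuating selection needs to reach equilibrium) so that all classes
are sampled at comparable generations. Each sample is $n$ individuals
($2n$ phased haplotypes) with known ancestral states, exportable as
phased VCF (`writeHapVCF()` / `readHapVCF()`).

# Summary statistics

All statistics are computed in 10 kb windows (`windowStats()`):
segregating sites $S$; nucleotide diversity $\pi$ (mean pairwise
differences, reported per window, per-bp variant by division);
Watterson's $\theta_W = S/a_n$; Tajima's $D$ with the standard
$e_1/e_2$ normalisation ($\mathrm{NaN}$ at $S = 0$); the variance
(sample, $n-1$), skewness (population-moment $g_1$) and excess kurtosis
(population-moment $g_2 - 3$) of the unfolded site-frequency spectrum
-- the moment conventions mirror common scientific-computing defaults
and are asserted against hand-computed fixtures; the noncentral
deviation statistic
$\mathrm{NCD}(\mathrm{TF}) = \sqrt{\sum_i (p_i - \mathrm{TF})^2 / n}$
over minor-allele frequencies at target frequencies 0.5, 0.4 and 0.3;
and Garud's $H_1$, $H_2$, $H_{12}$, $H_{123}$ and $H_2/H_1$ over exact
haplotype patterns, plus the five most common haplotype frequencies.

The NCD is the outgroup-free variant: only within-population
minor-allele frequencies enter. The square root is included (the
original definition); since renderings of the formula sometimes omit
it, `ncd(root = FALSE)` exposes the mean-squared variant. Because NCD
correlates with $S$, `standardizeNCD()` standardises each window
against the neutral mean and standard deviation of its $S$-bin
(bin width 25, $\mathrm{bin} = \lfloor S/25 \rfloor$), built by
`neutralNCDReference()` from neutral replicates; windows falling in
$S$-bins unobserved under neutrality fall back to the nearest populated
bin with a warning, and a zero neutral standard deviation yields
$\mathrm{NaN}$. Empty windows yield $\mathrm{NaN}$ for every statistic,
never zero, so downstream aggregation can distinguish absence from
signal. Neutral replicate envelopes (5%, 50%, 95% quantiles, linear
interpolation between order statistics) come from
`neutralQuantiles()`.

# Comparing selection modes

`compareModes()` contrasts replicate distributions of one statistic at
the focal window across modes: Welch two-sample $t$-tests (the
pooled-variance Student variant is a toggle) for every mode pair, with
the Hochberg step-up adjustment applied within the family of all mode
pairs for that statistic, plus Cohen's
$d = (\bar{x}_a - \bar{x}_b)/s_{\mathrm{pooled}}$ and the normal
overlapping coefficient $\mathrm{OVL} = 2\Phi(-|d|/2)$ as the measure
of distributional overlap. The normal-OVL identity is used rather than
an empirical density overlap because it is deterministic given $d$ and
matches the conventional interpretation of Cohen's $d$; both groups
constant is resolved by convention ($d = 0$, overlap 1 for equal means;
infinite $d$, overlap 0 otherwise).

# The discriminant pipeline

`assembleFeatures()` builds replicate-by-feature matrices from windowed
statistics under four seasonal sampling designs: (1) central window at
the end of summer; (2) central, adjacent, and a distal window (250 kb
away at full scale; the offset is clamped to the available sequence at
reduced scale) at the end of summer; (3) central window at the end of
both seasons; (4) central window at the middle and end of summer. The
18 per-window statistics ($S$, $\pi$, $\theta_W$, $D$, three SFS
moments, basic and standardized NCD at three target frequencies, five
Garud statistics) define the feature set; class labels are `Neutral`,
`FS_early`, `FS_long`, `HA_early`, `HA_long`. Features containing
missing values are dropped with a warning rather than imputed.

Feature selection is greedy forward minimisation of Wilks'
$\Lambda = \det(W)/\det(T)$ (pooled within-class over total scatter;
features are standardised internally, which leaves $\Lambda$ unchanged
but stabilises the determinants). A candidate is admitted when the
partial-$F$ statistic
$F = (\Lambda_{\mathrm{old}}/\Lambda_{\mathrm{new}} - 1)
\frac{n - g - p}{g - 1}$ has $p \le$ `niveau` (default 0.05).
Candidates that would make the scatter singular are skipped; ties in
$\Lambda$ break lexicographically for determinism; if selection cannot
start at all because of collinearity, the NCD (TF = 0.5) features are
removed and selection restarts once (logged). The classifier itself is
a linear discriminant with class means, pooled within-class covariance
and priors proportional to training class frequencies (uniform under
the balanced design); prediction maximises the usual linear score.
Held-out evaluation (`evaluateLDA()`) reports the row-normalised
confusion matrix, per-class accuracies and their unweighted mean,
matching the 150-train / 50-test design at full scale
(`splitTrainTest(trainFraction = 0.75)`).

# Synthetic data and what the tests show

Two generators support testing without simulation.
`makeFixtureHaplotypes()` builds haplotype matrices with exactly
specified haplotype spectra, so every statistic is asserted against
hand-computed values. `makeSyntheticFeatureTable()` draws
class-conditional Gaussian features with shared covariance -- exactly
the generative model the discriminant assumes -- which provides
closed-form Bayes-accuracy oracles (e.g. $\Phi(1) \approx 0.8413$ for
two unit-variance classes at $\pm 1$) and feature-recovery checks.
These generators emulate the *statistical* structure the pipeline
assumes, not real data: no linkage between features, no
non-Gaussianity, no class imbalance. Passing them shows the inference
machinery is correct, not that real data satisfy its assumptions.

The end-to-end checks run the full pipeline at a reduced scale chosen
once for interactive use: $N = 200$, $L = 90$ kb (nine 10 kb windows,
selected site centred in window 5), $\mu = 10^{-6}$, $r = 10^{-6}$,
$10N$ burn-in, 2,000 selection generations, 50 sampled individuals, 50
replicates per mode (fluctuating $s = 0.5$, $h = 0.6$; heterozygote
advantage $s = 0.1$; neutral; plus 30 replicates at $s = 1$ for
footprint direction checks). The raised mutation rate keeps per-window
SNP counts informative at the shorter sequence length. At this scale
drift is stronger and linked footprints narrower relative to the
window grid than at full scale, so the pipeline checks are
*qualitative*: footprint directions (diversity trough, $H_1$ peak, the
early NCD peak inverting to a long-term trough) and sampling-scheme
orderings (end-of-both-seasons sampling best for early-equilibrium
fluctuating selection; the multi-window design best long-term). Scheme
accuracies are averaged over 20 repeated stratified 70/30 train/test
splits, because a single 15-replicate held-out set estimates per-class
accuracy with granularity $1/15$, too coarse to rank schemes. The
`paperScaleConfig()` preset reproduces the full study conditions
($N = 10^4$, 5 Mb, 100,000 generations) for users with the compute to
run them; `deskScaleConfig()` is intermediate.

# Known limitations

* Constant population size across seasons; no demography (bottlenecks,
  admixture), no overlapping generations, no multilocus seasonal
  architectures.
* The first-hitting equilibrium definition undervalues the
  stabilisation time of oscillating trajectories (see above);
  alternative stability criteria would need a tolerance parameter.
* Wilks-based forward selection admits a null feature whenever the
  minimum partial-$F$ p-value among noise candidates clears `niveau`;
  with many noise features the selected set can therefore slightly
  exceed the informative set. Recovery tests assert that the
  informative features are found first, which is the property the
  classifier depends on.
* The sequence engine keeps whole mutation lists per haplotype;
  memory and time grow with $\theta L$, which is what limits the
  default scale of the end-to-end checks.
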