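---
title: "Mapping QTL for Rubisco activation rate and dynamic photosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL for Rubisco activation rate and dynamic photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sunqtl)
```

## The problem

When a lower-canopy leaf is hit by a sunfleck — a step from moderate to
saturating light — net photosynthesis ($A$) does not jump to its new
steady state. For the first many minutes it is limited by two slow
processes: activation of Rubisco by its chaperone Rubisco activase, and
stomatal opening. The speed of Rubisco activation is a promising breeding
target: genotypes that activate faster waste less of each sunfleck.

`sunqtl` implements the full analysis chain needed to treat that speed as
a quantitative trait in a doubled-haploid (DH) mapping population:

1. estimate the apparent Rubisco activation rate $1/\tau$ (min$^{-1}$)
   from minute-by-minute gas-exchange induction curves;
2. map QTL for $1/\tau$ and for steady-state $A$ and stomatal conductance
   $g_s$ with a from-scratch composite interval mapping (CIM) scan;
3. quantify, in silico, how insufficient chamber equilibration (recording
   "steady-state" phenotypes at 5, 10 or 15 min into induction) degrades
   QTL detection.

Because suitable public raw data do not ship with the package, a
first-class synthetic-data module generates everything the analysis
consumes — genetic map, DH genotypes, trait architectures and
mechanistic induction curves — with known ("planted") truth, so every
stage is testable end to end.

## Estimating the activation rate

### Normalization

During induction, stomata open and intercellular CO$_2$ ($c_i$) drifts,
so raw $A$ confounds Rubisco activation with CO$_2$ supply. Below
roughly 300 µmol mol$^{-1}$ the Rubisco-limited $A$–$c_i$ relation is
well approximated by a straight line through the origin, so $A$ is
normalized to a common $c_i$ of 300 µmol mol$^{-1}$:

$$A^* = A \times \frac{300}{c_i}.$$

In the forward model below this is exact: the noiseless normalized rate
is $A^*(t) = 300\,k\,S(t)$, a function of the activation state alone,
whatever the stomata do. This is the estimator-consistency identity the
test suite checks by rescaling the whole stomatal trajectory and
verifying the estimate is unchanged.

### The windowed log-linear regression

If activation relaxes exponentially with rate $1/\tau$ toward the fully
induced rate $A^*_{max}$, then $\ln(A^*_{max} - A^*(t))$ is affine in
$t$ with slope $-1/\tau$. `estimate_activation_rate()`:

- drops the first 2 min (dominated by processes other than Rubisco
  activation, e.g. stromal pH transients);
- fits OLS on the base window 2–5 min (at least 3 usable points, else
  status `insufficient_points`);
- extends the window strictly in time order, one later point at a time,
  keeping a point only while the cumulative $R^2$ stays above 0.9, and
  stopping at the first failing point. A cumulative rule (rather than
  testing each point in isolation) makes the window deterministic and
  insensitive to noise later in the trace;
- reports `one_over_tau` $= -$slope, the window, $R^2$ and a status
  (`ok` requires $R^2 > 0.9$, $\ge 3$ points and a positive rate).

Two choices deserve comment:

**$A^*_{max}$ is a steady-window mean, not a raw maximum.** The raw
maximum of a noisy trace is inflated, and an inflated $A^*_{max}$ biases
$1/\tau$ downward. `detect_steady_state()` uses a rolling 5-min window
and declares steadiness when the window's OLS slope, relative to its
mean, stays below 1 %/min for both $A^*$ and $g_s$ (both tunable);
$A^*_{max}$, $A_{ss}$ and $g_{s,ss}$ are means over the final qualifying
window. If no window qualifies the curve is flagged `not_steady` and the
global maximum is used as a fallback.

**The regression never looks past steady-state onset.** Once induction
is complete, $A^*_{max} - A^*(t)$ is at the rounding/noise floor and its
logarithm is numerically meaningless; such points can distort the slope
while leaving the cumulative $R^2$ high (the log range is huge). The
window is therefore a subset of [2 min, steady-state onset].

On noiseless model curves this estimator recovers planted rates across
0.1–0.75 min$^{-1}$ to better than $10^{-6}$ relative — provided
$A^*_{max}$ itself has converged. The exactness checks use 300-min
traces so the steady-window mean sits within $\sim 10^{-12}$ of the true
asymptote; at the default 45-min duration the slowest rates
($1/\tau \approx 0.1$) carry a small finite-trace bias (a property of
short traces, not of the regression), which is one reason the per-leaf
estimates are noticeably noisier for slow genotypes.

### Derived phenotypes

`snapshot_phenotypes()` returns $A$ and $g_s$ at the record nearest 5,
10 and 15 min (ties to the earlier record; minutes beyond the trace give
missing values). `phenotype_table()` aggregates replicate leaves into
per-genotype medians (midpoint rule), and `population_summary()` gives
Min/Q25/Median/Q75/Max/Mean with linear-interpolation (type-7)
quantiles, so tabulated outputs are reproducible bit for bit.

## The synthetic study

`simulate_study()` generates the conditions the analysis assumes:

- **Map**: 7 chromosomes ("1H"–"7H") of 161 cM (1127 cM total), markers
  every 2.15 cM (~530 markers) — the dimensions of a typical barley DH
  map.
- **Genotypes**: 127 DH lines; per line and chromosome one simulated
  gamete: first marker Bernoulli(½), then a two-state Markov chain whose
  switch probability between adjacent markers is the Haldane
  recombination fraction $r = \tfrac12(1 - e^{-2d/100})$. Haldane (no
  interference) is chosen over Kosambi because it matches the Markov
  simulation exactly and keeps the interval-mapping conditional
  probabilities closed-form.
- **Trait architecture**: line-level kinetic parameters are
  `mu + sum(a x) + Normal(0, sd)` with $x = \pm 1$ at planted QTL,
  truncated to physiological ranges. The default plants seven QTL
  mirroring a realistic architecture: one activation-rate QTL on 7H and
  three QTL each for carboxylation efficiency (drives steady-state $A$;
  2H/4H/7H) and steady-state $g_s$ (2H/5H/7H), each sized to explain
  roughly 6–14 % of its trait's line-level variance. With the $\pm 1$
  coding, `a` is the half-difference of class means — the "additivity"
  convention of QTL tables. Activation rates are centred at 0.36
  min$^{-1}$ with SD 0.145 (clipped to 0.08–0.85), spanning the
  0.1–0.75 min$^{-1}$ range reported for such populations.
- **Curves**: activation state $S(t) = 1 - (1 - S_0)e^{-t/\tau}$;
  stomata $g_s(t) = g_{s,ss} + (g_{s,0} - g_{s,ss})e^{-t/\tau_g} -
  d\,(t/\tau_d)\,e^{1 - t/\tau_d}$ (the gamma pulse is the transient
  closing dip commonly seen after a light step; its shape is a modelling
  choice, as only the phenomenology is documented); CO$_2$ supply
  $(g_s/1.6)(c_a - c_i)$ and Rubisco-limited demand $k\,S\,c_i$ solved
  jointly, giving $c_i = c_a / (1 + 1.6\,k\,S/g_s)$ and $A = k\,S\,c_i$.
  Gaussian measurement noise (SD 0.3 µmol m$^{-2}$ s$^{-1}$ on $A$, 0.01
  mol m$^{-2}$ s$^{-1}$ on $g_s$) is added per record and $c_i$ is then
  recomputed from the noisy $A$ and $g_s$, as a gas analyser would derive
  it. Traces are logged once per minute for 45 min.

What the simulator does **not** emulate: instrument drift, leaf-to-leaf
area and temperature variation, mesophyll-conductance and
non-photochemical-quenching dynamics, segregation distortion,
genotyping error and epistasis. Passing tests therefore demonstrate the
correctness and statistical behaviour of the analysis under the stated
model, not the biology of any particular dataset.

## The genome scan

The scan engine is ordinary least squares on two genotype classes:

- `marker_lod()`: $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$, intercept-only
  versus marker model. Exact fits are capped at LOD 300 (documented).
- `im_scan()`: Haley–Knott regression — at every 1 cM grid position
  (marker positions are included in the grid) the unobserved DH genotype
  is replaced by $E[x \mid \text{flanking markers}]$ under the Haldane
  model. At a typed marker this expectation equals the observed call, so
  the scan collapses exactly onto the marker regression (checked to
  $10^{-9}$). Missing flanks fall back to the nearest typed markers, one
  side if need be, 0.5 with no information. For balanced two-class DH
  data Haley–Knott is near-identical to the full ML mixture while
  remaining deterministic and verifiable against closed forms, which is
  why the EM mixture is out of scope.
- `cim_scan()`: the same regression with background marker cofactors in
  both null and full models, excluding cofactors within 10 cM (map
  distance, same chromosome) of the tested position. Cofactors default
  to forward stepwise selection (partial $F$, $p < 0.05$, at most 5) —
  standard CIM model settings. With zero cofactors CIM reduces exactly
  to interval mapping.
- `permutation_threshold()`: phenotypes shuffled over lines, genome-wide
  maximum LOD recorded per permutation, threshold = the $1-\alpha$
  type-7 quantile (1000 permutations, $\alpha = 0.05$ by default). The
  permutation stream is seeded per scan and recorded in the result.
- QTL calling: local maxima at or above the threshold, plateau ties
  resolved to the leftmost position, peaks merged within 20 cM. Each QTL
  reports its nearest map marker, additivity (half the fitted class-mean
  difference, signed by the parent-B allele) and the percent phenotypic
  variance explained by the peak term given the active cofactors.

Before scanning, `thin_markers()` selects markers every 10 cM (greedy
left-to-right, chromosome ends retained) for even genome coverage.

Monte-Carlo behaviour at study scale (127 lines, one ~10 %-variance
QTL), as measured by the test suite and the acceptance script rather
than assumed: detection frequency well above the 5 % null rate with
median peak-position error of a few cM; additivity and explained
variance evaluated *at the planted position* are unbiased, whereas
summaries of *detected peaks* show the usual winner's-curse inflation —
the validation utilities report both. Null scans exceed their own
permutation threshold at close to the nominal 5 %.

## The equilibration experiment

`run_equilibration_experiment()` re-creates the equilibration-time
question in silico. The mechanism is planted, not assumed: stomatal
kinetics ($\tau_g$, the closing dip, the starting conductance) vary
between lines independently of the steady-state QTL, so a snapshot taken
$m$ minutes into induction reads the steady-state trait through a
genotype-structured attenuation. Earlier snapshots are attenuated more
and carry more kinetic nuisance variance, so the LOD at the planted QTL
should fall as $m$ decreases — which is what replicate simulations show,
with mean LOD increasing strictly across 5, 10, 15 min and steady
state.

One design point matters for comparability: cofactors are selected once,
on the steady-state trait, and reused for every snapshot scan, so LOD
differences across snapshot times reflect the phenotype and never a
change of background model. The report also tabulates the population
distribution per snapshot, the mean and maximum percent underestimation
relative to steady state ($100(1 - \bar{x}_m/\bar{x}_{ss})$), and flags
lines whose 5-min $g_s$ snapshot falls inside the simulated closing dip
(the dip is retained deliberately — it is part of the observed
phenomenology).

## Numerical choices and degenerate inputs

- Quantiles: type 7 (linear interpolation) everywhere.
- Steady-state tolerance: 1 %/min relative window slope, 5-min window;
  both configurable. Traces that never steady are flagged and fall back
  to the global maximum.
- Points with $A^* \ge A^*_{max}$ are dropped before the logarithm; if
  that empties the 2–5 min base window the fit is `insufficient_points`.
- LOD cap 300 for numerically zero residual variance; monomorphic
  markers give LOD 0 with a warning.
- Peak plateaus resolve leftmost; peak merging radius 20 cM.
- Genotype files are 0/1/missing; missing phenotype values propagate and
  the affected lines are dropped per scan.
- All simulation is `set.seed`-driven; identical config and seed give
  byte-identical outputs, which the run manifests (md5 inventories)
  make checkable.

## Problem sizes used by the validation suite

The test suite and the acceptance script size their Monte-Carlo
experiments to be decisive yet quick: 200 replicates for the null
(type-I) and recovery experiments with 200-permutation thresholds per
replicate, 50 replicate simulations for the equilibration ordering, 200
noisy curves for the estimator-bias check against an independent
grid-search oracle, and 300-min noiseless traces for the exactness
checks. These are the package's own choices of experiment size; larger
runs sharpen the Monte-Carlo error but do not change any conclusion.

## Known limitations

- $1/\tau$ is *apparent*: mesophyll conductance and NPQ dynamics are
  not separated from Rubisco activation, by design.
- Estimates for very fast genotypes ($1/\tau \gtrsim 0.7$) are noisy at
  1-min logging: induction is nearly complete within the base window,
  so the log-differences sit close to the noise floor.
- The scan supports DH populations only; F2/RIL generalization would
  change the conditional-probability and class structure and is a
  documented extension point, not implemented.
- Numerical equality with any particular published QTL table is not a
  contract: it would require the original genotype data, and published
  CIM results depend on unreported software model settings.
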