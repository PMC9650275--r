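---
title: "Methods: miRNA classifier circuit design and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA classifier circuit design and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircircuit)
```

This vignette documents the models, numerical choices, and design decisions
behind `mircircuit`, and what the synthetic-data tests do and do not
establish.

## The steady-state circuit model

The bow-tie circuit is a feed-forward cascade of four reactions, each
modeled as a non-cooperative Hill relationship: the miR_high input `m`
represses Act1 (survival fraction `1 − m/(IC50miR + m)`), Act1 drives
miR-FF4 (`FF4MAX · Act1/(KD1 + Act1)`), miR-FF4 represses Act2, and Act2
drives the output (`OutMAX · Act2/(KD2 + Act2)`). All quantities are in
molecules/cell. Because the cascade has no feedback, its steady state is
exact by sequential substitution — `steady_state()` does no ODE integration
and no iteration. The test suite nevertheless checks it against an
independent fixed-point iteration (to 10⁻¹⁰ relative error over 1,000
random parameter sets), so the closed form is never trusted on its own.

Default parameters are the optimized set used for all screens: IC50miR =
IC50FF4 = 20, KD1 = KD2 = 10,251, Act1MAX = Act2MAX = 9,755, FF4MAX =
3,000, OutMAX = 30,000 molecules/cell. The On state is simulated at
[miR] = 3,000 molecules/cell (high physiological) and the Off state at 0.
At these values the model gives Out(On) ≈ 9,875, Out(Off) ≈ 380, a dynamic
range of ≈ 26-fold.

Two compositions were genuinely open and are isolated behind
`steady_state()` for sensitivity analysis:

- **OR-gate aggregation.** miRNAs on the shared miR_high sensor are
  *summed* into one input concentration. The sensor's transcript carries
  fully complementary sites for each miRNA; independent sites acting on one
  transcript compose approximately additively at sub-saturating levels.
- **miR_low composition.** Multiple miR_low inputs repress Act2
  *multiplicatively*, each with the shared IC50miR. Independent target
  sites imply a product of survival fractions; one IC50 is used because
  only one endogenous-miRNA IC50 is parameterized.

MAX-type parameters may be zero (disconnected-branch limits, e.g.
FF4MAX = 0 gives an On/Off ratio of exactly 1); the Hill denominators
IC50miR, IC50FF4, KD1, KD2 must be strictly positive.

## Classification margin, AUC, and truth

Circuits are scored on a labeled expression matrix (positive = the target
state). With per-sample predicted outputs,

- **average margin** = log10(geometric mean of positive outputs /
  geometric mean of negative outputs);
- **worst margin** = log10 of the smallest positive/negative output ratio,
  i.e. log10(min(pos)/max(neg));
- **cMargin** = their arithmetic mean.

The margin scale is log10: a cMargin of 1.16 corresponds to 10^1.16 ≈ 14.4
fold change, which is the arithmetic that makes the two conventions
consistent. Aggregation by geometric means is the default because it is the
mean that is linear on the log scale where the margins live; an
arithmetic-mean variant is available (`search_config(aggregate =
"arithmetic")`) because the wording "overall ratio between outputs" does
not pin the choice down, and both are exercised in the acceptance suite.

AUC is the Mann–Whitney rank statistic (ties count ½), verified in tests
against a brute-force pairwise count. The per-sample **truth** value marks
outputs at or above the geometric midpoint √(gm_pos · gm_neg) — the
symmetric cut on the log scale; the prose definition ("above the
classification margin") names no explicit threshold, so the midpoint rule
is this package's choice. The comparison uses a 10⁻⁹ log-units tolerance so
outputs exactly at the midpoint count as true.

Outputs are floored at ε = 10⁻⁶ molecules/cell (with a warning) before any
ratio, preventing infinite margins; the steady-state model itself cannot
produce exact zeros with positive parameters, so the floor matters only for
degenerate parameter choices.

## The search

Candidates are prefiltered by role using the binarized matrix (threshold
t = 1% of each sample's total miRNA pool, so `ratio_over_t > 1` means
relevant): miR_high candidates must exceed t in *all* positive samples and
not in all negatives; miR_low candidates must exceed t in at least one
negative and in *no* positive. Enumeration is then exhaustive within
`max_total_inputs` and `max_inputs_per_gate`, with a hard cap (default
2·10⁵ topologies) that errors rather than silently truncating. Ranking is
by cMargin, then fewer inputs, then a smaller OR-gate — the last preferring
designs that avoid miR_high sensors, which are the harder part to build —
then lexicographic ids for determinism.

**Bootstrap pruning** removes inputs that do not significantly improve
cMargin: per input, class-stratified resampling of samples (default 200
replicates) yields a distribution of ΔcMargin (with vs without the input);
the input with the largest one-sided fraction of Δ ≤ 0 is removed when that
fraction exceeds α = 0.05, and the loop repeats. The resampling indices are
shared across candidate inputs within an iteration, the seed is mandatory,
and the result is deterministic for a given seed. These settings (200
reps, α = 0.05, stratified) are this package's defaults; the method is
named in the source literature without settings.

One subtlety the model forces: an input expressed at a *constant nonzero*
level in every sample is not a zero-contribution input. A constant miR_low
level rescales Act2 everywhere, but the saturating Out(Act2) curve
compresses high-Act2 samples less than low-Act2 ones, so margins shift.
Only an input at level 0 everywhere has exactly Δ = 0; the pruning tests
use that case.

## Cytometry formulas

Positivity thresholds are the 99.9th percentile (type-7 quantile) of a
fluorophore-negative control, so 99.9% of control events fall outside the
gate; positivity is *strictly above* the threshold (boundary events are
negative, consistent with a closed control region). rel.U. =
[mean(reporter in reporter⁺) × freq(reporter⁺)] / [the same for the
transfection marker]; note mean × frequency equals sum/total, which is how
the naive test oracle computes it. Frequencies are taken over the events
passed in, which are assumed pre-gated to live singlets — the formula
follows the live/single gating step, so live-gated frequencies are the
consistent reading. Viability is the product of the scatter-live fraction
and the stain-negative fraction, both over the full event set, exactly as
the formula composes them (0.5 × 0.5 = 0.25, not conditional). Means are
arithmetic on raw intensities; compensation is accepted as pre-applied.

## Colony metrics

Cells carry coordinates relative to the colony center; the normalized
radius is clipped to [0, 1] (a 1.2× tolerance admits edge scatter, beyond
which assignment is rejected). Bins are 20 equal-width annuli by default,
cell-weighted (per-bin mean of cell intensities, no annulus-area
correction — the reported quantity is the mean over *cells* in a bin).
Profiles are normalized so the highest radial mean = 1; the AUC is the
trapezoidal area above the profile's own minimum (each condition gets its
own baseline), with SE propagated in quadrature using the trapezoid
weights. Bins with no cells are dropped from the curve; bins with one cell
have no SE and contribute zero to the propagated error (flagged via
`se_complete`). Because the curve lives on bin *centers*, the AUC of a
linear ramp is (x_k − x_1)²/2 ≈ 0.475 at 40 bins, approaching the ideal 0.5
only in the fine-bin limit — tests assert the exact finite-bin value.

## What the synthetic generators emulate

`generate_expression()` plants marker miRNAs at stated copies/cell on a
log-normal background. Defaults are the stated world of the application:
4 positive (pluripotent) samples vs 15 negative (differentiated) states;
planted positive markers at 3,000 copies/cell — the physiological On
level — and absent in negatives; planted negative markers absent in
positives and high in subsets of negatives; background log-normal with
meanlog = log(5), sdlog = 1, placing the median background miRNA far below
the 1%-of-pool threshold so that, as in real data, a handful of miRNAs
dominates the pool; replicate noise CV 0.2, typical of miRNA-seq replicate
scatter. `synthetic_ev1_like()` wraps this into three partially overlapping
source datasets with alias names, replicates, and a hairpin record, so the
merge → average → search pipeline is exercised end to end.

What a green test establishes: that the implementation computes the stated
quantities correctly and recovers planted structure under log-normal noise.
What it does not establish: performance on real miRNA-seq data, which has
overdispersion, batch effects between sources, and correlated miRNA
families that the generator deliberately does not model. In particular, the
printed result on the real merged dataset — a 3-input circuit
({miR-302a | miR-375, miR-489}) with cMargin 1.16 (≈ 14.4-fold) — cannot
be reproduced here because that dataset ships as a publication supplement,
not with this package; the synthetic stand-in checks topology recovery
under the same constraints, and the log10 convention check (10^1.16 ≈ 14.45
vs 14.4) is kept exact.

Cytometry fixtures are two-population log-normal mixtures per channel
(transfected vs untransfected), with an analytic closed form for the
implied rel.U. (`implied_relative_units()`, via the log-normal partial
expectation) serving as an independent oracle. Colony fixtures sample cells
uniformly over the disc (r = R√u) with intensity = f(r/R) + Gaussian noise
for named shapes (flat, edge-high, center-high, ring), with the true f
stored in the manifest.

All generators run on a private RNG stream seeded from the spec and restore
the caller's `.Random.seed`: the same spec yields byte-identical output,
and generation never perturbs user code.

## Known limitations

- No dynamic or stochastic simulation; the model is steady-state only, and
  resource competition between circuit plasmids is not modeled.
- Merging unifies by *exact* mature-sequence identity (after U→T
  uppercasing); isomiRs or single-nucleotide variants remain separate
  columns. Unified records are summed, not averaged — they are the same
  mature species counted under different names; the alternative is not
  implemented.
- The exhaustive search is exact but exponential in the candidate pool;
  the prefilter is what keeps it tractable, and a pool too large for the
  cap is an error, not a heuristic fallback.
- miSFIT tuners are consumed as repression factors from a configuration
  table; predicting repression from target-site sequence is out of scope.
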