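---
title: "Models and methods for spore germination, inactivation and homolog census analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for spore germination, inactivation and homolog census analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporekinetics)
```

# Scope

`sporekinetics` analyzes four quantitative readouts used to phenotype
bacterial spores, together with a synthetic-data generator that provides
ground truth for every stage:

1. **Single-spore germination kinetics** from phase-contrast time-lapse
   imaging: spore detection, 20 x 20-pixel mean-intensity traces,
   endpoint normalization, and changepoint fitting of Tlag, Trelease and
   Tlys.
2. **Population germination** from Tb-DPA fluorescence curves: maximum
   germination rate, release extent, optimal heat-activation selection,
   and relative CaDPA content per spore.
3. **Wet-heat survival** from serial-dilution spotting: viable-titer
   reconstruction and log-linear (D-value) inactivation fits.
4. **Duf421-family census**: global pairwise alignment to reference
   prototypes and length-based classification into YetF-like and
   2Duf-like groups.

# The four-phase intensity model

A germinating spore's phase-contrast image intensity, normalized to 1 at
the first frame and 0 at the end, is modeled as continuous and
piecewise-linear in four phases:

* **Lag** (`0 <= t < Tlag`): slow linear decay `1 - leak_slope * t`,
  reflecting limited CaDPA leakage before rapid release; the value at the
  end of the lag is `Ilag`.
* **Rapid CaDPA release** (`Tlag <= t < Trelease`): steep linear drop
  from `Ilag` to `Irelease`.
* **Cortex lysis** (`Trelease <= t < Tlys`): slower linear decay from
  `Irelease` to 0.
* **Post-lysis** (`t >= Tlys`): constant 0.

The literature describes the three phases without committing to a
functional form; we use linear segments because they make the fitting
problem exactly solvable and the synthetic ground truth analytic.  Time
is measured in minutes from the first frame, frames are 0-indexed, and
frame `k` corresponds to `t = k * frame_interval` (default 0.25 min,
i.e. one frame per 15 s).

## Fitting: constrained changepoint search

For a fixed breakpoint triple `(b1, b2, b3)` the model is **linear** in
`(Ilag, Irelease)` (the endpoint at 1 and the zero tail are fixed), so
the profiled sum of squared errors is a 2-parameter convex quadratic
program with three linear constraints:

* `Ilag <= 1` — the lag slope is non-positive;
* `Irelease >= 0` — the lysis segment decreases to zero;
* the release slope is at least `steepness_factor` (default 3) times the
  lag slope — without this, on noisy traces the leak phase can absorb
  the release phase.

The QP is solved in closed form by enumerating the unconstrained
optimum, the single-constraint optima and the constraint vertices.  All
segment sums are evaluated from prefix sums (O(1) per triple, in C++),
so **exhaustive enumeration of all ordered triples is cheap**: the
fitter enumerates exhaustively for traces up to 60 frames and switches
to a coarse grid (every `coarse_step = 4` frames) with exhaustive
refinement within one coarse step for longer traces.  Ties in SSE break
toward the lexicographically smallest triple.  No sub-frame
interpolation is attempted, so recovered times are accurate to one frame
interval at best.

A spore is called **germinated** when the piecewise fit improves on the
best unconstrained single-line fit by at least `min_improvement = 0.5`
(relative SSE reduction).  Upstream of the fit, a trace is only
normalized (and hence fitted) if its fractional intensity drop reaches
`drop_fraction_threshold = 0.4`; flat traces from dormant spores are
retained unnormalized for the population germinated fraction, because
forcing a zero endpoint onto a flat trace would fabricate a release
event.  The endpoint is the mean of the last `tail_frames = 4` frames
rather than the single last frame, to reduce noise sensitivity.

Reported durations follow the standard definitions: `delta_t_release =
Trelease - Tlag` (the duration of rapid CaDPA release, reported as a
positive interval) and `delta_t_lys = Tlys - Trelease`.  `Ilag` and
`Irelease` are the fitted model values at the breakpoints, not the raw
trace values; on noise-free data the two coincide.

# Spore detection and trace extraction

Detection operates on the first frame: Gaussian smoothing
(`smoothing_sd = 2` px), then local maxima above
`median + threshold_k * MAD` (MAD scaled by 1.4826 to estimate the
standard deviation robustly).  `threshold_k = 6` by default: a megapixel
frame contains tens of thousands of local noise maxima, and a 5-sigma
cut admits a few of them per frame while 6 sigma keeps the expected
number well below one; genuine spore peaks sit at ~30 sigma at the
default contrast.  Maxima closer than `min_separation = 20` px are
resolved toward the brighter peak, with exact ties broken toward the
smaller `(y, x)`.  The intensity trace is the arithmetic mean of the
half-open 20 x 20-pixel window `[x-10, x+10) x [y-10, y+10)`; an even
window has no center pixel, so the window is anchored this way on the
integer center.  Windows crossing the frame edge are discarded and
counted.  No drift or flat-field correction is applied (spores are
immobilized on the coverslip in this assay).

# The synthetic-data generator

The generator is the package's source of ground truth, and its defaults
define the simulated study conditions:

* **Population**: 300 spores per field (the typical number followed in
  one experiment), 90% germinating; non-germination is an explicit
  Bernoulli mixture.
* **Lag times**: lognormal, `meanlog = log(10)`, `sdlog = 0.3` minutes.
  No empirical distribution family for Tlag is established; lognormal is
  a modeling choice giving the right-skewed heterogeneity seen between
  individual spores.
* **Rapid release duration**: lognormal around ~1.2 min
  (`sdlog = 0.2`); **cortex lysis duration**: lognormal around ~7 min
  (`sdlog = 0.25`); **Irelease**: uniform in 0.40-0.55.  These are
  chosen jointly so that the release segment is steeper than the lysis
  segment by a factor of ~2 at worst and ~6 typically across the sampled
  range.  This is a structural requirement, not a convenience: a spore
  whose release and lysis slopes are collinear has no identifiable
  Trelease under any fitting method, because "rapid release" and
  "lysis" are then the same line.
* **Leak slope**: uniform in 0.001-0.005 normalized units/min, capped so
  that less than the full CaDPA store leaks during the lag.
* **Imaging**: 1340 x 1024-pixel 12-bit frames every 15 s; spores are
  hard discs of radius 4 px with amplitude 3000 counts over a background
  of 100, placed by dart throwing with pairwise separation >= 20 px so
  that analysis windows never overlap.  The background/amplitude pair is
  set so a germinating spore's windowed mean-intensity drop fraction
  (~0.79) clearly exceeds the 0.4 candidate threshold, as it does in
  real phase-contrast data where germination is obvious by eye.  Discs
  are deliberately not PSF-convolved: detection difficulty is tuned via
  `noise_sd` instead, keeping the center-pixel trace exactly equal to
  the analytic model (a property the test suite checks to machine
  precision).

What the generator does **not** emulate: optical point-spread functions
and defocus, stage drift, illumination gradients, spore-to-spore shape
variation, CaDPA re-uptake, and correlated (non-Gaussian) camera noise.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not robustness to every artifact of real microscopy.

Every generator is a pure function of its parameters and a seed: the
RNG state is restored after each call, and identical seeds give
identical outputs.

# Population germination curves

The plate-reader model superposes single-spore release schedules: spore
`i` contributes `total_signal / n` RFU when fully released, following
the same lag/leak/release timing as its intensity trace (lysis moves no
CaDPA, so the released fraction saturates at Trelease).  The expected
plateau is `baseline + total_signal * frac_germinating`, and the
boiled-control reading (`total_cadpa_signal`) corresponds to complete
release.

"Germination rate" is operationalized as the maximum slope of the
smoothed, baseline-subtracted curve; smoothing is a centered moving
average (default 5 readings), which preserves the slope of linear
segments exactly, and slopes are centered finite differences.  The
plateau is the mean of the final 10% of readings, and the release
extent is the plateau signal as a percentage of the total CaDPA signal.
Extent is invariant to any common rescaling of RFU units.  Whether real
instrument curves are blank-subtracted before plotting varies between
labs; here the baseline is always carried explicitly and subtracted
inside the metric computations.  Optimal heat activation is the
activation time whose curve has the greatest maximum rate, with ties
resolved toward the shorter activation (less risk of heat damage).

Relative CaDPA content divides the boil-release fluorescence (blank
subtracted) by the microscopically counted spore number and expresses
the result relative to a reference strain set at 100.

# Survival analysis

Viable titers are reconstructed from dilution-spot counts: replicate
counts are averaged, and the most dilute dilution whose mean falls in
the countable window of 3-30 colonies per 10 uL spot is used
(`titer = mean * 10^dilution / spot_volume`).  The window is a
practical plate-counting convention (below ~3 colonies Poisson noise
dominates; above ~30 colonies per spot crowding biases counts) and is
configurable.  When no dilution qualifies the closest one is used and
flagged; all-zero tables report the detection limit
(`1 colony * 10^min_dilution / spot_volume`) and are excluded from
fits.

Inactivation is summarized by a least-squares line through
`log10(titer)` versus time: `D = -1/slope` is the decimal reduction
time and `k = ln(10)/D` the first-order rate constant.  Only the strict
log-linear model is fitted; shoulders and tailing (Weibull,
log-logistic) are out of scope.  A non-negative slope reports an
infinite D with a `no_killing` flag rather than an error.  The
synthetic counts are Poisson draws around
`N(t) = n0 * 10^(-t/D) * volume * 10^(-dilution)`, so the table's
analytic means decrease exactly 10-fold per dilution step and per D
minutes of treatment — the conservation law the tests verify.

# Homolog census

The census classifies Duf421-family proteins by **length**: YetF-like
proteins carry only the Duf421 domain (210-253 residues across known
homologs), 2Duf-like proteins add a Duf1657 domain (285-290 residues).
The two ranges are configurable per taxon and must not overlap;
everything else is unclassified.

Identity and coverage come from a self-contained global pairwise aligner
(Needleman-Wunsch/Gotoh, affine gaps, BLOSUM62 from Biostrings, gap
open 10 / extend 0.5) rather than an external search server, so the
pipeline runs with no network or databases.  Two conventions matter:

* the **identity denominator excludes terminal-gap columns** — aligning
  a 231-residue Duf421 protein to a 286-residue 2Duf would otherwise be
  deflated mechanically by the 55-residue C-terminal extension;
* the traceback is deterministic (ties prefer diagonal, then vertical,
  then horizontal), so results are reproducible across platforms.

Because the aligner and its parameters differ from any particular
published pipeline, absolute identity values are parameter-dependent
and are validated against invariants (symmetry, self-identity 100%,
brute-force score enumeration in linear-gap mode) rather than against
published tables.

Hit filtering follows the standard practice for such surveys: with an
external E-value table, `E < 1e-30` and query coverage `> 85%`; without
one, coverage `> 85%` and identity above a configurable floor (default
20%, just below the weakest known family members).  The best hit per
species and query is the most significant (numerically smallest)
E-value; survey write-ups sometimes phrase this as the "highest"
E-value, and a `literal_max` switch is provided for that reading,
defaulting to most-significant.  The embedded YetF/2Duf prototype
sequences are **synthetic** (fixed random strings with the right domain
architecture and lengths, the 2Duf prototype sharing its Duf421 region
with the YetF prototype at ~30% identity); they support controlled
round-trip experiments, not biological inference.

# Numerical choices and degenerate inputs

* Breakpoint search requires at least 8 frames; shorter traces error.
* `I0 = Iend` exactly (a perfectly flat trace) is flagged non-candidate
  without dividing.
* SSE values are clamped at 0 to absorb floating-point cancellation in
  the prefix-sum algebra; the test suite checks the prefix-sum SSE
  against direct model evaluation to 1e-8.
* A singular QP Gram matrix (not reachable for valid breakpoints, since
  each segment contains at least one interior frame) falls back to the
  constraint-boundary candidates, among which `(Ilag, Irelease) = (1, 1)`
  is always feasible.
* `titer_from_spots` demands non-negative integer counts; `fit_decay`
  requires three positive, detectable titers.
* Alignment rejects residues outside the 20-letter alphabet plus X.

# Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations to the
study's own scale: 200 random traces for the enumeration-equivalence
check, 50 rendered spores for noise-free recovery, 300 spores (one
time-lapse field) for noisy recovery and classification, one full
1340 x 1024 frame with 100 spores for detection, 500 spores for the
plate-curve extent, 100 simulated killing experiments at D = 5 min, all
two-letter sequence pairs up to length 6 for the alignment oracle, and
a 36/20/10 protein set mirroring the published census group sizes.

# Known limitations

* Breakpoint times are frame-quantized; parameters varying faster than
  the 15-s frame interval are not resolvable.
* The germination call is a relative-SSE heuristic; traces that drop
  almost linearly from start to finish (no distinct phases) may be
  called non-germinated even if intensity fell.
* The log-linear survival model cannot represent shoulders or tails; D
  estimates from such data would be biased by design.
* The census never computes E-values; when no hit table is supplied the
  identity/coverage filter is a proxy, not a significance test.
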