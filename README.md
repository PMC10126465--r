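# sporekinetics

Quantitative analysis of bacterial spore phenotyping assays, built for
studies of spore germination and resistance (e.g. comparing wild-type
*Bacillus subtilis* spores with mutants lacking inner-membrane proteins
of the Duf421 family such as YetF, YdfS or 2Duf).

The package covers four readouts, each with a synthetic-data generator
that provides exact ground truth, so every analysis stage is verifiable
without any external data:

* **Single-spore germination kinetics.** Spores are located in the
  first frame of a phase-contrast time-lapse, the mean intensity of a
  20 × 20-pixel window is traced over time, normalized to 1 at the first
  frame and 0 at the end, and fitted with a continuous four-phase
  piecewise-linear model. The breakpoints are the classic kinetic
  parameters: T<sub>lag</sub> (onset of rapid CaDPA release),
  T<sub>release</sub> (release complete) and T<sub>lys</sub> (cortex
  lysis complete), with derived intervals ΔT<sub>release</sub> =
  T<sub>release</sub> − T<sub>lag</sub> and ΔT<sub>lys</sub> =
  T<sub>lys</sub> − T<sub>release</sub>, and intensities I<sub>lag</sub>
  and I<sub>release</sub> at the first two breakpoints. For fixed
  breakpoints the profiled SSE is a closed-form constrained quadratic
  program, so the breakpoint search is exact (exhaustive for short
  traces, coarse-grid plus exhaustive refinement for long ones).
* **Population germination** from Tb³⁺–DPA fluorescence curves:
  maximum germination rate (maximum smoothed slope), release extent as a
  percentage of the boiled-control CaDPA signal, optimal heat-activation
  selection, and relative CaDPA content per spore normalized to a
  reference strain (= 100).
* **Wet-heat survival** from serial 10-fold dilution spotting: viable
  titers from counts in the 3–30-colony window
  (titer = mean count · 10^dilution / volume), then a log-linear
  inactivation fit giving the decimal reduction time D = −1/slope and
  rate constant k = ln(10)/D.
* **Duf421 homolog census**: a self-contained global pairwise aligner
  (Needleman–Wunsch/Gotoh, BLOSUM62, affine gaps) provides percent
  identity and query coverage against YetF/2Duf prototypes, and
  proteins are classified by length — YetF-like (Duf421 only, 210–253
  aa) versus 2Duf-like (Duf421 + Duf1657, 285–290 aa) — with per-species
  counts and best-hit selection under the standard E-value < 1e−30,
  coverage > 85% filter.

## Worked example

Simulate one time-lapse field, detect the spores, fit every trace and
summarize the population; then a killing experiment and a census:

```r
library(sporekinetics)

im    <- imaging_params(width = 350, height = 350, duration = 50, noise_sd = 120)
truth <- generate_truth(population_params(n_spores = 40, seed = 11), im)
rs    <- render_stack(truth, im, seed = 12)

rois   <- detect_spores(rs$stack$frames[, , 1])   # 40 detections
traces <- extract_traces(rs$stack, rois)
kin    <- fit_population(traces)
summarize_population(kin, (0:200) * 0.25)
#> population_summary: 38 of 40 spores germinated (95.0%)
#>        parameter       mean         sd
#>            t_lag  9.8026316 2.28771535
#>        t_release 11.0526316 2.27364297
#>            t_lys 18.5131579 2.79837511
#>  delta_t_release  1.2500000 0.28474740
#>      delta_t_lys  7.4605263 1.91325949
#>            i_lag  0.9679903 0.02337928
#>        i_release  0.4665577 0.04293079

tab <- generate_survival_counts(n0 = 1e8, d_value = 5,
                                times = seq(0, 25, 5), dilutions = 0:6,
                                seed = 1)
analyze_survival(tab)$fit
#> decay_fit: D = 5.11 min (k = 0.45 /min) from 6 points

ps <- generate_protein_set(36, 20, 10, seed = 1)
census(call_homologs(ps))
#> homolog_census: 36 YetF-like, 20 2Duf-like, 10 unclassified across 66 species
```

Reading the output: 38 of the 40 simulated spores germinated (the
generator's default germinating fraction is 0.9, so 36/40 expected; 38
germinated in this draw and all were called correctly). Mean
T<sub>lag</sub> ≈ 9.8 min matches the generator's lognormal lag around
10 min; rapid CaDPA release lasts ≈ 1.25 min, cortex lysis ≈ 7.5 min.
The killing simulation with a true D of 5 min is recovered as 5.11 min
from Poisson-noisy duplicate spot counts, and the census recovers the
36/20/10 class composition exactly.

The methods, model assumptions and parameter choices are documented in
`vignettes/spore-phenotyping-methods.Rmd`.

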