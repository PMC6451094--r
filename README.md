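# spfret

Single-pair FRET (spFRET) TIRF trace analysis and simulation in R.

## What problem this solves

Single-pair FRET on a TIRF microscope watches individual surface-immobilized
protein–DNA complexes: a donor/acceptor dye pair reports conformational
states through the FRET efficiency E, molecule by molecule and frame by
frame. Turning such movies into numbers requires a chain of steps — channel
registration from bead images, spot detection and aperture photometry,
per-molecule crosstalk (α) and detection-efficiency (γ) corrections from
acceptor-photobleaching steps, Gaussian-mixture fits of FRET histograms,
per-molecule hidden Markov models with transition-density-plot (TDP)
kinetics, and photobleaching-corrected survival analysis of molecule
disappearance times. spfret implements that pipeline for R users
(biophysicists and quantitative biologists analyzing smFRET TIRF data),
together with a ground-truthed synthetic-data generator that emulates the
raw measurements, so every stage is testable without any instrument.

The package was built around the analysis of TBP–promoter-DNA complexes and
their remodeling by the ATPase Mot1: conformational states of the DNA/TBP
complex before and after Mot1 binding and ATP addition, two DNA/TBP
subpopulations attributed to the two TBP binding orientations, and
Mot1/ATP-dependent TBP dissociation kinetics. Reference parameter sets for
those conditions ship as simulation presets (`tbp_molwise_states()`,
`tbp_framewise_states()`, `tbp_dissociation_rates()`).

## The core quantities

* Corrected FRET efficiency per frame:
  `E = (I_A − α(I_D − b_D) − b_A) / (I_A − α(I_D − b_D) − b_A + γ(I_D − b_D))`,
  with α and γ estimated per molecule from acceptor-first bleach steps.
* FRET histograms (molecule-wise or frame-wise) fitted with constrained
  Gaussian mixtures `Σ A_i N(μ_i, σ_i)`, including a global amplitude-only
  fit with fixed peak positions/widths across conditions.
* Per-molecule 3-state Gaussian-emission HMMs (Baum–Welch, convergence
  |ΔlogL| < 1e-9), Viterbi state paths, TDPs as superposed fixed-width 2D
  Gaussians, gated subpopulation assignment, and mono-exponential dwell-time
  rates with the discretization correction `k = −ln(p_stay)/Δt`.
* Dissociation kinetics from paired survival experiments fitted with
  `f(t) = e^{−kt}` (amplitude fixed at 1): the photobleaching-corrected
  dissociation rate is `k₂ − k₁` (treatment minus control), with a
  molecule-bootstrap standard error.

## Worked example

Simulate 2,000 molecule-wise FRET values for pre-assembled DNA/TBP/Mot1
ternary complexes and fit a three-component mixture:

```r
library(spfret)
library(dplyr)

comps  <- filter(tbp_molwise_states(), condition == "dna_tbp_mot1")
values <- sim_molecule_fret(comps, n = 2000, seed = 7)
hist   <- fret_histogram(values$e_mol, mode = "molecule_wise")
fit    <- fit_fret_mixture(hist, n_components = 3)
tidy(fit)
#> # A tibble: 3 × 4
#>   component  area  mean     sd
#>       <int> <dbl> <dbl>  <dbl>
#> 1         1  7.58 0.241 0.0330
#> 2         2 27.0  0.335 0.128
#> 3         3 65.4  0.783 0.0717
glance(fit)$r_squared
#> [1] 0.986
```

The fit recovers the three conformational populations of the ternary
complex: a small low-FRET population near E ≈ 0.24, the intermediate
population near 0.34, and 65% of complexes in the Mot1-induced high-FRET
state near 0.78, with R² above 0.98. `autoplot(fit)` overlays the fitted
components on the histogram.

A paired survival experiment (500 molecules per arm, photobleaching
0.10 s⁻¹, dissociation 0.05 s⁻¹ in the treatment arm) and its
photobleaching-corrected rate:

```r
ex  <- sim_survival_experiment(survival_config(
  n_molecules = 500, bleach_rate = 0.10, dissociation_rate = 0.05,
  frame_time = 0.03, n_frames = 4000, seed = 7))
res <- dissociation_rate(
  build_survival(filter(ex$data, arm == "control"),   frame_time = 0.03),
  build_survival(filter(ex$data, arm == "treatment"), frame_time = 0.03),
  condition = "1 mM ATP + 3.4 nM Mot1")
res[, c("k1", "k2", "rate", "se")]
#> # A tibble: 1 × 4
#>       k1    k2   rate      se
#>    <dbl> <dbl>  <dbl>   <dbl>
#> 1 0.0983 0.148 0.0497 0.00863
```

`rate` is the excess decay of the treatment arm over its own-experiment
photobleaching control: here 0.050 ± 0.009 s⁻¹ against a simulated truth
of 0.05 s⁻¹.

End-to-end runs (simulate → correct → classify → histogram fit) are driven
by `run_pipeline()` with a YAML-able config; see `default_run_config()`.

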