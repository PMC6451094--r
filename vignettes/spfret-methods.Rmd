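---
title: "Models and methods behind spfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spfret)
library(dplyr)
```

spfret analyzes single-pair FRET (spFRET) time traces of surface-immobilized
protein–DNA complexes recorded on a dual-view TIRF microscope, and ships a
synthetic-data generator that emulates such recordings so that every stage of
the analysis can be validated against known ground truth. This vignette
explains the underlying models, the tunable parameters and their defaults,
the numerical choices, and what the package's tests do and do not establish
about real data.

## The measurement being emulated

A donor and an acceptor fluorophore report on the conformation of individual
TBP–promoter-DNA complexes: the apparent FRET efficiency
$E = I_A / (I_A + \gamma I_D)$ rises as DNA bending or protein binding brings
the dyes closer. Movies are recorded at frame times of 15–300 ms on an EMCCD
whose chip is split into a donor and an acceptor half; molecules appear as
diffraction-limited spots, and each spot yields a two-channel intensity trace
until one fluorophore photobleaches in a single step.

Three complications shape the entire pipeline:

* **Spectral crosstalk** — a fraction $\alpha$ of donor photons is detected
  in the acceptor channel.
* **Unequal detection efficiencies** — the factor $\gamma$ balances the two
  channels in the FRET formula.
* **Photobleaching** — truncates each trace; an *acceptor-first* bleach is
  informative, because the donor then reports the full photon budget and the
  step heights yield per-molecule $\alpha$ and $\gamma$.

## The synthetic-data generator

`sim_config()` + `sim_traces()` implement a hierarchical forward model:

1. **Hidden states.** Each molecule follows a discrete Markov chain over
   conformational states with a row-stochastic per-frame switch matrix; the
   initial state is drawn from the chain's stationary distribution. Static
   molecules (fraction `static_fraction`) occupy one state for the whole
   trace. `linear_chain_matrix()` builds the chain in which the outer states
   exchange only via the intermediate state, the topology observed for
   dynamic dual-labeled promoter DNA.
2. **Emission.** The apparent efficiency of frame $t$ is drawn i.i.d. from
   the occupied state's Gaussian $(\mu, \sigma)$. This reproduces the
   Gaussian FRET populations the histogram fits assume without modelling dye
   photophysics. Frame-wise widths come from the frame-wise reference table
   (`tbp_framewise_states()`); for *molecule-wise* populations the spread is
   molecule-to-molecule, so `sim_molecule_fret()` /`sim_molwise_traces()`
   draw one mean per molecule from the component Gaussian instead.
3. **Intensities.** With donor-only budget $T$ (default 500 counts/frame):
   $I_D = (1-E)\,T$, $I_A = \gamma E T$, so that
   $I_A/(I_A + \gamma I_D) = E$ exactly. The detected acceptor channel adds
   crosstalk $\alpha I_D$; both channels add background (default 50
   counts/frame/channel).
4. **Bleaching.** Exponential waiting times per fluorophore (defaults
   0.02 s$^{-1}$ each), single step, independent; after an acceptor bleach
   the donor jumps to the full budget, after a donor bleach both channels
   fall to background.
5. **Camera noise.** Default: Poisson shot noise plus Gaussian read noise
   (SD 10 counts); pure Gaussian read noise and an EMCCD excess-noise mode
   (Poisson deviations scaled by $\sqrt 2$) are selectable. The camera model
   is a package choice — the instrument is named in the source study but its
   noise model is not.

Background levels, the intensity budget, and the noise SDs were chosen once
to give traces with a signal-to-noise ratio comparable to published example
traces; they are configurable and the corrected-E histogram is insensitive
to the budget over a 4× range (a property test asserts means within ±0.01).

Movies (`sim_movie()`, `sim_bead_stack()`) render traces as Gaussian PSFs at
random positions with a configurable channel map, pixel origin top-left,
0-based integer pixel centers. Molecule placement enforces a minimum
separation (default 6 px), matching the sparse surface densities of these
experiments. `sim_survival_experiment()` draws paired exponential
disappearance-time samples (control: photobleaching rate $k_1$; treatment:
$k_1 + k_d$), discretized to the frame grid and right-censored at the
recording horizon.

All draws are organized in per-stage, per-molecule substreams derived from
one seed, so runs are bit-reproducible and toggling one stage does not
reshuffle another's randomness.

## Trace extraction

Channel registration uses least squares on bead centroids (translation,
affine — the default — or full second-order polynomial). Spots are local
maxima after light Gaussian smoothing with non-maximum suppression and
sub-pixel refinement by three-point log-parabolic interpolation, which is
exact for Gaussian profiles and avoids the pixel-locking bias of windowed
centroids. Bead pairs are matched by *mutual* nearest neighbour and the
translation component uses the median offset, both to resist occasional
mispairings. Photometry is aperture-based (radius 3 px, background annulus
5–7 px) rather than PSF fitting — robust at 15 ms frames and faithful to
intensity-based analysis. Molecules whose aperture leaves the chip are
dropped and itemized.

## Corrections and the FRET formula

The corrected efficiency per frame is

$$E = \frac{I_A - \alpha (I_D - b_D) - b_A}
          {I_A - \alpha (I_D - b_D) - b_A + \gamma\,(I_D - b_D)},$$

with backgrounds $b_D, b_A$. The source study never prints its formula;
this is the standard corrected ratiometric form consistent with per-molecule
$\alpha/\gamma$ estimation. E is kept unclamped internally; clamping to
$[0,1]$ is a display decision.

Bleach steps are found with a two-sided sliding-window mean-shift statistic
in units of the local noise SD (window 5 frames, threshold 5). A candidate
acceptor bleach must additionally leave the acceptor channel at the
crosstalk/background level (post-step background-corrected acceptor/donor
ratio < 0.2 by default): a FRET transition to a lower state produces the
same anti-correlated step but keeps genuine acceptor signal, and without the
level test such transitions would truncate dynamic traces and bias the
static/dynamic census.

Correction factors follow a fallback hierarchy — per-molecule (from
acceptor-first bleaches only), then population median, then configured
constants — with the source recorded per molecule. $\alpha$ is the
post-bleach acceptor/donor ratio; $\gamma$ is the acceptor drop over the
donor rise across the step. Three-color traces (frame-alternating 488/532 nm
excitation) are demultiplexed at extraction; direct excitation is removed by
subtracting a fixed fraction of the adjacent 532 nm green signal, and a
complex is called Mot1-bound when the windowed mean of the corrected 488 nm
series exceeds background + 3 SD for at least 3 consecutive frames.

## Histograms and mixture fits

Histograms use 0.02-wide bins on $[-0.1, 1.1]$ — fine enough to resolve
$\sigma = 0.04$ components without over-binning. Molecule-wise histograms
take one value per molecule (mean corrected E over the analysis window;
static molecules by default), frame-wise histograms one value per usable
frame.

Mixtures of Gaussians are fitted to the binned density by bounded
Levenberg–Marquardt least squares — the same route the field's histogram
fits take — with areas reported in % (they sum to 100 by construction).
An EM fit on raw values serves as an independent cross-check in the tests,
never as the implementation. Numerical choices that matter:

* **Starts.** A histogram-quantile spread and a count-weighted k-means seed,
  plus jittered restarts; the best SSE wins. The k-means start is what
  reliably finds small components (a 6% population under a 65% peak).
* **Width bound.** Component SDs are bounded below by 0.03: the narrowest
  real population width here is 0.04, and without the bound least squares
  can "win" with a single-bin spike.
* **Degeneracy guard.** Components closer than one SD trigger a warning.

`global_amplitude_fit()` implements the four-state global fit: shared peak
positions and widths, free amplitudes per histogram, and a small
*per-histogram* shift of the positions (default ≤ 0.01) — per histogram
because the measured conditions themselves show peaks shifted by up to 0.02
from slightly different background corrections. The low-FRET shoulder
(mean 0.18, SD 0.07) can be merged into the main low-FRET area for
reporting, matching the published convention. Goodness of fit is
$R^2 = 1 - SS_{res}/SS_{tot}$ on the fitted density.

## Per-molecule HMMs, TDPs and dwell times

Dynamic traces are modelled with a Gaussian-emission hidden Markov model
trained per molecule by Baum–Welch on the corrected E series (not on the
two intensity channels). Convergence is declared when the log-likelihood
changes by less than $10^{-9}$; the recursions are scaled and implemented in
C++, the likelihood is non-decreasing by construction (asserted in tests),
and the forward likelihood is verified against brute-force path enumeration
on short traces. Five seeded initializations with quantile-spread emission
means are run and the best likelihood kept; states are relabeled by
increasing mean E. A model is flagged degenerate when states duplicate,
empty out, or the BIC does not beat a single Gaussian.

The state count uses BIC with
$p = (K-1) + K(K-1) + 2K$ parameters, choosing the smallest count within
tolerance 0 of the best — the smallest model that describes the data. The
static/dynamic classifier (the study classified manually; automated here)
calls a trace dynamic iff the 3-state HMM improves BIC over one Gaussian
*and* the Viterbi path contains a transition flanked by dwells of ≥ 2
frames; traces with windows under 30 frames stay unassigned, and a
`manual_label` column overrides the automatic call. Reported static
percentages are over assigned molecules.

Transition density plots superimpose each decoded transition as a unit-mass
2D Gaussian (default SD 0.03 FRET) on a 101×101 grid over $[0,1]^2$; the
grid integral equals the transition count up to border losses (asserted to
0.1%). Subpopulation assignment gates transitions with rectangles around
the template adjacent-state transition coordinates (half-width 0.05 —
below half the smallest cross-subpopulation distance in the reference
conditions, so gates never overlap); each molecule goes to the
subpopulation capturing the majority of its transitions, and split or
transition-free molecules stay unassigned. Labels are per molecule and
fixed — no interconversion within a run, mirroring the observation the
analysis rests on. k-means-seeded gates are available when no template is
given.

Dwell times come from Viterbi runs (first/last dwell censored). Rates are
fitted by least squares of $C e^{-kt}$ to the dwell histogram on one-frame
bins; on a frame-quantized lattice this automatically applies the
geometric-to-exponential mapping $k = -\ln(p_{stay})/\Delta t$, and the
closed-form MLE (with the same discretization correction) is the
cross-check.

## Survival analysis and dissociation rates

Disappearance times of labeled TBP under direct red excitation give
time-resolved counts of surviving complexes. Control arms decay by
photobleaching alone ($k_1$, always fitted per experiment — bleaching
depends on alignment); treatment arms decay at $k_2 = k_1 + k_d$. Curves are
fitted by least squares to $f(t) = e^{-kt}$ with the amplitude fixed at 1
(so $f(0) = 1$ exactly), and the dissociation rate is $k_2 - k_1$ with a
quadrature-summed error. Negative differences are reported, not clipped —
the "no dissociation" control conditions need them.

Because the points of a survival curve are serially correlated, the
least-squares covariance is not a valid standard error. The SE is therefore
computed by a molecule-level bootstrap (200 replicates, deterministic
internal stream), falling back to the exponential event-count asymptotics
$k/\sqrt{d}$ when raw times are unavailable; a Monte-Carlo calibration test
(120 simulated experiments) asserts the reported SE matches the empirical
spread within 25% and the estimator is unbiased to 0.002 s$^{-1}$.
`concentration_series()` orders conditions and reports a Spearman rank
correlation, imposing no functional form.

## Problem sizes used in the tests

Recovery tests use 2,000 molecule-wise values per condition for mixture
fits; 100 molecules × 2,000 frames for HMM ensemble recovery; 300 traces ×
300 frames for the classifier censuses; 500 molecules per arm for each
paired survival experiment; and 300 dynamic molecules × 800 frames (15 ms)
for subpopulation assignment — sizes on the order of the original
experiments, at which the estimators' sampling errors sit comfortably
inside the tolerances being asserted.

## What passing tests do and do not show

The generator reproduces the statistical structure the analysis assumes:
Markovian switching, Gaussian emissions, single-step bleaching, Poisson +
read noise. It deliberately omits dye blinking and triplet states, spectral
fluctuations, stage drift, diffusing background, and frame-integration
effects (one draw per frame is adequate because dwell times far exceed the
frame time at the study's settings). Parameter recovery on these
simulations therefore validates the estimators *given the model*; it cannot
certify behavior under photophysical artifacts the model excludes. The
imaging round trip (render → detect → extract) covers well-separated spots
at realistic SNR, not crowded fields or drifting stages.

## Known limitations

* The HMM is trained per molecule, as in the source analysis; ensemble
  (global) HMMs across molecules are out of scope.
* Subpopulation gating needs either templates or a sensible k; heavily
  overlapping subpopulations (< 0.05 separation on every transition
  coordinate) cannot be gated.
* The P3 label is a catch-all for molecules that fit neither template; no
  kinetic claims attach to it.
* Survival fitting is mono-exponential by design; multi-exponential decays
  are out of scope.
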