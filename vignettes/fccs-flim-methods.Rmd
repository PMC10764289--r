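---
title: "Methods: two-colour FCCS affinity estimation and FLIM-FRET analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-colour FCCS affinity estimation and FLIM-FRET analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccsfret)
```

# The measurement problem

Whether a secreted ligand stays bound to its receptor while it is handed
from cell to cell cannot be decided from colocalization images alone. Two
fluctuation methods can: two-colour fluorescence cross-correlation
spectroscopy (FCCS), which counts co-diffusing green/red molecule pairs in a
femtolitre detection volume and converts them into an equilibrium
dissociation constant, and FLIM-FRET, which reads the donor fluorophore's
lifetime quenching as a proxy for sub-10-nm proximity to the acceptor.
`fccsfret` implements both analysis chains end to end, together with the
morphometric quantifications that typically accompany such a study
(filopodium classification, cell circularity, expression-domain ratios,
kinase-translocation-reporter activity profiles), and a Brownian-dynamics
photon-trace simulator that supplies every input with known ground truth.

Because raw photon traces from such studies are generally not deposited, the
package treats synthetic data generation as a first-class, tested module:
every estimator is validated by recovering the truth its inputs were
simulated with.

# The FCCS chain

## Calibration

Each spectral channel's confocal detection volume is modelled as a 3D
Gaussian with lateral waist $\omega$ and axial extent $z$; the effective
volume is $V_{ef} = \pi^{3/2}\omega^2 z$ and the structure parameter is
$S = z/\omega$. A reference dye of known diffusion coefficient
($D = 400\ \mu m^2 s^{-1}$, the accepted value for small rhodamine-class
dyes) is recorded at two dilutions per channel (3 and 6 nM green, 4 and
8 nM red, 10-s recordings). `calibrate_channel()` fits each
autocorrelation with the triplet-diffusion model in two stages: the
structure parameter is fitted freely per trace and pooled across the
dilution series (it is a property of the optics, not of the sample), then
each trace is refit with the pooled $S$ fixed, which removes the
axial–lateral trade-off from the per-trace diffusion times. The waist
follows from $\omega = \sqrt{4 D \tau_D}$, the axial extent from
$z = S\omega$. A dilution series whose diffusion times spread by more than
20 % is rejected. Fitted molecule numbers are checked against
$C\,V_{ef}\,N_A$ and recorded for audit, but the volume itself is derived
from the geometry, not the amplitudes.

The two-channel cross-correlation volume is
$$V_{cc} = \pi^{3/2}\,\frac{\omega_g^2+\omega_r^2}{2}
  \sqrt{\frac{z_g^2+z_r^2}{2}},$$
which reduces to $V_{ef}$ for identical channels and always lies between
the two per-channel volumes under a shared structure parameter. When only
instrument-reported effective volumes are available, `volume_from_veff()`
back-derives $\omega$ and $z$ under an assumed shared $S$; the resulting
$V_{cc}$ is exactly independent of the $S$ chosen. For the reported
channel volumes of 0.56 and 0.75 fl this yields

```{r}
cross_volume(volume_from_veff(0.56, 5, "green"),
             volume_from_veff(0.75, 5, "red"))
```

i.e. 0.65 fl to the reported precision.

## Correlation

`multi_tau_correlate()` computes
$G(\tau) = \langle\delta I_a(t)\,\delta I_b(t+\tau)\rangle /
(\langle I_a\rangle\langle I_b\rangle)$ on a quasi-logarithmic grid: 16
points per octave with pairwise rebinning (the multi-tau scheme), symmetric
normalization (head/tail means re-estimated per lag) to suppress drift
bias, shortest lag one bin, lag zero excluded as shot-noise dominated. At
unrebinned lags the result equals the definitional direct estimator to
machine precision — the test suite holds it against an independent
brute-force implementation.

Per-lag standard errors come from splitting the trace into ten segments and
taking the standard error of the per-segment curves. A standard deviation
over ten values is itself noisy, so the sigma profile is smoothed across
neighbouring lags (running geometric mean over five points) before it is
used for weighting; unsmoothed weights systematically over-weight lags
whose segment spread happened to come out small.

## Model fitting

Autocorrelations are fit with the triplet-diffusion model
$$G(\tau) = \frac{1}{N}\left(1+\frac{T}{1-T}e^{-\tau/\tau_{tr}}\right)
  \left(1+\frac{\tau}{\tau_D}\right)^{-1}
  \left(1+\frac{\tau}{S^2\tau_D}\right)^{-1/2},$$
cross-correlations with the pure-diffusion model ($T = 0$): the two
fluorophores of a complex blink independently, so blinking does not
cross-correlate. Fitting is weighted least squares (weights $1/\sigma^2$,
falling back to unweighted when no uncertainties exist) by
Levenberg–Marquardt with a deterministic ladder of at least five perturbed
starts over $(\tau_D, T)$; the best chi-square wins, ties broken toward the
smaller diffusion time. Numerical safeguards, each of which exists because
the unconstrained problem has a known pathology:

* **Fit window.** Lags beyond 16 times the curve's half-decay lag are
  excluded. Once the correlation has decayed, the tail carries no model
  information but is sensitive to slow baseline distortions (instrument
  drift in real data; the finite box's slowest diffusion modes in
  simulated data) that drag the structure parameter down a flat
  chi-square ridge.
* **Physical bounds.** A free structure parameter is confined to the
  confocal range $[2, 10]$; the triplet fraction to $[0, 0.5]$ and the
  triplet relaxation time to $[1, 50]\ \mu s$, and a solution whose
  material triplet term ($T > 1\%$) relaxes slower than $\tau_D/5$ is
  discarded in favour of the best conforming start (term swapping).
* **Nesting.** The pure-diffusion optimum (with $T = 0$) is always
  included among the triplet-model candidates, so adding the triplet term
  can never report a worse chi-square.
* **Sample fits.** The structure parameter is fixed from calibration for
  all sample fits (the measurements are taken under the calibration
  settings); the cross fit uses the cross-volume's own structure
  parameter $S_{cc} = \sqrt{\bar{z^2}/\bar{\omega^2}}$. The triplet
  relaxation time may be fixed from configuration when it is known to be
  unresolvable at the sample bin width.

## Concentrations, K_d, exclusion, bounds

With $N_1$, $N_2$ the fitted molecule numbers of the two autocorrelations
and $N_{cc}$ the amplitude reciprocal of the cross fit,
$$C_{green} = \frac{N_1}{V_{ef,g} N_A},\qquad
  C_{red} = \frac{N_2}{V_{ef,r} N_A},\qquad
  C_{cc} = \frac{N_1 N_2}{N_{cc}}\cdot\frac{1}{V_{cc} N_A},$$
$$K_d = \frac{(C_{green}-C_{cc})(C_{red}-C_{cc})}{C_{cc}}.$$
$N_{cc}$ is the amplitude reciprocal $1/G_{cc}(0)$, so the bound-molecule
number is $N_1 N_2 / N_{cc}$ — the only reading under which the $C_{cc}$
equation returns a complex concentration; for Gaussian volumes
$G_{cc}(0) = C_{complex}/(V_{cc} N_A C_{green} C_{red})$, making the
estimator consistent up to the ratio $V_g V_r / V_{cc}^2$ (0.994 for the
0.56/0.75 fl pair).

Measurements with either channel concentration strictly above 2,000 nM are
excluded (over-expression guard); the rule is configurable to the
both-channels reading, and the boundary value itself is retained. When the
fitted cross amplitude falls below three times the per-lag standard error
near zero lag, no point estimate is made: $C_{cc}$ is set to the floor's
concentration equivalent and $K_d$ is reported as a lower bound
(`kd_is_bound`), reproducing the "$K_d$ greater than some value"
convention for non-interacting controls. Lower bounds are never averaged
into mean $\pm$ s.d. summaries. Relative affinity rescales $1/K_d$
linearly so a non-binding anchor maps to 0 and a tight-binding anchor to
100; linearity in $1/K_d$ is this package's documented choice, as is any
particular set of histogram bin edges.

# The synthetic-data generator

`simulate_fccs_trace()` places each species of a mass-action equilibrium
mixture (complex concentration = the physical root of
$C^2-(G_t+R_t+K_d)C+G_tR_t=0$) Poisson-distributed in a periodic cube,
propagates isotropic Brownian steps of standard deviation
$\sqrt{2D\Delta t}$ per axis, accumulates every emitter's expected photon
rate through the two 3D Gaussian detection profiles, applies two-state
triplet blinking (stationary dark fraction $T$, relaxation time
$\tau_{tr}$), and draws per-bin counts from a Poisson distribution.
Complexes carry both fluorophores and emit the summed brightness.
Brightness is quoted in the counts-per-molecule convention, so the mean
count rate is $\sum_s C_s V_{ef} N_A \epsilon_s (1-T)$ — an analytic
expectation the test suite checks to three standard errors. Traces are
bit-identical given a seed: the simulator runs its own counter-seeded
xoshiro256++/ziggurat/Poisson stack, independent of R's RNG state, and a
master seed fans out to all stages through `child_seed()`.

Defaults describe the study conditions: 10-s recordings; free
ligand/receptor species at $4\ \mu m^2 s^{-1}$ and complexes at
$2.5\ \mu m^2 s^{-1}$ (membrane-proximal signalling proteins in embryonic
tissue diffuse at single-digit $\mu m^2 s^{-1}$); molecular brightness
4 kHz per fluorophore (in-vivo GFP/mCherry at moderate excitation); 15 %
triplet occupancy with a 5 µs relaxation time; detection waists 0.2 µm
with structure parameter 3; 50 µs count bins for samples and 2 µs for the
fast-diffusing calibration dye, with automatic sub-stepping whenever a full
bin step would exceed a tenth of the beam waist.

Numerical design of the box:

* The cube is periodic with side at least ten beam waists (2 µm for the
  0.2 µm waist). Its slowest surviving diffusion mode relaxes on
  $\sim(L/2\pi)^2/D$; beyond that lag the simulated correlation decays
  faster than the open-reservoir model. The fit window (16 half-decay
  lags) ends well below this scale for the default sample parameters.
* Emission is truncated beyond 2.5 waists laterally and 2.5 axial extents
  axially (below $4\times10^{-6}$ of the peak). A particle farther from
  the detection cylinder than five standard deviations of its displacement
  over $k$ bins is advanced by one aggregated Gaussian step across those
  $k$ bins — exact for Brownian increments, since the skipped emission is
  below the truncation threshold. This is what makes 10-s traces with
  thousands of particles affordable.
* Calibration dyes are simulated in a 6 µm box: at 3–8 nM a 2 µm box
  holds only ~15–40 emitters, so each trace would freeze a ±25 % Poisson
  concentration error, and a 4 µm box leaves the box-mode distortion close
  enough to the axial decay to disturb structure-parameter fits; calibration
  fits use a window of 24 half-decay lags to cover the full axial decay.
* Because the box freezes one Poisson draw of particle numbers per trace,
  amplitude checks in the tests compare fitted molecule numbers against
  realized emitter counts, not nominal concentrations.

What the generator does **not** emulate: spectral cross-talk, background
and afterpulsing (all zero by default; the analysis applies no corrections
either, matching the measurement protocol), photobleaching, incomplete
fluorophore maturation, dark acceptor states, cellular geometry
(membranes, cytonemes) and active transport. Passing recovery tests on
this generator therefore demonstrates the correctness of the estimator
chain under ideal single-phase diffusion — not robustness to every
artefact of in-vivo recordings.

`simulate_tcspc()` draws photon arrival times from an exponential lifetime
mixture plus Gaussian instrument-response jitter and histograms them on a
25 ns window (0.05 ns bins); photons jittered out of the window are
dropped and counted. `generate_cell_grid()` builds the reporter fixture: a
rectangular cell grid with a source clone, row distance as breadth-first
graph distance on 4-neighbour adjacency (cell rows, not micrometres), and
nuclear/cytoplasmic ratios drawn below or above the call threshold
according to a per-row activation probability.

# The FLIM-FRET chain

`fit_decay()` fits an exponential mixture convolved with a Gaussian IRF
(the exponentially-modified-Gaussian density, evaluated in log space) to a
TCSPC histogram by Poisson maximum likelihood — correct at low counts per
bin, where least squares is not. The overall intensity is profiled out
analytically; lifetimes, fractions and the IRF shift $t_0$ are optimized
from a deterministic multi-start (L-BFGS-B). Decays under 1,000 photons
are flagged low-signal. The amplitude-weighted mean lifetime
$\sum a_i\tau_i/\sum a_i$ is the default summary (the intensity-weighted
mean is available via `lifetime_weighting = "intensity"`; which one an
instrument reports is vendor-specific).

`roi_fret_analysis()` averages the fitted donor-only lifetimes into the
unquenched donor lifetime $\tau_D$, then per ROI computes
$E = 1-\tau_{DA}/\tau_D$ (clipped to $[0,1]$ with a flag) and the
donor–acceptor distance $r = R_0((1-E)/E)^{1/6}$ with
$R_0 = 52.4\ \mathring{A}$ for the EGFP–mCherry pair. $E$ of exactly 0 or
1 has no finite positive distance and is reported not-detectable. Note
that published per-construct $(E, r)$ pairs produced by vendor FLIM
software are generally not mutually consistent with the bare Förster
relation at the stated $R_0$ (they involve undocumented per-pixel
weighting); this package implements the bare relation and makes no attempt
to reverse-engineer vendor averaging.

# Validation problem sizes

The test suite and the acceptance script size their simulations as
follows, as this package's own choice of validation scale:

* Detection-volume calibration: the full dye design (two dilutions per
  channel, 10-s traces; the acceptance script records three repeats per
  dilution, averaging per-trace volume noise down to a few per cent) —
  recovers both effective volumes within 15 %.
* K_d recovery at the printed control (229 nM) and ligand–receptor
  (440 nM) affinities: 20 independent 10-s measurements each at 300 nM
  totals per channel, full pipeline; the means land within a few per cent
  of truth.
* The affinity-range sweep ($K_d$ = 100, 500, 2000 nM at 300 nM totals,
  20 seeds each) uses 4-s traces for the two tighter binders and the full
  10-s recording for the 2,000 nM condition, whose cross amplitude is only
  a few-fold above the noise floor.
* Lifetime and FRET recovery: $10^5$-photon decays, 10 repeats; lifetime
  bias is below 2 %, efficiency within 2 percentage points.

# Known limitations

* The estimator inherits FCCS's intrinsic requirements: concentrations
  within roughly 10–2,000 nM (hence the exclusion rule), and a cross
  amplitude above the noise floor — weak binders on short recordings come
  out as lower bounds, with the measurable-range selection bias that
  implies.
* Per-measurement $K_d$ is a convex function of the noisy fitted
  amplitudes, so single measurements scatter asymmetrically;
  study-level conclusions should use the aggregated summaries.
* The triplet term is unresolvable when the bin width exceeds a few
  relaxation times; fix `triplet_tau` from configuration in that regime.
* No cross-talk/background corrections are applied anywhere, by design;
  data with appreciable bleed-through require upstream correction.
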