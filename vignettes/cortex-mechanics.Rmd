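---
title: "Measuring actin-cortex mechanics and morphology with cortexmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring actin-cortex mechanics and morphology with cortexmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmech)
library(dplyr)
```

The actin cortex — the thin actomyosin network under the plasma membrane —
sets the surface tension and stiffness of rounded cells and drives mitotic
rounding. `cortexmech` implements the computational side of a
confinement-based measurement of cortex mechanics: a round cell is squeezed
between a dish and a wedged AFM cantilever, the gap height is oscillated,
and force and height recordings are converted into three per-cell readouts
(cortical tension, cortical stiffness, phase shift). Companion modules
quantify cortex-associated fluorescence and cortical thickness from
equatorial confocal images, and the roundness and size of cross-sections of
mitotic cells and spheroids. Every stage has a seeded forward simulator so
the whole pipeline is validated by parameter recovery.

## The confined-cell shape model

A non-adherent cell between two parallel plates is modelled as a surface of
minimal area at constant volume. We use the standard circular-arc
(constant-mean-curvature approximation) profile with a 90° contact angle at
both plates: the meridional profile is a circular arc of radius
$R_2 = h/2$ tangent to both plates, so the contact radius is
$r_\mathrm{con} = R_1 - h/2$ with $R_1$ the equatorial radius and $h$ the
plate gap. Closed forms follow for the volume, the contact area
$A_\mathrm{con} = \pi r_\mathrm{con}^2$, and the lateral and total surface
areas; `solve_shape()` inverts the volume (quadratic in
$r_\mathrm{con}$) so that per-sample geometry at constant volume costs a
square root, not an ODE solve. The exact unduloid (constant mean curvature)
solution differs from the circular arc at the sub-percent level in this
confinement regime and is a deliberate non-goal; the closed form is checked
against solid-of-revolution quadrature to $10^{-6}$ relative in the test
suite.

Two modelling choices are worth making explicit:

* the **total** surface area includes both plate-contact disks, because the
  cortex covers the whole cell surface and the area strain should reflect
  total cortex area. `include_caps = FALSE` switches to the free surface
  only;
* the cell volume is treated as constant within one recording, estimated
  once (e.g. from the equatorial cross-section at known gap height via
  `volume_from_equatorial_area()`).

```{r geometry}
sh <- cell_shape(R1 = 10, h = 10)
sh
solve_shape(sh$V, h = 10)$R1
```

## From force and height to tension, stiffness, phase

The Laplace-pressure force balance of the confined shape gives the
instantaneous **effective tension**

$$\gamma_\mathrm{eff}(t) = \frac{F(t)}{A_\mathrm{con}(t)\,(1/R_1(t) + 1/R_2(t))},$$

in mN/m with force in nN and lengths in µm. The rheological **strain** is
the relative surface-area change
$\varepsilon_A(t) = (A(t) - \langle A\rangle)/\langle A\rangle$, zero-mean
over the analysis window by construction. Cell height is reconstructed from
the piezo channel and calibration constants as elevation minus lowering plus
the wedge spike-height correction plus the cantilever deflection $F/k$
(`compute_cell_height()`); the surface-touch reference is an explicit
calibration input (`afm_calibration()`), not inferred from the trace.

The analysis window is chosen by `select_steady_window()`: the recording is
split into whole drive periods and the latest contiguous run of
`window_periods` periods (default 8, clamped to 5–10) in which per-period
force and height amplitudes vary less than 5% around their window medians is
used — i.e. steady-state oscillation after the transient relaxation phase.
Recordings shorter than the requested window fall back to the 5-period
minimum; fewer than 5 whole periods is an error.

Amplitudes and phases are extracted by harmonic least squares at the known
drive frequency — fitting $a + b\sin(2\pi f t) + c\cos(2\pi f t)$ — rather
than FFT bin-picking, which is exact for non-integer period counts and uses
only the fundamental component. The piezo may render the sine piecewise
linearly; the analyzer fits a true sinusoid regardless, so drive harmonics
land in the residual. The readouts are

* cortical tension $\gamma$: window mean of $\gamma_\mathrm{eff}$,
* cortical stiffness $K = \hat\gamma_\mathrm{eff}/\hat\varepsilon_A$
  (amplitude ratio),
* phase shift $\varphi = \varphi_\gamma - \varphi_\varepsilon$, wrapped to
  $(-180°, 180°]$; $0°$ indicates an elastic solid, $90°$ a viscous liquid,
* the complex modulus $K^* = K e^{i\varphi}$.

Phases outside $[-5°, 95°]$ are flagged `unphysical` rather than clipped,
and amplitudes below $3\times$ residual RMS$/\sqrt{n}$ are flagged
`low_snr`. The systematic cell-height uncertainty of about 0.5 µm is not
folded into the point estimates; `rheology_sensitivity()` reports the
readouts at $h \pm 0.5$ µm instead.

```{r rheology}
fx <- gen_afm_trace(gamma0 = 1.5, K_true = 20, phi_true_deg = 30, seed = 7)
res <- rheology_summary(fx$trace, fx$truth$V, fx$calibration)
tidy(res)
```

## The synthetic AFM trace generator

`gen_afm_trace()` forward-simulates the measurement at the study
conditions: a cell of free diameter 20 µm confined to 65% of its free
height, drive amplitude 0.25 µm at 1 Hz, sampled at 500 Hz for 12 periods.
The gap oscillates sinusoidally (optionally as a piecewise-linear sine, as
a piezo drive produces), per-sample geometry follows from `solve_shape()`,
and the cortex responds linearly on the strain's *fundamental* Fourier
component: $\gamma_\mathrm{eff}(t) = \gamma_0 + K\,\hat\varepsilon_A
\sin(2\pi f t + \varphi_\varepsilon + \varphi)$. The linear response is
applied to the fundamental because the analysis extracts only the
fundamental; the geometric non-linearity of $\varepsilon_A(t)$ is retained
in the force channel, so the analyzer is exercised on realistically
distorted waveforms. Gaussian force noise (default off; 0.1 nN in noisy
fixtures, the order of an AFM noise floor) and an exponential transient on
the oscillatory force component are optional. The piezo channel is built by
inverting the height reconstruction, so `compute_cell_height()` is exact on
synthetic traces.

What the generator does **not** emulate: cantilever dynamics and
hydrodynamic drag, drift, cell-shape irregularities, active tension
fluctuations, and volume changes during the recording. Passing recovery
tests therefore demonstrates correctness of the inference chain, not
robustness to every instrumental artefact.

Parameter recovery on noise-free traces is within (1%, 2%, 1°) for
$(\gamma_0, K, \varphi)$ over $\gamma_0 \in [0.5, 5]$ mN/m,
$K \in [5, 100]$ mN/m, $\varphi \in [0°, 90°]$ and confinement 60–70%; the
residual error reflects the harmonic distortion of the strain, not noise.

## Cortex fluorescence from equatorial images

For a round cell imaged in its equatorial plane, the circumference-averaged
radial intensity profile is modelled as a smoothed cytoplasmic step plus a
skewed-Gaussian cortical peak plus background:

$$I(r) = I_\mathrm{cyt}\,\tfrac12\!\left[1 -
\operatorname{erf}\!\Big(\tfrac{r-\mu}{\sigma_1\sqrt2}\Big)\right] +
I_\mathrm{cort}\, e^{-\frac{(r-\mu)^2}{2\sigma_2^2}}\left[1 +
\operatorname{erf}\!\Big(\tfrac{\alpha(r-\mu)}{\sigma_2\sqrt2}\Big)\right] +
I_\mathrm{BG}.$$

Conventions: the Gaussian is unit-peak, so $I_\mathrm{cort}$ is an
amplitude; the erf arguments use the standardised residual
$(r-\mu)/(\sigma\sqrt2)$ (the standard skew-normal construction, exposed as
a documented choice); $r$ is boundary-centred (negative inside the cell), so
$\mu$ is a small correction to the detected contour. The integrated
cortical signal has the closed form $I_\mathrm{2D,cortex} =
I_\mathrm{cort}\sigma_2\sqrt{2\pi}$ for every skewness (the odd erf term
integrates to zero), and the **cortex-to-cytoplasm ratio** is
$I_\mathrm{2D,cortex}/I_\mathrm{cyt}$, in µm. The fitted (background-free)
$I_\mathrm{cyt}$ is used for the normalisation.

The extraction chain is: boundary detection (Gaussian smoothing, Otsu
threshold, hole filling, largest connected component — a user mask always
overrides), 200 radial lines normal to the contour at equidistant
arc-length positions, each reaching 2 µm in and out, sampled by bilinear
interpolation at half-pixel steps, then line-averaged. Fitting is
Levenberg–Marquardt with a deterministic multi-start (boundary guess from
the profile maximum and from the steepest descent; width ladder; skewness
grid $\{0, \pm1, \pm3\}$), taking the lowest-residual fit. Because a
peak-free profile makes the peak term non-identifiable, a reduced step-only
model is also fitted and preferred when it loses essentially nothing
(within 2% of the residual RMS) — so `I_cort` is reported as exactly zero
for cortex-free inputs rather than as an arbitrary small peak.

For **cortical thickness**, an F-actin label and a membrane dye are imaged
in two channels; after removing the lateral channel shift (difference of
intensity centres of gravity), both averaged profiles are fitted with
$\alpha = 0$ and the thickness estimate is twice the peak offset,
$2(\mu_\mathrm{membrane} - \mu_\mathrm{actin})$. Negative estimates are
returned but flagged unphysical.

```{r imaging}
prof <- gen_radial_profile(alpha = 1, noise = "poisson", seed = 3)
fit <- fit_profile(prof, skewed = TRUE)
glance(fit) |> select(ratio_um, resid_rms)
tc <- gen_two_channel_cell(thickness_um = 0.3, seed = 5)
thickness_from_images(tc$actin, tc$membrane, tc$px_size_um)$thickness_um
```

In the noise simulators, "peak SNR 10" refers to a single pixel: intensities
are scaled so the profile peak corresponds to $10^2$ expected photons before
Poisson sampling. The measured profile is the average of the 200 radial
lines, and `gen_radial_profile(n_avg = 200)` reproduces exactly that
averaging (a single raw line at this noise level does not constrain the
skew parameters to within a few percent — $\mu$, $\sigma_1$ and $\alpha$
trade off almost freely — which is precisely why the measurement averages
over the circumference).

## Morphometry

`roundness()` fits an ellipse to a binary cross-section by second central
moments (the standard "fit ellipse" of image-analysis software; the major
axis is the full axis length $4\sqrt{\lambda_\mathrm{max}}$) and reports
$4\,\mathrm{Area}/(\pi\,\mathrm{major}^2)$ — 1 for a circle, $b/a$ for an
ellipse. Pixel discretisation biases the moment estimate by up to ~0.01 at
semi-axes around 10 px, which is why validation uses an absolute ±0.02
band. `largest_cross_section()` scans a z-stack for the slice with maximal
foreground area (ties resolve to the lowest z-index), the object-size
readout for spheroids and mitotic cells; masks and mitotic labels are inputs
(identification is manual upstream).

## Group statistics

`mann_whitney()` computes the rank-sum U with midrank ties and a two-tailed
p-value that is **exact by full enumeration** of group assignments for
combined $n \le 20$ (valid under ties), switching to a tie-corrected normal
approximation with continuity correction above. Summaries are the
five-number boxplot statistics with whiskers at 1.5 IQR, and significance
tiers ns/*/**/*** at 0.05/0.01/0.001. No multiple-testing correction is
applied — comparisons are reported per readout, matching how such
experiments are conventionally summarised — and this is deliberately left
to the user. `relative_change_test()` is the one-sided one-sample t-test of
mean relative change against 1 used for blot-style ratios.

`gen_cohort()` draws per-cell $(\gamma, K, \varphi)$ from lognormal
distributions (CV 0.2 by default) in a two-condition × two-phase design
whose default directions mimic an EMT-like perturbation: interphase tension
and stiffness down, mitotic tension and stiffness up, mitotic phase shift
down in the post condition. Effect sizes are **user parameters** (default:
50% shifts for tension/stiffness, half that for phase) — the underlying
study reports distributions only as boxplots, so no literature effect size
is asserted. With `generate_traces = TRUE`, one synthetic AFM trace per
cell feeds the full pipeline (`analyze_cohort()` → `cohort_stats()`).

```{r cohort}
co <- gen_cohort(n_per_group = 8, seed = 42)
cohort_stats(co$truth)
```

## Numerical choices and problem sizes

* Geometry: volumes/areas are closed-form; `solve_shape()` takes the
  positive quadratic root; infeasible inputs (cell too small to span the
  gap, unconfined radius) error early with named causes.
* Units are fixed internally at µm / nN / mN/m; conversions (e.g. the
  $10^{-3}$ between nN/(N/m) and µm of deflection) happen only at
  calibration boundaries. File formats encode units in column names
  (`time_s`, `force_nN`, `piezo_um`, `r_um`).
* Harmonic fits use `lm.fit` on the sin/cos design — no nonlinear
  optimisation is involved in the rheology path.
* Profile fits bound $\sigma_{1,2}$ below by a quarter sample step and
  $\alpha$ to $[-20, 20]$; the multi-start ladder is deterministic, so
  identical inputs give identical fits.
* All simulator randomness flows through a locally seeded RNG
  (`seed` arguments) that restores the caller's RNG state; identical seeds
  give bit-identical fixtures.
* Validation problem sizes (chosen to exercise every regime at desk scale):
  rheology recovery over a 3×3×3×3 parameter grid plus 50 noisy replicates;
  profile round trips over 50 Poisson replicates; thickness at 200–500 nm;
  type-I calibration over 200 null cohorts of 25 cells per group; the
  full-pipeline cohort check over 20 replicates of 25 cells per group.

## Known limitations

* The circular-arc shape is an approximation to the exact
  constant-mean-curvature surface; adhesion and contact angles ≠ 90° are
  out of scope.
* Single drive frequency: no frequency sweeps or power-law rheology fits.
* Boundary detection assumes one dominant bright cell; clumped cells
  require a user-supplied mask.
* The thickness estimator assumes symmetric peaks and sub-resolution
  chromatic z-shift; it inherits any residual lateral registration error.
* Proprietary AFM file formats are not parsed; traces are plain CSV.
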