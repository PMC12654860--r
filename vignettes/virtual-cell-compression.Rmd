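---
title: "Methods: virtual parallel-plate cell compression and its analysis"
author: "micropress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual parallel-plate cell compression and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropress)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `micropress`, in the spirit of a methods section: what
each stage assumes, which knobs matter, and what the built-in simulator
does and does not emulate.

## 1. The measurement chain

A single suspended cell is grasped between two plate-shaped
end-effectors. One plate advances at constant speed while a
semiconductor strain-gauge sensor records the reaction force and a
camera records the squashed silhouette. The analysis chain is:

1. **Calibration** converts raw ADC counts to force (`fit_calibration`,
   `convert_trace`).
2. **Geometry** measures, per frame, the contact length $D_t$ and the
   cell width $L_t$ between the plate inner edges (`measure_frame`).
3. **Mechanics** forms stress $\sigma_t = F_t / S_t$ with
   $S_t = \pi D_t^2/4$ and engineering strain
   $\varepsilon_t = (L_0 - L_t)/L_0$, and regresses $\sigma$ on
   $\varepsilon$ over the high-strain loading region to get the elastic
   modulus $E$ (`build_curve`, `fit_elastic_modulus`).
4. **Rheology** reduces runs at several speeds to apparent-modulus
   samples $E(t)$ and fits the power law
   $E(t) = E_0 (t/t_\mathrm{ref})^{-\beta}$ (`fit_power_law`).
5. **Population analysis** summarizes and compares condition-labelled
   modulus collections (`summarize_population`, `students_t_test`,
   `detect_modes`, `dose_response_check`).

Units are fixed throughout: µm, nN, s, kPa. The identity
$1\,\mathrm{nN}/\mu\mathrm{m}^2 = 1\,\mathrm{kPa}$ is used bit-for-bit
by both the simulator and the analyzers; a dedicated test checks it
against an SI reformulation to $10^{-9}$.

## 2. Sensor calibration model

The calibration loads the sensor tip with a steel ball
(default mass $3.27\times10^{-5}$ g) and rotates it through one
revolution in $n$ steps (default 50, i.e. 7.2° per step). At stage
angle $\theta$ the axis component of the ball's weight is
$mg\cos(\theta-\varphi)$, so the ADC output is a sinusoid in $\theta$.
`fit_calibration` solves the linear least-squares problem
$\mathrm{ADC} \sim \{\cos\theta, \sin\theta, 1\}$, which is exact for
this model class: with amplitudes $(A, B)$ and offset $C$,
$R=\sqrt{A^2+B^2}$, $\varphi=\operatorname{atan2}(B, A)$, and the
conversion coefficient is $mg/R$ in nN/ADU. Because the model class is
closed under the fit, a noise-free sweep is recovered exactly; this is
a test invariant, not an empirical observation.

Choices worth noting:

* **Free baseline.** The fit includes an offset term $C$ because real
  ADCs are offset; $C$ is identifiable from a full revolution and
  costs nothing.
* **Resolution** is not defined by instrument datasheet conventions
  here. This package uses an *operational* proxy: the standard
  deviation of the force-converted fit residuals. It scales linearly
  with ADC noise at fixed coefficient (tested over a noise grid) and
  reduces to zero for a noise-free sweep.
* **Error metrics.** RMSE and maximum absolute error of predicted vs
  measured force are computed in force units (nN) after conversion
  with the fitted coefficient. Their values depend entirely on the
  sensor noise scenario, so they are reported, never asserted against
  fixed numbers.
* **Gravity** is $g = 9.80665$ m/s² everywhere, configurable in the
  sweep record.
* Angles are degrees at every interface and radians only inside the
  trigonometry; the conversion is centralized in two helpers.

## 3. The virtual cell

`simulate_compression` emulates constant-speed compression of a
two-compartment viscoelastic cell:

* **Geometry.** The cell is a sphere of diameter $L_0$ (default 15 µm,
  a typical suspended-cell diameter). Compressed to strain
  $\varepsilon$, the plate contact is the chord of a rigidly truncated
  sphere, $D(\varepsilon) = L_0\sqrt{2\varepsilon-\varepsilon^2}$.
  This closed form has the right limits ($D(0)=0$, $D$ increasing,
  $D \le L_0$) and is cheap to verify; it deliberately ignores lateral
  bulging and volume conservation, which bright-field images do not
  constrain well anyway. It is a stand-in, not a contact-mechanics
  solution — Hertzian or finite-element contact is out of scope.
* **Material.** Each compartment follows power-law rheology
  $E_i(t) = E_{0,i}\, t^{-\beta_i}$ ($t_\mathrm{ref}=1$ s), the
  standard soft-glassy description of cells; $\beta=0$ is an elastic
  solid and $\beta=1$ a Newtonian liquid. The nucleus (diameter
  fraction 0.7 of $L_0$ by default) engages once the plate separation
  reaches it, at $\varepsilon^* = 1 - 0.7 = 0.3$. Past
  $\varepsilon^*$, the compartments are stacked along the compression
  axis, so the combined modulus is the strain-weighted harmonic
  (series) mean with weights $\varepsilon^*/\varepsilon$ and
  $1-\varepsilon^*/\varepsilon$. This is the simplest composition that
  yields a higher apparent stiffness at deeper indentation when the
  nucleus is stiffer. Note its consequence: when
  $\beta_\mathrm{cyto}\ne\beta_\mathrm{nuc}$ the deep-regime response
  is *not* an exact power law; the fitted deep-regime $\beta$ is an
  effective exponent between the two.
* **Signal.** Stress is $\sigma = E_\mathrm{eff}\,\varepsilon$, force
  is $F = \sigma\,\pi D^2/4$ plus additive Gaussian noise (default
  2 nN, the magnitude of the emulated sensor class's resolution).
  Defaults: speed 7.5 µm/s (middle of the instrument's 2.5–15 µm/s
  range), target strain 0.5, sampling 100 Hz — so a default run takes
  one second, like the instrument's compression videos.
* **Hysteresis.** The optional unloading branch mirrors the loading
  strain ramp with stress scaled by `unload_retention` (default 0.7).
  Real hysteresis is not quantified by the source data; the factor
  exists so branch-handling code has something to split, and the
  modulus regression uses loading points only.

`render_frame` draws a bright-field-like frame: two dark plate bands
with inner edges $L_t$ apart and a darker cell between them. The cell
silhouette is a flat contact collar of transverse extent $D_t$ at each
plate joined to an elliptical mid-body bulge (lateral extent
$\max(L_t, 1.2\,D_t)$). The collar is what a strongly squashed convex
cell looks like near the plates and is what makes contact length
measurable at pixel resolution. The renderer does not attempt optical
physics — no point-spread function, no defocus, no noise field; it
emulates geometry, not imaging.

**What passing tests show, and what they do not.** The simulator
reproduces the *statistical structure* the analysis assumes: sinusoidal
calibration sweeps, power-law force responses with contact-geometry
scaling, clean plate/cell contrast, and normal-mixture population
scatter. Tests passing on it demonstrate that the analysis recovers
known ground truth under those assumptions. They do not demonstrate
robustness to segmentation on low-contrast real micrographs, adhesion
or slip at the plates, non-spherical resting shapes, or drift in the
force baseline — all of which real data can exhibit.

## 4. Geometry measurement conventions

* Pixels are 0-based with intensities at pixel centers; all outputs are
  µm via `pixel_size` (default 0.1 µm/px). The compression axis is
  horizontal by default; vertical frames are transposed on entry.
* **Plates** are located on the transversely averaged intensity
  profile: the strongest rising gradient is the left inner edge, the
  strongest falling gradient to its right the right inner edge; both
  must exceed 25% of the profile's dynamic range, making detection
  invariant to affine intensity rescaling (tested over a scale/offset
  grid). A structureless image raises a detection error.
* **Segmentation** is an automatic Otsu threshold on the between-plate
  region followed by largest-connected-component selection (via
  EBImage). A manual-override path exists: geometry tables can be
  supplied directly as CSV instead of measured from frames.
* **Contact length** is the transverse mask extent in a 2-px band at
  each plate inner edge, averaged over the plates in contact. Two
  conventions matter at the pixel scale: the *minimum* extent within
  the band is used, because a squashed convex cell is narrowest right
  at the plate; and a profile that *widens* away from the plate faster
  than a flat collar (by more than 2 px) is classified as tangent —
  sub-resolution — contact and reported as $D_t = 0$ with a no-contact
  flag. Without the second rule, the steep $\sqrt{\,}$-shaped
  silhouette of a barely-touching sphere reads as a spurious
  ~10-px contact at its first pixel row.
* **Width** equals the plate separation while both plates are in
  contact, otherwise the axial extent of the mask. $L_0$ is the width
  at the first frame with detected contact.
* Round-trip accuracy of 1 px for both $D_t$ and $L_t$ over
  $L_t \in [4,15]$ µm, $D_t \in [0,12]$ µm, and pixel sizes
  0.05–0.2 µm/px is a tested invariant of the renderer/measurer pair.

## 5. Modulus extraction

Points without plate contact ($S_t = 0$) are excluded — not assigned
infinite stress — with a count kept on the curve. Branches are split at
the index of maximum strain. The regression window is the loading
points with $\varepsilon \ge (1-f)\,\varepsilon_\mathrm{max}$, with
window fraction $f = 0.3$ by default: the upper portion of the curve is
where plate-compression stress–strain plots are visibly linear, and a
fraction of the *achieved* strain is scale-free across cells. The OLS
fit keeps an intercept so a contact-onset stress offset cannot bias the
slope; on linear data shrinking $f$ from 0.3 to 0.1 moves the slope by
well under 2% (tested). At least 3 window points are required.

## 6. Rheology sampling and fitting

One compression run contributes one apparent-modulus sample per strain
checkpoint: the secant modulus $\sigma(\varepsilon^*)/\varepsilon^*$,
linearly interpolated between the bracketing loading points, paired
with the indentation time from contact onset (extrapolated to zero
strain) to the checkpoint. Defaults: checkpoint 0.15 for the
low-compression (cytoplasm) regime and 0.45 for the high-compression
(nucleus-engaging) regime, straddling the default nucleus-contact
strain of 0.3. Sweeping the speed over 2.5–15 µm/s spans a 6× range of
indentation times at fixed checkpoint, enough leverage for the two-
parameter log-log fit.

The fit itself is OLS of $\ln E$ on $\ln(t/t_\mathrm{ref})$:
$\beta = -$slope, $E_0 = e^{\mathrm{intercept}}$. The log transform
linearizes the model exactly, so noise-free recovery is exact to
rounding (a tested grid invariant), and refitting with a different
$t_\mathrm{ref}$ rescales $E_0$ by
$(t_\mathrm{ref}'/t_\mathrm{ref})^{-\beta}$ while leaving $\beta$
unchanged (analytic identity, tested). A nonlinear least-squares
refit on the natural scale (`method = "nls"`) is available as a
cross-check; it weights large moduli more and is not the default.
`compare_regimes` reports the $E_0$ ratio and $\beta$ difference
between regimes and flags whether the stiffer-and-more-solid-at-depth
ordering holds for those fits; the ordering is a property of the fitted
cell, not an invariant of arbitrary input, and is asserted only where
the generator constructs it.

## 7. Population presets and statistics

Each experimental condition is encoded as a mixture of normal
components truncated at 0.1 kPa (moduli are positive). Single-component
presets carry the condition's reported mean ± SD and sample size. Two
shapes are deliberately structural:

* **Progerin overexpression** is a two-component mixture
  (0.55·N(3.0, 0.7) + 0.45·N(7.0, 0.8) kPa) placing its peaks in the
  2–4 and 6–8 kPa bands that characterize the progerin phenotype. The
  weights are a near-even split chosen once; only the peak locations
  are constrained by the emulated observations.
* **Lamin A overexpression** is right-skewed but unimodal:
  0.7·N(3.0, 1.0) + 0.3·N(4.4, 1.3) kPa. The components sit closer
  than the 2-kPa mode-separation threshold, so the preset cannot flag
  bimodal through genuine structure, only through sampling artifacts
  (see below).

`sample_population` converts each drawn modulus into an elastic
($\beta=0$) virtual cell with both compartments at the drawn value, so
the cell's quasi-static stiffness equals the draw exactly. Population
recovery through the full pipeline then isolates the measurement
chain: any bias would come from simulation, geometry, or regression,
not from compartment bookkeeping.

Statistics follow the conventions of the emulated workflow: mean ±
sample SD with SEM; classic pooled-variance two-tailed Student's t-test
(Welch available behind a flag) with significance at $p<0.05$; the
implementation delegates to `stats::t.test(var.equal = TRUE)` and is
checked against the textbook formula to $10^{-10}$ in tests. **No
multiple-comparison correction is applied** — deliberately mirroring
the emulated analysis — which is a limitation to keep in mind when
many conditions are compared.

Histogram densities use fixed bins $[kw, (k+1)w)$ with density
$\mathrm{count}/(nw)$ ("fraction of cells per 1 kPa interval" when
$w=1$), so density × width sums to 1 exactly.

**Mode detection.** A Gaussian KDE with Silverman's bandwidth is
scanned for local maxima; candidates below 10% of the global peak are
discarded, and a candidate only counts as a separate mode if the
density between it and the global peak dips below 0.75× the
candidate's height. The prominence (valley) condition exists because,
without it, tail sampling ripple in 100-cell samples of *unimodal*
distributions — even single normals — produces spurious secondary
modes in several percent of samples; with it, misclassification across
the built-in presets is rare (~1 in 400 samples in the package's own
screening). The bimodality flag additionally requires two modes more
than 2 kPa apart, the separation of the two progerin stiffness bands.
The flag remains a statistical classification: on a fresh 100-cell
sample it can still misfire occasionally, which is why scenario
conclusions in the tests are drawn at fixed seeds.

## 8. End-effector comparison scenario

The needle-vs-plate scenario contrasts max-force distributions at equal
cell populations. The plate arm is the standard simulator. The needle
arm models the narrow tip's instability as an engage-or-slip mixture:
with probability 0.3 the needle stays centered and loads the whole
cell (plate-scale peak force); otherwise it slides off-axis and pokes
the cell over its fixed tip area (2 µm diameter) only. Both outcomes
are jittered by a multiplicative lognormal slip factor (sdlog 0.3).
The engage probability mirrors the emulated observation that a needle
deforms the nucleus in roughly a quarter of attempts versus nearly
always for plates. The resulting needle max-force variance exceeds the
plate variance — the qualitative claim the scenario exists to
reproduce. This is a phenomenological model of contact instability,
not contact mechanics.

## 9. Reproducibility machinery

All randomness is drawn behind explicit integer seeds through an
internal `with_seed` that saves and restores the caller's RNG state: no
function leaves a footprint on `.Random.seed`, and equal seeds give
byte-identical sweeps, traces, frames, populations, and written
reports (tested). `pipeline_config` validates every field with units,
rejects unknown fields, reports all violations at once, and stamps
every output file with an FNV-1a hash of the canonical configuration
JSON so outputs can be traced to their settings.

Problem sizes in the test suite and acceptance script are the reported
per-condition sample sizes (16–57 cells; 100 per arm for the
overexpression panel) at 100 Hz sampling — the sizes the emulated
experiments themselves used, which also keeps the whole suite fast.

## 10. Known limitations

* The truncated-sphere contact law and the series compartment mixing
  are modeling conveniences; absolute moduli from real data depend on
  the true contact geometry, and deep-regime power-law fits are
  effective, not exact, when compartment exponents differ.
* The renderer's idealized contrast means image-path tests bound
  pixel-quantization error only, not segmentation robustness.
* "Resolution" is this package's operational definition; compare with
  instrument datasheets with care.
* The bimodality flag has a small but nonzero false-positive rate per
  sample; treat it as a screening statistic, not a hypothesis test.
* No multiple-testing correction in the population module.
* Dynamic (oscillatory) rheology is out of scope; the power-law model
  is fit to step-like constant-speed indentations only.
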