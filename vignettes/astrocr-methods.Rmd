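---
title: "Methods: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrocr)
```

This vignette is the package's own account of the science it implements:
the measurement models, the synthetic data they are validated against, the
numerical choices, and the places where the design was genuinely open.

## What is being measured, and why indirectly

Astrocytes contact synapses through perisynaptic leaflets far below the
diffraction limit, so their growth cannot be seen as added branches. The
standard workaround treats the dye-filled soma as 100% astrocyte occupancy
and reads the occupancy of the unresolved neuropil from the fluorescence
ratio

$$\mathrm{VF}(i) = \frac{F(i) - F_0}{F_{\max} - F_0},$$

where $F_0$ is the background from a dye-free circle and $F_{\max}$ the
soma peak. Everything else in the package follows the same logic: an
indirect, assumption-laden measurement (dye coupling for gap-junction
permeability, puncta statistics for connexin organization, current
decomposition for K⁺ and glutamate clearance, fEPSP ratios for plasticity)
implemented exactly, and validated on synthetic data where the underlying
truth is known.

## The synthetic generators are the study conditions

Each generator renders the features the corresponding estimator relies on,
with ground truth attached, and is a pure function of its parameter record
(every record carries a mandatory `seed`, default 42):

* **Astrocyte images** (`gen_astrocyte_image`): a flat soma plateau
  ($F_{\max}$ = 200 arbitrary units over background 10) with a soft 0.25 µm
  logistic shoulder, six straight 0.75 µm-wide branches at 90% of the
  dynamic range, a uniform leaflet field at
  $F_0 + \mathrm{VF}\,(F_{\max}-F_0)$, and a 12 µm dye-free circle of pure
  background. The default 0.25 µm/px matches the resampling target of the
  morphometry pipeline; frames are 100 µm so the 8–30 µm analysis annulus
  fits. Imaging noise is additive Gaussian; the reference "noisy" condition
  uses a noise SD of 5% of the soma peak, a conservative two-photon
  operating point. Not emulated: depth attenuation, shot-noise scaling
  with intensity, curved or tapering branches, and soma asymmetry — so
  passing tests certify estimator correctness under the stated model, not
  robustness to every real-tissue artifact.
* **Coupled networks** (`gen_coupled_network`): cells uniform in a
  spherical shell (10–80 µm) with fluorescence
  $\exp(-d/C_\lambda)(1+\varepsilon)$, multiplicative noise
  $\varepsilon \sim N(0, 0.05)$ under the reference condition.
* **Puncta frames** (`gen_puncta_frame`): discs of the stated diameter
  placed by sequential hard-core rejection (minimum separation twice the
  diameter by default) on a smooth ramped background, rendered by 4×4
  sub-pixel area coverage, blurred by a Gaussian PSF, plus Gaussian noise.
* **Sweeps** (`gen_astro_sweeps`): strict linear superposition of
  unit-peak kernels $(1-e^{-t/\tau_r})e^{-t/\tau_d}$ — a fast transporter
  kernel (200 pA, rise 1 ms, decay 8 ms), a slow potassium kernel (100 pA,
  rise 20 ms, decay 300 ms), and a small non-facilitating residual
  potassium kernel (30 pA, 5/80 ms) that survives receptor blockade.
  Because superposition is exactly linear, the five-minus-four stimulus
  subtraction recovers the fifth-stimulus component sample-exactly before
  noise; that is the point, not an artifact. The kernels are
  phenomenological: no uptake kinetics or receptor gating is simulated.
* **LTP series** (`gen_ltp_series`) and **step responses**
  (`gen_step_response`): baseline at 100% with a monoexponential (5 min)
  approach to $100 \times$ the potentiation factor, 5% amplitude CV; and an
  ohmic plateau $\Delta V / R$ with a fast capacitive transient, 2% current
  noise.

Each group preset encodes the reported group means the package is built
to recover (`group_preset()`): volume fractions 3.2%/4.5%, length
constants 19.9/26.1 µm, coupled-cell means 12.6/4.2, Cx43 densities
0.24/0.12 µm⁻², proximal Cx30 diameters 1.4/2.24 µm, K⁺ facilitation ratios
0.81/1.21, transporter decay ratios 1.28/0.97, LTP 147%/168%, input
resistance 30/30 MΩ, Cx43 blot level 1.0/0.69. In the orchestrated
experiment (`run_experiment`), between-animal variability adds ground-truth
jitter with SDs equal to the reported SEM × √n — the dispersion the printed
errors imply — truncated to positive values (and, for the Cx43 density, to
two-thirds of the hard-core jamming density so every draw stays placeable).
The acceptance script omits this jitter: its targets are defined as fixed
ground truth plus measurement noise.

## Morphometry

**Mask construction.** Planes are resampled to 0.25 µm/px (bilinear),
filtered by coherence-enhancing diffusion (structure-tensor
anisotropic diffusion: gradient smoothing σ = 1 px, tensor integration
ρ = 4 px, baseline diffusivity α = 0.05, 10 explicit iterations at
dt = 0.2), collapsed by maximum-intensity projection, and binarized against
a 51 px local mean. The threshold offset above the local mean defaults to
**3 × MAD of the residual, floored at 1% of the dynamic range**, not zero:
a zero offset marks half of any noisy background as foreground, because
local-mean thresholding is sign-symmetric around the mean. The offset
remains a plain argument (`offset = 0` reproduces bare local-mean
thresholding).

**Sholl counting.** For each radius the one-pixel-wide rasterized circle is
walked in angular order; intersections are cyclic runs of foreground
pixels, with runs that touch through 8-adjacency (e.g. across a one-pixel
angular gap) merged, so the count equals the number of 8-connected
foreground components on the ring — the property the test suite checks
against an independent graph-components oracle. Radii whose circle leaves
the frame are reported `NA`, never zero. On clean synthetic stars the
within-group variance of Sholl counts is nearly degenerate (counts pin to
the branch number), so occasional small ANOVA p-values on null data
reflect speckle at tiny variance, not a morphological effect.

**Volume fraction.** Eight profiles at 22.5°, bilinear sub-pixel sampling
at a 1 px step. $F_{\max}$ is taken from the *mean* profile rather than a
single line: the max of an 8-fold average is far less noise-inflated, which
matters because an inflated $F_{\max}$ biases VF down. Branch excision
flags contiguous runs where a lightly smoothed profile (1 µm running mean)
exceeds a 5 µm running-median baseline by more than 10% of
$F_{\max}-F_0$. The "10%" excision criterion is conventionally stated without its base
(local baseline? soma peak? dynamic range?); this package uses the dynamic
range and keeps the threshold an argument. The running-median baseline
bridges branch calibers up to ~2.5 µm; wider structures are not excised,
which is the correct behavior for the branch widths the generator draws
(0.75 µm). $F_0$ comes from the darkest feasible 10 µm circle (a disc-mean
filter over all fully contained positions), or a user-supplied circle.
Values are not clamped to $[0, 1]$; noise-driven excursions are reported
as-is.

## Coupling

The fit is the zero-intercept least-squares line of $\ln F$ on $d$
($C_\lambda = -1/\text{slope}$); the exponential law has a unit prefactor,
so the intercept is fixed, but a free-intercept variant is available
because published semilog coupling plots show generic linear fits. The
patched cell ($d = 0$, $F = 1$) is kept — it contributes nothing under the
fixed intercept — and non-positive fluorescence values are excluded with a
warning. The count of coupled cells uses a configurable detection
threshold (default 0.02 of the patched soma, twice a 1% noise floor), a
quantity the measurement convention leaves unspecified.

## Connexin clusters

Segmentation follows the high-pass recipe: detail image = plane minus its
σ = 25 px Gaussian blur (σ read as pixels); foreground where the detail
image exceeds one standard deviation above the 99th percentile of the
smoothed picture; components of ≥ 5 pixels at 8-connectivity. Two choices
deserve explanation:

* **Both statistics are referenced to the smoothed picture's dark level**
  (its minimum): `thr = P99(smooth) − min(smooth) + SD(smooth)`. An
  absolute threshold quoted from the smoothed picture cannot be invariant
  to a constant intensity offset while the detail image is; measuring the
  smoothed statistics above their own dark level restores exact offset
  invariance (a property the test suite asserts) while preserving the
  formula's sensitivity to overall scene brightness.
* **The "one standard deviation" refers to the smoothed image** by
  default. The high-pass SD grows with the puncta content itself, which
  at realistic Cx43 densities pushes the threshold so high that sub-micron
  puncta fall below the five-pixel minimum; the smoothed-image SD is both
  the more natural reading of a threshold defined on the smoothed picture
  and the one that keeps small clusters detectable. The high-pass referent
  stays selectable (`sd_ref = "highpass"`).

Cluster diameter is the maximum pairwise distance between member pixel
*centers* (convex hull + calipers, equal to the brute-force $O(n^2)$
maximum). Because the pixel-center convention loses about half a pixel of
footprint at each end, the `cx30_proximal` preset sets the punctum contrast
so that the segmentation threshold falls moderately below the half-maximum
edge; at that operating point the caliper diameter tracks the drawn
diameter (the FWHM sizing convention). The `cx43` preset instead uses
bright puncta (amplitude 400 over background ~6, 2% noise) with a slice-
realistic PSF (σ = 0.175 µm), so that 0.5 µm discs reliably exceed five
pixels — with dim sub-micron puncta the five-pixel rule, taken literally,
would silently delete the channel. Both presets are documented SNR choices,
fixed once.

Radial profiles use 0.5 µm rings from 2.5 to 50 µm. Ring areas are clipped
to the frame by fine-grid quadrature (cell = dr/10), which keeps densities
unbiased near the frame border and makes
$\sum_\text{rings} \text{density} \times \text{area}$ equal the in-range
cluster count exactly; rings wholly outside the frame are `NA` and excluded
from summary means. The soma-proximal summary covers r < 10 µm. Delaunay
edges come from the full triangulation (boundary edges included, with a
flag to drop them); two centers fall back to the single edge, collinear
sets to consecutive path edges.

## Electrophysiology

Traces are stored signed (inward negative); reported amplitudes are
magnitudes. The `I_K` rule is implemented literally: amplitude is the
extremum from 200 ms after the last stimulus to the end of the sweep, and
when the minimum sits at the window's first sample (decay already under
way) the +200 ms value is the amplitude. At +200 ms the 8 ms transporter
kernel has decayed by $e^{-25}$, which is why the window cleanly separates
the components. The default potassium rise constant is 20 ms: the kernel's
rise term has then decayed to $5 \times 10^{-5}$ at the window start, so
the fitted decay is monoexponential to better than a millisecond — with
much slower rises the tail is visibly biexponential and no monoexponential
τ is well defined.

`fit_monoexp` fits $A e^{-t/\tau} + C$ with `minpack.lm::nlsLM`
(tolerances 1e-8, up to 1000 iterations), initialized log-linearly on the
early decay (samples before the signal falls below 5% of its initial
value — initializing on the full tail lets noise dominate the slope), with
a retry ladder of coarser initial τ values. Non-convergence and fits whose
τ standard error exceeds τ are flagged, never silently replaced.

The TBOA residual is reconstructed as a saturating-exponential rise fit
(from the 2% crossing to the peak) spliced at the empirical peak to a
monoexponential decay fit, with the rise limb rescaled so the two limbs
meet exactly at the peak; the pre-rescaling mismatch is reported as a
diagnostic. Subtracting the (non-facilitating) residual — realigned to the
fifth stimulus for the isolated response — leaves the pure transporter
current, whose decay is fitted over an 80 ms window from its extremum.

Input resistance is $\Delta V / \Delta I$ with $\Delta I$ averaged over
the final 20 ms of the step; a residual plateau slope above 5% of
$\Delta I$ flags the estimate. EPSC charge transfer is the trapezoidal
area of the baseline-subtracted trace over peaks and tail windows; the
window boundaries are required arguments (the convention defines them only
graphically, as dashed lines on example traces), with defaults of stimulus-train ± 20 ms and +50 ms to the
end of the depolarization. LTP magnitude normalizes to the 15 min baseline
mean and averages 50–60 min after HFS; a 40–50 min variant also
circulates for the same protocol, so the window is an argument and the
result records which was used — the package does not pick one for you.

## Statistics and the orchestrated experiment

Group comparisons default to the two-sided pooled-variance Student's t;
one-sided tests require an explicitly declared direction, because a policy of
"one-sided when a direction was expected" cannot be reconstructed
metric by metric. No multiple-testing correction is applied,
matching the comparison framework being modeled, and the report says so.
Shapiro–Wilk p-values are reported alongside and never switch the test.
The repeated-measures two-way ANOVA (group × radius, sphericity assumed)
rejects unbalanced designs; partial η² is
$SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$ with each effect's
own error stratum. Blot normalization divides by the run-calibrator lane,
then by calibrated actin, then by the control-group mean, which is
therefore exactly 1.0 and invariant to per-blot gain and global actin
rescaling.

`run_experiment` derives one seed per animal from the master seed, so the
whole report is a pure function of (config, seed). Problem sizes follow
the modeled cohort sizes (5–12 animals per group per metric); at those sizes the
full experiment, including image-based metrics, completes in a few minutes
on one CPU, and the test suite exercises reduced versions of the same
paths.

## Known limitations

* The CED parameters and adaptive-threshold settings of the original
  imaging scripts are unknown; the defaults here are chosen to segment the
  synthetic branches cleanly and are all exposed as arguments.
* Segmentation thresholds interact with punctum contrast; the provided
  presets document two operating points (FWHM-calibrated sizing vs
  high-contrast detection) rather than pretending one threshold serves
  both regimes.
* Clusters clipped by the frame border keep their clipped diameters; how
  the original analysis treated border clusters is unstated.
* No 3D Sholl analysis, branch tracing, colocalization across connexin
  channels, or biophysical simulation of diffusion and uptake; positions
  and soma centroids are inputs, not detected from images.
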