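---
title: "Methods: simulating and quantifying water-fat MRI of brown and white adipose tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying water-fat MRI of brown and white adipose tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batwfi)
```

## The problem

Brown adipose tissue (BAT) holds its lipid in small multilocular droplets
surrounded by water-rich, mitochondria-dense cytoplasm, so its proton
density fat fraction (PDFF) is far below that of white adipose tissue
(WAT), whose adipocytes are essentially one large lipid droplet.
Chemical-shift-encoded ("water-fat" or Dixon) MRI measures PDFF
voxel-by-voxel, which makes it a candidate tool for detecting BAT inside
WAT depots and for estimating how much of a depot is BAT-like. `batwfi`
implements that whole measurement chain in silico: digital tube phantoms
with controlled BAT/WAT mixtures, forward simulation of two multiecho
gradient-echo protocols, per-voxel PDFF estimation, and histogram-based
volumetry of the low-PDFF (BAT-like) compartment.

Because every stage is simulated, the package supports closed-loop
validation: the estimators can be scored against known ground truth, and
the analysis metrics can be checked against exact conservation laws.

## Signal model

The complex gradient-echo signal of a voxel at echo time $TE$ is

$$ s(TE) = \Big(\rho_W + \rho_F \sum_p \alpha_p e^{i 2\pi \Delta f_p TE}\Big)
  \, e^{i 2\pi \psi TE} \, e^{-R_2^* TE} $$

with water density $\rho_W$, fat density $\rho_F$, fat resonances at
offsets $\Delta f_p = \mathrm{shift}_p(\mathrm{ppm}) \cdot \gamma \cdot B_0$
with normalized amplitudes $\alpha_p$, field-map off-resonance $\psi$ (Hz)
and common transverse decay $R_2^* = 1/T_2^*$. PDFF is
$100\,|\rho_F| / (|\rho_W| + |\rho_F|)$.

Defaults: $B_0 = 3$ T, $\gamma = 42.577$ MHz/T, and a six-peak
triglyceride spectrum (shifts $-3.80, -3.40, -2.60, -1.94, -0.39, +0.60$
ppm; amplitudes $0.087, 0.693, 0.128, 0.004, 0.039, 0.048$). Vendor
reconstruction pipelines rarely disclose their exact lipid model, so the
spectrum is fully configurable (`fatSpectrum()`, YAML round-trip via
`writeSpectrumConfig()`); a single-peak model at $-3.40$ ppm
(`singlePeakSpectrum()`) is what the uncorrected estimator assumes. There
is deliberately no $T_1$ term: both simulated protocols use a 3-degree flip
angle, which keeps $T_1$ weighting negligible, and densities are treated as
already $T_1$-weighted. Eddy-current phase errors, noise-floor magnitude
bias and k-space effects are out of scope.

## The phantom generator

`buildPhantom()` rasterizes cylindrical sample tubes inside a
gadolinium-doped water box (default 55 x 75 x 40 mm) onto a fine isotropic
grid (default 0.25 mm), cropped to the tubes plus a 5 mm margin to keep
memory at desk scale. Three preconfigured replicas exist
(`experimentPhantomSpec()`):

* experiments 1 and 2 - one near-pure BAT tube and one near-pure
  perigonadal WAT tube;
* experiment 3 - graded mixtures (60/40 and 40/60 BAT/WAT by volume) plus
  a pure subcutaneous WAT tube, each with an analyzed VOI volume of
  0.6 cm^3.

Tissue ground truth is distributional: each fine cell of a tissue draws
its PDFF from a truncated normal (BAT $23 \pm 6$ %, perigonadal WAT
$88 \pm 7$ %, subcutaneous WAT $91 \pm 5$ %, background water 0 %) and its
$R_2^*$ likewise (BAT 60 /s above WAT's 35 /s, reflecting BAT's higher
intracellular water and iron; Gd-water 20 /s; SDs 10, 8 and 3 /s). The
draws are independent per cell given the tissue - the simplest model
consistent with reporting voxelwise means and SDs; it deliberately omits
any within-piece spatial correlation of PDFF.

Mixtures are packed by thresholding a smooth random field (white noise on
a lattice at the clump scale, trilinearly interpolated) at the exact
sample quantiles of the target fractions, emulating hand-packed pieces of
excised tissue with a characteristic piece size (default 1.5 mm) while
guaranteeing the achieved volume fractions match the target to well under
one percentage point. Whether the real tubes were layered or interleaved
is not knowable from the study description, so a two-layer `packing =
"layered"` mode is available as an alternative; the clumped mode is the
default because pieces were placed alternately and pressed together. The
$B_0$ field map is a low-order polynomial plus a long-wavelength ripple,
rescaled to at most 60 Hz - smooth by construction, representative of a
well-shimmed small-bore setup.

Two geometry profiles exist. The `"paper"` profile is the study-condition
geometry (tube radius 4 mm, length 30 mm, fine grid 0.25 mm). The
`"small"` profile (radius 3 mm, length 14 mm, proportionally smaller box
and VOI target 0.15 cm^3) exists so that multi-seed replicas run in
seconds; every tissue parameter, protocol constant, SNR and threshold is
identical between profiles, and the test suite sizes its replicas with the
small profile.

## Acquisition simulation

Two protocols are modelled (`quantitativeProtocol()`,
`highresProtocol()`):

| protocol | echoes | TE (ms) | acquired voxel (mm) | voxel volume |
|---|---|---|---|---|
| quantitative low-res | 6 | 1.5 + n x 1.3 | 1.1 x 1.1 x 2.2 | 2.66 mm^3 |
| high-res uncorrected | 4 | 3.8, 4.8, 5.8, 6.8 | 0.5 x 0.5 x 2.2 | 0.55 mm^3 |

`acquire()` synthesizes the fine-cell signals per echo and complex-averages
the cells whose centers fall inside each acquisition voxel. That box
averaging is the partial-volume mechanism: a voxel straddling BAT and WAT
reports an intermediate complex signal, exactly as in real acquisitions.
Center-inclusion binning is used rather than requiring nested grids, since
no practical fine spacing divides both 1.1 mm and 0.5 mm in-plane voxels;
on commensurate grids it reduces to exact box averaging. Circular complex
Gaussian noise is added with per-channel SD equal to the background-water
signal over `snr` (default 80 - the scanner's true SNR is unknown, and
signal averaging, NSA, is folded into this single number). The four
acquisitions of a replica (two protocols x coronal/sagittal) use
independent noise seeds derived deterministically from the master seed.
Orientation is implemented as an axis permutation of the ground truth with
the slab direction always the third acquisition axis; no slab excitation
profile or interpolation to the nominal reconstructed voxel is applied,
because interpolation correlates voxels and would distort the counting
statistics that the volume metrics rely on (a reconstructed-voxel zero-fill
mode was considered and rejected for that reason). The high-resolution
protocol's four echo times, acquired sequentially in reality, are
simulated on identical geometry with a single noise realization per
series - the tubes are static, so inter-acquisition motion is not modelled,
and how the scanner combined the four single-echo acquisitions is not
documented; the joint four-echo fit defined here is this package's stand-in.

## PDFF estimation

Both estimators minimize
$\sum_n |s_n - \mathrm{model}(TE_n)|^2$ per voxel by **variable
projection**: for any candidate $(\psi, R_2^*)$ the water/fat amplitudes
enter linearly and are solved in closed form, so the search is over two
nonlinear parameters only. A coarse grid ($\psi$: $\pm 200$ Hz in 2 Hz
steps; $R_2^*$: 0-250 /s in 5 /s steps) locates the basin; bounded local
refinement (L-BFGS-B for the quantitative fit, Brent's method on $\psi$
for the uncorrected fit) polishes it to a relative objective tolerance
near machine precision (configurable via `fitOptions()`). The quantitative fit (`fitQuantitative()`)
requires six echoes and estimates $(\rho_W, \rho_F, \psi, R_2^*)$ with the
multipeak spectrum; the uncorrected fit (`fitUncorrected()`) fixes
$R_2^* = 0$ and assumes the single-peak fat model, reproducing the
behaviour of online fat-fraction reconstructions that ignore decay. PDFF
is computed from the fitted amplitude magnitudes and clamped to
$[0, 100]$ %; complex-valued fitting is the default, with a magnitude mode
(`fitMode = "magnitude"`) available for sensitivity checks since the
vendor's fit mode is unknown. All-zero voxels are masked invalid; a voxel
whose refinement fails keeps its coarse-grid optimum and is flagged.

The field-map ambiguity (a solution with water and fat exchanged and
$\psi$ shifted by the dominant fat offset, about $-434$ Hz at 3 T) is
resolved by `swapCheck()`: both branches' residuals are compared per voxel
and near-ties go to the branch whose $\psi$ is closer to the 3 x 3 x 3
neighborhood median. No further spatial regularization is applied - the
phantom field map is smooth by construction, and on these phantoms the
swap rate at SNR 50+ is far below 0.1 %.

Numerical notes. The fit is deterministic; the L-BFGS-B "abnormal
termination" return at machine-precision objectives is treated as
convergence provided the refined objective does not exceed the coarse
optimum (both are recomputed on one code path before comparison, since
accumulation order otherwise produces spurious 1e-16-level differences).
$R_2^*$ is unidentifiable at exactly pure water or pure fat under a
noiseless single compartment; the PDFF itself remains exact there.

## Analysis metrics

The analysis layer mirrors the study's postprocessing. `tubeVOI()` builds
programmatic VOIs (replacing interactive segmentation): voxels inside the
tube with a half-voxel wall margin, restricted to the $n$ central slices
of the occupied slab extent (ties toward the lower index; 4 slices for the
pure-tissue replicas, 8 for the mixture replica at full size), and - when
an analyzed volume is configured - truncated to the
$\mathrm{round}(V/\mathrm{voxel\ volume})$ voxels nearest the tube axis, so
the VOI volume reproduces the configured 0.6 cm^3 to within one voxel.
`voiStats()` reports mean/SD/min/max over valid VOI voxels (sample SD,
$n-1$, everywhere). `pdffHistogram()` uses 1-percentage-point bins by
default (binning was a free choice), left-closed with a closed last bin so
counts conserve. `volUnderThreshold()` counts voxels with PDFF $\le t$
(inclusive, matching the metric's definition) times the voxel volume of
the grid the map lives on, and `volumeCurve()` evaluates it on a threshold
grid; at bin edges the curve equals the cumulative histogram times the
voxel volume, exactly. `aggregateAcquisitions()` combines the four
acquisitions: mean and SD of the VOI means, and the pointwise
mean/min/max envelope of the volume curves. The 50 % segmentation
threshold is a parameter (`thresholdPct`), not a constant: it is the
observed separation point between the BAT-like and WAT-like histogram
modes in this setting and need not generalize.

## What the simulations do and do not establish

Passing tests establish that: the estimators invert their own signal
model exactly (noiseless recovery to under 0.1 pp across the PDFF range);
the refined fit is never worse than a dense grid search; the uncorrected
estimator's bias at BAT-like fat fractions grows with $R_2^*$ in the
direction of a reduced apparent fat fraction; packing fractions,
histogram/curve conservation and monotonicity hold; and the tissue
orderings (BAT mean below WAT mean; mixture-tube volume metric ordered by
BAT content) are reproduced across seeds. They do not establish accuracy
on real tissue: the generator draws cell PDFFs independently from
truncated normals (no spatially correlated heterogeneity, no temperature
dependence of fat fraction), the box has no susceptibility or air-bubble
artifacts (the study excluded artifact slices rather than modelling them),
coil sensitivity and reconstruction interpolation are omitted, and the
"true" tissue means are themselves the study's measured values adopted as
ground truth. A bias of the high-fat estimates: the two systematic errors
of the uncorrected route (single-peak spectrum, ignored decay) partially
cancel above roughly 70 % PDFF, so its apparent accuracy there is
coincidental, not a validation.

## Problem sizes used by the checks

The packaged checks run the full-geometry mixture replica once
(quantitative protocol, VOI-restricted fit) and use the small profile for
multi-seed work: 20 seeds of the complete four-acquisition mixture
replica for the ordering properties, three seeds of the pure-tissue
replica, 10,000 single-voxel fits for the recovery summaries, and a
500-voxel dense-grid oracle comparison ($\psi$ step 1 Hz, $R_2^*$ step
2 /s). These sizes were chosen so a full run completes on one CPU core in
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## A worked example

```{r example, eval = FALSE}
cfg <- experimentConfig(3, seed = 7, profile = "small")
rep <- runExperiment(cfg)
sapply(rep$tubes, function(tb) tb$aggregate$meanOfMeans)
sapply(rep$tubes, function(tb) tb$volAtThresholdMean)
```

On seed 7 this prints VOI-mean PDFFs of 41.0, 54.0 and 90.7 % for the
BAT-dominant, WAT-dominant and WAT-only tubes, with low-PDFF volumes
(threshold 50 %) of 0.099, 0.064 and 0.000 cm^3 - the BAT-dominant tube
has the lowest mean PDFF and the largest BAT-like volume, and the pure
WAT tube contributes essentially nothing below threshold.
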