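---
title: "Quantifying plaque burden by saturation-recovery relaxometry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plaque burden by saturation-recovery relaxometry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueR1)
```

## The measurement problem

Amphiphilic gadolinium chelates accumulate in atherosclerotic plaque and
shorten its longitudinal relaxation time T1.  Two quantities then track
lesion burden in vivo: the **total plaque volume** (TPV), from regions
of interest drawn on a high-resolution anatomical scan, and the
**contrast-induced relaxation-rate change**

$$\Delta R_1 = R_{1,\mathrm{post}} - R_{1,\mathrm{pre}},
\qquad R_1\,[\mathrm{s^{-1}}] = \frac{1000}{T_1\,[\mathrm{ms}]},$$

which is proportional to the local agent concentration through the
longitudinal relaxivity, $\Delta R_1 = r_1 \cdot C_{\mathrm{Gd}}$.
Estimating $\Delta R_1$ requires voxelwise T1 maps before and after
injection.  This package implements that chain — mapping, segmentation,
ROI transfer, volumetry, statistics — and pairs it with a synthetic
vessel phantom whose ground truth makes every stage verifiable.

## Signal model and pixelwise fitting

A saturation-recovery acquisition samples each voxel at delays $t$ after
a saturation pulse, repeating every TR.  The signal model is

$$S(t) = S_0\left[\,1 - (1 - B)\,e^{-t/T_1}
  - \frac{B\,e^{-t/\mathrm{TR}}}{1 - B\,C\,e^{-t/\mathrm{TR}}}\right],$$

with $S_0$ the equilibrium signal, $B$ the cosine of the effective
saturation flip angle, and $C$ the excitation term, fixed to 1 to limit
the degrees of freedom.  At $B = 0$ (perfect saturation) this reduces to
the familiar $S_0(1 - e^{-t/T_1})$, a reduction the implementation
verifies to $10^{-10}$.  $B$ varies slowly in space with the B1 field —
the basis for the multi-pass scheme below.  Note that for $B > 0$ the
signed model dips slightly below zero at very short delays; since the
data are magnitude images, the fitters compare the data against
$|S(t)|$, and the zero-noise simulator likewise returns $|S|$.

`fitVoxel()`/`fitMap()` minimise squared residuals by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) over $(S_0, T_1, B)$, with
$T_1 \in [1, 10000]$ ms, $B \in [0, 0.99]$, $S_0 \ge 0$.  Three
numerical safeguards matter in practice:

* **Variable-projection grid initialisation.**  For fixed $(T_1, B)$
  the model is linear in $S_0$, so $S_0$ has a closed form and the
  residual over a coarse $(T_1, B)$ grid costs one small matrix–vector
  product per voxel.  Levenberg–Marquardt starts from the best few
  well-separated grid points plus a generic fallback, and the lowest
  deviance wins.  A single generic start is not reliable: the cost
  surface has a competing basin in which the $B\,e^{-t/TR}$ term mimics
  the recovery with $T_1 \to 0$ and large $B$, and another local minimum
  near the $B = 0$ bound for short $T_1$.
* **Analytic Jacobian.**  For $T_1$ near or above TR the two
  exponentials are nearly collinear and the cost surface forms a long
  flat ridge; forward-difference derivatives are then inaccurate enough
  to stall the optimiser short of the minimum, which the analytic
  Jacobian prevents.
* **Rician floor removal.**  Magnitude noise biases near-zero samples
  upward (the shortest delay is the worst).  `fitMap(noiseSd =)`
  applies the power-image correction $\sqrt{\max(M^2 - 2\sigma^2, 0)}$
  before fitting; the pipeline estimates $\sigma$ robustly from the
  image background (MAD of the darkest voxels of the shortest-delay
  volume, scaled for the Rayleigh distribution).

### Multi-pass B smoothing

Pass 1 fits all three parameters per voxel.  Each later pass replaces
every voxel's $B$ with the mean over its $(2r+1)^3$ neighbourhood
(default $r = 1$; an in-plane variant is available) and refits
$(S_0, T_1)$ with $B$ fixed.  The default is 3 passes.  Smoothing
contributors are filtered to fits whose $B$ is actually informative:
$T_1$ inside $(30, 1.2\cdot\mathrm{TR})$ ms — outside that window the
ridge degeneracy leaves $B$ unidentified — and $B \le 0.45$, since
larger values are the signature of the degenerate basin rather than of
any plausible saturation pulse.  Voxels with no valid neighbour take the
mean over growing neighbourhoods, which respects the slow spatial
variation of the field.

With five delays and three free parameters, the degenerate solutions are
not a numerical artefact: on noisy data they often fit genuinely better
than the truth-like solution.  The spatial-smoothness prior on $B$ is
the regularisation that resolves this, and it is why the pipeline also
**reuses the pre-contrast B field for the post-contrast fit**
(`fitMap(bField = )`): the B1 profile is a property of the session, not
of the contrast state, and sharing it both stabilises the fast-recovering
post-contrast voxels and cancels correlated $B$ errors in the
$\Delta R_1$ subtraction.

### Precision limits

The five-point scheme (77, 200, 350, 500, 1200 ms at TR 1500 ms) bounds
what any estimator can do.  At a noise level of 2 % of $S_0$, the
Cramér–Rao limit for per-voxel $T_1$ is several percent even with $B$
known exactly, and of order 10 % for the free-$B$ fit; the package's
fits sit at this limit (they match exhaustive grid search), so the test
suite asserts the achievable properties — that multi-pass smoothing
reduces $T_1$ RMSE, that noiseless recovery is exact, that ROI-level
$\Delta R_1$ tracks truth — rather than sub-bound voxelwise precision.
Lesion-level $\Delta R_1$ is accurate because averaging over the ROI
suppresses the voxelwise noise.

## The synthetic phantom

`phantomSpec()` describes one synthetic animal: a straight vessel along
the slice axis (lumen radius 0.55 mm, wall 0.2 mm — an idealised mouse
ascending aorta), wall-attached ellipsoidal plaque blobs, and four
compartments with pre-contrast T1 defaults of 2200 ms (blood), 1300 ms
(wall), 1100 ms (plaque) and 900 ms (background) — physiological
high-field values.  Equilibrium signal is piecewise-constant per
compartment, with a dim (air-like) background so intensity masks isolate
tissue.  The contrast agent accumulates only in plaque;
$T_{1,\mathrm{post}}$ follows $R_{1,\mathrm{post}} = R_{1,\mathrm{pre}}
+ r_1 C_{\mathrm{Gd}}$ with $r_1 = 18$ L·mmol⁻¹·s⁻¹, the plasma
relaxivity of the amphiphilic agent the design emulates.  The post-
contrast state is static (a single post-injection time point; no
kinetics).  The B field is a constant plus one long-wavelength Gaussian
bump (defaults: mean 0.1, amplitude 0.15, scale 3 mm, i.e.
$B \in [0, 0.3]$), honouring the slow-variation assumption.  Noise is
Rician — the modulus of a complex Gaussian perturbation — at 2 % of the
maximum $S_0$ by default for the mapping protocol and 1 % for the
(signal-averaged) anatomy protocol; neither value is reported by typical
scanner protocols, so both are exposed in the spec.  Voxels are
0.18 × 0.18 × 0.22 mm with slices along the last axis; world position is
`fovOrigin + (index − 1) · voxelSize` in mm.

What the phantom does **not** emulate: partial-volume mixing beyond
voxelisation (compartments are crisp), motion, flow artefacts in blood,
proton-density variation within compartments, coil sensitivity profiles,
and contrast-agent kinetics.  Passing tests therefore demonstrate the
correctness and calibration of the estimators under the stated model,
not robustness to every artefact of in vivo data.

## Segmentation, ROI transfer and volumetry

TPV follows the summed-ROI definition: per-slice ROI area × slice
thickness, i.e. voxel count × voxel volume.  `thresholdSegment()`
implements semiautomatic threshold segmentation with 26-connected
component filtering (8-connected in plane).  The pipeline's default
threshold policy works on the post − pre anatomy **difference image** —
the agent is plaque-confined, so the difference is lesion-specific: the
difference is smoothed in plane (3 × 3), and the threshold is the larger
of $k\hat\sigma$ ($k = 3$, $\hat\sigma$ by MAD) and half the peak
difference (the full-width-half-maximum rule, which compensates the
smoothing blur at the lesion boundary).  When the difference carries no
measurable noise the smoothing is skipped and the half-peak rule alone
applies, making noiseless segmentation exact.  A fixed-intensity
threshold on the post-contrast anatomy is available as an alternative
policy; no numeric threshold is canonical, which is why it is
configurable.

`transferROIs()` moves ROIs between grids through their shared world
frame.  Each target voxel is probed with a regular 4³ sub-grid of
points; it joins the ROI when at least half of its volume is covered by
the source mask (a nearest-neighbour mode is also provided).  This
handles field-of-view shifts and unequal voxel sizes; on matched grids
it is an exact identity, and a transfer-and-back round trip can lose at
most the boundary voxel layer.

Interobserver agreement is simulated by a seeded reader model — each
slice's ROI is randomly kept, dilated or eroded by one voxel — and
scored as the Pearson correlation of the two readers' TPV vectors.  Real
manual-delineation variability has structure (lesion conspicuity,
reader bias) that this model does not capture.

## Statistics

Group values are mean ± SEM (sample SD / √n).  Comparisons use the
unpaired two-tailed Mann–Whitney test via `stats::wilcox.test`: exact
U-distribution enumeration when the smaller group has ≤ 8 observations
and there are no ties — the regime of this design's groups of five,
where exact inference matters — and the normal approximation with tie
and continuity correction otherwise.  The test suite checks the exact
branch against full permutation enumeration.  Correlations are Pearson's
r via `stats::cor.test` (two-sided p from the t transform on n − 2 df)
with strength bands on $|r|$: strong (0.8, 1], substantial (0.6, 0.8],
moderate (0.4, 0.6], fair (0.2, 0.4], almost non-existent [0, 0.2].  The
conventional band edges overlap at 0.8/0.6/0.4/0.2; the half-open
closure with the boundary in the lower band follows how boundary values
are labelled in practice (an $|r|$ of exactly 0.4 reads "fair").  No
multiple-testing correction is applied, matching the analysis style this
package mirrors.  Cross-measure correlations pool progression and
regression animals across time points (configurable).

## The in-silico study

`defaultStudyConfig()` encodes the emulated design: five animals per
group and time point, progression at 9/13/17/21 weeks on diet
(20 animals) and regression at 13/19/25 weeks after the diet switch
(15 animals); each (animal, week) is an independent synthetic case.  The
group ladders calibrate the generator: plaque Gd concentration is
$\Delta R_1 / r_1$ for per-week nominal $\Delta R_1$ of
0.28/0.5/1.06/3.29 s⁻¹ (progression) and 0.49/0.58/1.33 s⁻¹
(regression), and lesion size follows nominal MRI-scale volumes of
0.44/0.63/1.36/1.91 mm³ (progression) and 1.04/1.25/1.45 mm³
(regression; the later regression points are chosen to continue the
group's shallower, more linear rise).  Ex vivo analogue measures (2D
plaque area, 3D preparation volume) are derived from ground-truth
geometry with fixed scale factors — area ≈ 0.0373 mm²/mm³ and a
volume shrinkage of ≈ 0.24 relative to the MRI scale, reflecting the
several-fold difference between in vivo and preparation-based volumes —
since preparation and microscopy are outside the package's scope.
Per-animal biological variability is lognormal with CV 0.25 on both
lesion size and uptake, a realistic spread that keeps five-animal groups
informative.  Size and uptake draws are independent, so correlations
between size- and uptake-based measures in the synthetic study are
carried by the time course, not by a per-animal coupling.

One global seed fans out to per-case seeds through a counter scheme, so
extending the cohort never perturbs existing animals; reports are
bit-reproducible under a fixed seed.  Per case, the pipeline fits the
pre map (3 passes), reuses its B field for the post map, forms
$\Delta R_1$, segments the anatomy difference, transfers the ROIs to the
map grid, and records TPV, reader-perturbed TPV, mean plaque
$\Delta R_1$, and truth.  `recoveryBenchmark()` reduces this to per-case
relative errors and estimate-versus-truth correlations.  Default problem
sizes — 32 × 32 × 10 voxel grids, ~700 fitted voxels per map, 35 cases —
keep a full study at a few minutes on one CPU while leaving every
compartment several voxels wide.

## Known limitations

* Voxelwise $T_1$ precision is protocol-limited (see above); results
  should be read at ROI level.
* The wall compartment is thin (≈ 1 voxel), so wall-$T_1$ statistics are
  boundary-dominated.
* The reader-perturbation model under-represents human variability;
  interobserver r in the synthetic study is optimistic.
* `transferROIs` handles rigid shifts and voxel-size changes only — no
  rotation or deformable alignment.
* NIfTI orientation metadata is limited to voxel size; the
  field-of-view origin travels in the JSON sidecars.
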