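# plaqueR1

Quantification of atherosclerotic plaque burden from contrast-enhanced
MRI: pixel-wise saturation-recovery T1 mapping with B1 correction,
ΔR1 quantification of gadolinium uptake, ROI-based plaque volumetry with
cross-resolution ROI transfer, and the accompanying group statistics.
The package targets preclinical relaxometry studies — vessel-wall imaging
of hyperlipidemic mouse models with an amphiphilic, plaque-accumulating
gadolinium agent — and ships a synthetic vessel-phantom generator with
full ground truth so that every stage of the analysis is testable end to
end without scanner data.

## The model

Saturation recovery samples the longitudinal magnetization at several
delays *t* after a saturation pulse.  Each voxel's magnitude signal is
fitted with

    S(t) = S0 · [ 1 − (1 − B)·e^(−t/T1) − B·e^(−t/TR) / (1 − B·C·e^(−t/TR)) ]

where `S0` is the equilibrium signal, `B` the cosine of the effective
saturation flip angle (B = 0 is perfect saturation, reducing the model to
`S0·(1 − e^(−t/T1))`), and `C` the excitation-pulse term, fixed to 1.
Fitting is per voxel by bounded Levenberg–Marquardt with a
variable-projection grid start, in several passes: the first pass fits
(S0, T1, B) freely; later passes replace B by its neighbourhood mean —
the B1 field varies slowly in space — and refit (S0, T1) with B fixed.

Relaxation rates and contrast uptake follow

    R1 [s⁻¹] = 1000 / T1 [ms]        ΔR1 = R1_post − R1_pre = r1 · C_Gd

with `r1` the agent's longitudinal relaxivity (default
18 L·mmol⁻¹·s⁻¹) and `C_Gd` its local concentration.  Total plaque
volume (TPV) sums per-slice ROI areas times slice thickness; plaque ROIs
drawn on the high-resolution anatomy are transferred to the T1-map grid
through world space, honouring differing voxel sizes and field-of-view
shifts.  Group summaries are mean ± SEM, comparisons use the unpaired
two-tailed Mann–Whitney test (exact for the small tie-free groups this
design produces), and correlations are Pearson's r with the conventional
strength bands (> 0.8 strong, 0.6–0.8 substantial, 0.4–0.6 moderate,
0.2–0.4 fair, ≤ 0.2 almost non-existent).

## Worked example

One synthetic animal (progression group, week 17 on high-fat diet),
paired pre/post-contrast acquisition, mapping and quantification:

```r
library(plaqueR1)

spec  <- phantomPreset("progression", week = 17, seed = 42)
study <- makePairedStudy(spec)
study
#> PairedStudy (seed 42)
#>   SR series: 32 x 32 x 10 voxels @ 0.18 x 0.18 x 0.22 mm with 5 delays
#>   anatomy:   32 x 32 x 10 voxels @ 0.18 x 0.18 x 0.22 mm
#>   truth plaque volume: 1.525 mm^3

mask <- compartmentLabels(study@truth) > 0L
pre  <- fitMap(study@pre,  passes = 3, mask = mask, noiseSd = 20)
post <- fitMap(study@post, mask = mask, noiseSd = 20, bField = bMap(pre))
pre
#> RelaxationMap: 32 x 32 x 10 voxels @ 0.18 x 0.18 x 0.22 mm
#>   698 fitted voxels (100.0% converged)
#>   T1 median 1189 ms, B median 0.253

dmap <- deltaR1(pre, post)
rois <- roiSet(compartmentLabels(study@truth) == 3L,
               voxelSize(study@truth), fovOrigin(study@truth))
roiMeanDeltaR1(dmap, rois)
#> 1.305            # s^-1; ground truth r1 * C_Gd = 1.301 s^-1
totalPlaqueVolume(rois)
#> VolumeResult: TPV 1.525 mm^3 (214 voxels, 6 slices with ROI)
```

The mean plaque ΔR1 of 1.305 s⁻¹ recovers the simulated uptake
(r1·C_Gd = 1.301 s⁻¹) to 0.3 %; the TPV is the plaque voxel count times
the voxel volume.  `runStudy(defaultStudyConfig(seed = 1))` chains the
same steps over the full design — five animals per group and time point,
progression imaged at 9/13/17/21 weeks on diet and regression at
13/19/25 weeks after the diet switch — and `recoveryBenchmark()` scores
every estimate against the generator's ground truth.

A thin command-line front end over the same functions is included at
`inst/cli/plaque-r1.R` (`simulate`, `fit`, `volumetry`, `stats`, `run`
subcommands, YAML study configs).

## Limitations

Voxel-level T1 precision is bounded by the five-point delay scheme: at
2 % magnitude noise the per-voxel error is on the order of 10 %, which
is why the pipeline reports ROI-level ΔR1 (noise averages out over the
lesion, and fixing the session's B1 field across the pre/post pair
cancels correlated errors).  See the methods vignette
(`vignettes/plaque-r1-methods.Rmd`) for the full account of the model,
the phantom, and the numerical design choices.
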