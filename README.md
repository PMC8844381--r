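# polarcall

Stain-free detection of embryo polarization onset from DIC time-lapse
recordings.

At the late 8-cell stage, mouse embryo blastomeres each form an apical
protein domain — *polarization*, the first cue of the
trophectoderm / inner-cell-mass fate split. Polarization is normally read
out with a fluorescent apical marker, which live clinical embryos cannot
be given. `polarcall` implements a pipeline that calls the polarization
onset frame from the label-free DIC channel alone:

1. **Compress** each 5-D recording (t, z, c, y, x): the DIC z-stack is
   fused to a single all-in-focus frame with a dual-tree complex wavelet
   transform (per-coefficient maximum magnitude across slices, lowest-z
   tie-break); the fluorescence z-stack is collapsed by maximum-intensity
   projection.
2. **Annotate** ground truth from fluorescence: onset = first frame whose
   closed apical cap covers ≥ 1/3 of a blastomere surface; compaction =
   first frame whose smallest inter-blastomere angle exceeds 120°
   (for equal radii `r` at center distance `d`,
   angle = 180° − 2·atan((d/2)/√(r² − d²/4))).
3. **Classify** each DIC frame as before/after onset with an ensemble of
   small CNNs (half SGD, half Adam), averaging member probability vectors
   element-wise and thresholding the after-onset mean at 0.5.
4. **Call the onset**: smooth the chronological labels with a window-3
   majority vote (ends untouched) and take the first after-onset index;
   a recording with no positive prediction falls back to the frame after
   its last.
5. **Evaluate** with the full statistical protocol: confusion metrics with
   1000-replicate percentile-bootstrap 95% CIs, ROC/AUC (Mann–Whitney,
   ties ½), two-proportion z-test, exact Wilcoxon matched-pairs
   signed-rank test, Pearson correlation, and multi-rater majority voting
   with seeded tie-breaks.

A synthetic embryo-movie generator with exact compaction and polarization
ground truth (depth-dependent defocus, growing apical cap, onset-coupled
DIC texture cue) makes the whole pipeline testable without any imaging
data.

## Worked example

The bundled experiment generates 50 synthetic embryos (40 train / 10
test, 64×64 px frames, ~24 frames per embryo), fuses them, trains the
6-member ensemble for 5 epochs, and evaluates (about seven minutes on one
CPU):

```r
library(polarcall)

res <- run_pipeline(list(seed = 1, ensemble = list(epochs = 5)))
glance(res$frame_report)
#> # A tibble: 1 × 5
#>   accuracy sensitivity specificity   auc n_frames
#>      <dbl>       <dbl>       <dbl> <dbl>    <int>
#> 1    0.988       0.975           1  1.00      250

glance(res$onset_report)
#> # A tibble: 1 × 6
#>   mae_model_s mae_proxy_s within_one_frame wilcoxon_p pearson_rho n_embryos
#>         <dbl>       <dbl>            <dbl>      <dbl>       <dbl>     <int>
#> 1        412.       9836.              0.9    0.00195       0.650        10
```

Reading the numbers: the ensemble classifies 98.8% of the 250 held-out
frames correctly; the called onset lands within ±1 frame of ground truth
for 9 of 10 test embryos with a mean absolute timing error of about 7
minutes, whereas using compaction as a proxy for polarization errs by
~2.7 hours on average — significantly worse by the paired Wilcoxon test
(p ≈ 0.002) — because compaction precedes polarization by several frames
in these cohorts.

Individual stages are plain functions over matrices and tibbles:
`fuse_aif_dtcwt()`, `max_intensity_projection()`,
`annotate_polarization_onset()`, `measure_interblastomere_angle()`,
`train_ensemble()`, `ensemble_predict()`, `compute_cam()`,
`smooth_labels()`, `call_onset()`, `time_discrepancy()`,
`evaluate_frames()`, `evaluate_onsets()`; reports have `tidy()`,
`glance()` and `autoplot()` methods. A thin command-line wrapper lives in
`exec/polarcall` (`simulate`, `fuse`, `annotate`, `run`).

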