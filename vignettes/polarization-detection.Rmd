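---
title: "Detecting embryo polarization onset from stain-free DIC recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting embryo polarization onset from stain-free DIC recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(polarcall)
```

## The problem

At the late 8-cell stage, each blastomere of the mouse embryo forms an
apical protein domain on its contact-free surface. This *polarization* is
the first cue of the trophectoderm-versus-inner-cell-mass fate decision, so
knowing *when* an embryo polarizes is clinically and biologically valuable.
The ground truth is visible only with a fluorescent reporter (for example
Ezrin-RFP accumulating in an apical cap), but staining or microinjection is
not an option for embryos that must stay viable. The question this package
addresses: can polarization onset be called from the label-free DIC channel
alone, using the fluorescence channel only once, to annotate training data?

The pipeline is:

1. **Compression (t, z, c, y, x) → (t, y, x)**. Each DIC z-stack is fused
   into a single all-in-focus (AIF) frame with a dual-tree complex wavelet
   transform (DTCWT); each fluorescence z-stack is collapsed by
   maximum-intensity projection (MIP).
2. **Annotation**. Polarization onset is the first frame whose largest
   *closed* apical cap covers at least 1/3 of a blastomere's visible
   surface (read off the fluorescence MIP); compaction is the first frame
   whose smallest inter-blastomere angle strictly exceeds 120°. Every frame
   at or after onset is labelled after-onset, every earlier frame
   before-onset.
3. **Classification**. An ensemble of small CNNs is trained on the labelled
   AIF DIC frames; at test time the member probability vectors are averaged
   element-wise and thresholded at 0.5.
4. **Onset calling**. Per test embryo, the chronological label sequence is
   smoothed by a window-3 majority vote (ends untouched) and the first
   after-onset index becomes the called onset.
5. **Evaluation**. Confusion metrics with 1000-replicate percentile
   bootstrap CIs, ROC/AUC, a two-proportion z-test for classifier-vs-rater
   accuracy, a two-sided exact Wilcoxon matched-pairs signed-rank test on
   paired onset errors, Pearson correlation of onset indices, and
   majority-vote aggregation of multiple raters with a seeded coin for
   3-3 ties.

## The wavelet fusion

An optical section far from a structure's focal plane carries little
high-frequency energy; an in-focus section carries much. The DTCWT gives
six complex, directionally selective subbands per scale and is
near shift-invariant, so per-coefficient magnitude comparison across
slices is meaningful. Fusion picks, for every highpass coefficient, the
slice with the largest magnitude (ties go to the lowest z index so results
are reproducible), fuses the lowpass band by averaging (or per-pixel
maximum local variance, if configured), and inverts.

The transform itself runs four parallel separable wavelet trees (row tree
× column tree, each "a" or "b") under circular extension, so each tree is
perfectly invertible and the forward-then-inverse round trip is exact to
floating point — the test suite asserts a relative error below 1e-6, and
observes ~1e-12. Level 1 uses the Antonini 9/7 biorthogonal pair with
tree b at the opposite polyphase; deeper levels use a 12-tap orthonormal
lowpass filter whose passband group delay approximates a quarter-sample
offset, with tree b its time reverse. That quarter-shift filter was
designed for this package with a paraunitary lattice parameterization:
perfect reconstruction holds for *any* lattice angles, and the angles were
optimized for linear passband phase at the quarter-sample target plus
stopband attenuation. Its defining properties (unit energy, vanishing
even-lag autocorrelation, group-delay deviation below 0.1 samples over the
passband) are unit-tested rather than assumed. Arbitrary frame shapes are
symmetrically padded to a multiple of `2^n_levels` and cropped back;
`n_levels` defaults to 4 and is clamped to `log2(min(dim))`; fusion output
is clamped to the input intensity range.

## The synthetic embryo generator

No imaging data ships with the package. Instead, `generate_recording()`
renders 5-D recordings with exact ground truth, and every downstream claim
is validated on those. Design choices worth knowing:

* **Geometry.** Eight equal-radius blastomeres sit in two rings of four
  (two z layers). Compaction is realized by moving centers together: the
  smallest inter-blastomere angle follows a linear trajectory that first
  strictly exceeds 120° at `compaction_frame`, and the critical contacting
  pair's radii and distance are recorded per frame so the angle series can
  be re-measured analytically with `measure_interblastomere_angle()`. The
  angle uses circle-overlap geometry — for equal radii `r` at distance
  `d`, angle `= 180° − 2·atan((d/2)/sqrt(r² − d²/4))`, so `d = r` gives
  exactly 120° — rather than pixel-level contour fitting, because the
  generator knows its geometry exactly; a contour-based estimator
  (`estimate_angle_from_masks()`, tangent fit over short boundary arcs) is
  provided for mask images and agrees within ~3° at ordinary resolutions.
* **Fluorescence.** A faint membrane outline everywhere; from
  `polarization_frame` on, a bright apical arc on the first polarized
  blastomere covering exactly the ground-truth cap fraction, which starts
  at 1/3 (the annotation threshold, inclusive) and grows by
  `cap_growth_per_frame` (default 0.06/frame).
* **DIC and defocus.** Each blastomere renders as a soft-edged disk with a
  membrane ring and an interior texture. A slice at optical distance `dz`
  from the cell's focal plane widens the edge to
  `sqrt(w0² + (defocus_sigma_per_um · dz)²)` and attenuates a texture of
  wavelength λ by `exp(−(σ·2π/λ)²/2)` — the analytic effect of Gaussian
  defocus on a sinusoid — so defocus genuinely destroys high-frequency
  content and AIF fusion genuinely restores it.
* **The polarization cue in DIC.** From the onset frame, a fine ripple
  (wavelength 5 px) appears along every membrane, with amplitude
  proportional to `dic_cue_strength` (default 1, giving a cue of roughly a
  fifth of the frame's contrast after fusion). A texture change, not a
  brightness change, was chosen so per-image standardization cannot
  trivially separate the classes; what DIC feature encodes polarization in
  real embryos is unknown, and no realism claim is attached to this knob.
  Setting it to 0 leaves only the compaction geometry as a (lagged,
  imperfect) correlate of the labels.
* **Timing.** Frame intervals are drawn uniformly from 1200–2400 s, z
  steps are 4 µm, and recordings default to 24 frames (a typical 8-cell
  window at half-hour intervals). Cohorts jitter recording length (±4
  frames), compaction frame (±2), the compaction-to-polarization lag
  (at least `min_lag = 3` frames; compaction typically precedes
  polarization), geometry and noise, with each embryo's seed derived
  deterministically from the master seed.
* **Noise** is additive Gaussian (`noise_sd`, default 0.02 of unit
  intensity, stored as 16-bit counts). Poisson shot noise, optical
  aberrations, cell divisions and photobleaching are *not* modelled — so
  passing tests demonstrate the pipeline's internal correctness and
  end-to-end recoverability under controlled conditions, not performance
  on real microscope data.

## The classifier

The desk-scale backbone is a 3-block conv net: 3×3 convolution (8, 16, 32
maps) → ReLU → 2×2 maxpool, then global average pooling (GAP) and a 2-way
dense softmax head; inputs are 64×64 per-image-standardized grayscale
frames. Six members differ in initialization seed and optimizer: the first
half SGD (momentum 0.9, learning rate 0.05), the second half Adam (1e-3),
batch 8, flip/90°-rotation augmentation (embryos have no canonical
orientation), global gradient-norm clipping at 5, and a step decay (×0.5
after 60%, ×0.25 after 85% of epochs) that stabilizes the short training
runs. Forty epochs is the configured default; the bundled end-to-end
experiment trains 5 epochs, which suffices on synthetic cohorts. A
residual-network backbone with pretrained initialization is the natural
upgrade on real data; no pretrained weights ship with this package, so
`backbone` other than `"smallconv"` or `pretrained_init = TRUE` raise
errors rather than silently substituting.

Because the head is linear over GAP features, the class activation map
`sum_f w[class, f]·featuremap_f` satisfies `mean(raw map) = logit − bias`
exactly; `compute_cam()` returns the raw map, its bilinear upsampling to
input resolution, and both sides of that identity, which the tests check
to 1e-4 for every trained member.

Ties: an ensemble mean after-onset probability exactly at the threshold is
called before-onset (conservative: a frame is only called polarized on
positive evidence); label-majority mode resolves 3-3 member votes the same
way. Human-rater aggregation, by contrast, flips a seeded fair coin on
ties, mirroring how a panel's tied vote carries no information.

## Temporal logic

Smoothing recomputes every strictly interior position as the majority of
the *raw* labels in its window, in one simultaneous pass — not
sequentially in place, which would make the result depend on scan order.
Ends stay untouched. The onset is the first after-onset index of the
smoothed series; for monotone series this coincides with the point where
the majority switches from before to after (the alternative reading), and
the tests pin the equivalence on monotone inputs. For adversarial
non-monotone series beginning with 1 the two readings can differ; the
first-index semantics is the one implemented. A recording with no
after-onset prediction uses the frame just past the end as its effective
onset, so a missed onset is penalized by the remaining recording length.
Discrepancies are stored signed in seconds (rounded to the nearest
second); paired statistics consume absolute values.

## Statistical choices

* Bootstrap CIs are percentile intervals (not BCa), resampling the
  analysis unit: frames for frame-level metrics, embryos for per-embryo
  discrepancy summaries. B defaults to 1000; intervals are deterministic
  given the seed. A point estimate falling outside its percentile interval
  is logged as a warning, not an error.
* AUC is the Mann–Whitney concordance probability with ties counted 1/2,
  and equals the area under the threshold-sweep ROC; the suite
  cross-checks it against brute-force pair counting and against an
  independent ROC implementation.
* The Wilcoxon matched-pairs signed-rank test drops zero differences,
  mid-ranks ties, reports `W = min(W+, W−)`, and computes the two-sided p
  by exact enumeration of all 2^n sign assignments for n ≤ 15 (valid under
  ties, where the classical exact tables are not), falling back to the
  tie-corrected normal approximation beyond. The implementation is checked
  against `stats::wilcox.test` in tie-free cases and against direct
  enumeration with ties.
* The two-proportion z-test is the pooled-variance form with a two-sided
  normal p; a pooled proportion of 0 or 1 is flagged rather than reported
  as a number.

## Problem sizes and determinism

The bundled end-to-end experiment generates 50 embryos (40 train / 10
test, ~24 frames each, 64×64 px, 5 z slices), trains the 6-member ensemble
for 5 epochs, and evaluates with B = 1000 — about seven minutes on one
CPU. These sizes are the package's desk-scale stand-in for a full imaging
study; the configuration scales all of them through `validate_config()`.
Every stage seed derives from the master seed as
`derive_seed(seed, stage_name)`, so adding a stage never perturbs earlier
stages and a fixed master seed reproduces the entire report byte for byte.

## Known limitations

* The synthetic DIC physics is stylized; no claim transfers to real DIC
  recordings without retraining and re-annotation.
* The contour-based angle estimator assumes two dominant contact
  endpoints and degrades for exterior angles well below 90°.
* Training the small backbone from scratch for very few epochs is noisy;
  individual members occasionally train poorly, which is precisely why
  the ensemble averages probabilities.
* TIFF storage is exact for 16-bit integer intensities (the generator's
  native range); floating-point tensors must be quantized before
  `write_recording()`.
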