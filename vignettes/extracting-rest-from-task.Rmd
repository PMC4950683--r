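---
title: "Extracting resting-state analogues from task fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting resting-state analogues from task fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restex)
```

## The problem

Seed-based functional connectivity is conventionally computed from
continuously acquired rest, yet much archived fMRI was collected under
block-design tasks. `restex` implements the strategies in common use for
recovering rest-like signal from such runs and the machinery for judging
how rest-like the result actually is. This vignette explains the models and
procedures, the parameters that matter, the synthetic data the package is
validated on, and the design decisions taken where more than one reading
was defensible.

## Timing model

A block design is a list of labelled events (onset, duration, in seconds)
with a repetition time `tr` and a volume count. Volume `i` (0-based) is
assigned its acquisition onset time `i * tr`, and all interval logic is
half-open `[onset, onset + duration)`. This convention is arbitrary but
unambiguous, and every cutting rule below is expressed in it.

Two designs ship as fixtures. The finger-tapping design (RFT) is
6 × 10 s task blocks interleaved with 7 × 10 s baselines: 130 s, 93 volumes
at TR 1.4 s. The emotion-discrimination design (EDT) is 4 emotion and
4 object blocks of 20 s, alternating with 20 s baselines plus a final
baseline. The EDT block list sums to 340 s although the design is usually
quoted as 320 s total; the arithmetic of the published block grid does not
match its own quoted total, and the fixture keeps the block list verbatim
rather than silently shortening a baseline. Nothing downstream depends on
which reconciliation is chosen — only on the blocks actually present.

The canonical HRF is the conventional double-gamma: a response gamma
peaking at 6 s minus an undershoot gamma peaking at 16 s scaled by 1/6,
unit dispersions, 32 s support, sampled on the TR grid and normalised to
unit maximum. All six parameters are exposed via `hrf_params()`. Boxcars
are built at TR resolution without microtime upsampling: the delay
estimation below works in whole-TR steps, so a finer grid would add nothing
the procedure could use.

## Delay estimation

`estimate_shift()` shifts the task model forward in integer TR steps
(front-padding with zeros, truncating at the run end), correlates each
shifted copy with a measured occipital ROI time course, and returns the
argmax, capped at 7 TRs (9.8 s at TR 1.4 s). Ties break toward the smaller
shift, for determinism. Constant inputs are rejected — the correlation is
undefined — rather than silently returned as zero.

The reference series is a genuinely open choice. Shifting the *raw boxcar*
(the default) means the estimated shift absorbs the entire hemodynamic
delay — rise time and subject-specific lag together. Shifting the
*HRF-convolved response* (`reference = "convolved"`) isolates the
subject-specific delay beyond the canonical shape. The two are not
equivalent: on simulated data whose evoked responses are canonical-HRF
convolutions of a delayed boxcar, the raw-boxcar estimator returns the
latent delay plus a constant offset of about 3–4 TRs (the best whole-TR
approximation to the canonical rise), while the convolved reference
recovers the latent delay exactly in the noiseless case. Both variants are
tested; parameter-recovery checks use the convolved reference because the
generator's ground truth is defined as the latent delay. Under the default
generator settings the recovered delays scatter around the truth with a
mean absolute error of roughly 0.5–1 TR across realisations of 8 subjects;
occasional subjects land 2 or more TRs off when a slow spontaneous
fluctuation happens to align with a shifted copy of the regressor.

## Extraction methods

* **ORIG** passes the run through unchanged.
* **BLOCK** (`segments_fixed()`): for each baseline block, the retained
  interval runs from 15 s after the preceding task block's end
  (`post_gap`) to 5 s after the following task block's onset
  (`pre_extension`). A baseline with no task neighbour on one side keeps
  its natural boundary there. The 5 s reading deserves a note: "the first
  5 s at the start of each task block count as rest" is interpreted as
  *extending* the baseline into the following task block, on the
  hemodynamic-delay rationale; the alternative reading (no extension) is
  available as `pre_extension_mode = "none"`. Both readings leave the RFT
  design with under 30 s of rest, so nothing that matters hinges on it.
* **BLOCKvar** (`segments_var()`): each baseline is
  `[onset + shift, onset + shift + duration)`, truncated at the run end,
  with the shift from `estimate_shift()`.
* **REG**: per-voxel OLS residuals against the HRF-convolved task
  regressors, one per task condition, plus an intercept. Nuisance series
  (motion, tissue, global) deliberately do **not** enter this regression —
  they belong to the connectivity stage, keeping the two-stage order
  observable and testable.
* **BlockREG**: REG first, then concatenation of the residuals using the
  BLOCKvar intervals. Reusing the delay-adaptive (rather than fixed)
  intervals follows from the method being described as a combination with
  the adaptive variant; `blockreg_intervals = "fixed"` selects the other
  reading.

Seconds-to-volume conversion rounds the interval start up and the end down
(`ceil`/`floor`), the conservative choice: a boundary volume is only kept
if its acquisition onset lies strictly inside the retained interval at both
ends. Concatenation gathers volumes by index — values are never altered —
and cuts every confound column identically, so the later nuisance
regression stays temporally aligned. Concatenation refuses to proceed below
a configurable minimum of 30 s retained; on the RFT design the fixed
cutting rule retains 14 s, so BLOCK is refused there, and the pipeline
records the skip rather than producing a map from 10 volumes.

## Connectivity

The processing order is fixed and deliberately observable: nuisance
regression, then band-pass, then seed correlation. For concatenated inputs
the filter runs on the concatenated series — extraction happens before the
standard rest preprocessing, not inside it; the per-segment alternative
would change edge behaviour and is intentionally not the default. Tests pin
the order by showing that permuting the stages changes the output.

Nuisance regression removes 6 motion parameters, white-matter and
ventricular series, optionally the global signal (`use_gsr`), plus an
intercept, per voxel by OLS. The band-pass is an order-2 Butterworth
applied forward and backward (zero-phase, so lag structure is preserved);
coefficients come from `signal::butter`, while the forward–backward
application is implemented in-package, vectorised over voxel columns with
odd-reflection padding and steady-state initial conditions. The initial
conditions matter here: the 0.009 Hz band edge puts filter poles close to
the unit circle, and zero-state filtering would leave edge transients
longer than a concatenated BLOCK run. The implementation agrees with
reference forward–backward filtering to ~1e-13 on shared fixtures. Runs
shorter than 12 volumes are rejected.

Seeds are 3×3×3-voxel cubes; the map is the voxelwise Pearson correlation
with the cube-mean time course, clipped to |r| ≤ 1 − 1e-7 and Fisher
z-transformed. The clip keeps the seed's own voxels finite (atanh(1) would
be infinite) while preserving ranks; z at a perfectly correlated voxel is
atanh(1 − 1e-7) ≈ 8.1.

## Similarity and group statistics

Each method's maps are compared with maps from genuine rest truncated to
the *same number of volumes* (`match_duration()`), so differences reflect
the extraction, not the amount of data. Three metrics are computed over the
identical masked voxel set:

* **ICC(A,1)** — two-way absolute-agreement single-measures intraclass
  correlation, voxels as targets, the two maps as raters. The
  absolute-agreement form is sensitive to mean and scale offsets between
  maps; the consistency form (C,1) is selectable. This sensitivity is
  exactly why ICC and R² can disagree, and a test pins the distinction.
* **Dice** at z ≥ 0.3, on the positive tail only. The threshold is applied
  to raw z values; whether maps should be variance-normalised first is an
  open question in the literature and is deliberately not second-guessed
  here. When both suprathreshold sets are empty the value is 0 and flagged.
* **R²** — squared Pearson correlation across voxels, affine-invariant;
  the signed r is kept for the Fisher transform.

Group statistics Fisher z-transform the correlation-type metrics (ICC via
atanh; R² via its signed r; Dice untransformed), then run a one-way
repeated-measures ANOVA on the method factor — subjects as the repeated
factor, the test-retest condition included as a level — and Welch
two-sample t-tests of each method against test-retest, two-sided and
uncorrected (a Bonferroni option exists but defaults off). The one-way
repeated-measures model is a deliberate simplification of a full mixed
factorial ANOVA; the method factor is the scientific question, and the
simpler model keeps the implementation in base R (`aov` with an
`Error(subject)` stratum) and exactly testable.

## The synthetic generator

`synth_truth()` defines the study conditions: a 20×20×10-voxel grid with
five 3×3×3 "network" masks (dmn, cuneus, thalamus, sensorimotor, auditory)
plus an occipital ROI used for delay estimation. Each network's voxels
share a band-limited latent series — Gaussian noise hard-masked in the
frequency domain to 0.009–0.08 Hz and rescaled to unit variance — matching
the analysis band so connectivity is identifiable. All voxels additionally
receive a global fluctuation (amplitude 0.3, random positive per-voxel
loadings), a motion-coupled artefact (0.2) built from six random-walk
motion parameters, tissue-signal leakage (0.1), and unit-variance white
noise. Task runs add an evoked response per configured network: the summed
condition boxcar, delayed by the subject's integer-TR hemodynamic delay,
convolved with the canonical HRF, unit-peak-normalised and scaled by the
network amplitude (occipital 1.2, sensorimotor 0.8, dmn −0.6 — the
negative dmn amplitude models task deactivation, giving the extraction
methods genuine task contamination to remove in a network of interest).
Per-subject delays are drawn uniformly from 2–5 TRs; integer delays make
exact recovery a testable property, and non-integer robustness is a
separate concern. Rest runs are 360 s; none of the amplitudes are
calibrated to any empirical SNR figure — they are chosen once for
identifiability at desk scale.

The generator emulates the statistical structure the pipeline depends on:
band-limited shared fluctuations, evoked responses with subject-specific
delays, global/motion/tissue nuisance, white noise. It does not emulate
scanner drift, spikes, physiological aliasing, spatial autocorrelation from
smoothing, EPI distortion, or anatomical geometry. Passing tests therefore
demonstrate that the pipeline's mathematics is correct and that the
methods' *relative* behaviour (duration effects, task-contamination
removal) emerges as expected — not that any particular similarity value
will be observed on real 7 T data.

## End-to-end behaviour

`run_experiment()` ties the stages together deterministically from a master
seed (per-subject, per-run RNG streams are derived from it). With the
default conditions — 8 subjects, EDT design, GSR on — the group-mean ICC
and R² order as: test-retest above REG above BLOCK. The ordering has two
causes the generator makes explicit: REG keeps the full run length while
BLOCK keeps ~88 s of 340 s (fewer samples mean noisier correlation maps),
and concatenation splices discontinuities into the series. The experiment
runs in a few minutes on one CPU at these sizes; 8 subjects rather than a
realistic 20–30 keeps the full suite fast while leaving group statistics
meaningful.

## Known limitations

* Event-related and parametric designs, HRF derivative terms, FIR/
  deconvolution task removal and ICA-based cleanup are out of scope.
* Delay estimation is whole-TR only, and a single shift per subject/run.
* Real-data mode expects caller-supplied tissue masks and mm-to-voxel
  mapping via the NIfTI header; no segmentation or registration is
  attempted.
* The Dice threshold interacts with run length through the variance of z;
  comparisons across methods of very different durations should lean on
  ICC and R², which the duration-matched reference handles cleanly.
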