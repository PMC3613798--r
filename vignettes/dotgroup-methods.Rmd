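---
title: "Models and methods behind dotgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dotgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotgroup)
```

`dotgroup` implements a complete desk-scale pipeline for studying
perceptual grouping by colour and by motion: a random-dot stimulus
simulator, a synthetic multi-subject BOLD generator with known ground
truth, a two-level GLM with number-of-groupings parametric modulators,
sign-flip cluster inference, conjunction by masking, and behavioural and
eye-tracking summaries. This vignette records the models, the parameter
choices, and the design decisions taken where more than one reasonable
reading existed.

## The stimulus model

A stimulus is a field of `n_dots = 680` dots of 10 px diameter on a
1024 × 768 px area. Dots start on a cell-centred grid and each is offset
independently on x and y by a uniform draw in ±10 px, giving even but
unstructured coverage. The grid shape is chosen as the factor pair of the
dot count with the most nearly square cells — 34 columns × 20 rows for the
defaults. Offsets can push an edge dot slightly outside the field; it is
wrapped immediately, consistent with the running wrap rule.

Per frame, an ungrouped dot updates as

1. heading jitter: θ′ = θ + U(−0.2, 0.2) rad;
2. rightward bias: v = s·(cos θ′, sin θ′) + (1.5, 0) px/frame;
3. renormalisation: displacement = s · v/‖v‖ with s = 1.7 px/frame.

The stored heading becomes the direction of the realised displacement, so
the bias accumulates and the background streams left to right while every
dot still moves exactly 1.7 px per frame. The pre-bias magnitude to which
the heading unit vector is scaled is not uniquely determined by the verbal
description of the update; we scale to the nominal speed itself, which
makes the bias-to-speed ratio (1.5/1.7) scale-free and keeps the update
independent of the units of s.

Up to three circular grouping regions of 100 px diameter are placed by
rejection sampling, with every disc fully inside the field. We read "no
two regions coincident" as non-overlapping discs (pairwise centre distance
of at least one diameter); the weaker reading — merely not identical — is
noted but rejected, since touching regions would visibly merge groups.

In the **colour-grouping** condition the regions stay fixed and all dots
move as background dots; a dot whose centre is inside any region (ties
count as inside; the dot radius is ignored) displays the single group
colour, drawn once per stimulus from the full 8-bit RGB cube and shared by
all regions, and reverts exactly to its own base colour on exit. In the
**motion-grouping** condition membership is fixed at initialisation: all
grouped dots, across groups, follow one shared unbiased random walk with
identical per-frame displacements, and the shared heading is reversed by a
full 180° whenever the next step would carry any grouped dot past a screen
edge (we considered per-axis reflection and rejected it as a departure
from the stated reversal). Because departing groups would leave holes, the
motion-grouping field is advanced through 100 undisplayed burn-in frames
before the 5 s display. Greyscale stimuli replace each random colour by
the CIE 1976 L\* lightness of that colour (sRGB primaries, D65 white,
IEC 61966-2-1 linearisation; grey = round(255·L\*/100)), so the greyscale
field inherits the luminance distribution of a colour field.

Static stimuli are a single frame drawn at random from a freshly generated
zero-group moving sequence of the matching colour type. With no groups the
burn-in is a distributional no-op, so static frames skip it.

The frame rate is not fixed by the stimulus geometry itself; from the dot size
(10 px ≈ 0.2°, hence ≈ 50 px/°) and the dot speed (1.7 px/frame ≡ 1.7°/s)
the implied rate is 50 Hz, which is the default and is configurable. One
root seed drives independent named streams (positions, colours, regions,
motion, group colour, static-frame choice), so a change in one stage's
draw count never perturbs another stage and every sequence is exactly
reproducible.

## The synthetic BOLD model

One session has `n_volumes = 110` retained volumes at TR 3.264 s, with
7 lead-in volumes simulated and discarded (T1 equilibration). Trials sit
on a fixed 8 s pitch (5 s stimulus + 3 s blank); the category sequence
over the six presentation categories (each moving condition with and
without groupings, plus the two statics) is a first-order Markov chain
with self-transition probability 0.3 against a uniform 1/6, which favours
short runs of the same category. Grouped moving trials draw 1–3 groupings
uniformly. A schedule is redrawn (rarely needed at realistic lengths)
until every category appears and both moving conditions have varying
grouping counts, mirroring a presented experiment in which all cells
occur; without this guarantee the parametric modulator would occasionally
be undefined in a session.

The forward model for a voxel is

y = baseline + Σ amplitude·(boxcar ⊛ HRF) + slope·(centred modulator ⊛ HRF)
  + drift + AR(1) noise,

using exactly the regressor construction the analysis fits, so the
noiseless model is inverted to machine precision (a property the tests
assert). Defaults, chosen once as representative of visual-cortex fMRI:
baseline 100 with condition amplitudes of 0.1–1.0 (≈ 0.1–1 % signal
change), grouping slopes of 0.4 %/group in attribute-selective regions and
0.3 in the shared region, AR(1) noise with coefficient 0.3 and unit
marginal SD, drift as two sinusoids of periods 200 s and 320 s (amplitudes
1.5 and 1.0) — both slower than 160 s so the 120 s high-pass must remove
them — and a between-subject SD of 20 % of each effect. The toy volume is
20³ voxels: full-brain geometry adds nothing to correctness and is hostile
to desk-scale simulation. The effect layout encodes the qualitative
dissociation the analysis is designed to detect: a colour-slope sphere
("V4-like"), a motion-slope sphere ("V5-like"), two contiguous,
non-overlapping compartments carrying one slope each ("IPS-like"), and one
region carrying both slopes ("cerebellum-like"). The masks themselves are
disjoint.

Head-motion nuisance series are slow random walks that do not enter the
signal; the keypress regressor is the HRF-convolved train of simulated
response times. Simulated behavioural accuracy by grouping count (85, 80,
89, 85 % for 0–3) and RTs near 2.9 s follow the observed task-difficulty
profile. The gaze generator produces fixation-like scatter at a
configurable sampling rate with optional dispersion gain during grouping
epochs and random invalid samples; gain 1 is the null of no oculomotor
response to grouping.

What the generator does **not** emulate: spatial autocorrelation of the
noise (voxels are independent), anatomical geometry and spatial
normalisation, scanner physics, slice timing, and motion-correlated signal
artefacts. Tests passing on this generator therefore validate the
estimator chain and its calibration under the stated noise model, not
robustness to spatially structured real-scanner noise.

## The analysis model

**Design.** Events are boxcars convolved with the canonical double-gamma
HRF (peak delay 6 s, undershoot delay 16 s, unit dispersions, undershoot
ratio 6, 32 s support), sampled through a 16× microtime grid. The
six-condition variant splits each moving condition by the presence of
groupings; the four-condition variant adds, per moving condition, a linear
parametric modulator whose event weights are the grouping count
mean-centred across that condition's events — centring decorrelates the
modulator from the condition mean and fixes the otherwise arbitrary
sharing of signal between the two. Every task regressor carries its
temporal derivative (finite difference of the oversampled convolution);
derivatives are treated as confounds and never enter contrasts, the more
conservative of the two readings of "derivatives were added for each
contrast vector". Nuisance series are appended unconvolved; each session
keeps its own intercept, nuisance block and drift basis, while task betas
are shared across a subject's concatenated sessions.

**Filtering.** The 120 s high-pass projects out the discrete-cosine set
with periods ≥ 120 s from both data and design. The projection is
idempotent, spares the intercept (the DCT set is orthogonal to the
constant), and is exactly equivalent to including the DCT columns as
confounds — the fit tracks the projected-out degrees of freedom so both
routes give identical t-maps, a property the tests assert. Runs shorter
than the cutoff are passed through with a warning.

**Estimation and inference.** Per-voxel OLS (no prewhitening; AR
whitening is out of scope, and the simulated AR(1) noise mildly inflates
first-level dof rather than biasing estimates), residual dof
= volumes − rank − DCT order. Contrast t-maps use
t = c'β̂ / sqrt(σ̂²·c'(X'X)⁻¹c); voxels with zero residual variance are
flagged, never divided. The second level is the summary-statistics
random-effects route: a one-sample t on subject contrast images,
df = subjects − 1, zero-variance voxels flagged. Cluster-extent inference
thresholds the group t-map at voxelwise p < 0.001 (one-sided), labels
clusters by 18-connectivity (faces + edges — the convention of the
standard neuroimaging packages; 6 and 26 available), and calibrates the
familywise-corrected cluster p against the permutation distribution of the
maximum cluster size under random sign flips of the subject maps — exact
under symmetric errors and fully testable at desk scale, unlike
random-field theory, which is out of scope. Fewer than 100 permutations
is refused as an unstable null. A Bonferroni factor across the declared
contrast family can be folded in. Conjunctions mask one contrast's
suprathreshold voxels (default p < 0.001) by a second contrast's
suprathreshold set at the uncorrected mask threshold (default p < 0.05).

A calibration caveat the package states openly: with spatially independent
subject maps and a 0.001 cluster-forming threshold, suprathreshold voxels
are nearly all isolated, the maximum cluster extent is almost always 1,
and the permutation p-value is therefore heavily discrete. The sign-flip
test remains valid — its realised familywise error is far *below* the
nominal 5 % — but it cannot be made to sit *at* 5 % without spatially
smooth maps (smoothing is out of scope) or a continuous cluster statistic
such as mass (the implemented statistic is extent by design). The
acceptance suite therefore contains one intentionally strict calibration
check that documents this conservatism.

**Behaviour and eye tracking.** Accuracy is the fraction of trials whose
reported grouping count equals the true count, per true count, with RTs
averaged over correct trials and paired two-sided t-tests across subjects
between counts; empty cells are reported missing, and identically-zero
difference vectors (e.g. two perfect cells) get p = 1 by convention.
Eye-tracking sessions are kept only when strictly more than 80 % of
samples are valid. Gaze dispersion per stimulus epoch is
sqrt((var x + var y)/2) over the epoch's valid samples — a bare
"standard deviation of the eye position" does not fix the axis treatment
or temporal support, so this whole-epoch form is the default and a
sliding-window variant is available behind a flag; neither is asserted to
be the original. The reported statistic is the Pearson correlation between
epoch dispersion and a binary grouping indicator, flagged undefined below
3 epochs or under zero variance.

## Numerical choices and degenerate inputs

* Rejection sampling for region placement is capped (10,000 draws) purely
  to guard pathological geometries; the default geometry cannot hit the
  cap.
* The kinematic update guards a zero-norm velocity (impossible at the
  default bias < speed) by falling back to the jittered heading.
* Residual variances below the data's double-precision floor are clamped
  to exactly zero so that exact fits are flagged rather than producing
  astronomically large t-values.
* Modulators whose event weights are identically zero (a session where one
  moving condition happens to have a constant grouping count) are dropped
  from that session's design; subject-level combination uses the sessions'
  shared task columns and warns.
* Cluster labelling is a breadth-first search over suprathreshold voxels
  only, so permutation nulls with few suprathreshold voxels cost almost
  nothing.

## Problem sizes used by the validation suite

The suite runs the calibration at 500 null cohorts of 16 subjects on 20³
voxels with 200 sign flips, and slope recovery on 50 cohorts of 16
subjects × 2 sessions × 110 volumes, sizes chosen to give stable Monte
Carlo estimates (binomial SE ≈ 1 % for the calibration, slope-mean SE
≈ 0.7 % of the true slope for recovery) on a single desk-class CPU. The
high-pass frequency-response probe uses a 600-volume run so that spectral
leakage of the probe sinusoids, not the filter, stays below the measured
thresholds.

## Known limitations

* No spatial smoothing, realignment or normalisation; maps live in toy
  voxel coordinates.
* OLS without AR prewhitening slightly misstates first-level standard
  errors under autocorrelated noise; the second level, which all reported
  inference uses, is unaffected.
* The extent-based permutation test is conservative on spatially
  independent maps (see above).
* The stimulus exporter stores continuous positions and 8-bit colours; it
  does not render frames (an image/video export can be layered on the
  frame table).
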