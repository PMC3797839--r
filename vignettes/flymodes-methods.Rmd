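---
title: "Six-mode segmentation of fly locomotion: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six-mode segmentation of fly locomotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymodes)
```

## The phenotyping model

A walking fly in a horizontal arena is reduced to two directed quantities
per frame: where its centroid is going (the direction of progression,
`alpha_v`, the direction of the instantaneous velocity vector) and where its
body is pointing (the head direction `alpha_b`). Locomotor coordination is
summarized by the *angular interval* `phi = wrap(alpha_v - alpha_b)`: zero
when the fly walks where it faces, 90° when it walks sideways, 180° when it
walks backwards. Three binary predicates — is the fly covering ground, is
its body rotating, is its path curving — jointly classify every frame into
one of six coordination modes:

| | no rotation | rotation |
|---|---|---|
| straight path | A (fixed front on straight path) | B (rotation on straight path) |
| curved path | C (fixated front on curved path) | D (rotation on curved path) |
| no progression | L (lingering) | R (rotation in place) |

Each predicate is *span-level*, not frame-level: the unit of evaluation is
an inter-arrest segment, a maximal run of frames on which the relevant
signal (speed `v_c`, body angular velocity `omega_b`, or path-direction
angular velocity `omega_v`) stays outside its arrest tolerance band. A
segment counts as progression when the spatial spread of its centroid
positions (maximum pairwise distance) exceeds `d_ling`; as body rotation
when the angular spread (max − min of the unwrapped orientation) exceeds
`theta_ling`; as path curvature when the angular spread of the direction of
progression exceeds `psi_str`. Frames inside a speed segment that fails the
spread test are *lingering even though instantaneously moving* — lingering
is a staying-in-place episode that tolerates sub-threshold wobble.
Curvature is evaluated only within progression spans: a path direction is
meaningless while the animal stays in place.

## Data-intrinsic thresholds

The thresholds are not magic numbers; they are read off the data. For each
fly, the distribution of spread values over its inter-arrest segments is
bimodal (or trimodal): a lower component generated by tracker noise and
postural wobble, and an upper component generated by genuine excursions. A
Gaussian mixture fitted by EM separates them, and the x-value at which the
weighted component densities intersect is the segmentation threshold; per-fly
intersections are averaged. For body rotation the lower (wobble) peak is
sometimes itself better described by two Gaussians, so the component count
(2 vs 3) is chosen per fly by BIC and the intersection between the two
*rightmost* components is used. Distances from the wall of
progression-segment frames, pooled over flies, are fitted with a
3-component mixture whose intersections define wall / near-wall / central
zones.

The shipped default configuration is the reference operating point of the
method: `d_ling` = 4.7 mm (about one body length), `theta_ling` = 12°,
`psi_str` = 13°, central-zone boundary 10 mm from the wall, and circling
criteria `p_rot` > 0.85 or a single rotational episode exceeding 360°.
`threshold_set()` returns it, and `fit_threshold_set()` re-derives all of
it from data.

```{r}
threshold_set()
```

### EM details

The mixture fit uses 10 restarts from quantile-spread initializations
(first restart at evenly spaced quantiles, the rest at seeded random
quantiles), a log-likelihood tolerance of 1e-8, at most 500 iterations, and
discards restarts in which a component standard deviation collapses below
1e-6 of the data range. The fit is deterministic given its seed. When the
intersection quadratic has no root strictly between the two component
means (heavy overlap), the argmin of the summed weighted density on a
10,000-point grid between the means is used instead. These are declared
package defaults; no reference values for them exist.

## Smoothing and derivative estimation

Positions and orientations are smoothed in two stages: a repeated running
median (window `rrm_window = 5` frames, repeated `passes = 3` times)
removes isolated tracker glitches that would bias any least-squares
smoother, then a tricube-weighted local *linear* regression
over `lowess_window = 13` frames (≈0.5 s at 25 Hz) provides both the
smoothed value and, as its local slope, the time derivative. Speed and its
direction come from the smoothed derivatives of x and y; `alpha_v` is then
unwrapped, re-smoothed by the same procedure, and differentiated to give
`omega_v`. Body orientation is unwrapped before smoothing so cumulative
rotations beyond 360° survive (a 540° pirouette has an angular spread of
540°, not 180°).

Two numerical choices deserve emphasis:

* **Arrest tolerance bands.** A smoothed real-valued signal is never
  exactly zero, so arrests are defined as `|signal| <= eps`. The defaults,
  `eps_v` = 2 mm/s and `eps_omega` = 10°/s, sit roughly three standard
  deviations above the noise floor of the corresponding derivative
  estimators under typical tracking noise (0.2 mm in position, 3° in axis
  angle, at 25 Hz with the default smoothing), and one to two orders of
  magnitude below typical walking speeds (~30 mm/s) and rotation rates.
  This placement is what makes transitions sharp: the smoothing kernel's
  tails decay through the tolerance band within ~2–3 frames of a step
  change, so segment boundaries land within a couple of frames of the true
  event even though the kernel itself spans 13 frames.
* **Direction hold at low speed.** The direction of a velocity vector of
  near-zero magnitude is pure noise. Below 3 mm/s the last reliable
  direction is held (carried forward) before the re-smoothing of
  `alpha_v`, so arrest-period direction noise cannot leak into neighboring
  moving frames and fake path curvature.

One temporal-resolution caveat follows from the cascade: `omega_v` passes
through two smoothing stages, so a step change in path curvature *during
continuous progression* is smeared over roughly half a second. Curvature
onsets and offsets adjacent to arrests are sharp (the progression span
boundary truncates the smear). Analyses that need frame-accurate curvature
transitions mid-run should shorten `lowess_window` at the cost of noise
robustness.

## Head/tail resolution and backward walking

Axis-tracking software reports the body axis as an angle with period 180°:
`alpha1` and `alpha1 + 180°` describe the same axis. Within each
wall-to-wall segment (maximal run of valid frames between wall-contact and
jump exclusions) the package takes the frame of maximum raw centroid speed
as reference — at speed, the head faces the direction of progression — and
propagates the choice to all other frames by always taking the conjugate
that minimizes the wrap-aware frame-to-frame orientation change
(implemented exactly by unwrapping the doubled axis angle). The physical
assumption is that a fly does not rotate its body 180° in 40 ms. The
payoff is backward walking: when the velocity vector reverses within one
frame while the body orientation stays continuous, the angular interval
jumps to 180° and the digitizer emits code 4, instead of the body appearing
to teleport. Segments whose peak speed never reaches the arrest tolerance
have no usable reference and are flagged `ambiguous` (orientation resolved
only up to conjugacy).

Ties for the maximum-speed reference frame are broken by taking the
earliest frame; threshold comparisons are strict (`>`); digitizer bin edges
at 22.5° + k·45° assign boundary values to the lower-|phi| bin. All three
rules are measure-zero decisions fixed for determinism.

## The symbolic layer

Every valid frame becomes a two-character token: the mode letter and the
digitized angular interval (0 aligned, 1 diagonal, 2 sideways, 3
diagonally backward, 4 backward; 9 for non-progressing frames, where the
interval is undefined; left and right are collapsed because the analysis
does not distinguish them). Invalid frames become the unmatchable token
`--`, which keeps string offsets aligned with frames and stops
regular-expression matches from crossing gaps. Mode clusters are maximal
same-letter runs of at least 3 frames; shorter runs are sub-clusters,
bypassed in the transition chain (their neighbors become adjacent, and
same-mode neighbors merge so the transition matrix keeps a structurally
zero diagonal). Transition matrices are counted on midsection frames only —
the phase between the first and last half-maximum speed crossing of a
movement segment — because starts and ends have strongly non-stationary
mode usage. Rows are normalized to probabilities (outgoing convention);
`normalize = "column"` is available because the alternative reading of the
normalization is defensible.

## What the synthetic generator emulates — and what it does not

`generate_session()` Euler-integrates a scripted sequence of modes at the
tracker frame rate: centroid motion from scripted speed and path curvature,
body orientation from scripted rotation plus, optionally, a first-order
relaxation toward the direction of progression at rate `gain` (1/s). Intact
flies behave as a high-gain system; drugged dynamics are emulated by
lowering the gain, which widens the angular interval on the same path.
Tracker imperfections are modeled as additive Gaussian noise on positions
and on the axis-valued angle, and the head/tail ambiguity is restored by
emitting only `alpha_b mod 180`. Body orientation is always continuous;
a scripted `phi0` redirects the *path* (the one-frame velocity reversal
signature of backward walking), never the body.

The generator validates that scripted parameters actually realize each
mode's defining predicates (e.g. a lingering step must not translate) and
errors otherwise, naming the step. The reference `six_mode_script()`
brackets curvature changes with arrests, respecting the `omega_v`
resolution caveat above, and stays in the central zone of the default
arena so no wall re-aiming perturbs the planted labels.

What passing the synthetic suites does **not** show about real data: real
flies change speed continuously rather than stepwise, groom, interact with
walls, and produce tracker artifacts (identity of head/tail across long
wall contacts, merged blobs) that no additive-noise model captures. The
synthetic results validate the algorithmic chain — signal estimation,
segmentation, classification, symbolization — not the biological
calibration of the thresholds, which is what the mixture-fitting machinery
is for on real recordings.

## Choices made where the design was genuinely open

* Smoothing parameters (13-frame local regression, 5-frame running median,
  3 passes) are declared defaults at ≈0.5 s scale; the robust-smoothing
  approach itself is standard for trajectory differentiation.
* The per-fly 2-vs-3 component decision for the body-rotation mixture is
  made by BIC; the original procedure left it informal.
* `p_rot` is computed over frames (time-weighted), reading "cumulative
  percentage within a movement segment" as a time share.
* The staging `theta_max` is the maximum single-episode cumulative angle
  among rotational episodes overlapping the movement segment.
* Zone re-masking is single-pass: zone boundaries derived once are not fed
  back to re-mask wall frames iteratively. `wall_boundary` defaults to
  3 mm (≈ one body length) and is re-derivable from the zone fit.
* Jump exclusion (no reference definition exists) uses a spike rule: a
  frame is a jump when both its incoming and outgoing implied speeds
  exceed 200 mm/s, an order of magnitude above normal walking; this marks
  the displaced frame, leaves its neighbors valid, and is idempotent.

## Problem sizes used in the validation suites

The test and acceptance suites run on synthetic sessions of 400–500 frames
(16–20 s at 25 Hz), mixture-recovery experiments with 8 synthetic flies of
5,000 spread samples each, and oracle-equivalence sweeps of 100 random
instances per operation. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping the default suite fast.

## Known limitations

* Temporal resolution of curvature transitions mid-progression is ~0.5 s
  (see above).
* Head/tail resolution is per wall-to-wall segment; a segment whose fastest
  frame is a backward-walking frame would be resolved backwards. Real
  recordings make this vanishingly rare (backward bouts are slow and
  short), but it is a structural assumption, not a theorem.
* The EM threshold machinery needs enough inter-arrest segments per fly
  (≥ 20 per component) and genuinely bimodal spreads; `fit_threshold_set()`
  falls back to its initial values with a warning otherwise.
* Group-level inference (ANOVA, rank tests, log-linear models on mode
  proportions) is intentionally out of scope; the package produces the
  descriptive per-session quantities those tests consume.
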