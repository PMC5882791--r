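---
title: "Methods: simulation and scoring of a digital visual screening battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and scoring of a digital visual screening battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokesight)
```

strokesight implements the computational core of a tablet-based visual
screening battery for stroke survivors: a tumbling-E near-acuity test driven
by an adaptive staircase, kinetic perimetry with moving fixation anchors and
reaction-time-corrected isopters, digital line-bisection and cancellation
tests for visual inattention, and the diagnostic test-accuracy statistics
used to validate such a battery against bedside screening and formal
perimetry. Because the package has no touchscreen attached, it also ships a
generative observer model so that every scoring path can be exercised, and
its calibration checked, entirely in software. This vignette records the
models, the tunable parameters and the design decisions.

## Screen geometry

All positions are expressed in degrees of visual angle for a flat panel
viewed perpendicularly at a working distance of 330 mm (the near-reading
distance at which the battery is administered). A physical offset of $d$ mm
from the fixation point subtends $\arctan(d/D)$ with $D$ the viewing
distance; no small-angle approximation is used anywhere, so stimulus sizing
stays correct for large, low-vision letters. The default device profile
(2560x1600 px at 300 ppi) is ordinary tablet hardware, but every conversion
takes an explicit `screen_spec()`, so the package is device-agnostic.

The peripheral target reproduces the Goldmann size III stimulus: 4 mm$^2$ at
the 300 mm perimeter bowl radius, i.e. an equal-area disc of diameter
$2\arctan(\sqrt{A/\pi}/D_{ref}) \approx 0.431$ deg. The rendered target
matches this *angular* subtense at the tablet's own 330 mm distance rather
than the physical 4 mm$^2$, because equivalence for the observer is angular.
The exact rendered size is a package convention — the battery it models is
documented only as subtending "a similar angle" to Goldmann III.

## Acuity: 2-down-1-up staircase

An optotype at level $L$ logMAR has limbs of $10^L$ arcmin and a height of
$5 \times 10^L$ arcmin; heights are converted to millimetres by the exact
tangent at 330 mm. The adaptive rule is the standard transformed up-down
staircase: the level drops one step after two consecutive correct swipe
responses and rises one step after any error (a missing response counts as
an error — conservative for screening). Defaults: start 0.8 logMAR, step
0.2 until the second reversal and 0.1 thereafter, termination at 6 reversals
or 30 trials, floor -0.3 / ceiling 1.4, threshold = mean of the last 4
reversal levels, non-gradable with fewer than 4 reversals. The source
battery does not publish its staircase internals; these are conventional
psychophysics defaults, and all of them are `staircase_config()` parameters.

The 2-down-1-up rule targets the 70.7%-correct point of the psychometric
function. The simulated observer uses a high-threshold rule
$P(\mathrm{correct}) = \gamma + (1-\gamma-\lambda)\,[L \ge \theta]$ with
guess rate $\gamma = 0.25$ (4AFC) and lapse rate $\lambda$; on this step
function the staircase oscillates between the lowest lattice level at or
above $\theta$ and one fine step below it, so the reversal-mean estimator
converges to the midpoint of that pair (e.g. 0.15 for $\theta = 0.2$ on a
0.1 lattice). The tests assert the mean of 500 simulated runs against this
closed-form convergence point, not against $\theta$ itself.

## Kinetic perimetry

The fixation anchor visits the four screen corners; from each corner the
black target appears at the screen edge and moves inward at constant angular
speed (default 3 deg/s) along meridians pointing into the opposite screen
quadrant (defaults 15/45/75 deg within each quadrant, two repeats), giving
24 boundary presentations per eye plus four centre-anchored catch trials.
Corner anchoring is what lets a 10-inch panel test eccentricities in the
60-degree range. None of the counts, speeds or meridian placements of the
original battery are published; these are explicit `perimetry_config()`
defaults chosen as ordinary kinetic-perimetry practice.

The patient taps when the target is first seen. During the reaction latency
$\tau$ the target continues inward, so the perceptual boundary lies at
$\mathrm{raw} + v\tau$; this correction is exact (to floating point) for an
observer with constant latency, which the acceptance checks exploit. $\tau$
is estimated as the median tap latency on the centre-anchored catch trials,
restricted to detections still at suprathreshold eccentricity (at least half
the start eccentricity): a catch target that crossed into a spared central
island is reporting entry time, not latency, and would inflate the estimate.
The source battery incorporates reaction time without stating how it is
measured; this estimator is the package's documented invention, with a
configurable fallback (0.5 s, flagged) when no catch trial is usable.

A fixation loss observed by the tester deletes the presentation and inserts
a retest. Deletion is a flag, not removal, so the deleted fraction remains
auditable; scoring uses the latest valid repeat per meridian.

### Classification

Per eye, a meridian is defective when undetected or when its corrected
eccentricity falls below `defect_fraction` (default 0.5) of the tested
extent; a quadrant is defective when more than half its meridians are. A
defect is homonymous when the same visual-field quadrants are defective in
both eyes; two stacked quadrants on one side grade as hemianopia, exactly
one as quadrantanopia. Macula sparing is declared when, despite the defect,
centre-anchored catch trials into the defective hemifield were detected
within the sparing radius (default 5 deg, plus a 2 deg tolerance for
latency noise) in both eyes.

Sessions are non-gradable when the deleted fraction exceeds 0.3 in either
eye, or when more than 25% of presentations in *expected-seen* quadrants go
unanswered. The restriction to expected-seen quadrants is deliberate: in a
complete hemianopia the blind-side presentations are legitimately
unanswered, and counting them would misgrade every dense defect as
non-gradable. An unanswered trial on the seen side, by contrast, indicates
inattention to the task, not to the stimulus.

### Field filter

The "see what the patient sees" view paints the binocular defect region
(the homonymous defective quadrants, intersected across eyes, minus the
spared central disc) over a camera image centred on fixation, replacing it
with the region's mean colour; all other pixels are untouched. The image
half-width is mapped to the maximum tested eccentricity — only the sparing
disc depends on that scale.

## Inattention

Line bisection uses six horizontal lines (100 mm, centre offsets of both
signs); the deviation of each tap is a signed percentage of the half-length,
positive rightward. Cancellation uses a balanced 40-target board (20 per
side, jittered 5x8 grid, seeded, none on the midline); balance makes the
laterality index interpretable. The laterality index is
$LI = (R - L)/(R + L)$ over marked targets, so positive values mean left
omissions; the formula and its cutoff are not published by the source
battery and are package conventions. Stroke thickness is calibrated to the
measured acuity (the threshold letter-height equivalent, floored at
0.5 mm), so low vision does not preclude testing; non-gradable acuity falls
back to a flagged maximum thickness.

Grading follows a two-test screen: the battery is "consistent with
inattention" when either $|LI| > 0.14$ or the mean bisection deviation
magnitude exceeds 10%, with the side taken from the omissions (positive LI
or rightward deviation both mean left-sided inattention). Both cutoffs are
flagged as non-normative configuration: in the clinical workflow this
grading is adjudicated by an expert, and the defaults exist so that the
pipeline has a deterministic rule to test.

## Simulated observers

`observer_profile()` bundles: per-eye visibility predicates built from the
defect taxonomy (normal; homonymous hemianopia left/right; the four
homonymous quadrantanopias; macula-sparing hemianopia, default 5 deg
sparing); a lognormal reaction-time distribution (default median 0.5 s,
log-sd 0.2, i.e. latency sd near 0.1 s); lapse 0.02 and guess 0.25; a
lateralised cancellation gradient (clamped linear, normalised so strength 1
extinguishes the most peripheral target on the neglected side); a systematic
bisection bias with Gaussian motor jitter; and a fixation-loss rate. All
sessions are seeded and bit-reproducible, and simulations restore the
caller's RNG state.

The detection model finds the entry eccentricity of each inward ray into
the seen region by bisection (80 iterations, so the boundary is recovered
to well below the 1e-9 deg tolerance used by the exactness checks). It
assumes the seen set along a ray is an interval ending at fixation, which
holds for the whole archetype taxonomy; a target seen *only* at fixation
itself is treated as undetected, which is what makes a complete hemianopia
produce no response on blind-side meridians. What the generator does not
model: eye movements and fixation quality (losses are an exogenous rate,
not a gaze process), extinction under bilateral stimulation, fatigue,
response bias differences between taps and swipes, and hemianopia-neglect
interaction. Passing tests therefore demonstrate the correctness and
calibration of the scoring pipeline under this generative model, not the
clinical accuracy of the battery on real patients.

Cohort simulation treats each instrument (app, bedside confrontation, gold
standard) as a categorical channel with truth-conditional
sensitivity/specificity and an independent untestable rate — exactly the
structure the 3x3 accuracy analysis consumes. The untestable rates are free
parameters, not estimates: the validation study reports untestability only
qualitatively.

## Test-accuracy statistics

The intention-to-diagnose analysis keeps "unable to assess" as an explicit
third category in a 3x3 table. Complete-case analysis drops the unable row
and column; the untestable-as-incorrect policy scores an unable index result
as a false negative against a positive reference and a false positive
against a negative one (unable reference results are always excluded).
Sensitivity, specificity, PPV and NPV carry exact Clopper-Pearson intervals
(beta-quantile inversion of the binomial tails). Every estimate object
records its convention — reference axis, policy, CI method — because the
published accuracy row for the field comparison corresponds to treating the
*column* (app) margin of the printed table as the reference axis, and a
silently transposed table produces plausible but wrong numbers. Display
rounding is half-up at 2 d.p.; computation is full precision.

The paired sample-size calculation is McNemar-based: with discordance
$\psi$ (defaulting to independence, $p_0(1-p_1)+p_1(1-p_0)$) and
$\delta = |p_1 - p_0|$,
$n = (z_{1-\alpha/2}\sqrt{\psi} + z_{power}\sqrt{\psi - \delta^2})^2 / \delta^2$,
rounded up, counting subjects who contribute a paired result. The validation
study used an unspecified online calculator for its own planning, so this
method is a documented package choice, checked in the tests against an
exact trinomial enumeration of the McNemar test's power, not against the
study's printed participant count.

## Numerical and scale choices

- Polar convention: meridian 0 deg at the right horizontal,
  counter-clockwise, per-eye maps in patient-view coordinates.
- Corrected eccentricities are clamped to the meridian's tested extent;
  nothing is extrapolated beyond the screen edge.
- Quadrant membership of an axis-lying point follows its meridian in
  [0, 360), making boundary handling deterministic.
- Stochastic checks use 200 simulated perimetry sessions, 500 staircase
  runs and a 10,000-patient cohort — sizes at which Monte-Carlo error is
  far smaller than the tolerances being asserted while the whole suite
  stays fast.
- Sessions are versioned JSON (schema 1.0) with raw events alongside
  derived scores; reports recompute every classification from the raw data
  and state whether the stored values agree.

## Known limitations

Single high-contrast isopter only (no static or threshold perimetry, no
age-normative database); no crowding or per-letter scoring in acuity; the
cancellation analysis scores omissions only, not search dynamics; the
non-gradable thresholds, defect fraction and inattention cutoffs are
screening conventions that should be tuned against expert adjudication
before any clinical interpretation.
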