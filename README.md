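# strokesight

Up to two thirds of stroke survivors have visual problems — homonymous field
loss, visual inattention (neglect), reduced acuity — yet bedside screening by
confrontation is quick but insensitive, and formal perimetry is accurate but
slow and scarce on stroke units. Tablet-based screening batteries sit between
the two: a staircase acuity test, kinetic perimetry with moving fixation
anchors, and digital bisection/cancellation tasks, administered in minutes at
the bedside.

`strokesight` is the computational core of such a battery, for researchers
who need to study, calibrate or reanalyse it without the hardware:

- **Screen geometry** — pixels, millimetres and degrees of visual angle at a
  330 mm working distance; Goldmann size III equivalence
  (4 mm² at 300 mm ⇒ 2·atan(√(A/π)/D) ≈ 0.431°).
- **Acuity** — tumbling-E sizing (5·10^logMAR arcmin letter height, exact
  tangent) and a 2-down-1-up staircase: threshold = mean of the last four
  reversal levels.
- **Kinetic perimetry** — corner fixation anchors, inward targets at
  constant angular speed v, reaction-time-corrected isopters
  (boundary = raw + v·τ, τ from catch-trial latencies), delete-and-retest
  bookkeeping, and three-way grading: stroke-related defect (hemianopia /
  quadrantanopia / macula-sparing), within normal limits, non-gradable.
  A camera-view filter paints the binocular defect with its mean colour.
- **Inattention** — acuity-calibrated line bisection (signed % of
  half-length) and balanced face cancellation with laterality index
  LI = (R−L)/(R+L); two-test screen with left/right sub-classification.
- **Simulated observers** — field-defect archetypes, lognormal reaction
  times, lapse/guess rates, neglect gradients, fixation losses; fully
  seeded, so every scoring path is testable and parameter recovery can be
  measured.
- **Test accuracy** — 3×3 intention-to-diagnose contingency tables with an
  explicit "unable to assess" category, complete-case and
  untestable-as-incorrect policies, sensitivity/specificity/PPV/NPV with
  exact Clopper–Pearson intervals, and McNemar-based paired sample size.

## Worked example

The package ships the published validation study's 3×3 table of app versus
bedside confrontation results for field deficit:

```r
library(strokesight)
tab <- screening_field_table()
tab
#> <contingency_3x3> rows: confrontation, cols: app
#>          positive negative unable
#> positive       15        4      1
#> negative        6       20      1
#> unable          2        0      0

itd_measures(tab, reference_axis = "columns", policy = "complete-case")
#> <accuracy_estimates> n useable = 45, reference = columns, policy = complete-case
#>   sensitivity: 0.71 (0.48-0.89)  [15/21]
#>   specificity: 0.83 (0.63-0.95)  [20/24]
#>   PPV:         0.79 (0.54-0.94)  [15/19]
#>   NPV:         0.77 (0.56-0.91)  [20/26]
```

Dropping the "unable" margins leaves 45 patients usable by both tests; with
the app margin as reference axis, the four accuracy metrics above are the
published row for this comparison (to the printed 2 d.p.). The convention
record is attached to every estimate because the same 2×2 core read with the
other axis as reference gives a different, equally plausible-looking row.

Simulating a complete session for a left hemianopic observer and scoring it:

```r
prof <- observer_profile(field = make_field_defect("hemianopia", side = "left"),
                         seed = 9)
rec <- simulate_session(prof, patient_pseudo_id = "demo-09")
cat(render_report(rec), sep = "\n")
#> Visual screening report - session demo-09 (schema 1.0)
#>
#> == Acuity ==
#> Threshold: 0.15 logMAR (18 trials, 6 reversals)
#>
#> == Visual fields ==
#> Grade: stroke-related defect - homonymous hemianopia left
#> Reaction time (s): left 0.456, right 0.474
#> Stored grade agrees with recomputation: TRUE
#>
#> == Inattention ==
#> Grade: within normal limits
#> Laterality index: 0.000
#> Mean bisection deviation: -0.2%
#> Omissions left/right: 0/0
```

The report recomputes every classification from the stored raw events and
states whether it matches what was stored. Sessions round-trip through
versioned JSON (`write_session()` / `read_session()`); isopters export as
CSV and field maps/filtered images as PNG. A thin command-line front end
with `fixtures`, `simulate-session`, `score-session`, `report`, `accuracy`
and `cohort-sim` subcommands lives at `inst/cli/strokesight.R`.

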