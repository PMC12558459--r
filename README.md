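# keeneye

Computerized dual-task assessment of visual hemispatial neglect.

Visual neglect — the failure to consciously perceive stimuli in the hemispace
opposite a brain lesion, typically left space after right-hemisphere stroke —
is routinely screened with paper-and-pencil tests that miss compensated and
subclinical cases. The dual-task protocol implemented here loads attention by
combining a central digit-identification task with peripheral circle
localization: on each of 75 brief (100 ms) trials, a circle appears at one of
14 screen positions (7 per hemifield, spanning the upper, middle and lower
bands) or at two mirror positions at once, and the participant reports the
digit and the side(s). Because stimuli vanish before a voluntary visual
search can start, compensatory scanning strategies cannot mask the deficit.

`keeneye` is for researchers and clinicians who run or study this kind of
protocol: it generates the stimulus schedules, validates and scores response
logs, applies the published diagnostic criteria, runs the spatial and
psychometric analyses, and ships a generative patient simulator so the whole
pipeline can be exercised and validated without clinical data.

## The scoring model

From each 75-trial session the package derives per-position omission counts
and nine summary error counts — missed left/right circles on unilateral
(`LSU`, `RSU`, max 21) and bilateral (`LSB`, `RSB`, max 33) trials,
opposite-side "hallucination" reports capturing allochiria (`LH`, `RH`), and
central-digit errors by trial kind (`NIL`, `NIR`, `NIB`) — plus seven
coefficients. With BP = 33 bilateral presentations and LP = 54 lateralized
presentations per side:

- asymmetry, bilateral: `KA_bilateral = (LSB − RSB) / (2·BP − RSB − LSB)` ∈ [−1, 1]
- asymmetry, overall: `KA_all = (LSB + LSU − RSB − RSU) / (2·LP − RSB − RSU − LSB − LSU)`
- productivity (per side): `KPrL_bilateral = (BP − LSB)/BP`, `KPrL_all = (LP − LSB − LSU)/LP`,
  and the right-side analogues
- efficiency: `KEf_all = (D − H)/(D + H)` with `D` the number of detected
  circles and `H = RH + LH` the mislocalization reports

`KA` near 0 means no lateral bias; +1 is complete left neglect. Zero-denominator
cases (e.g. a fully silent session) are tagged `NA` with a warning.

Diagnosis uses either the published single-feature thresholds —
**LSB ≥ 14** or **KA_all ≥ 0.17** — or a classification tree grown from
scratch with Gini splits under rpart-style `minsplit`/`minbucket`/`cp`
control and stratified 10-fold cross-validation. Vertical neglect is tested
by comparing omissions above (positions 1, 4, 8, 11) and below (3, 6, 10, 13)
the horizontal midline with an exact Wilcoxon signed-rank test under the
directional hypothesis down > up; a median-binarization screen rates each
position's diagnostic sensitivity/specificity, and Guilford's phi quantifies
agreement with external binary diagnoses.

## Worked example

```r
library(keeneye)

sch   <- generate_main_schedule(seed = 7)            # 75-trial main series
ses   <- simulate_session(profile_preset("vn"), sch, # a neglect-like patient
                          seed = 99, subject_id = "P01")
sheet <- score_session(ses)
sheet
#> <keen_scoresheet>
#>   misses  L: uni 17  bi 31   R: uni  4  bi  6
#>   halluc  L: 2  R: 2   digit errs L/R/B: 12/14/10
#>   KA_bilateral 0.862  KA_all 0.760  KEf_all 0.852
#>   KPr bilateral L/R 0.061/0.818  all L/R 0.111/0.815

classify_rule(sheet, "LSB14")   # "neglect"  (31 >= 14)
classify_rule(sheet, "KA017")   # "neglect"  (0.760 >= 0.17)

vertical_counts(sheet)          # up 17, down 24: lower-field disadvantage
```

This simulated patient misses 31 of 33 left circles under bilateral
presentation but only 17 of 21 under unilateral presentation — the
extinction dissociation the bilateral trials exist to expose — and both
published criteria classify the session as neglect.

A labelled cohort and the full analysis stack:

```r
co <- simulate_cohort(cohort_spec(n_neglect = 38, n_control = 64, seed = 11))
pred <- vapply(co$sheets, classify_rule, character(1), rule = "LSB14")
confusion_metrics(confusion_matrix(co$labels, pred))

cv <- cross_validate(cohort_features(co$sheets, "raw"), co$labels,
                     fit_params(folds = 10, seed = 11))
cv$pooled_metrics
```

A thin command-line front end lives at `inst/scripts/keeneye`
(`schedule`, `validate`, `score`, `simulate`, `classify`, `analyze`).

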