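---
title: "Methods: scoring, classification and simulation in keeneye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, classification and simulation in keeneye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keeneye)
```

## The protocol

Each trial shows a 1000 ms fixation cross, then — for 100 ms — a central
digit (1–4) together with one 8 mm circle in one hemifield or two circles,
one per hemifield. A 2000 ms mask follows and the participant reports digit
and side(s). The display geometry is fixed: 14 positions, 7 per hemifield at
horizontal offsets ±1.5, ±7.5, ±13.5 cm and vertical offsets 0, ±4, ±8 cm
from screen centre, mirror-symmetric about the vertical midline. The main
series presents each of 25 configurations (14 unilateral, 7 bilateral
mirror pairs, 4 bilateral diagonal pairs) exactly 3 times, 75 trials in all;
by counting, that is 42 unilateral and 33 bilateral trials, 54 circle
presentations per side, and 9 presentations per position except positions
2, 5, 7, 9, 12, 14 (6 each).

Where the protocol's published description leaves freedom, the package makes
these choices:

* **Digit assignment.** No digit distribution is prescribed; digits are
  drawn i.i.d. uniformly from {1, 2, 3, 4} by the schedule RNG —
  maximally uninformative and reproducible.
* **Randomization.** The 75 trials are a single uniform permutation from
  the seeded RNG; no anti-repetition constraint is imposed, because the
  protocol requires only a randomized order.
* **Training series.** Seven trials whose stimulus duration descends
  linearly 1000, 850, …, 100 ms (only the endpoints are prescribed), over a
  fixed configuration set that varies circle count, side and eccentricity.
* **Visual angle.** `cm_to_visual_angle()` uses the centre-referenced
  arctangent, `atan(offset/distance)`, at the protocol's 60 cm viewing
  distance. Published angle ranges for this display are slightly wider than
  this convention yields at the extreme offsets; since the conversion used
  there is not specified, the package documents its own convention and does
  not treat the printed range as normative.
* **Determinism.** Every generator takes a seed, stores it in the object it
  returns, and restores the caller's RNG state on exit.

## Scoring semantics

Scoring is per trial and per side, independently:

* *miss* — a presented side absent from the report (`LSU`/`RSU` on
  unilateral, `LSB`/`RSB` on bilateral trials, plus the position's counter);
* *hallucination* — a reported side with no circle (`RH`/`LH`), possible
  only on the 21 unilateral trials of the opposite side, hence the bound
  ≤ 21;
* *digit error* — wrong or indefinite digit (`NIL`/`NIR` by presented side
  on unilateral trials, `NIB` on bilateral ones). A digit error on a trial
  whose circle was also missed counts in both tallies; the count
  definitions are independent.

Two consequences worth spelling out: a "both" report on a unilateral-left
trial scores one detection plus one right hallucination, and a "right"-only
report on the same trial scores `LSU + RH`. An indefinite side report
("something flashed") is coded as no side reported: it counts as an omission
on every presented side and never as a hallucination — the conservative
reading, consistent with treating indefinite digit reports as errors.

`BP` and `LP` are always recomputed by counting over the session's own
schedule, so truncated protocols score correctly; for the canonical series
they equal 33 and 54.

The efficiency coefficient `KEf_all = (D − H)/(D + H)` is implemented
exactly as defined. Note its true range is (−1, 1]: it goes negative if
mislocalization reports outnumber detections, even though it is nominally
described as a 0–1 index. Coefficients with zero denominators (e.g. `KA_all`
for a session with every circle missed) return `NA` with a warning rather
than a clamped value — total bilateral failure is clinically meaningful and
should not masquerade as a number.

## Classification

Two built-in rules reflect the published decision criteria: neglect iff
`LSB ≥ 14`, and neglect iff `KA_all ≥ 0.17`. The fitted trees behind those
criteria are *not* hard-coded; the package instead provides the inducer so
they can be re-derived from data.

`fit_cart()` is a from-scratch binary CART: candidate thresholds are
midpoints of consecutive sorted unique feature values; splits are chosen by
Gini impurity decrease; a split is accepted only when the node holds at
least `minsplit` observations, both children at least `minbucket`, and the
resubstitution misclassification risk improves by at least `cp` times the
root risk. The `cp` semantics follow the rpart convention (improvement
scaled by root risk) because the tuning vocabulary
(`minsplit = 20`, `minbucket = 7`, `cp = 0.01`) comes from that ecosystem;
this makes results directly cross-checkable against an independent rpart
fit, which the test suite does. Ties in impurity decrease break toward the
alphabetically lower feature name and then the lower threshold, so fits are
deterministic; majority ties at leaves resolve to `no_neglect`, explicitly
favouring specificity. Missing feature values are a hard error — no
surrogate splits.

Cross-validation uses class-stratified, seeded folds (stratification is a
design choice; only equal-sized folds are prescribed). Because it is
ambiguous whether published single-value model metrics of this kind are
pooled cross-validated or resubstitution values, `cross_validate()` returns
both, labelled.

## Spatial and nonparametric analyses

The vertical analysis sums omissions over positions {1, 4, 8, 11} (upper)
and {3, 6, 10, 13} (lower). The normative description uses both hemifields,
but a left-restricted variant also appears in that literature; both are
available via `side_filter`, defaulting to `"all"`, and the filter used is
carried in the result so outputs are never ambiguous. The default
alternative is directional, down > up, reflecting the typical lower-left
locus of neglect.

`wilcoxon_signed_rank()` and `mann_whitney()` use midranks for ties and
compute exact p-values by complete enumeration — over all 2^n sign
assignments when n ≤ 12 retained pairs, and over all group assignments when
`choose(n1+n2, n1) ≤ 20000` — which remains exact under ties, where the
classical exact distribution does not apply. Larger samples fall back to
the normal approximation with tie-corrected variance and no continuity
correction. Effect sizes are rank-biserial: matched-pairs
`(W⁺ − W⁻)/(W⁺ + W⁻)` and two-sample `1 − 2U/(n₁n₂)`. Holm correction is
delegated to `stats::p.adjust`.

The per-position screen binarizes each position's pooled omission counts at
the pooled *lower* median (a sample value; the interpolated median would
not be attainable by any subject), ties at the median coding 1. The pooled
rather than stratified median is used because the screen is defined on the
whole cohort. A position at which every subject scores the same (typically
0 omissions, common at near-centre right positions) therefore codes
everyone 1: sensitivity 1, specificity 0, flagged with a warning — this is
the mechanism behind perfect-sensitivity/zero-specificity cells in screens
of easy positions, not a bug.

## The simulator

Each presented circle is detected independently with probability

```
p = p_base(side) × vertical_penalty^[y < 0] × extinction_penalty^[bilateral & side = left]
```

— a multiplicative model chosen for analytic tractability: every expected
count is then a sum of Bernoulli means, which `expected_scoresheet()`
computes exactly, along with binomial variances. Hallucinations occur with
fixed per-opportunity probability on unilateral trials of the opposite
side, independent of detection (the simplest model consistent with per-side
scoring; a miss-coupled allochiria mode would be an extension). Digit
accuracy depends only on trial kind. Coefficients of expected counts are
*plug-in* values — the formulas applied to expected counts — not exact
expectations of ratios; Monte-Carlo means of per-subject coefficients can
differ slightly (Jensen's inequality), which matters when comparing to
group means of ratio-valued indices.

### Preset calibration

The two built-in profiles target the published group means of the
validation cohort's productivity coefficients. Writing `v` for the vertical
penalty, the schedule places 12 of the 33 bilateral left presentations and
6 of the 21 unilateral left presentations in the lower band, so

```
E[KPrL_bilateral] = p_base_left · ext · (21 + 12v)/33
E[KPrL_all]       = (33·E[KPrL_bilateral] + 21·p_base_left·(15 + 6v)/21·…)/54
```

Fixing `v` (0.80 for the neglect-like profile, 0.95 for the control-like
one — a moderate vs mild lower-field disadvantage) leaves two equations in
`p_base_left` and the extinction penalty, solved in closed form; the right
baseline comes from the bilateral right productivity the same way, and
hallucination/digit parameters are group-mean error counts divided by the
number of opportunities (21 or 42/33). This yields, for the neglect-like
preset, `p_base_left = 0.2338`, `extinction = 0.4474`,
`p_base_right = 0.8660`: expected LSB 29.80 and LSU 16.37, matching the
target group means to two decimals. For the control-like preset,
`p_base_left = 0.7909`, `extinction = 0.9775`, `p_base_right = 0.8790`
(expected LSB 7.95, LSU 4.63). One caveat is inherent: the group mean of a
ratio coefficient such as `KA_all` is not the ratio of group-mean counts,
so the plug-in `KA_all` of the neglect preset (≈ 0.70) sits slightly below
the corresponding published mean of per-subject ratios (≈ 0.75); the
presets are calibrated to the productivity coefficients and count means
only, and no claim is made about matching published standard deviations,
which conflate profile heterogeneity with binomial noise.

Cohorts draw per-subject parameters from normal distributions truncated to
[0, 1] around the preset means (detection parameters sd 0.08,
hallucination/digit parameters sd 0.02 by default) — enough heterogeneity
to spread the score distributions without moving the group means
appreciably. The default cohort is 38 neglect-like and 64 control-like
subjects, mirroring the validation cohort's composition.

### What the simulator does and does not emulate

It reproduces the statistical signatures the analyses rely on:
left-lateralized omissions, the unilateral/bilateral extinction
dissociation (`E[LSB]/33 > E[LSU]/21` whenever the extinction penalty
bites), a lower-field omission excess, rare opposite-side mislocalizations,
and dual-task digit errors. It does **not** model reaction times, fatigue
or learning across trials, eccentricity-dependent detection (the far-right
disadvantage seen even in controls), response biases that depend on
detection history, or lesion anatomy. Passing tests on simulated cohorts
therefore validate the *pipeline* — scoring arithmetic, classifiers,
statistics — under a known generative model; they are not evidence about
real patients.

## Numerical and validation choices

* Exact-test enumeration limits (2^12 sign vectors; 20000 group
  assignments) keep exactness wherever the protocol's own analyses need it
  while bounding memory and time.
* Floating-point comparisons in split selection and p-value tail counts use
  a 1e−12 / 1e−9 slack so midpoint thresholds and tied statistics are
  handled reproducibly across platforms.
* The validation suite checks the tree inducer against a brute-force
  enumeration oracle on instances up to n = 30 with up to 3 features, the
  exact tests against complete enumeration at small n and against the
  classical exact distribution on tie-free data, and simulator parameter
  recovery over 500 seeded sessions (Monte-Carlo count means within 4
  standard errors of the analytic expectations). Cohort-level checks use
  the 38/64 default at fixed seeds; these sizes keep the full suite to a
  few minutes on a single CPU while leaving the Monte-Carlo margins wide.

## Known limitations

* The package scores verbal-report logs; it does not render stimuli or
  capture responses (no PsychoPy runtime).
* The CART inducer targets exactly the two-class, numeric-feature problem
  the protocol needs: no surrogate splits, no categorical features, no
  internal cost-complexity pruning sequence beyond the `cp` acceptance
  gate.
* `KEf_all`'s undefined case (no detections and no hallucinations) and the
  asymmetry coefficients' undefined cases are propagated as `NA`; downstream
  rule classification with an undefined `KA_all` raises an explicit error
  rather than guessing.
* Simulator presets are calibrated to group means only; matching published
  dispersions or the published decision-tree structures is out of scope.
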