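---
title: "Methods: agreement statistics for CHW hypertension screening"
author: "htnagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement statistics for CHW hypertension screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htnagree)
```

## The problem

Community health workers (CHWs) equipped with a branching-logic decision
support app can screen for hypertension in settings where physicians are
scarce. Validating that workflow is a diagnostic-accuracy question: across
paired, blinded encounters — each subject assessed once by a CHW and once by
a physician, with the same automatic cuff — how closely do the CHW's
classifications track the physician reference, and is that agreement good
enough against pre-specified minimally acceptable criteria (MAC)?

`htnagree` packages the full statistical machinery of that design: the
classification engine itself, chance-corrected agreement with clinical
weights and non-inferiority tests, per-item binary agreement metrics,
Bland–Altman measurement comparison, counterfactual attribution of
disagreements, the design's simulation-based power analysis, and a
synthetic paired-encounter generator so every analysis is runnable without
field data.

## The classification engine

Blood pressure is measured one to three times per session. If the first
reading is at or above the repeat trigger of 130/85 mmHg (disjunctive:
SBP ≥ 130 *or* DBP ≥ 85), two further readings are taken and their
component-wise mean is the effective session pressure; otherwise the single
first reading is used. The effective pressure is kept at full precision —
averaging two integer readings can produce a half, and no rounding happens
before threshold comparison.

Elevation means SBP ≥ 140 or DBP ≥ 90 mmHg, both inclusive. The primary
visit's three-way decision table:

| elevated | prior diagnosis | on antihypertensives | status |
|---|---|---|---|
| any | any | yes | confirmed |
| yes | yes | no | confirmed |
| yes | no | no | possible |
| no | any | no | no hypertension |

Two completions of the table deserve comment because only two branches are
forced by the protocol description (elevated with no history → possible;
history plus elevation → confirmed):

* **Current antihypertensive use forces "confirmed" regardless of the
  measured pressure.** Treated, controlled hypertension is still
  hypertension; the alternative (classifying a well-controlled treated
  subject as non-hypertensive) would also make the discordance-attribution
  results incoherent, since history differences could then never flip a
  normotensive classification.
* **A prior diagnosis without current elevation and without treatment is
  "no hypertension".** A historical label alone, unmedicated and not
  currently elevated, does not meet the confirmatory criteria.

A "prior history of elevated blood pressure" and a formal hypertension
diagnosis are collapsed into a single `prior_htn_dx` flag; the field
protocol may have distinguished them, but no analysis here depends on the
distinction.

At the secondary (confirmatory) visit — required for subjects classified
*possible* — history is not re-taken; only an interim diagnosis or an
interim antihypertensive prescription can alter it, and the outcome is
binary: confirmed if elevated or any interim event, otherwise no current
hypertension.

## Weighted kappa with clinical weights

Agreement on the three-way classification uses weighted Cohen's kappa,

$$\kappa_w = \frac{P_{o,w} - P_{e,w}}{1 - P_{e,w}},\qquad
P_{o,w} = \sum_{ij} w_{ij}\, p_{ij},\qquad
P_{e,w} = \sum_{ij} w_{ij}\, p_{i\cdot}\, p_{\cdot j},$$

with Cicchetti-style clinical weights that penalise dangerous
misclassification hardest: a CHW "No" against a physician "Confirmed"
earns weight 0, a missed "Possible" 1/3, and the benign
Possible/Confirmed confusion 2/3 (`cicchetti_weights()`).

The standard error is the Fleiss–Cohen–Everitt (1969) large-sample formula
(see `?weighted_kappa` for the expression). It is the de facto standard in
agreement software, reduces to the usual Cohen-kappa standard error under
identity weights, and — a useful consistency check — produces a symmetric
Wald interval, which matches the shape of the intervals the motivating
study prints. Zero marginals simply drop out of the sums, so tables with
empty categories need no special casing; only a fully degenerate table
(expected weighted agreement 1) leaves kappa undefined, which is raised as
an error from `weighted_kappa()` and reported as an `NA` marker from
`binary_metrics()`.

Non-inferiority against a MAC (default κ = 0.61, the lower edge of
"substantial agreement") uses the one-sided lower bound
$\hat\kappa_w - 1.645\,\mathrm{SE}$: the criterion is cleared when the
bound exceeds the MAC. Proportional agreement uses the same construction on
the Wald scale, $p \pm z\sqrt{p(1-p)/N}$, with a MAC of 90%. The Wald
choice (over Wilson or Clopper–Pearson) is deliberate: it is what
reproduces the printed accuracy intervals of the motivating study to one
decimal, which the test suite checks.

```{r kappa}
tab <- study_crosstabs()$primary
weighted_kappa(tab, cicchetti_weights(3))
proportional_agreement(tab)
```

## Binary history metrics and 2x2 reconstruction

Per-item history agreement uses the 2×2 machinery: overall agreement,
unweighted kappa, the Matthews correlation coefficient, sensitivity,
specificity, PPV and NPV, with the physician as reference. Denominator-zero
metrics are *undefined* and reported as `NA`, never coerced to 0 — with
rare items (e.g. one reference-positive out of 359) several metrics are
otherwise meaningless. `reconstruct_2x2()` rebuilds a full table from the
marginals a report prints (N, positives, sensitivity, agreement), with a
feasibility check that every implied cell is a nonnegative integer.

On any 2×2 with symmetric marginals, kappa equals the MCC exactly; the
suite verifies this by brute-force enumeration up to N = 12.

## Bland–Altman

Measurement agreement (SBP, DBP, height, weight, BMI) is summarised by the
mean physician-minus-CHW difference (bias), its t-based confidence
interval, and limits of agreement bias ± 1.96·SD. Bias is significant when
the interval excludes 0. The orientation matters: a positive SBP bias means
physicians record higher pressures — the "white coat" direction.

## Discordance attribution

For each discordant pair the package decides counterfactually what drove
the disagreement. Only two history fields can flip the decision table
(`prior_htn_dx`, `taking_antihypertensive`; their interim counterparts at
secondary visits), so the rule is:

1. identical decision-relevant history ⇒ the pressures must be responsible
   (**BP only**);
2. otherwise, if both effective pressures fall on the same side of 140/90,
   pressure cannot explain the flip (**history only**);
3. otherwise **both**.

Direction is underdiagnosis when the CHW category is the less severe one.
This is the minimal operationalisation consistent with the decision table;
it attributes borderline cases where both inputs differ to "both" rather
than trying to order them.

## The power analysis

The design's power model draws the physician category from (0.86, 0.09,
0.05) and lets the CHW agree with probability `chw_agreement`; remaining
disagreement goes 2:1 to the adjacent category (e.g. at 80% agreement a
physician "No" becomes CHW "Possible" 13.3% and "Confirmed" 6.7% of the
time). The worked split is stated only for the outer categories; for the
middle category both neighbours are adjacent, so its disagreement splits
50/50 — a symmetric minimal assumption whose influence is small since that
category carries 9% of the mass.

The exact population kappa of this model at 80% agreement is

```{r popk}
population_weighted_kappa(generative_spec(chw_agreement = 0.80))
```

i.e. 0.481 — almost exactly 0.13 below the MAC of 0.61, which reconciles
the design's framing of the alternative as "an inferior weighted kappa
difference of 0.13": the alternative *is* the population kappa of the
stated generative model, not an independently chosen value.

`kappa_power()` simulates datasets of size n, computes
$z = (\hat\kappa_w - 0.61)/\mathrm{SE}$ per replicate, and rejects when
$z < -1.645$; power is the rejection fraction (Monte-Carlo SE
$\sqrt{p(1-p)/\text{reps}}$). Degenerate replicates are counted as
non-rejections rather than resampled — at n ≥ 100 they essentially never
occur, and resampling would bias the estimate. The accuracy criterion's
power is exact-binomial: the largest critical value c with
$P(X \le c \mid n, 0.90) \le 0.05$, power $P(X \le c \mid n, 0.80)$.

Defaults are 10,000 replicates; the test suite uses 2,000 (Monte-Carlo SE
≈ 0.009) and the bundled analysis scripts 2,000–10,000, sizes at which the
whole power analysis runs in seconds.

## The synthetic cohort generator

`generate_cohort()` emulates the paired-encounter study so the entire
pipeline is exercisable end to end:

* **Latent status** from an 86/9/5% split — the anticipated physician
  split at initial assessment.
* **Latent blood pressure** from status-conditional truncated normals:
  normotensive SBP ~ N(111, 12) truncated below 137, elevated components
  anchored at the reported status-conditional means (149 and 144 mmHg for
  possible/confirmed), treated-controlled subjects a below-threshold
  component. Truncation 2–3 mmHg short of the 140/90 threshold guarantees
  that a noiseless, bias-free evaluator reproduces the latent split
  exactly (the generator checks this consistency and raises a calibration
  error otherwise), while the margin plus measurement noise generates
  realistic borderline discordance.
* **Demographics**: age truncated-normal (mean 45.9, SD 16.1, ≥ 18) with
  the hypertensive strata ~9–13 years older; 83% female; heights/weights
  consistent with a mean BMI of 29.2.
* **History**: diabetes status-conditional (8.3%/38.5%/29.5%, marginally
  12%), capturing its association with hypertension via documented
  constants rather than a fitted regression; other items at their marginal
  prevalences. The CHW record flips each item independently with per-item
  probabilities back-solved from the published per-item agreement (e.g.
  smokes ≈ 0.3%, prior hypertension history ≈ 10.9%).
* **Measurement**: each reading is latent value + evaluator bias +
  independent noise; physicians carry a +1.51 mmHg systolic bias (white
  coat direction), CHWs a +0.62 cm height bias. The repeat protocol is
  applied to the recorded (rounded) first reading, exactly as the app sees
  it. Per-reading noise SDs default to 6 mmHg systolic / 4.5 diastolic,
  0.8 cm height, 0.4 kg weight.
* **Follow-up**: physician-possible subjects return for the confirmatory
  visit unless lost to follow-up (probability 2/13); interim
  diagnosis/prescription events occur with probability 5%.

The noise defaults were fixed once by the generator's own calibration
procedure (`calibrate_cohort_spec()`): a coarse grid over the systolic
noise SD and a common scaling of the two decision-relevant flip
probabilities, accepting the first candidate whose 10,000-subject cohort
yields a primary weighted kappa inside (0.72, 0.88) and an SBP bias inside
(0.44, 2.58) — the reported uncertainty bands of the quantities being
emulated. At the chosen defaults the pipeline returns κ_w ≈ 0.86 and bias
≈ 1.5 mmHg.

**What the generator does not emulate** — and hence what passing tests do
not establish about field data: community/CHW clustering (all records are
exchangeable), correlated history errors (flips are independent across
items), any association of measurement error with true pressure (the real
white-coat effect is reportedly stronger above 120 mmHg), digit preference
in readings, and drift between visits (latent pressure is held fixed).
Parameter-recovery tests show the *pipeline* is unbiased for the
generator's truth; they cannot show the generator matches the field.

## Numerical and design choices

* Thresholds are inclusive (≥) everywhere; the repeat trigger is
  disjunctive (SBP ≥ 130 **or** DBP ≥ 85) — the standard clinical reading
  of "130/85".
* Effective pressures are never rounded before comparison.
* Kappa variance: Fleiss–Cohen–Everitt; proportion intervals: Wald; bias
  interval: t-based with normal-quantile 1.96 limits of agreement — each
  chosen to match standard practice and, where the motivating study prints
  intervals, verified to reproduce them at the printed precision.
* Report output is rounded to 2 decimals (kappa) / 1 decimal (percent)
  only at the printing layer; all computation is full precision.
* No bootstrap or exact kappa inference, no multi-rater generalisations,
  no continuity corrections: out of scope by design.

## Reproducibility

Every stochastic path (tables, cohorts, power) is a pure function of an
integer seed; cohorts serialize to byte-identical CSV given the same spec.
The `analysis/` scripts run the whole workflow — desk statistics from the
published tables, a synthetic study-sized cohort, the full agreement
report, and the power analysis — writing plain-text tables under
`results/`.
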