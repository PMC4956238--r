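---
title: "Methods: scoring, outcomes and diagnostic validity in backscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, outcomes and diagnostic validity in backscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backscreen)
```

## The problem

About one in ten people with non-specific back pain develop persistent
symptoms, and this minority accounts for most of the associated costs.
Psychosocial risk factors ("yellow flags") predict the transition from
acute to chronic pain, and two screening questionnaires are in routine
German use to detect patients at risk early: the German translation of the
Örebro Musculoskeletal Pain Screening Questionnaire (ÖMPSQ) and the
Heidelberger Kurzfragebogen Rückenschmerz (HKF-R 10). `backscreen`
implements the full validation workflow for such instruments: scoring,
6-month outcome dichotomization, and a diagnostic-validity engine (ROC
coordinate tables, AUC, Youden-optimal cut-offs, likelihood ratios and
prevalence-adjusted predictive values), together with a calibrated
synthetic cohort generator so that every stage is testable without patient
data.

## Questionnaire scoring

### ÖMPSQ (German version)

Twenty-one of the 25 items are scored (four sociodemographic items are
excluded). The per-item transformation is

* reverse coding, $x \mapsto 10 - x$, for items 12, 16, 17 and 21–25, so
  that a higher transformed value always means higher risk;
* doubling, $x \mapsto 2x$, for the number-of-pain-sites item with its six
  categories;
* identity otherwise.

The linear total is the sum of the 21 transformed values, spanning 4–212,
with risk bands low ($<91$), medium ($91$–$106$) and high ($>106$). Three
work-related items (8, 16, 17) carry a "not working" checkbox treated as a
missing value; a present scale value overrides a ticked box (this avoids
needless substitution on double entries). Up to 3 missing items (about 14%
of 21) are mean-substituted; more than 3 invalidates the record.

Numerical and ordering choices, made once and kept fixed:

* processing order is checkbox resolution → range validation → reverse
  coding/doubling → mean substitution. Substitution therefore operates on
  *transformed* values, keeping the substituted value on the risk scale;
  it replaces each missing value with the arithmetic mean of the present
  transformed values and hence preserves that mean exactly.
* totals are kept as reals (substitution can produce fractions) and the
  band comparison uses the unrounded total.
* `MISSING` is an explicit state distinct from 0; blank cells and a
  configurable NA token both parse to it.
* the instrument itself is not reprinted in the validation literature, so
  the full item table — including which two non-pain-sites items carry the
  1–10 scale (here items 6 and 7, a documented placeholder) — is shipped
  as data (`ompsq_item_spec()`, `inst/extdata/ompsq_items.yaml`). An
  alternate numbering, or the original Swedish 4–210 variant, is a config
  change, and the 4–212 bound is derived from the table
  (`ompsq_total_range()`), never hard-coded.

### HKF-R 10

The HKF-R 10 score is a regression-weighted sum ("positive and negative
sum products") over 26 scored items; item 5, the last-week pain VAS
(0–100), is excluded from scoring and reserved as the follow-up pain
outcome. Five categories partition the score: low risk ($\le -2.5$),
probably low ($-2.5 < s \le 8$), no prediction possible ($8 < s < 28$),
probably high ($28 \le s < 37$), high ($s \ge 37$). Missing values are
never imputed for this instrument: any missing scored item invalidates the
record, while a missing item 5 leaves the baseline score valid but flags
the record as unusable for the pain outcome.

The published regression weights are not reprinted with the validation
literature, so the bundled weight file
(`inst/extdata/hkf_weights_synthetic.yaml`) and item manifest are clearly
labelled **synthetic**: they exercise the machinery (signed weights,
intercept, all five categories are attainable) but carry no clinical
meaning. Real use requires the licensed instrument's weights through
`read_weight_spec()`. The instrument is described as having 27 items while
its published item groups sum to 26 scored items plus item 5; the manifest
is configuration, with completeness defined by the manifest, so either
reading is a data change.

## Outcome dichotomization at 6 months

ROC analysis needs binary states, so the follow-up key variables are
dichotomized into "recovered" (test-negative) versus "not recovered":

| outcome          | raw value                          | recovered when |
|------------------|------------------------------------|----------------|
| ÖMPSQ pain       | item10 × item11 (0–100)            | product $< 17$ |
| ÖMPSQ function   | sum of items 21–25, raw (0–50)     | sum $\ge 45$   |
| ÖMPSQ sick leave | self-reported days in 6 months     | days $= 0$     |
| HKF-R 10 pain    | item 5 VAS (0–100)                 | VAS $< 30$     |

The function outcome uses the items' *raw* direction (10 = full ability),
which is opposite to baseline scoring where those items are
reverse-coded; the asymmetry is deliberate and documented in
`dichotomize_function()`. Sick leave is additionally trichotomized (0 /
1–30 / >30 days) for description; the dichotomy and trichotomy agree by
construction (recovered ⇔ "none"). A record missing an outcome's key
variable simply drops from that outcome's sub-sample — each outcome is
paired with the participants holding a valid baseline score on the
relevant instrument *and* a present label (`build_subsamples()`).

## The diagnostic-validity engine

Let the "diseased" state be *not recovered* and call a participant
test-positive when the baseline score is at or above the cut-off $c$ (the
direction is a convention; the original coordinate software does not state
$\ge$ versus $>$, so `strict = TRUE` exposes the alternative). For each
candidate cut-off the confusion matrix yields

$$\mathrm{Se} = \frac{TP}{TP+FN},\quad \mathrm{Sp} = \frac{TN}{TN+FP},
\quad J = \mathrm{Se}+\mathrm{Sp}-1,$$
$$\mathrm{PLR} = \frac{\mathrm{Se}}{1-\mathrm{Sp}},\quad
\mathrm{NLR} = \frac{1-\mathrm{Se}}{\mathrm{Sp}},\quad
\mathrm{ACC} = \frac{TP+TN}{n}.$$

Candidate cut-offs are the midpoints between consecutive distinct observed
scores plus one sentinel below the minimum and one above the maximum —
$k+1$ coordinate points for $k$ distinct scores, mirroring the coordinate
tables of the classical statistics packages. Division by zero yields an
infinite likelihood ratio, and a predictive value with an empty
denominator is flagged undefined (`NA`) rather than raising an error.

The AUC is the Mann–Whitney probability that a random diseased subject
outscores a random non-diseased one, computed from mean ranks so that ties
count one half exactly. Its standard error is the Hanley–McNeil
distribution-free formula with $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$;
significance against the chance area 0.5 is a normal z-test, and the
asymptotic 95% CI is $A \pm 1.96\,\mathrm{SE}$ clipped to $[0,1]$. The
Youden-optimal cut-off maximizes $J$, with ties broken toward the smallest
cut-off. Internal consistency — trapezoidal area under the coordinate
polyline equals the rank AUC, every coordinate point equals a brute-force
recount — is asserted in the test suite.

Predictive values are post-test probabilities and depend on the pre-test
probability. With pre-test odds $o = p/(1-p)$,

$$\mathrm{PPV} = \frac{o\,\mathrm{PLR}}{1 + o\,\mathrm{PLR}}, \qquad
\mathrm{NPV} = \frac{1}{1 + o\,\mathrm{NLR}},$$

so `adjust_pv()` re-computes PPV/NPV at any population prevalence (default
0.10, the estimated German figure) from the prevalence-independent
likelihood ratios; at the sample prevalence it reproduces the confusion
matrix's own predictive values to machine precision. Efficiency bands for
likelihood ratios (very high / high / moderate / low) and quality bands
for percentage-valued measures (AUC, sensitivity/specificity and their
sum) follow the conventional screening literature; the printed source
bands overlap at their endpoints, resolved here as half-open intervals
(e.g. PLR in $[5, 10)$ is "high", $\ge 10$ "very high"). All computations
keep full precision; rounding (half away from zero, 2 decimals) happens
only at presentation.

```{r example-metrics}
cm <- confusion_matrix(tp = 44, fp = 15, tn = 46, fn = 17)
as.data.frame(report_from_matrices(list(pain = cm))[,
  c("sensitivity", "specificity", "plr", "nlr", "ppv_adjusted",
    "npv_adjusted")])
```

## Preliminary group comparison

Before the ROC analysis, a one-way ANOVA checks that baseline totals
differ between recovered and non-recovered participants
(`oneway_anova()`, fitted via `stats::aov`). With the generator's default
discrimination this relationship is strong (p < 0.001), mirroring the
preliminary analyses such validation studies report; exact p-values depend
on the raw data and are treated as qualitative.

## The synthetic cohort generator

No raw patient data accompany the validation literature, so
`generate_cohort()` emulates the study conditions as its defaults:
265 baseline participants, invalid-baseline rates 24/265 (ÖMPSQ) and
23/265 (HKF-R 10), a 133/265 follow-up return, outcome prevalences
0.50/0.37/0.52/0.70, target AUCs 0.785/0.738/0.818/0.678, work-item
checkbox missingness informed by 46 ticks across 265 participants and
three items, a low stray-empty-cell rate (0.003 per cell, matching the
order of the reported 16 unexplained empty work items), and 17/133 missing
follow-up sick-leave counts.

The generative model:

1. a latent risk $\theta_i \sim N(0,1)$ drives every item: each scored
   item is a discretized, range-clipped affine function of $\theta$ plus
   independent noise, with reverse-coded items moving against the risk.
   Calibration targets the *total* score's discrimination, not per-item
   realism — no item-level distributions are published.
2. outcome states attach to the relevant baseline score by rank matching
   against a binormal draw: states are Bernoulli(prevalence), severities
   sit on the exact normal quantile grids of the two binormal class
   distributions separated by $\Delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$
   (`effect_size_for_auc()`), and the $j$-th smallest score receives the
   state of the $j$-th smallest severity. The observed score's empirical
   AUC against the states then matches the binormal target up to score-tie
   granularity, with $O(1/n)$ rather than $O(1/\sqrt{n})$ calibration
   error. Matching runs separately within returners and non-returners
   because the published discrimination figures are measurements on the
   follow-up sub-samples — that is the stratum whose AUC must hit the
   target.
3. follow-up key variables are drawn on the correct side of each outcome's
   cut-off given the state, so the dichotomization recovers the latent
   states exactly.
4. dropout is completely at random by default; a `risk_dropout` knob makes
   the return probability fall with $\theta$ (selection bias of the kind
   such studies suspect) for sensitivity analyses.
5. one master seed feeds a per-stage seed sequence, so generation is
   byte-identical given the seed and stages are independently
   regenerable.

What the generator does **not** emulate: the psychometric factor structure
of the depression and pain-coping subscales (items covary only through
$\theta$), participant commentary on work items, item-level response
distributions, and any real HKF-R 10 weighting. Passing recovery tests
therefore shows that the *pipeline* is consistent and well calibrated, not
that the instruments behave this way in real cohorts.

## Problem sizes and runtime choices

The parameter-recovery analysis uses one cohort of $n = 5000$ baseline
participants (about 2200 analysable per outcome after dropout and
validation), where the binomial 99% CI for a prevalence near 0.5 is about
±0.027 and the generator's AUC calibration error is well inside ±0.02.
Property-style tests run on samples of 20–200 scores against $O(n^2)$
brute-force oracles, and replicate counts (12 seeds) for the stochastic
sanity checks are sized so that a 95%-of-seeds property fails with
negligible probability when true. The full test suite runs in well under a
minute.

## Known limitations

* The bundled HKF-R 10 weights and item manifest are synthetic; category
  boundary logic is exact, but scores from the bundled file are not
  clinically interpretable.
* The published per-study cut-offs (e.g. 84/92/72/46) and AUC p-values are
  functions of unavailable raw scores; the package reproduces the
  *machinery* and the count-derived quantities, and treats those locations
  as report inputs (`cutoffs` in `run_study()`).
* The ≥-positivity convention and the midpoint candidate cut-offs are
  conventions of the classical coordinate tables; both are configurable
  but the defaults were chosen once and left alone.
* Prevalence re-adjustment assumes the likelihood ratios transport across
  populations — the usual, and usually imperfect, screening assumption.
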