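---
title: "Methods: a stepwise rule-based diagnosis of fibrosing lung diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stepwise rule-based diagnosis of fibrosing lung diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrostep)
```

## The problem and the model

Eight diseases produce radiologically overlapping lung fibrosis: four
interstitial pneumonias (UIP/IPF, fibrosing NSIP, chronic hypersensitivity
pneumonitis, pleuroparenchymal fibroelastosis) and four scarring processes
(post-tuberculous, post-irradiation, fibrosing sarcoidosis, progressive
massive fibrosis). Because biopsy is increasingly avoided, the diagnostic
model here is a *deterministic expert rule list* over a structured
clinico-radiological record rather than a learned classifier: each rule is a
conjunction of findings that a multi-disciplinary team would accept as
diagnostic, rules are evaluated in a fixed order, and the first terminal
match wins. This gives three properties a clinical algorithm needs and a
statistical model does not provide for free: an auditable evidence trace per
patient, label-free operation (no training step, no leakage), and exact
reproducibility.

The rule content is grounded in a feature-significance analysis: for each
(disease, feature) pair a one-vs-rest 2×2 Pearson chi-square test over the
first-step cohort decides whether the feature discriminates that disease
from all others. Features that are both highly prevalent within a disease
and significant (honeycombing for UIP/IPF, head-cheese sign for chronic HP,
platy-thorax for PPFE, perilymphatic nodules for sarcoidosis, calcific
nodules/tree-in-bud/cavitation for TB, occupational dust exposure for PMF,
an irradiation history for post-irradiation fibrosis) become the rules'
required evidence; significant but less specific findings (rheumatologic
history, skin erythema, arthralgia, nodal enlargement, consolidative
calcification) are recorded as *supportive* — they change the reported
confidence note, never the label. That monotonicity is enforced by a
property test.

### Rule order as a design decision

The ordering is the one genuinely open design choice, and it is fixed as
follows:

* the irradiation gate runs first, because 13% of post-irradiation cases
  are lower-lobe and would otherwise leak into the interstitial branch;
* within the upper-lobe branch, TB stigmata are tested before platy-thorax,
  so PPFE is only diagnosed when TB discriminators are absent. This is the
  clinically conservative order and it reproduces the observed direction of
  the residual TB-vs-PPFE confusion (burnt-out TB without calcification,
  cavitation or tuberculin evidence is indistinguishable from PPFE on this
  feature set — both branches of that confusion are *designed to fail* the
  same way the expert consensus did);
* head-cheese sign alone suffices for chronic HP (it was 100% prevalent and
  exclusive to HP in the significance cohort), while the crazy-paving route
  additionally requires a supportive exposure or laboratory result. An HP
  patient with neither sign therefore falls through to the NSIP rule — again
  the documented error direction.
* records with no lobar predominance return `INDETERMINATE` rather than a
  guess; the study cohorts contain no such patients, so the behaviour is
  specified but unexercised by the reproduction.

### Malignancy overlay

Malignant transformation of a scar is predicted by bright T2 signal together
with DWI restriction on MRI, **or** SUV above 3.0 on PET (an OR, because each
was independently significant). The overlay is evaluated independently of
the terminal rule and typed by it: scar carcinoma on post-TB, metastasis on
post-irradiation. On any other final label the predictors are reported as a
note without a malignancy type, since the study observed malignant
transformation only in those two diseases. `suv_threshold` (default 3.0,
dimensionless standardized uptake value) is the only tunable numeric of the
classifier; the nodal short-axis cut-off (1 cm) and pulmonary-trunk calibre
(3.3 cm) are documentation of how the boolean inputs are defined, not
runtime parameters.

## The synthetic cohorts

No patient-level data are deposited, so the package reconstructs both study
cohorts from the published summary statistics; the generator is first-class,
tested code.

**Significance cohort (n = 150).** Disease sizes 34/19/16/2/16/11/21/31.
Every feature with a published per-disease count is allocated *exactly* that
count in `exact_counts` mode (the integer counts are treated as
authoritative over the printed percentages, which are occasionally
inconsistent with them — e.g. post-TB consolidation printed as 98% when
20/21 = 95.2%). The seed only permutes which patients carry a feature; a
per-disease substream derived by stable hashing of the label keeps profiles
independent of each other. Overlays put scar carcinoma on 7 post-TB patients
(selected among smokers, matching the reported 100% smoking prevalence of
scar carcinoma) and metastases on 8 post-irradiation patients, each with the
full MRI/PET triad. Upper and lower lobar predominance are allocated
complementarily so the mutual-exclusion invariant holds at exact marginals.
Quantities the paper reports only as cohort totals (48/150 smokers, 92 M /
58 F, five rapidly progressive courses) are distributed across diseases
consistently with those totals and the per-disease statements that exist
(76.2% smoking in post-TB; the 13 allergen-exposed HP patients female); ages
are drawn from a normal (mean 58.4, SD 11.3) truncated to the reported
33–76 range.

**Validation cohort (n = 100).** True-label sizes 23/19/18/17/14/6/3 (no
true PPFE). Every patient carries the canonical, fully deterministic
presentation of their disease except six documented atypical records — three
NSIP-like HP patients (no head-cheese, no crazy paving, basal traction
bronchiectasis with ground glass, supportive labs negative or not done), one
HP-like NSIP patient (head-cheese present), two PPFE-like post-TB patients
(upper peripheral fibrosis with platy-thorax and no TB stigmata) — plus one
scar-carcinoma and one metastasis overlay. Their exact feature profiles are
described only qualitatively in the source, so the generator encodes the
*minimal* profiles consistent with the reported misclassification
directions.

**What the generator does not emulate.** Features are independent within a
disease apart from the explicitly forced constraints (lobar exclusivity,
overlay triads, overlay-on-smokers): only marginal prevalences are
published, so independence is the minimal assumption, and real within-
disease feature correlations are unknowable from the source. Continuous
image-derived measurements, disease severity, comorbidity and reader
disagreement are all outside the record schema. Passing tests therefore
demonstrate that the *algorithm logic* reproduces the published analysis on
cohorts with the published composition — not that it would attain the same
accuracy on an independent clinical population.

**Tri-state fields.** Laboratory and MRI results are `true/false/not_done`.
An unperformed test is never evidence against a diagnosis (classification
treats `not_done` as "criterion not satisfied", never as a negative), and
prevalence denominators remain the disease's full patient count, matching
the published table's convention.

## Statistical components and numerical choices

**Chi-square.** The 2×2 Pearson statistic is computed in closed form with
p from the χ²(1 df) distribution; a zero margin returns "not applicable"
rather than an error. Yates continuity correction is available but off by
default: recomputing every numerically printed p-value of the significance
table from its printed counts under *uncorrected* one-vs-rest Pearson
reproduces them to their printed precision (0.007, 0.046, 0.049, 0.051,
0.058, 0.06, 0.08, 0.17, 0.215, 0.57, 0.6, 0.66, 0.678, 0.72, 0.93 …), which
both fixes the comparison construction (each disease against all others) and
rules out the corrected variant. No multiple-testing adjustment is applied
by default, matching the original analysis; a `p.adjust` pass-through is
provided.

Four cells the source prints as "< 0.001" are *inconsistent with their own
printed counts* under this (verified) test: HP ground glass (p = 0.0024),
post-irradiation ground glass (p = 0.0054), post-irradiation traction
bronchiectasis (p = 0.0086) and post-TB traction bronchiectasis
(p = 0.061 — not significant at 0.05). The package reports the recomputed
values; the corresponding acceptance expectation is left failing rather than
masked, since the printed values cannot be reproduced from the printed
counts by any 2×2 construction we could identify.

**Exact intervals.** Sensitivity and specificity carry two-sided
Clopper–Pearson intervals from the beta-quantile closed form, with the
boundary forms lower = (α/2)^(1/n) (all successes) and
upper = 1 − (α/2)^(1/n) (none). This choice is validated two ways: it
reproduces every printed interval bound (85.18% for 23/23, 95.32% for 77/77,
73.97% for 18/19, 92.96% for 98/100, 15.81% for 2/2), and it agrees to
< 1e-4 with an independent oracle that inverts the exact binomial tails by
root finding (tolerance 1e-9) for every (s, n) with n ≤ 120 — the cohort
scale of this study. Known print inconsistencies in the source, reported
as-computed here: the post-irradiation sensitivity CI prints 75.29%, which
is the exact bound for 13/13 rather than its own row's 14/14 (76.84%); the
post-TB NPV prints 97.7% while 83/85 = 97.647% rounds to 97.6%; and the
PPFE row prints PPV as NA where 0/2 = 0% is computable.

**Metrics.** All ratios with zero denominators are "not applicable" (PPFE
sensitivity with no true positives in the cohort, balanced accuracy when
either component is undefined), never 0/0 artifacts. Formatting follows the
source's style — one-decimal percentages, three-decimal balanced accuracy —
but all computations and tests use the unrounded values.

## Problem sizes and determinism

Everything is desk-scale by design: the cohorts are 150 and 100 patients,
the significance stage tests 8 × 33 cells, and the Bernoulli-mode sanity
check uses a single 10,000-replicate draw against a 3-standard-error band.
The full test suite runs in well under a minute. In exact-counts mode the
entire pipeline is deterministic given the master seed, and the headline
result (94/100 correct) is independent of the seed altogether, because the
seed only permutes assignment within fixed marginals.

## Known limitations

* The rule list reconstructs a published flow diagram whose exact box order
  is not fully specified in text; the encoded order is the one that
  reproduces all documented behaviour, but other orders could reproduce it
  too.
* PPFE appears in the significance cohort with n = 2, so its "100%"
  prevalences rest on two patients; the algorithm's PPFE rule is
  correspondingly the least validated (the validation cohort contains no
  true PPFE at all).
* Secondary (non-idiopathic) UIP with upper-lobe honeycombing is absent from
  both cohorts and would currently route to the upper-lobe branch, not to
  UIP/IPF.
* The generator's independence assumption understates real feature
  co-occurrence; significance results on Bernoulli-mode cohorts will vary
  around, and can differ from, the exact-counts reproduction.
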