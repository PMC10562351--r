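---
title: "Methods: synthetic multi-site AKI prediction and federated averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multi-site AKI prediction and federated averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the labeling rules,
the generator that stands in for private hospital data, the modeling and
federated-averaging machinery, and the design decisions taken where the
problem left genuine latitude.

## 1. The prediction task

One binary prediction per ICU stay: will the patient meet KDIGO AKI
criteria, given a 6-hour window of clinical data that ends 24 hours before
the event? The 24-hour lead time is the clinically meaningful part — a
prediction made as the creatinine is already rising has no preventive
value. Controls contribute one random 6-hour window placed at least 30
hours after admission, so case and control windows occupy comparable
stretches of the stay.

A note on the window convention: "a 6-h feature window beginning 24 h
before the event" and "a 24-h lead time" conflict — a window *starting* at
onset − 24 h ends only 18 h before onset. We anchor the window end at
onset − 24 h, i.e. the window is `(onset − 30, onset − 24]`, which honors
the lead time; the alternative anchoring is available via
`window_anchor = "start_24h_before"`. All intervals in the package are
half-open `(start, end]` with times in decimal hours, admission at 0.

## 2. KDIGO 2012 labeling

Baseline creatinine is provenance-aware: ward admissions use the lowest
pre-admission value, direct emergency-department admissions the first
available value; candidates at or above 4 mg/dL are excluded. At each
measurement time `t` the creatinine criteria are:

* stage 1 — rise of ≥ 0.3 mg/dL above the running minimum of the trailing
  48 h, or value ≥ 1.5 × reference;
* stage 2 — ≥ 2.0 × reference; stage 3 — ≥ 3.0 × reference, or
  ≥ 4.0 mg/dL *with* a qualifying acute rise (toggleable via
  `scr4_requires_rise`).

The "within 7 days" qualifier on the fold-change rules is ambiguous. We
read it as *the rise occurred within the prior 7 days*: the reference is
`min(baseline, running minimum over the trailing 168 h)`
(`ratio_window = "trailing7d"`, the default). The alternative — the
baseline value gated to 168 h after the baseline measurement
(`"baseline_anchor"`) — is implemented behind the same switch. The default
was chosen because a clock anchored at a pre-admission measurement silently
disables the fold-change rules for most of a long stay, which cannot be the
intended reading; it also matches how published KDIGO implementations
operationalize the rule.

Urine-output criteria operate on roughly hourly charting: stage 1 when the
mean rate over a 6-h span falls below 0.5 mL/kg/h, stage 2 over 12 h,
stage 3 below 0.3 mL/kg/h over 24 h or anuria for ≥ 12 h. A span is the
set of records in `(t − L, t]`; charting gaps longer than 2 h break the
span (irregular charting must not manufacture oliguria), and the mean rate
is the mean of the recorded hourly volumes divided by weight. Any dialysis
event implies stage 3. Onset is the earliest in-ICU time at which any
criterion fires (ties resolved creatinine → urine → dialysis); the stage is
the maximum attained over the stay.

Correctness is not argued but tested: on 1,000 randomized adversarial
stays the labeler must agree *exactly* — onset, stage and criterion — with
a brute-force scan over all measurement pairs and spans, implemented
independently in the test suite.

## 3. The synthetic generator

Real multi-hospital ICU data are private, so the generator is a first-class
module, not a fixture. Each stay draws latent features (age, weight,
baseline creatinine, urine output level, vitals, 33 laboratory analytes,
15 drug-exposure flags) from fixed population distributions; site
heterogeneity enters as location/scale shifts on those latents, and AKI is
drawn from a logistic model on standardized latents with a shared
coefficient vector. The default risk model weights low urine output,
elevated baseline creatinine, diuretic exposure, tachycardia, hypotension,
azotemia, age, lactate and vasopressor use — the predictors that dominate
clinical AKI models. The per-site intercept is solved so the expected
prevalence matches the configured value, which keeps realized prevalence
within binomial error by construction.

Key generator choices:

* **Charting resolution.** Creatinine every 6–24 h (randomized), urine and
  vitals hourly, labs 6-hourly. Urine must be near-hourly for the
  oliguria criteria to be evaluable; sparse creatinine exercises the
  carry-forward aggregation.
* **Risk acts on what models can see.** The urine term of the true model
  is the output level in mL/h (rate × weight), the same quantity the
  trailing 8-h/24-h urine features measure, so the Bayes AUROC is an
  honest, approachable ceiling for trained classifiers.
* **Injection geometry.** For stays drawn as AKI, trajectories are
  rewritten so that labeling recovers the intended episode: creatinine
  jumps to 1.55×/2.1×/3.15× baseline at onset (margins keep each stage
  strictly inside its band), and urine falls to 0.47 mL/kg/h for a
  stage-calibrated span — 0.47 and the 0.60 mL/kg/h floor on normal hours
  are chosen so the first sub-threshold 6-h mean lands within one charting
  hour of the requested onset. For anuria the start hour is solved from
  the surrounding rate. The round-trip (inject → label) must recover the
  stage exactly and the onset within one charting interval in 100% of 500
  randomized episodes.
* **Onsets** are uniform on `[54 h, discharge − 36 h]`: late enough that
  the case window and its trailing 24-h urine lookback are fully observed,
  with 36 h of stay after onset so every staging span completes.
* **Missingness** is per-(stay, lab analyte) with default probability 0.1,
  which exercises mean imputation without dominating the signal.
* **Era split** tags a random 25% of stays as the later "temporal" era.

What the generator does *not* emulate: physiologic feedback (treatment
response, creatinine recovery), informative missingness, inter-feature
correlation beyond the shared risk factor, drift between eras, or any
waveform/image data. Passing tests therefore demonstrate that the
*pipeline* is correct and that the federated mechanics behave as designed —
not that the models would attain the same performance on real patients.

## 4. Cohort rules

Exclusions follow the study order — age < 20, ESRD on chronic RRT, AKI
before admission, first hemodialysis within 24 h, stay < 30 h (a stay of
exactly 30.0 h is kept; the rule is strict), repeat admission — with each
stay tallied once under its first matching criterion, so
`n_included + Σ tally = n_input` is an identity, not a hope. "AKI before
admission" runs the creatinine rules on the pre-admission lookback
(default 168 h, configurable); "receiving RRT" is read as *chronic*
dialysis, i.e. paired with the ESRD flag, since incident ICU dialysis is an
outcome here, not an exclusion.

## 5. Features, imputation, models

The two shipped registries are data, not code: `parsimonious_21` holds the
named reduced feature set (trailing 8-h and 24-h urine sums, diuretic use,
pulse, creatinine, systolic/mean pressure, temperature, BUN, RAS-blocker
use, respiratory rate, age, hemoglobin, platelets, WBC, lactate,
bilirubin, prothrombin time, vasopressor, NSAID, gentamicin/vancomycin)
and `full_60` extends it with weight, two further vitals, 26 labs and 10
drug classes. Users can supply their own registry data frame.

Aggregations: in-window mean for vitals/labs (the conventional choice, and
the one mean-imputation presumes); `last` with a 48-h carry-forward for
creatinine, because a 6-h window rarely contains a creatinine draw and the
most recent value at prediction time is the clinically available quantity;
trailing sums for urine; 7-day lookback for drug flags. Missing entries
are imputed with means fitted on the derivation era of the fitting site
only — a leakage test with era-distinct distributions asserts that
temporal-era values never reach the imputer.

Model families and defaults (hyperparameters are unstated in the source
design, so these are recorded package defaults, all overridable):
gradient boosting — 300 trees, depth 4, learning rate 0.1; random forest —
500 trees; logistic regression — unpenalized; neural network — the shared
MLP below. Cross-validation is stratified 5-fold with the imputer refit
inside each training fold. Platt scaling is fitted on the pooled
out-of-fold scores (a dedicated split would spend data; out-of-fold scores
are already honest) by Newton iteration on the smoothed-target likelihood,
and the fitted map is checked to be strictly monotone, hence
AUROC-preserving. The operating threshold for sensitivity/specificity
tables defaults to 0.5 on the calibrated probability and is configurable —
no threshold is inferred from data. LASSO selection uses the glmnet
binomial path with AUROC-based cross-validation and the one-standard-error
penalty, returning nonzero-coefficient features in registry order.

## 6. The neural network and federated averaging

The MLP (input → 64 → 32 → 1, rectifier hidden, sigmoid output, binary
cross-entropy, Adam at learning rate 10⁻², batch 32) is implemented in the
package with closed-form gradients rather than delegated, so that federated
averaging is bit-controllable: analytic gradients are checked against
central finite differences at 10⁻⁵ relative error, a K = 1 federated run
reproduces plain training to 10⁻¹⁰, and identical sites leave the
aggregate equal to each local update. Inputs are z-scored; in the
federated path scaling (like imputation) is site-local preprocessing
fitted on the site's training split. Because Adam at 10⁻² overfits this
scale of data within a few epochs, the non-federated trainer holds out a
stratified 15% slice and keeps the best-validation-AUROC epoch — the exact
analogue of the federated protocol's best-round selection, and disabled
(`validation_fraction = 0`) wherever bit-equivalence is asserted.

The protocol: per round, the server broadcasts global weights; each of the
K sites runs E local epochs on its 80% derivation split; the server forms
the element-wise weighted mean (weights `n_k / Σn_k`; uniform averaging is
behind a flag, since the source design says only "aggregated") and scores
the aggregate on every site's 20% validation split. Defaults K = 5,
R = 30 rounds, E = 2, B = 32, η = 10⁻². Optimizer moments reset each
round by default — stateless sites restarting from the broadcast are the
conservative reading — with `persist_state = TRUE` available (and used for
the plain-training equivalence). The best aggregate is the round with the
highest unweighted mean validation AUROC; each site also tracks its best
local model. Only weight sets and scalar scores cross the site boundary;
the structure of the exchanged payload is asserted in tests.

The exported single-site comparator is trained on the origin site's 80%
split with the same total epoch budget (R × E) and best-epoch selection on
the origin's validation split, so the federated-versus-local contrast
isolates pooling, not training budget or selection machinery. In the final
comparison both models are evaluated on each site's locally imputed and
scaled temporal data; external validation of a frozen exported model
(`run_external_validation()`), by contrast, freezes the origin imputer and
calibrator, matching the deployment reading.

## 7. Benchmark, problem sizes, and what the tests claim

The default benchmark is five sites of 4,000 stays with prevalences 0.30,
0.28, 0.33, 0.31 and 0.62 (one high-prevalence site), site-specific shifts
on informative latents, and a 25% temporal era. These sizes are the
package's study conditions: large enough that binomial prevalence control,
the Bayes ceiling and the federated direction are stable, small enough
that the full acceptance suite — including ten seeds of the complete
federated study and a 10,000-stay model-ceiling run — completes on a
desktop in minutes. The acceptance properties: the labeler-oracle and
injection round-trips are exact; rank AUROC equals pair counting; every
family's temporal AUROC stays at or below the Bayes ceiling (+0.01 slack)
with the neural network and gradient boosting within 0.03 of it; the
21-feature model matches the 60-feature model within 0.02 AUROC; and
across ten benchmark seeds the federated aggregate beats the exported
single-site model at a majority of external sites, with the origin-site
gain smaller than the mean external gain.

## 8. Numerical conventions and degenerate inputs

Half-open windows everywhere; urine records snap to the ceiling hour of
their timestamp; AUROC uses midranks (ties count one half); precision at a
threshold with no positive calls is reported as 0 with a message; empty
calibration bins are omitted; `p_t = 1` is dropped from decision-curve
grids; chi-square tests carry no continuity correction and Mann–Whitney
uses the tie-corrected normal approximation; all seeds derive from a
single master seed through a mixing function, so every artifact is a pure
function of its configuration. Baseline-free stays, single-class labels,
degenerate (constant) scores, empty cohorts and shape-mismatched weight
sets raise immediate, named errors rather than propagating silently.

## 9. Limitations

The generator's independence and stationarity assumptions make the
synthetic task easier than real ICU prediction; absolute AUROCs here say
nothing about clinical performance. The federated simulation is
synchronous and fault-free — no stragglers, encryption, secure aggregation
or differential privacy. SHAP-style attribution is replaced by
permutation importance, which is model-agnostic and test-owned but shares
permutation importance's known correlation caveats.
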