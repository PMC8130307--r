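---
title: "Methods: dual-source pharmacovigilance signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-source pharmacovigilance signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrsignal)
```

## The problem

Post-marketing drug safety surveillance asks whether a marketed drug raises
the rate of an adverse reaction. No single real-world data source answers
this well on its own: hospital electronic health records (EHR) carry
time-stamped prescriptions, diagnoses and laboratory results for a
comparatively small population, while spontaneous reporting systems (SRS,
e.g. FAERS) carry millions of case reports but no denominators or timelines.
`adrsignal` implements a data-processing pipeline that estimates the same
drug--ADR association in both sources -- a hazard ratio (HR) from a matched
EHR cohort and a reporting odds ratio (ROR) from SRS 2x2 tables -- and pools
the two into fixed- and random-effects risk ratios. The worked ADR throughout
is drug-induced ear disorders, where pure-tone audiometry (PTA) supplies an
objective outcome measurement alongside diagnosis codes.

## Data model

The EHR side lives in a "CDM-lite": the person, drug_exposure,
condition_occurrence and measurement tables of an OMOP-style model, reduced
to exactly the columns the pipeline consumes. The person table carries the
four covariates used for confounding control -- sex, birth year (age),
outpatient visit count, and hospitalization days. The SRS side is one row per
(already deduplicated) case report with pipe-delimited drug and reaction code
sets. All interchange is plain CSV with ISO-8601 dates; read/write round
trips are byte-lossless, which the tests verify over randomly generated
stores.

## Audiometry outcomes

A pure-tone audiogram records the hearing threshold (dB HL) per ear at the
six standard frequencies 250--8000 Hz. `pta6()` is the arithmetic mean of the
six thresholds; `classify_ear()` flags an ear abnormal when any threshold is
*strictly above* 20 dB HL. The strictness is a deliberate literal reading of
the clinical rule "abnormal when values for each frequency are above 20 dB";
a flat 20 dB audiogram is still normal. Because the field also uses >=
conventions, the boundary is configurable (`strict = FALSE`). The per-patient
category (`NORMAL`, `L`, `R`, `LR`) enters the EHR measurement table, and any
non-`NORMAL` hearing test counts as an outcome event on equal footing with an
ear-disorder diagnosis code. The rule is applied per frequency and per ear,
not to the PTA6 average -- the average is retained only as a descriptive
value. Bone-conduction audiometry is out of scope.

## Cohort construction

The case definition excludes, in a fixed order, patients with (1) systemic
diseases known to cause ear disorders, (2) prior ear surgery, and (3)
exposure to drugs with established ototoxicity; each exclusion is tallied at
the first step that matches, giving the attrition trail. For each candidate
drug the analysis table anchors every exposed patient at their **first**
prescription (a new-user-style index; the data model does not say which
prescription anchors time, and first exposure is the standard choice). The
outcome event is the first diagnosis or abnormal hearing test on or after the
index; the two event streams can also be analyzed separately. Two outcome
encodings coexist deliberately:

* `event`/`time_days` -- full-follow-up event indicator and time (to the
  first event, or to administrative censoring at the study end). This feeds
  the Cox model, which handles censoring itself.
* `outcome` -- a binary flag for an event inside a 365-day risk window. This
  feeds the 2x2 tables used for meta-analysis, where a fixed window keeps the
  case/control proportions comparable across sources.

An event on the index date itself is assigned `time_days = 1`: zero-length
intervals are not representable in a Cox model and one day is the smallest
honest duration. Matched controls inherit the index date of their exposed
partner, so calendar time and follow-up opportunity are identical within a
pair.

## Propensity matching and Cox estimation

Exposure is modelled by logistic regression on the four covariates
(maximum likelihood via IRLS; (quasi-)separation and single-class inputs are
errors, not silent successes). Matching is greedy 1:1 nearest-neighbour
without replacement on the logit of the score, with a caliper of 0.2 SD of
the logit score -- the standard recommendation when the source analysis
specifies none. Determinism is by construction, not by seed: exposed subjects
are processed in descending score order (ties by person id) and distance ties
go to the lower control id. Balance is reported as standardized mean
differences before/after matching; |SMD| < 0.1 is the conventional pass mark.

The hazard ratio comes from a Cox proportional-hazards fit on the matched
pairs with exposure as the only term (covariates are controlled by the
matching; an `adjust_covariates = TRUE` mode additionally adjusts for them,
since summary tables in this literature are ambiguous about which was done).
Ties use the Efron correction by default, with Breslow available for
cross-checks. Tests validate the fit against a brute-force grid search of the
partial likelihood on small fixtures and against planted-parameter recovery
(HR 2.0 recovered within [1.8, 2.2] at 2000 subjects per arm; 95% Wald CI
coverage within 3 points of nominal).

## Disproportionality and meta-analysis

For a drug D and reaction R, each SRS report falls in exactly one cell of the
2x2 table (a = D&R, b = D only, c = R only, d = neither), and

* ROR = ad / bc, with Wald CI `exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`;
* RR = [a/(a+b)] / [c/(c+d)], with the analogous Wald variance.

Zero cells receive the Haldane--Anscombe correction: 0.5 added to **all
four** cells of that table only (matching the default of the R meta-analysis
ecosystem this workflow mirrors), so estimates are always finite. Exact
Fisher-style intervals are out of scope; the Wald form is what the reported
`point (low-high)` style implies.

Per drug, the EHR matched-cohort 2x2 (exposed vs matched controls, windowed
outcome) and the SRS report-level 2x2 are pooled as risk ratios:

* fixed effect by Mantel--Haenszel on the count scale, with the
  Greenland--Robins variance for log RR_MH;
* random effects by DerSimonian--Laird: inverse-variance weights with the
  moment estimator tau^2 = max(0, (Q - (k-1)) / (S1 - S2/S1)), where
  S1 = sum(w), S2 = sum(w^2).

With one study both pool to that study's RR exactly; with homogeneous studies
(Q <= k-1) tau^2 truncates to zero and the random estimate equals the
inverse-variance fixed one. `forest_table()` flattens results into rows ready
for a forest plot, with MH weights under the fixed model and 1/(v+tau^2)
weights under the random model. The `metafor` package is used in the test
suite as an independent oracle for both estimators, never as the
implementation.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated; they are not tuning knobs.

* **EHR**: covariates follow a middle-aged outpatient population (age ~
  N(52, 16) truncated to 18--90, visits ~ NegBin(mean 10, SD ~9), hospital
  days ~ NegBin(mean 2, SD ~6) -- loosely matched to the printed cohort means
  of the motivating setting). Exposure is logistic in the centred covariates
  with the intercept calibrated so the empirical prevalence hits the
  configured value. Outcomes arise from a homogeneous Poisson process over
  the whole study window at rate
  `baseline_hazard * exp(covariate effects + log HR x exposed)`; by
  memorylessness, time from *any* index date to the next event is exponential
  at that rate, so the proportional-hazards assumption of the analysis model
  holds exactly and Cox recovery is unbiased. Using the whole window (rather
  than starting the process at a person's entry) is what makes inherited
  control index dates valid.
* **SRS**: drug mentions are independent Bernoulli per report; for a planted
  pair the conditional reaction probabilities (p1 given drug, p0 otherwise)
  are solved by root-finding so the population ROR equals the planted value
  while the reaction keeps its marginal frequency; a planted ROR that no
  (p0, p1) in (0,1) can realise is rejected at config time. Reports are
  generated already deduplicated.
* **Audiograms**: thresholds on the clinical 5 dB grid; abnormal ears carry
  at least one threshold above 20 dB; patients exposed to a designated drug
  are tested after first exposure and turn abnormal with an elevated
  probability, which lets a hearing-test-only effect propagate to the hazard
  ratio with no diagnosis codes at all.

Not emulated: co-prescription networks, dose and duration, time-varying
hazards, reporting biases (stimulated reporting, notoriety effects),
duplicate or incomplete SRS reports, and vocabulary mapping. Passing tests
therefore demonstrate statistical correctness of the machinery under clean
proportional-hazards data -- not robustness to the messiness of real
extracts.

## Numerical choices and problem sizes

Percentages in population tables are rounded half-up (one decimal by default)
because that is how such tables are conventionally printed; base R's
round-half-even would disagree in boundary cases. Confidence intervals are
fixed at two-sided 95% and significance is CI-exclusion of 1, with no
multiplicity correction -- the screening convention of the workflow this
package implements. The logistic fit converges at epsilon 1e-10 (max 50
IRLS steps); the Cox fit at 1e-10 (max 50 Newton steps).

The validation suite sizes its simulations to give stable Monte-Carlo
behaviour while keeping a full run in minutes on one CPU: Cox recovery uses
2000 subjects per arm (1000 replicates for the coverage estimate),
de-confounding uses 20,000 patients with all four covariates planted as
confounders (crude HR inflated ~1.9x, matched log-bias < 0.03), and the
type-I-error sweep uses 25 independent end-to-end null runs of 10 drugs each
(250 null pairs per source, checked against the binomial 3-sigma band around
5%). Planted-recovery checks in the acceptance script use 50,000 patients /
200,000 reports.

## A small worked example

```{r demo, message = FALSE}
cfg <- pipeline_config(
  candidate_drugs = c("drug_pos", "drug_null"),
  sim_ehr = ehr_sim_config(
    n_patients = 4000,
    drugs = list(drug_pos = list(prevalence = 0.08, log_hr = log(2.5)),
                 drug_null = list(prevalence = 0.08, log_hr = 0)),
    baseline_event_hazard = 1.5e-4,
    exposure_coefs = c(age = 0.02, visits = 0.02),
    outcome_coefs = c(age = 0.01)),
  sim_srs = srs_sim_config(
    n_reports = 20000,
    drug_probs = c(drug_pos = 0.05, drug_null = 0.05),
    reaction_probs = c(ear_disorder = 0.05),
    planted = data.frame(drug = "drug_pos", reaction = "ear_disorder",
                         log_ror = log(2))),
  seed = 3)
report <- run_pipeline(cfg, verbose = FALSE)
render_report(report)
```

The planted drug is flagged in both sources and by both pooled models; the
null drug is not.

## Known limitations

* Greedy matching is order-dependent and not globally optimal; optimal
  (network-flow) matching is out of scope, and the tests only assert
  greedy-optimal agreement on fixtures where the two coincide.
* Wald intervals undercover for very sparse 2x2 tables even after continuity
  correction; the pipeline reports them regardless because the downstream
  meta-analysis needs a variance, but single-digit cell counts deserve
  scepticism.
* The EHR arm contributes a *matched-cohort* 2x2 to the meta-analysis while
  the SRS arm contributes a report-level table; pooling mixes a cohort risk
  ratio with a reporting risk ratio. This mirrors the source workflow and is
  flagged here rather than hidden.
* One index prescription per patient; re-exposure and dose are ignored.
```
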