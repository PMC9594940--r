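---
title: "Scoring the pretreatment immune phenotype and evaluating neoadjuvant pathologic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the pretreatment immune phenotype and evaluating neoadjuvant pathologic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irhpc)
```

## The problem

Neoadjuvant anti-PD-1 therapy produces durable responses in a subset of
resectable non-small cell lung cancer patients, but pretreatment markers of
who will respond are weak.  Because checkpoint blockade works by reactivating
a pre-existing adaptive immune response, the hypothesis behind this package
is that the ordinary HE-stained diagnostic biopsy, taken before any
treatment, already carries morphological evidence of that response.  The
package implements a pretreatment scoring system built on that idea — the
immune-related histologic phenotype criteria (irHPC) — together with the full
pathologic-response evaluation used to validate it: per cent residual viable
tumour (%RVT) in the resection specimen, the response classes derived from
it, the derived neutrophil-to-lymphocyte ratio (dNLR), PD-L1 tumour
proportion score (TPS) rules, inter-rater agreement statistics and
Kaplan–Meier survival summaries.

## The irHPC score

Four biopsy features enter an additive score.  Tumour-infiltrating
lymphocytes (TILs), eosinophils and neutrophils are graded 0/1+/2+/3+ by the
reading pathologist; dense plasma cells in the tumour-related stroma are
recorded as present or absent.  TIL and eosinophil grades contribute their
face value (0–3 points each), the presence of dense plasma cells contributes
one point, and the neutrophil grade is *subtracted*:

$$
S \;=\; \mathrm{TIL} + \mathrm{Eos} - \mathrm{Neut} + \mathbf{1}[\text{dense plasma cells}] ,
\qquad S \in [-3,\, 7].
$$

The mirrored-magnitude neutrophil penalty (grade $g$ contributes $-g$) is a
design decision: the source criteria state only that neutrophils are scored
negatively, and the symmetric reading is the one consistent with the
attainable score range observed in practice (non-responder reference scores
reach $-2$).  A score of at least 2 points predicts pathologic response
(cPR/MPR) at resection; the cutoff is a parameter (`cutoff = 2`, rule
$\geq$, so a score of exactly 2 predicts response).  The package scores
recorded grades; what histology constitutes 1+ versus 2+ is the
pathologist's call and out of scope.

```{r}
irhpc_score(til = 3, eosinophils = 1, neutrophils = 2, dense_plasma = TRUE)
classify_prediction(2)
```

## %RVT and the response classes

Response in the resection specimen is quantified as per cent residual viable
tumour over the tumour bed, with component areas summed across all slides of
a case:

$$
\%\mathrm{RVT} = \frac{\mathrm{RVT}}{\mathrm{RVT} + \mathrm{necrosis} + \mathrm{regression\ bed}} \times 100,
\qquad
\%\mathrm{RVT}_{\text{w/o necr}} = \frac{\mathrm{RVT}}{\mathrm{RVT} + \mathrm{regression\ bed}} \times 100 .
$$

Classes partition $[0, 100]$: cPR $= \{0\}$, MPR $= (0, 10]$, pPR
$= (10, 90]$, nPR $= (90, 100]$.  The half-open, inclusive-upper convention
is a deliberate choice: the class labels are printed as integer ranges
("1–10%", "11–90%"), and inclusive upper bounds are the only continuous
reading under which a value of exactly 10% stays MPR while arbitrary
non-integer percents remain classifiable.  "MPR achieved" pools cPR and MPR.
Classification is applied to the cross-rater mean percent (per-rater classes
are also reported), no rounding is applied before classification, and the
with-necrosis denominator is the default since it is the established
baseline convention; dropping necrosis is an explicit flag.  Dropping
necrosis can only raise the percent, so a case near the MPR boundary can
change class — the motivating example is a tumour bed of RVT 10, necrosis
60, regression 30, which reads 10% (MPR) with necrosis and 25% (pPR)
without:

```{r}
percent_rvt(10, 60, 30)
percent_rvt(10, 60, 30, include_necrosis = FALSE)
```

`necrosis_sensitivity()` runs this comparison cohort-wide and tests the
paired differences with the Wilcoxon signed-rank test (zeros dropped, exact
null up to 25 non-zero pairs, tie-corrected normal approximation beyond).

## Biomarkers

The dNLR is `neutrophils / (leukocytes − neutrophils)` from the pretreatment
complete blood count, dichotomised at a strict `> 3` (a ratio of exactly 3
is *not* high).  PD-L1 TPS is evaluable only when the IHC slide carries at
least 100 viable tumour cells (inclusive); TPS bands are $[0,1)$ negative,
$[1,50)$ positive-low, $[50,100]$ high.  The association between eosinophils
occupying both the tumour parenchyma and the stroma and TPS at a cutoff is
tested with Pearson's chi-square *without* continuity correction — the
uncorrected statistic is the one whose p-values match the published
contingency tables at both cutoffs, so that convention is fixed and
documented rather than left as an option.

## Agreement statistics

Overall per cent agreement (OPA) counts every unordered pair of raters
within a case as one comparison and pools pairs across cases.  The 95%
confidence interval is a Wilson score interval on the pooled proportion by
default (well-behaved near 0 and 1); Clopper–Pearson is selectable.
Treating within-case pairs as independent is an approximation, but it is
the approximation implied whenever "35 concordant of 45 pairs" is quoted as
a single proportion.  Fleiss' kappa uses the standard
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$ computation and the customary
interpretation bands (≤ 0.40 poor to fair, 0.41–0.60 moderate, 0.61–0.80
substantial, 0.81–1.00 almost perfect); kappa is rounded to two decimals
before banding so the two-decimal band edges leave no gaps.  Cases whose
number of available ratings differs from the modal count are dropped with a
warning, and a matrix using a single category throughout leaves kappa
undefined (flagged) rather than fabricating a value.  No installed package
provides these two statistics, so both are implemented here and
cross-checked in the tests against a brute-force pairwise loop and a
hand-worked table.

## Survival

Kaplan–Meier estimation is delegated to `survival::survfit()` behind
`km_fit()`; `rate_at()` evaluates the right-continuous step function (at an
event time the post-event value applies), and `km_by_group()` tabulates 1-
and 2-year rates (12/24 months) for the groupings of interest: MPR achieved,
irHPC at the cutoff, and dNLR.  Two conventions follow the study design:
deaths unrelated to treatment are *removed entirely* from the survival
analysis set rather than censored (matching an analysis set of 29 of 31
patients), and median follow-up is the simple median of observed follow-up
times with a min–max range, not a confidence interval; a reverse-KM
follow-up estimate is available as an option but is not the default because
the published summaries print plain ranges.

## The synthetic cohort generator

No patient-level data are released with the source study, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, and `example_cohort()` builds one fixed, fully synthetic
cohort whose *marginal counts* match the published ones (31 cases with 6
cPR/9 MPR/13 pPR/3 nPR; 15 biopsy cases whose reference scores split 7/8
versus 0/7 at the cutoff; a 15×3 rater matrix with 35/45 concordant pairs;
109 PD-L1 records with one insufficient slide and the two published
eosinophil-by-TPS cross-tabs; 17 cases whose %RVT rises when necrosis is
dropped).

The generator's model, with all parameters in `sim_config()`:

* latent grades: TILs ~ (0.20, 0.30, 0.30, 0.20) over 0–3, eosinophils
  ~ (0.40, 0.30, 0.20, 0.10), neutrophils ~ (0.50, 0.30, 0.15, 0.05), dense
  plasma prevalence 0.40 — chosen once as plausible biopsy marginals that
  put the latent score mass around 1–3;
* response: logistic link $\Pr(\mathrm{MPR}) = \operatorname{logit}^{-1}(-2.4 + 1.1\,S)$,
  calibrated so the marginal MPR rate sits near the published 48% under the
  grade marginals above; 40% of responders are cPR (6 of 15);
* %RVT: point mass at 0 for cPR, uniform on (1, 10] for MPR with residual
  tumour, uniform on (11, 100] otherwise; necrosis present with probability
  0.60 (1/6 for cPR, where necrosis is uncommon) occupying 5–30% of the
  non-viable bed; raters observe the percent with SD 2 points;
* rater noise: a symmetric ±1 slip model (exact with probability 0.80,
  otherwise one grade up or down, clipped to 0–3) — the simplest ordinal
  noise model, since only the existence of variability is documented; binary
  features flip with probability 0.10;
* blood: leukocytes ~ Normal(7, 1.2) × 10⁹/L, neutrophil fraction
  0.66 + 0.05 × grade + Normal(0, 0.08), tying the dNLR to the neutrophil
  grade and putting roughly a third of patients above 3;
* survival: exponential hazards per month, DFS 0.004 (MPR) vs 0.012
  (non-MPR) and OS 0.001 vs 0.003 — giving 2-year survival near the
  published group rates — with administrative censoring at 45 months and a
  2/31 chance of a treatment-unrelated death;
* PD-L1: eosinophil-both probability 45/108; TPS category probabilities
  (negative, positive-low, high) of (0.400, 0.333, 0.267) given
  eosinophil-both and (0.492, 0.445, 0.063) otherwise, reproducing the
  published 12/45-versus-4/63 enrichment in expectation.

What the generator does *not* emulate: correlated rater errors (raters are
conditionally independent given the truth), spatial heterogeneity within a
tumour bed, informative censoring, non-exponential hazards, and any
association between %RVT and the blood counts beyond what the score link
induces.  Passing tests on simulated data therefore show that the
estimators recover the quantities they target under the stated model, not
that the model captures every feature of real cohorts.

## Numerical choices and degenerate inputs

* Validation is data, not exceptions: `read_cohort()` returns violations
  per row and field; the pipeline aborts only at `run_study()` entry.
* `percent_rvt()` raises an explicit error on an empty denominator (an
  all-zero tumour bed, or RVT = regression = 0 in without-necrosis mode).
* An empty response group in `score_group_summary()` reports an undefined
  percentage with a flag, never 0/0.
* Wilcoxon zero differences are dropped (classic convention); if all
  differences are zero the test is reported degenerate.
* Chi-square tables with an empty margin are flagged degenerate rather
  than tested.
* Percentages are reported to one decimal and kappa to two, matching the
  precision of the published summaries; nothing is rounded before
  classification or testing.

## Problem sizes

The test suite exercises the estimator-recovery properties at sizes chosen
to make Monte-Carlo tolerances tight while keeping the default run fast:
10⁴ cases for rater-agreement recovery, 1000–2000 subjects for exponential
survival recovery and the logistic score-effect check, 2000 cases for the
null-kappa check, and 100 random matrices against the brute-force OPA
oracle.  All tolerances are three Monte-Carlo standard errors of the
quantity under test.

## Known limitations

The irHPC weights are the published unit weights; no refitting is offered.
The group-wise survival rates, the published kappa of 0.54 and the
Kruskal–Wallis p of 0.480 depend on per-patient values that were never
released, so the package reproduces the estimators and the printed marginal
counts, not those patient-level numbers.  The OPA confidence interval
ignores the within-case correlation of rater pairs.  Competing risks, Cox
regression and log-rank testing are out of scope.
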