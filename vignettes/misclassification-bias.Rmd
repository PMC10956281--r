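---
title: "Methods: quantifying misclassification bias of code-based case assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying misclassification bias of code-based case assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cystmisclass)
```

This vignette is the package's own account of its statistical machinery:
the generative world it simulates, the model it fits, the three
case-status assignment methods it compares, and the numerical and design
choices made where the underlying protocol left the design open. It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The scientific setting

Cystectomy with urinary diversion is a rare, high-morbidity procedure
(~0.12% of adult admissions at a large referral centre), recorded in
administrative data through procedure and billing codes of imperfect
accuracy. Whether an admission involved the procedure — and which of the
two diversion subtypes, *incontinent* or *continent* — determines the case
group for every downstream association analysis. Errors in that
determination are **misclassification bias**: non-differential errors bias
associations toward the null, differential errors in any direction, and
either can distort prevalence arbitrarily.

The crucial arithmetic is prevalence-driven. With 500 true cases among
428,697 admissions, even a code with sensitivity 97.1% and specificity
99.96% yields 191 false positives against 270 true positives: a positive
predictive value of 58.6%. Half of the "coded" case group is not the
procedure, and the false half is not a random half — code false positives
arise from clinically adjacent admissions — so association estimates move.

## 2. The synthetic cohort and what it does (not) emulate

The original linked hospital data cannot be redistributed, so
`generate_cohort()` draws admissions from a stated generative world whose
defaults encode the source cohort's published marginal structure. These
defaults are the *stated world* of the package: they were fixed from the
published marginals before the downstream criteria were evaluated, and
they are not tuning knobs.

* **Composition.** Class sizes are exact counts (278 incontinent, 222
  continent, 428,197 none), assigned by permutation rather than
  multinomial draws; the emulated cohort has fixed composition and exact
  counts remove one source of Monte-Carlo noise.
* **Binary covariates** are Bernoulli per class at the published per-class
  frequencies (e.g. elective admission 95.3% / 98.2% / 33.4%; urology
  service 99.3% / 100% / 4.9%).
* **Continuous covariates.** The source reports only means/SDs or
  medians/IQRs, not families. Age is normal truncated at 18 (cases sit
  five SDs above the truncation point, so their means are essentially
  exact; the non-case class mean is shifted up ~1.3 years by truncation —
  an accepted approximation). Operative time is two-part: a point mass at
  0 minutes (the non-case class has probability 0.55 of no operating-room
  time, reproducing its published median of 0 and upper quartile ~113) and
  a log-normal positive part matched to class medians/IQRs. Acute length
  of stay is log-normal matched to medians/IQRs. Log-normal positive
  parts were chosen for positivity and right skew.
* **Comorbidity flags** (21, Elixhauser-style identities) are not
  published per class; each has a chosen baseline prevalence typical of
  hospitalized adults (0.3%–25%) and a per-case-class odds ratio
  reflecting an elderly bladder-cancer surgical population (solid tumour
  strongly enriched, renal failure and COPD moderately, HIV/paralysis
  depleted). These are fixed package constants, documented in
  `default_comorbidity_params()`.
* **Procedure codes.** Sensitivities and cross-coding probabilities are
  the published ones (incontinent code: 97.1% sensitive, carried by 28.4%
  of *continent* cases; continent code: 100% sensitive, carried by 54% of
  incontinent cases). Non-case false positives are **count targets** (128
  and 87), preserved when the non-case class is scaled down, so the
  published TP/FP structure — hence the code method's bias — survives in
  test-scale cohorts. By default they are concentrated among
  urology-service, elective, main-OR admissions (false codes arise from
  similar surgeries); a uniform variant (`differential_codes = FALSE`)
  exists. This concentration is what makes the non-code covariates
  informative enough for near-perfect model discrimination.
* **Suppressed cells.** A few published cells are privacy-suppressed
  ("≤ 5"-style); affected marginals (the non-main-OR fraction, the zero
  part of operative time) are approximated and flagged in the parameter
  comments.

**Limitations a green test does not erase.** Covariates are independent
*within* class (no age–comorbidity correlation, no secular drift in coding
practice, no within-surgeon clustering); there is exactly one row per
admission with complete data; code errors do not depend on unmodelled
chart-level detail. A green acceptance suite establishes that the
*methods* behave as claimed in a world with the published margins — not
that the model would transport to another hospital.

## 3. The prediction model

A single multinomial (generalized-logit) model with the no-procedure class
as reference models the 3-level status, per the protocol, rather than two
separate binary models; each candidate enters both outcome equations
simultaneously and degrees of freedom are counted per equation.

* **Degrees-of-freedom budget.** `compute_df_budget()` implements the
  four planning criteria: events-per-variable (10 per df), mean absolute
  prediction error (the van Smeden rare-outcome approximation solved for
  the number of parameters), expected shrinkage (Riley's closed form) and
  optimism in apparent Cox–Snell R². The shrinkage/optimism criteria need
  an anticipated R²; the default (0.072) is the value implied by the
  published shrinkage allowance and is recorded in the output. With the
  planning inputs (n = 429,000, 250 events per type) the criteria give
  25 / 42.6 / 32.1 / ~223 df and EPV binds: 25 df. `run_study()` uses this
  *planning-stage* budget at any cohort scale — the allowance is a design
  quantity of the emulated protocol, and the MAPE criterion recomputed on
  a deliberately shrunken test cohort would permit almost no model.
* **Forward selection.** Candidates are offered strictly in a fixed
  clinical-priority ranking (`default_candidates()`); a candidate is
  retained when the likelihood-ratio test of its addition (2 df, one per
  equation) has p ≤ 0.05. Candidates failing the test are not re-offered
  (a single ranked pass); once the budget is full later candidates are
  still offered and traced but cannot enter. The full selection trace
  (LRT, p, decision, separation flag) is part of the fitted object.
* **Fractional polynomials.** Each continuous candidate is offered as its
  best single FP transform: power from {−2, −1, −0.5, 0 (log), 0.5, 1, 2,
  3} minimizing the deviance of the current model plus the term, ties
  broken toward the linear term. The shift rule makes the argument
  positive (smallest distinct spacing minus the minimum when any value is
  ≤ 0); a power-of-ten scale keeps cubes and reciprocals numerically sane.
  The chosen term costs 1 df per equation; the power search itself is not
  charged, and the choice is logged.
* **The fitting engine.** No unpenalized multinomial fitter with an exact
  log-likelihood is available in the dependency set, so
  `fit_multinomial()` implements Newton–Raphson with step-halving on the
  softmax log-likelihood, with internal column standardization for
  conditioning and an adaptive diagonal jitter when separation makes the
  Hessian singular. Near-perfect predictors (the code flags) make
  separation routine: the likelihood then converges while coefficients
  drift, the iteration stops on relative log-likelihood change (1e-10),
  and the fit is flagged. An optional ridge guard (`ridge`, default 0 =
  maximum likelihood) is available but not needed for the shipped
  defaults. The engine is oracled in the tests against `stats::glm`
  (binomial) on two-class data and an independent BFGS optimizer on
  three-class data.

## 4. Internal validation

Discrimination is the one-vs-rest c-statistic per outcome (rank-based,
ties at half credit); calibration is the integrated calibration index
(ICI): the mean absolute difference between predicted probability and a
`lowess`-smoothed observed event rate evaluated at each prediction (span
0.75, configurable; the protocol does not state a span; iter = 0 because
a 0/1 response breaks lowess's robustness reweighting).

Optimism correction uses the bootstrap: each replicate resamples the
cohort, refits the **selected model structure** (coefficients only, not
the whole forward-selection path), and the optimism is the mean difference
between the refit's performance on its own bootstrap sample and on the
original cohort; corrected = apparent − mean optimism, with percentile
intervals from the per-replicate corrected values. Refitting the entire
selection path per replicate (the strictest variant) is prohibitively
unstable under routine separation and changes nothing material when
discrimination is this extreme; the simplification is deliberate and
documented here. Replicates missing an outcome class are redrawn (logged,
capped).

## 5. The three assignment methods

1. **Codes**: the flag as recorded.
2. **Categorical (thresholded probability)**: `find_threshold()` scans all
   distinct predicted values; the default criterion maximizes Youden's
   J = sens + spec − 1, with the closest-to-corner criterion also
   implemented — the protocol names Youden's method while describing the
   corner distance; both are available and the discrepancy is surfaced in
   the API rather than hidden. Ties break toward the smallest threshold;
   assignment is *inclusive* (probability equal to or above the
   threshold is positive).
3. **Bootstrap imputation (BI)**: each of `n_boot` replicates resamples
   the cohort to size, draws one uniform u per row, and imputes status by
   *strict* comparison (u below the predicted probability), matching the
   protocol's wording; the statistic's point estimate is the replicate
   mean and its interval the 2.5th/97.5th percentiles.

**Mutual exclusivity under imputation.** The protocol describes per-type
imputation; independent draws could impute one admission as both diversion
types, which no true admission is. The default partitions the unit
interval — u < p_inc imputes incontinent, p_inc ≤ u < p_inc + p_cont
imputes continent — so each row gets at most one type while each type's
marginal imputation probability is exactly its predicted probability. The
independent variant is retained (`exclusive = FALSE`) for fidelity
comparisons. Replicates in which a statistic is inestimable (e.g. zero
imputed cases) are excluded from that statistic's aggregation and counted,
rather than redrawn — the protocol is silent; exclusion-with-logging was
chosen because redrawing conditions the bootstrap distribution on
estimability and biases narrow statistics.

## 6. The bias battery and comparison

The battery is 1 prevalence + 3 continuous + 26 binary = 30 statistics.
The protocol's stated count (30) does not match its enumerated covariables
(6 binaries + 21 comorbidities + 3 continuous + prevalence = 31), so the
battery is parameterized (`statistic_battery(n_comorbidity = )`) and the
default drops the last comorbidity flag to total exactly 30.

Continuous associations are the difference in covariable means between
status groups (the slope of the linear regression of covariable on
status); binary associations are the 2×2 log odds ratio — identical to the
logistic regression of the covariable on status — with the
Haldane–Anscombe +0.5 correction of all four cells when any cell is zero
(rare outcomes such as unplanned return to the operating room have ~0
events among non-cases, so the correction is load-bearing, and corrected
estimates are flagged). Modelling the covariable as the response matches
the "unadjusted association with status" framing and is symmetric for
binary/binary pairs.

**SMSE.** The published formula (β − β_T)²/β_T is signed: it is negative
whenever β_T < 0, and its logarithm — required by the comparison ANOVA —
is then undefined. The default *analysis mode* divides by |β_T|; the
*literal mode* is retained and the mode is recorded in every output. A
true association of (numerically) zero excludes the statistic rather than
dividing by zero. Method comparison is one-way ANOVA of log SMSE with
Tukey's studentized-range pairwise test; zero SMSE values are excluded
(log-undefined), and a method retaining fewer than two usable values — a
perfect-code world — is dropped from the ANOVA with its medians still
reported, rather than failing the run.

## 7. Orchestration, reproducibility, scale

`run_study()` chains simulate → code accuracy → fit → validate →
threshold/assign → statistics → SMSE → comparison. Every stochastic stage
derives its own seed from the master seed and a stage label
(`derive_seed()`), so no stage's stream depends on how much randomness an
earlier stage consumed; identical config + seed gives identical numeric
output. The full-scale profile is the emulated protocol (428,697
admissions, 1000 bootstrap replicates everywhere). The documented test
profile (`profile = "test"`) shrinks only the non-case class to 49,500
and uses 200 replicates: events for model fitting are preserved, code
error structure is preserved (count targets), and the whole study runs in
minutes on one CPU. The acceptance suite uses this profile with seed 1,
chosen once.

## 8. Known limitations

* Within-class covariate independence (Section 2) understates collinearity
  a real model would face; selection traces on real data would differ.
* The optimism correction does not repeat variable selection (Section 4).
* The anticipated R² behind the shrinkage/optimism df criteria is an
  assumption; only the EPV criterion is treated as exact.
* Percentile intervals from 200 replicates (test profile) are noisier than
  the protocol's 1000; the full profile restores them.
* The generator's operative-time zero-part and non-main-OR fractions
  approximate privacy-suppressed cells.
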