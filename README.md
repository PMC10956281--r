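# cystmisclass

Misclassification bias from code-based case assignment in administrative
hospital data — a tested, end-to-end simulation and analysis pipeline.

## The problem

Health-administrative research usually identifies cases (here: cystectomy
with urinary diversion, split into *incontinent* and *continent* subtypes)
by procedure codes. Even codes with near-perfect sensitivity and
specificity fail for a rare procedure: at a prevalence of ~0.12% of
admissions, a specificity of 99.96% still produces as many false positives
as true positives, so the positive predictive value collapses to ~50% and
every association measured on "coded" cases is biased. This package
implements and evaluates the remedy: fit a multinomial prediction model
for case status from administrative covariates, and *impute* case status
probabilistically (bootstrap imputation, BI) instead of thresholding codes
or predicted probabilities.

The bias of an estimated association β against its true value β_T is
summarized by the standardized mean squared error

    SMSE = (β − β_T)² / β_T

(the default analysis mode divides by |β_T| so the log-scale ANOVA that
compares assignment methods is defined; see the methods vignette).
Assignment methods are compared by one-way ANOVA of log SMSE over a
battery of 30 statistics (prevalence, 3 continuous associations, 26 binary
log odds ratios) with Tukey's studentized-range test.

Because the original hospital data are not redistributable, a synthetic
cohort generator reproduces the cohort's published marginal structure:
class sizes 278 / 222 / 428,197, per-class covariate marginals, and the
procedure-code operating characteristics (including cross-coding between
the two diversion subtypes and false positives concentrated in
urology-service elective admissions).

## What is in the package

| module | user-facing functions |
| --- | --- |
| synthetic cohort | `cohort_spec()`, `test_profile_spec()`, `generate_cohort()`, `assign_codes()`, `write_cohort()` / `read_cohort()` |
| classification accuracy | `contingency_table()`, `compute_accuracy()`, `format_accuracy()`, `reference_accuracy_counts()` |
| prediction model | `compute_df_budget()`, `select_fp1()`, `forward_select()`, `predict_probabilities()`, `internal_validate()`, `save_model()` / `load_model()`, `fit_multinomial()` |
| status assignment | `assign_by_code()`, `find_threshold()`, `assign_by_threshold()`, `bootstrap_impute()` |
| bias quantification | `statistic_battery()`, `compute_statistics()`, `smse()`, `smse_table()`, `compare_methods()` |
| orchestration | `run_config()`, `run_study()`, `cli_main()` (script `inst/cli/cystmisclass`) |

## Worked example

```r
library(cystmisclass)

## accuracy of the incontinent-diversion procedure code, from the shipped
## reference 2x2 counts
counts <- reference_accuracy_counts()
row <- subset(counts, classifier == "code" & diversion == "incontinent")
compute_accuracy(contingency_table(row$tp, row$fp, row$fn, row$tn))
#> classifier: TP=270 FP=191 FN=8 TN=428228
#>   Sens 97.1%  Spec 100.0%  +PV 58.6%  -PV 100.0%  +LR 2178.5  -LR 0.0
```

A 97%-sensitive, 99.96%-specific code still has a +PV of only 58.6%: of
461 code-positive admissions, 191 are false. Running a small end-to-end
study shows what that does to association estimates:

```r
cfg <- run_config(profile = "test", seed = 1,
                  spec = cohort_spec(n_incontinent = 120, n_continent = 100,
                                     n_none = 8000),
                  n_boot_validation = 50, n_boot_imputation = 50)
bundle <- run_study(cfg)

bundle$validation
#> Internal validation (50 bootstrap replicates)
#> c-statistic:
#>       outcome apparent  optimism corrected ci_low ci_high
#> 1 incontinent   0.9998 0.0005852    0.9992 0.9966  0.9998
#> 2   continent   0.9997 0.0002488    0.9995 0.9990  0.9999

bundle$comparison$incontinent
#> SMSE by assignment method (log-scale ANOVA F = 7.246 , p = 0.001228 )
#>        method median     q25    q75  n
#> 1          bi 0.0128 0.00157 0.0474 30
#> 2 categorical 0.0265 0.00465 0.0800 30
#> 3        code 0.1195 0.03436 0.7104 30
#> Tukey pairwise (diff of mean log SMSE):
#>                   diff    lwr  upr    p adj
#> categorical-bi   0.881 -0.890 2.65 0.464641
#> code-bi          2.768  0.996 4.54 0.000998
#> code-categorical 1.887  0.115 3.66 0.034070
```

The fitted model discriminates almost perfectly (optimism-corrected
c-statistic 0.999), yet the code-based assignment carries an order of
magnitude more misclassification bias (median SMSE 0.12) than bootstrap
imputation (0.013), and the ANOVA on log SMSE separates them. At the full
test profile (49,500 non-case admissions, 200 replicates) the separation
of BI from *both* other methods is decisive; see `test-acceptance.R`.

## Command line

```sh
Rscript inst/cli/cystmisclass simulate --seed 3 --out out/      # cohort CSV
Rscript inst/cli/cystmisclass run-all --profile test --out out/ # full bundle
Rscript inst/cli/cystmisclass accuracy                          # reference tables
```
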