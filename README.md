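# meddietr

Mediterranean-diet adherence scoring and island–mainland cohort
comparison for food-frequency-questionnaire (FFQ) data.

The package is aimed at nutritional epidemiologists working with birth
or population cohorts whose dietary intake is recorded as day/week/month
consumption frequencies and who want a reproducible pipeline from raw
FFQ responses to adherence scores, group comparisons and a machine-
learning view of group separation.

## What it computes

* **Daily frequencies.** A response of *f* times per period becomes
  *f*, *f*/7 or *f*/30 servings/day for daily, weekly and monthly
  reports.
* **MDSS** (Mediterranean Diet Serving Score). Fourteen food
  categories each award 1–3 points when servings match the
  recommendation per main meal, day or week, with no negative points:

  `MDSS = Σ_c  p_c · 1{ s_c within the recommended range }`,  p_c ∈ {1,2,3}.

  With the fermented-beverage category excluded (pregnancy cohort) the
  attainable maximum is 23 points and totals ≥ 12.5 count as adherent;
  including it restores the original 24-point score with cut-off 13.5.
* **MDS-preg.** Nine binary components (vegetables/fruits/whole grains
  ≥ 3/day; fish/dairy/nuts ≥ 2/day; legumes > 1.5/week; MUFA:SFA ratio
  > 1.6; red + processed meat < 4.5/week); totals 0–3 / 4–6 / 7–9 map
  to low / moderate / high adherence.
* **Group comparison.** Two-sided Mann–Whitney U per variable (exact
  for small untied samples, tie-corrected normal approximation
  otherwise) with a Bonferroni-corrected per-test level α/m, plus
  stratified tables and PCA loadings of the scaled cumulative
  food-group frequencies.
* **Classification.** A probability random forest (500 trees, √p mtry)
  distinguishing island (class 0) from mainland (class 1) over repeated
  random 75/25 splits, summarized as mean ± 95% CI of accuracy, Cohen's
  kappa, MCC, rank-based AUC (= U/(n₁n₀)), sensitivity and specificity,
  with impurity-importance-based variable selection at 1% mean
  importance and re-training.
* **Synthetic cohorts.** Because the motivating cohort is not publicly
  deposited, a configurable two-population generator (calibrated to the
  published baseline proportions, with a single `effect_scale` knob
  from null to full-strength differences) makes every stage testable.

## Worked example

```r
library(meddietr)

cohort <- generate_cohort(default_cohort_config(), seed = 42)
#> Synthetic FFQ cohort: 266 participants ( 149 island / 117 mainland ), 77 FFQ items

tab <- build_analysis_table(cohort)   # daily -> cumulative -> scores -> filter
dim(tab)
#> [1] 266 107    # participant_id, location, class + 104 variables

summary(tab$mdss_total)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.000   5.000   6.000   6.564   8.000  14.000

head(compare_all(tab)[, c("variable", "U", "p_raw", "tier", "significant")], 5)
#>   variable           U         p_raw tier  significant
#> 1 income         5526. 0.00000000568 ***   TRUE
#> 2 education      5748  0.000000248   ***   TRUE
#> 3 healthy_muesli 6289  0.0000832     ***   TRUE
#> 4 work_activity  9720. 0.000279      ***   TRUE
#> 5 contraception  6704. 0.000328      ***   TRUE

rf <- repeat_classification(tab, n_repeats = 50, base_seed = 11)
rf
#> Random-forest classification over 50 random 75/25 splits (mean +/- 95% CI):
#>   accuracy     0.679 +/- 0.017
#>   auc          0.774 +/- 0.013
#>   kappa        0.326 +/- 0.034
#>   mcc          0.348 +/- 0.033
#>   sensitivity  0.468 +/- 0.035
#>   specificity  0.850 +/- 0.019
#> Top variables by mean importance:
#>   income                       3.8%
#>   education                    3.1%
#>   dressing                     2.8%
#>   healthy_muesli               2.7%
#>   bmi_prepregnancy             2.5%

length(select_variables(rf))   # variables at >= 1% mean importance
#> [1] 35
```

Reading the output: the socio-economic variables (income, education,
work activity) separate the two synthetic populations most strongly —
both in the rank tests (smallest p-values, significant after Bonferroni
correction) and in the forest importances — while the classifier's
moderate kappa/MCC (~0.33–0.35) says the groups overlap substantially:
exactly the structure the generator plants. Specificity above
sensitivity reflects the island majority class being easier to
recognize.

The full pipeline (simulate → preprocess → score → compare → classify)
runs from one config and writes all stage outputs plus a JSON manifest:

```r
run_pipeline(default_pipeline_config(seed = 11), "run1/")
```

or from a shell via the thin CLI wrapper
`Rscript inst/cli/meddiet.R run --seed 11 --out run1/` (subcommands
`simulate`, `preprocess`, `score`, `compare`, `classify` run single
stages).

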