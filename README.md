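# ipacuity

Quantitative prediction of best-corrected visual acuity (BCVA) for cataract
patients from seven routine clinical indices: age, body mass index (BMI),
mean arterial pressure (MAP), intraocular pressure (IOP), HbA1c, LDL-C and
gender. The package is aimed at clinical-modelling researchers who want a
transparent, closed-form alternative to opaque learners: every prediction is
a linear combination of normalized risk factors and their pairwise
interactions, so factor significance can be read directly off the fitted
coefficients.

## The model

Each risk factor reading `X` is min-max normalized onto the dimensionless
interval `[-1, +1]`:

    X* = (X - (X_max + X_min)/2) / ((X_max - X_min)/2)

where `X_min`, `X_max` are the factor's cohort extremes (gender is coded
+1 male / -1 female). The normalized factors `v1..v7` are expanded into a
design matrix `V` whose columns are the 7 single factors, the 21 pairwise
products `v_i v_j` (i < j) and a constant — `7 + 7·6/2 + 1 = 29` terms,
with coefficient symbols `a1..a29`. The outcome vector `Y` (decimal acuity,
or its normalized counterpart) is modelled as `Y = V M`, and the coefficient
vector is the least-squares minimizer of the loss `∅ = ||V M − Y||²`,

    M = (VᵀV)⁻¹ Vᵀ Y,

computed through a QR decomposition (an SVD pseudoinverse handles
rank-deficient designs on request). Because all factors share one scale,
`|a_k|` measures how strongly term `k` moves the prediction; ranking the
coefficient magnitudes separates significant factors from minor ones, and
refitting after deleting factors (term counts 29, 22, 16, 11, 7, 4, 2)
quantifies how prediction quality degrades when indices are missing.
Prediction agreement is summarised per patient by
`AT = (actual − predicted)/actual × 100 %`.

No public patient-level dataset exists for this problem, so the package
ships a synthetic cohort generator (truncated-normal marginals matched to
the reference cohort's summary statistics, planted-coefficient outcomes)
that makes the entire pipeline testable end to end, plus the published
reference model (`reference_model()`) for predicting new patients.

## Worked example

```r
library(ipacuity)

coh <- simulate_cohort(300, seed = 42)   # synthetic cataract cohort
fit <- fit_ipa(coh)                      # 29-term closed-form fit
glance(fit)
#> # A tibble: 1 × 8
#>       n n_factors n_terms  loss correlation variance slope intercept
#>   <int>     <int>   <int> <dbl>       <dbl>    <dbl> <dbl>     <dbl>
#> 1   300         7      29 0.182       0.989    0.978 0.978    0.0121

classify_factors(fit)
#> # A tibble: 7 × 5
#>   factor term   coefficient  rank significance
#>   <chr>  <chr>        <dbl> <int> <chr>
#> 1 age    Age        -0.337      3 significant
#> 2 bmi    BMI        -0.172      6 significant
#> 3 iop    IOP        -0.140      8 significant
#> 4 ldl_c  LDL-C       0.0579    20 minor
#> 5 hba1c  HbA1c       0.0512    21 minor
#> 6 map    MAP         0.0354    24 minor
#> 7 gender Gender     -0.0209    26 minor

new_patient <- tibble::tibble(
  patient_id = "P-new", age = 72, bmi = 27.4, map = 101,
  iop = 18, hba1c = 7.1, ldl_c = 130, gender = "F"
)
predict(fit, new_patient)
#> [1] 0.584844

at_summary(coh$bcva, predict(fit, coh))
#> <agreement_report> n = 300, AT = -0.24% +/- 6.02%
#>   |AT| below 6%: 237/300
```

The `glance()` row says the training fit explains 97.8 % of the outcome
variation (`variance` is the squared actual-vs-predicted correlation; note
it equals the regression `slope`, an OLS identity). The classification table
reads the factor significance off the coefficient magnitudes: age, BMI and
IOP dominate, while LDL-C, HbA1c, MAP and gender contribute little on their
own. The new patient's predicted decimal acuity, 0.58, falls below the 0.80
risk threshold used to flag potential cataract/amblyopia risk. The agreement
report shows near-zero mean AT with 237/300 patients predicted within 6 %.

A thin command-line wrapper over the same functions ships at
`system.file("cli", "ipa.R", package = "ipacuity")` with subcommands
`simulate`, `fit`, `predict`, `rank`, `truncate`, `agreement`, `grid`.

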