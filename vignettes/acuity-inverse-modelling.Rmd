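---
title: "Inverse-problem modelling of visual acuity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-problem modelling of visual acuity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipacuity)
```

## The model and its assumptions

`ipacuity` predicts best-corrected visual acuity (BCVA, decimal scale) of
cataract patients from seven clinical indices — age, BMI, MAP, IOP, HbA1c,
LDL-C and gender — with a deliberately simple, fully interpretable model.
Three assumptions shape everything:

1. **A shared dimensionless scale.** Each factor is min-max normalized onto
   `[-1, +1]` against its cohort extremes, so coefficients are directly
   comparable and coefficient magnitude doubles as a significance measure.
   The price is sensitivity to the cohort extremes: the bounds are part of
   the model, are serialized with it, and carry a provenance tag, because a
   prediction made under different bounds is meaningless.
2. **First-order structure with pairwise interactions only.** The design
   holds each factor singly, every unordered pair product, and a constant —
   `k + k(k-1)/2 + 1` terms (29 for `k = 7`). No quadratic or higher-order
   terms exist, and the schema enforces that structurally through its term
   `kind` tags rather than by convention.
3. **Least squares is the estimand.** The coefficient vector is the
   minimizer of `||VM - Y||²`. The closed-form normal-equations solution is
   what the package computes — via QR, not an explicit inverse, since the two
   agree whenever the problem is well posed and QR is numerically stable.
   There is no regularisation and there are no standard errors; the method's
   notion of "significance" is coefficient magnitude, not inference.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `outcome_scale` | `"raw"` | — | Agreement (AT) divides by actual acuity, which is only safe on the raw decimal scale (cohort minimum 0.1). The packaged reference coefficients, by contrast, act on the normalized outcome; `predict()` maps them back through the outcome bounds. |
| `policy` (normalization) | `"allow"` | — | Verification cohorts routinely exceed training bounds; the affine map is well defined beyond `[-1, +1]`, so extrapolation with an `oor_*` flag is the honest default. `clip` and `error` are available. |
| `singular` | `"error"` | — | A rank-deficient fit (e.g. subsample smaller than 29) is usually a design mistake; the minimum-norm pseudoinverse is opt-in and warns. |
| `risk_threshold` | 0.80 | decimal acuity | Acuity below 0.8 conventionally flags cataract/amblyopia risk. |
| AT threshold | 6 | % | The conventional "good agreement" cut; counts use `|AT|` by default because AT is signed (a `signed` mode exists). |
| `n_significant` | 3 | factors | The top-3 convention used when splitting significant from minor factors. |
| `noise_sd` | 0.05 | normalized outcome | Generator default; keeps the synthetic fit quality in the range reported for real cohorts (r² ≈ 0.93–0.98) rather than making recovery trivially exact. |

## The synthetic cohort generator

No patient-level data are published for this problem, so the generator
emulates the reference cohort's *marginal* structure: each continuous factor
is a truncated normal with the reference mean/SD on the reference min/max
interval (age 78 ± 10.83 on [50, 103], BMI 24.39 ± 3.98 on [13.06, 43.55],
MAP 97.24 ± 15.43 on [57, 161], IOP 16.13 ± 3.66 on [6, 35], HbA1c
6.80 ± 1.88 on [1.5, 15.7], LDL-C 98.69 ± 34.96 on [19, 234]); gender is a
balanced ±1 Bernoulli (the reference cohort's gender mean is 0, its median
−1 — the ratio is under-determined, so 0.5 is the default with a spec
override); age is integer-rounded as clinical tables report it. Sampling is
inverse-CDF on the truncated interval, which makes draws sequence-exact
under one seed — no rejection loop whose iteration count could perturb the
stream.

Factors are sampled **independently**: the reference tables state marginals
only, and inventing a correlation structure would manufacture evidence. This
is the generator's main departure from real data, where age, MAP, HbA1c and
LDL-C are surely correlated. Consequently, passing tests demonstrate that
the *pipeline* is correct (normalization, expansion, estimation, ranking,
ablation, agreement), not that the reference cohort's dataset-dependent
diagnostics (loss 1.1186, variance 0.9285, AT 9.12 ± 27 %) are recoverable —
those depend on unavailable patient-level data and are out of scope by
design.

Outcomes are generated by *planting* a known coefficient vector (by default
the published reference vector) on the normalized design, adding Gaussian
noise, and — only when simulating realistic raw cohorts — mapping to decimal
acuity and clamping to [0.1, 1.1]. Parameter-recovery experiments leave the
outcome unclamped: clamping is a nonlinearity that would (correctly) break
the exact-recovery guarantee the noiseless contract promises.

```{r recovery}
recovery_experiment(632, noise_sd = 0, seed = 1)$max_abs_error
recovery_experiment(632, noise_sd = 0.05, seed = 1)$rmse
```

## Numerical choices

* **Solver.** QR for full-rank designs; SVD pseudoinverse (minimum-norm)
  for rank-deficient ones, behind an explicit opt-in. Residual orthogonality
  `Vᵀ(VM − Y) ≈ 0` is property-tested on every fit family, and the solution
  is cross-checked against an independent numerical minimizer of the loss
  (BFGS from multiple starts) to 1e−6.
* **Ranking ties** break by schema index, so ranks are a deterministic
  permutation even for degenerate coefficient vectors.
* **Diagnostics direction.** The regression line is *predicted on actual*;
  on a training fit with a constant term its slope equals r², a useful
  internal consistency check that the tests assert to 1e−8.
* **Degenerate inputs.** Zero-range factors are rejected at bounds fitting;
  constant actual vectors make correlation undefined and abort; AT is a hard
  error at actual = 0 (unreachable on faithful data, where acuity ≥ 0.1)
  with an explicit lenient skip mode.
* **Histogram convention.** AT bins are half-open `[e_i, e_{i+1})` with
  explicit under/overflow bins, so counts always sum to `n`.
* **Serialization.** Model JSON writes doubles at 17 significant digits,
  which round-trips IEEE doubles bit-exactly; the tests assert
  `read(write(m))` is identical.

## Design choices where the design was open

* **Outcome scale duality.** The published reference coefficients produce
  the *normalized* outcome (their constant, −0.1345, maps to acuity 0.533 —
  squarely in the observed range, while a raw-scale reading would be
  nonsensical), so `reference_model()` is flagged `outcome_scale =
  "normalized"` and `predict()` denormalizes by default. Freshly fitted
  models default to the raw outcome because every agreement statistic
  divides by actual acuity.
* **Truncation drop order.** The default ladder drops the worst-ranked
  single factor first, recomputed from the full fit. The reference
  analysis's literal order (gender, MAP, LDL-C, HbA1c, IOP, BMI) swaps
  LDL-C and HbA1c relative to its own ranks; it is preserved verbatim as
  `reference_drop_order()` rather than silently "corrected", and neither
  order is treated as the other.
* **Truncated models are refit**, not zeroed: deleting a factor's columns
  and re-estimating is what produces distinct ladder losses; zeroing
  coefficients of the full fit would conflate estimation with ablation.
* **Worked-example discrepancy.** The normalization of BMI 28.44 against
  bounds (13.06, 43.55) is +0.00886 by the formula; a published account
  prints +0.0093 while its companion value −0.8725 matches the formula to
  2e−4. The package implements the formula literally and treats the odd
  print as rounding.
* **Grid resolution.** The three-factor risk grid (age 30–80 yr,
  BMI 13.97–28.01 kg/m², IOP 7–19 mmHg) defaults to 11 points per axis —
  fine enough to resolve the 0.80 risk contour, small enough to scan by eye.

## Problem sizes used in validation

The test suite and acceptance script run entirely on synthetic data at the
study's own scale where that is cheap (632-patient cohorts for recovery and
design-shape checks; 20 replicate seeds for noisy recovery; 50 random
instances for the solver-vs-minimizer cross-check) and at a few hundred
patients for ablation and agreement experiments, keeping the full suite in
the order of seconds on one CPU.

## Known limitations

* Independent marginals understate real-world collinearity, which would
  inflate coefficient variance and reshuffle near-tied ranks.
* Coefficient-magnitude "significance" is not statistical inference; no
  uncertainty accompanies the ranks.
* The linear-with-pairwise-interactions family cannot express saturation or
  threshold effects in acuity; out-of-range extrapolation is linear by
  construction.
* Min-max bounds are extreme-value statistics: a single outlier patient
  rescales a factor's entire axis.
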