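test_that("derived clinical indices follow their defining formulas", {
  expect_equal(compute_map(100, 100), 100)
  expect_equal(compute_map(120, 80), (120 + 160) / 3)
  expect_equal(compute_map(161, 161), 161)
  expect_error(compute_map(80, 120), class = "ipa_error_blood_pressure")
  expect_error(compute_map(120, 0), class = "ipa_error_blood_pressure")

  expect_equal(compute_bmi(100, 2), 25)
  expect_equal(compute_bmi(50, 1), 50)
  expect_equal(compute_bmi(65, 1.7), 65 / 2.89)
  expect_error(compute_bmi(-1, 1.7), class = "ipa_error_domain")
})

test_that("gender encoding accepts synonyms and rejects the rest", {
  expect_equal(encode_gender(c("male", "M", "1", "+1")), rep(1, 4))
  expect_equal(encode_gender(c("female", "F", "-1")), rep(-1, 3))
  expect_equal(encode_gender(c(-1, 1)), c(-1, 1))
  expect_error(encode_gender("unknown"), class = "ipa_error_encoding")
  expect_error(encode_gender(2), class = "ipa_error_encoding")
})

test_that("bounds fitting records observed extremes and rejects degenerate factors", {
  b <- fit_factor_bounds(tibble::tibble(bmi = c(43.55, 20.1, 13.06)), "bmi")
  expect_equal(b$min, 13.06)
  expect_equal(b$max, 43.55)
  expect_equal(b$source, "fitted")
  expect_error(
    fit_factor_bounds(tibble::tibble(iop = c(5, 5, 5)), "iop"),
    class = "ipa_error_degenerate"
  )
  b2 <- fit_factor_bounds(tibble::tibble(age = c(-1, 0, 1)), "age")
  expect_equal(c(b2$min, b2$max), c(-1, 1))
  # single-sex cohorts keep the fixed gender bounds
  b3 <- fit_factor_bounds(tibble::tibble(gender = c(1, 1, 1)), "gender")
  expect_equal(c(b3$min, b3$max), c(-1, 1))
})

test_that("min-max normalization reproduces the worked clinical example", {
  # published normalization of BMI readings against cohort bounds
  expect_equal(normalize_value(15.00, 13.06, 43.55), -0.8725, tolerance = 1e-3)
  expect_equal(normalize_value(28.44, 13.06, 43.55),
    (28.44 - (43.55 + 13.06) / 2) / ((43.55 - 13.06) / 2),
    tolerance = 1e-12
  )
  expect_equal(normalize_value(13.06, 13.06, 43.55), -1)
  expect_equal(normalize_value(43.55, 13.06, 43.55), 1)
  expect_equal(normalize_value((13.06 + 43.55) / 2, 13.06, 43.55), 0)
})

test_that("denormalization inverts normalization exactly", {
  expect_equal(denormalize_value(-1, 13.06, 43.55), 13.06)
  expect_equal(denormalize_value(0, 10, 30), 20)
  expect_equal(denormalize_value(0.5, 0, 10), 7.5)
  withr::with_seed(99, {
    for (i in 1:20) {
      lo <- runif(1, -50, 50)
      hi <- lo + runif(1, 0.1, 100)
      x <- runif(5, lo - 20, hi + 20) # also outside the bounds
      expect_equal(denormalize_value(normalize_value(x, lo, hi), lo, hi), x,
        tolerance = 1e-12
      )
    }
  })
})

test_that("normalization is strictly monotone and affine-equivariant", {
  x <- seq(-3, 7, by = 0.5)
  z <- normalize_value(x, -2, 5)
  expect_true(all(diff(z) > 0))
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- runif(1, 0.1, 5)
      b <- runif(1, -10, 10)
      lo <- runif(1, -5, 0)
      hi <- runif(1, 1, 8)
      x <- runif(10, lo, hi)
      expect_equal(
        normalize_value(a * x + b, a * lo + b, a * hi + b),
        normalize_value(x, lo, hi),
        tolerance = 1e-10
      )
    }
  })
})

test_that("self-normalized cohorts hit -1/+1 at the factor extremes", {
  coh <- sample_cohort(50, seed = 21)
  norm <- normalize_cohort(coh)
  for (f in setdiff(ipa_factors(), "gender")) {
    expect_equal(min(norm[[f]]), -1)
    expect_equal(max(norm[[f]]), 1)
    expect_true(all(abs(norm[[f]]) <= 1 + 1e-12))
    expect_false(any(norm[[paste0("oor_", f)]]))
  }
  expect_true(all(norm$gender %in% c(-1, 1)))
})

test_that("out-of-range policy governs verification-cohort normalization", {
  bounds <- factor_bounds("iop", 6, 35)
  rec <- tibble::tibble(patient_id = "V1", iop = 50)
  allowed <- normalize_cohort(rec, bounds = bounds, policy = "allow")
  expect_equal(allowed$iop, (50 - 20.5) / 14.5)
  expect_true(allowed$oor_iop)
  clipped <- normalize_cohort(rec, bounds = bounds, policy = "clip")
  expect_equal(clipped$iop, 1)
  expect_true(clipped$oor_iop)
  expect_error(
    normalize_cohort(rec, bounds = bounds, policy = "error"),
    regexp = "V1.*iop|iop.*V1",
    class = "ipa_error_range"
  )
})
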