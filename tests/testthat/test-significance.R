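test_that("coefficient-magnitude ranking reproduces the reference ranks", {
  rt <- rank_terms(reference_model())
  expect_equal(rt$term[rt$rank == 1], "Age × LDL-C")
  expect_equal(rt$term[rt$rank == 2], "Age")
  expect_equal(rt$term[rt$rank == 29], "MAP × Gender")
  expect_equal(rt$coefficient[rt$rank == 29], 0.0086)
  expect_setequal(rt$rank, 1:29)
  # the published rank of each single factor
  singles <- rt[1:7, ]
  expect_equal(singles$rank, c(2L, 5L, 25L, 7L, 21L, 16L, 26L))
})

test_that("rank ties break by schema order and match a sort oracle", {
  m <- reference_model()
  m$coefficients[] <- 0.5 # all equal magnitude
  rt <- rank_terms(m)
  expect_equal(rt$rank, 1:29)

  withr::with_seed(71, {
    for (i in 1:5) {
      m$coefficients[] <- rnorm(29)
      rt <- rank_terms(m)
      oracle <- order(order(-abs(m$coefficients))) # brute-force rank by sort
      expect_equal(rt$rank, oracle)
    }
  })
})

test_that("factor classification splits significant from minor factors", {
  cls <- classify_factors(reference_model())
  expect_equal(cls$factor[cls$significance == "significant"], c("age", "bmi", "iop"))
  expect_equal(
    cls$factor[cls$significance == "minor"],
    c("ldl_c", "hba1c", "map", "gender")
  )
  all_sig <- classify_factors(reference_model(), n_significant = 7)
  expect_true(all(all_sig$significance == "significant"))
  one <- classify_factors(reference_model(), n_significant = 1)
  expect_equal(one$factor[one$significance == "significant"], "age")
  expect_error(classify_factors(reference_model(), n_significant = 8),
    class = "ipa_error_domain"
  )
})

test_that("truncation ladder steps through the full term-count series", {
  coh <- simulate_cohort(200, seed = 81)
  lad <- truncation_ladder(coh, drop_order = reference_drop_order())
  expect_equal(lad$n_factors, 7:1)
  expect_equal(lad$n_terms, c(29L, 22L, 16L, 11L, 7L, 4L, 2L))
  expect_true(all(diff(lad$loss) >= -1e-10))
  expect_true(all(diff(lad$variance) <= 1e-10))
  expect_equal(lad$slope, lad$variance, tolerance = 1e-8)
  expect_equal(lad$r2, lad$variance)
  # dropping an absent factor is a schema error
  expect_error(truncation_ladder(coh, drop_order = "not_a_factor"),
    class = "ipa_error_schema"
  )
})

test_that("default drop order removes the least significant factor first", {
  coh <- simulate_cohort(250, seed = 82)
  full <- fit_ipa(coh)
  worst_first <- rev(classify_factors(full, n_significant = 1)$factor)[1:6]
  lad <- truncation_ladder(coh)
  expect_equal(lad$dropped[-1], worst_first)
})

test_that("a factor sufficient for a noiseless outcome keeps loss at zero", {
  coh <- sample_cohort(100, seed = 83)
  norm <- normalize_cohort(coh)
  planted <- setNames(rep(0, 29), paste0("a", 1:29))
  planted["a1"] <- 0.7 # age only
  planted["a29"] <- 0.2
  norm$bcva <- plant_outcome(norm, planted)
  lad <- truncation_ladder(norm, normalized = TRUE,
                           drop_order = reference_drop_order())
  expect_true(all(lad$loss < 1e-16))
})

test_that("grid evaluation equals the reduced formula with pinned zeros", {
  m <- reference_model()
  axes <- tibble::tibble(
    factor = c("age", "bmi", "iop"),
    min = c(30, 13.97, 7), max = c(80, 28.01, 19), n = c(5, 5, 5)
  )
  grid <- evaluate_reduced_grid(m, axes)
  expect_equal(nrow(grid), 125)

  co <- reference_coefficients()
  b <- m$bounds
  v1 <- normalize_value(grid$age, b$min[b$factor == "age"], b$max[b$factor == "age"])
  v2 <- normalize_value(grid$bmi, b$min[b$factor == "bmi"], b$max[b$factor == "bmi"])
  v3 <- normalize_value(grid$iop, b$min[b$factor == "iop"], b$max[b$factor == "iop"])
  # independent reduced-formula evaluation: only the terms of the three axis
  # factors and the constant survive when all others sit at normalized zero
  reduced <- co["a1"] * v1 + co["a2"] * v2 + co["a4"] * v3 +
    co["a8"] * v1 * v2 + co["a10"] * v1 * v3 + co["a15"] * v2 * v3 + co["a29"]
  expect_equal(grid$predicted, unname(reduced), tolerance = 1e-12)
  expect_equal(
    grid$predicted_bcva,
    denormalize_value(grid$predicted, 0.1, 1.1),
    tolerance = 1e-12
  )
  expect_equal(grid$risk_flag, grid$predicted_bcva < 0.8)
})

test_that("grid midpoints with all axes at bounds centres predict the constant", {
  m <- reference_model()
  b <- m$bounds
  mid <- function(f) (b$min[b$factor == f] + b$max[b$factor == f]) / 2
  axes <- tibble::tibble(
    factor = c("age", "bmi"),
    min = c(mid("age") - 1, mid("bmi") - 1),
    max = c(mid("age") + 1, mid("bmi") + 1),
    n = c(3, 3)
  )
  grid <- evaluate_reduced_grid(m, axes)
  centre <- grid[5, ] # middle of the 3 x 3 lattice: both axes at their midpoint
  expect_equal(centre$predicted, unname(reference_coefficients()["a29"]),
    tolerance = 1e-9
  )
})

test_that("grid validation rejects bad axes", {
  m <- reference_model()
  expect_error(
    evaluate_reduced_grid(m, tibble::tibble(factor = "age", min = 30, max = 80, n = 1)),
    class = "ipa_error_domain"
  )
  expect_error(
    evaluate_reduced_grid(m, tibble::tibble(factor = "nope", min = 0, max = 1, n = 3)),
    class = "ipa_error_schema"
  )
})
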