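test_that("closed-form solve interpolates a tiny exact system", {
  # single factor, records x = (-1, 0, 1), y = (0, 1, 2): coefficients (1, 1)
  V <- cbind(x = c(-1, 0, 1), const = 1)
  m <- ipa_solve(V, c(0, 1, 2))
  expect_equal(unname(m), c(1, 1), tolerance = 1e-12)
  expect_equal(ipa_loss(c(0, 1, 2), drop(V %*% m)), 0, tolerance = 1e-20)
})

test_that("solver matches the brute-force minimiser on random instances", {
  for (s in 1:10) {
    inst <- random_instance(seed = 100 + s)
    m_closed <- ipa_solve(inst$V, inst$y)
    m_oracle <- oracle_least_squares(inst$V, inst$y)
    expect_equal(unname(m_closed), m_oracle, tolerance = 1e-6)
  }
})

test_that("residuals are orthogonal to the design on every fit", {
  for (s in 1:5) {
    inst <- random_instance(seed = 200 + s)
    m <- ipa_solve(inst$V, inst$y)
    resid <- drop(inst$V %*% m) - inst$y
    expect_lt(
      max(abs(crossprod(inst$V, resid))),
      1e-8 * max(abs(crossprod(inst$V, inst$y)))
    )
  }
})

test_that("rank-deficient designs follow the configured policy", {
  V <- cbind(c(1, 2, 3), c(2, 4, 6), 1) # collinear
  y <- c(1, 2, 3.5)
  expect_error(ipa_solve(V, y), class = "ipa_error_rank")
  expect_warning(m <- ipa_solve(V, y, singular = "pseudoinverse"))
  # pseudoinverse solution still minimises the loss
  m_ok <- ipa_solve(V[, c(1, 3)], y)
  expect_equal(
    ipa_loss(y, drop(V %*% m)),
    ipa_loss(y, drop(V[, c(1, 3)] %*% m_ok)),
    tolerance = 1e-10
  )
})

test_that("fit is invariant to row order and equivariant to term order", {
  coh <- random_normalized_cohort(60, seed = 31)
  schema <- build_term_schema()
  V <- build_design_matrix(coh, schema)
  y <- withr::with_seed(32, drop(V %*% rnorm(29)) + rnorm(60, 0, 0.1))
  m <- ipa_solve(V, y)
  perm <- withr::with_seed(33, sample(60))
  expect_equal(ipa_solve(V[perm, ], y[perm]), m, tolerance = 1e-9)
  cperm <- withr::with_seed(34, sample(29))
  m2 <- ipa_solve(V[, cperm], y)
  expect_equal(unname(m2), unname(m)[cperm], tolerance = 1e-9)
})

test_that("noiseless planted coefficients are recovered exactly", {
  coh <- random_normalized_cohort(100, seed = 41)
  planted <- withr::with_seed(42, rnorm(29))
  y <- plant_outcome(coh, planted)
  coh$y <- y
  fit <- fit_ipa(coh, outcome = "y", normalized = TRUE,
                 bounds = factor_bounds(ipa_factors(), rep(-1, 7), rep(1, 7)))
  expect_equal(unname(fit$coefficients), planted, tolerance = 1e-9)
  expect_equal(fit$diagnostics$loss, 0, tolerance = 1e-16)
})

test_that("training diagnostics obey the OLS identities", {
  # identity and scale cases
  a <- c(0.2, 0.5, 0.9, 0.4)
  d <- diagnose(a, a)
  expect_equal(d$correlation, 1)
  expect_equal(d$variance, 1)
  expect_equal(d$slope, 1)
  expect_equal(d$intercept, 0)
  expect_equal(d$loss, 0)
  d2 <- diagnose(a, 2 * a)
  expect_equal(d2$slope, 2)
  expect_equal(d2$intercept, 0)
  expect_equal(d2$variance, 1)
  expect_error(diagnose(rep(1, 4), a), class = "ipa_error_domain")

  # on any training fit with a constant term, slope(pred ~ actual) = r^2
  for (s in 1:5) {
    inst <- random_instance(seed = 300 + s)
    m <- ipa_solve(inst$V, inst$y)
    d <- diagnose(inst$y, drop(inst$V %*% m))
    expect_equal(d$slope, d$variance, tolerance = 1e-8)
    expect_equal(d$variance, d$correlation^2, tolerance = 1e-10)
  }
})

test_that("training loss never increases when terms are added", {
  coh <- simulate_cohort(150, seed = 51)
  f <- ipa_factors()
  losses <- vapply(seq_along(f), function(k) {
    glance(fit_ipa(coh, factors = f[1:k]))$loss
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("predictions follow the schema alignment of the coefficients", {
  m <- reference_model()
  zero <- tibble::as_tibble(setNames(as.list(rep(0, 7)), ipa_factors()))
  expect_equal(
    predict(m, zero, normalized = TRUE, scale = "model"),
    unname(reference_coefficients()["a29"])
  )
  one <- zero
  one$age <- 1
  expect_equal(
    predict(m, one, normalized = TRUE, scale = "model"),
    unname(sum(reference_coefficients()[c("a1", "a29")]))
  )
  both <- zero
  both$age <- 1
  both$ldl_c <- 1
  expect_equal(
    predict(m, both, normalized = TRUE, scale = "model"),
    -0.6798 + 0.1231 - 0.8183 - 0.1345
  )
  # raw-scale prediction maps through the outcome bounds
  expect_equal(
    predict(m, zero, normalized = TRUE, scale = "raw"),
    denormalize_value(-0.1345, 0.1, 1.1)
  )
})

test_that("tidy and glance summarise a fitted model", {
  coh <- simulate_cohort(120, seed = 61)
  fit <- fit_ipa(coh)
  td <- tidy(fit)
  expect_equal(nrow(td), 29)
  expect_named(td, c("term", "symbol", "kind", "estimate", "rank"))
  expect_setequal(td$rank, 1:29)
  g <- glance(fit)
  expect_equal(g$n, 120)
  expect_equal(g$n_terms, 29)
  expect_equal(g$slope, g$variance, tolerance = 1e-8)
})
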