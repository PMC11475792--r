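# independent brute-force least-squares oracle: minimise ||V b - y||^2
# numerically (BFGS with analytic gradient, two starts), never via the
# closed-form route under test
oracle_least_squares <- function(V, y) {
  loss_fn <- function(b) sum((V %*% b - y)^2)
  grad_fn <- function(b) drop(2 * crossprod(V, V %*% b - y))
  starts <- list(
    rep(0, ncol(V)),
    rep(0.5, ncol(V))
  )
  fits <- lapply(starts, function(b0) {
    stats::optim(b0, loss_fn, grad_fn,
      method = "BFGS",
      control = list(maxit = 2000, reltol = 1e-16)
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  best$par
}

# random well-posed regression instance on the [-1, 1] design scale
random_instance <- function(seed, n_max = 100, p_max = 29) {
  withr::with_seed(seed, {
    p <- sample(2:p_max, 1)
    n <- sample((p + 20):max(p + 20, n_max), 1)
    V <- matrix(runif(n * p, -1, 1), n, p)
    V[, p] <- 1 # constant column
    beta <- rnorm(p)
    y <- drop(V %*% beta) + rnorm(n, 0, 0.1)
    list(V = V, y = y, n = n, p = p)
  })
}

# small normalized cohort with named factor columns
random_normalized_cohort <- function(n, seed, factors = ipa_factors()) {
  withr::with_seed(seed, {
    cols <- lapply(factors, function(f) {
      if (identical(f, "gender")) sample(c(-1, 1), n, replace = TRUE) else runif(n, -1, 1)
    })
    names(cols) <- factors
    tibble::as_tibble(cols)
  })
}
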