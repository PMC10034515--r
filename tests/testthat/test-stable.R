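test_that("stable_params validates ranges", {
  expect_error(stable_params(0, 0, 1, 0), "alpha")
  expect_error(stable_params(2.1, 0, 1, 0), "alpha")
  expect_error(stable_params(1, 2, 1, 0), "beta")
  expect_error(stable_params(1, 0, -1, 0), "gamma")
  expect_s3_class(stable_params(2, 0, 1, 0), "stable_params")
})

test_that("characteristic function is 1 at omega = 0 and matches closed forms", {
  om <- seq(-5, 5, length.out = 41)
  # phi(0) = 1 for arbitrary parameters
  expect_equal(stable_cf(0, stable_params(1.3, 0.4, 0.7, -0.2)), 1 + 0i)
  # Gaussian: alpha = 2, beta = 0, variance 2*gamma
  g <- stable_params(2, 0, 0.5, 0.3)
  expect_lt(max(Mod(stable_cf(om, g) -
                      exp(1i * 0.3 * om - 0.5 * om^2))), 1e-6)
  # Cauchy: alpha = 1, beta = 0, scale gamma
  cch <- stable_params(1, 0, 0.8, -0.1)
  expect_lt(max(Mod(stable_cf(om, cch) -
                      exp(1i * -0.1 * om - 0.8 * abs(om)))), 1e-6)
})

test_that("density matches Gaussian and Cauchy closed forms", {
  x <- seq(-4, 4, length.out = 33)
  g <- stable_params(2, 0, 0.5, 0.3)        # N(0.3, sd = 1)
  expect_lt(max(abs(stable_pdf(x, g) - dnorm(x, 0.3, 1))), 1e-6)
  cch <- stable_params(1, 0, 0.8, -0.1)
  expect_lt(max(abs(stable_pdf(x, cch) - dcauchy(x, -0.1, 0.8))), 1e-6)
})

test_that("density integrates to 1", {
  # doubly-infinite for a light-ish tail; truncated at +/- 1000 for the
  # heavier tail, where the Fourier-inversion quadrature is noise-limited
  # far out but the excluded tail mass is ~1e-4 << the 1e-3 tolerance
  p1 <- stable_params(1.6, 0.5, 1, 0)
  total1 <- integrate(function(x) stable_pdf(x, p1), -Inf, Inf,
                      rel.tol = 1e-6)$value
  expect_lt(abs(total1 - 1), 1e-3)
  p2 <- stable_params(1.2, -0.3, 0.5, 1)
  total2 <- integrate(function(x) stable_pdf(x, p2), 1 - 1000, 1 + 1000,
                      rel.tol = 1e-6, subdivisions = 500L)$value
  expect_lt(abs(total2 - 1), 1e-3)
})

test_that("sampler matches closed-form special cases in distribution", {
  set.seed(11)
  g <- rstable(20000, stable_params(2, 0, 0.5, 0.3))  # N(0.3, 1)
  expect_lt(abs(mean(g) - 0.3), 0.03)
  expect_lt(abs(sd(g) - 1), 0.03)
  expect_gt(ks.test(g, pnorm, 0.3, 1)$p.value, 0.01)
  cch <- rstable(20000, stable_params(1, 0, 0.8, -0.1))
  expect_gt(ks.test(cch, pcauchy, -0.1, 0.8)$p.value, 0.01)
})

test_that("fit recovers Gaussian parameters from seeded draws", {
  set.seed(2023)
  x <- rnorm(1e5, 0.3, 1)                  # alpha = 2, gamma = 0.5, mu = 0.3
  fit <- fit_stable(x)
  co <- coef(fit)
  expect_lt(abs(co[["mu"]] - 0.3), 0.01)
  expect_gte(co[["alpha"]], 1.85)
  expect_lte(co[["alpha"]], 2)
  expect_lt(abs(co[["gamma"]] - 0.5), 0.05)
})

test_that("fit recovers a heavy-tailed location", {
  set.seed(7)
  x <- rcauchy(5e4, location = 0.4, scale = 0.3)
  fit <- fit_stable(x)
  co <- coef(fit)
  expect_lt(abs(co[["alpha"]] - 1), 0.1)
  # location tolerance is loose: in this parameterization the location is
  # very sensitive to small alpha/beta errors near alpha = 1
  expect_lt(abs(co[["mu"]] - 0.4), 0.15)
})

test_that("stable_fit methods work", {
  set.seed(3)
  fit <- fit_stable(rnorm(2000, 0, 0.2))
  expect_s3_class(fit, "stable_fit")
  expect_named(coef(fit), c("alpha", "beta", "gamma", "mu"))
  expect_output(print(fit), "alpha")
  d <- predict(fit, seq(-1, 1, 0.5), type = "density")
  expect_true(all(d >= 0))
  sim <- simulate(fit, nsim = 100, seed = 1)
  expect_length(sim, 100)
  expect_identical(sim, simulate(fit, nsim = 100, seed = 1))
})

test_that("fit rejects too-small or degenerate-friendly input", {
  expect_error(fit_stable(runif(5)), "min_samples|at least")
  fit <- fit_stable(rep(0.4, 50))          # constant: flagged degenerate
  expect_true(fit$degenerate)
  expect_equal(coef(fit)[["mu"]], 0.4)
})

test_that("gaussianity test behaves and preserves the RNG stream", {
  set.seed(10)
  g <- rnorm(800)
  u <- runif(800)
  rng_before <- .Random.seed
  res_g <- gaussianity_test(g)
  expect_identical(.Random.seed, rng_before)   # subsampling must not disturb
  expect_gt(res_g$p.value, 0.01)
  expect_lt(gaussianity_test(u)$p.value, 0.01)
  # large inputs are subsampled deterministically
  big <- c(g, rnorm(9200))
  rng_before <- .Random.seed
  r1 <- gaussianity_test(big); r2 <- gaussianity_test(big)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(.Random.seed, rng_before)
})
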