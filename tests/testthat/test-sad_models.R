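quad_mass <- function(model, upper = Inf) {
  stats::integrate(function(x) sad_density(model, x), 1, upper,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}

test_that("double power-law constants satisfy continuity and unit mass", {
  for (p in list(c(0.36, 1.54, 2313), c(0.5, 2.0, 100), c(1.2, 1.2, 50))) {
    k <- double_pl_constants(p[1], p[2], p[3])
    resid <- k[["A"]] * p[3]^(-1 - p[1]) - k[["B"]] * p[3]^(-1 - p[2])
    expect_lt(abs(resid) / (k[["A"]] * p[3]^(-1 - p[1])), 1e-12)
    m <- double_power_law(p[1], p[2], p[3])
    expect_equal(quad_mass(m), 1, tolerance = 1e-6)
  }
  # equal exponents collapse to the single-regime continuous power law
  k <- double_pl_constants(1.7, 1.7, 500)
  expect_equal(unname(k[["A"]]), 1.7, tolerance = 1e-12)
  expect_equal(unname(k[["B"]]), 1.7, tolerance = 1e-12)
  expect_error(double_pl_constants(0.5, -0.1, 10), class = "sads_domain_error")
})

test_that("shifted power-law constant normalizes the density", {
  expect_equal(shifted_pl_constant(1.3, 0, Inf), 1.3)
  m <- shifted_power_law(0.89, 20.34, 1e6)
  expect_equal(quad_mass(m, upper = 1e6), 1, tolerance = 1e-6)
  # A strictly increasing in alpha at fixed x0, x_max
  As <- vapply(c(0.5, 0.8, 1.1, 1.4), shifted_pl_constant, numeric(1),
               x0 = 5, x_max = 1e5)
  expect_true(all(diff(As) > 0))
  expect_error(shifted_pl_constant(1, 0, 0.5), class = "sads_domain_error")
})

test_that("mean abundance matches closed forms and quadrature", {
  expect_equal(mean_abundance(power_law(2)), 2)
  m <- shifted_power_law(1.6, 12.5, 1e5)
  num <- stats::integrate(function(x) x * sad_density(m, x), 1, 1e5,
                          rel.tol = 1e-12)$value
  expect_equal(mean_abundance(m), num, tolerance = 1e-8)
  expect_error(mean_abundance(shifted_power_law(0.89, 20.34)),
               class = "sads_diverging_mean_error")
  expect_error(mean_abundance(power_law(0.89)),
               class = "sads_diverging_mean_error")
  tpl <- truncated_power_law(0.5, 1e-3)
  num_tpl <- stats::integrate(function(x) x * sad_density(tpl, x), 1, Inf,
                              rel.tol = 1e-10)$value
  expect_equal(mean_abundance(tpl), num_tpl, tolerance = 1e-6)
})

test_that("samplers are deterministic per seed and honor the stopping rule", {
  m <- double_power_law(0.36, 1.54, 2313)
  expect_identical(sad_sample(m, 500, seed = 9), sad_sample(m, 500, seed = 9))
  expect_false(identical(sad_sample(m, 500, seed = 9), sad_sample(m, 500, seed = 10)))

  v <- sample_to_reads(m, 5e4, seed = 4)
  expect_gte(total_reads(v), 5e4)
  expect_lt(total_reads(v) - 5e4, v$x[richness(v)])
})

test_that("empirical mean of power-law draws matches the model mean", {
  m <- power_law(2)
  x <- sad_sample(m, 1e5, seed = 21)
  # rounding adds at most 1/2 to the continuous mean of 2
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean_abundance(m)), 3 * se + 0.5)
})

test_that("discretized samplers match their model CCD", {
  models <- list(
    power_law(1.5),
    truncated_power_law(0.6, 1e-3),
    lognormal_model(1, 2),
    weibull_model(0.5, 10),
    double_power_law(0.36, 1.54, 300),
    shifted_power_law(0.89, 20.34, 1e5)
  )
  for (m in models) {
    x <- sad_sample(m, 1e5, seed = 31)
    ks <- vapply(unique(round(10^seq(0, log10(stats::quantile(x, 0.999)), length.out = 40))),
      function(k) {
        # exact CCD of the rounded draw: P(X_cont > k - 1/2)
        abs(mean(x >= k) - (1 - sad_cdf(m, max(k - 0.5, 1))))
      }, numeric(1))
    expect_lt(max(ks), 0.01)
  }
})

test_that("family limits coincide exactly", {
  x <- 10^seq(0, 6, length.out = 50)
  expect_equal(sad_density(truncated_power_law(0.7, 0), x, log = TRUE),
               sad_density(power_law(0.7), x, log = TRUE))
  expect_equal(sad_density(double_power_law(1.3, 1.3, 1), x),
               sad_density(power_law(1.3), x), tolerance = 1e-12)
  expect_equal(sad_density(shifted_power_law(1.3, 0), x),
               sad_density(power_law(1.3), x), tolerance = 1e-12)
})

test_that("quantile functions invert the CDF", {
  p <- c(0.01, 0.2, 0.5, 0.9, 0.999)
  for (m in list(power_law(0.9), truncated_power_law(0.5, 1e-4),
                 lognormal_model(0, 1.5), weibull_model(0.6, 5),
                 double_power_law(0.4, 1.6, 200), shifted_power_law(1.1, 8, 1e6))) {
    expect_equal(sad_cdf(m, sad_quantile(m, p)), p, tolerance = 1e-6)
  }
})

test_that("model JSON serialization round-trips", {
  for (m in list(power_law(1.57), truncated_power_law(0.52, 1e-4),
                 shifted_power_law(0.89, 20.34),
                 double_power_law(0.36, 1.54, 2313))) {
    m2 <- parse_sad_model(sad_model_json(m))
    expect_equal(m2$params, m$params, tolerance = 1e-12)
  }
})
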