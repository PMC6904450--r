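test_that("power-law MLE equals the closed form and a numerical maximizer", {
  x <- rep(exp(1), 3)
  expect_equal(fit_power_law(c(x, rep(exp(1), 7)))$model$params$alpha, 1)

  v <- small_community(alpha = 1.3, n = 2000, seed = 8)
  fit <- fit_power_law(v)
  # independent route: 1-D likelihood maximization
  num <- optimize(function(a) sum(sad_density(power_law(a), v$x, log = TRUE)),
                  c(0.01, 10), maximum = TRUE, tol = 1e-12)$maximum
  expect_equal(fit$model$params$alpha, num, tolerance = 1e-8)
  expect_equal(unname(fit$stderr["alpha"]),
               fit$model$params$alpha / sqrt(richness(v)))
  expect_equal(fit$AIC, -2 * fit$logL + 2)
})

test_that("each family's MLE refits its own continuous draws within 3 standard errors", {
  # recovery of the estimator itself, free of read-count discretization
  # (sampler fidelity incl. rounding is covered by the CCD test; the
  # integer-data recoveries used by the analyses are tested on the double
  # and shifted fits below)
  cases <- list(
    list(model = power_law(0.89), get = function(f) f$model$params$alpha,
         fit = function(x) fit_power_law(x), truth = 0.89, se = "alpha"),
    list(model = truncated_power_law(0.5, 1e-3), get = function(f) f$model$params$beta,
         fit = function(x) fit_truncated_power_law(x), truth = 0.5, se = "beta"),
    list(model = lognormal_model(0.5, 1.8), get = function(f) f$model$params$meanlog,
         fit = function(x) fit_lognormal(x), truth = 0.5, se = "meanlog"),
    list(model = weibull_model(0.6, 4), get = function(f) f$model$params$shape,
         fit = function(x) fit_weibull(x), truth = 0.6, se = "shape")
  )
  n_seeds <- 10
  for (cs in cases) {
    hits <- 0
    for (i in seq_len(n_seeds)) {
      x <- sad_sample(cs$model, 5000, seed = 200 + i, discretize = FALSE)
      f <- cs$fit(x)
      se <- unname(f$stderr[cs$se])
      if (is.finite(se) && abs(cs$get(f) - cs$truth) <= 3 * se) hits <- hits + 1
    }
    expect_gte(hits, ceiling(0.9 * n_seeds))
  }
})

test_that("AIC comparison behaves like the weight formula demands", {
  v <- small_community(alpha = 1.1, n = 300, seed = 12)
  f1 <- fit_power_law(v)
  cmp1 <- akaike(list(f1))
  expect_equal(cmp1$delta_aic, 0)
  expect_equal(cmp1$weight, 1)

  # two identical fits split the weight evenly
  cmp2 <- akaike(list(f1, f1))
  expect_equal(cmp2$weight, c(0.5, 0.5))

  # delta AIC (0, 2) -> weights from the exp(-delta/2) formula
  f2 <- f1
  f2$AIC <- f1$AIC + 2
  cmp3 <- akaike(list(f1, f2))
  expect_equal(cmp3$weight, c(0.7310586, 0.2689414), tolerance = 1e-3)

  # permutation invariance of the ordering
  cmp4 <- akaike(list(f2, f1))
  expect_equal(sort(cmp4$delta_aic), sort(cmp3$delta_aic))
  expect_equal(cmp4$weight[2], cmp3$weight[1])

  # shifting all logL leaves weights unchanged
  g1 <- f1; g2 <- f2
  g1$logL <- g1$logL + 50; g1$AIC <- g1$AIC - 100
  g2$logL <- g2$logL + 50; g2$AIC <- g2$AIC - 100
  expect_equal(akaike(list(g1, g2))$weight, cmp3$weight)

  # fits on different data cannot be compared
  f3 <- fit_power_law(small_community(alpha = 1.1, n = 301, seed = 13))
  expect_error(akaike(list(f1, f3)), class = "sads_comparison_error")
})

test_that("model selection prefers the generating truncated power law", {
  x <- sad_sample(truncated_power_law(0.5, 1e-4), 1e4, seed = 77)
  cmp <- fit_candidate_models(x)
  expect_equal(cmp$family[cmp$delta_aic == 0], "truncated_power_law")
  expect_equal(sum(cmp$weight), 1)
})

test_that("two-stage double power-law fit recovers its generating parameters", {
  truth <- c(delta = 0.36, alpha = 1.54, x_c = 2313)
  ests <- vapply(1:3, function(i) {
    x <- sad_sample(double_power_law(truth[1], truth[2], truth[3]), 18022,
                    seed = 400 + i)
    f <- fit_double_power_law(x)
    c(f$model$params$delta, f$model$params$alpha)
  }, numeric(2))
  expect_lt(abs(mean(ests[1, ]) - truth[["delta"]]), 0.05)
  expect_lt(abs(mean(ests[2, ]) - truth[["alpha"]]), 0.15)
})

test_that("pure power-law data yields no real break: head and tail exponents agree", {
  x <- sad_sample(power_law(1.2), 5000, seed = 55)
  f <- fit_double_power_law(x)
  pooled_se <- sqrt(sum(f$stderr[c("delta", "alpha")]^2, na.rm = TRUE))
  expect_lt(abs(f$model$params$delta - f$model$params$alpha), 3 * pooled_se + 0.1)
})

test_that("a forced degenerate cutoff reduces the double fit to the pure power law", {
  v <- small_community(alpha = 0.9, n = 600, seed = 14)
  f_forced <- fit_double_power_law(v, x_c = 1)
  f_pl <- fit_power_law(v)
  expect_equal(f_forced$model$params$delta, f_pl$model$params$alpha)
  expect_equal(f_forced$model$params$alpha, f_pl$model$params$alpha)
  expect_equal(f_forced$logL, f_pl$logL)
})

test_that("shifted power-law iteration lands on the likelihood stationary point", {
  x <- sad_sample(shifted_power_law(0.89, 20.34), 3695, seed = 60)
  f <- fit_shifted_power_law(x, tol = 1e-6)
  expect_true(f$converged)
  a <- f$model$params$alpha; x0 <- f$model$params$x0; S <- f$n
  # both score equations satisfied to ~10x the tolerance
  a_resid <- a - S / sum(log((f$data + x0) / (1 + x0)))
  x0_resid <- (1 + x0) - a * S / ((1 + a) * sum(1 / (f$data + x0)))
  expect_lt(abs(a_resid), 1e-5)
  expect_lt(abs(x0_resid), 1e-4)
  # independent route: direct 2-D likelihood maximization
  o <- optim(c(log(1), log(1)), function(p) {
    -sum(sad_density(shifted_power_law(exp(p[1]), exp(p[2])), f$data, log = TRUE))
  }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(a, exp(o$par[1]), tolerance = 1e-3)
  expect_equal(x0, exp(o$par[2]), tolerance = 1e-2)
})

test_that("shifted fit on unshifted data drives x0 to the boundary", {
  x <- sad_sample(power_law(1.5), 3000, seed = 61)
  f <- fit_shifted_power_law(x)
  expect_lt(f$model$params$x0, 0.5)
})

test_that("x_max estimation inverts the mean-abundance equation", {
  alpha <- 0.88; x0 <- 150
  for (x_max_true in c(1e4, 1e7, 1e10)) {
    mu <- mean_abundance(shifted_power_law(alpha, x0, x_max_true))
    expect_equal(estimate_x_max(alpha, x0, mu), x_max_true, tolerance = 1e-6)
  }
  # mean is monotone increasing in x_max
  mus <- vapply(10^(3:8), function(xm) mean_abundance(shifted_power_law(alpha, x0, xm)),
                numeric(1))
  expect_true(all(diff(mus) > 0))
  expect_error(estimate_x_max(alpha, x0, 0.9), class = "sads_domain_error")
  # a mean no finite x_max can reach on a light tail flags unbounded
  xm <- estimate_x_max(2.5, 0, 1e9)
  expect_true(is.infinite(xm) && isTRUE(attr(xm, "unbounded")))
})

test_that("tail fit with automatic cutoff recovers the tail exponent", {
  x <- sad_sample(power_law(0.89), 4000, seed = 62)
  f <- fit_power_law_tail(x)
  expect_lt(abs(f$model$params$alpha - 0.89), 3 * unname(f$stderr["alpha"]) + 0.05)
})
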