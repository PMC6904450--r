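test_that("reads per species matches truncated-series sums and limits", {
  for (a in c(1.1, 1.57, 3)) {
    expect_equal(reads_per_species(a), brute_reads_per_species(a),
                 tolerance = 1e-6)
  }
  expect_equal(reads_per_species(50), 1, tolerance = 1e-10)
  # near the divergence the ratio blows up like 1/(alpha - 1)
  expect_gt(reads_per_species(1.01), 50)
  expect_equal(reads_per_species(1.01), brute_reads_per_species(1.01),
               tolerance = 1e-6)
  expect_error(reads_per_species(0.9), class = "sads_divergent_sum_error")
})

test_that("the theoretical accumulation exponent is min(alpha, 1)", {
  expect_equal(theoretical_gamma(0.89), 0.89)
  expect_equal(theoretical_gamma(1.57), 1)
  expect_warning(g <- theoretical_gamma(1), "logarithmic")
  expect_equal(g, 1)
})

test_that("the sublinear-regime richness formula is self-inverse", {
  alpha <- 0.6; S <- 1e4; N_max <- 1e8
  # forward: reads implied by S; back: S implied by those reads
  N <- S * N_max^(1 - alpha) / ((1 - alpha) * zeta_fn(1 + alpha))
  expect_equal(richness_given_effort(alpha, N, N_max), S, tolerance = 1e-9)
  expect_warning(richness_given_effort(0.2, 100, 2), "not >> 1")
})

test_that("N_max follows the single-top-OTU scaling law", {
  expect_equal(n_max_from_richness(2 * 300, 0.5) / n_max_from_richness(300, 0.5),
               2^(1 / 0.5), tolerance = 1e-12)
  expect_equal(n_max_from_richness(zeta_fn(2), 1), 1, tolerance = 1e-12)
})

test_that("max abundance scales as S^(1/alpha) across simulated communities", {
  alpha <- 0.5
  sizes <- c(500, 1500, 5000, 15000)
  pts <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    xs <- vapply(1:5, function(r) {
      max(sad_sample(power_law(alpha), sizes[i], seed = 700 + 10 * i + r))
    }, numeric(1))
    c(S = sizes[i], xmax = exp(mean(log(xs))))
  }))
  slope <- coef(lm(log(pts[, "xmax"]) ~ log(pts[, "S"])))[2]
  expect_equal(unname(slope), 1 / alpha, tolerance = 0.35)
})

test_that("accumulation endpoints are exact and the mean matches the hypergeometric form", {
  v <- small_community(alpha = 0.7, n = 500, seed = 42)
  N <- total_reads(v)
  grid <- unique(round(10^seq(0, log10(N), length.out = 12)))
  curve <- accumulation_curve(v, grid = grid, replicates = 20, seed = 9)
  expect_equal(curve$S_mean[curve$N == 1], 1)
  expect_equal(curve$S_mean[curve$N == N], richness(v))
  expect_equal(curve$S_sd[curve$N == N], 0)
  expect_true(all(diff(curve$S_mean) >= 0))
  expect_true(all(curve$S_mean <= richness(v)))

  analytic <- expected_richness_hypergeometric(v, curve$N)
  tol <- 2 * pmax(curve$S_sd / sqrt(attr(curve, "replicates")), 0.5)
  expect_true(all(abs(curve$S_mean - analytic) <= tol))
})

test_that("the closed-form rarefaction mean agrees with vegan", {
  skip_if_not_installed("vegan")
  v <- small_community(alpha = 1.2, n = 200, seed = 17)
  depths <- c(10, 100, 500)
  ours <- expected_richness_hypergeometric(v, depths)
  theirs <- as.numeric(vegan::rarefy(matrix(v$x, nrow = 1), depths))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("rarefaction never exceeds the pool and rejects over-deep grids", {
  v <- small_community(n = 100, seed = 2)
  expect_error(accumulation_curve(v, grid = c(10, total_reads(v) + 1)),
               class = "sads_domain_error")
})

test_that("gamma fitting is exact on noiseless power-law points", {
  N <- 10^seq(1, 5, length.out = 8)
  curve <- data.frame(N = N, S_mean = 3 * N^0.5)
  g <- fit_gamma(curve)
  expect_equal(g$gamma, 0.5, tolerance = 1e-12)
  expect_equal(g$ci95, 0, tolerance = 1e-9)
})

test_that("piecewise fitting recovers a constructed two-regime curve", {
  N1 <- 10^seq(1, 3.8, length.out = 8)
  N2 <- 10^seq(4.2, 6.5, length.out = 8)
  brk <- 10^4
  S1 <- 2 * N1^0.9
  S2 <- (2 * brk^0.9 / brk^0.33) * N2^0.33
  curve <- data.frame(N = c(N1, N2), S_mean = c(S1, S2))
  g <- fit_gamma_piecewise(curve)
  expect_equal(g$gamma, 0.9, tolerance = 0.02)
  expect_equal(g$gamma2, 0.33, tolerance = 0.02)
  expect_true(g$breakpoint >= max(N1) * 0.9 && g$breakpoint <= min(N2) * 1.1)
})

test_that("gamma fitting rejects degenerate windows", {
  curve <- data.frame(N = c(10, 100, 1000), S_mean = c(0, 5, 10))
  expect_error(fit_gamma(curve), class = "sads_domain_error")
  expect_error(fit_gamma(data.frame(N = c(10, 20), S_mean = c(2, 3))),
               class = "sads_domain_error")
})

test_that("chao1 follows the singleton-doubleton arithmetic", {
  expect_equal(chao1(abundance_vector(c(3, 4, 5))), 3)  # no singletons
  v <- abundance_vector(c(1, 1, 2, 5, 9))               # f1 = 2, f2 = 1
  expect_equal(chao1(v), 7)
  v2 <- abundance_vector(c(1, 1, 1, 5))                 # f2 = 0, bias-corrected
  expect_equal(chao1(v2), 4 + 3 * 2 / 2)
})

test_that("chao1 understates true richness for deep-tailed communities", {
  short <- 0
  for (i in 1:10) {
    truth <- sample_to_reads(power_law(0.5), 2e4, seed = 900 + i)
    sub <- accumulation_curve(truth, grid = round(total_reads(truth) / 20),
                              replicates = 1, seed = 900 + i)
    # chao1 on the subsample vs the generating community's richness
    pool <- rep.int(seq_len(richness(truth)), truth$x)
    sub_counts <- withr::with_seed(900 + i, {
      tabulate(sample(pool, round(total_reads(truth) / 20)))
    })
    est <- chao1(abundance_vector(sub_counts[sub_counts > 0]))
    if (est <= richness(truth)) short <- short + 1
  }
  expect_gte(short, 9)
})
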