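test_that("reference trajectories evaluate to their stated limits", {
  up <- default_trajectories("upper")
  expect_equal(unname(eval_trajectory(up, 1e-9)[["x_c"]]), 52.6, tolerance = 1e-6)
  expect_equal(unname(eval_trajectory(up, 1e12)[["delta"]]), 0.32, tolerance = 1e-9)
  expect_equal(unname(eval_trajectory(up, 1e12)[["alpha"]]), 1.42, tolerance = 1e-9)
  dp <- default_trajectories("deep")
  expect_equal(unname(eval_trajectory(dp, 1e12)[["alpha"]]), 0.88, tolerance = 1e-9)
  expect_equal(unname(eval_trajectory(dp, 1e-9)[["mean_x"]]), 23.6, tolerance = 1e-6)
  expect_error(default_trajectories("abyssal"))
})

test_that("trajectory fitting round-trips noiseless generated series", {
  N <- 10^seq(4, 7.5, length.out = 10)
  series <- rbind(
    data.frame(N_reads = N, parameter = "x_c", mean = 0.0002 * N^1.1 + 52.6),
    data.frame(N_reads = N, parameter = "delta",
               mean = 0.32 * (1 + 0.71 * exp(-N / 570007))),
    data.frame(N_reads = N, parameter = "alpha",
               mean = 1.42 * (1 - 0.2 * exp(-N / 110185)))
  )
  traj <- fit_trajectories(series, forms = list(
    x_c = list(type = "power_const"),
    delta = list(type = "sat_exp", sign = +1),
    alpha = list(type = "sat_exp", sign = -1)
  ))
  expect_equal(traj$curves$x_c$coef, c(0.0002, 1.1, 52.6), tolerance = 1e-4)
  expect_equal(traj$curves$delta$coef, c(0.32, 0.71, 570007), tolerance = 1e-3)
  expect_equal(traj$curves$alpha$coef, c(1.42, 0.2, 110185), tolerance = 1e-3)
  # saturating forms plateau at c1
  expect_equal(unname(eval_trajectory(traj, 1e15)[["delta"]]), 0.32, tolerance = 1e-6)
})

test_that("parameter series over aggregated subsets is self-consistent", {
  sim <- synth_survey(double_power_law(0.4, 1.6, 150), n_samples = 20,
                      reads_per_sample = 5000, seed = 23, target_reads = 1e5)
  tab <- sim$table
  # degenerate aggregation: every sample once equals the global fit
  suppressWarnings({
    ser_all <- parameter_series(tab, "double", subset_sizes = ncol(tab),
                                reps = 1, seed = 5, bins = 1)
  })
  glob <- fit_double_power_law(aggregate_counts(tab))
  a_row <- ser_all[ser_all$parameter == "alpha", ]
  expect_equal(a_row$mean, glob$model$params$alpha, tolerance = 1e-12)
  expect_equal(a_row$n_fits, 1L)

  # tail exponent stays flat (within 2 sd) across aggregation levels
  suppressWarnings({
    ser <- parameter_series(tab, "double", subset_sizes = c(5, 10, 20),
                            reps = 4, seed = 6, bins = 3)
  })
  a_bins <- ser[ser$parameter == "alpha", ]
  spread <- max(a_bins$mean) - min(a_bins$mean)
  expect_lt(spread, 2 * max(a_bins$sd) + 0.3)
})

test_that("generation at scale is deterministic per seed and respects edge cases", {
  dp <- default_trajectories("deep")
  r1 <- generate_at_scale(dp, 1e5, seed = 3, reference = 3695)
  r2 <- generate_at_scale(dp, 1e5, seed = 3, reference = 3695)
  expect_identical(r1$S, r2$S)
  expect_gte(r1$total_reads, 1e5)
  expect_equal(r1$ratio, r1$S / 3695)

  tiny <- generate_at_scale(dp, 1, seed = 1)
  expect_equal(tiny$S, 1L)
})

test_that("generated richness grows sublinearly with target depth", {
  dp <- default_trajectories("deep")
  up <- default_trajectories("upper")
  for (traj in list(dp, up)) {
    Ns <- c(1e5, 1e6, 1e7)
    S <- vapply(seq_along(Ns), function(i) {
      mean(vapply(1:3, function(r) {
        generate_at_scale(traj, Ns[i], seed = 40 + 10 * i + r)$S
      }, numeric(1)))
    }, numeric(1))
    slopes <- diff(log(S)) / diff(log(Ns))
    expect_true(all(slopes < 1))
    expect_true(all(slopes > 0))
  }
})

test_that("trajectories at the surveys' own depths sit near their plateaus", {
  # upper survey ~3.3e6 reads; deep survey ~1.8e6 reads
  up <- eval_trajectory(default_trajectories("upper"), 3.3e6)
  expect_equal(unname(up[["alpha"]]), 1.42, tolerance = 0.1)
  dp <- eval_trajectory(default_trajectories("deep"), 1.8e6)
  expect_equal(unname(dp[["alpha"]]), 0.88, tolerance = 0.1)
})

test_that("seed-to-seed variation of generated richness is bounded", {
  # heavy-tailed draws mean S fluctuates more than a sqrt-n CLT would
  # suggest (the tails have infinite variance); the bound reflects that
  res <- richness_ratio_at_scale(default_trajectories("upper"), 1e6,
                                 reference = 1, n_seeds = 8, base_seed = 5)
  expect_lt(res$sd_S / res$mean_S, 0.25)
})
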