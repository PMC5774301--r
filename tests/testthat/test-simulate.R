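test_that("parameter samplers respect their stated ranges", {
  set.seed(41)
  for (i in 1:200) {
    p <- sample_sigmoidal_params()
    expect_gt(p$a1, 0)
    expect_true(p$I_max >= 0.3 && p$I_max <= 20)
    expect_true(p$t_mid >= 3 && p$t_mid <= 27)
  }
  set.seed(42)
  for (i in 1:200) {
    p <- sample_double_sigmoidal_params()
    expect_true(p$t_mid2_prime > p$t_mid1_prime)
    expect_lte(p$t_mid2_prime, 27)
    expect_gte(p$t_mid2_prime - p$t_mid1_prime, 1)
    expect_lt(p$I_final, p$I_max)  # ratio capped at 0.85
    expect_true(p$a2_prime >= 0.001 && p$a2_prime <= 40)
    expect_gt(p$a1_prime, 0)
  }
})

test_that("sampler medians sit at the interval midpoints", {
  set.seed(43)
  draws <- replicate(10000, {
    p <- sample_sigmoidal_params()
    c(p$I_max, p$t_mid)
  })
  expect_equal(median(draws[1, ]), 10.15, tolerance = 0.02)
  expect_equal(median(draws[2, ]), 15, tolerance = 0.02)
  # the slope-angle transform: a 45-degree angle is slope 1
  expect_equal(tan(pi / 4), 1)
  expect_equal(median(tan(runif(10000, 0, pi / 2))), 1, tolerance = 0.05)
})

test_that("temporal sampling regimes cover the window as specified", {
  eq <- sample_times("equidistant")
  expect_length(eq, 55)
  expect_equal(eq[1], 3)
  expect_equal(eq[55], 30)
  expect_equal(unique(round(diff(eq), 10)), 0.5)

  set.seed(44)
  for (regime in c("uniform", "beta_early", "beta_center", "beta_late")) {
    tt <- sample_times(regime)
    expect_length(tt, 55)
    expect_true(all(tt >= 3 & tt <= 30))
    expect_false(is.unsorted(tt))
  }
  # center-weighted beta sampling has mean 3 + 27/2
  set.seed(45)
  m <- mean(replicate(200, mean(sample_times("beta_center"))))
  expect_equal(m, 16.5, tolerance = 0.01 * 16.5)
})

test_that("noise models honor their amplitude contracts", {
  clean <- sigmoidal_value(equidistant_times(), sigmoidal_params(5, 14, 1))
  set.seed(46)
  expect_identical(add_noise(clean, "additive", 0), clean)
  noisy <- add_noise(clean, "additive", 0.6)
  expect_lte(max(abs(noisy - clean)), 0.5 * 0.6 * max(clean))

  # centered multiplicative noise is the identity at amplitude 0
  expect_identical(add_noise(clean, "multiplicative", 0), clean)
  # literal multiplicative noise scales the signal by the amplitude
  lit <- add_noise(clean, "multiplicative", 0.5,
                   multiplicative_form = "literal")
  expect_true(all(lit >= clean * 0.25 & lit <= clean))
})

test_that("the simulation grid enumerates every cell deterministically", {
  g1 <- simulate_grid(model_kinds = "sigmoidal",
                      regimes = c("equidistant", "uniform"),
                      noise_types = "additive",
                      amplitudes = c(0, 0.75), n_replicates = 3, seed = 47)
  expect_equal(nrow(g1$manifest), 1 * 2 * 1 * 2 * 3)
  expect_true(all(vapply(g1$samples,
                         function(s) length(s$times) == 55, logical(1))))

  g2 <- simulate_grid(model_kinds = "sigmoidal",
                      regimes = c("equidistant", "uniform"),
                      noise_types = "additive",
                      amplitudes = c(0, 0.75), n_replicates = 3, seed = 47)
  expect_identical(g1$manifest, g2$manifest)
  expect_identical(g1$samples[[4]]$noisy, g2$samples[[4]]$noisy)
})

test_that("admissible parameter sets pass their own clean-curve checks", {
  g <- simulate_grid(model_kinds = c("sigmoidal", "double_sigmoidal"),
                     regimes = "equidistant", noise_types = "additive",
                     amplitudes = 0, n_replicates = 10, seed = 48)
  cfg <- decision_config()
  for (s in g$samples) {
    mx <- max(s$clean)
    expect_false(check_no_signal(mx, diff(range(s$clean)), cfg))
    expect_lt(s$clean[1] / mx, cfg$max_start_intensity)
    if (s$model_kind == "sigmoidal") {
      d <- derive_sigmoidal(s$params, max(s$times))
      expect_gt(d$end_ratio, cfg$min_end_ratio_sigmoidal)
      expect_gt(d$start_time, 0)
    } else {
      d <- derive_double_sigmoidal(s$params, max(s$times))
      expect_lt(d$end_ratio, cfg$max_end_ratio_double)
      expect_gt(d$start_time, 0)
      expect_gt(d$decay_start_time, 0)
    }
  }
})
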