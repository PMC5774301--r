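test_that("sigmoidal descriptors match the tangent-line construction", {
  # tangent through (t_mid, I_max/2) with slope a1 I_max / 4:
  # solving 0 = I_max/2 + s (t - t_mid) gives t_mid - 2/a1, and
  # I_max = I_max/2 + s (t - t_mid) gives t_mid + 2/a1.
  d <- derive_sigmoidal(sigmoidal_params(1, 5, 2), last_obs_time = 30)
  expect_equal(d$midpoint_slope, 0.5)
  expect_equal(d$start_time, 4)
  expect_equal(d$end_time, 6)
  expect_equal(d$growth_duration, 2)
  expect_equal(d$end_ratio, stats::plogis(2 * 25), tolerance = 1e-12)

  # the duration depends only on the slope parameter
  d2 <- derive_sigmoidal(sigmoidal_params(40, 11, 2), last_obs_time = 30)
  expect_equal(d2$growth_duration, d$growth_duration)

  # steep curves collapse onto the midpoint
  d3 <- derive_sigmoidal(sigmoidal_params(1, 5, 1e5), last_obs_time = 30)
  expect_lt(d3$growth_duration, 1e-4)
  expect_equal(d3$start_time, 5, tolerance = 1e-4)
})

test_that("double-sigmoidal midpoints satisfy their defining crossings", {
  p <- double_sigmoidal_params(I_max = 1, I_final = 0.25,
                               t_mid1_prime = 0.25, t_mid2_prime = 0.7,
                               a1_prime = 20, a2_prime = 15)
  d <- derive_double_sigmoidal(p, last_obs_time = 1)
  expect_true(d$available)
  expect_equal(double_sigmoidal_value(d$t_mid1, p), p$I_max / 2,
               tolerance = 1e-8)
  expect_equal(double_sigmoidal_value(d$t_mid2, p),
               (p$I_max + p$I_final) / 2, tolerance = 1e-8)
  expect_true(d$t_mid1 < d$t_star && d$t_star < d$t_mid2)
  expect_gt(d$slope1, 0)
  expect_lt(d$slope2, 0)
  expect_gt(d$growth_duration, 0)
  expect_gt(d$decay_duration, 0)

  # tangent construction over-covers the central rise
  expect_lt(double_sigmoidal_value(d$start_time, p), p$I_max / 2)
  expect_gt(double_sigmoidal_value(d$end_time, p), p$I_max / 2)
})

test_that("well-separated phases reduce to two independent logistics", {
  p <- double_sigmoidal_params(I_max = 1, I_final = 0,
                               t_mid1_prime = 0.2, t_mid2_prime = 0.8,
                               a1_prime = 5 / 0.04, a2_prime = 5 / 0.04)
  d <- derive_double_sigmoidal(p, last_obs_time = 1)
  expect_true(d$available)
  expect_equal(d$t_mid1, p$t_mid1_prime, tolerance = 0.01)
  expect_equal(d$t_mid2, p$t_mid2_prime, tolerance = 0.01)
})

test_that("degenerate decay (I_final = I_max) is flagged, not an error", {
  p <- double_sigmoidal_params(I_max = 1, I_final = 1,
                               t_mid1_prime = 0.3, t_mid2_prime = 0.7,
                               a1_prime = 10, a2_prime = 10)
  d <- derive_double_sigmoidal(p, last_obs_time = 1)
  expect_false(d$available)
  expect_match(d$reason, "I_final")
})

test_that("derived descriptors are equivariant under denormalization", {
  p <- double_sigmoidal_params(I_max = 0.8, I_final = 0.2,
                               t_mid1_prime = 0.3, t_mid2_prime = 0.65,
                               a1_prime = 25, a2_prime = 18)
  rec <- structure(list(time_scale = 30, intensity_scale = 6),
                   class = "normalization_record")
  d_norm <- derive_double_sigmoidal(p, last_obs_time = 1)
  d_raw_direct <- derive_double_sigmoidal(
    denormalize_double_sigmoidal_params(p, rec), last_obs_time = 30)
  d_raw_mapped <- denormalize_derived(d_norm, rec)
  for (nm in c("t_mid1", "t_mid2", "t_star", "start_time", "end_time",
               "decay_start_time", "decay_end_time")) {
    expect_equal(d_raw_mapped[[nm]], d_raw_direct[[nm]],
                 tolerance = 1e-6, label = nm)
  }
  expect_equal(d_raw_mapped$slope1, d_raw_direct$slope1, tolerance = 1e-4)
  expect_equal(d_raw_mapped$end_ratio, d_norm$end_ratio, tolerance = 1e-9)
})
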