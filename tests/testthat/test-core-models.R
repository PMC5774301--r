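test_that("sigmoidal evaluation has the logistic midpoint, limits, and slope", {
  p <- sigmoidal_params(I_max = 3.2, t_mid = 7.5, a1 = 1.3)
  expect_equal(sigmoidal_value(p$t_mid, p), p$I_max / 2)
  expect_equal(sigmoidal_value(1e6, p), p$I_max)
  expect_equal(sigmoidal_value(-1e6, p), 0)

  # slope at the midpoint equals a1 * I_max / 4 (central difference)
  h <- 1e-6
  num_slope <- (sigmoidal_value(p$t_mid + h, p) -
                  sigmoidal_value(p$t_mid - h, p)) / (2 * h)
  expect_equal(num_slope, p$a1 * p$I_max / 4, tolerance = 1e-6)

  # point symmetry about the midpoint: f(t) + f(2 t_mid - t) = I_max
  t <- seq(-20, 30, by = 0.37)
  expect_equal(sigmoidal_value(t, p) + sigmoidal_value(2 * p$t_mid - t, p),
               rep(p$I_max, length(t)))

  expect_error(sigmoidal_value(Inf, p), "finite")
  expect_error(sigmoidal_params(-1, 0, 1), "positive")
  expect_error(sigmoidal_params(1, 0, 0), "positive")
})

test_that("base double-sigmoidal is a bounded product with one maximum", {
  t <- seq(-10, 40, by = 0.01)
  v <- dsig_base_value(t, 1.5, 1.5, 10, 14)
  expect_true(all(v > 0 & v < 1))
  # equal slopes put the maximum halfway between the primed midpoints
  expect_equal(t[which.max(v)], 12, tolerance = 0.01)
  expect_equal(grid_sign_changes(v), 1)
  expect_error(dsig_base_value(0, 1, 1, 5, 4), "larger")
})

test_that("find_tstar matches the dense-grid argmax and the root property", {
  # symmetric case: slopes equal, so t* is the midpoint average
  p_sym <- double_sigmoidal_params(1, 0.2, 10, 14, 1, 1)
  expect_equal(find_tstar(p_sym), 12, tolerance = 1e-8)

  # steep-decay corner case: checked against brute-force grid argmax
  p <- double_sigmoidal_params(2, 0.5, 10, 11, 1, 10)
  ts <- find_tstar(p)
  g <- seq(5, 20, by = 1e-4)
  ts_grid <- g[which.max(dsig_base_value(g, p$a1_prime, p$a2_prime,
                                         p$t_mid1_prime, p$t_mid2_prime))]
  expect_equal(ts, ts_grid, tolerance = 1e-4)

  # defining property: h(u*) = 0 for the stationarity function
  u <- ts - p$t_mid1_prime
  L <- p$t_mid2_prime - p$t_mid1_prime
  h_val <- p$a1_prime * (exp(p$a2_prime * (L - u)) + 1) -
    p$a2_prime * (exp(p$a1_prime * u) + 1)
  expect_equal(h_val, 0, tolerance = 1e-6)
})

test_that("find_tstar agrees with the grid argmax across random draws", {
  set.seed(301)
  for (i in 1:25) {
    p <- sample_double_sigmoidal_params()
    expect_true(tstar_matches_grid(p))
  }
})

test_that("double-sigmoidal curve peaks at I_max, honors limits, and has a continuous derivative", {
  p <- double_sigmoidal_params(4, 1.2, 8, 17, 1.4, 0.8)
  ts <- find_tstar(p)
  expect_equal(double_sigmoidal_value(ts, p), p$I_max)
  expect_equal(double_sigmoidal_value(1e6, p), p$I_final)
  expect_equal(double_sigmoidal_value(-1e6, p), 0)

  # first derivative is continuous at the cut: both one-sided slopes
  # vanish at the maximum
  h <- 1e-5
  left <- (double_sigmoidal_value(ts, p) -
             double_sigmoidal_value(ts - h, p)) / h
  right <- (double_sigmoidal_value(ts + h, p) -
              double_sigmoidal_value(ts, p)) / h
  expect_equal(left, 0, tolerance = 1e-3)
  expect_equal(right, 0, tolerance = 1e-3)

  # monotone rise before t*, monotone decay after
  g_pre <- seq(ts - 15, ts, length.out = 2000)
  g_post <- seq(ts, ts + 25, length.out = 2000)
  expect_true(all(diff(double_sigmoidal_value(g_pre, p)) >= 0))
  expect_true(all(diff(double_sigmoidal_value(g_post, p)) <= 0))
})

test_that("general sigmoidal reduces to the three-parameter model and has the stated slope", {
  p4 <- general_sigmoidal_params(I_init = 0, I_max = 2.5, t_mid = 6,
                                 a1 = 0.9)
  p3 <- sigmoidal_params(I_max = 2.5, t_mid = 6, a1 = 0.9)
  t <- seq(-5, 25, by = 0.31)
  expect_equal(general_sigmoidal_value(t, p4), sigmoidal_value(t, p3))

  p4b <- general_sigmoidal_params(I_init = 0.7, I_max = 2.5, t_mid = 6,
                                  a1 = 0.9)
  expect_equal(general_sigmoidal_value(6, p4b), (2.5 + 0.7) / 2)
  h <- 1e-6
  slope <- (general_sigmoidal_value(6 + h, p4b) -
              general_sigmoidal_value(6 - h, p4b)) / (2 * h)
  expect_equal(slope, 0.9 / 4 * (2.5 - 0.7), tolerance = 1e-6)
})

test_that("the naive product reproduces the documented corner case", {
  g <- seq(0, 30, by = 0.001)
  # narrowly separated midpoints, one steep slope, nonzero asymptotes:
  # a local minimum appears, so the curve is not double-sigmoidal
  bad <- naive_product_value(g, I_init = 0, I_final = 0.5, I_max = 2,
                             a1 = 1, a2 = 10, t_mid1 = 10, t_mid2 = 11)
  expect_gt(grid_sign_changes(bad), 1)

  # with both asymptotes at zero the product has exactly one maximum
  good <- naive_product_value(g, I_init = 0, I_final = 0, I_max = 2,
                              a1 = 1, a2 = 10, t_mid1 = 10, t_mid2 = 11)
  expect_equal(grid_sign_changes(good), 1)

  # flat decay with I_final = 1 degenerates toward the plain sigmoidal
  flat <- naive_product_value(g, I_init = 0, I_final = 1, I_max = 2,
                              a1 = 1, a2 = 1e-9, t_mid1 = 10, t_mid2 = 11)
  sig <- general_sigmoidal_value(g, general_sigmoidal_params(0, 2, 10, 1))
  expect_equal(flat, sig, tolerance = 1e-6)
})

test_that("random base double-sigmoidals always have exactly one extremum", {
  set.seed(302)
  for (i in 1:200) {
    p <- sample_double_sigmoidal_params()
    lo <- p$t_mid1_prime - 20 / p$a1_prime
    hi <- p$t_mid2_prime + 20 / p$a2_prime
    g <- seq(lo, hi, length.out = 4001)
    v <- dsig_base_value(g, p$a1_prime, p$a2_prime,
                         p$t_mid1_prime, p$t_mid2_prime)
    expect_equal(grid_sign_changes(v), 1)
  }
})
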