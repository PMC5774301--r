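test_that("the no-signal test trips on either a low maximum or a low range", {
  cfg <- decision_config(min_intensity_max = 0.1, min_intensity_range = 0.1)
  expect_true(check_no_signal(0, 0, cfg))
  expect_false(check_no_signal(10, 9, cfg))
  # either failing test suffices
  expect_true(check_no_signal(10, 0.05, cfg))
  expect_true(check_no_signal(0.05, 10, cfg))
  # boundary: thresholds must be exceeded strictly
  expect_true(check_no_signal(0.1, 0.1, cfg))
})

test_that("the decision truth table is honored", {
  cfg <- decision_config()
  expect_equal(decide_category(FALSE, FALSE, -100, -200, cfg)$category,
               "ambiguous")
  expect_equal(decide_category(TRUE, FALSE, -100, -200, cfg)$category,
               "sigmoidal")
  expect_equal(decide_category(FALSE, TRUE, -100, -200, cfg)$category,
               "double_sigmoidal")
  expect_equal(decide_category(TRUE, TRUE, -500, -400, cfg)$category,
               "sigmoidal")
  expect_equal(decide_category(TRUE, TRUE, -400, -500, cfg)$category,
               "double_sigmoidal")
  # exact tie goes to the simpler model
  expect_equal(decide_category(TRUE, TRUE, -400, -400, cfg)$category,
               "sigmoidal")
})

test_that("AIC bonuses shift the comparison but cannot rescue a failed fit", {
  favor_dbl <- decision_config(aic_bonus_double = -200)
  expect_equal(decide_category(TRUE, TRUE, -500, -400,
                               favor_dbl)$category, "double_sigmoidal")
  # a failed double fit stays out no matter the bonus
  huge <- decision_config(aic_bonus_double = -1e9)
  expect_equal(decide_category(TRUE, FALSE, -100, -1e6, huge)$category,
               "sigmoidal")
  expect_equal(decide_category(FALSE, FALSE, -100, -1e6, huge)$category,
               "ambiguous")
})

test_that("per-model checks fail with named reasons", {
  cfg <- decision_config()
  failed_fit <- structure(list(model_kind = "sigmoidal", converged = FALSE),
                          class = "fit_result")
  out <- check_model(failed_fit, NULL, cfg, first_obs_time = 0.1)
  expect_false(out$pass)
  expect_equal(out$reasons, "no_fit")

  # a genuine clean fit passes all checks
  tc <- clean_sigmoidal_tc()
  norm <- normalize_time_course(tc)
  fit <- fit_model(norm$tc, "sigmoidal", fit_config(seed = 2),
                   record = norm$record)
  derived <- derive_sigmoidal(fit$params_normalized,
                              max(norm$tc$time))
  ok <- check_model(fit, derived, cfg, norm$tc$time[1])
  expect_true(ok$pass)
  expect_length(ok$reasons, 0)
  expect_lt(fit$aic, -10)

  # an end ratio at 0.80 fails the strict sigmoidal gate
  fake_derived <- derived
  fake_derived$end_ratio <- 0.80
  bad <- check_model(fit, fake_derived, cfg, norm$tc$time[1])
  expect_false(bad$pass)
  expect_true("end_ratio" %in% bad$reasons)
})

test_that("clean curves are classified end to end", {
  sig <- fit_and_categorize(clean_sigmoidal_tc(),
                            fit_cfg = fit_config(seed = 21))
  expect_equal(sig$category, "sigmoidal")

  dbl <- fit_and_categorize(clean_double_tc()$tc,
                            fit_cfg = fit_config(seed = 22))
  expect_equal(dbl$category, "double_sigmoidal")

  # flat noise around zero is no signal before any fitting happens
  set.seed(23)
  flat <- time_course(equidistant_times(), runif(55, 0, 0.05))
  ns <- fit_and_categorize(flat)
  expect_equal(ns$category, "no_signal")
  expect_null(ns$sigmoidal)
})

test_that("the recorded booleans replay to the reported category", {
  rep <- fit_and_categorize(clean_double_tc()$tc,
                            fit_cfg = fit_config(seed = 31))
  replay <- decide_category(rep$sigmoidal$check$pass,
                            rep$double_sigmoidal$check$pass,
                            rep$sigmoidal$fit$aic,
                            rep$double_sigmoidal$fit$aic,
                            decision_config())
  expect_equal(replay$category, rep$category)
  expect_equal(replay$rule, rep$decisive_rule)
})

test_that("no-signal labels are stable under intensity down-scaling", {
  set.seed(24)
  y <- runif(55, 0, 0.08)
  t <- equidistant_times()
  expect_equal(fit_and_categorize(time_course(t, y))$category, "no_signal")
  for (f in c(0.5, 0.1, 0.01)) {
    expect_equal(fit_and_categorize(time_course(t, y * f))$category,
                 "no_signal")
  }
})
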