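#' Decision-tree configuration
#'
#' Every cutoff of the classification decision tree, user-adjustable. All
#' intensity thresholds except the no-signal pair operate on the normalized
#' `[0, 1]` scale; the no-signal thresholds apply to the raw data before
#' normalization. Comparisons are strict, exactly as worded: AIC must be
#' *smaller than* `aic_threshold`, the end ratio must be *over*
#' `min_end_ratio_sigmoidal` for a sigmoidal call and *below*
#' `max_end_ratio_double` for a double-sigmoidal call.
#'
#' @param min_intensity_max No-signal cutoff on the raw maximum intensity
#'   (default 0.1; data with maximum at or below it carry no signal).
#' @param min_intensity_range No-signal cutoff on the raw intensity range
#'   (default 0.1).
#' @param aic_threshold Absolute quality gate on the fit AIC (default -10).
#' @param max_start_intensity Maximum allowed model prediction at the first
#'   observation, normalized scale (default 0.05).
#' @param min_end_ratio_sigmoidal Minimum end ratio for accepting a
#'   sigmoidal fit (default 0.85).
#' @param max_end_ratio_double Maximum end ratio for accepting a
#'   double-sigmoidal fit (default 0.75).
#' @param aic_bonus_sigmoidal,aic_bonus_double Constants added to the
#'   respective AIC before the head-to-head comparison (default 0; a
#'   negative bonus favors that model).
#' @return A list of class `"decision_config"`.
#' @export
decision_config <- function(min_intensity_max = 0.1,
                            min_intensity_range = 0.1,
                            aic_threshold = -10,
                            max_start_intensity = 0.05,
                            min_end_ratio_sigmoidal = 0.85,
                            max_end_ratio_double = 0.75,
                            aic_bonus_sigmoidal = 0,
                            aic_bonus_double = 0) {
  vals <- list(min_intensity_max = min_intensity_max,
               min_intensity_range = min_intensity_range,
               aic_threshold = aic_threshold,
               max_start_intensity = max_start_intensity,
               min_end_ratio_sigmoidal = min_end_ratio_sigmoidal,
               max_end_ratio_double = max_end_ratio_double,
               aic_bonus_sigmoidal = aic_bonus_sigmoidal,
               aic_bonus_double = aic_bonus_double)
  for (nm in names(vals)) stopifnot_finite(vals[[nm]], nm)
  if (min_end_ratio_sigmoidal <= 0 || min_end_ratio_sigmoidal >= 1 ||
      max_end_ratio_double <= 0 || max_end_ratio_double >= 1) {
    stop("end-ratio thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(vals, class = "decision_config")
}

#' No-signal test
#'
#' A time course carries no signal when its raw maximum intensity does not
#' exceed `min_intensity_max` or its raw intensity range does not exceed
#' `min_intensity_range`; either failing test suffices.
#'
#' @param max_intensity Raw-scale maximum intensity.
#' @param intensity_range Raw-scale range (max minus min).
#' @param cfg A [decision_config()].
#' @return `TRUE` when the data should be labeled `"no_signal"`.
#' @export
check_no_signal <- function(max_intensity, intensity_range, cfg) {
  max_intensity <= cfg$min_intensity_max ||
    intensity_range <= cfg$min_intensity_range
}

#' Acceptance checks for one fitted model
#'
#' A fit is acceptable only if all of the following hold: the fit
#' converged and its descriptors could be derived; the AIC is below the
#' absolute threshold; the growth start time (and, for the
#' double-sigmoidal, the decay start time) is positive; the model's
#' predicted intensity at the first observation is below the
#' start-intensity cutoff; and the end ratio clears its model-specific
#' gate (high for sigmoidal, low for double-sigmoidal).
#'
#' @param fit A [fit_model()] result on normalized data.
#' @param derived The matching [derive_sigmoidal()] /
#'   [derive_double_sigmoidal()] result (normalized scale).
#' @param cfg A [decision_config()].
#' @param first_obs_time First observation time on the normalized scale
#'   (where the start intensity is evaluated).
#' @return A list with `pass` (logical), `checks` (named logicals),
#'   `reasons` (names of failed checks), and `start_intensity`.
#' @export
check_model <- function(fit, derived, cfg, first_obs_time) {
  kind <- fit$model_kind
  checks <- c(converged = isTRUE(fit$converged))
  if (!checks[["converged"]]) {
    return(list(pass = FALSE, checks = checks, reasons = "no_fit",
                start_intensity = NA_real_))
  }
  checks[["derived_available"]] <- isTRUE(derived$available)
  if (!checks[["derived_available"]]) {
    return(list(pass = FALSE, checks = checks,
                reasons = "derived_unavailable",
                start_intensity = NA_real_))
  }
  p <- fit$params_normalized
  start_intensity <- if (kind == "sigmoidal") {
    sigmoidal_value(first_obs_time, p)
  } else {
    double_sigmoidal_value(first_obs_time, p, t_star = derived$t_star)
  }
  checks[["aic"]] <- fit$aic < cfg$aic_threshold
  checks[["start_time"]] <- derived$start_time > 0
  if (kind == "double_sigmoidal") {
    checks[["decay_start_time"]] <- derived$decay_start_time > 0
  }
  checks[["start_intensity"]] <- start_intensity < cfg$max_start_intensity
  checks[["end_ratio"]] <- if (kind == "sigmoidal") {
    derived$end_ratio > cfg$min_end_ratio_sigmoidal
  } else {
    derived$end_ratio < cfg$max_end_ratio_double
  }
  list(pass = all(checks), checks = checks,
       reasons = names(checks)[!checks],
       start_intensity = start_intensity)
}

#' Head-to-head decision between the two models
#'
#' Both models failing their checks yields `"ambiguous"`; exactly one
#' passing yields that label. When both pass, the model with the strictly
#' smaller bonus-adjusted AIC wins; an exact tie goes to the simpler
#' (sigmoidal) model.
#'
#' @param sigmoidal_pass,double_pass Logical check outcomes.
#' @param aic_sigmoidal,aic_double The two AIC scores.
#' @param cfg A [decision_config()] (supplies the AIC bonuses).
#' @return A list with `category` and `rule`, a short tag naming the
#'   decisive branch.
#' @export
decide_category <- function(sigmoidal_pass, double_pass,
                            aic_sigmoidal = NA_real_,
                            aic_double = NA_real_,
                            cfg = decision_config()) {
  if (!sigmoidal_pass && !double_pass) {
    return(list(category = "ambiguous", rule = "both_failed"))
  }
  if (sigmoidal_pass && !double_pass) {
    return(list(category = "sigmoidal", rule = "only_sigmoidal_passed"))
  }
  if (!sigmoidal_pass && double_pass) {
    return(list(category = "double_sigmoidal",
                rule = "only_double_passed"))
  }
  adj_sig <- aic_sigmoidal + cfg$aic_bonus_sigmoidal
  adj_dbl <- aic_double + cfg$aic_bonus_double
  if (adj_dbl < adj_sig) {
    list(category = "double_sigmoidal", rule = "aic_comparison")
  } else {
    list(category = "sigmoidal", rule = "aic_comparison")
  }
}

#' Fit both models and classify a time course
#'
#' The complete pipeline: test for signal; normalize to the unit square;
#' fit the sigmoidal and double-sigmoidal models by multi-start
#' Levenberg-Marquardt; derive curve descriptors; run the per-model
#' acceptance checks; and decide among `"no_signal"`, `"sigmoidal"`,
#' `"double_sigmoidal"`, and `"ambiguous"`. When `fit_cfg$seed` is set,
#' the two models use seeds fanned out deterministically from it, so the
#' whole report is reproducible.
#'
#' @param tc A [time_course()] (or a data.frame with `time` and
#'   `intensity` columns).
#' @param fit_cfg A [fit_config()].
#' @param decision_cfg A [decision_config()].
#' @return A list of class `"classification_report"` with the category,
#'   the decisive rule, the no-signal diagnostics, the normalization
#'   record, and per-model blocks each holding the fit (normalized and
#'   raw parameters), derived descriptors on both scales, and the check
#'   outcomes. The decision is a pure function of the recorded booleans
#'   and AIC scores.
#' @examples
#' t <- seq(3, 30, by = 0.5)
#' y <- sigmoidal_value(t, sigmoidal_params(5, 14, 1))
#' fit_and_categorize(time_course(t, y),
#'                    fit_cfg = fit_config(seed = 1))$category
#' @export
fit_and_categorize <- function(tc, fit_cfg = fit_config(),
                               decision_cfg = decision_config()) {
  if (!inherits(tc, "time_course")) {
    if (is.data.frame(tc) && all(c("time", "intensity") %in% names(tc))) {
      tc <- time_course(tc$time, tc$intensity)
    } else {
      stop("`tc` must be a time_course or a data.frame with columns ",
           "`time` and `intensity`", call. = FALSE)
    }
  }
  raw_max <- max(tc$intensity)
  raw_range <- diff(range(tc$intensity))
  report <- list(category = NA_character_, decisive_rule = NA_character_,
                 raw_max = raw_max, raw_range = raw_range,
                 no_signal = FALSE, normalization = NULL,
                 sigmoidal = NULL, double_sigmoidal = NULL)
  class(report) <- "classification_report"

  if (check_no_signal(raw_max, raw_range, decision_cfg)) {
    report$category <- "no_signal"
    report$no_signal <- TRUE
    report$decisive_rule <- "no_signal_threshold"
    return(report)
  }

  norm <- normalize_time_course(tc)
  tc_norm <- norm$tc
  record <- norm$record
  report$normalization <- record
  t_first <- tc_norm$time[1]
  t_last <- tc_norm$time[nrow(tc_norm)]

  model_block <- function(kind, stream) {
    cfg <- fit_cfg
    if (!is.null(cfg$seed)) cfg$seed <- child_seed(cfg$seed, stream)
    fit <- fit_model(tc_norm, kind, cfg, record = record)
    derived <- NULL
    derived_raw <- NULL
    if (fit$converged) {
      derived <- if (kind == "sigmoidal") {
        derive_sigmoidal(fit$params_normalized, t_last)
      } else {
        derive_double_sigmoidal(fit$params_normalized, t_last)
      }
      derived_raw <- denormalize_derived(derived, record)
    }
    check <- check_model(fit, derived, decision_cfg, t_first)
    list(fit = fit, derived_normalized = derived,
         derived_raw = derived_raw, check = check)
  }

  report$sigmoidal <- model_block("sigmoidal", 1L)
  report$double_sigmoidal <- model_block("double_sigmoidal", 2L)

  decision <- decide_category(report$sigmoidal$check$pass,
                              report$double_sigmoidal$check$pass,
                              report$sigmoidal$fit$aic,
                              report$double_sigmoidal$fit$aic,
                              decision_cfg)
  report$category <- decision$category
  report$decisive_rule <- decision$rule
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Time-course classification\n")
  cat("  category:     ", x$category, "\n", sep = "")
  cat("  decisive rule:", x$decisive_rule, "\n")
  cat(sprintf("  raw max %.4g, raw range %.4g\n", x$raw_max, x$raw_range))
  for (kind in c("sigmoidal", "double_sigmoidal")) {
    blk <- x[[kind]]
    if (is.null(blk)) next
    cat("  ", kind, ": ", sep = "")
    if (!blk$fit$converged) {
      cat("no converged fit\n")
    } else {
      cat(sprintf("AIC %.2f, rss %.4g, passed checks: %s\n",
                  blk$fit$aic, blk$fit$rss,
                  if (blk$check$pass) "yes"
                  else paste("no (", paste(blk$check$reasons,
                                           collapse = ", "), ")",
                             sep = "")))
    }
  }
  invisible(x)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: converged=%s", x$model_kind, x$converged))
  if (x$converged) {
    cat(sprintf(", rss=%.4g, AIC=%.2f (%d obs, %d params, %d starts)",
                x$rss, x$aic, x$n_obs, x$n_params, x$n_starts_used))
  }
  cat("\n")
  invisible(x)
}
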