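#' Multi-start fitting configuration
#'
#' Controls the multi-start Levenberg-Marquardt protocol. Starting vectors
#' are drawn uniformly from per-parameter intervals on the normalized
#' scale; slope parameters are drawn log-uniformly because realistic slope
#' distributions are heavy-tailed. The harder six-parameter
#' double-sigmoidal surface gets twice as many restarts by default.
#'
#' @param n_starts_sigmoidal Restarts for the sigmoidal model (default 20).
#' @param n_starts_double Restarts for the double-sigmoidal model
#'   (default 40).
#' @param seed Integer seed making the start draws reproducible; `NULL`
#'   uses the ambient RNG stream.
#' @param max_iterations Maximum Levenberg-Marquardt iterations per start.
#' @param start_ranges Named list of start intervals on the normalized
#'   scale: `I_max`, `t_mid` (also used for the first primed midpoint),
#'   `slope` (log-uniform), `L` (primed midpoint distance), `final_ratio`
#'   (`I_final / I_max`).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(n_starts_sigmoidal = 20,
                       n_starts_double = 40,
                       seed = NULL,
                       max_iterations = 100,
                       start_ranges = list(
                         I_max = c(0.3, 1.5),
                         t_mid = c(0.01, 1.2),
                         slope = c(0.5, 180),
                         L = c(0.01, 1),
                         final_ratio = c(0, 1)
                       )) {
  stopifnot(n_starts_sigmoidal >= 1, n_starts_double >= 1,
            max_iterations >= 1)
  for (r in start_ranges) {
    if (length(r) != 2 || r[2] <= r[1]) {
      stop("start ranges must be non-degenerate intervals", call. = FALSE)
    }
  }
  structure(list(n_starts_sigmoidal = n_starts_sigmoidal,
                 n_starts_double = n_starts_double,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_iterations = max_iterations,
                 start_ranges = start_ranges),
            class = "fit_config")
}

#' Residuals of a model against a (normalized) time course
#'
#' @param tc A [time_course()], typically on the normalized scale.
#' @param model_kind `"sigmoidal"` or `"double_sigmoidal"`.
#' @param params The matching parameter object.
#' @return Vector of residuals, observed minus predicted.
#' @export
model_residuals <- function(tc, model_kind, params) {
  pred <- switch(model_kind,
                 sigmoidal = sigmoidal_value(tc$time, params),
                 double_sigmoidal = double_sigmoidal_value(tc$time, params),
                 stop("unknown model kind: ", model_kind, call. = FALSE))
  tc$intensity - pred
}

#' Akaike information criterion for a least-squares fit
#'
#' Full Gaussian-likelihood AIC,
#' `n log(2 pi) + n log(rss / n) + n + 2 (k + 1)`, where the `+1` counts
#' the residual variance as an estimated parameter. Keeping the constant
#' terms makes the absolute acceptance threshold (default -10 in
#' [decision_config()]) meaningful on normalized data. An exactly zero
#' residual sum of squares is clamped to `n` times the machine epsilon so
#' comparisons stay finite; the clamp is flagged.
#'
#' @param rss Residual sum of squares, >= 0.
#' @param n_obs Number of observations (> `n_params`).
#' @param n_params Number of model parameters (3 or 6 here).
#' @return A list with `aic` and logical `rss_clamped`.
#' @export
compute_aic <- function(rss, n_obs, n_params) {
  stopifnot(n_obs > n_params, rss >= 0)
  clamped <- FALSE
  floor_rss <- .Machine$double.eps * n_obs
  if (rss < floor_rss) {
    rss <- floor_rss
    clamped <- TRUE
  }
  aic <- n_obs * log(2 * pi) + n_obs * log(rss / n_obs) + n_obs +
    2 * (n_params + 1)
  list(aic = aic, rss_clamped = clamped)
}

# --- internal parameter transforms -----------------------------------------
# LM runs unconstrained; positivity of I_max, slopes and the midpoint
# distance L is enforced by optimizing logarithms, and I_final is tied to
# I_max through a logit-transformed ratio so I_final in [0, I_max] always
# holds. t_mid2' = t_mid1' + L guarantees t_mid2' > t_mid1'.

sig_theta_to_params <- function(theta) {
  sigmoidal_params(I_max = exp(theta[1]), t_mid = theta[2],
                   a1 = exp(theta[3]))
}

sig_start_to_theta <- function(start) {
  c(log(start$I_max), start$t_mid, log(start$a1))
}

dbl_theta_to_params <- function(theta) {
  I_max <- exp(theta[1])
  double_sigmoidal_params(
    I_max = I_max,
    I_final = I_max * stats::plogis(theta[6]),
    t_mid1_prime = theta[2],
    t_mid2_prime = theta[2] + exp(theta[3]),
    a1_prime = exp(theta[4]),
    a2_prime = exp(theta[5])
  )
}

dbl_start_to_theta <- function(start) {
  ratio <- min(max(start$final_ratio, 1e-4), 1 - 1e-4)
  c(log(start$I_max), start$t_mid1_prime, log(start$L),
    log(start$a1_prime), log(start$a2_prime), stats::qlogis(ratio))
}

# Starts are drawn one vector at a time so that, for a fixed seed, the
# first k starts are identical whatever the total start count (the best
# AIC is then nonincreasing in n_starts).
draw_starts <- function(model_kind, n_starts, ranges) {
  runifr <- function(r) stats::runif(1, r[1], r[2])
  logunif <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  one <- function(i) {
    if (model_kind == "sigmoidal") {
      data.frame(I_max = runifr(ranges$I_max),
                 t_mid = runifr(ranges$t_mid),
                 a1 = logunif(ranges$slope))
    } else {
      data.frame(I_max = runifr(ranges$I_max),
                 t_mid1_prime = runifr(ranges$t_mid),
                 L = runifr(ranges$L),
                 a1_prime = logunif(ranges$slope),
                 a2_prime = logunif(ranges$slope),
                 final_ratio = runifr(ranges$final_ratio))
    }
  }
  do.call(rbind, lapply(seq_len(n_starts), one))
}

# Residuals computed directly from the transformed parameter vector;
# these are the optimizer's objective and avoid per-evaluation object
# construction. Parameter vectors the optimizer wanders into where the
# model is undefined or numerically meaningless yield large flat
# residuals instead of errors.
sig_resid_theta <- function(theta, t, y) {
  if (any(!is.finite(theta)) || any(abs(theta) > 50)) {
    return(rep(1e6, length(y)))
  }
  r <- y - exp(theta[1]) * stats::plogis(exp(theta[3]) * (t - theta[2]))
  if (any(!is.finite(r))) rep(1e6, length(y)) else r
}

dbl_resid_theta <- function(theta, t, y) {
  # theta[3] is log(L); distances below ~1e-8 of the normalized window are
  # numerically degenerate (t_mid2' would collapse onto t_mid1' after
  # denormalization) and are rejected.
  if (any(!is.finite(theta)) || any(abs(theta) > 50) || theta[3] < -18) {
    return(rep(1e6, length(y)))
  }
  I_max <- exp(theta[1])
  t_mid1 <- theta[2]
  L <- exp(theta[3])
  a1 <- exp(theta[4])
  a2 <- exp(theta[5])
  I_final <- I_max * stats::plogis(theta[6])
  u_star <- tryCatch(tstar_root(a1, a2, L), error = function(e) NA_real_)
  if (!is.finite(u_star)) return(rep(1e6, length(y)))
  u <- t - t_mid1
  base <- stats::plogis(a1 * u) * stats::plogis(-a2 * (u - L))
  f_max <- stats::plogis(a1 * u_star) * stats::plogis(-a2 * (u_star - L))
  pred <- ((I_max - I_final) / f_max) * base + I_final
  growth <- u <= u_star
  pred[growth] <- (I_max / f_max) * base[growth]
  r <- y - pred
  if (any(!is.finite(r))) rep(1e6, length(y)) else r
}

#' Fit one model by multi-start Levenberg-Marquardt least squares
#'
#' Runs [minpack.lm::nls.lm()] from `n_starts` random starting vectors on
#' the normalized data, records residual sum of squares and AIC per start,
#' and returns the start with the smallest AIC (equivalently the smallest
#' RSS, since the parameter count is fixed per model). The fit is
#' deterministic given the data and `cfg$seed`.
#'
#' @param tc_norm A normalized [time_course()] (see
#'   [normalize_time_course()]).
#' @param model_kind `"sigmoidal"` or `"double_sigmoidal"`.
#' @param cfg A [fit_config()].
#' @param record Optional normalization record; when supplied, raw-scale
#'   parameters are attached to the result.
#' @return A list of class `"fit_result"` with fields `model_kind`,
#'   `params_normalized`, `params_raw` (or `NULL`), `rss`, `aic`,
#'   `rss_clamped`, `n_obs`, `n_params`, `converged`, `n_starts_used`, and
#'   `per_start_log` (one row per start: starting values, rss, aic,
#'   convergence flag). `converged` is `FALSE` when every start failed;
#'   no exception is thrown in that case.
#' @export
fit_model <- function(tc_norm, model_kind = c("sigmoidal",
                                              "double_sigmoidal"),
                      cfg = fit_config(), record = NULL) {
  model_kind <- match.arg(model_kind)
  n <- nrow(tc_norm)
  n_params <- if (model_kind == "sigmoidal") 3L else 6L
  if (n <= n_params) {
    stop("need more observations than model parameters", call. = FALSE)
  }
  n_starts <- if (model_kind == "sigmoidal") cfg$n_starts_sigmoidal
              else cfg$n_starts_double
  to_params <- if (model_kind == "sigmoidal") sig_theta_to_params
               else dbl_theta_to_params
  to_theta <- if (model_kind == "sigmoidal") sig_start_to_theta
              else dbl_start_to_theta

  starts <- with_local_seed(cfg$seed,
                            draw_starts(model_kind, n_starts,
                                        cfg$start_ranges))

  log_rows <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    theta0 <- to_theta(as.list(starts[i, ]))
    # nls.lm warns on iteration-capped runs; those starts are already
    # treated as unconverged via the info code.
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = theta0,
        fn = if (model_kind == "sigmoidal") sig_resid_theta
             else dbl_resid_theta,
        t = tc_norm$time, y = tc_norm$intensity,
        control = minpack.lm::nls.lm.control(maxiter = cfg$max_iterations)
      )),
      error = function(e) NULL
    )
    ok <- FALSE
    rss_i <- NA_real_
    aic_i <- NA_real_
    params_i <- NULL
    if (!is.null(fit)) {
      params_i <- tryCatch(to_params(fit$par), error = function(e) NULL)
      if (!is.null(params_i)) {
        resid_i <- model_residuals(tc_norm, model_kind, params_i)
        rss_i <- sum(resid_i^2)
        aic_i <- compute_aic(rss_i, n, n_params)$aic
        ok <- is.finite(rss_i) && fit$info %in% 1:3 &&
          !(model_kind == "double_sigmoidal" && fit$par[3] < -18)
      }
    }
    log_rows[[i]] <- cbind(starts[i, , drop = FALSE],
                           data.frame(rss = rss_i, aic = aic_i,
                                      converged = ok))
    if (ok && (is.null(best) || aic_i < best$aic)) {
      best <- list(params = params_i, rss = rss_i, aic = aic_i)
    }
  }
  per_start_log <- do.call(rbind, log_rows)
  rownames(per_start_log) <- NULL

  if (is.null(best)) {
    return(structure(list(model_kind = model_kind,
                          params_normalized = NULL, params_raw = NULL,
                          rss = NA_real_, aic = NA_real_,
                          rss_clamped = FALSE,
                          n_obs = n, n_params = n_params,
                          converged = FALSE, n_starts_used = n_starts,
                          per_start_log = per_start_log),
                     class = "fit_result"))
  }
  aic_info <- compute_aic(best$rss, n, n_params)
  params_raw <- if (!is.null(record)) {
    if (model_kind == "sigmoidal") {
      denormalize_sigmoidal_params(best$params, record)
    } else {
      denormalize_double_sigmoidal_params(best$params, record)
    }
  }
  structure(list(model_kind = model_kind,
                 params_normalized = best$params,
                 params_raw = params_raw,
                 rss = best$rss, aic = aic_info$aic,
                 rss_clamped = aic_info$rss_clamped,
                 n_obs = n, n_params = n_params,
                 converged = TRUE, n_starts_used = n_starts,
                 per_start_log = per_start_log),
            class = "fit_result")
}
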