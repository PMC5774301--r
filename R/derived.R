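#' Descriptors of a fitted sigmoidal curve
#'
#' Computes the biologically interpretable quantities of the sigmoidal
#' model. The midpoint slope is `a1 * I_max / 4`. The tangent line through
#' the midpoint `(t_mid, I_max / 2)` with that slope defines the growth
#' window: its intercept with the time axis gives the start of growth,
#' `t_mid - 2 / a1`; its intercept with the plateau `I_max` gives the end,
#' `t_mid + 2 / a1`; the growth duration is their difference, `4 / a1`.
#' These tangent-based estimates are conservative: the curve is still
#' slightly below `I_max / 2` at the start point and above it at the end
#' point.
#'
#' @param p A [sigmoidal_params()] object.
#' @param last_obs_time Time of the last observation; used for the end
#'   ratio, the model prediction there divided by the model's maximum
#'   prediction `I_max`.
#' @return A list of class `"derived_params"` with fields `t_mid`,
#'   `midpoint_slope`, `start_time`, `end_time`, `growth_duration`,
#'   `end_ratio`, and `available = TRUE`.
#' @examples
#' derive_sigmoidal(sigmoidal_params(1, 5, 2), last_obs_time = 10)
#' @export
derive_sigmoidal <- function(p, last_obs_time) {
  stopifnot_finite(last_obs_time, "last_obs_time")
  slope <- p$a1 * p$I_max / 4
  structure(list(
    model_kind = "sigmoidal",
    available = TRUE,
    t_mid = p$t_mid,
    midpoint_slope = slope,
    start_time = p$t_mid - 2 / p$a1,
    end_time = p$t_mid + 2 / p$a1,
    growth_duration = 4 / p$a1,
    end_ratio = sigmoidal_value(last_obs_time, p) / p$I_max
  ), class = "derived_params")
}

# Expanding-bracket bisection for f(t) = target, moving left or right from
# t_star. Doubles the window until the sign condition holds; returns NA if
# it never does (e.g. target below the curve's asymptote).
dsig_root <- function(p, t_star, target, side, tol = 1e-10) {
  f <- function(t) double_sigmoidal_value(t, p, t_star = t_star) - target
  d <- max(1 / p$a1_prime, 1 / p$a2_prime,
           p$t_mid2_prime - p$t_mid1_prime, 1e-3)
  inner <- t_star
  for (i in 1:60) {
    outer <- if (side == "left") t_star - d else t_star + d
    if (f(outer) < 0) {
      lo <- min(inner, outer)
      hi <- max(inner, outer)
      return(stats::uniroot(f, lower = lo, upper = hi, tol = tol)$root)
    }
    d <- d * 2
  }
  NA_real_
}

#' Descriptors of a fitted double-sigmoidal curve
#'
#' The primed parameters of the double-sigmoidal model determine, but do
#' not equal, the curve's true midpoints and slopes; this function extracts
#' them numerically. `t_mid1` is the unique time before the maximum `t*`
#' where the curve crosses `I_max / 2`; `t_mid2` is the unique time after
#' `t*` where it crosses `(I_max + I_final) / 2` (halfway from the maximum
#' to the final asymptote). The midpoint slopes are central finite
#' differences of the curve at those times. Tangent lines through each
#' midpoint with its slope give the growth window (intercepts with 0 and
#' `I_max`) and the decay window (intercepts with `I_max` and `I_final`),
#' mirroring the sigmoidal construction.
#'
#' When `I_final` equals `I_max` the decay midpoint does not exist; the
#' result is then flagged unavailable (`available = FALSE`) rather than
#' raising an error.
#'
#' @param p A [double_sigmoidal_params()] object.
#' @param last_obs_time Time of the last observation (for the end ratio,
#'   prediction there over the maximum prediction `I_max`).
#' @param tol Bisection tolerance for the midpoint roots (default `1e-10`,
#'   intended for the normalized time scale).
#' @param fd_step Central finite-difference step for the midpoint slopes;
#'   default `1e-6` times the characteristic time scale.
#' @return A list of class `"derived_params"` with fields `t_mid1`,
#'   `t_mid2`, `slope1` (> 0), `slope2` (< 0), `t_star`, `start_time`,
#'   `end_time`, `growth_duration`, `decay_start_time`, `decay_end_time`,
#'   `decay_duration`, `end_ratio`, and `available`.
#' @export
derive_double_sigmoidal <- function(p, last_obs_time, tol = 1e-10,
                                    fd_step = NULL) {
  stopifnot_finite(last_obs_time, "last_obs_time")
  t_star <- find_tstar(p)
  time_scale <- max(1, abs(t_star), p$t_mid2_prime - p$t_mid1_prime)
  if (is.null(fd_step)) fd_step <- 1e-6 * time_scale

  unavailable <- function(reason) {
    structure(list(model_kind = "double_sigmoidal", available = FALSE,
                   reason = reason, t_star = t_star,
                   end_ratio = double_sigmoidal_value(last_obs_time, p,
                                                      t_star) / p$I_max),
              class = "derived_params")
  }

  t_mid1 <- dsig_root(p, t_star, p$I_max / 2, side = "left", tol = tol)
  if (!is.finite(t_mid1)) return(unavailable("growth midpoint not bracketed"))
  if (p$I_final >= p$I_max) return(unavailable("no decay: I_final = I_max"))
  mid2_level <- (p$I_max + p$I_final) / 2
  t_mid2 <- dsig_root(p, t_star, mid2_level, side = "right", tol = tol)
  if (!is.finite(t_mid2)) return(unavailable("decay midpoint not bracketed"))

  fd_slope <- function(t) {
    (double_sigmoidal_value(t + fd_step, p, t_star) -
       double_sigmoidal_value(t - fd_step, p, t_star)) / (2 * fd_step)
  }
  slope1 <- fd_slope(t_mid1)
  slope2 <- fd_slope(t_mid2)
  if (!is.finite(slope1) || slope1 <= 0 || !is.finite(slope2) ||
      slope2 >= 0) {
    return(unavailable("degenerate midpoint slope"))
  }

  structure(list(
    model_kind = "double_sigmoidal",
    available = TRUE,
    t_star = t_star,
    t_mid1 = t_mid1,
    t_mid2 = t_mid2,
    slope1 = slope1,
    slope2 = slope2,
    start_time = t_mid1 - (p$I_max / 2) / slope1,
    end_time = t_mid1 + (p$I_max / 2) / slope1,
    growth_duration = p$I_max / slope1,
    decay_start_time = t_mid2 + (p$I_max - mid2_level) / slope2,
    decay_end_time = t_mid2 + (p$I_final - mid2_level) / slope2,
    decay_duration = (p$I_final - p$I_max) / slope2,
    end_ratio = double_sigmoidal_value(last_obs_time, p, t_star) / p$I_max
  ), class = "derived_params")
}

#' Rescale derived descriptors to raw units
#'
#' Times scale by `time_scale`, intensities by `intensity_scale`, slopes by
#' their ratio; the end ratio is scale free.
#'
#' @param d A `"derived_params"` object on the normalized scale.
#' @param record A normalization record.
#' @return A `"derived_params"` object in raw units.
#' @export
denormalize_derived <- function(d, record) {
  if (!isTRUE(d$available)) return(d)
  ts <- record$time_scale
  is <- record$intensity_scale
  out <- d
  for (nm in c("t_mid", "t_star", "t_mid1", "t_mid2", "start_time",
               "end_time", "decay_start_time", "decay_end_time",
               "growth_duration", "decay_duration")) {
    if (!is.null(out[[nm]])) out[[nm]] <- out[[nm]] * ts
  }
  for (nm in c("midpoint_slope", "slope1", "slope2")) {
    if (!is.null(out[[nm]])) out[[nm]] <- out[[nm]] * is / ts
  }
  out
}
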