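#' Construct a time course
#'
#' The universal input: paired observations of time and intensity.
#' Observations are sorted by time internally; times need not be
#' equidistant. At least 7 observations are required so that both model
#' families (3 and 6 free parameters) remain over-determined.
#'
#' @param time Numeric vector of observation times (finite).
#' @param intensity Numeric vector of intensities (finite), same length.
#' @return A `data.frame` of class `"time_course"` with columns `time` and
#'   `intensity`, sorted by time.
#' @examples
#' tc <- time_course(seq(0, 10, by = 1), stats::plogis(seq(-5, 5)))
#' @export
time_course <- function(time, intensity) {
  if (length(time) != length(intensity)) {
    stop("`time` and `intensity` must have equal length", call. = FALSE)
  }
  if (length(time) < 7) {
    stop("a time course needs at least 7 observations", call. = FALSE)
  }
  stopifnot_finite(time, "time")
  stopifnot_finite(intensity, "intensity")
  ord <- order(time)
  structure(data.frame(time = time[ord], intensity = intensity[ord]),
            class = c("time_course", "data.frame"))
}

#' Normalize a time course to the unit square
#'
#' Fitting is performed on data mapped onto `[0, 1] x [0, 1]`: times are
#' divided by the maximum time and intensities by the maximum intensity.
#' Minima are deliberately *not* subtracted — the sigmoidal model already
#' starts at 0, and baseline subtraction would change the model family.
#' Negative intensities (e.g. background-subtracted data) are permitted and
#' simply map below 0.
#'
#' All decision-tree thresholds that refer to intensities (start-intensity
#' cutoff, AIC gate) operate on this normalized scale.
#'
#' @param tc A [time_course()].
#' @return A list with elements `tc` (the normalized [time_course()]) and
#'   `record`, a `"normalization_record"` holding the two positive divisors
#'   `time_scale` and `intensity_scale`.
#' @export
normalize_time_course <- function(tc) {
  time_scale <- max(tc$time)
  intensity_scale <- max(tc$intensity)
  if (time_scale <= 0) {
    stop("maximum time must be positive to normalize", call. = FALSE)
  }
  if (intensity_scale <= 0) {
    stop("maximum intensity must be positive to normalize (no signal?)",
         call. = FALSE)
  }
  list(
    tc = time_course(tc$time / time_scale, tc$intensity / intensity_scale),
    record = structure(list(time_scale = time_scale,
                            intensity_scale = intensity_scale),
                       class = "normalization_record")
  )
}

#' Map fitted sigmoidal parameters back to raw units
#'
#' Intensities scale by `intensity_scale`, times by `time_scale`, and the
#' slope parameter `a1` (inverse time) by `1 / time_scale`; the midpoint
#' slope `a1 * I_max / 4` therefore scales by
#' `intensity_scale / time_scale`.
#'
#' @param p Normalized-scale [sigmoidal_params()].
#' @param record A normalization record from [normalize_time_course()].
#' @return Raw-scale [sigmoidal_params()].
#' @export
denormalize_sigmoidal_params <- function(p, record) {
  sigmoidal_params(I_max = p$I_max * record$intensity_scale,
                   t_mid = p$t_mid * record$time_scale,
                   a1 = p$a1 / record$time_scale)
}

#' Map fitted double-sigmoidal parameters back to raw units
#'
#' Both primed midpoints scale by `time_scale`, both primed slopes by
#' `1 / time_scale`, and both intensity parameters by `intensity_scale`.
#' `t*` is equivariant: `t*_raw = t*_norm * time_scale`.
#'
#' @param p Normalized-scale [double_sigmoidal_params()].
#' @param record A normalization record from [normalize_time_course()].
#' @return Raw-scale [double_sigmoidal_params()].
#' @export
denormalize_double_sigmoidal_params <- function(p, record) {
  double_sigmoidal_params(
    I_max = p$I_max * record$intensity_scale,
    I_final = p$I_final * record$intensity_scale,
    t_mid1_prime = p$t_mid1_prime * record$time_scale,
    t_mid2_prime = p$t_mid2_prime * record$time_scale,
    a1_prime = p$a1_prime / record$time_scale,
    a2_prime = p$a2_prime / record$time_scale
  )
}
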