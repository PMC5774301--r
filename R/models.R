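#' Sigmoidal model parameters
#'
#' Container for the three parameters of the logistic growth model
#' \deqn{I(t) = I_{max} / (1 + \exp(-a_1 (t - t_{mid}))),}
#' where `I_max` is the asymptotic maximum intensity, `t_mid` the time at
#' which the curve reaches half its maximum, and `a1` (inverse time units)
#' controls steepness: the slope at the midpoint is `a1 * I_max / 4`.
#'
#' @param I_max Maximum intensity, > 0.
#' @param t_mid Midpoint time.
#' @param a1 Slope parameter, > 0 (inverse time units).
#' @return An object of class `"sigmoidal_params"`.
#' @examples
#' p <- sigmoidal_params(I_max = 2, t_mid = 5, a1 = 1)
#' sigmoidal_value(5, p) # I_max / 2
#' @export
sigmoidal_params <- function(I_max, t_mid, a1) {
  stopifnot_finite(I_max, "I_max")
  stopifnot_finite(t_mid, "t_mid")
  stopifnot_finite(a1, "a1")
  if (I_max <= 0) stop("`I_max` must be positive", call. = FALSE)
  if (a1 <= 0) stop("`a1` must be positive", call. = FALSE)
  structure(list(I_max = I_max, t_mid = t_mid, a1 = a1),
            class = "sigmoidal_params")
}

#' Double-sigmoidal model parameters
#'
#' Container for the six parameters of the rise-and-decay model. The model
#' is built from the *base* double-sigmoidal, the product of a rising and a
#' decaying logistic, which is cut at its unique maximum `t*` and each
#' branch rescaled so the curve rises from 0 to `I_max` at `t*` and then
#' decays to the asymptote `I_final`.
#'
#' The primed midpoints and slopes (`t_mid1_prime`, `t_mid2_prime`,
#' `a1_prime`, `a2_prime`) determine, but do not equal, the curve's true
#' midpoints and midpoint slopes; those are extracted numerically by
#' [derive_double_sigmoidal()].
#'
#' @param I_max Maximum intensity, > 0.
#' @param I_final Final asymptotic intensity, in `[0, I_max]`.
#' @param t_mid1_prime,t_mid2_prime Primed midpoint times of the rising and
#'   decaying logistic factors; `t_mid2_prime > t_mid1_prime` is enforced.
#' @param a1_prime,a2_prime Primed slope parameters, both > 0.
#' @return An object of class `"double_sigmoidal_params"`.
#' @examples
#' p <- double_sigmoidal_params(I_max = 1, I_final = 0.3,
#'                              t_mid1_prime = 8, t_mid2_prime = 16,
#'                              a1_prime = 2, a2_prime = 1)
#' find_tstar(p)
#' @export
double_sigmoidal_params <- function(I_max, I_final, t_mid1_prime,
                                    t_mid2_prime, a1_prime, a2_prime) {
  for (nm in c("I_max", "I_final", "t_mid1_prime", "t_mid2_prime",
               "a1_prime", "a2_prime")) {
    stopifnot_finite(get(nm), nm)
  }
  if (I_max <= 0) stop("`I_max` must be positive", call. = FALSE)
  if (I_final < 0 || I_final > I_max) {
    stop("`I_final` must lie in [0, I_max]", call. = FALSE)
  }
  if (a1_prime <= 0 || a2_prime <= 0) {
    stop("slope parameters must be positive", call. = FALSE)
  }
  if (t_mid2_prime <= t_mid1_prime) {
    stop("`t_mid2_prime` must be larger than `t_mid1_prime`", call. = FALSE)
  }
  structure(list(I_max = I_max, I_final = I_final,
                 t_mid1_prime = t_mid1_prime, t_mid2_prime = t_mid2_prime,
                 a1_prime = a1_prime, a2_prime = a2_prime),
            class = "double_sigmoidal_params")
}

#' General (four-parameter) sigmoidal parameters
#'
#' The four-parameter logistic rising from `I_init` at minus infinity to
#' `I_max` at plus infinity; the three-parameter model is recovered at
#' `I_init = 0`. Used mainly as a building block and numerical oracle.
#'
#' @param I_init Initial asymptote.
#' @param I_max Final asymptote, > `I_init`.
#' @param t_mid Midpoint time (maximum-slope time).
#' @param a1 Slope parameter, > 0; the maximum slope is
#'   `(a1 / 4) * (I_max - I_init)`.
#' @return An object of class `"general_sigmoidal_params"`.
#' @export
general_sigmoidal_params <- function(I_init, I_max, t_mid, a1) {
  for (nm in c("I_init", "I_max", "t_mid", "a1")) stopifnot_finite(get(nm), nm)
  if (a1 <= 0) stop("`a1` must be positive", call. = FALSE)
  if (I_max <= I_init) stop("`I_max` must exceed `I_init`", call. = FALSE)
  structure(list(I_init = I_init, I_max = I_max, t_mid = t_mid, a1 = a1),
            class = "general_sigmoidal_params")
}

#' Evaluate the sigmoidal model
#'
#' @param t Numeric vector of times (finite).
#' @param p A [sigmoidal_params()] object.
#' @return Intensities, strictly increasing in `t`, bounded in `(0, I_max)`.
#' @export
sigmoidal_value <- function(t, p) {
  stopifnot_finite(t, "t")
  p$I_max * stats::plogis(p$a1 * (t - p$t_mid))
}

#' Evaluate the base double-sigmoidal
#'
#' The product of a rising logistic (midpoint `t_mid1_prime`, slope
#' `a1_prime`) and a decaying logistic (midpoint `t_mid2_prime`, slope
#' `a2_prime`). Values lie in `(0, 1)` and vanish at both infinities; the
#' function has exactly one local maximum (see [find_tstar()]).
#'
#' @param t Numeric vector of times.
#' @param a1_prime,a2_prime Positive slope parameters.
#' @param t_mid1_prime,t_mid2_prime Midpoints, `t_mid2_prime > t_mid1_prime`.
#' @return Unitless values in `(0, 1)`.
#' @export
dsig_base_value <- function(t, a1_prime, a2_prime, t_mid1_prime,
                            t_mid2_prime) {
  stopifnot_finite(t, "t")
  if (a1_prime <= 0 || a2_prime <= 0) {
    stop("slope parameters must be positive", call. = FALSE)
  }
  if (t_mid2_prime <= t_mid1_prime) {
    stop("`t_mid2_prime` must be larger than `t_mid1_prime`", call. = FALSE)
  }
  stats::plogis(a1_prime * (t - t_mid1_prime)) *
    stats::plogis(-a2_prime * (t - t_mid2_prime))
}

#' Locate the maximum of the base double-sigmoidal
#'
#' The base double-sigmoidal has exactly one local extremum, a maximum at
#' `t*`. Writing `u = t - t_mid1_prime` and `L = t_mid2_prime -
#' t_mid1_prime`, the stationarity condition reduces to the root of
#' \deqn{h(u) = a'_1 (e^{a'_2 (L - u)} + 1) - a'_2 (e^{a'_1 u} + 1),}
#' which is strictly decreasing, so bracketing plus bisection converges to
#' the unique root. `t* = t_mid1_prime + u*`.
#'
#' @param p A [double_sigmoidal_params()] object.
#' @param tol Root tolerance on `u` (default `1e-10`, intended for the
#'   normalized time scale).
#' @return The time `t*` at which the base curve is maximal.
#' @export
find_tstar <- function(p, tol = 1e-10) {
  p$t_mid1_prime + tstar_root(p$a1_prime, p$a2_prime,
                              p$t_mid2_prime - p$t_mid1_prime, tol)
}

# Root u* of h(u) = a1 (e^{a2 (L-u)} + 1) - a2 (e^{a1 u} + 1). h is a
# difference of two positive terms, so its sign (and root) equals that of
# the difference of their logarithms, computed overflow-free via
# softplus: log(a (e^x + 1)) = log(a) + x + log1p(e^{-x}). The log form
# is also strictly decreasing, so Newton steps safeguarded by a
# sign-change bracket are guaranteed to converge.
tstar_root <- function(a1, a2, L, tol = 1e-10) {
  softplus <- function(x) {
    if (x > 0) x + log1p(exp(-x)) else log1p(exp(x))
  }
  dla <- log(a1) - log(a2)
  h <- function(u) dla + softplus(a2 * (L - u)) - softplus(a1 * u)
  dh <- function(u) {
    -a2 * stats::plogis(a2 * (L - u)) - a1 * stats::plogis(a1 * u)
  }
  # expand a bracket around [0, L] until it straddles the sign change
  # (h(-Inf) = +Inf, h(+Inf) = -Inf)
  lo <- 0
  hi <- L
  h_lo <- h(lo)
  h_hi <- h(hi)
  step <- max(L, 1 / a1, 1 / a2, 1)
  iter <- 0L
  while (h_lo < 0) {
    hi <- lo
    h_hi <- h_lo
    lo <- lo - step
    h_lo <- h(lo)
    step <- step * 2
    iter <- iter + 1L
    if (iter > 200L) stop("bracket search failed for t*", call. = FALSE)
  }
  step <- max(L, 1 / a1, 1 / a2, 1)
  iter <- 0L
  while (h_hi > 0) {
    lo <- hi
    h_lo <- h_hi
    hi <- hi + step
    h_hi <- h(hi)
    step <- step * 2
    iter <- iter + 1L
    if (iter > 200L) stop("bracket search failed for t*", call. = FALSE)
  }
  if (h_lo == 0) return(lo)
  if (h_hi == 0) return(hi)
  u <- (lo + hi) / 2
  for (iter in 1:100) {
    hu <- h(u)
    if (hu == 0) return(u)
    if (hu > 0) lo <- u else hi <- u
    u_new <- u - hu / dh(u)
    if (!is.finite(u_new) || u_new <= lo || u_new >= hi) {
      u_new <- (lo + hi) / 2
    }
    if (abs(u_new - u) < tol || (hi - lo) < tol) return(u_new)
    u <- u_new
  }
  u
}

# Scaling constants of the two branches: c1 = I_max / f_max for the growth
# phase, c2 = (I_max - I_final) / f_max for the decay phase.
dsig_scaling <- function(p, t_star = NULL) {
  if (is.null(t_star)) t_star <- find_tstar(p)
  f_max <- dsig_base_value(t_star, p$a1_prime, p$a2_prime,
                           p$t_mid1_prime, p$t_mid2_prime)
  list(t_star = t_star, f_max = f_max,
       c1 = p$I_max / f_max,
       c2 = (p$I_max - p$I_final) / f_max)
}

#' Evaluate the double-sigmoidal model
#'
#' Piecewise rescaling of the base double-sigmoidal about its maximum:
#' `c1 * f_base(t)` for `t <= t*` and `c2 * f_base(t) + I_final` for
#' `t > t*`, with `c1 = I_max / f_max` and `c2 = (I_max - I_final) / f_max`.
#' The curve rises from 0 to `I_max` at `t*`, decays to `I_final`, and is
#' continuous with a continuous first derivative (the second derivative is
#' discontinuous at `t*`).
#'
#' @param t Numeric vector of times.
#' @param p A [double_sigmoidal_params()] object.
#' @param t_star Optional precomputed [find_tstar()] value (saves the root
#'   search in tight loops).
#' @return Intensities.
#' @export
double_sigmoidal_value <- function(t, p, t_star = NULL) {
  stopifnot_finite(t, "t")
  sc <- dsig_scaling(p, t_star)
  base <- dsig_base_value(t, p$a1_prime, p$a2_prime,
                          p$t_mid1_prime, p$t_mid2_prime)
  out <- sc$c2 * base + p$I_final
  growth <- t <= sc$t_star
  out[growth] <- sc$c1 * base[growth]
  out
}

#' Evaluate the general four-parameter sigmoidal
#'
#' @param t Numeric vector of times.
#' @param p A [general_sigmoidal_params()] object.
#' @return Intensities rising from `I_init` to `I_max`.
#' @export
general_sigmoidal_value <- function(t, p) {
  stopifnot_finite(t, "t")
  p$I_init + (p$I_max - p$I_init) * stats::plogis(p$a1 * (t - p$t_mid))
}

#' Naive product of a rising and a decaying sigmoidal
#'
#' The literal product of the four-parameter rising logistic and the
#' inverse (decaying) logistic. For some parameter regions — narrowly
#' separated midpoints with one steep and one shallow slope — this product
#' develops a spurious local minimum and is not double-sigmoidal, which is
#' why the package's double-sigmoidal model uses the cut-and-rescale
#' construction instead. Provided as a numerical oracle.
#'
#' @param t Numeric vector of times.
#' @param I_init,I_final,I_max Intensity parameters of the two factors.
#' @param a1,a2 Positive slope parameters.
#' @param t_mid1,t_mid2 Midpoints of the rising and decaying factors.
#' @return The product curve values.
#' @export
naive_product_value <- function(t, I_init, I_final, I_max, a1, a2,
                                t_mid1, t_mid2) {
  stopifnot_finite(t, "t")
  if (a1 <= 0 || a2 <= 0) {
    stop("slope parameters must be positive", call. = FALSE)
  }
  rising <- I_init + (I_max - I_init) * stats::plogis(a1 * (t - t_mid1))
  decaying <- I_final + (1 - I_final) * stats::plogis(-a2 * (t - t_mid2))
  rising * decaying
}
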