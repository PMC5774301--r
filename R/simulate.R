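#' Draw random sigmoidal parameters
#'
#' Samples the benchmark parameter distribution for sigmoidal truth
#' curves: `I_max` uniform on `[0.3, 20]`, `t_mid` uniform on `[3, 27]`,
#' and the slope obtained by drawing a slope *angle* uniformly on
#' `[0, pi/2]` and taking its tangent (a heavy-tailed slope
#' distribution). Uses the current RNG stream.
#'
#' @return A [sigmoidal_params()] object.
#' @export
sample_sigmoidal_params <- function() {
  sigmoidal_params(I_max = stats::runif(1, 0.3, 20),
                   t_mid = stats::runif(1, 3, 27),
                   a1 = tan(stats::runif(1, 0, pi / 2)))
}

#' Draw random double-sigmoidal parameters
#'
#' Samples the benchmark distribution for double-sigmoidal truth curves:
#' `I_max` uniform on `[0.3, 20]`, first primed midpoint uniform on
#' `[3, 26]`, decay slope `a2'` uniform on `[0.001, 40]`, the distance `L`
#' between primed midpoints uniform on `[1, 27 - t_mid1']`, the final
#' asymptote ratio `I_final / I_max` uniform on `[0, 0.85]`, and the
#' growth slope `a1'` as `tan(theta)` with `theta` uniform on `[0, pi/2]`.
#' By construction `t_mid2' = t_mid1' + L <= 27`.
#'
#' @return A [double_sigmoidal_params()] object.
#' @export
sample_double_sigmoidal_params <- function() {
  I_max <- stats::runif(1, 0.3, 20)
  t_mid1 <- stats::runif(1, 3, 26)
  a2 <- stats::runif(1, 0.001, 40)
  L <- stats::runif(1, 1, 27 - t_mid1)
  ratio <- stats::runif(1, 0, 0.85)
  double_sigmoidal_params(I_max = I_max, I_final = ratio * I_max,
                          t_mid1_prime = t_mid1,
                          t_mid2_prime = t_mid1 + L,
                          a1_prime = tan(stats::runif(1, 0, pi / 2)),
                          a2_prime = a2)
}

#' Draw observation times for one simulated sample
#'
#' 55 time points on the window `[3, 30]` under one of five regimes:
#' equidistant (steps of 0.5), uniform random, or beta-distributed times
#' (`27 * Beta(alpha, beta) + 3`) concentrating sampling near the
#' beginning (`alpha = 0.5, beta = 1.5`), center (`2, 2`), or end
#' (`1.5, 0.5`) of the window. Random regimes use the current RNG stream;
#' times are returned sorted.
#'
#' @param regime One of `"equidistant"`, `"uniform"`, `"beta_early"`,
#'   `"beta_center"`, `"beta_late"`.
#' @param n_points Number of time points (default 55).
#' @return Sorted numeric vector of times in `[3, 30]`.
#' @export
sample_times <- function(regime = c("equidistant", "uniform", "beta_early",
                                    "beta_center", "beta_late"),
                         n_points = 55) {
  regime <- match.arg(regime)
  switch(regime,
         equidistant = seq(3, 30, length.out = n_points),
         uniform = sort(stats::runif(n_points, 3, 30)),
         beta_early = sort(27 * stats::rbeta(n_points, 0.5, 1.5) + 3),
         beta_center = sort(27 * stats::rbeta(n_points, 2, 2) + 3),
         beta_late = sort(27 * stats::rbeta(n_points, 1.5, 0.5) + 3))
}

#' Add noise to a clean intensity vector
#'
#' Additive noise adds `u * amplitude * max(I)` per point with `u` uniform
#' on `[-0.5, 0.5]`. Multiplicative noise multiplies each point by a
#' factor built from `2^x` with `x` uniform on `[-1, 1]`; two forms are
#' provided. The `"centered"` form, `I * (1 + amplitude * (2^x - 1))`,
#' reduces to the identity at amplitude 0 and is the benchmark default.
#' The `"literal"` form, `I * amplitude * 2^x`, scales the whole signal by
#' the amplitude (and annihilates it at amplitude 0); it is kept available
#' as an alternative reading of the multiplicative recipe.
#'
#' @param intensities Clean intensity vector.
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @param amplitude Noise amplitude as a fraction of the maximum, in
#'   `[0, 1.5]`.
#' @param multiplicative_form `"centered"` (default) or `"literal"`.
#' @return Noisy intensity vector (same length). Uses the current RNG
#'   stream.
#' @export
add_noise <- function(intensities,
                      noise_type = c("additive", "multiplicative"),
                      amplitude,
                      multiplicative_form = c("centered", "literal")) {
  noise_type <- match.arg(noise_type)
  multiplicative_form <- match.arg(multiplicative_form)
  stopifnot(amplitude >= 0, amplitude <= 1.5)
  n <- length(intensities)
  if (noise_type == "additive") {
    u <- stats::runif(n, -0.5, 0.5)
    intensities + u * amplitude * max(intensities)
  } else {
    x <- stats::runif(n, -1, 1)
    if (multiplicative_form == "centered") {
      intensities * (1 + amplitude * (2^x - 1))
    } else {
      intensities * amplitude * 2^x
    }
  }
}

# A parameter set is admissible for the benchmark only if its *noise-free*
# curve, observed at the sample times, would not be classified as
# ambiguous or no-signal by definition: it must pass the no-signal
# cutoffs and its own model's acceptance checks (positive start times,
# low start intensity, end-ratio gate), all evaluated analytically from
# the true parameters.
clean_curve_admissible <- function(model_kind, params, times, cfg) {
  t_last <- times[length(times)]
  if (model_kind == "sigmoidal") {
    clean <- sigmoidal_value(times, params)
    mx <- max(clean)
    derived <- derive_sigmoidal(params, t_last)
    ok <- !check_no_signal(mx, diff(range(clean)), cfg) &&
      clean[1] / mx < cfg$max_start_intensity &&
      derived$end_ratio > cfg$min_end_ratio_sigmoidal &&
      derived$start_time > 0
    return(list(ok = ok, clean = clean))
  }
  t_star <- find_tstar(params)
  clean <- double_sigmoidal_value(times, params, t_star = t_star)
  mx <- max(clean)
  # cheap checks first; the midpoint root searches only run for survivors
  cheap_ok <- !check_no_signal(mx, diff(range(clean)), cfg) &&
    clean[1] / mx < cfg$max_start_intensity &&
    double_sigmoidal_value(t_last, params, t_star = t_star) /
      params$I_max < cfg$max_end_ratio_double
  if (!cheap_ok) return(list(ok = FALSE, clean = clean))
  derived <- derive_double_sigmoidal(params, t_last)
  ok <- isTRUE(derived$available) &&
    derived$start_time > 0 &&
    derived$decay_start_time > 0
  list(ok = ok, clean = clean)
}

simulate_one <- function(model_kind, regime, noise_type, amplitude,
                         replicate, cfg, n_points, multiplicative_form,
                         max_tries) {
  times <- sample_times(regime, n_points)
  for (try in seq_len(max_tries)) {
    params <- if (model_kind == "sigmoidal") sample_sigmoidal_params()
              else sample_double_sigmoidal_params()
    adm <- clean_curve_admissible(model_kind, params, times, cfg)
    if (adm$ok) {
      noisy <- add_noise(adm$clean, noise_type, amplitude,
                         multiplicative_form)
      return(list(model_kind = model_kind, regime = regime,
                  noise_type = noise_type, amplitude = amplitude,
                  replicate = replicate, params = params,
                  times = times, clean = adm$clean, noisy = noisy,
                  n_tries = try))
    }
  }
  stop("configuration error: parameter rejection rate too high for cell ",
       model_kind, "/", regime, "/", noise_type, "/", amplitude,
       call. = FALSE)
}

#' Generate the simulation benchmark grid
#'
#' For every combination of truth model, temporal sampling regime, noise
#' type, and noise amplitude, draws `n_replicates` independent parameter
#' sets, rejecting and resampling any set whose noise-free curve would by
#' definition fail the classification checks (no-signal cutoffs, positive
#' start times, start-intensity cutoff, and the model's end-ratio gate),
#' then attaches clean and noisy intensity vectors at freshly drawn
#' sample times. The default configuration enumerates
#' `2 models x 5 regimes x 2 noise types x 11 amplitudes x 50 replicates
#' = 11,000` parameter sets.
#'
#' Each sample receives its own RNG seed derived deterministically from
#' the top-level `seed` and the sample's position in the enumeration
#' (multiplicative-congruential fan-out), so a fixed seed regenerates the
#' grid bit-identically and any single sample can be reproduced in
#' isolation from its manifest seed.
#'
#' @param model_kinds Truth models to simulate.
#' @param regimes Temporal sampling regimes (see [sample_times()]).
#' @param noise_types Noise models (see [add_noise()]).
#' @param amplitudes Noise amplitudes; default 11 equally spaced values
#'   from 0 to 1.5.
#' @param n_replicates Parameter sets per cell (default 50).
#' @param seed Top-level integer seed.
#' @param decision_cfg A [decision_config()] supplying the admissibility
#'   cutoffs.
#' @param n_points Time points per sample (default 55).
#' @param multiplicative_form Passed to [add_noise()].
#' @param max_tries Rejection-sampling cap per sample before declaring a
#'   configuration error.
#' @return A list of class `"simulation_grid"` with `samples` (list of
#'   per-sample records: parameters, times, clean and noisy intensities,
#'   seed) and `manifest` (one data.frame row per sample: identifiers,
#'   cell coordinates, seed, and true parameter columns).
#' @examples
#' g <- simulate_grid(model_kinds = "sigmoidal", regimes = "equidistant",
#'                    noise_types = "additive", amplitudes = 0,
#'                    n_replicates = 2, seed = 7)
#' g$manifest
#' @export
simulate_grid <- function(model_kinds = c("sigmoidal", "double_sigmoidal"),
                          regimes = c("equidistant", "uniform",
                                      "beta_early", "beta_center",
                                      "beta_late"),
                          noise_types = c("additive", "multiplicative"),
                          amplitudes = seq(0, 1.5, length.out = 11),
                          n_replicates = 50,
                          seed = 1,
                          decision_cfg = decision_config(),
                          n_points = 55,
                          multiplicative_form = c("centered", "literal"),
                          max_tries = 2000) {
  multiplicative_form <- match.arg(multiplicative_form)
  stopifnot(n_replicates >= 1, all(amplitudes >= 0), all(amplitudes <= 1.5))
  cells <- expand.grid(replicate = seq_len(n_replicates),
                       amplitude = amplitudes,
                       noise_type = noise_types,
                       regime = regimes,
                       model_kind = model_kinds,
                       stringsAsFactors = FALSE)
  n_samples <- nrow(cells)
  samples <- vector("list", n_samples)
  manifest <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    s_seed <- child_seed(seed, i)
    smp <- with_local_seed(s_seed, simulate_one(
      cells$model_kind[i], cells$regime[i], cells$noise_type[i],
      cells$amplitude[i], cells$replicate[i], decision_cfg, n_points,
      multiplicative_form, max_tries))
    smp$sample_id <- sprintf("s%05d", i)
    smp$seed <- s_seed
    samples[[i]] <- smp
    p <- smp$params
    manifest[[i]] <- data.frame(
      sample_id = smp$sample_id,
      model_kind = smp$model_kind,
      regime = smp$regime,
      noise_type = smp$noise_type,
      amplitude = smp$amplitude,
      replicate = smp$replicate,
      seed = s_seed,
      I_max = p$I_max,
      t_mid = if (smp$model_kind == "sigmoidal") p$t_mid else NA_real_,
      a1 = if (smp$model_kind == "sigmoidal") p$a1 else NA_real_,
      I_final = if (smp$model_kind == "sigmoidal") NA_real_ else p$I_final,
      t_mid1_prime = if (smp$model_kind == "sigmoidal") NA_real_
                     else p$t_mid1_prime,
      t_mid2_prime = if (smp$model_kind == "sigmoidal") NA_real_
                     else p$t_mid2_prime,
      a1_prime = if (smp$model_kind == "sigmoidal") NA_real_
                 else p$a1_prime,
      a2_prime = if (smp$model_kind == "sigmoidal") NA_real_
                 else p$a2_prime,
      stringsAsFactors = FALSE
    )
  }
  structure(list(samples = samples,
                 manifest = do.call(rbind, manifest),
                 seed = seed,
                 multiplicative_form = multiplicative_form),
            class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("simulation grid: %d samples (%d models x %d regimes x %d noise types x %d amplitudes)\n",
              nrow(m), length(unique(m$model_kind)),
              length(unique(m$regime)), length(unique(m$noise_type)),
              length(unique(m$amplitude))))
  invisible(x)
}
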