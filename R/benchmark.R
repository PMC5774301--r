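#' Normalized mean absolute error between two intensity vectors
#'
#' The mean absolute difference between the noise-free and predicted
#' intensity vectors, normalized by the maximum of the noise-free vector.
#' Invariant under joint rescaling of both vectors.
#'
#' @param clean Noise-free intensity vector (maximum must be positive).
#' @param predicted Predicted intensity vector, same length.
#' @return A nonnegative fraction.
#' @export
nmae <- function(clean, predicted) {
  if (length(clean) == 0 || length(clean) != length(predicted)) {
    stop("`clean` and `predicted` must be equal-length, non-empty",
         call. = FALSE)
  }
  m <- max(clean)
  if (m <= 0) stop("max(clean) must be positive", call. = FALSE)
  mean(abs(clean - predicted)) / m
}

# Raw-scale prediction used for the error metric: the chosen category's
# fitted curve, or for ambiguous calls the lower-AIC converged fit (the
# error is computed regardless of whether the classification matched the
# truth). NULL when no model converged.
benchmark_prediction <- function(report, times) {
  pick <- switch(report$category,
                 sigmoidal = "sigmoidal",
                 double_sigmoidal = "double_sigmoidal",
                 ambiguous = {
                   aics <- c(
                     sigmoidal =
                       if (isTRUE(report$sigmoidal$fit$converged))
                         report$sigmoidal$fit$aic else Inf,
                     double_sigmoidal =
                       if (isTRUE(report$double_sigmoidal$fit$converged))
                         report$double_sigmoidal$fit$aic else Inf)
                   if (all(!is.finite(aics))) NULL
                   else names(aics)[which.min(aics)]
                 },
                 NULL)
  if (is.null(pick)) return(NULL)
  p <- report[[pick]]$fit$params_raw
  if (is.null(p)) return(NULL)
  if (pick == "sigmoidal") sigmoidal_value(times, p)
  else double_sigmoidal_value(times, p)
}

#' Run the classifier over a simulation grid
#'
#' Classifies every (noisy) sample of a [simulate_grid()] result with
#' [fit_and_categorize()] and summarizes, per grid cell, the fraction of
#' each predicted category and the mean normalized mean absolute error
#' ([nmae()]) between the noise-free curve and the chosen fitted curve.
#' The error is computed for every sample with at least one converged
#' fit, regardless of whether the category call matched the truth;
#' samples with no converged fit contribute a missing error and are
#' excluded from cell means.
#'
#' Fitting seeds are fanned out deterministically from each sample's own
#' seed, so the benchmark is reproducible from the grid alone.
#'
#' @param grid A `"simulation_grid"` object.
#' @param fit_cfg A [fit_config()]; its `seed` field is ignored in favor
#'   of the per-sample fan-out.
#' @param decision_cfg A [decision_config()].
#' @param progress Print a dot per 50 samples to stderr.
#' @return A list of class `"benchmark_result"` with `records` (one row
#'   per sample: cell coordinates, truth, predicted category, nmae, both
#'   AIC scores) and `aggregates` (one row per cell: category fractions
#'   summing to 1 and the mean nmae).
#' @export
run_benchmark <- function(grid, fit_cfg = fit_config(),
                          decision_cfg = decision_config(),
                          progress = FALSE) {
  stopifnot(inherits(grid, "simulation_grid"))
  samples <- grid$samples
  n <- length(samples)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- samples[[i]]
    cfg <- fit_cfg
    cfg$seed <- child_seed(smp$seed, 101L)
    report <- fit_and_categorize(time_course(smp$times, smp$noisy),
                                 fit_cfg = cfg,
                                 decision_cfg = decision_cfg)
    pred <- benchmark_prediction(report, smp$times)
    err <- if (is.null(pred)) NA_real_ else nmae(smp$clean, pred)
    rows[[i]] <- data.frame(
      sample_id = smp$sample_id,
      model_kind = smp$model_kind,
      regime = smp$regime,
      noise_type = smp$noise_type,
      amplitude = smp$amplitude,
      replicate = smp$replicate,
      category = report$category,
      nmae = err,
      aic_sigmoidal = report$sigmoidal$fit$aic %||% NA_real_,
      aic_double = report$double_sigmoidal$fit$aic %||% NA_real_,
      stringsAsFactors = FALSE
    )
    if (progress && i %% 50 == 0) message(".", appendLF = FALSE)
  }
  records <- do.call(rbind, rows)
  if (progress) message("")

  cell_key <- interaction(records$model_kind, records$regime,
                          records$noise_type, records$amplitude,
                          drop = TRUE)
  agg_rows <- lapply(split(records, cell_key), function(d) {
    data.frame(
      model_kind = d$model_kind[1],
      regime = d$regime[1],
      noise_type = d$noise_type[1],
      amplitude = d$amplitude[1],
      n = nrow(d),
      frac_sigmoidal = mean(d$category == "sigmoidal"),
      frac_double_sigmoidal = mean(d$category == "double_sigmoidal"),
      frac_ambiguous = mean(d$category == "ambiguous"),
      frac_no_signal = mean(d$category == "no_signal"),
      mean_nmae = if (all(is.na(d$nmae))) NA_real_
                  else mean(d$nmae, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  aggregates <- do.call(rbind, agg_rows)
  aggregates <- aggregates[order(aggregates$model_kind, aggregates$regime,
                                 aggregates$noise_type,
                                 aggregates$amplitude), ]
  rownames(aggregates) <- NULL
  structure(list(records = records, aggregates = aggregates),
            class = "benchmark_result")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark over %d samples, %d cells\n",
              nrow(x$records), nrow(x$aggregates)))
  print(x$aggregates, digits = 3)
  invisible(x)
}
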