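#' Read a time course from a delimited text file
#'
#' Expects a header row; the delimiter is inferred from the file
#' extension (`.csv` is comma-separated, anything else tab-separated)
#' unless given. Rows with missing or unparseable values in either column
#' are dropped with a warning naming how many and which (0-based) rows.
#'
#' @param path Path to a CSV/TSV file.
#' @param time_column,intensity_column Column names (defaults `"time"`,
#'   `"intensity"`).
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @return A [time_course()].
#' @export
read_time_course <- function(path, time_column = "time",
                             intensity_column = "intensity",
                             delim = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(time_column, intensity_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column `%s` not found in %s; available columns: %s",
                   col, path, paste(names(df), collapse = ", ")),
           call. = FALSE)
    }
  }
  tv <- suppressWarnings(as.numeric(df[[time_column]]))
  iv <- suppressWarnings(as.numeric(df[[intensity_column]]))
  bad <- !is.finite(tv) | !is.finite(iv)
  if (any(bad)) {
    warning(sprintf("%s: dropped %d row(s) with non-finite values (rows %s)",
                    path, sum(bad),
                    paste(which(bad) - 1L, collapse = ", ")),
            call. = FALSE)
  }
  if (sum(!bad) < 7) {
    stop(sprintf("%s: fewer than 7 usable rows after validation", path),
         call. = FALSE)
  }
  time_course(tv[!bad], iv[!bad])
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with
#' `#` are ignored. Values that parse as numbers become numeric. Keys
#' matching [fit_config()] and [decision_config()] arguments configure
#' the respective objects via [config_from_keys()]. Writing with
#' [write_run_config()] and reading back round-trips losslessly.
#'
#' @param path Path to the configuration file.
#' @return Named list of raw key-value pairs.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop("malformed config line (expected `key = value`): ", ln,
           call. = FALSE)
    }
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param keys Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(keys, path) {
  stopifnot(length(names(keys)) == length(keys))
  fmt <- function(v) {
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }
  writeLines(paste(names(keys), "=", vapply(keys, fmt, character(1))),
             path)
  invisible(path)
}

#' Build fitting and decision configurations from flat keys
#'
#' Keys matching [fit_config()] arguments (`n_starts_sigmoidal`,
#' `n_starts_double`, `seed`, `max_iterations`) and [decision_config()]
#' arguments override the defaults; unknown keys are ignored.
#'
#' @param keys Named list, e.g. from [read_run_config()].
#' @return List with elements `fit` ([fit_config()]) and `decision`
#'   ([decision_config()]).
#' @export
config_from_keys <- function(keys = list()) {
  pick <- function(fn) {
    args <- intersect(names(keys), names(formals(fn)))
    do.call(fn, keys[args])
  }
  list(fit = pick(fit_config), decision = pick(decision_config))
}

# One flat row of a classification report for tabular output. Model
# parameters are reported in both normalized and raw units; derived
# descriptors in raw units.
report_row <- function(report, id) {
  row <- list(id = id, category = report$category,
              decisive_rule = report$decisive_rule,
              raw_max = report$raw_max, raw_range = report$raw_range)
  grab <- function(prefix, obj, fields) {
    out <- list()
    for (f in fields) {
      out[[paste0(prefix, f)]] <-
        if (!is.null(obj) && !is.null(obj[[f]])) obj[[f]] else NA_real_
    }
    out
  }
  sig <- report$sigmoidal
  dbl <- report$double_sigmoidal
  row <- c(row,
           list(aic_sigmoidal = sig$fit$aic %||% NA_real_,
                aic_double = dbl$fit$aic %||% NA_real_),
           grab("sig_norm_", sig$fit$params_normalized,
                c("I_max", "t_mid", "a1")),
           grab("sig_raw_", sig$fit$params_raw,
                c("I_max", "t_mid", "a1")),
           grab("sig_", sig$derived_raw,
                c("midpoint_slope", "start_time", "end_time",
                  "growth_duration", "end_ratio")),
           grab("dbl_norm_", dbl$fit$params_normalized,
                c("I_max", "I_final", "t_mid1_prime", "t_mid2_prime",
                  "a1_prime", "a2_prime")),
           grab("dbl_raw_", dbl$fit$params_raw,
                c("I_max", "I_final", "t_mid1_prime", "t_mid2_prime",
                  "a1_prime", "a2_prime")),
           grab("dbl_", dbl$derived_raw,
                c("t_mid1", "t_mid2", "slope1", "slope2", "t_star",
                  "start_time", "end_time", "decay_start_time",
                  "decay_end_time", "decay_duration", "end_ratio")))
  as.data.frame(row, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated samples and a manifest to a directory
#'
#' One CSV per sample (columns `time`, `intensity` holding the noisy
#' values) plus `manifest.tsv` (one row per sample: identifiers, cell
#' coordinates, per-sample seed, true parameters, and the sample file
#' name). The benchmark can be reproduced from this directory alone:
#' noisy data come from the files and noise-free curves are recomputed
#' from the manifest's true parameters.
#'
#' @param grid A [simulate_grid()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_simulation_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "simulation_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(grid$samples))
  for (i in seq_along(grid$samples)) {
    smp <- grid$samples[[i]]
    files[i] <- paste0(smp$sample_id, ".csv")
    utils::write.csv(data.frame(time = smp$times, intensity = smp$noisy),
                     file.path(dir, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- grid$manifest
  manifest$file <- files
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Rebuild a simulation grid from a manifest directory
#'
#' Inverse of [write_simulation_grid()]: reads `manifest.tsv`, loads each
#' sample's noisy data from its file, and recomputes the noise-free curve
#' from the manifest's true parameters.
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return A `"simulation_grid"` object suitable for [run_benchmark()].
#' @export
read_simulation_grid <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  dir <- dirname(manifest_path)
  manifest <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    df <- utils::read.csv(file.path(dir, m$file))
    params <- if (m$model_kind == "sigmoidal") {
      sigmoidal_params(m$I_max, m$t_mid, m$a1)
    } else {
      double_sigmoidal_params(m$I_max, m$I_final, m$t_mid1_prime,
                              m$t_mid2_prime, m$a1_prime, m$a2_prime)
    }
    clean <- if (m$model_kind == "sigmoidal") {
      sigmoidal_value(df$time, params)
    } else {
      double_sigmoidal_value(df$time, params)
    }
    samples[[i]] <- list(sample_id = m$sample_id,
                         model_kind = m$model_kind, regime = m$regime,
                         noise_type = m$noise_type,
                         amplitude = m$amplitude,
                         replicate = m$replicate, seed = m$seed,
                         params = params, times = df$time,
                         clean = clean, noisy = df$intensity)
  }
  structure(list(samples = samples,
                 manifest = manifest[, setdiff(names(manifest), "file")],
                 seed = NA_integer_),
            class = "simulation_grid")
}
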