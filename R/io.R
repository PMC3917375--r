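#' Write and read cell state traces as TSV
#'
#' Long format with one row per (time step, flagellum): columns
#' `time_s`, `flagellum_id`, `motor_state` (`CCW`/`CW`),
#' `waveform_state` (`normal`/`semi_coiled`/`curly_1`) and `run_state`
#' (`run`/`tumble`). The round trip is lossless for these fields;
#' `read_cell_tsv()` reconstructs a cell object whose time resolution is
#' inferred from the time stamps.
#'
#' @param cell A `cell_record` or `observed_cell`.
#' @param path File path.
#' @return `write_cell_tsv()` returns `path` invisibly;
#'   `read_cell_tsv()` returns an `observed_cell`.
#' @export
write_cell_tsv <- function(cell, path) {
  long <- if (inherits(cell, "cell_record")) tidy(cell) else {
    n <- nrow(cell$motor)
    purrr::map_dfr(seq_len(cell$n_flag), function(k) {
      tibble::tibble(
        time_s = seq_len(n) * cell$window,
        flagellum_id = k,
        motor_state = c("CCW", "CW")[cell$motor[, k] + 1L],
        waveform_state = if (is.null(cell$waveform)) NA_character_ else
          names(waveform_levels)[match(cell$waveform[, k],
                                       waveform_levels)],
        run_state = ifelse(cell$run, "run", "tumble"))
    })
  }
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname write_cell_tsv
#' @export
read_cell_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("time_s", "flagellum_id", "motor_state", "run_state")
  missing <- setdiff(needed, names(long))
  if (length(missing))
    stop("malformed cell TSV, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- sort(unique(long$flagellum_id))
  times <- sort(unique(long$time_s))
  step <- if (length(times) > 1) times[2] - times[1] else times[1]
  wide <- function(col, map) {
    vapply(ids, function(k) {
      v <- long[long$flagellum_id == k, ][[col]]
      map(v)
    }, integer(length(times)))
  }
  motor <- wide("motor_state", function(v) as.integer(v == "CW"))
  wf <- if (!all(is.na(long$waveform_state)))
    wide("waveform_state",
         function(v) unname(waveform_levels[v]))
  first <- long[long$flagellum_id == ids[1], ]
  structure(list(cell_id = sub("[.]tsv$", "", basename(path)),
                 n_flag = length(ids), window = step,
                 duration = length(times) * step, strain = NA_character_,
                 motor = matrix(motor, ncol = length(ids)),
                 waveform = if (!is.null(wf))
                   matrix(wf, ncol = length(ids)),
                 run = first$run_state == "run"),
            class = "observed_cell")
}

#' Simulate a dataset to disk
#'
#' Runs [sample_population()] and writes one TSV per cell plus a
#' `manifest.json` sidecar recording the configuration, seed, file list
#' and MD5 checksums, so a dataset is verifiable and bitwise
#' reproducible from `(config, seed)`.
#'
#' @param config A [population_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The cohort, invisibly; side effect: files under `outdir`.
#' @export
simulate_dataset <- function(config = population_config(), outdir,
                             seed = NULL) {
  cohort <- sample_population(config, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap_chr(cohort$cells, function(cell, i) {
    f <- file.path(outdir, sprintf("%s.tsv",
                                   cell$cell_id %||% paste0("cell_", i)))
    write_cell_tsv(cell, f)
    f
  })
  manifest <- list(
    package = "runtumble",
    config = config_as_list(config),
    seed = cohort$seed,
    n_cells = length(files),
    files = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$params <- unclass(out$params)
  out
}

#' Read a simulated dataset from disk
#'
#' @param dir A directory written by [simulate_dataset()].
#' @return A list with `cells` (observed cells) and `manifest`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cells <- purrr::map(file.path(dir, manifest$files), read_cell_tsv)
  list(cells = cells, manifest = manifest)
}

#' End-to-end analysis of a dataset
#'
#' Computes the standard analysis tables from a cohort, list of cells or
#' dataset directory: the per-cell summary (TB, CB, eta), per-group
#' effective flagellar numbers with the power-law fit, the mean-max-CW
#' statistic, the population cross-correlation and the transition-rate
#' estimates. Optionally writes each table as TSV.
#'
#' @param x A `cohort`, list of cells, or dataset directory path.
#' @param cb_filter CW-bias filter for the eta / N_eff analyses.
#' @param max_lag_s Cross-correlation lag range (s).
#' @param outdir Optional output directory for TSV tables.
#' @return A list with `per_cell`, `groups`, `power_law` (when >= 2
#'   groups), `max_cw`, `cross_correlation`, `rates`.
#' @export
analyze_dataset <- function(x, cb_filter = c(0, 0.25), max_lag_s = 3,
                            outdir = NULL) {
  cells <- if (is.character(x)) read_dataset(x)$cells else
    as_cell_list(x)
  if (length(cells) == 0) stop("empty dataset", call. = FALSE)
  per_cell <- summarize_cells(cells)
  kept <- filter_cells(per_cell, cb_range = cb_filter,
                       require_eta = TRUE)
  groups <- if (nrow(kept)) fit_n_eff_groups(kept)
  power_law <- if (!is.null(groups) &&
                   length(unique(groups$n_flag)) >= 2)
    fit_power_law(groups)
  max_cw <- mean_max_cw(cells)
  cc <- tryCatch(population_cross_correlation(cells, max_lag_s),
                 error = function(e) NULL)
  rates <- estimate_rates(cells)
  out <- list(per_cell = per_cell, groups = groups,
              power_law = power_law, max_cw = max_cw,
              cross_correlation = cc, rates = rates)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(per_cell, file.path(outdir, "per_cell.tsv"))
    if (!is.null(groups))
      readr::write_tsv(groups, file.path(outdir, "group_fits.tsv"))
    readr::write_tsv(max_cw, file.path(outdir, "max_cw.tsv"))
    if (!is.null(cc))
      readr::write_tsv(cc, file.path(outdir, "cross_correlation.tsv"))
  }
  out
}

#' Calibrate fluctuation parameters from a targets table
#'
#' Thin wrapper around [scan_fluctuation_params()] that accepts the
#' targets as a TSV path (columns `statistic`, `x`, `value`, `sem`) or
#' tibble and optionally writes the chi-squared surface.
#'
#' @param targets Path to a targets TSV or a tibble.
#' @param ... Passed to [scan_fluctuation_params()].
#' @param outdir Optional directory for `chi2_surface.tsv` and
#'   `best_fit.json`.
#' @return A `calibration_grid`.
#' @export
fit_fluctuations <- function(targets, ..., outdir = NULL) {
  if (is.character(targets)) {
    targets <- readr::read_tsv(targets, show_col_types = FALSE)
    needed <- c("statistic", "x", "value", "sem")
    missing <- setdiff(needed, names(targets))
    if (length(missing))
      stop("malformed targets TSV, missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  grid <- scan_fluctuation_params(targets, ...)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(grid$surface, file.path(outdir, "chi2_surface.tsv"))
    jsonlite::write_json(as.list(c(grid$best,
                                   chi2_reduced = grid$chi2_best)),
                         file.path(outdir, "best_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  grid
}

#' Write and read a configuration as YAML
#'
#' Keys mirror the model parameter names of [model_params()] and
#' [population_config()].
#'
#' @param config A `population_config`.
#' @param path File path.
#' @return `read_config()` returns a `population_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(population_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(raw$params)) raw$params <- do.call(model_params, raw$params)
  if (!is.null(raw$nflag_probs))
    raw$nflag_probs <- as.numeric(raw$nflag_probs)
  do.call(population_config, raw)
}
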