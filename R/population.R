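#' Configuration for a synthetic single-cell population
#'
#' Describes the cohort emulated by [sample_population()]: how many
#' cells, the flagellar-number distribution, the spread of per-cell CW
#' bias, trace durations, and the observation window of the emulated
#' image analysis.
#'
#' Defaults mirror the measurement conditions the analyses assume:
#' per-cell mean CW bias 0.11 +/- 0.07 (mean +/- SD, truncated), trace
#' durations uniform on 8-40 s (photobleaching-limited), flagellar state
#' calls in 100-ms windows, and a zero-truncated Poisson flagellar-number
#' distribution with mean 3.4 (a stand-in: the source histograms print
#' no values).
#'
#' @param n_cells Number of cells.
#' @param strain_mode `"wildtype_fluctuating"` (shared CheY-P noise) or
#'   `"constant_cb"` (independent flagella at a fixed per-cell bias).
#' @param nflag_probs Probabilities for flagellar numbers `1..length()`;
#'   default a zero-truncated Poisson(3.4) truncated at 8.
#' @param cb_mean,cb_sd Mean and SD of the per-cell CW bias draw
#'   (truncated normal).
#' @param cb_limits Truncation interval for the per-cell bias draw
#'   (open below).
#' @param duration_range Trace duration interval (s), drawn uniformly.
#' @param window Observation window (s) for [discretize_observations()];
#'   `NULL` keeps full-resolution records.
#' @param heterogeneity For fluctuating mode: `"per_cell_y"` (default)
#'   maps each cell's drawn bias target through the inverse Hill curve
#'   to a per-cell mean CheY-P level; `"population_filter"` keeps the
#'   common `y_mean` and instead screens traces with the acceptance
#'   filter (`accept_on`, `cb_range` of [simulate_cell()]).
#' @param accept_on,cb_range,max_attempts Acceptance-filter settings
#'   passed to [simulate_cell()] (used by `"population_filter"`).
#' @param params A [model_params()] object.
#' @return An object of class `population_config` (named list).
#' @export
population_config <- function(n_cells = 69,
                              strain_mode = c("wildtype_fluctuating",
                                              "constant_cb"),
                              nflag_probs = ztpois_probs(3.4, 8),
                              cb_mean = 0.11, cb_sd = 0.07,
                              cb_limits = c(0, 1),
                              duration_range = c(8, 40), window = 0.1,
                              heterogeneity = c("per_cell_y",
                                                "population_filter"),
                              accept_on = "hill",
                              cb_range = c(0.13, 0.145),
                              max_attempts = 1000,
                              params = model_params()) {
  strain_mode <- match.arg(strain_mode)
  heterogeneity <- match.arg(heterogeneity)
  params <- as_model_params(params)
  stopifnot(n_cells >= 0, all(duration_range > 0),
            is.null(window) || window >= params$dt,
            all(nflag_probs >= 0), sum(nflag_probs) > 0,
            cb_limits[1] >= 0, cb_limits[2] <= 1)
  structure(list(n_cells = n_cells, strain_mode = strain_mode,
                 nflag_probs = nflag_probs / sum(nflag_probs),
                 cb_mean = cb_mean, cb_sd = cb_sd, cb_limits = cb_limits,
                 duration_range = duration_range, window = window,
                 heterogeneity = heterogeneity, accept_on = accept_on,
                 cb_range = cb_range, max_attempts = max_attempts,
                 params = params),
            class = "population_config")
}

#' Zero-truncated Poisson probabilities
#'
#' @param mean_n Mean of the untruncated Poisson.
#' @param max_n Largest supported count.
#' @return Normalized probabilities for counts `1..max_n`.
#' @export
ztpois_probs <- function(mean_n, max_n = 8) {
  p <- stats::dpois(seq_len(max_n), mean_n)
  p / sum(p)
}

# truncated-normal draw by rejection (narrow use: per-cell CW bias)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x <= upper])
  }
  out[seq_len(n)]
}

# inverse of the Hill response: concentration whose CW bias is cb
hill_inverse <- function(cb, params) {
  params$kd * (cb / (1 - cb))^(1 / params$hill_h)
}

#' Sample a synthetic population of observed cells
#'
#' Draws per-cell flagellar number, duration and bias target from the
#' configured population, simulates each cell with [simulate_cell()],
#' and (unless `window` is `NULL`) windows the ground-truth records into
#' observation-style state calls with [discretize_observations()].
#'
#' @param config A [population_config()].
#' @param seed Integer seed; datasets are bitwise reproducible from
#'   `(config, seed)`.
#' @return An object of class `cohort`: list with `cells` (the
#'   analysis-facing records — windowed observations when a window is
#'   configured), `truth` (full-resolution `cell_record`s), `config` and
#'   `seed`.
#' @export
sample_population <- function(config = population_config(), seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)
  n <- config$n_cells
  if (n == 0)
    return(structure(list(cells = list(), truth = list(),
                          config = config, seed = seed),
                     class = "cohort"))
  n_flag <- sample.int(length(config$nflag_probs), n, replace = TRUE,
                       prob = config$nflag_probs)
  duration <- stats::runif(n, config$duration_range[1],
                           config$duration_range[2])
  cb_target <- rtruncnorm(n, config$cb_mean, config$cb_sd,
                          config$cb_limits[1], config$cb_limits[2])
  cell_seeds <- sample.int(.Machine$integer.max, n)

  truth <- purrr::map(seq_len(n), function(i) {
    if (config$strain_mode == "constant_cb") {
      cell <- simulate_cell(n_flag[i], duration[i], config$params,
                            strain_mode = "constant_cb",
                            cb = cb_target[i], seed = cell_seeds[i])
    } else if (config$heterogeneity == "per_cell_y") {
      p <- config$params
      p$y_mean <- hill_inverse(cb_target[i], p)
      cell <- simulate_cell(n_flag[i], duration[i], p,
                            strain_mode = "wildtype_fluctuating",
                            accept_on = "none", seed = cell_seeds[i])
    } else {
      cell <- simulate_cell(n_flag[i], duration[i], config$params,
                            strain_mode = "wildtype_fluctuating",
                            accept_on = config$accept_on,
                            cb_range = config$cb_range,
                            max_attempts = config$max_attempts,
                            seed = cell_seeds[i])
    }
    cell$cell_id <- sprintf("cell_%03d", i)
    cell
  })
  cells <- if (is.null(config$window)) truth else
    purrr::map(truth, discretize_observations, window = config$window)
  structure(list(cells = cells, truth = truth, config = config,
                 seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cells (%s, %s)\n", length(x$cells),
              x$config$strain_mode,
              if (is.null(x$config$window)) "full resolution"
              else sprintf("%g-s windows", x$config$window)))
  invisible(x)
}

majority_calls <- function(states, win_index, alphabet) {
  # per-window majority vote; exact ties carry the previous window's call
  counts <- vapply(alphabet,
                   function(s) rowsum((states == s) + 0, win_index)[, 1],
                   numeric(length(unique(win_index))))
  counts <- matrix(counts, ncol = length(alphabet))
  call <- integer(nrow(counts))
  prev <- alphabet[1]
  for (i in seq_len(nrow(counts))) {
    mx <- max(counts[i, ])
    top <- alphabet[counts[i, ] == mx]
    call[i] <- if (length(top) == 1) top else if (prev %in% top) prev
      else top[1]
    prev <- call[i]
  }
  call
}

#' Window a ground-truth record into observation-style state calls
#'
#' Emulates the image-analysis observation process: within each window
#' (100 ms by default) the motor, waveform and run/tumble calls are each
#' the majority state among the full-resolution samples; exact ties
#' carry the previous window's call. Because motor dwell times are much
#' longer than the window, windowed biases track the full-resolution
#' truth closely (within ~0.02 at the default parameters).
#'
#' @param cell A `cell_record`.
#' @param window Window length (s), at least one time step.
#' @return An object of class `observed_cell` with windowed `motor`,
#'   `waveform` and `run` series plus metadata.
#' @export
discretize_observations <- function(cell, window = 0.1) {
  stopifnot(inherits(cell, "cell_record"))
  if (window < cell$dt)
    stop("window must be at least one time step", call. = FALSE)
  n <- nrow(cell$motor)
  per <- max(1L, round(window / cell$dt))
  n_win <- floor(n / per)
  idx <- seq_len(n_win * per)
  win <- rep(seq_len(n_win), each = per)
  motor <- vapply(seq_len(cell$n_flag), function(k)
    majority_calls(cell$motor[idx, k], win, c(0L, 1L)), integer(n_win))
  wf <- if (!is.null(cell$waveform))
    vapply(seq_len(cell$n_flag), function(k)
      majority_calls(cell$waveform[idx, k], win,
                     unname(waveform_levels)), integer(n_win))
  run <- majority_calls(as.integer(cell$run[idx]), win, c(0L, 1L)) == 1L
  structure(list(cell_id = cell$cell_id, n_flag = cell$n_flag,
                 window = window, duration = n_win * window,
                 strain = cell$strain_mode,
                 motor = matrix(motor, nrow = n_win),
                 waveform = if (!is.null(wf)) matrix(wf, nrow = n_win),
                 run = run),
            class = "observed_cell")
}

#' @export
print.observed_cell <- function(x, ...) {
  cat(sprintf("<observed_cell> %s: %d flagella, %d windows of %g s\n",
              x$cell_id %||% "?", x$n_flag, nrow(x$motor), x$window))
  invisible(x)
}
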