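#' Simulate a single flagellar motor (telegraph process)
#'
#' Fixed-step simulation of the two-state CCW/CW motor: at each step a
#' CCW motor switches CW with probability `cb(t)/omega * dt` and a CW
#' motor switches CCW with probability `(1 - cb(t))/omega * dt`, so the
#' stationary CW occupancy tracks the driving bias `cb(t)` and mean
#' dwell times are `omega/(1-cb)` (CW) and `omega/cb` (CCW). The initial
#' state is drawn Bernoulli(`cb(0)`).
#'
#' @param cb Instantaneous CW-bias series in `[0,1]`, or a single
#'   constant bias (then `duration` is required).
#' @param omega Characteristic motor switching time (s).
#' @param dt Time step (s). `dt * max(rate)` must not exceed 0.1.
#' @param duration Trace length (s) when `cb` is a constant.
#' @param seed Optional integer seed.
#' @return Integer vector of motor states (0 = CCW, 1 = CW).
#' @examples
#' m <- simulate_motor(0.13, duration = 10, seed = 1)
#' mean(m)  # ~0.13
#' @export
simulate_motor <- function(cb, omega = 0.5, dt = 0.001, duration = NULL,
                           seed = NULL) {
  if (any(cb < 0 | cb > 1)) stop("`cb` must lie in [0,1]", call. = FALSE)
  if (length(cb) == 1) {
    if (is.null(duration))
      stop("supply `duration` with a constant bias", call. = FALSE)
    cb <- rep(cb, round(duration / dt))
  }
  max_rate <- max(cb, 1 - cb) / omega
  if (max_rate * dt > 0.1)
    stop("dt * max(rate) exceeds 0.1: reduce dt for a stable ",
         "discretization", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  motor_sim_cpp(cb, omega, dt, -1L)
}

#' Overlay the three-state filament waveform on a motor trace
#'
#' Converts a binary CCW/CW motor trace into a waveform trace over
#' \{normal, semi-coiled, curly-1\}. CCW intervals are `normal`. At each
#' CCW->CW switch the filament enters `curly-1` with probability
#' `r_nc/(r_ns + r_nc)` (ratio of the normal-exit rates; 0.222 at the
#' defaults) and `semi-coiled` otherwise; within a CW interval
#' semi-coiled converts to curly-1 at rate `lambda_sc` and curly-1 never
#' reverts; the CW->CCW switch returns the filament to normal.
#'
#' @param motor Integer motor trace from [simulate_motor()].
#' @param params A [model_params()] object (`r_ns`, `r_nc`, `lambda_sc`).
#' @param dt Time step (s).
#' @param seed Optional integer seed.
#' @return Integer vector of waveform codes (0 = normal, 1 =
#'   semi-coiled, 2 = curly-1); see [waveform_levels].
#' @export
overlay_waveforms <- function(motor, params = model_params(),
                              dt = params$dt, seed = NULL) {
  params <- as_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  p_curly <- params$r_nc / (params$r_ns + params$r_nc)
  waveform_overlay_cpp(as.integer(motor), p_curly, params$lambda_sc, dt)
}

#' Waveform state codes
#'
#' Integer codes used in waveform traces: 0 `normal`, 1 `semi_coiled`,
#' 2 `curly_1`.
#' @format A named integer vector.
#' @export
waveform_levels <- c(normal = 0L, semi_coiled = 1L, curly_1 = 2L)

#' Run/tumble assignment from per-flagellum waveform traces
#'
#' The default veto rule is a logical AND over flagella: the cell runs
#' at a time step iff every flagellum is `normal` (CCW), and tumbles
#' otherwise. Two refinements can be enabled:
#' \describe{
#'   \item{curly-run rule}{each maximal contiguous interval in which
#'     exactly one flagellum is `curly-1` and all others `normal` is
#'     relabelled a run with probability `curly_run_prob` (one Bernoulli
#'     draw per interval; 0.18 by default), reflecting the observation
#'     that cells still run a minority of the time with a single curly-1
#'     filament.}
#'   \item{X-rule}{time steps with at least `x_rule` normal flagella and
#'     every CW flagellum in `curly-1` are runs (no randomness). The
#'     plain veto rule is `x_rule = n_flag`.}
#' }
#'
#' @param waveforms Integer matrix (time steps x flagella) of waveform
#'   codes, or a list of equal-length waveform vectors.
#' @param params A [model_params()] object (`curly_run_prob`).
#' @param rule `"veto"` (default), `"curly_run"` or `"x_rule"`.
#' @param x_rule Threshold for the X-rule variant, `1 <= X <= n_flag`.
#' @param seed Optional integer seed (used by the curly-run draws).
#' @return Logical vector, `TRUE` where the cell runs.
#' @export
apply_run_rule <- function(waveforms, params = model_params(),
                           rule = c("veto", "curly_run", "x_rule"),
                           x_rule = NULL, seed = NULL) {
  rule <- match.arg(rule)
  params <- as_model_params(params)
  if (is.list(waveforms)) {
    lens <- lengths(waveforms)
    if (length(unique(lens)) != 1)
      stop("waveform traces must have equal length", call. = FALSE)
    waveforms <- do.call(cbind, waveforms)
  }
  w <- as.matrix(waveforms)
  n_flag <- ncol(w)
  n_normal <- rowSums(w == waveform_levels[["normal"]])
  n_semi <- rowSums(w == waveform_levels[["semi_coiled"]])
  n_curly <- rowSums(w == waveform_levels[["curly_1"]])
  run <- n_normal == n_flag
  if (rule == "x_rule") {
    if (is.null(x_rule) || x_rule < 1 || x_rule > n_flag)
      stop("`x_rule` must satisfy 1 <= X <= n_flag", call. = FALSE)
    run <- run | (n_normal >= x_rule & n_semi == 0)
  } else if (rule == "curly_run") {
    if (!is.null(seed)) set.seed(seed)
    eligible <- n_curly == 1 & n_semi == 0
    r <- rle(eligible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      if (stats::runif(1) < params$curly_run_prob)
        run[starts[j]:ends[j]] <- TRUE
    }
  }
  run
}

#' Simulate a whole cell: shared signal, independent motors
#'
#' Builds one cell record: a single instantaneous CW-bias series drives
#' all `n_flag` motors (each with its own noise stream), the filament
#' waveform is overlaid per flagellum, and the run/tumble series is
#' assigned by [apply_run_rule()].
#'
#' In `"wildtype_fluctuating"` mode the bias series is the
#' Hill-transformed CheY-P trace, regenerated until the trace-acceptance
#' filter passes (see `accept_on`). In `"constant_cb"` mode the bias is
#' fixed at `cb` and the flagella switch independently, so the measured
#' tumble bias satisfies the veto prediction `1 - TB = (1 - CB)^n_flag`
#' up to sampling error.
#'
#' @param n_flag Number of flagella (>= 1).
#' @param duration Trace length (s).
#' @param params A [model_params()] object.
#' @param strain_mode `"wildtype_fluctuating"` or `"constant_cb"`.
#' @param cb Fixed clockwise bias for `constant_cb` mode (defaults to
#'   `params$cb`).
#' @param accept_on Acceptance statistic for fluctuating mode:
#'   `"hill"` (default; the time-average of the Hill-transformed bias
#'   of the CheY-P trace must lie in `cb_range`), `"occupancy"` (the
#'   cell's realized mean CW bias averaged over flagella), or `"none"`.
#' @param cb_range Acceptance interval for the mean CW bias.
#' @param max_attempts Regeneration cap for the acceptance filter.
#' @param rule,x_rule Run/tumble rule, as in [apply_run_rule()].
#' @param waveforms If `FALSE`, skip the waveform overlay (the run rule
#'   then reduces to the motor-state veto).
#' @param seed Optional integer seed; fixed seeds give bitwise
#'   reproducible cells.
#' @return An object of class `cell_record`: a list with the motor and
#'   waveform state matrices, the run/tumble series, the driving bias
#'   series, the CheY-P trace (fluctuating mode), and metadata. Use
#'   [tidy()][generics::tidy] for a long-format tibble.
#' @examples
#' cell <- simulate_cell(3, 20, strain_mode = "constant_cb", seed = 1)
#' cell_tumble_bias(cell)
#' @export
simulate_cell <- function(n_flag, duration, params = model_params(),
                          strain_mode = c("wildtype_fluctuating",
                                          "constant_cb"),
                          cb = NULL,
                          accept_on = c("hill", "occupancy", "none"),
                          cb_range = c(0.13, 0.145), max_attempts = 1000,
                          rule = "veto", x_rule = NULL, waveforms = TRUE,
                          seed = NULL) {
  strain_mode <- match.arg(strain_mode)
  accept_on <- match.arg(accept_on)
  params <- as_model_params(params)
  stopifnot(n_flag >= 1)
  n_steps <- round(duration / params$dt)
  if (n_steps < 1) stop("duration shorter than one step", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  # substreams: one per motor, one per waveform overlay, one for the
  # CheY-P/acceptance loop, one for the run rule
  sub <- derive_seeds(seed, 2L * n_flag + 2L)

  if (strain_mode == "constant_cb") {
    cb <- if (is.null(cb)) params$cb else cb
    cb_series <- rep(cb, n_steps)
    chey <- NULL
    attempts <- 1L
    motors <- vapply(seq_len(n_flag), function(k) {
      simulate_motor(cb, params$omega, params$dt, duration, seed = sub[k])
    }, integer(n_steps))
    motors <- matrix(motors, nrow = n_steps)
  } else {
    mode <- c(none = 0L, hill = 1L, occupancy = 2L)[[accept_on]]
    set.seed(sub[2L * n_flag + 1L])
    res <- fluctuating_cell_cpp(n_steps, n_flag, params$y_mean, params$dt,
                                params$tau, ou_amplitude(params),
                                params$kd, params$hill_h, params$omega,
                                cb_range[1], cb_range[2], mode,
                                max_attempts)
    if (!res$accepted)
      stop(errorCondition(
        sprintf("cell rejected by the trace-acceptance filter %d times",
                max_attempts),
        tried_means = res$tried_means,
        class = c("runtumble_acceptance_error", "error")))
    chey <- res$y
    cb_series <- res$cb
    motors <- res$motors
    attempts <- res$attempts
  }

  wf <- if (waveforms) {
    m <- vapply(seq_len(n_flag), function(k) {
      overlay_waveforms(motors[, k], params, params$dt,
                        seed = sub[n_flag + k])
    }, integer(n_steps))
    matrix(m, nrow = n_steps)
  } else {
    # without the overlay, CW maps to semi-coiled so the veto is unchanged
    matrix(as.integer(motors), nrow = n_steps)
  }
  run <- apply_run_rule(wf, params, rule = rule, x_rule = x_rule,
                        seed = sub[2L * n_flag + 2L])

  structure(list(n_flag = n_flag, dt = params$dt, duration = duration,
                 strain_mode = strain_mode, motor = motors, waveform = wf,
                 run = run, cb_series = cb_series, chey = chey,
                 cb_driving = if (strain_mode == "constant_cb") cb else NA,
                 attempts = attempts, seed = seed, params = params),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s, %d flagella, %.1f s at dt = %g s\n",
              x$strain_mode, x$n_flag, x$duration, x$dt))
  cat(sprintf("  measured CB = %.3f, TB = %.3f (attempts = %d)\n",
              cell_cw_bias(x), cell_tumble_bias(x), x$attempts))
  invisible(x)
}

#' @rdname simulate_cell
#' @param x,... A `cell_record`; further arguments ignored.
#' @export
tidy.cell_record <- function(x, ...) {
  n <- nrow(x$motor)
  wf_names <- names(waveform_levels)
  purrr::map_dfr(seq_len(x$n_flag), function(k) {
    tibble::tibble(
      time_s = seq_len(n) * x$dt,
      flagellum_id = k,
      motor_state = c("CCW", "CW")[x$motor[, k] + 1L],
      waveform_state = wf_names[match(x$waveform[, k], waveform_levels)],
      run_state = ifelse(x$run, "run", "tumble"))
  })
}
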