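#' Simulate a CheY-P concentration time trace
#'
#' Integrates the mean-reverting (Ornstein-Uhlenbeck) recursion
#' `Y(t+dt) = Y(t) - (Y(t) - <Y>)/tau * dt + A * xi`, with `xi` a standard
#' normal draw per step, `Y(0) = <Y>`, and values clipped at zero inside
#' the recursion. The per-step amplitude `A` is `sqrt(sigma2*dt/tau)` in
#' `"verbatim"` noise mode (stationary variance `sigma2/2`) or
#' `sqrt(2*sigma2*dt/tau)` in `"variance_matched"` mode (stationary
#' variance `sigma2`).
#'
#' @param duration Trace length (s), at least one step.
#' @param params A [model_params()] object.
#' @param seed Optional integer seed; identical inputs give a bitwise
#'   identical trace.
#' @return A tibble of class `chey_trace` with columns `time_s` and
#'   `y_uM`; attributes `dt` and `seed`.
#' @examples
#' tr <- simulate_chey_trace(1, model_params(), seed = 1)
#' mean(tr$y_uM)
#' @export
simulate_chey_trace <- function(duration, params = model_params(),
                                seed = NULL) {
  params <- as_model_params(params)
  n <- round(duration / params$dt)
  if (n < 1) stop("duration must be at least one time step", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- ou_sim_cpp(n, params$y_mean, params$y_mean, params$dt, params$tau,
                  ou_amplitude(params))
  out <- tibble::tibble(time_s = seq_len(n) * params$dt, y_uM = y)
  class(out) <- c("chey_trace", class(out))
  attr(out, "dt") <- params$dt
  attr(out, "seed") <- seed
  out
}

#' Instantaneous CW bias from CheY-P concentration
#'
#' Hill response curve `CB(Y) = Y^H / (Kd^H + Y^H)`: strictly increasing
#' in `Y`, equal to 1/2 at the midpoint `Kd`, and satisfying the
#' reflection symmetry `CB(Kd*x) + CB(Kd/x) = 1`.
#'
#' @param y CheY-P concentration (uM), nonnegative (vectorized).
#' @param params A [model_params()] object supplying `kd` and `hill_h`
#'   (individual values may be overridden).
#' @param kd,hill_h Optional overrides of the curve parameters.
#' @return CW bias in `[0, 1)`.
#' @examples
#' hill_cw_bias(3.1)   # 0.5 at the midpoint
#' hill_cw_bias(2.59)  # ~0.1356
#' @export
hill_cw_bias <- function(y, params = model_params(), kd = params$kd,
                         hill_h = params$hill_h) {
  if (any(y < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative", call. = FALSE)
  hill_cpp(as.numeric(y), kd, hill_h)
}

trace_values <- function(trace) {
  if (is.data.frame(trace)) trace$y_uM else as.numeric(trace)
}

#' Trace-acceptance filter on the mean CW bias
#'
#' Checks that the time-averaged Hill-transformed CW bias of a CheY-P
#' trace lies inside `cb_range`, emulating the screening of simulated
#' traces against the measured population mean. Rejected traces are
#' regenerated with fresh noise by [simulate_accepted_chey()].
#'
#' @param trace A `chey_trace` tibble or numeric vector of
#'   concentrations.
#' @param params A [model_params()] object (Hill curve parameters).
#' @param cb_range Closed acceptance interval for the mean CW bias.
#' @return `TRUE` if the trace is accepted.
#' @export
accept_trace <- function(trace, params = model_params(),
                         cb_range = c(0.13, 0.145)) {
  y <- trace_values(trace)
  if (length(y) == 0) stop("empty trace", call. = FALSE)
  m <- mean(hill_cw_bias(y, params))
  m >= cb_range[1] && m <= cb_range[2]
}

#' @rdname accept_trace
#' @inheritParams simulate_chey_trace
#' @param max_attempts Attempt cap before a calibration error is raised;
#'   the error condition carries the attempted mean-CB values in its
#'   `tried_means` field.
#' @return `simulate_accepted_chey()` returns an accepted `chey_trace`
#'   with an `attempts` attribute.
#' @export
simulate_accepted_chey <- function(duration, params = model_params(),
                                   cb_range = c(0.13, 0.145),
                                   max_attempts = 1000, seed = NULL) {
  params <- as_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  tried <- numeric(0)
  for (att in seq_len(max_attempts)) {
    tr <- simulate_chey_trace(duration, params)
    m <- mean(hill_cw_bias(tr$y_uM, params))
    if (m >= cb_range[1] && m <= cb_range[2]) {
      attr(tr, "attempts") <- att
      return(tr)
    }
    tried <- c(tried, m)
  }
  stop(errorCondition(
    sprintf("no CheY-P trace accepted in %d attempts (mean CB %.3f +/- %.3f)",
            max_attempts, mean(tried), stats::sd(tried)),
    tried_means = tried, class = c("runtumble_acceptance_error", "error")))
}
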