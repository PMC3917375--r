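#' Model parameters for the chemotaxis swimming simulator
#'
#' Bundles every tunable constant of the stochastic model in one validated
#' record: the motor switching time, the CheY-P fluctuation process, the
#' Hill response curve mapping CheY-P concentration to instantaneous CW
#' bias, and the flagellar waveform kinetics used by the run/tumble rules.
#'
#' Defaults are the wild-type operating point of the model: a motor
#' switching time `omega` of 0.5 s together with an average CW bias of
#' 0.13 implies CCW->CW and CW->CCW rates of 0.26 and 1.74 s^-1 (see
#' [motor_rates()]). The CheY-P process has mean 2.59 uM (whose Hill
#' image is CB = 0.1356), fluctuation variance `sigma2` = 1.0 uM^2 and
#' relaxation rate 0.2 s^-1, i.e. timescale `tau` = 5 s, and the
#' response curve has midpoint 3.1 uM and Hill coefficient 10.3.
#'
#' The fluctuation timescale deserves a note: the source measurements
#' are reported once as a time ("0.2 s") and once as a rate
#' ("0.2 s^-1"). This package adopts the rate reading (`tau` = 1/0.2 =
#' 5 s) because seconds-scale signaling fluctuations are what the
#' underlying network models predict, because the trace-acceptance
#' screening of simulated CheY-P traces is only practicable with a
#' slow timescale, and because only this reading reproduces the
#' multi-flagellar effective-flagellar-number renormalization (see the
#' methods vignette). Pass `tau = 0.2` to explore the fast reading.
#'
#' @param omega Characteristic motor switching time (s).
#' @param cb Population-average clockwise bias of a single motor, used to
#'   derive the telegraph rates in constant-bias simulations.
#' @param y_mean Mean CheY-P concentration (uM).
#' @param sigma2 CheY-P fluctuation variance parameter (uM^2). In the
#'   default `"variance_matched"` noise mode the per-step amplitude is
#'   `sqrt(2*sigma2*dt/tau)`, so the stationary variance of the process
#'   equals `sigma2` (the quantity the model tables call the variance in
#'   [CheY-P]); in `"verbatim"` mode the amplitude is
#'   `sqrt(sigma2*dt/tau)` (the recursion as printed) and the stationary
#'   variance is `sigma2/2`.
#' @param tau Characteristic timescale of CheY-P fluctuations (s); the
#'   OU relaxation rate is `1/tau`.
#' @param kd Midpoint of the CW bias vs CheY-P response curve (uM).
#' @param hill_h Hill coefficient of the response curve (dimensionless).
#' @param lambda_sc Semi-coiled to curly-1 waveform conversion rate (s^-1).
#' @param r_ns,r_nc Normal-exit waveform rates (s^-1) into semi-coiled and
#'   curly-1 respectively; only their ratio matters for the entry
#'   branching probability `r_nc/(r_ns + r_nc)` = 0.222.
#' @param curly_run_prob Probability that a maximal interval with exactly
#'   one curly-1 flagellum (all others normal) is relabelled a run when
#'   the curly-run rule is enabled.
#' @param dt Simulation time step (s).
#' @param noise_mode `"variance_matched"` (default) or `"verbatim"`
#'   (see `sigma2`).
#' @return An object of class `model_params` (a named list).
#' @seealso [motor_rates()], [simulate_cell()], [simulate_chey_trace()]
#' @examples
#' p <- model_params()
#' hill_cw_bias(p$y_mean, p)  # ~0.136, the wild-type operating CW bias
#' @export
model_params <- function(omega = 0.5, cb = 0.13, y_mean = 2.59,
                         sigma2 = 1.0, tau = 5, kd = 3.1, hill_h = 10.3,
                         lambda_sc = 0.68, r_ns = 0.28, r_nc = 0.08,
                         curly_run_prob = 0.18, dt = 0.001,
                         noise_mode = c("variance_matched", "verbatim")) {
  noise_mode <- match.arg(noise_mode)
  p <- list(omega = omega, cb = cb, y_mean = y_mean, sigma2 = sigma2,
            tau = tau, kd = kd, hill_h = hill_h, lambda_sc = lambda_sc,
            r_ns = r_ns, r_nc = r_nc, curly_run_prob = curly_run_prob,
            dt = dt, noise_mode = noise_mode)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  stopifnot(
    "omega must be > 0" = p$omega > 0,
    "cb must be in [0,1]" = p$cb >= 0 && p$cb <= 1,
    "y_mean must be > 0" = p$y_mean > 0,
    "sigma2 must be >= 0" = p$sigma2 >= 0,
    "tau must be > 0" = p$tau > 0,
    "dt must satisfy 0 < dt < tau" = p$dt > 0 && p$dt < p$tau,
    "kd must be > 0" = p$kd > 0,
    "hill coefficient must be > 0" = p$hill_h > 0,
    "waveform rates must be >= 0" =
      p$lambda_sc >= 0 && p$r_ns >= 0 && p$r_nc >= 0,
    "normal-exit rates must not both be zero" = p$r_ns + p$r_nc > 0,
    "curly_run_prob must be in [0,1]" =
      p$curly_run_prob >= 0 && p$curly_run_prob <= 1
  )
  invisible(p)
}

as_model_params <- function(p) {
  if (inherits(p, "model_params")) return(p)
  do.call(model_params, p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  motor:    omega = %g s, cb = %g (k_ccw_cw = %g, k_cw_ccw = %g s^-1)\n",
              x$omega, x$cb, x$cb / x$omega, (1 - x$cb) / x$omega))
  cat(sprintf("  CheY-P:   <Y> = %g uM, sigma2 = %g uM^2, tau = %g s (%s)\n",
              x$y_mean, x$sigma2, x$tau, x$noise_mode))
  cat(sprintf("  response: Kd = %g uM, H = %g\n", x$kd, x$hill_h))
  cat(sprintf("  waveform: lambda_sc = %g s^-1, entry curly-1 prob = %.3f\n",
              x$lambda_sc, x$r_nc / (x$r_ns + x$r_nc)))
  cat(sprintf("  dt = %g s\n", x$dt))
  invisible(x)
}

#' Telegraph switching rates implied by a CW bias and motor time
#'
#' The two-state motor switches CCW->CW at rate `cb/omega` and CW->CCW at
#' `(1-cb)/omega`, so that the stationary CW occupancy is `cb` and the
#' relaxation time of the telegraph process is `omega`.
#'
#' @param cb Clockwise bias in `[0,1]` (vectorized).
#' @param omega Characteristic motor switching time (s).
#' @return A tibble with columns `k_ccw_cw` and `k_cw_ccw` (s^-1).
#' @examples
#' motor_rates(0.13, 0.5)  # 0.26 and 1.74 s^-1
#' @export
motor_rates <- function(cb, omega = 0.5) {
  stopifnot(all(cb >= 0 & cb <= 1), omega > 0)
  tibble::tibble(k_ccw_cw = cb / omega, k_cw_ccw = (1 - cb) / omega)
}

# per-step OU noise amplitude for the configured noise mode
ou_amplitude <- function(p) {
  base <- p$sigma2 * p$dt / p$tau
  sqrt(if (p$noise_mode == "variance_matched") 2 * base else base)
}

# Derive reproducible child seeds from one integer seed. Used to give
# flagella and cells independent substreams.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
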