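#' Tumble bias predicted by the veto model
#'
#' Under the veto model a cell runs only while every one of its `n`
#' flagella rotates CCW; any single CW flagellum vetoes the run. For
#' independently switching flagella with common clockwise bias `cb` the
#' tumble bias is therefore `TB = 1 - (1 - CB)^n`. Real-valued `n` is
#' allowed so the same curve serves the effective-flagellar-number
#' generalization `1 - TB = (1 - CB)^N_eff`.
#'
#' @param cb Clockwise bias in `[0,1]` (vectorized).
#' @param n Flagellar number, real, `>= 0` (vectorized).
#' @return Tumble bias in `[0,1]`, monotone nondecreasing in both
#'   arguments.
#' @examples
#' veto_tumble_bias(0.13, 1:5)
#' @export
veto_tumble_bias <- function(cb, n) {
  if (any(cb < 0 | cb > 1, na.rm = TRUE))
    stop("`cb` must lie in [0, 1]", call. = FALSE)
  if (any(n < 0, na.rm = TRUE))
    stop("`n` must be nonnegative", call. = FALSE)
  1 - (1 - cb)^n
}

#' Deviation from the veto model
#'
#' The statistic `eta = log(1 - TB) / log(1 - CB) - N_flag` compares the
#' number of independent flagella implied by a cell's swimming behavior
#' with the number counted directly. It is exactly zero when the measured
#' tumble bias satisfies the veto prediction, and negative when flagella
#' switch in a correlated fashion (the cell tumbles less than `N_flag`
#' independent flagella would).
#'
#' @param tb Measured tumble bias, `0 <= tb < 1` (vectorized).
#' @param cb Measured clockwise bias, `0 < cb < 1` (vectorized).
#' @param n_flag Counted flagellar number (vectorized).
#' @return The deviation statistic (dimensionless).
#' @examples
#' deviation_eta(veto_tumble_bias(0.13, 3), 0.13, 3)  # 0
#' @export
deviation_eta <- function(tb, cb, n_flag) {
  if (any(cb <= 0 | cb >= 1, na.rm = TRUE))
    stop("eta is undefined for cb <= 0 or cb >= 1; exclude such cells",
         call. = FALSE)
  if (any(tb < 0 | tb >= 1, na.rm = TRUE))
    stop("eta is undefined for tb >= 1; exclude such cells", call. = FALSE)
  log1p(-tb) / log1p(-cb) - n_flag
}

# eta with NA (not an error) for undefined cells; used by summaries
eta_or_na <- function(tb, cb, n_flag) {
  ok <- !is.na(tb) & !is.na(cb) & cb > 0 & cb < 1 & tb >= 0 & tb < 1
  out <- rep(NA_real_, length(ok))
  out[ok] <- log1p(-tb[ok]) / log1p(-cb[ok]) - n_flag[ok]
  out
}

drop_degenerate_cells <- function(data, warn = TRUE) {
  ok <- data$cb > 0 & data$cb < 1 & data$tb >= 0 & data$tb < 1
  if (warn && any(!ok))
    warning(sum(!ok), " cell(s) with cb in {0,1} or tb = 1 excluded ",
            "from fitting", call. = FALSE)
  data[ok, , drop = FALSE]
}

#' Fit the effective flagellar number to a group of cells
#'
#' Finds the exponent `N_eff` minimizing the sum of squared tumble-bias
#' residuals `sum((tb_i - (1 - (1 - cb_i)^N_eff))^2)` over the cells of
#' one flagellar-number group, i.e. fits the generalized veto curve
#' `1 - TB = (1 - CB)^N_eff` by ordinary least squares in TB-space. For a
#' single cell the closed form `log(1 - tb) / log(1 - cb)` is returned.
#' The alternative `objective = "log"` fits in log-survival space, where
#' the estimate has the closed form
#' `sum(x_i y_i) / sum(x_i^2)` with `x = log(1 - cb)`, `y = log(1 - tb)`.
#'
#' @param data A data frame with numeric columns `tb` and `cb` (one row
#'   per cell). Degenerate cells (`cb` of 0 or 1, `tb = 1`) are dropped
#'   with a warning.
#' @param objective `"tb"` (default) for least squares on the tumble-bias
#'   scale, `"log"` for least squares on `log(1 - TB)`.
#' @param bounds Search interval for `N_eff`.
#' @param n_flag Optional group label carried into the result.
#' @return An object of class `neff_fit` with elements `n_eff`,
#'   `r_squared` (of the fitted curve in TB-space), `n_cells`, `n_flag`
#'   and `objective`. [tidy()][generics::tidy] returns it as a one-row
#'   tibble.
#' @examples
#' cells <- tibble::tibble(cb = c(0.1, 0.15, 0.2),
#'                         tb = veto_tumble_bias(cb, 2))
#' fit_n_eff(cells)$n_eff  # 2
#' @export
fit_n_eff <- function(data, objective = c("tb", "log"),
                      bounds = c(1e-6, 20), n_flag = NA_real_) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(data), all(c("tb", "cb") %in% names(data)))
  if (nrow(data) == 0) stop("no cells supplied", call. = FALSE)
  data <- drop_degenerate_cells(data)
  if (nrow(data) == 0)
    stop("no non-degenerate cells remain", call. = FALSE)
  x <- log1p(-data$cb)
  y <- log1p(-data$tb)
  closed <- y / x
  n_eff <- if (nrow(data) == 1) {
    closed
  } else if (objective == "log") {
    sum(x * y) / sum(x^2)
  } else {
    sse <- function(n) sum((data$tb - veto_tumble_bias(data$cb, n))^2)
    # multistart around the per-cell closed-form solutions guards against
    # flat stretches of the objective at extreme bounds
    starts <- unique(pmin(pmax(stats::median(closed), bounds[1]), bounds[2]))
    opt <- stats::optimize(sse, bounds, tol = 1e-9)
    for (s in starts) {
      local <- stats::optimize(sse, c(max(bounds[1], s / 4),
                                      min(bounds[2], s * 4)), tol = 1e-9)
      if (local$objective < opt$objective) opt <- local
    }
    opt$minimum
  }
  r2 <- if (nrow(data) >= 2 && stats::var(data$tb) > 0)
    r_squared_fixed(data, n_eff) else NA_real_
  structure(list(n_eff = n_eff, r_squared = r2, n_cells = nrow(data),
                 n_flag = n_flag, objective = objective),
            class = "neff_fit")
}

#' @export
print.neff_fit <- function(x, ...) {
  cat(sprintf("<neff_fit> N_eff = %.4f (R^2 = %s, %d cells%s)\n",
              x$n_eff,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              x$n_cells,
              if (is.na(x$n_flag)) "" else sprintf(", N_flag = %g", x$n_flag)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_n_eff
#' @param x,... An `neff_fit` object; further arguments ignored.
#' @export
tidy.neff_fit <- function(x, ...) {
  tibble::tibble(n_flag = x$n_flag, n_eff = x$n_eff,
                 r_squared = x$r_squared, n_cells = x$n_cells)
}

#' @rdname fit_n_eff
#' @export
glance.neff_fit <- function(x, ...) tidy(x)

r_squared_fixed <- function(data, n_curve) {
  pred <- veto_tumble_bias(data$cb, n_curve)
  ss_res <- sum((data$tb - pred)^2)
  ss_tot <- sum((data$tb - mean(data$tb))^2)
  1 - ss_res / ss_tot
}

#' Coefficient of determination against a fixed veto curve
#'
#' Scores how well the fixed curve `TB = 1 - (1 - CB)^n_curve` describes
#' a set of cells, without refitting: `R^2 = 1 - SS_res / SS_tot` where
#' residuals are taken from the fixed curve and the total sum of squares
#' from the mean tumble bias. Used to quantify how the naive prediction
#' (with `n_curve` equal to the counted flagellar number) fails for
#' multi-flagellated wild-type cells. May be negative.
#'
#' @inheritParams fit_n_eff
#' @param n_curve Exponent of the fixed curve.
#' @return A single numeric value `<= 1`.
#' @export
curve_r_squared <- function(data, n_curve) {
  stopifnot(is.data.frame(data), all(c("tb", "cb") %in% names(data)))
  if (nrow(data) < 2)
    stop("need at least two cells", call. = FALSE)
  if (stats::var(data$tb) == 0)
    stop("zero tumble-bias variance: R^2 undefined", call. = FALSE)
  r_squared_fixed(data, n_curve)
}

#' Fit the generalized veto curve within each flagellar-number group
#'
#' Convenience wrapper around [fit_n_eff()] that groups a per-cell
#' summary table by `n_flag` and returns one fitted `N_eff` per group.
#'
#' @param data A data frame with columns `n_flag`, `tb`, `cb`.
#' @inheritParams fit_n_eff
#' @return A tibble with columns `n_flag`, `n_eff`, `r_squared`,
#'   `n_cells`, suitable for [fit_power_law()].
#' @export
fit_n_eff_groups <- function(data, objective = c("tb", "log"),
                             bounds = c(1e-6, 20)) {
  objective <- match.arg(objective)
  stopifnot("n_flag" %in% names(data))
  data |>
    dplyr::group_by(.data$n_flag) |>
    dplyr::group_map(function(g, key) {
      tidy(fit_n_eff(g, objective = objective, bounds = bounds,
                     n_flag = key$n_flag[[1]]))
    }) |>
    dplyr::bind_rows()
}

#' Power-law summary of effective vs actual flagellar number
#'
#' Fits `N_eff = a * N_flag^b` across flagellar-number groups by
#' unweighted least squares in log-log space,
#' `log(n_eff) = log(a) + b * log(n_flag)`.
#'
#' @param group_fits A data frame with columns `n_flag` and `n_eff`
#'   (e.g. from [fit_n_eff_groups()]); at least two distinct `n_flag`
#'   values, all `n_eff > 0`.
#' @return An object of class `powerlaw_fit` with elements `a`
#'   (prefactor), `b` (exponent) and the underlying `lm` fit.
#' @examples
#' fit_power_law(tibble::tibble(n_flag = c(1, 4), n_eff = c(1.27, 2.54)))
#' @export
fit_power_law <- function(group_fits) {
  stopifnot(is.data.frame(group_fits),
            all(c("n_flag", "n_eff") %in% names(group_fits)))
  gf <- group_fits[!is.na(group_fits$n_eff), , drop = FALSE]
  if (length(unique(gf$n_flag)) < 2)
    stop("need at least two groups with distinct n_flag", call. = FALSE)
  if (any(gf$n_eff <= 0))
    stop("n_eff must be positive for a power-law fit", call. = FALSE)
  fit <- stats::lm(log(n_eff) ~ log(n_flag), data = gf)
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 fit = fit, data = tibble::as_tibble(gf)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> N_eff = %.3f * N_flag^%.3f (%d groups)\n",
              x$a, x$b, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x,... A `powerlaw_fit` object; further arguments ignored.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("prefactor", "exponent"),
                 estimate = c(x$a, x$b))
}

#' @rdname fit_power_law
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n_groups = nrow(x$data),
                 r_squared = summary(x$fit)$r.squared)
}

#' Reduced chi-squared of simulated against observed summaries
#'
#' `chi2_red = sum(((sim - obs) / sem)^2) / dof` with
#' `dof = length(obs) - n_params`. The global variant
#' [global_reduced_chi_square()] sums the component reduced chi-squared
#' values across independent summary datasets, as used by the
#' fluctuation-parameter calibration.
#'
#' @param sim,obs,sem Equal-length numeric vectors of simulated values,
#'   observed values and their standard errors (`sem > 0`).
#' @param n_params Number of fitted parameters charged against the
#'   degrees of freedom.
#' @return An object of class `chisq_result` with elements
#'   `chi2_reduced`, `dof` and (for the global variant) `per_dataset`.
#' @export
reduced_chi_square <- function(sim, obs, sem, n_params = 0) {
  stopifnot(length(sim) == length(obs), length(obs) == length(sem))
  if (any(sem <= 0)) stop("all SEMs must be positive", call. = FALSE)
  dof <- length(obs) - n_params
  if (dof < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  structure(list(chi2_reduced = sum(((sim - obs) / sem)^2) / dof,
                 dof = dof, per_dataset = NULL),
            class = "chisq_result")
}

#' @rdname reduced_chi_square
#' @param components A list of `chisq_result` objects (one per dataset).
#' @export
global_reduced_chi_square <- function(components) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, logical(1), "chisq_result")))
  per <- vapply(components, function(x) x$chi2_reduced, numeric(1))
  structure(list(chi2_reduced = sum(per),
                 dof = sum(vapply(components, function(x) x$dof,
                                  numeric(1))),
                 per_dataset = per),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> reduced chi^2 = %.4f (dof = %d%s)\n",
              x$chi2_reduced, x$dof,
              if (is.null(x$per_dataset)) ""
              else paste0(", ", length(x$per_dataset), " datasets")))
  invisible(x)
}
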