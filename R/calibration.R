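#' Population summary statistics used for calibration
#'
#' Computes, from a list of cells (or a `cohort`), the four summary
#' datasets the fluctuation-parameter calibration matches: the mean
#' maximum CW count per tumble vs flagellar number, the pair
#' cross-correlation curve (averaged over cells, thinned to `lag_grid`),
#' the fitted effective flagellar number per group, and the group mean
#' of the deviation statistic eta.
#'
#' @param cells A list of cells or a `cohort`.
#' @param lag_grid Lags (s) at which the cross-correlation is reported.
#' @param cb_filter CW-bias filter applied to the per-cell summary
#'   before the eta / N_eff statistics (see [filter_cells()]).
#' @return A tibble with columns `statistic`, `x`, `value`, `sem`.
#'   Statistics: `"mean_max_cw"`, `"cross_correlation"`, `"n_eff"`,
#'   `"eta"`.
#' @export
population_summary_stats <- function(cells,
                                     lag_grid = seq(0, 1, by = 0.2),
                                     cb_filter = c(0, 0.25)) {
  cells <- as_cell_list(cells)
  summ <- summarize_cells(cells) |>
    filter_cells(cb_range = cb_filter, require_eta = TRUE)

  max_cw <- mean_max_cw(cells)
  t_max <- tibble::tibble(statistic = "mean_max_cw", x = max_cw$n_flag,
                          value = max_cw$mean_max_cw, sem = max_cw$sem)

  cc <- tryCatch(population_cross_correlation(cells,
                                              max_lag_s = max(lag_grid)),
                 error = function(e) NULL)
  t_cc <- if (is.null(cc)) NULL else {
    sel <- purrr::map_int(lag_grid,
                          ~ which.min(abs(cc$lag_s - .x)))
    tibble::tibble(statistic = "cross_correlation", x = cc$lag_s[sel],
                   value = cc$value[sel], sem = cc$sem[sel])
  }

  groups <- fit_n_eff_groups(summ)
  # SEM of N_eff propagated from the per-cell closed-form spread
  neff_sem <- summ |>
    dplyr::mutate(closed = log1p(-.data$tb) / log1p(-.data$cb)) |>
    dplyr::summarise(sem = stats::sd(.data$closed) / sqrt(dplyr::n()),
                     .by = "n_flag")
  groups <- dplyr::left_join(groups, neff_sem, by = "n_flag")
  t_neff <- tibble::tibble(statistic = "n_eff", x = groups$n_flag,
                           value = groups$n_eff, sem = groups$sem)

  eta <- summ |>
    dplyr::summarise(value = mean(.data$eta),
                     sem = stats::sd(.data$eta) / sqrt(dplyr::n()),
                     .by = "n_flag") |>
    dplyr::arrange(.data$n_flag)
  t_eta <- tibble::tibble(statistic = "eta", x = eta$n_flag,
                          value = eta$value, sem = eta$sem)

  dplyr::bind_rows(t_max, t_cc, t_neff, t_eta)
}

simulate_calibration_population <- function(sigma2, tau, config, seed) {
  p <- config$params
  p$sigma2 <- sigma2
  p$tau <- tau
  cfg <- config
  cfg$params <- p
  sample_population(cfg, seed = seed)
}

#' Calibrate the fluctuation parameters by reduced chi-squared scan
#'
#' Scans a grid of fluctuation variance (`sigma2`) and timescale (`tau`)
#' values. At each grid point a synthetic population is simulated (with
#' common random numbers: the same seed at every point, so the surface
#' is smooth in the parameters), its summary statistics are computed
#' with [population_summary_stats()], and each statistic is scored
#' against the matching target rows by [reduced_chi_square()] with
#' `n_params = 2`; the global objective is the sum of the component
#' reduced chi-squared values. Grid points whose simulation fails (for
#' example the trace-acceptance filter cannot be satisfied) are marked
#' invalid and excluded from the argmin with a warning.
#'
#' @param targets A tibble with columns `statistic`, `x`, `value`,
#'   `sem` (SEMs positive), as produced by [population_summary_stats()]
#'   on reference data.
#' @param sigma2_values,tau_values Grid values (uM^2 and s). Defaults
#'   bracket sigma2 in 0.25-2.0 by 0.25; the tau grid is uniform on the
#'   relaxation-rate scale (rates 0.05-1.0 s^-1 by 0.05, i.e.
#'   timescales 1-20 s), so the default operating point tau = 5 s
#'   (rate 0.2 s^-1) is exactly representable.
#' @param config A [population_config()] describing the population
#'   simulated at each grid point (fluctuating mode).
#' @param seed Integer seed (shared across grid points).
#' @return An object of class `calibration_grid`: `surface` tibble
#'   (`sigma2`, `tau`, `chi2`, `valid`), `best` (named vector), the
#'   per-point component values, and the call settings.
#'   [tidy()][generics::tidy] returns the surface;
#'   [autoplot()][ggplot2::autoplot] draws it.
#' @export
scan_fluctuation_params <- function(targets,
                                    sigma2_values = seq(0.25, 2, 0.25),
                                    tau_values = 1 / seq(0.05, 1, 0.05),
                                    config = population_config(),
                                    seed = NULL) {
  stopifnot(is.data.frame(targets),
            all(c("statistic", "x", "value", "sem") %in% names(targets)))
  if (length(sigma2_values) < 1 || length(tau_values) < 1)
    stop("empty calibration grid", call. = FALSE)
  if (any(targets$sem <= 0))
    stop("target SEMs must be positive", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  grid <- tidyr::expand_grid(sigma2 = sigma2_values, tau = tau_values)
  lag_grid <- sort(unique(
    targets$x[targets$statistic == "cross_correlation"]))
  scores <- purrr::pmap(grid, function(sigma2, tau) {
    sim <- tryCatch({
      pop <- simulate_calibration_population(sigma2, tau, config, seed)
      population_summary_stats(pop,
        lag_grid = if (length(lag_grid)) lag_grid else seq(0, 1, 0.2))
    }, error = function(e) NULL)
    if (is.null(sim))
      return(list(chi2 = NA_real_, valid = FALSE, components = NULL))
    comps <- chi2_components(sim, targets, n_params = 2)
    if (is.null(comps))
      return(list(chi2 = NA_real_, valid = FALSE, components = NULL))
    g <- global_reduced_chi_square(comps)
    list(chi2 = g$chi2_reduced, valid = TRUE,
         components = g$per_dataset)
  })
  surface <- grid
  surface$chi2 <- purrr::map_dbl(scores, "chi2")
  surface$valid <- purrr::map_lgl(scores, "valid")
  if (!any(surface$valid))
    stop("no valid grid point", call. = FALSE)
  if (any(!surface$valid))
    warning(sum(!surface$valid), " grid point(s) failed and were ",
            "excluded", call. = FALSE)
  best_i <- which.min(ifelse(surface$valid, surface$chi2, Inf))
  structure(list(surface = tibble::as_tibble(surface),
                 best = c(sigma2 = surface$sigma2[best_i],
                          tau = surface$tau[best_i]),
                 chi2_best = surface$chi2[best_i],
                 components = purrr::map(scores, "components"),
                 config = config, seed = seed),
            class = "calibration_grid")
}

# match simulated to target rows per statistic; NULL if any dataset has
# too few points for positive dof
chi2_components <- function(sim, targets, n_params = 2) {
  stats_names <- unique(targets$statistic)
  comps <- purrr::map(stats_names, function(s) {
    tg <- targets[targets$statistic == s, ]
    sm <- sim[sim$statistic == s, ]
    j <- purrr::map_int(tg$x, function(x) {
      d <- abs(sm$x - x)
      if (!length(d) || min(d) > 1e-6) NA_integer_ else which.min(d)
    })
    ok <- !is.na(j) & !is.na(sm$value[j])
    if (sum(ok) - n_params < 1) return(NULL)
    reduced_chi_square(sm$value[j[ok]], tg$value[ok], tg$sem[ok],
                       n_params = n_params)
  })
  comps <- purrr::compact(comps)
  if (length(comps) == 0) NULL else comps
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat(sprintf(paste0("<calibration_grid> %d points; best sigma2 = %g ",
                     "uM^2, tau = %g s (chi2_red = %.3f)\n"),
              nrow(x$surface), x$best[["sigma2"]], x$best[["tau"]],
              x$chi2_best))
  invisible(x)
}

#' @rdname scan_fluctuation_params
#' @param x,... A `calibration_grid`; further arguments ignored.
#' @export
tidy.calibration_grid <- function(x, ...) x$surface

#' @rdname scan_fluctuation_params
#' @export
glance.calibration_grid <- function(x, ...) {
  tibble::tibble(sigma2 = x$best[["sigma2"]], tau = x$best[["tau"]],
                 chi2_reduced = x$chi2_best,
                 n_points = nrow(x$surface),
                 n_valid = sum(x$surface$valid))
}
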