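#' Figure-style plots of the standard analyses
#'
#' `reproduce_figure()` regenerates the package's standard diagnostic
#' figures from one or two cohorts (typically a fluctuating "wild-type"
#' cohort and a constant-bias control):
#' \describe{
#'   \item{`"eta"`}{group mean of the deviation statistic eta vs
#'     flagellar number, with SEM bars.}
#'   \item{`"max-cw"`}{mean maximum CW flagella per tumble vs flagellar
#'     number.}
#'   \item{`"cross-correlation"`}{population-averaged pair
#'     cross-correlation vs lag.}
#'   \item{`"neff-collapse"`}{survival-form collapse: `1 - TB` against
#'     `(1 - CB)^N_eff` per cell, which lies on the identity line when
#'     the generalized veto model holds.}
#'   \item{`"power-law"`}{fitted `N_eff` vs `N_flag` with the power-law
#'     fit overlaid.}
#' }
#'
#' @param id Figure id (see Details); an unknown id raises an error
#'   listing the valid ids.
#' @param cohorts A named list of cohorts / cell lists (names become
#'   legend labels).
#' @param cb_filter CW-bias filter for eta / N_eff panels.
#' @return A `ggplot` object.
#' @export
reproduce_figure <- function(id, cohorts, cb_filter = c(0, 0.25)) {
  ids <- c("eta", "max-cw", "cross-correlation", "neff-collapse",
           "power-law")
  if (!id %in% ids)
    stop("unknown figure id '", id, "'; valid ids: ",
         paste(ids, collapse = ", "), call. = FALSE)
  if (inherits(cohorts, "cohort")) cohorts <- list(cohort = cohorts)
  summ <- purrr::imap_dfr(cohorts, function(co, nm) {
    summarize_cells(co) |>
      filter_cells(cb_range = cb_filter, require_eta = TRUE) |>
      dplyr::mutate(cohort = nm)
  })
  switch(id,
    "eta" = {
      d <- summ |>
        dplyr::summarise(
          eta = mean(.data$eta),
          sem = stats::sd(.data$eta) / sqrt(dplyr::n()),
          .by = c("cohort", "n_flag"))
      ggplot2::ggplot(d, ggplot2::aes(.data$n_flag, .data$eta,
                                      color = .data$cohort)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2) +
        ggplot2::geom_pointrange(ggplot2::aes(
          ymin = .data$eta - .data$sem, ymax = .data$eta + .data$sem)) +
        ggplot2::labs(x = "number of flagella",
                      y = expression(eta)) +
        ggplot2::theme_minimal()
    },
    "max-cw" = {
      d <- purrr::imap_dfr(cohorts, function(co, nm)
        dplyr::mutate(mean_max_cw(co), cohort = nm))
      ggplot2::ggplot(d, ggplot2::aes(.data$n_flag, .data$mean_max_cw,
                                      color = .data$cohort)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
        ggplot2::geom_pointrange(ggplot2::aes(
          ymin = .data$mean_max_cw - .data$sem,
          ymax = .data$mean_max_cw + .data$sem)) +
        ggplot2::labs(x = "number of flagella",
                      y = "max CW flagella per tumble") +
        ggplot2::theme_minimal()
    },
    "cross-correlation" = {
      d <- purrr::imap_dfr(cohorts, function(co, nm)
        dplyr::mutate(population_cross_correlation(co), cohort = nm))
      ggplot2::ggplot(d, ggplot2::aes(.data$lag_s, .data$value,
                                      color = .data$cohort)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2) +
        ggplot2::geom_line() +
        ggplot2::geom_ribbon(ggplot2::aes(
          ymin = .data$value - .data$sem,
          ymax = .data$value + .data$sem, fill = .data$cohort),
          alpha = 0.2, color = NA) +
        ggplot2::labs(x = "lag (s)", y = "cross-correlation") +
        ggplot2::theme_minimal()
    },
    "neff-collapse" = {
      d <- summ |>
        dplyr::left_join(
          summ |> dplyr::group_by(.data$cohort) |>
            dplyr::group_modify(~ fit_n_eff_groups(.x)) |>
            dplyr::ungroup() |>
            dplyr::select("cohort", "n_flag", "n_eff"),
          by = c("cohort", "n_flag")) |>
        dplyr::mutate(x = (1 - .data$cb)^.data$n_eff,
                      y = 1 - .data$tb)
      ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                      color = .data$cohort)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::labs(x = expression((1 - CB)^N[eff]),
                      y = "1 - TB") +
        ggplot2::theme_minimal()
    },
    "power-law" = {
      d <- summ |>
        dplyr::group_by(.data$cohort) |>
        dplyr::group_modify(~ fit_n_eff_groups(.x)) |>
        dplyr::ungroup()
      pl <- fit_power_law(d[d$cohort == d$cohort[1], ])
      curve <- tibble::tibble(
        n_flag = seq(min(d$n_flag), max(d$n_flag), length.out = 50),
        n_eff = pl$a * n_flag^pl$b)
      ggplot2::ggplot(d, ggplot2::aes(.data$n_flag, .data$n_eff)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
        ggplot2::geom_line(data = curve, color = "red") +
        ggplot2::geom_point(ggplot2::aes(color = .data$cohort)) +
        ggplot2::labs(x = expression(N[flag]), y = expression(N[eff])) +
        ggplot2::theme_minimal()
    })
}

#' @rdname fit_power_law
#' @param object A `powerlaw_fit`.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  curve <- tibble::tibble(
    n_flag = seq(min(object$data$n_flag), max(object$data$n_flag),
                 length.out = 100),
    n_eff = object$a * n_flag^object$b)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$n_flag, .data$n_eff)) +
    ggplot2::geom_line(data = curve, color = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(N[flag]), y = expression(N[eff]),
      subtitle = sprintf("N_eff = %.2f x N_flag^%.2f", object$a,
                         object$b)) +
    ggplot2::theme_minimal()
}

#' @rdname scan_fluctuation_params
#' @param object A `calibration_grid`.
#' @export
autoplot.calibration_grid <- function(object, ...) {
  best <- tibble::tibble(sigma2 = object$best[["sigma2"]],
                         tau = object$best[["tau"]])
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$sigma2, .data$tau,
                               fill = .data$chi2)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = best, fill = NA, color = "red",
                        shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = expression(chi[red]^2)) +
    ggplot2::labs(x = expression(sigma^2 ~ "(uM"^2 * ")"),
                  y = expression(tau ~ "(s)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
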