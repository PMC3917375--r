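# Accessors shared by simulated (dt-resolution) and observed (windowed)
# cells. Both carry a motor state matrix, a run/tumble vector and a step
# duration.
state_step <- function(cell) {
  if (inherits(cell, "observed_cell")) cell$window else cell$dt
}
motor_matrix <- function(cell) cell$motor
run_vector <- function(cell) cell$run

#' Per-cell clockwise and tumble bias
#'
#' `cell_cw_bias()` is the cell's mean CW bias: the CW time-fraction of
#' each flagellum, averaged (unweighted) across flagella.
#' `cell_tumble_bias()` is the fraction of time steps labelled tumble.
#'
#' @param cell A `cell_record` (from [simulate_cell()]) or
#'   `observed_cell` (from [discretize_observations()]).
#' @return A single numeric value in `[0, 1]`.
#' @export
cell_cw_bias <- function(cell) {
  m <- motor_matrix(cell)
  if (is.null(m) || nrow(m) == 0) stop("empty trace", call. = FALSE)
  mean(colMeans(m))
}

#' @rdname cell_cw_bias
#' @export
cell_tumble_bias <- function(cell) {
  r <- run_vector(cell)
  if (length(r) == 0) stop("empty trace", call. = FALSE)
  mean(!r)
}

#' Summarize cells into the per-cell analysis table
#'
#' Computes, for each cell, the measured tumble bias, clockwise bias and
#' deviation statistic eta (NA where undefined, i.e. `cb` of 0 or 1 or
#' `tb = 1`).
#'
#' @param cells A list of `cell_record` / `observed_cell` objects, or a
#'   `cohort` from [sample_population()].
#' @return A tibble with columns `cell_id`, `strain`, `n_flag`,
#'   `duration_s`, `tb`, `cb`, `eta`.
#' @export
summarize_cells <- function(cells) {
  cells <- as_cell_list(cells)
  purrr::imap_dfr(cells, function(cell, i) {
    tb <- cell_tumble_bias(cell)
    cb <- cell_cw_bias(cell)
    tibble::tibble(
      cell_id = cell$cell_id %||% as.character(i),
      strain = cell$strain_mode %||% cell$strain %||% NA_character_,
      n_flag = cell$n_flag,
      duration_s = cell$duration %||%
        (length(run_vector(cell)) * state_step(cell)),
      tb = tb, cb = cb,
      eta = eta_or_na(tb, cb, cell$n_flag))
  })
}

as_cell_list <- function(cells) {
  if (inherits(cells, "cohort")) return(cells$cells)
  if (inherits(cells, c("cell_record", "observed_cell"))) return(list(cells))
  cells
}

#' Segment a trace into tumble events
#'
#' Maximal contiguous tumble intervals with half-open time bounds
#' `[start_s, end_s)`. Events touching either trace boundary are marked
#' incomplete and are excluded from the maximum-CW statistics by default
#' (their extent is censored). `max_cw` is the maximum simultaneous
#' number of CW flagella during the event.
#'
#' @inheritParams cell_cw_bias
#' @return A tibble with columns `start_s`, `end_s`, `max_cw`,
#'   `complete`.
#' @export
tumble_events <- function(cell) {
  r <- run_vector(cell)
  step <- state_step(cell)
  n_cw <- rowSums(motor_matrix(cell))
  rl <- rle(!r)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  idx <- which(rl$values)
  purrr::map_dfr(idx, function(j) {
    tibble::tibble(
      start_s = (starts[j] - 1) * step,
      end_s = ends[j] * step,
      max_cw = max(n_cw[starts[j]:ends[j]]),
      complete = starts[j] > 1 && ends[j] < length(r))
  })
}

#' Mean maximum number of CW flagella per tumble
#'
#' For each flagellar-number group, the mean over complete tumble events
#' of the maximum simultaneous CW count during the event, with its SEM
#' over events (or, with `by_cell = TRUE`, a per-cell mean first and the
#' SEM over cells). For independently switching flagella this statistic
#' stays near 1 and rises only through chance overlap of tumbles;
#' correlated switching drives it toward `n_flag`.
#'
#' @param cells A list of cells or a `cohort`.
#' @param by_cell Average within cells before averaging across them.
#' @return A tibble with columns `n_flag`, `mean_max_cw`, `sem`,
#'   `n_events` (and `n_cells`).
#' @export
mean_max_cw <- function(cells, by_cell = FALSE) {
  cells <- as_cell_list(cells)
  ev <- purrr::imap_dfr(cells, function(cell, i) {
    e <- tumble_events(cell)
    e <- e[e$complete, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    tibble::tibble(cell_id = as.character(i), n_flag = cell$n_flag,
                   max_cw = e$max_cw)
  })
  if (nrow(ev) == 0)
    return(tibble::tibble(n_flag = numeric(), mean_max_cw = numeric(),
                          sem = numeric(), n_events = integer(),
                          n_cells = integer()))
  if (by_cell) {
    ev |>
      dplyr::summarise(m = mean(.data$max_cw), n_ev = dplyr::n(),
                       .by = c("cell_id", "n_flag")) |>
      dplyr::summarise(mean_max_cw = mean(.data$m),
                       sem = stats::sd(.data$m) / sqrt(dplyr::n()),
                       n_events = sum(.data$n_ev),
                       n_cells = dplyr::n(), .by = "n_flag") |>
      dplyr::arrange(.data$n_flag)
  } else {
    ev |>
      dplyr::summarise(mean_max_cw = mean(.data$max_cw),
                       sem = stats::sd(.data$max_cw) / sqrt(dplyr::n()),
                       n_events = dplyr::n(),
                       n_cells = dplyr::n_distinct(.data$cell_id),
                       .by = "n_flag") |>
      dplyr::arrange(.data$n_flag)
  }
}

#' Pairwise cross-correlation of flagellar rotation states
#'
#' For every unordered pair of flagella on a cell, the Pearson-normalized
#' cross-covariance of the mean-subtracted binary CW indicators is
#' computed on the overlapping samples at each lag, then averaged over
#' pairs. Because flagellum pairs are unordered the curve is symmetrized
#' over the lag sign. Pairs containing a zero-variance flagellum (never
#' or always CW) are skipped with a warning. [population_cross_correlation()]
#' averages the per-cell curves with a SEM over cells.
#'
#' @inheritParams cell_cw_bias
#' @param max_lag_s Largest lag (s); the grid is symmetric about zero.
#' @return A tibble with columns `lag_s` and `value` and attribute
#'   `n_pairs`.
#' @export
pair_cross_correlation <- function(cell, max_lag_s = 3) {
  m <- motor_matrix(cell)
  if (ncol(m) < 2)
    stop("cross-correlation needs at least two flagella", call. = FALSE)
  step <- state_step(cell)
  max_lag <- min(round(max_lag_s / step), nrow(m) - 1)
  keep <- which(apply(m, 2, stats::var) > 0)
  if (length(keep) < ncol(m))
    warning(ncol(m) - length(keep),
            " zero-variance flagellum(s) skipped", call. = FALSE)
  if (length(keep) < 2)
    stop("no flagellum pair with variance remains", call. = FALSE)
  pairs <- utils::combn(keep, 2, simplify = FALSE)
  vals <- purrr::map(pairs, function(p) {
    v <- cross_corr_cpp(as.numeric(m[, p[1]]), as.numeric(m[, p[2]]),
                        max_lag)
    (v + rev(v)) / 2  # symmetrize: unordered pairs have no lag sign
  })
  out <- tibble::tibble(
    lag_s = seq(-max_lag, max_lag) * step,
    value = rowMeans(do.call(cbind, vals)))
  attr(out, "n_pairs") <- length(pairs)
  out
}

#' @rdname pair_cross_correlation
#' @param cells A list of cells (each with `n_flag >= 2`) or a `cohort`.
#' @return For the population variant, a tibble with columns `lag_s`,
#'   `value`, `sem`, `n_cells`.
#' @export
population_cross_correlation <- function(cells, max_lag_s = 3) {
  cells <- as_cell_list(cells)
  cells <- purrr::keep(cells, ~ .x$n_flag >= 2)
  curves <- purrr::map(cells, function(cell) {
    tryCatch(pair_cross_correlation(cell, max_lag_s),
             error = function(e) NULL)
  })
  curves <- purrr::compact(curves)
  if (length(curves) == 0)
    stop("no multi-flagellated cell yields a correlation curve",
         call. = FALSE)
  # align on the shortest lag grid
  n_min <- min(vapply(curves, nrow, integer(1)))
  trim <- function(x) {
    k <- (nrow(x) - n_min) / 2
    x[(1 + k):(nrow(x) - k), ]
  }
  curves <- purrr::map(curves, trim)
  v <- do.call(cbind, purrr::map(curves, "value"))
  tibble::tibble(lag_s = curves[[1]]$lag_s,
                 value = rowMeans(v, na.rm = TRUE),
                 sem = apply(v, 1, stats::sd, na.rm = TRUE) /
                   sqrt(rowSums(!is.na(v))),
                 n_cells = length(curves))
}

state_dwell_stats <- function(states, step, alphabet) {
  # transitions i->j counts and total dwell time per state from one trace
  r <- rle(as.vector(states))
  dwell <- vapply(alphabet, function(s) sum(r$lengths[r$values == s]) * step,
                  numeric(1))
  from <- r$values[-length(r$values)]
  to <- r$values[-1]
  trans <- table(factor(from, levels = alphabet),
                 factor(to, levels = alphabet))
  list(dwell = dwell, trans = trans)
}

#' Estimate motor and waveform transition rates from traces
#'
#' Each transition rate is the number of observed `i -> j` transitions
#' divided by the total dwell time in state `i`, with a Poisson standard
#' error `sqrt(count)/time`. Also classifies the waveform sequence of
#' every CW episode (`N-S-N`, `N-S-C-N`, `N-C-N`, by entry and whether
#' the semi-coiled filament converted to curly-1) and, optionally,
#' splits cells into single- vs multi-flagellated groups.
#'
#' @param cells A list of cells or a `cohort` (waveform traces required
#'   for the waveform rates).
#' @param split_by_nflag Return separate estimates for cells with one vs
#'   several flagella.
#' @return A list of class `rate_estimates`: `motor` and `waveform`
#'   tibbles (`from`, `to`, `rate`, `se`, `n_transitions`, `dwell_s`)
#'   and a `sequences` tibble of per-episode waveform sequence counts.
#' @export
estimate_rates <- function(cells, split_by_nflag = FALSE) {
  cells <- as_cell_list(cells)
  if (split_by_nflag) {
    groups <- list(single = purrr::keep(cells, ~ .x$n_flag == 1),
                   multi = purrr::keep(cells, ~ .x$n_flag > 1))
    groups <- groups[lengths(groups) > 0]
    out <- purrr::imap(groups, ~ estimate_rates(.x, FALSE))
    return(structure(out, class = "rate_estimates_by_group"))
  }
  motor_alpha <- c(0L, 1L)
  wf_alpha <- unname(waveform_levels)
  acc_m <- list(dwell = stats::setNames(numeric(2), motor_alpha),
                trans = matrix(0, 2, 2))
  acc_w <- list(dwell = stats::setNames(numeric(3), wf_alpha),
                trans = matrix(0, 3, 3))
  seqs <- character(0)
  for (cell in cells) {
    step <- state_step(cell)
    m <- motor_matrix(cell)
    w <- cell$waveform
    for (k in seq_len(ncol(m))) {
      sm <- state_dwell_stats(m[, k], step, motor_alpha)
      acc_m$dwell <- acc_m$dwell + sm$dwell
      acc_m$trans <- acc_m$trans + unclass(sm$trans)
      if (!is.null(w)) {
        sw <- state_dwell_stats(w[, k], step, wf_alpha)
        acc_w$dwell <- acc_w$dwell + sw$dwell
        acc_w$trans <- acc_w$trans + unclass(sw$trans)
        seqs <- c(seqs, cw_episode_sequences(w[, k]))
      }
    }
  }
  rate_tbl <- function(acc, labels) {
    grid <- expand.grid(i = seq_along(labels), j = seq_along(labels))
    grid <- grid[grid$i != grid$j, ]
    tibble::tibble(
      from = labels[grid$i], to = labels[grid$j],
      n_transitions = acc$trans[cbind(grid$i, grid$j)],
      dwell_s = unname(acc$dwell[grid$i]),
      rate = ifelse(dwell_s > 0, n_transitions / dwell_s, NA_real_),
      se = ifelse(dwell_s > 0, sqrt(n_transitions) / dwell_s, NA_real_))
  }
  structure(list(
    motor = rate_tbl(acc_m, c("CCW", "CW")),
    waveform = rate_tbl(acc_w, names(waveform_levels)),
    sequences = if (length(seqs))
      tibble::as_tibble(table(sequence = seqs)) else
      tibble::tibble(sequence = character(), n = integer())),
    class = "rate_estimates")
}

cw_episode_sequences <- function(wf) {
  # label each complete CW episode by its waveform path
  r <- rle(as.vector(wf) != waveform_levels[["normal"]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values & starts > 1 & ends < length(wf))
  vapply(idx, function(j) {
    states <- unique(rle(wf[starts[j]:ends[j]])$values)
    if (identical(states, waveform_levels[["semi_coiled"]])) "N-S-N"
    else if (identical(states, unname(waveform_levels[c("semi_coiled",
                                                        "curly_1")])))
      "N-S-C-N"
    else if (identical(states, waveform_levels[["curly_1"]])) "N-C-N"
    else "other"
  }, character(1))
}

#' Matched null simulation with independent flagella
#'
#' Simulates replicate cells in constant-bias mode (no shared CheY-P
#' fluctuations) matched to a cell summary (`n_flag`, `cb`, `duration`)
#' and returns, per replicate, the statistics used for null comparison:
#' the mean maximum CW count per tumble, the lag-0 pair
#' cross-correlation and the measured eta.
#'
#' @param n_flag,cb,duration Matched cell summary.
#' @param n_rep Number of replicate cells.
#' @param params A [model_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with columns `replicate`, `mean_max_cw`, `lag0_corr`,
#'   `eta`.
#' @export
independent_null <- function(n_flag, cb, duration, n_rep = 1,
                             params = model_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_rep)
  purrr::map_dfr(seq_len(n_rep), function(i) {
    cell <- simulate_cell(n_flag, duration, params,
                          strain_mode = "constant_cb", cb = cb,
                          waveforms = FALSE, seed = sub[i])
    ev <- tumble_events(cell)
    ev <- ev[ev$complete, , drop = FALSE]
    lag0 <- if (n_flag >= 2)
      tryCatch({
        cc <- pair_cross_correlation(cell, max_lag_s = 0)
        cc$value[cc$lag_s == 0]
      }, error = function(e) NA_real_)
    else NA_real_
    tb <- cell_tumble_bias(cell)
    cbh <- cell_cw_bias(cell)
    tibble::tibble(replicate = i,
                   mean_max_cw = if (nrow(ev)) mean(ev$max_cw) else NA_real_,
                   lag0_corr = lag0,
                   eta = eta_or_na(tb, cbh, n_flag))
  })
}

#' Filter a per-cell summary table on clockwise bias
#'
#' Keeps cells whose measured CW bias lies in `cb_range` (closed upper
#' bound). With `require_eta = TRUE` cells whose eta is undefined
#' (`cb` of 0 or 1, `tb = 1`) are also dropped. The number of exclusions
#' is reported as a message.
#'
#' @param data A per-cell summary tibble (see [summarize_cells()]).
#' @param cb_range Two-element numeric interval, default `c(0, 0.25)`.
#' @param require_eta Also require a defined eta.
#' @return The filtered tibble.
#' @export
filter_cells <- function(data, cb_range = c(0, 0.25),
                         require_eta = FALSE) {
  stopifnot(is.data.frame(data), "cb" %in% names(data))
  keep <- data$cb >= cb_range[1] & data$cb <= cb_range[2]
  if (require_eta)
    keep <- keep & data$cb > 0 & data$cb < 1 & !is.na(data$tb) &
      data$tb < 1
  if (any(!keep))
    message(sum(!keep), " cell(s) excluded by the CW-bias filter [",
            cb_range[1], ", ", cb_range[2], "]")
  data[keep, , drop = FALSE]
}
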