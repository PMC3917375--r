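test_that("the hand-built trace yields the frozen summary statistics", {
  toy <- make_toy_cell()
  expect_equal(cell_tumble_bias(toy), 0.25)
  expect_equal(cell_cw_bias(toy), 0.15)
  summ <- summarize_cells(list(toy))
  expect_equal(summ$eta, -1.22985498772, tolerance = 1e-9)
  expect_equal(summ$n_flag, 3)
})

test_that("per-flagellum CW fractions average unweighted", {
  motor <- cbind(c(rep(1L, 2), rep(0L, 8)), c(rep(1L, 4), rep(0L, 6)))
  cell <- make_observed(motor, run = rowSums(motor) == 0)
  expect_equal(cell_cw_bias(cell), 0.3)  # mean of 0.2 and 0.4
  one <- make_observed(matrix(c(rep(1L, 5), rep(0L, 15)), ncol = 1),
                       run = rep(TRUE, 20))
  expect_equal(cell_cw_bias(one), 0.25)
  allccw <- make_observed(matrix(0L, 10, 2), run = rep(TRUE, 10))
  expect_equal(cell_cw_bias(allccw), 0)
  expect_equal(cell_tumble_bias(allccw), 0)
})

test_that("tumble segmentation finds maximal intervals and boundaries", {
  toy <- make_toy_cell()
  ev <- tumble_events(toy)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 0.4)
  expect_equal(ev$end_s, 0.9)
  expect_equal(ev$max_cw, 3)   # window 6: all three CW
  expect_true(ev$complete)
  # all-run trace has no events
  allrun <- make_observed(matrix(0L, 10, 2), run = rep(TRUE, 10))
  expect_equal(nrow(tumble_events(allrun)), 0)
  # a tumble at the trace start is incomplete
  m <- matrix(0L, 10, 1); m[1:2, 1] <- 1L
  edge <- make_observed(m, run = m[, 1] == 0L)
  ev2 <- tumble_events(edge)
  expect_false(ev2$complete)
  expect_equal(nrow(mean_max_cw(list(edge))), 0)  # excluded by default
})

test_that("mean max-CW matches a brute-force event scanner", {
  set.seed(23)
  brute <- function(cell) {
    r <- !cell$run
    ncw <- rowSums(cell$motor)
    vals <- c(); cur <- NULL
    for (i in seq_along(r)) {
      if (r[i]) cur <- c(cur, ncw[i])
      else { if (!is.null(cur)) vals <- c(vals, max(cur)); cur <- NULL }
    }
    # drop events touching either boundary
    if (r[1] && length(vals)) vals <- vals[-1]
    if (r[length(r)]) cur <- NULL
    vals
  }
  cells <- purrr::map(1:6, function(i) {
    m <- matrix(rbinom(90, 1, 0.25), ncol = 3)
    make_observed(m, run = rowSums(m) == 0)
  })
  got <- mean_max_cw(cells)
  all_vals <- unlist(purrr::map(cells, brute))
  expect_equal(got$mean_max_cw, mean(all_vals))
  expect_equal(got$n_events, length(all_vals))
  expect_equal(got$sem, sd(all_vals) / sqrt(length(all_vals)))
})

test_that("single-flagellum events always have max_cw 1", {
  set.seed(31)
  m <- matrix(rbinom(200, 1, 0.2), ncol = 1)
  cell <- make_observed(m, run = m[, 1] == 0L)
  ev <- tumble_events(cell)
  expect_true(all(ev$max_cw == 1))
})

test_that("cross-correlation matches the naive oracle and its symmetries", {
  set.seed(41)
  m <- matrix(rbinom(400, 1, 0.3), ncol = 2)
  cell <- make_observed(m, run = rowSums(m) == 0, window = 0.1)
  cc <- pair_cross_correlation(cell, max_lag_s = 0.5)
  nv <- naive_ccf(m[, 1], m[, 2], 5)
  expect_equal(cc$value, (nv + rev(nv)) / 2, tolerance = 1e-12)
  # identical traces: exactly 1 at lag 0
  twin <- make_observed(cbind(m[, 1], m[, 1]), run = rep(TRUE, 200))
  cc2 <- pair_cross_correlation(twin, max_lag_s = 0.3)
  expect_equal(cc2$value[cc2$lag_s == 0], 1)
  # pair order does not matter
  swap <- make_observed(m[, 2:1], run = rep(TRUE, 200))
  expect_equal(pair_cross_correlation(swap, 0.5)$value, cc$value)
  expect_true(all(abs(cc$value) <= 1 + 1e-12))
})

test_that("a shifted copy peaks at its shift", {
  set.seed(43)
  x <- rbinom(500, 1, 0.3)
  k <- 7
  m <- cbind(x, dplyr::lag(x, k, default = 0L))
  cell <- make_observed(m, run = rep(TRUE, 500), window = 0.1)
  cc <- pair_cross_correlation(cell, max_lag_s = 2)
  # the unordered-pair curve is symmetric, so the peak sits at +/- k
  expect_equal(abs(cc$lag_s[which.max(cc$value)]), k * 0.1)
})

test_that("independent constant-bias motors decorrelate", {
  cell <- simulate_cell(2, 500, strain_mode = "constant_cb",
                        waveforms = FALSE, seed = 51)
  cc <- pair_cross_correlation(cell, max_lag_s = 1)
  expect_lt(abs(cc$value[cc$lag_s == 0]), 0.05)  # 3 MC SE of ~0
})

test_that("zero-variance flagella are skipped with a warning", {
  m <- cbind(rbinom(100, 1, 0.4), 0L, rbinom(100, 1, 0.4))
  cell <- make_observed(m, run = rep(TRUE, 100))
  expect_warning(cc <- pair_cross_correlation(cell, 0.3),
                 "zero-variance")
  expect_equal(attr(cc, "n_pairs"), 1)
  allzero <- make_observed(matrix(0L, 50, 2), run = rep(TRUE, 50))
  expect_error(suppressWarnings(pair_cross_correlation(allzero, 0.3)),
               "remains")
})

test_that("transition rates are count-over-dwell with Poisson errors", {
  # one N->S transition over 10 s of normal dwell, window 1 s
  w <- matrix(c(rep(0L, 10), 1L, 1L), ncol = 1)
  m <- (w > 0) + 0L
  cell <- make_observed(m, run = w[, 1] == 0, window = 1,
                        waveform = w)
  r <- estimate_rates(list(cell))
  ns <- r$waveform[r$waveform$from == "normal" &
                     r$waveform$to == "semi_coiled", ]
  expect_equal(ns$rate, 0.1)
  expect_equal(ns$se, 0.1)  # sqrt(1)/10
  nc <- r$waveform[r$waveform$from == "normal" &
                     r$waveform$to == "curly_1", ]
  expect_equal(nc$rate, 0)
})

test_that("rates estimated from simulation recover the generators", {
  cell <- simulate_cell(2, 500, strain_mode = "constant_cb", seed = 61)
  r <- estimate_rates(list(cell))
  m <- r$motor
  up <- m[m$from == "CCW" & m$to == "CW", ]
  down <- m[m$from == "CW" & m$to == "CCW", ]
  expect_lt(abs(up$rate - 0.26), 3 * up$se)
  expect_lt(abs(down$rate - 1.74), 3 * down$se)
  # semi-coiled -> curly-1 conversion at lambda_sc
  sc <- r$waveform[r$waveform$from == "semi_coiled" &
                     r$waveform$to == "curly_1", ]
  expect_lt(abs(sc$rate - 0.68), 3 * sc$se)
})

test_that("episode branching and sequence classes follow the overlay", {
  cells <- purrr::map(1:3, function(i)
    simulate_cell(2, 400, model_params(cb = 0.3),
                  strain_mode = "constant_cb", seed = 70 + i))
  r <- estimate_rates(cells)
  seqs <- r$sequences
  direct <- sum(seqs$n[seqs$sequence == "N-C-N"])
  total <- sum(seqs$n[seqs$sequence != "other"])
  expect_gt(total, 1000)
  p <- 0.08 / 0.36
  expect_lt(abs(direct / total - p), 3 * sqrt(p * (1 - p) / total))
  expect_false("other" %in% seqs$sequence)
})

test_that("single- and multi-flagellated groups can be split", {
  cells <- list(simulate_cell(1, 50, strain_mode = "constant_cb",
                              seed = 81),
                simulate_cell(3, 50, strain_mode = "constant_cb",
                              seed = 82))
  r <- estimate_rates(cells, split_by_nflag = TRUE)
  expect_named(r, c("single", "multi"))
})

test_that("the independent null brackets the fluctuating statistics", {
  null <- independent_null(3, 0.13, 30, n_rep = 12, seed = 91)
  expect_true(all(null$mean_max_cw >= 1, na.rm = TRUE))
  expect_true(all(is.finite(null$lag0_corr)))
  # eta centered at zero for independent flagella
  expect_lt(abs(mean(null$eta, na.rm = TRUE)),
            3 * sd(null$eta, na.rm = TRUE) /
              sqrt(sum(!is.na(null$eta))))
})

test_that("null mean max-CW is nondecreasing in flagellar number", {
  set.seed(13)
  means <- purrr::map_dbl(c(1, 3, 5), function(nf) {
    mean(independent_null(nf, 0.15, 40, n_rep = 10,
                          seed = 100 + nf)$mean_max_cw, na.rm = TRUE)
  })
  expect_true(all(diff(means) > -0.05))
  expect_equal(means[1], 1)
})

test_that("the CW-bias filter keeps the configured range", {
  summ <- tibble::tibble(cell_id = as.character(1:69),
                         n_flag = rep(1:5, length.out = 69),
                         tb = rep(0.2, 69),
                         cb = c(rep(0.12, 61), rep(0.3, 8)))
  expect_message(kept <- filter_cells(summ, c(0, 0.25)), "8 cell")
  expect_equal(nrow(kept), 61)
  expect_identical(filter_cells(summ, c(0, 1)), summ)
  expect_message(filter_cells(tibble::tibble(cb = 0.3, tb = 0.1),
                              c(0, 0.25)), "1 cell")
  # eta-bearing analyses additionally need cb > 0 and tb < 1
  deg <- tibble::tibble(cb = c(0, 0.1, 0.2), tb = c(0.1, 1, 0.2))
  expect_equal(nrow(suppressMessages(
    filter_cells(deg, c(0, 0.25), require_eta = TRUE))), 1)
})
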