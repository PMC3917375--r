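# Fixtures built in code: a hand-specified 3-flagella trace and small
# constructors used across the test files.

# 20 windows of 0.1 s; flagellum 1 CW on windows 5-8, flagellum 2 on
# 6-9, flagellum 3 on window 6. Veto rule => tumble exactly on 5-9,
# so TB = 5/20 = 0.25 and CB = mean(0.2, 0.2, 0.05) = 0.15.
make_toy_cell <- function() {
  motor <- matrix(0L, nrow = 20, ncol = 3)
  motor[5:8, 1] <- 1L
  motor[6:9, 2] <- 1L
  motor[6, 3] <- 1L
  make_observed(motor, run = rowSums(motor) == 0, window = 0.1)
}

make_observed <- function(motor, run, window = 0.1, waveform = NULL,
                          n_flag = ncol(motor)) {
  structure(list(cell_id = "toy", n_flag = n_flag, window = window,
                 duration = nrow(motor) * window, strain = "toy",
                 motor = motor, waveform = waveform, run = run),
            class = "observed_cell")
}

# cells lying exactly on a generalized veto curve
cells_on_curve <- function(cb, n_eff) {
  tibble::tibble(cb = cb, tb = veto_tumble_bias(cb, n_eff))
}

# independent brute-force N_eff oracle: grid search in TB-space
grid_n_eff <- function(data, step = 1e-4, upper = 20) {
  grid <- seq(step, upper, by = step)
  sse <- vapply(grid, function(n)
    sum((data$tb - (1 - (1 - data$cb)^n))^2), numeric(1))
  grid[which.min(sse)]
}

# naive cross-correlation oracle (overlap-normalized Pearson per lag)
naive_ccf <- function(x, y, max_lag) {
  mx <- mean(x); my <- mean(y)
  vapply(-max_lag:max_lag, function(l) {
    if (l >= 0) { a <- x[1:(length(x) - l)]; b <- y[(1 + l):length(y)] }
    else { a <- x[(1 - l):length(x)]; b <- y[1:(length(y) + l)] }
    a <- a - mx; b <- b - my
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
}
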