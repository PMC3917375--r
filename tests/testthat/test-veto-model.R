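test_that("veto tumble bias matches closed-form evaluation", {
  expect_equal(veto_tumble_bias(0, 5), 0)
  expect_equal(veto_tumble_bias(0.13, 1), 0.13)
  expect_equal(veto_tumble_bias(0.13, 3), 0.341497, tolerance = 1e-6)
  expect_equal(veto_tumble_bias(1, 2), 1)
  expect_error(veto_tumble_bias(-0.1, 2), "\\[0, 1\\]")
  expect_error(veto_tumble_bias(1.1, 2), "\\[0, 1\\]")
  expect_error(veto_tumble_bias(0.1, -1), "nonnegative")
})

test_that("veto tumble bias is monotone in both arguments and bounded", {
  cb <- seq(0, 1, by = 0.05)
  for (n in c(0.5, 1, 2, 3.7, 5)) {
    tb <- veto_tumble_bias(cb, n)
    expect_true(all(tb >= 0 & tb <= 1))
    expect_true(all(diff(tb) >= 0))
  }
  n <- seq(0.5, 10, by = 0.5)
  for (c0 in c(0.05, 0.13, 0.4)) {
    expect_true(all(diff(veto_tumble_bias(c0, n)) >= 0))
  }
})

test_that("eta deviation matches hand-evaluated log ratios", {
  # inverse of the veto curve by construction
  expect_equal(deviation_eta(veto_tumble_bias(0.13, 3), 0.13, 3), 0)
  # log ratio exactly 1 when tb == cb
  expect_equal(deviation_eta(0.13, 0.13, 2), -1)
  # ln(0.75)/ln(0.85) - 3
  expect_equal(deviation_eta(0.25, 0.15, 3), -1.22985498772,
               tolerance = 1e-9)
  expect_error(deviation_eta(0.2, 0, 2), "undefined")
  expect_error(deviation_eta(0.2, 1, 2), "undefined")
  expect_error(deviation_eta(1, 0.2, 2), "undefined")
})

test_that("eta composed with the veto curve vanishes on the open domain", {
  set.seed(7)
  cb <- runif(200, 0.01, 0.95)
  n <- runif(200, 1, 8)
  eta <- deviation_eta(veto_tumble_bias(cb, n), cb, n)
  expect_equal(eta, rep(0, 200), tolerance = 1e-10)
})

test_that("N_eff fit recovers exact curves regardless of cb spread", {
  for (n_eff in c(0.7, 2, 4.5)) {
    cells <- cells_on_curve(c(0.03, 0.08, 0.11, 0.19, 0.24), n_eff)
    fit <- fit_n_eff(cells)
    expect_equal(fit$n_eff, n_eff, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("single-cell N_eff fit uses the closed-form inverse", {
  fit <- fit_n_eff(tibble::tibble(tb = 0.341497, cb = 0.13))
  expect_equal(fit$n_eff, 3, tolerance = 1e-5)
  expect_equal(fit$n_cells, 1)
})

test_that("N_eff fit agrees with the brute-force grid oracle", {
  set.seed(21)
  for (rep in 1:4) {
    n_true <- runif(1, 1, 6)
    cells <- tibble::tibble(
      cb = runif(20, 0.05, 0.25),
      tb = pmin(pmax(veto_tumble_bias(cb, n_true) +
                       rnorm(20, sd = 0.02), 0), 0.99))
    fit <- fit_n_eff(cells)
    expect_equal(fit$n_eff, grid_n_eff(cells), tolerance = 1e-3)
  }
})

test_that("N_eff fit recovers a noisy generating exponent", {
  set.seed(5)
  cells <- tibble::tibble(
    cb = runif(50, 0.05, 0.25),
    tb = pmin(pmax(veto_tumble_bias(cb, 1.8) + rnorm(50, sd = 0.02),
                   0), 0.99))
  expect_equal(fit_n_eff(cells)$n_eff, 1.8, tolerance = 0.15)
})

test_that("N_eff fit excludes degenerate cells and errors when empty", {
  cells <- tibble::tibble(tb = c(0.2, 0.3), cb = c(0, 0.15))
  expect_warning(fit <- fit_n_eff(cells), "excluded")
  expect_equal(fit$n_cells, 1)
  expect_error(fit_n_eff(tibble::tibble(tb = numeric(), cb = numeric())),
               "no cells")
  expect_error(
    suppressWarnings(fit_n_eff(tibble::tibble(tb = 1, cb = 0))),
    "non-degenerate")
})

test_that("log-space objective has the closed-form ratio solution", {
  set.seed(9)
  cells <- tibble::tibble(
    cb = runif(30, 0.05, 0.3),
    tb = pmin(veto_tumble_bias(cb, 2.5) + rnorm(30, sd = 0.01), 0.99))
  x <- log1p(-cells$cb)
  y <- log1p(-cells$tb)
  expect_equal(fit_n_eff(cells, objective = "log")$n_eff,
               sum(x * y) / sum(x^2), tolerance = 1e-12)
})

test_that("fixed-curve R^2 matches a by-hand sum-of-squares computation", {
  cells <- cells_on_curve(c(0.05, 0.1, 0.15, 0.22), 3)
  expect_equal(curve_r_squared(cells, 3), 1)
  # 5 hand-specified pairs scored against the n = 2 curve
  hand <- tibble::tibble(cb = c(0.05, 0.10, 0.15, 0.20, 0.25),
                         tb = c(0.12, 0.18, 0.30, 0.33, 0.46))
  pred <- 1 - (1 - hand$cb)^2
  ss_res <- sum((hand$tb - pred)^2)
  ss_tot <- sum((hand$tb - mean(hand$tb))^2)
  expect_equal(curve_r_squared(hand, 2), 1 - ss_res / ss_tot)
  expect_error(
    curve_r_squared(tibble::tibble(cb = c(0.1, 0.2), tb = c(0.3, 0.3)), 2),
    "zero")
  expect_error(curve_r_squared(hand[1, ], 2), "two cells")
})

test_that("power-law fit solves exact and degenerate cases", {
  fit <- fit_power_law(tibble::tibble(n_flag = c(1, 4),
                                      n_eff = c(1.27, 2.54)))
  expect_equal(fit$a, 1.27, tolerance = 1e-9)
  expect_equal(fit$b, 0.5, tolerance = 1e-9)
  flat <- fit_power_law(tibble::tibble(n_flag = 1:3, n_eff = rep(1.4, 3)))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$a, 1.4, tolerance = 1e-12)
  lin <- fit_power_law(tibble::tibble(n_flag = 1:5, n_eff = 2 * (1:5)))
  expect_equal(lin$a, 2, tolerance = 1e-9)
  expect_equal(lin$b, 1, tolerance = 1e-9)
  expect_error(fit_power_law(tibble::tibble(n_flag = 1, n_eff = 1.3)),
               "two groups")
  expect_error(fit_power_law(tibble::tibble(n_flag = 1:2,
                                            n_eff = c(-1, 2))),
               "positive")
})

test_that("power-law recovery is exact on noise-free inputs", {
  set.seed(3)
  for (rep in 1:5) {
    a <- runif(1, 0.5, 3)
    b <- runif(1, -1, 1.5)
    gf <- tibble::tibble(n_flag = 1:6, n_eff = a * (1:6)^b)
    fit <- fit_power_law(gf)
    expect_equal(fit$a, a, tolerance = 1e-9)
    expect_equal(fit$b, b, tolerance = 1e-9)
  }
})

test_that("reduced chi-squared matches hand arithmetic", {
  expect_equal(reduced_chi_square(1:3, 1:3, rep(0.1, 3))$chi2_reduced, 0)
  expect_equal(
    reduced_chi_square(c(1.1, 2.2), c(1.0, 2.0), c(0.1, 0.2))$chi2_reduced,
    1)
  # mixed-residual hand example: ((0.2/0.5)^2 + (0.1/0.2)^2 + (0.1/0.1)^2)/3
  r <- reduced_chi_square(c(1.2, 2.1, 0.9), c(1.0, 2.0, 1.0),
                          c(0.5, 0.2, 0.1))
  expect_equal(r$chi2_reduced, 0.47)
  # n_params reduces the dof
  r2 <- reduced_chi_square(c(1.2, 2.1, 0.9), c(1.0, 2.0, 1.0),
                           c(0.5, 0.2, 0.1), n_params = 1)
  expect_equal(r2$chi2_reduced, 0.705)
  expect_equal(r2$dof, 2)
  expect_error(reduced_chi_square(1, 1, 0.1, n_params = 1), "freedom")
  expect_error(reduced_chi_square(1:2, 1:2, c(0.1, 0)), "positive")
})

test_that("reduced chi-squared is invariant under joint permutation", {
  set.seed(13)
  sim <- rnorm(10); obs <- rnorm(10); sem <- runif(10, 0.1, 1)
  p <- sample(10)
  expect_equal(reduced_chi_square(sim, obs, sem)$chi2_reduced,
               reduced_chi_square(sim[p], obs[p], sem[p])$chi2_reduced)
})

test_that("global reduced chi-squared sums its components", {
  a <- reduced_chi_square(c(1.2, 2.1, 0.9), c(1, 2, 1), c(0.5, 0.2, 0.1))
  b <- reduced_chi_square(c(1.1, 2.2), c(1.0, 2.0), c(0.1, 0.2))
  g <- global_reduced_chi_square(list(a, b))
  expect_equal(g$chi2_reduced, a$chi2_reduced + b$chi2_reduced)
  expect_equal(g$per_dataset, c(a$chi2_reduced, b$chi2_reduced))
  # order of datasets does not matter
  expect_equal(global_reduced_chi_square(list(b, a))$chi2_reduced,
               g$chi2_reduced)
})

test_that("tidy methods return one-row summaries", {
  fit <- fit_n_eff(cells_on_curve(c(0.1, 0.2), 2), n_flag = 3)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n_flag, 3)
  pl <- fit_power_law(tibble::tibble(n_flag = c(1, 4),
                                     n_eff = c(1.27, 2.54)))
  expect_equal(generics::tidy(pl)$estimate, c(1.27, 0.5),
               tolerance = 1e-9)
  expect_equal(generics::glance(pl)$n_groups, 2)
})
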