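test_that("uncentered R2 matches its defining formula", {
  y <- c(0.1, -0.2, 0.3)
  expect_equal(uncentered_r2(y, y), 1.0)
  expect_equal(uncentered_r2(y, rep(0, 3)), 0.0)
  expect_equal(uncentered_r2(c(1, 2), c(1, 1)), 1 - 1 / 5)  # = 0.8
  expect_error(uncentered_r2(c(0, 0), c(1, 1)), class = "undefined_r2_error")
  expect_error(uncentered_r2(1:3, 1:2), class = "argument_error")
})

test_that("fit_gains solves the exact two-parameter system", {
  set.seed(1)
  X <- cbind(rnorm(50), rnorm(50))
  y <- 2 * X[, 1] + 1 * X[, 2]
  f <- fit_gains(X, y)
  expect_equal(f$Kp, 2, tolerance = 1e-12)
  expect_equal(f$Kv, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_lt(f$rmse, 1e-12)
  expect_error(fit_gains(cbind(X[, 1], 2 * X[, 1]), y),
               class = "conditioning_error")
  expect_error(fit_gains(X[1:3, ], y[1:3]),
               class = "insufficient_data_error")
})

test_that("fit_gains matches Monte-Carlo OLS accuracy (analytic SE oracle)", {
  set.seed(2)
  n <- 500; sigma <- 0.01
  X <- cbind(rnorm(n, sd = 0.5), rnorm(n, sd = 0.5))
  se <- sigma * sqrt(diag(solve(crossprod(X))))
  err_p <- err_v <- numeric(200)
  for (r in 1:200) {
    y <- 2 * X[, 1] + 1 * X[, 2] + rnorm(n, sd = sigma)
    f <- fit_gains(X, y)
    err_p[r] <- f$Kp - 2; err_v[r] <- f$Kv - 1
  }
  expect_lt(mean(abs(err_p)), 3 * se[1])
  expect_lt(mean(abs(err_v)), 3 * se[2])
  # unbiasedness at Monte-Carlo resolution
  expect_lt(abs(mean(err_p)), 4 * se[1] / sqrt(200))
})

test_that("fit_gains equals a brute-force normal-equations solve", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 5 + seed
    X <- cbind(rnorm(n), rnorm(n))
    y <- rnorm(n)
    f <- fit_gains(X, y)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(c(f$Kp, f$Kv), as.numeric(beta), tolerance = 1e-10)
  }
})

test_that("gains are scale-equivariant and R2 scale-invariant", {
  set.seed(3)
  X <- cbind(rnorm(30), rnorm(30))
  y <- 1.5 * X[, 1] - 0.4 * X[, 2] + rnorm(30, sd = 0.1)
  f1 <- fit_gains(X, y)
  f2 <- fit_gains(X, 10 * y)
  expect_equal(c(f2$Kp, f2$Kv), 10 * c(f1$Kp, f1$Kv))
  expect_equal(f2$r2, f1$r2)
  expect_equal(f2$rmse, 10 * f1$rmse)
})

test_that("discrete-onset fit inverts the noiseless generator", {
  sim <- simulate_standing(nz_params("standing_translation",
                                     n_trials = 8, n_unperturbed = 2,
                                     seed = 5))
  f <- fit_discrete_onset(sim$dataset, "com", "moment", "pooled")
  expect_equal(f$gains$Kp, sim$truth$Kp, tolerance = 1e-9)
  expect_equal(f$gains$Kv, sim$truth$Kv, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # per-subject scope reproduces the pooled result for a single subject
  fs <- fit_discrete_onset(sim$dataset, "com", "moment", "subject")
  expect_length(fs, 1L)
  expect_equal(fs[[1]]$gains$Kp, sim$truth$Kp, tolerance = 1e-9)
  # EMG gains are direction-split and scaled by the muscle drive gain
  fe <- fit_discrete_onset(sim$dataset, "com", "emg_gas", "subject")[[1]]
  expect_true(fe$gains$direction_split)
  expect_equal(unname(fe$gains$Kp["forward"]),
               sim$truth$emg_scale[["gas"]] * sim$truth$Kp,
               tolerance = 1e-9)
  ft <- fit_discrete_onset(sim$dataset, "com", "emg_ta", "subject")[[1]]
  expect_equal(unname(ft$gains$Kp["backward"]),
               -sim$truth$emg_scale[["ta"]] * sim$truth$Kp,
               tolerance = 1e-9)
})

test_that("discrete-onset fit needs at least four usable trials", {
  sim <- simulate_standing(nz_params("standing_translation", n_trials = 6,
                                     n_unperturbed = 2, seed = 6))
  small <- balance_dataset(sim$dataset$trials[c(1, 7, 8)], validate = FALSE)
  expect_error(fit_discrete_onset(small, "com", "moment", "pooled"),
               class = "insufficient_data_error")
})

test_that("phase-binned fit recovers the raised-cosine profile", {
  sim <- simulate_walking(nz_params("belt_continuous", n_strides = 150,
                                    seed = 7))
  fb <- fit_phase_binned(sim$dataset, 16)
  tab <- fb$per_bin
  sf <- sim$truth$stance_fraction
  mids <- (tab$bin_lo + tab$bin_hi) / 2 * sf
  truth <- sim$truth$Kp_fun(mids)
  expect_gt(cor(tab$Kp, truth), 0.99)
  # each estimate lies within the true within-bin envelope where the gain
  # is appreciable (the estimate is a within-bin weighted average)
  for (b in which(truth > 0.1 * max(truth))) {
    ss <- seq(tab$bin_lo[b], tab$bin_hi[b], length.out = 40) * sf
    expect_gte(tab$Kp[b], min(sim$truth$Kp_fun(ss)) - 1e-6)
    expect_lte(tab$Kp[b], max(sim$truth$Kp_fun(ss)) + 1e-6)
  }
  expect_error(fit_phase_binned(sim$dataset, 16, min_strides = 1000L),
               class = "insufficient_data_error")
})

test_that("constant-gain fit matches binned fit when gains are constant", {
  sim <- simulate_walking(nz_params("belt_continuous", constant_gains = TRUE,
                                    true_Kp = 1.4, true_Kv = 0.5,
                                    n_strides = 60, seed = 8))
  fc <- fit_constant_gain(sim$dataset)
  fb <- fit_phase_binned(sim$dataset, 16)
  expect_equal(fc$gains$Kp, 1.4, tolerance = 1e-8)
  expect_equal(fc$gains$Kv, 0.5, tolerance = 1e-8)
  expect_equal(fb$per_bin$Kp, rep(1.4, 16), tolerance = 1e-6)
  expect_equal(fb$per_bin$Kv, rep(0.5, 16), tolerance = 1e-6)
})

test_that("strong phase variation favors the binned model", {
  sim <- simulate_walking(sim_params("belt_continuous", n_strides = 80,
                                     seed = 9))
  fb <- fit_phase_binned(sim$dataset, 16)
  fc <- fit_constant_gain(sim$dataset)
  expect_gt(fb$r2, fc$r2_bin_avg)
  expect_gt(fb$r2_overall, fc$r2_overall)
})

test_that("unit modulator reduces to the constant fit bit-for-bit", {
  sim <- simulate_walking(sim_params("belt_continuous", n_strides = 60,
                                     seed = 10))
  fc <- fit_constant_gain(sim$dataset)
  fu <- fit_modulated_gain(sim$dataset, "unit")
  expect_identical(fu$gains$Kp, fc$gains$Kp)
  expect_identical(fu$gains$Kv, fc$gains$Kv)
  expect_identical(fu$r2, fc$r2)
  expect_identical(fu$rmse, fc$rmse)
})

test_that("modulated fit inverts data generated by the modulated law", {
  # replace the moment of a noiseless constant-gain dataset by the
  # Fy-modulated law, leaving everything else canonical
  sim <- simulate_walking(nz_params("belt_continuous", constant_gains = TRUE,
                                    true_Kp = 0, true_Kv = 0,
                                    n_strides = 60, seed = 11))
  Kp_true <- 1.1; Kv_true <- 0.35
  ds <- sim$dataset
  for (i in seq_along(ds$trials)) {
    tr <- ds$trials[[i]]
    m <- tr$subject$mass; g <- tr$subject$gravity; l <- tr$subject$com_height
    td <- sim$truth$deviations[[i]]
    m_nd <- apply_delay(tr$data$grf_vertical / (m * g), 0.1, tr$fs)
    dx <- apply_delay(td$d_com_pos / l, 0.1, tr$fs)
    dv <- apply_delay(td$d_com_vel / sqrt(g * l), 0.1, tr$fs)
    extra <- m * g * l * m_nd * (Kp_true * dx + Kv_true * dv)
    extra[is.na(extra)] <- 0
    ds$trials[[i]]$data$ankle_moment <- tr$data$ankle_moment + extra
  }
  f <- fit_modulated_gain(ds, "fy")
  expect_equal(f$gains$Kp, Kp_true, tolerance = 1e-6)
  expect_equal(f$gains$Kv, Kv_true, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-9)
})

test_that("a modulator uncorrelated with the gain profile does not help", {
  sim <- simulate_walking(sim_params("belt_continuous", n_strides = 80,
                                     seed = 12))
  fc <- fit_constant_gain(sim$dataset)
  ffy <- fit_modulated_gain(sim$dataset, "fy")
  fcop <- fit_modulated_gain(sim$dataset, "cop_bound")
  fb <- fit_phase_binned(sim$dataset, 16)
  # neither sensory modulator closes the gap to the phase-binned model
  expect_lt(ffy$r2, fb$r2_overall)
  expect_lt(fcop$r2, fb$r2_overall)
})

test_that("delay sweep handles a single grid value and empty grids", {
  sim <- simulate_standing(sim_params("standing_translation", n_trials = 6,
                                      n_unperturbed = 2, seed = 13))
  sw <- delay_sensitivity(sim$dataset, 0.1)
  expect_equal(nrow(sw), 1L)
  expect_equal(attr(sw, "tau_best"), 0.1)
  expect_error(delay_sensitivity(sim$dataset, numeric(0)),
               class = "argument_error")
})

test_that("pooling EMG across directions degrades the fit", {
  sim <- simulate_standing(sim_params("standing_translation", n_trials = 12,
                                      n_unperturbed = 2, seed = 14))
  fe <- fit_discrete_onset(sim$dataset, "com", "emg_gas", "subject")[[1]]
  expect_gt(fe$per_direction$forward$r2, 0.9)
  # single regression over both directions on the same rows
  rows <- balancefb:::discrete_rows(sim$dataset$trials, "com", "emg_gas",
                                    delay_config("com"))
  pooled <- fit_gains(cbind(rows$x1, rows$x2), rows$y)
  expect_lt(pooled$r2, fe$per_direction$forward$r2 - 0.1)
})

test_that("fit results serialize to the flat CSV layout", {
  sim <- simulate_walking(sim_params("belt_continuous", n_strides = 40,
                                     seed = 15))
  fb <- fit_phase_binned(sim$dataset, 8, min_strides = 10L)
  fc <- fit_constant_gain(sim$dataset, n_bins = 8, min_strides = 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_results(list(fb, fc), path)
  tab <- read.csv(path)
  expect_named(tab, c("model", "output", "bin_lo", "bin_hi", "Kp", "Kv",
                      "r2", "rmse", "n_rows", "scope"))
  expect_equal(nrow(tab), 16L)  # 8 binned + 8 post-hoc constant rows
  expect_setequal(unique(tab$model), c("com", "constant"))
})
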