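make_fy_trial <- function(fy, fs = 100, mass = 70) {
  n <- length(fy)
  dat <- data.frame(time = (seq_len(n) - 1) / fs)
  for (cl in setdiff(TRIAL_COLUMNS, c("time", "grf_vertical")))
    dat[[cl]] <- 0
  dat$grf_vertical <- fy
  balance_trial(subject = subject_constants("S01", mass, 0.95),
                data = dat, condition = "unperturbed",
                protocol = "belt_discrete", walking_speed = 1.2, fs = fs)
}

test_that("gait events sit at threshold crossings of a square-wave Fy", {
  fs <- 100; bw <- 70 * 9.81
  fy <- rep(c(0, bw, 0, bw, 0), each = 50)  # steps every 0.5 s
  tr <- make_fy_trial(fy)
  ev <- detect_gait_events(tr, threshold_fraction = 0.05)
  expect_equal(ev$hs, c(0.50, 1.50))
  expect_equal(ev$to, c(1.00, 2.00))
})

test_that("gait events are robust to additive force noise (debounce)", {
  set.seed(42)
  bw <- 70 * 9.81
  fy <- rep(c(0, 700, 0, 700, 0), each = 50) + rnorm(250, sd = 5)
  tr <- make_fy_trial(fy)
  ev <- detect_gait_events(tr, threshold_fraction = 0.05)
  expect_equal(ev$hs, c(0.50, 1.50), tolerance = 0.02)
  expect_equal(ev$to, c(1.00, 2.00), tolerance = 0.02)
})

test_that("constant Fy yields a no-events error", {
  tr <- make_fy_trial(rep(70 * 9.81, 100))
  expect_error(detect_gait_events(tr), class = "no_events_error")
})

test_that("phase normalization is linear between heel strikes", {
  tr <- random_trial(1, n = 300, walking = TRUE, condition = "unperturbed",
                     protocol = "belt_discrete")
  ev <- list(hs = c(1.0, 2.0), to = 1.6)
  ph <- phase_normalize(tr, ev)
  at <- function(t) ph[which.min(abs(ph$time - t)), ]
  expect_equal(at(1.5)$s, 0.5)
  expect_equal(at(1.0)$s, 0.0)
  expect_equal(at(1.5)$stance_fraction, 0.6)  # toe-off at 60% of stride
  expect_true(at(1.5)$in_stance)
  expect_false(at(1.7)$in_stance)
  expect_false(at(0.5)$valid)
  expect_error(phase_normalize(tr, list(hs = c(2, 1), to = 1.5)),
               class = "event_order_error")
  expect_error(phase_normalize(tr, list(hs = 1.0, to = 1.6)),
               class = "event_error")
})

# analytic walking trial: signals are functions of phase, stride time 1 s
phase_trial <- function(n_strides, f, noise_sd = 0, seed = 1,
                        subject = subject_constants("S01", 70, 0.95),
                        condition = "unperturbed", pert = NULL) {
  fs <- 100; Ts <- 1
  n <- n_strides * fs * Ts
  tt <- (seq_len(n) - 1) / fs
  s <- (tt %% Ts) / Ts
  set.seed(seed)
  dat <- data.frame(time = tt)
  for (cl in setdiff(TRIAL_COLUMNS, "time"))
    dat[[cl]] <- f(s, cl) + rnorm(n, sd = noise_sd)
  hs <- seq(0, n_strides - 1, by = Ts)
  balance_trial(subject = subject, data = dat, condition = condition,
                protocol = "belt_continuous", walking_speed = 1.2, fs = fs,
                perturbation = pert,
                events = list(hs_left = hs, to_left = hs + 0.6,
                              hs_right = hs + 0.5,
                              to_right = head(hs, -1) + 1.1))
}

sig_fun <- function(s, cl) {
  base <- switch(cl, com_pos = 0.05 * sin(2 * pi * s),
                 com_vel = 0.3 * cos(2 * pi * s),
                 ankle_moment = 40 * pmax(sin(pi * s / 0.6), 0),
                 grf_vertical = 600 * (s < 0.6), 0.1)
  base
}

test_that("reference equals the stride when all strides are identical", {
  tr <- phase_trial(6, sig_fun)
  ref <- compute_reference(balance_dataset(list(tr)), "walking")
  # grid nodes that coincide with sample phases reproduce the stride exactly;
  # the in-between nodes are linear interpolants of the 100 Hz samples
  at_sample <- seq(1, 200, by = 2)   # s = k/100
  expect_equal(ref$means[at_sample, "com_pos"],
               0.05 * sin(2 * pi * ref$s_grid[at_sample]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ref$means[, "com_pos"], 0.05 * sin(2 * pi * ref$s_grid),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(ref$n_used, 5L)  # last partial stride has no closing HS
})

test_that("antisymmetric strides average to a zero reference", {
  f_alt <- function(sign) function(s, cl) sign * sig_fun(s, cl)
  t1 <- phase_trial(2, f_alt(1))
  t2 <- phase_trial(2, f_alt(-1))
  ref <- suppressWarnings(
    compute_reference(balance_dataset(list(t1, t2)), "walking"))
  expect_lt(max(abs(ref$means)), 1e-12)
})

test_that("reference of noisy strides converges at the Monte-Carlo rate", {
  tr <- phase_trial(100, sig_fun, noise_sd = 0.02, seed = 9)
  ref <- compute_reference(balance_dataset(list(tr)), "walking")
  err <- abs(ref$means[, "com_pos"] - 0.05 * sin(2 * pi * ref$s_grid))
  bound <- 3 * 0.02 / sqrt(ref$n_used)
  expect_gt(mean(err < bound), 0.98)  # pointwise 3-sigma, allow rare tails
  expect_lt(max(err), 2 * bound)
})

test_that("reference errors without unperturbed strides", {
  tr <- phase_trial(3, sig_fun, condition = "perturbed",
                    pert = list(onset = 1, direction = "forward",
                                magnitude = 1))
  expect_error(compute_reference(balance_dataset(list(tr),
                                                 validate = FALSE),
                                 "walking"),
               class = "reference_error")
})

test_that("deviations: identity, offset linearity, domain checks", {
  tr <- phase_trial(6, sig_fun)
  ds <- balance_dataset(list(tr))
  ref <- compute_reference(ds, "walking")
  ph <- phase_normalize(tr, list(hs = tr$events$hs_left,
                                 to = tr$events$to_left))
  dev <- compute_deviations(tr, ref, ph)
  expect_lt(max(abs(dev$d_com_pos[dev$valid])), 1e-9)
  tr2 <- tr; tr2$data$com_pos <- tr2$data$com_pos + 0.02
  dev2 <- compute_deviations(tr2, ref, ph)
  expect_equal(dev2$d_com_pos[dev2$valid],
               rep(0.02, sum(dev2$valid)), tolerance = 1e-9)
  expect_error(compute_deviations(tr, ref, NULL), class = "domain_error")
})

test_that("standing deviations subtract the 0.5 s pre-onset means", {
  tr <- random_trial(11, n = 400)
  tr$perturbation$onset <- 2.0
  ds <- balance_dataset(list(tr), validate = FALSE)
  ref <- compute_reference(ds, "standing")
  win <- tr$data$time >= 1.5 & tr$data$time < 2.0
  expect_equal(unname(ref$means["com_pos"]), mean(tr$data$com_pos[win]))
  dev <- compute_deviations(tr, ref)
  expect_equal(dev$d_com_pos, tr$data$com_pos - ref$means[["com_pos"]])
})

test_that("non-dimensionalization follows the l_max / sqrt(g l) / m g l rules", {
  cst <- subject_constants("S01", 70, 0.95)
  expect_equal(nondimensionalize(100, "torque", cst),
               100 / (70 * 9.81 * 0.95))  # = 0.153288
  expect_equal(nondimensionalize(sqrt(9.81 * 0.95), "velocity", cst), 1.0)
  expect_equal(nondimensionalize(0, "position", cst), 0)
  expect_equal(nondimensionalize(0.19, "position", cst), 0.2)
  expect_equal(nondimensionalize(0.3, "emg", cst, emg_ref = 0.6), 0.5)
  expect_error(nondimensionalize(0.3, "emg", cst),
               class = "normalization_error")
})

test_that("nondimensional deviations are subject-invariant", {
  # two subjects whose SI signals are the same nondimensional curves scaled
  # by their own l, sqrt(g l), m g l
  make <- function(m, l) {
    scale <- list(com_pos = l, com_vel = sqrt(9.81 * l),
                  ankle_moment = m * 9.81 * l)
    f <- function(s, cl) {
      sc <- scale[[cl]]
      sig_fun(s, cl) * (if (is.null(sc)) 1 else sc)
    }
    phase_trial(6, f, subject = subject_constants("X", m, l,
                                                  mvc = c(ta = 1, sol = 1,
                                                          gas = 1)))
  }
  devs <- lapply(list(c(60, 0.85), c(95, 1.05)), function(ml) {
    tr <- make(ml[1], ml[2])
    tr2 <- tr
    tr2$data$com_pos <- tr2$data$com_pos + 0.01 * ml[2]  # nondim offset 0.01
    ds <- balance_dataset(list(tr), validate = FALSE)
    ref <- compute_reference(ds, "walking")
    ph <- phase_normalize(tr2, list(hs = tr2$events$hs_left,
                                    to = tr2$events$to_left))
    d <- compute_deviations(tr2, ref, ph)
    balancefb:::nondimensionalize_deviations(d, tr2, ref)
  })
  sel <- devs[[1]]$valid
  expect_equal(devs[[1]]$d_com_pos[sel], devs[[2]]$d_com_pos[sel],
               tolerance = 1e-9)
  expect_equal(devs[[1]]$d_ankle_moment[sel], devs[[2]]$d_ankle_moment[sel],
               tolerance = 1e-9)
})

test_that("apply_delay shifts, masks, interpolates and composes", {
  x <- sin(2 * pi * (0:499) / 100)   # 1 Hz sine at 100 Hz
  expect_identical(apply_delay(x, 0, 100), x)
  y1 <- apply_delay(x, 0.01, 100)
  expect_true(is.na(y1[1]))
  expect_equal(y1[-1], x[-length(x)])
  # quarter-period delay turns sine into shifted cosine phase
  y <- apply_delay(x, 0.25, 100)
  tt <- (0:499) / 100
  expect_lt(max(abs(y - sin(2 * pi * (tt - 0.25)))[-(1:25)]), 1e-9)
  # fractional delay via linear interpolation stays within 1e-3
  yf <- apply_delay(x, 0.2513, 100)
  ok <- !is.na(yf)
  expect_lt(max(abs(yf[ok] - sin(2 * pi * (tt[ok] - 0.2513)))), 1e-3)
  # composition on integer shifts
  y12 <- apply_delay(apply_delay(x, 0.03, 100), 0.04, 100)
  y3 <- apply_delay(x, 0.07, 100)
  ok <- !is.na(y12)
  expect_equal(y12[ok], y3[ok])
  expect_error(apply_delay(x, -0.1, 100), class = "argument_error")
  expect_error(apply_delay(x, 5.0, 100), class = "delay_error")
})
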