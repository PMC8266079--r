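# Shared fixtures: all built in code at test time, nothing stored on disk.

NOISE_OFF <- c(com_pos = 0, com_vel = 0, ankle_moment = 0, emg = 0,
               grf = 0, cop = 0)

# fully noiseless stated world: no measurement noise, no independent ankle
# noise, no spontaneous sway
nz_params <- function(protocol, ...) {
  sim_params(protocol, noise = NOISE_OFF, ankle_angle_noise = 0,
             sway_rms = 0, ...)
}

# a small structurally valid trial with randomized series
random_trial <- function(seed = 1, n = 120, fs = 100,
                         condition = "perturbed",
                         protocol = "standing_translation",
                         walking = FALSE) {
  set.seed(seed)
  tt <- (seq_len(n) - 1) / fs
  dat <- data.frame(time = tt)
  for (cl in setdiff(TRIAL_COLUMNS, "time")) dat[[cl]] <- rnorm(n)
  ev <- if (walking)
    list(hs_left = c(0, 0.5), to_left = 0.3,
         hs_right = 0.25, to_right = 0.55)
  else list(hs_left = numeric(0), to_left = numeric(0),
            hs_right = numeric(0), to_right = numeric(0))
  pert <- if (condition == "perturbed")
    list(onset = tt[floor(n / 2)], direction = sample(c("forward",
                                                        "backward"), 1),
         magnitude = runif(1, 0.5, 2)) else NULL
  balance_trial(
    subject = subject_constants(sprintf("S%02d", seed), 60 + seed,
                                0.9 + seed / 100,
                                mvc = c(ta = 1, sol = 1.2, gas = 0.8)),
    data = dat, condition = condition, protocol = protocol,
    walking_speed = if (protocol == "standing_translation") 0 else 1.2,
    fs = fs, perturbation = pert, events = ev)
}

# 10-subject standing cohort simulated under default (noisy) conditions,
# fitted per subject with both models; returns per-subject R2 vectors
cohort_r2 <- function(run_seed, n_subjects = 10, n_trials = 10) {
  r2c <- r2j <- numeric(n_subjects)
  for (sb in seq_len(n_subjects)) {
    subj <- subject_constants(sprintf("S%02d", sb), 58 + 2 * sb,
                              0.88 + 0.01 * sb,
                              mvc = c(ta = 1, sol = 1, gas = 1))
    p <- sim_params("standing_translation", subject = subj,
                    n_trials = n_trials, n_unperturbed = 2,
                    seed = run_seed * 100 + sb)
    s <- simulate_standing(p)
    r2c[sb] <- fit_discrete_onset(s$dataset, "com", "moment", "pooled")$r2
    r2j[sb] <- fit_discrete_onset(s$dataset, "joint", "moment", "pooled")$r2
  }
  list(com = r2c, joint = r2j)
}
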