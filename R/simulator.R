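# Ground-truth generator: a linearized inverted pendulum whose reactive ankle
# moment is produced by the delayed proportional-derivative COM feedback law
# itself, so identification exactness is a testable property. Integration runs
# at 1 kHz with a ring-buffer delay (tau exact to 1 ms) and is downsampled to
# the canonical 100 Hz. Noise is *measurement* noise: it is added to the
# emitted signals, never into the closed loop, so the latent feedback relation
# stays exact at every noise level.

SIM_FS <- 1000L
OUT_FS <- 100L

#' Simulation parameters
#'
#' Full generative description of a synthetic dataset: subject constants,
#' true feedback gains (scalar for standing, a raised-cosine stance profile
#' for walking), neural delays, per-signal measurement-noise levels, the
#' perturbation schedule and the random seed. The defaults describe the
#' emulated experiments: platform translations with fast/medium/slow
#' acceleration profiles in standing; pelvis pushes and discrete belt-speed
#' changes at the contralateral toe-off phase; and continuous pseudo-random
#' belt-speed variation over hundreds of strides.
#'
#' @param protocol one of `"standing_translation"`, `"pelvis_push"`,
#'   `"belt_discrete"`, `"belt_continuous"`.
#' @param subject a [subject_constants()] object; `NULL` builds a default
#'   70 kg / 0.95 m subject (with unit MVC references for standing, none for
#'   walking, where EMG is normalized by peak unperturbed activity).
#' @param true_Kp,true_Kv non-dimensional scalar gains (standing, and walking
#'   when `constant_gains = TRUE`).
#' @param gain_peak_Kp,gain_peak_Kv,gain_peak_phase,gain_width walking gain
#'   profile: raised-cosine window in stride phase, peaking mid-stance
#'   (default peak at 0.30, width 0.5, i.e. support [0.05, 0.55], inside the
#'   0.6 stance fraction and zero in swing).
#' @param constant_gains use `true_Kp`/`true_Kv` at every phase instead of
#'   the raised-cosine profile.
#' @param tau_T,tau_m moment and EMG neural delays (s).
#' @param emg_scale per-muscle multiplier on the feedback drive (Eq.-style
#'   direction-gated EMG: plantarflexors rectify the positive drive, tibialis
#'   anterior the negative drive).
#' @param noise named per-signal additive Gaussian measurement noise SDs
#'   (SI units; `emg` in normalized units).
#' @param ankle_angle_noise independent noise on the ankle angle/velocity
#'   (rad, rad/s): the ankle angle is the pendulum-consistent angle plus this
#'   noise, making it correlated with, but not linearly predictive of, the
#'   COM.
#' @param stride_time,stance_fraction,walking_speed gait template constants.
#'   The default 1.0 s stride places 100 Hz samples exactly on the 200-point
#'   reference phase grid.
#' @param n_trials,n_unperturbed perturbed/unperturbed trial counts for the
#'   discrete protocols.
#' @param n_strides,n_ref_strides perturbed/unperturbed stride counts for the
#'   continuous protocol.
#' @param magnitudes peak base-acceleration magnitudes (m/s^2) cycled over
#'   perturbed trials and paired with fast/medium/slow pulse durations;
#'   `NULL` picks the protocol default (3.5/2.5/1.5 for platform
#'   translations, 1.5/1.0/0.6 for walking perturbations).
#' @param onset_phase stride phase at which discrete walking perturbations
#'   start (default 0.10, the contralateral toe-off).
#' @param belt_cutoff_hz,belt_rms low-pass cutoff and RMS (m/s^2) of the
#'   continuous pseudo-random belt acceleration.
#' @param sway_rms,sway_cutoff_hz spontaneous-sway process noise: low-pass
#'   filtered random acceleration (m/s^2) driving the deviation dynamics in
#'   every trial. Being inside the loop it scatters unperturbed trials
#'   around zero without breaking the exact delayed feedback relation.
#' @param reset_pos,reset_vel fraction of the COM deviation position/velocity
#'   retained when the base-of-support frame switches at each heel strike (a
#'   crude stand-in for the stepping strategy, which keeps the closed loop
#'   bounded through the zero-gain swing phase).
#' @param seed integer seed; every signal draws from its own named stream
#'   derived from it.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(protocol = "standing_translation",
                       subject = NULL,
                       true_Kp = 2.0, true_Kv = 0.6,
                       gain_peak_Kp = 1.2, gain_peak_Kv = 0.4,
                       gain_peak_phase = 0.30, gain_width = 0.50,
                       constant_gains = FALSE,
                       tau_T = 0.100, tau_m = 0.060,
                       emg_scale = c(ta = 0.5, sol = 0.8, gas = 0.6),
                       noise = c(com_pos = 0.002, com_vel = 0.010,
                                 ankle_moment = 1.0, emg = 0.010,
                                 grf = 5.0, cop = 0.002),
                       ankle_angle_noise = 0.02,
                       stride_time = 1.0, stance_fraction = 0.6,
                       walking_speed = 1.2,
                       n_trials = 12L, n_unperturbed = 4L,
                       n_strides = 400L, n_ref_strides = 20L,
                       magnitudes = NULL,
                       onset_phase = 0.10,
                       belt_cutoff_hz = 1.0, belt_rms = 0.10,
                       sway_rms = 0.05, sway_cutoff_hz = 0.7,
                       reset_pos = 0.1, reset_vel = 0.2,
                       seed = 1L) {
  if (!protocol %in% PROTOCOLS)
    bfb_stop("argument_error", "unknown protocol '%s'", protocol)
  # peak base accelerations, fast/medium/slow: platform translations are
  # stronger than pelvis pushes (~15% body weight) or belt steps
  if (is.null(magnitudes))
    magnitudes <- if (protocol == "standing_translation")
      c(3.5, 2.5, 1.5) else c(1.5, 1.0, 0.6)
  # standing subjects carry MVC references; walking EMG is normalized by the
  # peak unperturbed activity instead (no MVC available there)
  if (is.null(subject))
    subject <- subject_constants("SYN1", 70, 0.95,
                                 mvc = if (protocol == "standing_translation")
                                   c(ta = 1, sol = 1, gas = 1) else NULL)
  if (any(noise < 0) || ankle_angle_noise < 0)
    bfb_stop("argument_error", "noise SDs must be >= 0")
  if (!constant_gains && protocol != "standing_translation") {
    lo <- gain_peak_phase - gain_width / 2
    hi <- gain_peak_phase + gain_width / 2
    if (lo < 0 || hi > stance_fraction)
      bfb_stop("argument_error",
               "raised-cosine gain window [%.3g, %.3g] must lie inside stance",
               lo, hi)
  }
  structure(as.list(environment()), class = "sim_params")
}

# deterministic per-signal substreams: toggling one signal's noise never
# changes another signal's draws
stream_seed <- function(seed, name, idx = 0L) {
  h <- sum(utf8ToInt(name)) * 97
  as.integer((as.numeric(seed) * 2654435 + h + idx * 7919) %% (2^31 - 2)) + 1L
}

stream_rnorm <- function(n, sd, seed, name, idx) {
  if (sd == 0) return(numeric(n))
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(stream_seed(seed, name, idx))
  rnorm(n, sd = sd)
}

gain_profile_fun <- function(p) {
  if (p$protocol == "standing_translation" || p$constant_gains)
    return(list(Kp = function(s) rep(p$true_Kp, length(s)),
                Kv = function(s) rep(p$true_Kv, length(s))))
  rc <- function(s) {
    d <- s - p$gain_peak_phase
    w <- p$gain_width
    ifelse(abs(d) <= w / 2, 0.5 * (1 + cos(2 * pi * d / w)), 0)
  }
  list(Kp = function(s) p$gain_peak_Kp * rc(s),
       Kv = function(s) p$gain_peak_Kv * rc(s))
}

# core: integrate one trial's deviation dynamics and assemble signals
sim_core <- function(p, dur, pert_acc, reset_idx, phase_fun, templates,
                     trial_idx, condition, pert_meta, events) {
  g <- p$subject$gravity; l <- p$subject$com_height; m <- p$subject$mass
  n <- as.integer(round(dur * SIM_FS))
  t_hi <- (seq_len(n) - 1L) / SIM_FS
  s_hi <- phase_fun(t_hi)
  prof <- gain_profile_fun(p)
  kp_t <- prof$Kp(s_hi); kv_t <- prof$Kv(s_hi)
  sim <- ip_simulate_cpp(n, 1 / SIM_FS, g, l,
                         as.integer(round(p$tau_T * SIM_FS)),
                         kp_t, kv_t, pert_acc,
                         p$reset_pos, p$reset_vel, as.integer(reset_idx),
                         0, 0, 0.5 * l)
  if (!sim$ok)
    bfb_stop("instability_error",
             "closed loop unstable at t=%.3f s (Kp=%.3g, Kv=%.3g)",
             sim$fail_step / SIM_FS, max(kp_t), max(kv_t))
  x <- sim$x; v <- sim$v; tnd <- sim$moment_nd
  dm <- as.integer(round(p$tau_m * SIM_FS))
  xd <- c(rep(0, dm), x[seq_len(n - dm)])
  vd <- c(rep(0, dm), v[seq_len(n - dm)])
  drive <- prof$Kp(s_hi) * xd / l + prof$Kv(s_hi) * vd / sqrt(g * l)
  keep <- seq(1L, n, by = SIM_FS / OUT_FS)
  tt <- t_hi[keep]; s <- s_hi[keep]
  tmpl <- templates(s)
  dT <- m * g * l * tnd[keep]
  dx <- x[keep]; dv <- v[keep]
  drv <- drive[keep]
  emg <- list(
    ta = tmpl$emg_ta + pmax(-drv, 0) * p$emg_scale[["ta"]],
    sol = tmpl$emg_sol + pmax(drv, 0) * p$emg_scale[["sol"]],
    gas = tmpl$emg_gas + pmax(drv, 0) * p$emg_scale[["gas"]])
  nz <- function(col, sd_name, idx2)
    stream_rnorm(length(keep), p$noise[[sd_name]], p$seed, sd_name,
                 trial_idx * 101L + idx2)
  dat <- data.frame(
    time = tt,
    com_pos = tmpl$com_pos + dx + nz("com_pos", "com_pos", 1L),
    com_vel = tmpl$com_vel + dv + nz("com_vel", "com_vel", 2L),
    ankle_angle = tmpl$ankle_angle + dx / l +
      stream_rnorm(length(keep), p$ankle_angle_noise, p$seed, "q", trial_idx),
    ankle_vel = tmpl$ankle_vel + dv / l +
      stream_rnorm(length(keep), p$ankle_angle_noise, p$seed, "qd", trial_idx),
    ankle_moment = tmpl$ankle_moment + dT + nz("ankle_moment", "ankle_moment",
                                               3L),
    emg_ta = emg$ta + nz("emg_ta", "emg", 4L),
    emg_sol = emg$sol + nz("emg_sol", "emg", 5L),
    emg_gas = emg$gas + nz("emg_gas", "emg", 6L),
    grf_vertical = tmpl$grf + nz("grf", "grf", 7L),
    cop_ap = tmpl$cop + dT / (m * g) + nz("cop", "cop", 8L))
  truth <- data.frame(time = tt, s = s, d_com_pos = dx, d_com_vel = dv,
                      d_ankle_moment = dT, drive = drv)
  tr <- balance_trial(subject = p$subject, data = dat, condition = condition,
                      protocol = p$protocol,
                      walking_speed = if (p$protocol == "standing_translation")
                        0 else p$walking_speed,
                      fs = OUT_FS, perturbation = pert_meta, events = events)
  list(trial = tr, truth = truth)
}

standing_templates <- function(p) {
  m <- p$subject$mass; g <- p$subject$gravity
  function(s) list(com_pos = rep(0, length(s)), com_vel = rep(0, length(s)),
                   ankle_angle = rep(0, length(s)),
                   ankle_vel = rep(0, length(s)),
                   ankle_moment = rep(0, length(s)),
                   emg_ta = rep(0.05, length(s)),
                   emg_sol = rep(0.05, length(s)),
                   emg_gas = rep(0.05, length(s)),
                   grf = rep(m * g, length(s)),
                   cop = rep(0, length(s)))
}

walking_templates <- function(p) {
  m <- p$subject$mass; g <- p$subject$gravity
  sf <- p$stance_fraction; Ts <- p$stride_time
  heel <- -0.08; toe <- 0.17
  function(s) {
    u <- pmin(s / sf, 1)
    stance <- s < sf
    fy <- ifelse(stance, m * g * (sin(pi * u) + 0.2 * sin(3 * pi * u)), 0)
    list(
      com_pos = 0.06 * sin(2 * pi * s) - 0.02 * cos(4 * pi * s),
      com_vel = (0.06 * 2 * pi * cos(2 * pi * s) +
                   0.02 * 4 * pi * sin(4 * pi * s)) / Ts,
      ankle_angle = 0.15 * sin(2 * pi * s + 0.8),
      ankle_vel = 0.15 * 2 * pi * cos(2 * pi * s + 0.8) / Ts,
      ankle_moment = ifelse(stance, 60 * sin(pi * u)^2, 0),
      emg_ta = ifelse(stance, 0.25 * exp(-(u / 0.15)^2), 0.18),
      emg_sol = ifelse(stance, 0.30 * sin(pi * u)^2, 0.02),
      emg_gas = ifelse(stance, 0.40 * sin(pi * u^0.8)^2, 0.02),
      grf = fy,
      cop = ifelse(stance, heel + 0.02 + (toe - heel - 0.04) * u,
                   toe - 0.02))
  }
}

walking_events <- function(p, dur) {
  Ts <- p$stride_time; sf <- p$stance_fraction
  hs_l <- seq(0, dur - 1e-9, by = Ts)
  ev <- list(hs_left = hs_l, to_left = hs_l + sf * Ts,
             hs_right = hs_l + 0.5 * Ts,
             to_right = hs_l + (0.5 + sf) * Ts)
  lapply(ev, function(v) v[v < dur - 1e-9])
}

#' Simulate a perturbed-standing dataset
#'
#' Platform-translation trials: forward and backward base-acceleration pulses
#' with fast/medium/slow profiles (shorter pulses pair with larger
#' magnitudes), plus unperturbed trials. The reactive ankle moment is the
#' delayed PD feedback law applied to the COM deviation; EMG is the
#' direction-gated (half-wave rectified) feedback drive; the ankle angle is
#' the pendulum angle plus independent noise.
#'
#' @param params a [sim_params()] with `protocol = "standing_translation"`.
#' @return list with `dataset` (a `balance_dataset`) and `truth`
#'   (per-trial noiseless deviations, true gains and delays).
#' @export
simulate_standing <- function(params) {
  p <- params
  if (p$protocol != "standing_translation")
    bfb_stop("argument_error", "params$protocol must be standing_translation")
  durs <- c(0.10, 0.20, 0.30)          # fast / medium / slow pulse half-widths
  onset <- 1.5; dur <- 4.0
  n <- as.integer(dur * SIM_FS)
  tmpl <- standing_templates(p)
  trials <- list(); truths <- list()
  idx <- 0L
  schedule <- expand.grid(prof = seq_along(durs),
                          dir = c("forward", "backward"),
                          rep = seq_len(ceiling(p$n_trials / (2 * length(durs)))),
                          stringsAsFactors = FALSE)
  schedule <- schedule[seq_len(min(nrow(schedule), p$n_trials)), ]
  for (i in seq_len(nrow(schedule))) {
    idx <- idx + 1L
    pd <- durs[schedule$prof[i]]
    a <- p$magnitudes[((schedule$prof[i] - 1L) %% length(p$magnitudes)) + 1L]
    sgn <- if (schedule$dir[i] == "forward") 1 else -1
    t_hi <- (seq_len(n) - 1L) / SIM_FS
    acc <- numeric(n)
    acc[t_hi >= onset & t_hi < onset + pd] <- sgn * a
    acc[t_hi >= onset + pd & t_hi < onset + 2 * pd] <- -sgn * a
    acc <- acc + sway_noise(p, n, idx + 1L)
    res <- sim_core(p, dur, acc, integer(0), function(t) rep(0, length(t)),
                    tmpl, idx, "perturbed",
                    list(onset = onset, direction = schedule$dir[i],
                         magnitude = a),
                    list(hs_left = numeric(0), to_left = numeric(0),
                         hs_right = numeric(0), to_right = numeric(0)))
    trials[[idx]] <- res$trial; truths[[idx]] <- res$truth
  }
  for (j in seq_len(p$n_unperturbed)) {
    idx <- idx + 1L
    res <- sim_core(p, dur, sway_noise(p, n, idx + 1L), integer(0),
                    function(t) rep(0, length(t)), tmpl, idx, "unperturbed",
                    NULL,
                    list(hs_left = numeric(0), to_left = numeric(0),
                         hs_right = numeric(0), to_right = numeric(0)))
    trials[[idx]] <- res$trial; truths[[idx]] <- res$truth
  }
  dataset <- balance_dataset(trials, provenance = "synthetic")
  list(dataset = dataset,
       truth = list(Kp = p$true_Kp, Kv = p$true_Kv, tau_T = p$tau_T,
                    tau_m = p$tau_m, emg_scale = p$emg_scale,
                    deviations = truths, params = p))
}

#' Simulate a perturbed-walking dataset
#'
#' Smooth periodic gait templates (double-humped vertical GRF that vanishes
#' in swing, heel-to-toe COP progression, stance plantarflexion moment, gait
#' events emitted exactly) carry a deviation loop identical to the standing
#' one except that the feedback gains follow the phase-dependent profile and
#' the base-of-support frame switches at each heel strike. Perturbations are
#' force/belt pulses at a scheduled stride phase (`pelvis_push`,
#' `belt_discrete`) or continuous low-pass-filtered pseudo-random belt
#' acceleration (`belt_continuous`).
#'
#' @param params a [sim_params()] with a walking protocol.
#' @return list with `dataset` and `truth` (including the true gain profile
#'   on the 200-point phase grid).
#' @export
simulate_walking <- function(params) {
  p <- params
  if (p$protocol == "standing_translation")
    bfb_stop("argument_error", "params$protocol must be a walking protocol")
  Ts <- p$stride_time
  tmpl <- walking_templates(p)
  phase_fun <- function(t) (t %% Ts) / Ts
  reset_times <- function(dur) {
    # both legs' heel strikes switch the base-of-support frame
    rt <- sort(c(seq(0, dur, by = Ts), seq(0.5 * Ts, dur, by = Ts)))
    unique(as.integer(round(rt * SIM_FS)) + 1L)
  }
  trials <- list(); truths <- list()
  idx <- 0L
  add_trial <- function(dur, acc, condition, pert_meta) {
    idx <<- idx + 1L
    n <- as.integer(round(dur * SIM_FS))
    ri <- reset_times(dur); ri <- ri[ri <= n]
    res <- sim_core(p, dur, acc, ri, phase_fun, tmpl, idx, condition,
                    pert_meta, walking_events(p, dur))
    trials[[idx]] <<- res$trial; truths[[idx]] <<- res$truth
  }
  if (p$protocol == "belt_continuous") {
    dur <- p$n_strides * Ts
    n <- as.integer(round(dur * SIM_FS))
    acc <- lp_noise(n, p$belt_cutoff_hz, p$belt_rms, p$seed, "belt") +
      sway_noise(p, n, 1L)
    add_trial(dur, acc, "perturbed",
              list(onset = 0, direction = "forward",
                   magnitude = p$belt_rms))
    dur_u <- p$n_ref_strides * Ts
    n_u <- as.integer(round(dur_u * SIM_FS))
    add_trial(dur_u, sway_noise(p, n_u, 2L), "unperturbed", NULL)
  } else {
    dur <- 6 * Ts
    n <- as.integer(round(dur * SIM_FS))
    onset <- 2 * Ts + p$onset_phase * Ts
    base_dur <- if (p$protocol == "pelvis_push") 0.15 else 0.10
    # vary pulse width with magnitude so trial responses are not collinear
    dur_scale <- c(1, 2 / 3, 4 / 3)
    dirs <- rep(c("forward", "backward"), length.out = p$n_trials)
    for (i in seq_len(p$n_trials)) {
      mi <- ((i - 1L) %% length(p$magnitudes)) + 1L
      a <- p$magnitudes[mi]
      pulse_dur <- base_dur * dur_scale[((mi - 1L) %% 3L) + 1L]
      sgn <- if (dirs[i] == "forward") 1 else -1
      t_hi <- (seq_len(n) - 1L) / SIM_FS
      acc <- numeric(n)
      acc[t_hi >= onset & t_hi < onset + pulse_dur] <- sgn * a
      add_trial(dur, acc + sway_noise(p, n, i), "perturbed",
                list(onset = onset, direction = dirs[i], magnitude = a))
    }
    for (j in seq_len(p$n_unperturbed))
      add_trial(dur, sway_noise(p, n, p$n_trials + j), "unperturbed", NULL)
  }
  prof <- gain_profile_fun(p)
  s_grid <- (0:199) / 200
  dataset <- balance_dataset(trials, provenance = "synthetic")
  list(dataset = dataset,
       truth = list(profile = data.frame(s = s_grid, Kp = prof$Kp(s_grid),
                                         Kv = prof$Kv(s_grid)),
                    Kp_fun = prof$Kp, Kv_fun = prof$Kv,
                    tau_T = p$tau_T, tau_m = p$tau_m,
                    stance_fraction = p$stance_fraction,
                    deviations = truths, params = p))
}

# low-pass filtered Gaussian base acceleration (two cascaded causal
# first-order passes), scaled to the requested RMS
lp_noise <- function(n, cutoff_hz, rms, seed, name, idx = 0L) {
  if (rms == 0) return(numeric(n))
  w <- stream_rnorm(n, 1, seed, name, idx)
  alpha <- (1 / SIM_FS) / (1 / SIM_FS + 1 / (2 * pi * cutoff_hz))
  for (pass in 1:2)
    w <- as.numeric(stats::filter(alpha * w, 1 - alpha, method = "recursive"))
  w * rms / sqrt(mean(w^2))
}

# spontaneous sway: internal process noise driving the deviation dynamics.
# Unlike measurement noise it enters the closed loop, so the delayed feedback
# relation between the emitted latent signals remains exact.
sway_noise <- function(p, n, trial_idx)
  lp_noise(n, p$sway_cutoff_hz, p$sway_rms, p$seed, "sway", trial_idx)

#' Generate a deterministic suite of small canonical fixture datasets
#'
#' Writes one scaled-down dataset per protocol (canonical trial files plus a
#' ground-truth sidecar CSV with the phase grid and true gains) under `dir`.
#' The same seed reproduces the directory byte-for-byte.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
make_fixture_suite <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    standing = sim_params("standing_translation", n_trials = 8L,
                          n_unperturbed = 2L, seed = seed),
    pelvis = sim_params("pelvis_push", n_trials = 6L, n_unperturbed = 2L,
                        walking_speed = 1.25, seed = seed + 1L),
    belt = sim_params("belt_discrete", n_trials = 6L, n_unperturbed = 2L,
                      walking_speed = 1.1, seed = seed + 2L),
    continuous = sim_params("belt_continuous", n_strides = 40L,
                            n_ref_strides = 10L, seed = seed + 3L))
  for (nm in names(specs)) {
    p <- specs[[nm]]
    sim <- if (p$protocol == "standing_translation") simulate_standing(p)
           else simulate_walking(p)
    sub <- file.path(dir, nm)
    write_dataset(sim$dataset, sub)
    if (!is.null(sim$truth$profile))
      write.csv(data.frame(sim$truth$profile, tau_T = p$tau_T,
                           tau_m = p$tau_m),
                file.path(sub, "ground_truth.csv"), row.names = FALSE)
    else
      write.csv(data.frame(s = NA, Kp = sim$truth$Kp, Kv = sim$truth$Kv,
                           tau_T = p$tau_T, tau_m = p$tau_m),
                file.path(sub, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}
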