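# Regression-input preprocessing: gait events from vertical GRF, stride-phase
# normalization, unperturbed reference trajectories, phase-locked deviations,
# non-dimensionalization, and delayed-signal construction.

SIGNAL_COLUMNS <- setdiff(TRIAL_COLUMNS, "time")

#' Detect gait events from the vertical ground reaction force
#'
#' Heel strike is an upward crossing of `threshold_fraction` x body weight,
#' toe off a downward crossing, debounced by a 100 ms minimum inter-event
#' gap. Events are detected for the leg the trial's `grf_vertical` channel
#' belongs to (the analysis leg, left by convention).
#'
#' @param trial a `balance_trial` with `grf_vertical` present.
#' @param threshold_fraction threshold as a fraction of body weight
#'   (default 0.05).
#' @param leg which leg the force channel belongs to.
#' @return list with numeric vectors `hs` (heel strikes) and `to` (toe offs),
#'   seconds.
#' @export
detect_gait_events <- function(trial, threshold_fraction = 0.05,
                               leg = "left") {
  fy <- trial$data$grf_vertical
  thr <- threshold_fraction * trial$subject$mass * .G
  above <- fy > thr
  up <- which(!above[-length(above)] & above[-1]) + 1L
  down <- which(above[-length(above)] & !above[-1]) + 1L
  debounce <- function(idx) {
    if (!length(idx)) return(idx)
    keep <- idx[1]
    for (i in idx[-1]) if ((i - keep[length(keep)]) / trial$fs >= 0.1)
      keep <- c(keep, i)
    keep
  }
  up <- debounce(up); down <- debounce(down)
  if (!length(up) && !length(down))
    bfb_stop("no_events_error",
             "grf_vertical never crosses %.3g x body weight", threshold_fraction)
  list(hs = trial$data$time[up], to = trial$data$time[down], leg = leg)
}

#' Stride-phase normalization
#'
#' Assigns every sample a gait phase `s` in [0, 1), interpolated linearly
#' between consecutive heel strikes of the analysis leg, plus the within-
#' stance fraction (`u_stance`) resolved from the stride's toe off. Samples
#' outside the span of detected strides are flagged invalid.
#'
#' @param trial a `balance_trial`.
#' @param events list with `hs` and `to` vectors (e.g. from
#'   [detect_gait_events()] or the trial's stored `events`).
#' @return data.frame with columns `time`, `s`, `stride`, `in_stance`,
#'   `u_stance`, `stance_fraction`, `valid`.
#' @export
phase_normalize <- function(trial, events) {
  hs <- events$hs
  to <- events$to
  if (length(hs) < 2L)
    bfb_stop("event_error", "need >= 2 heel strikes, got %d", length(hs))
  if (any(diff(hs) <= 0) || (length(to) >= 2L && any(diff(to) <= 0)))
    bfb_stop("event_order_error", "gait events out of order")
  tt <- trial$data$time
  n <- length(tt)
  out <- data.frame(time = tt, s = NA_real_, stride = NA_integer_,
                    in_stance = FALSE, u_stance = NA_real_,
                    stance_fraction = NA_real_, valid = FALSE)
  for (i in seq_len(length(hs) - 1L)) {
    t0 <- hs[i]; t1 <- hs[i + 1L]
    sel <- tt >= t0 & tt < t1
    if (!any(sel)) next
    out$s[sel] <- (tt[sel] - t0) / (t1 - t0)
    out$stride[sel] <- i
    out$valid[sel] <- TRUE
    to_i <- to[to > t0 & to < t1]
    if (length(to_i)) {
      to_i <- to_i[1]
      sf <- (to_i - t0) / (t1 - t0)
      out$stance_fraction[sel] <- sf
      st <- sel & tt < to_i
      out$in_stance[st] <- TRUE
      out$u_stance[st] <- (tt[st] - t0) / (to_i - t0)
    }
  }
  out
}

#' Reference trajectory from unperturbed data
#'
#' Standing: scalar per-signal means over the 0.5 s pre-onset windows of the
#' perturbation trials (falling back to the full span of unperturbed trials
#' when no onsets exist). Walking: per-signal means over unperturbed strides
#' on a fixed 200-point stride-phase grid.
#'
#' @param dataset a `balance_dataset` (walking mode uses its unperturbed
#'   trials; standing mode its perturbed trials' pre-onset windows).
#' @param mode `"standing"` or `"walking"`.
#' @param n_grid phase grid resolution for walking references.
#' @return an object of class `reference_trajectory`.
#' @export
compute_reference <- function(dataset, mode = c("standing", "walking"),
                              n_grid = 200L) {
  mode <- match.arg(mode)
  if (mode == "standing") {
    acc <- matrix(0, nrow = 0, ncol = length(SIGNAL_COLUMNS),
                  dimnames = list(NULL, SIGNAL_COLUMNS))
    n_used <- 0L
    pert <- Filter(function(tr) tr$condition == "perturbed", dataset$trials)
    src <- if (length(pert)) pert else
      Filter(function(tr) tr$condition == "unperturbed", dataset$trials)
    if (!length(src))
      bfb_stop("reference_error", "no trials available to build a reference")
    for (tr in src) {
      if (!is.null(tr$perturbation)) {
        on <- tr$perturbation$onset
        sel <- tr$data$time >= on - 0.5 & tr$data$time < on
      } else sel <- rep(TRUE, nrow(tr$data))
      if (!any(sel)) next
      acc <- rbind(acc, colMeans(as.matrix(tr$data[sel, SIGNAL_COLUMNS])))
      n_used <- n_used + 1L
    }
    if (!n_used)
      bfb_stop("reference_error", "no usable pre-onset windows")
    return(structure(list(mode = "standing",
                          means = colMeans(acc), n_used = n_used),
                     class = "reference_trajectory"))
  }
  # walking: phase-average unperturbed strides on the grid
  s_grid <- (seq_len(n_grid) - 1L) / n_grid
  sums <- matrix(0, nrow = n_grid, ncol = length(SIGNAL_COLUMNS),
                 dimnames = list(NULL, SIGNAL_COLUMNS))
  n_str <- 0L
  for (tr in Filter(function(t) t$condition == "unperturbed", dataset$trials)) {
    ev <- list(hs = tr$events$hs_left, to = tr$events$to_left)
    if (length(ev$hs) < 2L) next
    ph <- phase_normalize(tr, ev)
    for (i in unique(ph$stride[ph$valid])) {
      sel <- which(ph$stride == i)
      if (length(sel) < 4L) next
      s <- ph$s[sel]
      # periodic linear interpolation onto the grid
      for (cl in SIGNAL_COLUMNS) {
        v <- tr$data[[cl]][sel]
        sums[, cl] <- sums[, cl] +
          approx(c(s, s[length(s)] + diff(s)[1]), c(v, v[1]),
                 xout = s_grid, rule = 2)$y
      }
      n_str <- n_str + 1L
    }
  }
  if (!n_str)
    bfb_stop("reference_error", "no unperturbed strides to build a reference")
  if (n_str < 5L)
    warning(sprintf("reference built from only %d unperturbed strides", n_str))
  structure(list(mode = "walking", s_grid = s_grid, means = sums / n_str,
                 n_used = n_str),
            class = "reference_trajectory")
}

ref_eval <- function(ref, signal, s) {
  # periodic linear interpolation of a walking reference at phases s
  g <- ref$s_grid
  v <- ref$means[, signal]
  approx(c(g, 1), c(v, v[1]), xout = s)$y
}

#' Deviations from the reference
#'
#' Walking deviations are phase-locked: measured minus the reference
#' evaluated at the sample's own stride phase. Standing deviations subtract
#' the scalar pre-onset means. Samples without a valid phase are flagged
#' invalid (never imputed).
#'
#' @param trial a `balance_trial`.
#' @param ref a `reference_trajectory`.
#' @param phase for walking references, the data.frame from
#'   [phase_normalize()]; ignored for standing.
#' @return data.frame of per-sample deviations (columns `d_<signal>`), plus
#'   `time`, phase columns and a `valid` flag.
#' @export
compute_deviations <- function(trial, ref, phase = NULL) {
  dat <- trial$data
  if (ref$mode == "standing") {
    out <- data.frame(time = dat$time)
    for (cl in SIGNAL_COLUMNS)
      out[[paste0("d_", cl)]] <- dat[[cl]] - ref$means[[cl]]
    out$valid <- TRUE
    return(out)
  }
  if (is.null(phase))
    bfb_stop("domain_error", "walking deviations require a phase table")
  if (!any(phase$valid))
    bfb_stop("domain_error", "no sample has a phase inside the reference domain")
  out <- phase
  for (cl in SIGNAL_COLUMNS) {
    d <- rep(NA_real_, nrow(dat))
    ok <- phase$valid
    d[ok] <- dat[[cl]][ok] - ref_eval(ref, cl, phase$s[ok])
    out[[paste0("d_", cl)]] <- d
  }
  out
}

#' Non-dimensionalization
#'
#' Positions are scaled by the standing COM height l_max, velocities by
#' sqrt(g l_max), torques by m g l_max, and EMG by a reference activity
#' (maximal voluntary contraction for standing; the peak of the
#' gait-cycle-average unperturbed activity for walking).
#'
#' @param x numeric quantity (vector ok).
#' @param kind one of `"position"`, `"velocity"`, `"torque"`, `"emg"`.
#' @param const a [subject_constants()] object.
#' @param emg_ref EMG normalization reference (required for `kind = "emg"`).
#' @return the non-dimensional quantity.
#' @export
nondimensionalize <- function(x, kind = c("position", "velocity", "torque",
                                          "emg"),
                              const, emg_ref = NULL) {
  kind <- match.arg(kind)
  g <- const$gravity; l <- const$com_height; m <- const$mass
  switch(kind,
         position = x / l,
         velocity = x / sqrt(g * l),
         torque   = x / (m * g * l),
         emg      = {
           if (is.null(emg_ref) || !is.finite(emg_ref) || emg_ref <= 0)
             bfb_stop("normalization_error",
                      "missing MVC/peak reference for EMG normalization")
           x / emg_ref
         })
}

# EMG reference per muscle: MVC when stored on the subject, else the peak of
# the phase-averaged unperturbed activity (walking reference), else error.
emg_reference <- function(trial, ref) {
  vapply(MUSCLES, function(mu) {
    mvc <- trial$subject$mvc[[mu]] %||% NA_real_
    if (is.finite(mvc)) return(mvc)
    if (ref$mode == "walking") return(max(ref$means[, paste0("emg_", mu)]))
    bfb_stop("normalization_error",
             "no MVC stored and no walking reference for muscle '%s'", mu)
  }, numeric(1))
}

# apply the per-kind scalings to a deviation table in place
nondimensionalize_deviations <- function(dev, trial, ref) {
  s <- trial$subject
  dev$d_com_pos <- nondimensionalize(dev$d_com_pos, "position", s)
  dev$d_com_vel <- nondimensionalize(dev$d_com_vel, "velocity", s)
  dev$d_ankle_moment <- nondimensionalize(dev$d_ankle_moment, "torque", s)
  er <- emg_reference(trial, ref)
  for (mu in MUSCLES) {
    cl <- paste0("d_emg_", mu)
    dev[[cl]] <- nondimensionalize(dev[[cl]], "emg", s, emg_ref = er[[mu]])
  }
  dev  # ankle angle/velocity stay in rad, rad/s
}

#' Delay a sampled signal
#'
#' Returns `y(t) = x(t - tau)`. Delays that are integer multiples of the
#' sample period are exact shifts; otherwise the delayed value is obtained by
#' linear interpolation. The leading `tau` seconds are marked invalid (`NA`),
#' never zero-filled, so they are excluded from regressions.
#'
#' @param x numeric signal sampled at `fs`.
#' @param tau delay in seconds (>= 0).
#' @param fs sampling rate in Hz.
#' @return numeric vector of the same length with leading `NA`s.
#' @export
apply_delay <- function(x, tau, fs) {
  if (!is.finite(tau) || tau < 0)
    bfb_stop("argument_error", "tau must be a non-negative number")
  n <- length(x)
  if (tau >= n / fs)
    bfb_stop("delay_error", "tau (%g s) is not shorter than the signal (%g s)",
             tau, n / fs)
  if (tau == 0) return(x)
  shift <- tau * fs
  if (abs(shift - round(shift)) < 1e-9) {
    k <- as.integer(round(shift))
    return(c(rep(NA_real_, k), x[seq_len(n - k)]))
  }
  idx <- seq_len(n) - shift           # fractional source index
  y <- approx(seq_len(n), x, xout = idx)$y
  y[idx < 1] <- NA_real_
  y
}
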