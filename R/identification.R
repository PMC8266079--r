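# Delayed feedback-gain identification: no-intercept two-parameter least
# squares from delayed kinematic deviations to reactive ankle moment or EMG,
# at discrete onsets or binned over the stance phase, pooled or per subject,
# with constant-gain and sensory-modulated variants and a delay sweep.

#' Neural-delay configuration
#'
#' Default latencies between a kinematic deviation and its reflection in
#' muscle activity (`tau_m`) or joint moment (`tau_T`, which additionally
#' includes the electromechanical delay). The COM (task-level) model uses
#' 60/100 ms; the ankle-joint (local) model 40/80 ms, reflecting the shorter
#' latency of local reflex pathways.
#'
#' @param model `"com"` or `"joint"`.
#' @param tau_m,tau_T optional overrides, seconds (>= 0).
#' @return list with `tau_m`, `tau_T`, `model`.
#' @export
delay_config <- function(model = c("com", "joint"), tau_m = NULL,
                         tau_T = NULL) {
  model <- match.arg(model)
  def <- if (model == "com") c(0.060, 0.100) else c(0.040, 0.080)
  tau_m <- tau_m %||% def[1]
  tau_T <- tau_T %||% def[2]
  if (tau_m < 0 || tau_T < 0)
    bfb_stop("argument_error", "delays must be >= 0")
  list(tau_m = tau_m, tau_T = tau_T, model = model)
}

#' Uncentered coefficient of determination
#'
#' `1 - sum((y_meas - y_mod)^2) / sum(y_meas^2)`, without mean-centering.
#' Appropriate for no-intercept models of deviations from a reference; can be
#' negative, and is reported as-is.
#'
#' @param y_meas measured values.
#' @param y_mod model-reconstructed values.
#' @return the uncentered R-squared.
#' @export
uncentered_r2 <- function(y_meas, y_mod) {
  if (length(y_meas) != length(y_mod) || !length(y_meas))
    bfb_stop("argument_error", "y_meas and y_mod must have equal length >= 1")
  ss <- sum(y_meas^2)
  if (ss <= 0)
    bfb_stop("undefined_r2_error", "sum(y_meas^2) is zero; R2 undefined")
  1 - sum((y_meas - y_mod)^2) / ss
}

new_fit_result <- function(model, output, scope, Kp, Kv, delays, r2, rmse,
                           n_rows, bins = NULL, per_bin = NULL,
                           per_direction = NULL, direction_split = FALSE,
                           extra = list()) {
  structure(c(list(model = model, output = output, scope = scope,
                   gains = list(Kp = Kp, Kv = Kv, bins = bins,
                                delays = delays,
                                direction_split = direction_split),
                   r2 = r2, rmse = rmse, n_rows = n_rows,
                   per_bin = per_bin, per_direction = per_direction),
              extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s output=%s scope=%s\n",
              x$model, x$output, x$scope))
  if (length(x$gains$Kp) == 1L && is.null(x$per_bin))
    cat(sprintf("  Kp=%.4g Kv=%.4g  R2=%.4g RMSE=%.4g (n=%d)\n",
                x$gains$Kp, x$gains$Kv, x$r2, x$rmse, x$n_rows))
  else
    cat(sprintf("  %d bins; stance-average R2=%.4g RMSE=%.4g (n=%d)\n",
                length(x$gains$Kp), x$r2, x$rmse, x$n_rows))
  if (!is.null(x$per_direction))
    for (d in names(x$per_direction))
      cat(sprintf("  [%s] Kp=%.4g Kv=%.4g R2=%.4g\n", d,
                  x$per_direction[[d]]$Kp, x$per_direction[[d]]$Kv,
                  x$per_direction[[d]]$r2))
  invisible(x)
}

#' Two-parameter no-intercept least squares
#'
#' Ordinary least squares of the response on exactly two regressors (delayed
#' position and velocity deviations), with no intercept: all quantities are
#' deviations from a reference, and the fit statistic (uncentered R-squared)
#' is likewise uncentered.
#'
#' @param X numeric matrix with two columns (delayed position, velocity).
#' @param y numeric response vector.
#' @param cond_limit condition-number limit above which the design is
#'   declared collinear.
#' @return list with `Kp`, `Kv`, `r2`, `rmse`, `n_rows`, `cond`.
#' @export
fit_gains <- function(X, y, cond_limit = 1e8) {
  X <- as.matrix(X)
  if (ncol(X) != 2L)
    bfb_stop("argument_error", "X must have exactly two columns")
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(X) < 4L)
    bfb_stop("insufficient_data_error",
             "need >= 4 valid rows, got %d", nrow(X))
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- if (sv[2] > 0) sv[1] / sv[2] else Inf
  if (!is.finite(cond) || cond > cond_limit)
    bfb_stop("conditioning_error",
             "rank-deficient design (condition number %.3g)", cond)
  beta <- qr.solve(X, y)
  yhat <- drop(X %*% beta)
  list(Kp = unname(beta[1]), Kv = unname(beta[2]),
       # an all-zero response (e.g. a noiseless swing bin) has no defined R2
       r2 = if (sum(y^2) > 0) uncentered_r2(y, yhat) else NA_real_,
       rmse = sqrt(mean((y - yhat)^2)),
       n_rows = length(y), cond = cond)
}

# ---- shared row builders ----------------------------------------------------

model_input_cols <- function(model) {
  if (model == "com") c("d_com_pos", "d_com_vel")
  else c("d_ankle_angle", "d_ankle_vel")
}

output_col <- function(output) {
  if (output == "moment") "d_ankle_moment" else paste0("d_", output)
}

is_standing <- function(dataset)
  all(vapply(dataset$trials, function(tr) tr$protocol, character(1)) ==
        "standing_translation")

trial_groups <- function(dataset) {
  key <- vapply(dataset$trials, function(tr)
    paste(tr$subject$subject_id, tr$walking_speed, sep = "@"), character(1))
  split(dataset$trials, key)
}

trial_events <- function(trial) {
  if (length(trial$events$hs_left) >= 2L)
    list(hs = trial$events$hs_left, to = trial$events$to_left)
  else detect_gait_events(trial)
}

nearest_index <- function(tt, t, fs) {
  i <- which.min(abs(tt - t))
  if (abs(tt[i] - t) > 0.5 / fs + 1e-9) return(NA_integer_)
  i
}

# one regression row per (trial x onset): inputs at onset + t_input, output at
# onset + t_input + tau. Unperturbed trials contribute rows at the matching
# time offsets (standing) or stride phases (walking) — the near-zero rows.
discrete_rows <- function(trials, model, output, delays, t_input = 0.150) {
  standing <- trials[[1]]$protocol == "standing_translation"
  ds_grp <- balance_dataset(trials, validate = FALSE)
  ref <- compute_reference(ds_grp,
                           mode = if (standing) "standing" else "walking")
  tau <- if (output == "moment") delays$tau_T else delays$tau_m
  in_cols <- model_input_cols(model)
  out_col <- output_col(output)
  pert <- Filter(function(tr) tr$condition == "perturbed", trials)
  unpert <- Filter(function(tr) tr$condition == "unperturbed", trials)
  if (!length(pert))
    bfb_stop("insufficient_data_error", "no perturbed trials in group")
  rows <- list()
  add_row <- function(dev, tr, t_in, direction) {
    i_in <- nearest_index(dev$time, t_in, tr$fs)
    i_out <- nearest_index(dev$time, t_in + tau, tr$fs)
    if (is.na(i_in) || is.na(i_out)) return()
    vals <- c(dev[[in_cols[1]]][i_in], dev[[in_cols[2]]][i_in],
              dev[[out_col]][i_out])
    if (anyNA(vals)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      x1 = vals[1], x2 = vals[2], y = vals[3],
      direction = direction, subject = tr$subject$subject_id)
  }
  offsets <- numeric(0)   # input-sample offset after the preceding heel strike
  onsets <- numeric(0)
  for (tr in pert) {
    ph <- if (standing) NULL else phase_normalize(tr, trial_events(tr))
    dev <- nondimensionalize_deviations(compute_deviations(tr, ref, ph),
                                        tr, ref)
    t_in <- tr$perturbation$onset + t_input
    add_row(dev, tr, t_in, tr$perturbation$direction)
    onsets <- c(onsets, tr$perturbation$onset)
    if (!standing) {
      hs <- trial_events(tr)$hs
      prev <- max(hs[hs <= t_in], -Inf)
      if (is.finite(prev)) offsets <- c(offsets, t_in - prev)
    }
  }
  for (tr in unpert) {
    ph <- if (standing) NULL else phase_normalize(tr, trial_events(tr))
    dev <- nondimensionalize_deviations(compute_deviations(tr, ref, ph),
                                        tr, ref)
    if (standing) {
      add_row(dev, tr, stats::median(onsets) + t_input, "none")
    } else if (length(offsets)) {
      off <- mean(offsets)
      hs <- trial_events(tr)$hs
      for (h in hs[-length(hs)]) add_row(dev, tr, h + off, "none")
    }
  }
  do.call(rbind, rows)
}

#' Discrete-onset feedback-gain fit
#'
#' One regression row per perturbation: kinematic deviations sampled 150 ms
#' after perturbation onset, response sampled a neural delay later (moment:
#' +100 ms for the COM model, +80 ms for the joint model; EMG: +60/40 ms).
#' Unperturbed trials contribute near-zero rows at matching offsets. Moment
#' fits pool both perturbation directions in a single regression; EMG fits
#' estimate separate gains per direction.
#'
#' @param dataset a `balance_dataset` with perturbed trials.
#' @param model `"com"` (task-level) or `"joint"` (local ankle kinematics).
#' @param output `"moment"` or one of `"emg_ta"`, `"emg_sol"`, `"emg_gas"`.
#' @param scope `"pooled"` (stack all subjects' non-dimensional rows) or
#'   `"subject"` (named list of per-subject fits).
#' @param delays optional [delay_config()] override.
#' @param t_input input sampling latency after onset (s), default 0.150.
#' @return a `fit_result`, or a named list of them for `scope = "subject"`.
#' @export
fit_discrete_onset <- function(dataset, model = c("com", "joint"),
                               output = "moment",
                               scope = c("pooled", "subject"),
                               delays = NULL, t_input = 0.150) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  delays <- delays %||% delay_config(model)
  stopifnot(output %in% c("moment", paste0("emg_", MUSCLES)))
  groups <- trial_groups(dataset)
  grp_rows <- lapply(groups, discrete_rows, model = model, output = output,
                     delays = delays, t_input = t_input)
  fit_one <- function(rows, scope_label) {
    if (is.null(rows) || nrow(rows) < 4L)
      bfb_stop("insufficient_data_error",
               "fewer than 4 usable trials for scope %s", scope_label)
    if (output == "moment" || output == "both_directions_emg") {
      f <- fit_gains(cbind(rows$x1, rows$x2), rows$y)
      return(new_fit_result(model, output, scope_label, f$Kp, f$Kv, delays,
                            f$r2, f$rmse, f$n_rows))
    }
    # EMG: direction-split gains; unperturbed rows enter both fits
    per_dir <- list()
    yhat <- rep(NA_real_, nrow(rows))
    for (d in c("forward", "backward")) {
      sel <- rows$direction %in% c(d, "none")
      # a muscle silent for this direction (gated out) has nothing to fit
      if (sum(sel) < 4L || sum(rows$y[sel]^2) == 0) next
      f <- fit_gains(cbind(rows$x1[sel], rows$x2[sel]), rows$y[sel])
      per_dir[[d]] <- f
      own <- rows$direction == d
      yhat[own] <- f$Kp * rows$x1[own] + f$Kv * rows$x2[own]
    }
    if (!length(per_dir))
      bfb_stop("insufficient_data_error", "no direction has >= 4 EMG rows")
    scored <- !is.na(yhat)
    r2 <- uncentered_r2(rows$y[scored], yhat[scored])
    rmse <- sqrt(mean((rows$y[scored] - yhat[scored])^2))
    new_fit_result(model, output, scope_label,
                   Kp = vapply(per_dir, `[[`, numeric(1), "Kp"),
                   Kv = vapply(per_dir, `[[`, numeric(1), "Kv"),
                   delays, r2, rmse, sum(scored),
                   per_direction = per_dir, direction_split = TRUE)
  }
  if (scope == "pooled")
    return(fit_one(do.call(rbind, grp_rows), "pooled"))
  all_rows <- do.call(rbind, grp_rows)
  subj <- unique(all_rows$subject)
  setNames(lapply(subj, function(sb)
    fit_one(all_rows[all_rows$subject == sb, ], paste0("subject:", sb))),
    subj)
}

# stance/stride rows for the binned, constant and modulated walking fits:
# response and (already delayed) regressors at every valid sample, tagged by
# phase bin. Modulator columns (delayed, non-dimensional) are always carried.
binned_rows <- function(dataset, model, delays, n_bins,
                        domain = c("stance", "stride")) {
  domain <- match.arg(domain)
  rows <- list()
  n_strides <- 0L
  for (grp in trial_groups(dataset)) {
    ref <- compute_reference(balance_dataset(grp, validate = FALSE),
                             mode = "walking")
    for (tr in Filter(function(t) t$condition == "perturbed", grp)) {
      ph <- phase_normalize(tr, trial_events(tr))
      n_strides <- n_strides + length(unique(ph$stride[ph$valid]))
      dev <- nondimensionalize_deviations(compute_deviations(tr, ref, ph),
                                          tr, ref)
      in_cols <- model_input_cols(model)
      x1 <- apply_delay(dev[[in_cols[1]]], delays$tau_T, tr$fs)
      x2 <- apply_delay(dev[[in_cols[2]]], delays$tau_T, tr$fs)
      fy_nd <- tr$data$grf_vertical / (tr$subject$mass * .G)
      foot_len <- tr$foot$toe - tr$foot$heel
      copb <- pmin(tr$data$cop_ap - tr$foot$heel,
                   tr$foot$toe - tr$data$cop_ap) / foot_len
      m_fy <- apply_delay(fy_nd, delays$tau_T, tr$fs)
      m_cop <- apply_delay(copb, delays$tau_T, tr$fs)
      frac <- if (domain == "stance") ph$u_stance else ph$s
      keep <- ph$valid & !is.na(frac) & !is.na(x1) & !is.na(x2) &
        (domain == "stride" | ph$in_stance)
      if (!any(keep)) next
      bin <- pmin(floor(frac[keep] * n_bins) + 1L, n_bins)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = bin, x1 = x1[keep], x2 = x2[keep],
        y = dev$d_ankle_moment[keep], m_fy = m_fy[keep], m_cop = m_cop[keep],
        subject = tr$subject$subject_id)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    bfb_stop("insufficient_data_error", "no usable stance samples")
  attr(out, "n_strides") <- n_strides
  out
}

bin_edges <- function(n_bins) cbind(lo = (0:(n_bins - 1)) / n_bins,
                                    hi = (1:n_bins) / n_bins)

per_bin_table <- function(rows, n_bins, predict_fun, fit_fun = NULL) {
  ed <- bin_edges(n_bins)
  tab <- data.frame(bin = seq_len(n_bins), bin_lo = ed[, "lo"],
                    bin_hi = ed[, "hi"], Kp = NA_real_, Kv = NA_real_,
                    r2 = NA_real_, rmse = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    sel <- rows$bin == b
    nb <- sum(sel)
    tab$n[b] <- nb
    if (nb < 4L) next   # empty/starved bin: flagged absent, never zero-filled
    if (!is.null(fit_fun)) {
      f <- fit_fun(rows[sel, ])
      tab$Kp[b] <- f$Kp; tab$Kv[b] <- f$Kv
      yhat <- f$Kp * rows$x1[sel] + f$Kv * rows$x2[sel]
    } else {
      yhat <- predict_fun(rows[sel, ])
    }
    y <- rows$y[sel]
    if (sum(y^2) > 0) tab$r2[b] <- uncentered_r2(y, yhat)
    tab$rmse[b] <- sqrt(mean((y - yhat)^2))
  }
  tab
}

#' Phase-binned feedback-gain fit
#'
#' Divides the stance phase (or the full stride with `domain = "stride"`)
#' into `n_bins` bins and solves an independent two-parameter regression in
#' each: response is the ankle-moment deviation at every sample in the bin,
#' regressors are the delayed kinematic deviations. Reports per-bin gains and
#' fit statistics plus their stance averages.
#'
#' @inheritParams fit_discrete_onset
#' @param n_bins number of phase bins (default 16 over stance).
#' @param domain `"stance"` (bins span stance exactly) or `"stride"`.
#' @param min_strides lower bound on the number of strides available.
#' @return a `fit_result` with vector gains and a `per_bin` table; `r2` and
#'   `rmse` are the averages over non-absent bins, `r2_overall` the uncentered
#'   R-squared over all rows.
#' @export
fit_phase_binned <- function(dataset, n_bins = 16L, model = c("com", "joint"),
                             output = "moment", delays = NULL,
                             domain = c("stance", "stride"),
                             min_strides = 20L) {
  model <- match.arg(model)
  domain <- match.arg(domain)
  if (output != "moment")
    bfb_stop("argument_error", "phase-binned fits support output = 'moment'")
  delays <- delays %||% delay_config(model)
  rows <- binned_rows(dataset, model, delays, n_bins, domain)
  if (attr(rows, "n_strides") < min_strides)
    bfb_stop("insufficient_data_error", "need >= %d strides, got %d",
             min_strides, attr(rows, "n_strides"))
  tab <- per_bin_table(rows, n_bins, NULL,
                       fit_fun = function(rr) fit_gains(cbind(rr$x1, rr$x2),
                                                        rr$y))
  yhat <- tab$Kp[rows$bin] * rows$x1 + tab$Kv[rows$bin] * rows$x2
  sc <- !is.na(yhat)
  new_fit_result(model, output, "pooled", Kp = tab$Kp, Kv = tab$Kv, delays,
                 r2 = mean(tab$r2, na.rm = TRUE),
                 rmse = mean(tab$rmse, na.rm = TRUE),
                 n_rows = nrow(rows), bins = bin_edges(n_bins),
                 per_bin = tab,
                 extra = list(r2_overall = uncentered_r2(rows$y[sc], yhat[sc]),
                              domain = domain))
}

#' Constant-gain fit over the stance phase
#'
#' Single (Kp, Kv) pair over all stance rows, with per-bin fit statistics of
#' that one model evaluated post hoc for comparison with the phase-binned
#' fit.
#'
#' @inheritParams fit_phase_binned
#' @return a `fit_result` with `model = "constant"`.
#' @export
fit_constant_gain <- function(dataset, n_bins = 16L, model = c("com", "joint"),
                              delays = NULL, min_strides = 20L) {
  model <- match.arg(model)
  delays <- delays %||% delay_config(model)
  rows <- binned_rows(dataset, model, delays, n_bins, "stance")
  if (attr(rows, "n_strides") < min_strides)
    bfb_stop("insufficient_data_error", "need >= %d strides, got %d",
             min_strides, attr(rows, "n_strides"))
  f <- fit_gains(cbind(rows$x1, rows$x2), rows$y)
  tab <- per_bin_table(rows, n_bins,
                       predict_fun = function(rr) f$Kp * rr$x1 + f$Kv * rr$x2)
  tab$Kp <- f$Kp; tab$Kv <- f$Kv
  new_fit_result("constant", "moment", "pooled", Kp = f$Kp, Kv = f$Kv, delays,
                 r2 = f$r2, rmse = f$rmse, n_rows = f$n_rows,
                 bins = bin_edges(n_bins), per_bin = tab,
                 extra = list(r2_overall = f$r2,
                              r2_bin_avg = mean(tab$r2, na.rm = TRUE),
                              rmse_bin_avg = mean(tab$rmse, na.rm = TRUE)))
}

#' Sensory-modulated constant-gain fit
#'
#' Constant COM feedback gains multiplied by a delayed sensory modulator:
#' the vertical ground reaction force (`"fy"`, non-dimensionalized by body
#' weight) or the fore-aft distance between the COP and the nearest foot
#' bound (`"cop_bound"`, non-dimensionalized by foot length). The model
#' `dT(t) = M(t - tau) (Kp dCOM(t - tau) + Kv dCOMdot(t - tau))` is linear in
#' (Kp, Kv) given M and is solved on modulator-scaled regressors.
#' `modulator = "unit"` (M = 1) reduces exactly to [fit_constant_gain()].
#'
#' @inheritParams fit_phase_binned
#' @param modulator `"fy"`, `"cop_bound"`, or `"unit"`.
#' @return a `fit_result` with `model = "fy_modulated"`, `"cop_modulated"` or
#'   `"constant"`.
#' @export
fit_modulated_gain <- function(dataset, modulator = c("fy", "cop_bound",
                                                      "unit"),
                               n_bins = 16L, model = "com", delays = NULL,
                               min_strides = 20L) {
  modulator <- match.arg(modulator)
  delays <- delays %||% delay_config(model)
  rows <- binned_rows(dataset, model, delays, n_bins, "stance")
  if (attr(rows, "n_strides") < min_strides)
    bfb_stop("insufficient_data_error", "need >= %d strides, got %d",
             min_strides, attr(rows, "n_strides"))
  m <- switch(modulator, fy = rows$m_fy, cop_bound = rows$m_cop,
              unit = rep(1, nrow(rows)))
  if (all(abs(m) < 1e-12, na.rm = TRUE))
    bfb_stop("degenerate_modulator_error",
             "modulator is identically zero over stance")
  f <- fit_gains(cbind(rows$x1 * m, rows$x2 * m), rows$y)
  tab <- per_bin_table(rows, n_bins, predict_fun = function(rr) {
    mm <- switch(modulator, fy = rr$m_fy, cop_bound = rr$m_cop,
                 unit = rep(1, nrow(rr)))
    f$Kp * rr$x1 * mm + f$Kv * rr$x2 * mm
  })
  tab$Kp <- f$Kp; tab$Kv <- f$Kv
  tag <- switch(modulator, fy = "fy_modulated", cop_bound = "cop_modulated",
                unit = "constant")
  new_fit_result(tag, "moment", "pooled", Kp = f$Kp, Kv = f$Kv, delays,
                 r2 = f$r2, rmse = f$rmse, n_rows = f$n_rows,
                 bins = bin_edges(n_bins), per_bin = tab,
                 extra = list(r2_overall = f$r2,
                              r2_bin_avg = mean(tab$r2, na.rm = TRUE),
                              rmse_bin_avg = mean(tab$rmse, na.rm = TRUE)))
}

#' Delay sensitivity sweep
#'
#' Reruns the discrete-onset fit with the response delay swept over a grid
#' and reports the R-squared curve and its argmax. A peak near the default
#' 100 ms supports a feedback interpretation rather than passive skeletal
#' coupling.
#'
#' @inheritParams fit_discrete_onset
#' @param tau_grid numeric vector of candidate response delays (s).
#' @return data.frame with columns `tau`, `r2`; the argmax delay is attached
#'   as attribute `tau_best`.
#' @export
delay_sensitivity <- function(dataset, tau_grid, model = "com",
                              output = "moment", t_input = 0.150) {
  if (!length(tau_grid))
    bfb_stop("argument_error", "tau_grid must be non-empty")
  r2 <- vapply(tau_grid, function(tau) {
    dl <- delay_config(model, tau_T = tau, tau_m = tau)
    fit_discrete_onset(dataset, model = model, output = output,
                       scope = "pooled", delays = dl, t_input = t_input)$r2
  }, numeric(1))
  out <- data.frame(tau = tau_grid, r2 = r2)
  attr(out, "tau_best") <- tau_grid[which.max(r2)]
  out
}

#' Serialize fit results to a flat CSV
#'
#' One row per bin x model x scope with columns `model`, `output`, `bin_lo`,
#' `bin_hi`, `Kp`, `Kv`, `r2`, `rmse`, `n_rows`, `scope`. Scalar fits occupy
#' a single row with the full phase span.
#'
#' @param fits a `fit_result` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    if (!is.null(f$per_bin))
      data.frame(model = f$model, output = f$output,
                 bin_lo = f$per_bin$bin_lo, bin_hi = f$per_bin$bin_hi,
                 Kp = f$per_bin$Kp %||% f$gains$Kp,
                 Kv = f$per_bin$Kv %||% f$gains$Kv,
                 r2 = f$per_bin$r2, rmse = f$per_bin$rmse,
                 n_rows = f$per_bin$n, scope = f$scope)
    else
      data.frame(model = f$model, output = f$output, bin_lo = 0, bin_hi = 1,
                 Kp = f$gains$Kp[1], Kv = f$gains$Kv[1], r2 = f$r2,
                 rmse = f$rmse, n_rows = f$n_rows, scope = f$scope)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
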