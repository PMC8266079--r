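# Canonical trial/dataset data model and on-disk format.
#
# A trial file is UTF-8 CSV with a '#'-prefixed key=value header block
# (subject constants, protocol, perturbation metadata, gait-event lists,
# foot bounds) followed by columnar samples. All numbers are written with
# 17 significant digits so write -> read round-trips bit-exactly.

TRIAL_SCHEMA_ID <- "balancefb-trial-1"

#' @rdname balance_trial
#' @export
TRIAL_COLUMNS <- c("time", "com_pos", "com_vel", "ankle_angle", "ankle_vel",
                   "ankle_moment", "emg_ta", "emg_sol", "emg_gas",
                   "grf_vertical", "cop_ap")

PROTOCOLS <- c("standing_translation", "pelvis_push", "belt_discrete",
               "belt_continuous")

MUSCLES <- c("ta", "sol", "gas")

fmt17 <- function(x) sprintf("%.17g", x)

#' Subject constants
#'
#' Anthropometric constants used for non-dimensionalization: body mass `m`,
#' COM height during quiet standing `l_max`, and the gravitational
#' acceleration, fixed at 9.81 m/s^2 by convention.
#'
#' @param subject_id character label.
#' @param mass body mass in kg (> 0).
#' @param com_height COM height l_max in m (> 0).
#' @param mvc optional named numeric vector of maximal-voluntary-contraction
#'   EMG reference values (names among `ta`, `sol`, `gas`), used to normalize
#'   standing EMG.
#' @return an object of class `subject_constants`.
#' @export
subject_constants <- function(subject_id, mass, com_height, mvc = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    bfb_stop("schema_error", "subject_id must be a single character label")
  if (!is.finite(mass) || mass <= 0)
    bfb_stop("schema_error", "mass must be a positive number")
  if (!is.finite(com_height) || com_height <= 0)
    bfb_stop("schema_error", "com_height (l_max) must be a positive number")
  if (!is.null(mvc)) {
    if (is.null(names(mvc)) || !all(names(mvc) %in% MUSCLES))
      bfb_stop("schema_error", "mvc names must be among: %s",
               paste(MUSCLES, collapse = ", "))
  }
  structure(list(subject_id = subject_id, mass = mass,
                 com_height = com_height, gravity = .G, mvc = mvc),
            class = "subject_constants")
}

#' Construct and validate a trial
#'
#' One synchronized recording of perturbed or unperturbed standing/walking:
#' time series of COM kinematics (anterior-posterior, relative to the base of
#' support), ankle kinematics, ankle moment (plantarflexion positive), EMG
#' envelopes, vertical ground reaction force and COP, plus perturbation
#' metadata and gait events. Time is trial-local seconds starting at 0 with
#' uniform sampling; units are SI on disk.
#'
#' @param subject a [subject_constants()] object.
#' @param data data.frame with columns `r toString(TRIAL_COLUMNS)`.
#' @param condition `"unperturbed"` or `"perturbed"`.
#' @param protocol one of `"standing_translation"`, `"pelvis_push"`,
#'   `"belt_discrete"`, `"belt_continuous"`.
#' @param walking_speed m/s; 0 for standing.
#' @param fs sampling rate in Hz.
#' @param perturbation for perturbed trials, `list(onset =, direction =,
#'   magnitude =)` with direction `"forward"` (anterior COM deviation) or
#'   `"backward"`; `NULL` otherwise.
#' @param events named list of numeric event-time vectors `hs_left`,
#'   `to_left`, `hs_right`, `to_right` (heel strike / toe off, seconds).
#' @param foot fore-aft foot bounds `list(heel =, toe =)` in the COP frame
#'   (m), used for the COP-to-bound modulator.
#' @return an object of class `balance_trial`.
#' @export
balance_trial <- function(subject, data, condition, protocol,
                          walking_speed = 0, fs = 100,
                          perturbation = NULL,
                          events = list(hs_left = numeric(0),
                                        to_left = numeric(0),
                                        hs_right = numeric(0),
                                        to_right = numeric(0)),
                          foot = list(heel = -0.08, toe = 0.17)) {
  tr <- structure(list(subject = subject, data = data, condition = condition,
                       protocol = protocol, walking_speed = walking_speed,
                       fs = fs, perturbation = perturbation, events = events,
                       foot = foot),
                  class = "balance_trial")
  validate_trial(tr)
  tr
}

#' Validate a trial against the canonical-schema invariants
#'
#' Checks presence of all sample columns, non-empty uniform sampling (time
#' step uniform to 1e-6 s), subject constants, protocol/condition labels,
#' a single in-span perturbation onset for perturbed trials, and strictly
#' increasing, alternating gait events per leg.
#'
#' @param trial a `balance_trial`.
#' @return the trial, invisibly; errors otherwise.
#' @export
validate_trial <- function(trial) {
  if (!inherits(trial, "balance_trial"))
    bfb_stop("schema_error", "not a balance_trial object")
  s <- trial$subject
  if (!inherits(s, "subject_constants"))
    bfb_stop("schema_error", "trial$subject must be subject_constants")
  if (!identical(s$gravity, .G))
    bfb_stop("schema_error", "gravity must be fixed at 9.81 m/s^2")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trial$data))
  if (length(missing_cols))
    bfb_stop("schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  n <- nrow(trial$data)
  if (n < 1L)
    bfb_stop("validation_error", "trial has 0 samples")
  if (!all(vapply(trial$data[TRIAL_COLUMNS], is.numeric, logical(1))))
    bfb_stop("schema_error", "all sample columns must be numeric")
  if (anyNA(trial$data[TRIAL_COLUMNS]))
    bfb_stop("schema_error", "sample columns must not contain NA")
  tt <- trial$data$time
  if (n >= 2L) {
    dt <- diff(tt)
    if (any(abs(dt - 1 / trial$fs) > 1e-6))
      bfb_stop("sampling_error",
               "non-uniform time step beyond 1e-6 s tolerance (fs = %g)",
               trial$fs)
  }
  if (abs(tt[1]) > 1e-9)
    bfb_stop("validation_error", "time must start at 0 (trial-local seconds)")
  if (!trial$condition %in% c("unperturbed", "perturbed"))
    bfb_stop("schema_error", "condition must be unperturbed or perturbed")
  if (!trial$protocol %in% PROTOCOLS)
    bfb_stop("schema_error", "unknown protocol '%s'", trial$protocol)
  if (trial$protocol == "standing_translation" && trial$walking_speed != 0)
    bfb_stop("validation_error", "standing trials must have walking_speed 0")
  if (trial$condition == "perturbed") {
    p <- trial$perturbation
    if (is.null(p) || is.null(p$onset) || length(p$onset) != 1L)
      bfb_stop("validation_error",
               "perturbed trial must have exactly one onset")
    if (p$onset < tt[1] || p$onset > tt[n])
      bfb_stop("validation_error", "perturbation onset outside recorded span")
    if (!p$direction %in% c("forward", "backward"))
      bfb_stop("schema_error", "perturbation direction must be forward/backward")
  } else if (!is.null(trial$perturbation)) {
    bfb_stop("validation_error", "unperturbed trial carries perturbation metadata")
  }
  for (leg in c("left", "right")) {
    hs <- trial$events[[paste0("hs_", leg)]] %||% numeric(0)
    to <- trial$events[[paste0("to_", leg)]] %||% numeric(0)
    for (ev in list(hs, to))
      if (length(ev) >= 2L && any(diff(ev) <= 0))
        bfb_stop("event_order_error", "%s-leg events not strictly increasing", leg)
    if (length(hs) && length(to)) {
      merged <- rbind(data.frame(t = hs, type = "hs"),
                      data.frame(t = to, type = "to"))
      merged <- merged[order(merged$t), ]
      if (any(merged$type[-1] == merged$type[-nrow(merged)]))
        bfb_stop("event_order_error",
                 "%s-leg heel-strike/toe-off events do not alternate", leg)
    }
  }
  invisible(trial)
}

trial_header <- function(trial) {
  s <- trial$subject
  kv <- c(
    schema = TRIAL_SCHEMA_ID,
    subject_id = s$subject_id,
    mass = fmt17(s$mass),
    com_height = fmt17(s$com_height),
    gravity = fmt17(s$gravity),
    condition = trial$condition,
    protocol = trial$protocol,
    walking_speed = fmt17(trial$walking_speed),
    fs = fmt17(trial$fs),
    foot_heel = fmt17(trial$foot$heel),
    foot_toe = fmt17(trial$foot$toe)
  )
  if (trial$condition == "perturbed") {
    p <- trial$perturbation
    kv <- c(kv, pert_onset = fmt17(p$onset), pert_direction = p$direction,
            pert_magnitude = fmt17(p$magnitude))
  }
  for (ev in c("hs_left", "to_left", "hs_right", "to_right")) {
    v <- trial$events[[ev]] %||% numeric(0)
    kv <- c(kv, setNames(paste(fmt17(v), collapse = ","), paste0("events_", ev)))
  }
  if (!is.null(s$mvc))
    for (m in names(s$mvc))
      kv <- c(kv, setNames(fmt17(s$mvc[[m]]), paste0("mvc_", m)))
  paste0("# ", names(kv), "=", unname(kv))
}

#' Write a trial to a canonical file
#'
#' Writes the `#`-prefixed key=value header followed by the sample columns.
#' Numeric fields are written at full double precision (17 significant
#' digits); two writes of the same trial are byte-identical.
#'
#' @param trial a validated `balance_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    bfb_stop("io_error", "cannot open '%s' for writing: %s", path,
             conditionMessage(e)))
  on.exit(close(con))
  writeLines(trial_header(trial), con, sep = "\n")
  writeLines(paste(TRIAL_COLUMNS, collapse = ","), con, sep = "\n")
  mat <- vapply(trial$data[TRIAL_COLUMNS], fmt17, character(nrow(trial$data)))
  if (nrow(trial$data) == 1L) mat <- matrix(mat, nrow = 1L)
  writeLines(apply(mat, 1L, paste, collapse = ","), con, sep = "\n")
  invisible(path)
}

parse_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 0) next
    kv[[substr(body, 1L, eq - 1L)]] <- substr(body, eq + 1L, nchar(body))
  }
  kv
}

num_list <- function(s) {
  if (is.null(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Read a trial from a canonical file
#'
#' @param path path to a canonical trial file written by [write_trial()].
#' @return a validated `balance_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path))
    bfb_stop("io_error", "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr_n <- which(!startsWith(lines, "#"))[1] - 1L
  kv <- parse_header(lines[seq_len(hdr_n)])
  if (!identical(kv$schema, TRIAL_SCHEMA_ID))
    bfb_stop("schema_error", "unrecognized schema id '%s'", kv$schema %||% "")
  dat <- read.csv(text = paste(lines[-seq_len(hdr_n)], collapse = "\n"))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(dat))
  if (length(missing_cols))
    bfb_stop("schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  mvc_keys <- grep("^mvc_", names(kv), value = TRUE)
  mvc <- if (length(mvc_keys))
    setNames(vapply(kv[mvc_keys], as.numeric, numeric(1)),
             sub("^mvc_", "", mvc_keys)) else NULL
  subj <- subject_constants(kv$subject_id, as.numeric(kv$mass),
                            as.numeric(kv$com_height), mvc = mvc)
  pert <- NULL
  if (identical(kv$condition, "perturbed"))
    pert <- list(onset = as.numeric(kv$pert_onset),
                 direction = kv$pert_direction,
                 magnitude = as.numeric(kv$pert_magnitude))
  balance_trial(
    subject = subj, data = dat[TRIAL_COLUMNS],
    condition = kv$condition, protocol = kv$protocol,
    walking_speed = as.numeric(kv$walking_speed), fs = as.numeric(kv$fs),
    perturbation = pert,
    events = list(hs_left = num_list(kv$events_hs_left),
                  to_left = num_list(kv$events_to_left),
                  hs_right = num_list(kv$events_hs_right),
                  to_right = num_list(kv$events_to_right)),
    foot = list(heel = as.numeric(kv$foot_heel), toe = as.numeric(kv$foot_toe)))
}

#' Construct a dataset (collection of trials)
#'
#' @param trials list of `balance_trial` objects.
#' @param provenance label: one of the four protocols or `"synthetic"`.
#' @param validate check cross-trial invariants (shared sampling rate per
#'   protocol; at least one unperturbed trial per subject per speed).
#' @return an object of class `balance_dataset`.
#' @export
balance_dataset <- function(trials, provenance = "synthetic", validate = TRUE) {
  ds <- structure(list(trials = trials, provenance = provenance),
                  class = "balance_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' @rdname balance_dataset
#' @param dataset a `balance_dataset`.
#' @export
validate_dataset <- function(dataset) {
  if (!length(dataset$trials))
    bfb_stop("validation_error", "dataset has no trials")
  for (tr in dataset$trials) validate_trial(tr)
  key <- vapply(dataset$trials, function(tr) tr$protocol, character(1))
  fs <- vapply(dataset$trials, function(tr) tr$fs, numeric(1))
  for (p in unique(key))
    if (length(unique(fs[key == p])) != 1L)
      bfb_stop("validation_error",
               "trials of protocol '%s' have differing sampling rates", p)
  grp <- paste(vapply(dataset$trials, function(tr) tr$subject$subject_id,
                      character(1)),
               vapply(dataset$trials, function(tr) tr$walking_speed, numeric(1)))
  cond <- vapply(dataset$trials, function(tr) tr$condition, character(1))
  for (g in unique(grp))
    if (!any(cond[grp == g] == "unperturbed"))
      bfb_stop("validation_error",
               "no unperturbed trial for subject/speed group '%s'", g)
  invisible(dataset)
}

#' Write / read a dataset as a directory of canonical trial files
#'
#' @param dataset a `balance_dataset`.
#' @param dir directory (created if needed).
#' @return `write_dataset`: `dir` invisibly; `read_dataset`: a
#'   `balance_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  validate_dataset(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$trials)
  for (i in seq_len(n))
    write_trial(dataset$trials[[i]],
                file.path(dir, sprintf("trial_%04d.csv", i)))
  writeLines(dataset$provenance, file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    bfb_stop("io_error", "no trial files found in '%s'", dir)
  prov_file <- file.path(dir, "provenance.txt")
  prov <- if (file.exists(prov_file)) readLines(prov_file)[1] else "unknown"
  balance_dataset(lapply(files, read_trial), provenance = prov)
}

#' @export
print.balance_trial <- function(x, ...) {
  cat(sprintf("<balance_trial> %s %s/%s, %d samples @ %g Hz, speed %g m/s\n",
              x$subject$subject_id, x$protocol, x$condition,
              nrow(x$data), x$fs, x$walking_speed))
  if (!is.null(x$perturbation))
    cat(sprintf("  perturbation: %s, magnitude %g, onset %g s\n",
                x$perturbation$direction, x$perturbation$magnitude,
                x$perturbation$onset))
  invisible(x)
}

#' @export
print.balance_dataset <- function(x, ...) {
  cat(sprintf("<balance_dataset> '%s': %d trials (%d perturbed), %d subjects\n",
              x$provenance, length(x$trials),
              sum(vapply(x$trials, function(tr) tr$condition == "perturbed",
                         logical(1))),
              length(unique(vapply(x$trials,
                                   function(tr) tr$subject$subject_id,
                                   character(1))))))
  invisible(x)
}

# ---- supplementary .mat import ---------------------------------------------

#' Import a supplementary MATLAB archive into the canonical schema
#'
#' Optional importer for the experiment archives distributed as MATLAB files
#' (`DataBeltPerturb.mat`, `DataContinuousPerturb.mat`, `DataPelvisPush.mat`,
#' `DataStandingBalance.mat`). Reading .mat requires the pre-installed
#' `python` with `scipy`; the mapping from internal variable names to the
#' canonical schema is declared in the versioned table
#' `inst/extdata/mat_mapping.csv` and may need revision against each archive's
#' actual layout. Unmapped variables are logged (message) and ignored.
#'
#' @param path path to the .mat file.
#' @param protocol expected protocol label (one of the four canonical ones).
#' @return a `balance_dataset`.
#' @export
import_supplementary <- function(path, protocol) {
  if (!protocol %in% PROTOCOLS)
    bfb_stop("argument_error", "unknown protocol '%s'", protocol)
  if (!file.exists(path))
    bfb_stop("io_error", "no such file: %s", path)
  py <- Sys.which("python")
  if (!nzchar(py))
    bfb_stop("import_error",
             "the .mat importer requires 'python' with scipy on the PATH")
  bridge <- system.file("py", "mat_bridge.py", package = "balancefb")
  out_json <- tempfile(fileext = ".json")
  status <- system2(py, c(bridge, shQuote(path), shQuote(out_json)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(out_json))
    bfb_stop("import_error", "mat bridge failed:\n%s",
             paste(status, collapse = "\n"))
  raw <- jsonlite::read_json(out_json, simplifyVector = FALSE)
  if (is.null(raw$trials))
    bfb_stop("import_error",
             "unknown internal layout; variables found: %s",
             paste(raw$variables %||% "none", collapse = ", "))
  if (!is.null(raw$protocol) && !identical(raw$protocol, protocol))
    bfb_stop("import_error",
             "archive declares protocol '%s' but '%s' was expected",
             raw$protocol, protocol)
  map <- read.csv(system.file("extdata", "mat_mapping.csv",
                              package = "balancefb"))
  map <- map[map$protocol %in% c(protocol, "*"), ]
  trials <- lapply(raw$trials, function(rt) mat_trial(rt, map, protocol,
                                                      raw$fs %||% 100))
  balance_dataset(trials, provenance = protocol)
}

mat_trial <- function(rt, map, protocol, fs) {
  get1 <- function(canon, default = NULL) {
    src <- map$mat_variable[map$canonical_field == canon]
    for (s in src) if (!is.null(rt[[s]])) {
      v <- rt[[s]]
      return(if (is.list(v)) unlist(v) else v)
    }
    default
  }
  known <- unique(map$mat_variable)
  unmapped <- setdiff(names(rt), known)
  if (length(unmapped))
    message("import_supplementary: ignoring unmapped variable(s): ",
            paste(unmapped, collapse = ", "))
  n <- length(get1("time"))
  dat <- as.data.frame(setNames(
    lapply(TRIAL_COLUMNS, function(cl) as.numeric(get1(cl, rep(0, n)))),
    TRIAL_COLUMNS))
  cond <- get1("condition", "unperturbed")
  pert <- NULL
  if (identical(cond, "perturbed"))
    pert <- list(onset = as.numeric(get1("pert_onset")),
                 direction = get1("pert_direction"),
                 magnitude = as.numeric(get1("pert_magnitude", 0)))
  balance_trial(
    subject = subject_constants(as.character(get1("subject_id", "S?")),
                                as.numeric(get1("mass", 70)),
                                as.numeric(get1("com_height", 0.95))),
    data = dat, condition = cond, protocol = protocol,
    walking_speed = as.numeric(get1("walking_speed", 0)),
    fs = as.numeric(fs), perturbation = pert,
    events = list(hs_left = as.numeric(get1("hs_left", numeric(0))),
                  to_left = as.numeric(get1("to_left", numeric(0))),
                  hs_right = as.numeric(get1("hs_right", numeric(0))),
                  to_right = as.numeric(get1("to_right", numeric(0)))),
    foot = list(heel = as.numeric(get1("foot_heel", -0.08)),
                toe = as.numeric(get1("foot_toe", 0.17))))
}
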