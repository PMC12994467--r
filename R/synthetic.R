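# Synthetic paired-posture cohort generator.
#
# The physical premise: the cardiac dipole loop (VCG) is a property of the
# heart, not of electrode placement, so the same loop projected through a
# supine lead field and a prone lead field yields a paired supine/prone
# 12-lead recording. The dipole trajectory is built as a sum of Gaussian
# kernels (one or more per wave: P, Q, R, S, T), each with an amplitude
# (mV), a width (s), a centre relative to the R peak (s), and a fixed 3-D
# direction. Gaussian-kernel dipoles are the standard construction for
# synthetic ECGs; they give closed per-beat loops and analytically known
# fiducial points, which downstream tests use as ground truth.

#' Default dipole beat-shape parameters
#'
#' One row per Gaussian kernel: `wave` label, `group` (P / QRS / STT),
#' amplitude in mV, width and centre in seconds (centre relative to the R
#' peak), and a unit 3-D direction (X left, Y inferior, Z posterior-negative
#' convention).
#'
#' @return A data frame of kernel parameters.
#' @export
default_beat_params <- function() {
  p <- data.frame(
    wave   = c("P",    "Q",     "R",    "S",    "T"),
    group  = c("P",    "QRS",   "QRS",  "QRS",  "STT"),
    amp    = c(0.12,   0.08,    1.30,   0.25,   0.35),
    width  = c(0.022,  0.008,   0.011,  0.012,  0.055),
    center = c(-0.170, -0.028,  0.000,  0.030,  0.280),
    dx     = c(0.50,   -0.40,   0.65,   -0.60,  0.60),
    dy     = c(0.85,   -0.50,   0.60,   -0.30,  0.50),
    dz     = c(-0.15,  0.30,    -0.45,  0.60,   -0.30),
    stringsAsFactors = FALSE
  )
  nrm <- sqrt(p$dx^2 + p$dy^2 + p$dz^2)
  p$dx <- p$dx / nrm; p$dy <- p$dy / nrm; p$dz <- p$dz / nrm
  p
}

# Modify beat-shape parameters to emulate a diagnosis class.
apply_class_modifier <- function(params, label) {
  stopifnot(label %in% diagnosis_classes())
  add_wave <- function(p, wave, group, amp, width, center, d) {
    d <- d / sqrt(sum(d^2))
    rbind(p, data.frame(wave = wave, group = group, amp = amp, width = width,
                        center = center, dx = d[1], dy = d[2], dz = d[3],
                        stringsAsFactors = FALSE))
  }
  qrs <- params$group == "QRS"
  t_dir <- unlist(params[params$wave == "T", c("dx", "dy", "dz")])
  switch(label,
    Normal = params,
    ST_elevation = add_wave(params, "ST", "STT", 0.18, 0.050, 0.110, t_dir),
    ST_depression = add_wave(params, "ST", "STT", -0.14, 0.050, 0.110, t_dir),
    Old_MI = {
      # loss of initial anterior forces: R suppressed, Q deepened -> QS-type
      params$amp[params$wave == "R"] <- params$amp[params$wave == "R"] * 0.15
      params$amp[params$wave == "Q"] <- params$amp[params$wave == "Q"] * 5
      params$width[params$wave == "Q"] <- params$width[params$wave == "Q"] * 2
      params
    },
    CLBBB = {
      params$width[qrs] <- params$width[qrs] * 2.2
      params$center[params$wave == "S"] <- 0.055
      add_wave(params, "Rp", "QRS", 0.55, 0.020, 0.090, c(0.9, 0.25, 0.25))
    },
    CRBBB_RBBB = {
      params$width[qrs] <- params$width[qrs] * 1.8
      params$center[params$wave == "S"] <- 0.048
      # delayed rightward-anterior terminal force (rSR' in right precordials)
      add_wave(params, "Rp", "QRS", 0.50, 0.018, 0.085, c(-0.35, 0.10, -0.90))
    },
    LAH = {
      # left-axis rotation of the QRS loop in the frontal (X-Y) plane
      th <- -100 * pi / 180
      x <- params$dx[qrs]; y <- params$dy[qrs]
      params$dx[qrs] <- cos(th) * x - sin(th) * y
      params$dy[qrs] <- sin(th) * x + cos(th) * y
      params
    })
}

# Analytic fiducials (seconds relative to R) implied by a kernel table.
# Onsets/offsets of P and QRS use the 3-width point (the kernel is ~ zero
# beyond it); the T offset uses the tangent-method end, which for a Gaussian
# lobe is centre + 2 widths (steepest-descent tangent hits baseline there).
params_fiducials <- function(params) {
  span <- 3
  grp <- function(g) params[params$group == g, , drop = FALSE]
  p <- grp("P"); q <- grp("QRS"); s <- grp("STT")
  last_t <- s[which.max(s$center), ]
  list(
    p_present = nrow(p) > 0 && max(p$amp) > 0,
    p_onset = if (nrow(p) > 0) min(p$center - span * p$width) else NA_real_,
    qrs_onset = min(q$center - span * q$width),
    r_peak = q$center[which.max(abs(q$amp))],
    qrs_offset = max(q$center + span * q$width),
    t_offset = last_t$center + 2 * last_t$width
  )
}

#' Simulate an orthogonal-lead VCG from a dipole-kernel model
#'
#' Places `n_beats` repetitions of the kernel set on a regular RR grid. Beat
#' amplitudes can jitter multiplicatively (`beat_jitter`, lognormal sd on the
#' whole beat) without altering the loop shape. The analytic ground truth
#' (R-peak samples and per-beat fiducials) is attached as `attr(, "truth")`.
#'
#' @param beat_params Kernel table as from [default_beat_params()].
#' @param fs Sampling rate, Hz.
#' @param n_beats Number of beats (>= 1).
#' @param rr_s RR interval in seconds (ignored when `duration_s` is given;
#'   then spacing is derived so all beats fit with full pre/post context).
#' @param duration_s Optional total record duration in seconds.
#' @param seed Optional integer seed for the jitter stream.
#' @param beat_jitter Lognormal sd of the per-beat amplitude factor.
#' @param subject_id Identifier carried into the record.
#' @return A [vcg_record()] with a `truth` attribute.
#' @export
simulate_vcg <- function(beat_params = default_beat_params(), fs = 500,
                         n_beats = 8, rr_s = 1.0, duration_s = NULL,
                         seed = NULL, beat_jitter = 0, subject_id = "sim") {
  stopifnot(n_beats >= 1, fs > 0)
  pre <- 0.45   # context before the first R peak
  post <- 0.52  # context after the last R peak
  if (is.null(duration_s)) {
    duration_s <- pre + post + (n_beats - 1) * rr_s
  } else if (n_beats > 1) {
    rr_s <- (duration_s - pre - post) / (n_beats - 1)
    if (rr_s < 0.6)
      abort_pronecg("ConfigError", "duration too short for n_beats")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  r_times <- pre + (seq_len(n_beats) - 1) * rr_s
  jit <- with_seed(seed, exp(stats::rnorm(n_beats, 0, beat_jitter)))
  if (beat_jitter == 0) jit <- rep(1, n_beats)
  xyz <- matrix(0, n, 3)
  for (b in seq_len(n_beats)) {
    for (w in seq_len(nrow(beat_params))) {
      k <- beat_params[w, ]
      g <- k$amp * jit[b] * exp(-((t - r_times[b] - k$center)^2) / (2 * k$width^2))
      xyz <- xyz + outer(g, c(k$dx, k$dy, k$dz))
    }
  }
  rec <- vcg_record(xyz, fs = fs, subject_id = subject_id)
  fid <- params_fiducials(beat_params)
  to_idx <- function(off) round((r_times + off) * fs) + 1  # 1-based samples
  truth <- list(
    r_peaks = to_idx(fid$r_peak),
    fiducials = data.frame(
      beat = seq_len(n_beats),
      p_onset = if (fid$p_present) to_idx(fid$p_onset) else NA_integer_,
      qrs_onset = to_idx(fid$qrs_onset),
      r_peak = to_idx(fid$r_peak),
      qrs_offset = to_idx(fid$qrs_offset),
      t_offset = to_idx(fid$t_offset),
      p_present = fid$p_present
    ),
    beat_params = beat_params
  )
  attr(rec, "truth") <- truth
  rec
}

# ---- lead fields ------------------------------------------------------------

#' Posture-specific lead-field matrices
#'
#' A lead field maps the dipole (X, Y, Z) to the 12 leads. The supine field
#' is the Dower/Uijen composite the VCG conversion route assumes (Uijen-slot
#' rows for all leads except V3, which uses Dower), so the supine 12-lead is
#' exactly the projection that route reconstructs. The prone field keeps the
#' limb-lead rows identical (limb electrodes do not move) and replaces the
#' precordial rows with a stylized mirrored-back geometry: prone V1/V4 are
#' attenuated, sign-flipped images of supine V4/V1, prone V2 a sign-flipped
#' image of supine V2, prone V3 the midpoint of prone V2 and V4, prone V5 an
#' attenuated lateral mix, and prone V6 unchanged (its electrode stays at
#' the standard site). The prone geometry is a stylized stand-in, not a
#' measured torso model.
#'
#' @param posture `"supine"` or `"prone"`.
#' @return A `lead_field` object: list with `posture` and `matrix` (12 x 3).
#' @export
lead_field <- function(posture = c("supine", "prone")) {
  posture <- match.arg(posture)
  uij <- transform_matrix("uijen")$rows
  dow <- transform_matrix("dower")$rows
  sup8 <- uij
  sup8["V3", ] <- dow["V3", ]
  sup <- expand_to_12(sup8)
  m <- sup
  if (posture == "prone") {
    m["V1", ] <- -0.80 * sup["V4", ]
    m["V2", ] <- -0.85 * sup["V2", ]
    m["V4", ] <- -0.80 * sup["V1", ]
    m["V3", ] <- (m["V2", ] + m["V4", ]) / 2  # prone V3 midway between prone V2 and V4
    m["V5", ] <- 0.70 * (sup["V5", ] + sup["V6", ]) / 2
    # V6 row unchanged: prone V6 sits at the standard V6 site
  }
  structure(list(posture = posture, matrix = m), class = "lead_field")
}

#' Project a VCG through a lead field into a 12-lead ECG
#'
#' Each lead is `row %*% (X, Y, Z)` plus independent Gaussian noise of sd
#' `noise_sd` (mV). The record inherits the field's posture tag and the
#' VCG's ground-truth attribute.
#'
#' @param vcg A [vcg_record()].
#' @param field A [lead_field()].
#' @param noise_sd Additive noise sd in mV (0 disables noise).
#' @param seed Optional integer seed for the noise stream.
#' @return An [ecg_record()].
#' @export
project_leads <- function(vcg, field, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(vcg, "vcg_record"), inherits(field, "lead_field"))
  signals <- vcg$xyz %*% t(field$matrix)
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(signals), 0, noise_sd),
                                    nrow(signals), ncol(signals)))
    signals <- signals + noise
  }
  rec <- ecg_record(signals, fs = vcg$fs, posture = field$posture,
                    subject_id = vcg$subject_id)
  attr(rec, "truth") <- attr(vcg, "truth")
  rec
}

# ---- cohort -----------------------------------------------------------------

default_class_mix <- function() {
  counts <- c(Normal = 24, ST_elevation = 7, Old_MI = 8, ST_depression = 11,
              CLBBB = 4, CRBBB_RBBB = 11, LAH = 5)
  counts / sum(counts)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the development-cohort conditions the conversion models
#' are designed for: 70 subjects contributing 590 prone cardiac cycles in
#' total, 10-s records at 500 Hz, and a diagnosis mix matching the
#' development cohort class counts.
#'
#' @param n_subjects Number of subjects.
#' @param total_beats Total beats summed over subjects (per posture).
#' @param fs Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param noise_sd Additive measurement noise sd, mV.
#' @param class_mix Named proportions over [diagnosis_classes()]; must sum
#'   to 1.
#' @param seed Integer seed governing every random draw downstream.
#' @param beat_jitter Per-beat lognormal amplitude sd.
#' @param subject_var Between-subject lognormal sd of kernel amplitudes.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 70, total_beats = 590, fs = 500,
                          duration_s = 10, noise_sd = 0.02,
                          class_mix = default_class_mix(), seed = 1,
                          beat_jitter = 0.03, subject_var = 0.12) {
  if (n_subjects < 1) abort_pronecg("ConfigError", "n_subjects must be >= 1")
  if (noise_sd < 0) abort_pronecg("ConfigError", "noise_sd must be >= 0")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% diagnosis_classes()))
    abort_pronecg("ConfigError", "class_mix must be named by diagnosis classes")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-6)
    abort_pronecg("ConfigError", "class_mix proportions must be >= 0 and sum to 1")
  structure(list(n_subjects = n_subjects, total_beats = total_beats, fs = fs,
                 duration_s = duration_s, noise_sd = noise_sd,
                 class_mix = class_mix, seed = seed,
                 beat_jitter = beat_jitter, subject_var = subject_var),
            class = "cohort_config")
}

# Allocate per-subject beat counts from {7..10} adjusted to hit the total.
allocate_beats <- function(n_subjects, total_beats) {
  counts <- sample(7:10, n_subjects, replace = TRUE)
  while (sum(counts) > total_beats) {
    i <- sample(which(counts > 5), 1)
    counts[i] <- counts[i] - 1
  }
  while (sum(counts) < total_beats) {
    i <- sample(which(counts < 12), 1)
    counts[i] <- counts[i] + 1
  }
  counts
}

# Largest-remainder allocation of class labels to subjects.
allocate_labels <- function(n, mix) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_by_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_by_frac[seq_len(rem)]] <- counts[order_by_frac[seq_len(rem)]] + 1
  }
  sample(rep(names(mix), counts))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate a paired prone/supine cohort
#'
#' For each subject one dipole loop (VCG) is generated from subject-specific
#' kernel parameters (base shape, between-subject variation, then the
#' subject's diagnosis-class modifier) and projected through both posture
#' lead fields — so prone and supine records of a subject share a
#' byte-identical VCG, the generator's core physical premise. Covariates are
#' drawn from truncated normals centred on development-cohort medians.
#'
#' @param config A [cohort_config()].
#' @return An `ecg_cohort`: a list of per-subject entries (`subject_id`,
#'   `prone`, `supine`, `vcg`, `covariates`, `label`, `n_beats`) with the
#'   config attached as an attribute.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    beats <- allocate_beats(n, config$total_beats)
    labels <- allocate_labels(n, config$class_mix)
    sub_seeds <- sample.int(.Machine$integer.max - 1, n * 3)
    fields <- list(supine = lead_field("supine"), prone = lead_field("prone"))
    male <- stats::rbinom(n, 1, 0.586)
    age <- round(rtrunc_norm(n, 58, 16, 18, 90))
    height <- round(rtrunc_norm(n, 168, 8, 145, 195), 1)
    weight <- round(rtrunc_norm(n, 67, 12, 40, 110), 1)
    chest <- round(rtrunc_norm(n, 90.3, 6, 70, 120), 1)
    waist <- round(rtrunc_norm(n, 86.4, 9, 60, 120), 1)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      sid <- sprintf("S%03d", i)
      params <- default_beat_params()
      scale_all <- exp(stats::rnorm(1, 0, config$subject_var))
      params$amp <- params$amp * scale_all * exp(stats::rnorm(nrow(params), 0, 0.05))
      params$width <- params$width * exp(stats::rnorm(nrow(params), 0, 0.04))
      params <- apply_class_modifier(params, labels[i])
      vcg <- simulate_vcg(params, fs = config$fs, n_beats = beats[i],
                          duration_s = config$duration_s,
                          seed = sub_seeds[3 * i - 2],
                          beat_jitter = config$beat_jitter, subject_id = sid)
      prone <- project_leads(vcg, fields$prone, config$noise_sd,
                             seed = sub_seeds[3 * i - 1])
      supine <- project_leads(vcg, fields$supine, config$noise_sd,
                              seed = sub_seeds[3 * i])
      subjects[[i]] <- list(
        subject_id = sid, prone = prone, supine = supine, vcg = vcg,
        covariates = subject_covariates(sid, male[i], age[i], height[i],
                                        weight[i], chest[i], waist[i]),
        label = labels[i], n_beats = beats[i]
      )
    }
    structure(subjects, class = "ecg_cohort", config = config)
  })
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<ecg_cohort> %d subjects, %d beats total, fs=%g Hz, noise_sd=%g mV\n",
              length(x), sum(vapply(x, function(s) s$n_beats, 0)),
              cfg$fs, cfg$noise_sd))
  invisible(x)
}

#' Cohort accessors
#'
#' @param cohort An `ecg_cohort`.
#' @return `cohort_covariates`: one-row-per-subject covariate data frame;
#'   `cohort_labels`: named character vector of diagnosis labels.
#' @export
cohort_covariates <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) s$covariates))
}

#' @rdname cohort_covariates
#' @export
cohort_labels <- function(cohort) {
  stats::setNames(vapply(cohort, function(s) s$label, ""),
                  vapply(cohort, function(s) s$subject_id, ""))
}
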