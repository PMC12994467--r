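# Shared fixtures, built in code. Small cohorts are memoized per option set
# so several test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n_subjects = 10, total_beats = 85, noise_sd = 0,
                         seed = 5, class_mix = NULL) {
  key <- paste(n_subjects, total_beats, noise_sd, seed,
               paste(class_mix, collapse = ","), sep = "|")
  if (is.null(.fixture_env[[key]])) {
    args <- list(n_subjects = n_subjects, total_beats = total_beats,
                 noise_sd = noise_sd, seed = seed)
    if (!is.null(class_mix)) args$class_mix <- class_mix
    .fixture_env[[key]] <- simulate_cohort(do.call(cohort_config, args))
  }
  .fixture_env[[key]]
}

small_tables <- function(cohort) {
  key <- paste0("tables|", digest_cohort(cohort))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_cohort_tables(cohort)
  .fixture_env[[key]]
}

digest_cohort <- function(cohort) {
  cfg <- attr(cohort, "config")
  paste(length(cohort), cfg$seed, cfg$noise_sd, sep = "-")
}

# A bare R-wave train: Gaussian bumps of the given amplitudes at the given
# times (s), over `dur` seconds at `fs` Hz.
gaussian_train <- function(times, amps = 1, fs = 500, dur = 10,
                           width = 0.012) {
  amps <- rep_len(amps, length(times))
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- numeric(length(t))
  for (k in seq_along(times)) {
    x <- x + amps[k] * exp(-((t - times[k])^2) / (2 * width^2))
  }
  x
}

# A single hand-built beat on one lead, with exactly known fiducials.
# R peak 1.0 mV at 0.5 s, S -0.3 mV at 0.54 s, biphasic T (+0.2 / -0.1).
handmade_beat <- function(fs = 500, dc = 0, scale = 1, p_amp = 0.1) {
  t <- (seq_len(round(1.2 * fs)) - 1) / fs
  x <- 1.0 * exp(-((t - 0.50)^2) / (2 * 0.010^2)) -
       0.3 * exp(-((t - 0.54)^2) / (2 * 0.010^2)) +
       0.2 * exp(-((t - 0.76)^2) / (2 * 0.030^2)) -
       0.1 * exp(-((t - 0.86)^2) / (2 * 0.030^2)) +
       p_amp * exp(-((t - 0.34)^2) / (2 * 0.020^2))
  x <- x * scale + dc
  sig <- matrix(rep(x, 12), ncol = 12)
  colnames(sig) <- ecg_leads()
  rec <- ecg_record(sig, fs = fs, posture = "supine", subject_id = "hand")
  fid <- beat_fiducials(p_onset = round(0.28 * fs), qrs_onset = round(0.46 * fs),
                        r_peak = round(0.50 * fs), qrs_offset = round(0.58 * fs),
                        t_offset = round(0.95 * fs))
  list(rec = rec, fid = fid)
}

dummy_covariates <- function(sid = "S001") {
  subject_covariates(sid, male = 1, age = 60, height = 168, weight = 67,
                     chest = 90, waist = 86)
}

# Random feature table in the approach-3 schema (independent features), with
# the target an exact function of one named feature.
random_feature_table <- function(n, target_from = "prone_V4", coef = 2,
                                 seed = 1, n_subjects = 8) {
  withr::local_seed(seed)
  feats <- matrix(rnorm(n * 18), n, 18)
  colnames(feats) <- c(paste0("prone_", ecg_leads()),
                       c("male", "age", "height", "weight", "chest", "waist"))
  tab <- as.data.frame(feats)
  tab$target_V1 <- coef * tab[[target_from]]
  tab$group <- sample(sprintf("S%02d", seq_len(n_subjects)), n, replace = TRUE)
  tab
}
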