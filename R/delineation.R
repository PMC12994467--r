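# Beat detection and delineation. R peaks are found with a Pan-Tompkins
# style energy detector (band-pass, squared derivative, moving-window
# integration, adaptive threshold, 200 ms refractory). Fiducials are then
# located around each R peak with conventional slope/tangent rules and the
# cycle is carved into the three modelling windows: P-R, QRS, ST-T.
#
# All sample indices are 1-based (R convention). Windows are half-open
# [start, end).

bandpass_ecg <- function(x, fs, low = 5, high = 25) {
  ny <- fs / 2
  bf <- signal::butter(2, c(low / ny, min(high / ny, 0.95)), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

lowpass_ecg <- function(x, fs, cutoff = 15) {
  ny <- fs / 2
  bf <- signal::butter(2, min(cutoff / ny, 0.95), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

moving_avg <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> y
  y[is.na(y)] <- 0
  y
}

#' Detect R peaks on a single lead
#'
#' Band-pass (5-25 Hz), differentiate, square, integrate over 150 ms, then
#' pick local energy maxima above an adaptive threshold with a 200 ms
#' refractory period. Peaks are snapped to the extremum of the band-passed
#' signal so a detection marks the R apex.
#'
#' @param x Numeric amplitude series (mV).
#' @param fs Sampling rate, Hz.
#' @return Strictly increasing integer sample indices (possibly empty).
#' @export
detect_r_peaks <- function(x, fs) {
  if (length(x) < fs) abort_pronecg("FormatError", "need at least 1 s of signal")
  if (stats::sd(x) < 1e-12) return(integer(0))
  bp <- bandpass_ecg(x, fs)
  energy <- moving_avg(c(0, diff(bp))^2, max(3, round(0.15 * fs)))
  thr <- 0.2 * max(energy)
  if (max(energy) < 1e-12) return(integer(0))
  # local maxima of the energy envelope above threshold
  cand <- which(energy > thr)
  cand <- cand[cand > 1 & cand < length(x)]
  cand <- cand[energy[cand] >= energy[cand - 1] & energy[cand] >= energy[cand + 1]]
  if (length(cand) == 0) return(integer(0))
  # greedy refractory suppression, strongest first
  cand <- cand[order(energy[cand], decreasing = TRUE)]
  keep <- integer(0)
  refractory <- round(0.2 * fs)
  for (k in cand) {
    if (all(abs(k - keep) >= refractory)) keep <- c(keep, k)
  }
  # snap each detection to the band-passed extremum nearby
  half <- round(0.08 * fs)
  peaks <- vapply(keep, function(k) {
    lo <- max(1, k - half); hi <- min(length(x), k + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # a second refractory pass after snapping
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if (p - out[length(out)] >= refractory) out <- c(out, p)
    }
    peaks <- out
  }
  as.integer(peaks)
}

consensus_lead <- function(rec) {
  if ("II" %in% colnames(rec$signals)) "II"
  else if ("V2" %in% colnames(rec$signals)) "V2"
  else abort_pronecg("MissingLead", "need lead II (or V2) for delineation")
}

#' Beat fiducials
#'
#' Constructor/validator for the five fiducial points of one cardiac cycle.
#' When no P wave is found (`p_present = FALSE`) the P-R window falls back
#' to a fixed 120 ms span before QRS onset and `p_onset` holds that
#' fallback start.
#'
#' @param p_onset,qrs_onset,r_peak,qrs_offset,t_offset 1-based sample indices.
#' @param p_present Logical; was a P deflection found?
#' @return A `beat_fiducials` object.
#' @export
beat_fiducials <- function(p_onset, qrs_onset, r_peak, qrs_offset, t_offset,
                           p_present = TRUE) {
  v <- c(p_onset, qrs_onset, r_peak, qrs_offset, t_offset)
  if (any(!is.finite(v)) || any(diff(v) <= 0))
    abort_pronecg("FormatError",
                  "fiducials must satisfy p_onset < qrs_onset < r_peak < qrs_offset < t_offset")
  structure(list(p_onset = as.integer(p_onset), qrs_onset = as.integer(qrs_onset),
                 r_peak = as.integer(r_peak), qrs_offset = as.integer(qrs_offset),
                 t_offset = as.integer(t_offset), p_present = isTRUE(p_present)),
            class = "beat_fiducials")
}

#' Delineate one beat
#'
#' Locates QRS onset/offset by the point where the slope magnitude stays
#' below 5% of the beat's maximum slope (searched within 120 ms of the R
#' peak), the T offset by the tangent method on the <= 15 Hz low-passed
#' ST-T, and the P wave in the window from 300 ms before R up to QRS onset.
#' Fiducials are found on lead II (fallback V2) and apply to all leads of
#' the record.
#'
#' @param rec An [ecg_record()].
#' @param r_index R-peak sample index with >= 300 ms context before and
#'   >= 450 ms after.
#' @param flat_thresh P-wave detection threshold, mV.
#' @return A [beat_fiducials()] object.
#' @export
delineate <- function(rec, r_index, flat_thresh = 0.05) {
  fs <- rec$fs
  n <- nrow(rec$signals)
  if (r_index - round(0.3 * fs) < 1 || r_index + round(0.45 * fs) > n)
    abort_pronecg("EdgeBeat", sprintf("R at sample %d lacks context", r_index))
  x <- rec$signals[, consensus_lead(rec)]
  sm <- lowpass_ecg(x, fs, cutoff = 40)
  slope <- c(0, diff(sm)) * fs
  win <- round(0.12 * fs)
  qrs_region <- max(1, r_index - win):min(n, r_index + win)
  max_slope <- max(abs(slope[qrs_region]))
  thr <- 0.05 * max_slope
  sustain <- max(2, round(0.012 * fs))

  below_back <- function(from, lo) {
    # first index scanning backwards where |slope| stays below thr for `sustain`
    run <- 0L
    for (k in seq(from, lo)) {
      if (abs(slope[k]) < thr) run <- run + 1L else run <- 0L
      if (run >= sustain) return(k + sustain - 1L)
    }
    lo
  }
  below_fwd <- function(from, hi) {
    run <- 0L
    for (k in from:hi) {
      if (abs(slope[k]) < thr) run <- run + 1L else run <- 0L
      if (run >= sustain) return(k - sustain + 1L)
    }
    hi
  }
  qrs_onset <- below_back(r_index - max(2, round(0.006 * fs)),
                          max(1, r_index - win))
  qrs_offset <- below_fwd(r_index + max(2, round(0.006 * fs)),
                          min(n, r_index + win))

  # T offset: tangent method on the low-passed ST-T
  stt_end <- min(n, r_index + round(0.5 * fs))
  baseline0 <- mean(sm[max(1, qrs_onset - round(0.08 * fs)):(qrs_onset - 1)])
  lp <- lowpass_ecg(x, fs, cutoff = 15)
  t_search <- (qrs_offset + round(0.08 * fs)):stt_end
  dev <- abs(lp[t_search] - baseline0)
  k_T <- t_search[which.max(dev)]
  a <- abs(lp - baseline0)
  da <- c(0, diff(a)) # per-sample
  desc <- k_T:stt_end
  k_star <- desc[which.min(da[desc])]
  t_offset <- if (da[k_star] < 0) {
    min(stt_end, k_star + round(a[k_star] / (-da[k_star])))
  } else stt_end
  t_offset <- max(t_offset, qrs_offset + round(0.1 * fs))

  # P wave: search from 300 ms before R up to just before QRS onset
  p_lo <- max(1, r_index - round(0.3 * fs))
  p_hi <- qrs_onset - max(2, round(0.01 * fs))
  p_present <- FALSE
  p_onset <- qrs_onset - round(0.12 * fs)
  if (p_hi - p_lo > round(0.04 * fs)) {
    pw <- lp[p_lo:p_hi]
    pbase <- stats::median(pw)
    pdev <- abs(pw - pbase)
    pk <- which.max(pdev)
    if (pdev[pk] >= flat_thresh) {
      p_present <- TRUE
      cross <- max(0.006, 0.04 * pdev[pk])
      on_rel <- 1L
      for (k in seq(pk, 1)) {
        if (pdev[k] < cross) { on_rel <- k; break }
      }
      p_onset <- p_lo + on_rel - 1L
    }
  }
  if (p_onset >= qrs_onset) p_onset <- qrs_onset - round(0.12 * fs)
  p_onset <- max(1, p_onset)
  beat_fiducials(p_onset, qrs_onset, r_index, qrs_offset, t_offset,
                 p_present = p_present)
}

#' Segment windows of a beat
#'
#' The three modelling windows, half-open and tiling `[p_onset, t_offset)`
#' exactly: `PR = [p_onset, qrs_onset)`, `QRS = [qrs_onset, qrs_offset)`,
#' `STT = [qrs_offset, t_offset)`.
#'
#' @param fid A [beat_fiducials()].
#' @return Data frame with columns `kind`, `start`, `end`.
#' @export
segment_windows <- function(fid) {
  stopifnot(inherits(fid, "beat_fiducials"))
  data.frame(kind = c("PR", "QRS", "STT"),
             start = c(fid$p_onset, fid$qrs_onset, fid$qrs_offset),
             end = c(fid$qrs_onset, fid$qrs_offset, fid$t_offset),
             stringsAsFactors = FALSE)
}

#' Measure wave amplitudes of one beat on one lead
#'
#' All amplitudes are referenced to the P-R baseline (mean amplitude over
#' the P-R window). P and T waves report bidirectional extrema; the ST level
#' is taken at J + 60 ms.
#'
#' @param rec An [ecg_record()].
#' @param lead Lead name.
#' @param fid A [beat_fiducials()].
#' @return A `wave_amplitudes` list: `p_pos`, `p_neg`, `q`, `r`, `s`,
#'   `st_level`, `t_pos`, `t_neg` (mV).
#' @export
measure_amplitudes <- function(rec, lead, fid) {
  if (!lead %in% colnames(rec$signals))
    abort_pronecg("MissingLead", paste("no lead", lead))
  x <- rec$signals[, lead]
  fs <- rec$fs
  pr <- fid$p_onset:(fid$qrs_onset - 1)
  baseline <- mean(x[pr])
  y <- x - baseline
  qrs <- fid$qrs_onset:(fid$qrs_offset - 1)
  r_val <- max(0, max(y[qrs]))
  r_at <- qrs[which.max(y[qrs])]
  before <- qrs[qrs < r_at]
  after <- qrs[qrs > r_at]
  q_val <- if (length(before) > 0) min(0, min(y[before])) else 0
  s_val <- if (length(after) > 0) min(0, min(y[after])) else 0
  st_idx <- min(nrow(rec$signals), fid$qrs_offset + round(0.06 * fs))
  stt <- fid$qrs_offset:(fid$t_offset - 1)
  p_win <- if (fid$p_present) fid$p_onset:(fid$qrs_onset - 1) else integer(0)
  structure(list(
    p_pos = if (length(p_win)) max(0, max(y[p_win])) else 0,
    p_neg = if (length(p_win)) min(0, min(y[p_win])) else 0,
    q = q_val, r = r_val, s = s_val,
    st_level = y[st_idx],
    t_pos = max(0, max(y[stt])),
    t_neg = min(0, min(y[stt])),
    baseline = baseline, lead = lead
  ), class = "wave_amplitudes")
}

#' Delineate every usable beat of a record
#'
#' Runs [detect_r_peaks()] on the consensus lead (II, fallback V2) and
#' delineates every beat with sufficient edge context.
#'
#' @param rec An [ecg_record()].
#' @return List of `ecg_beat` objects (each holds `fid` and `windows`).
#' @export
delineate_record <- function(rec) {
  lead <- consensus_lead(rec)
  peaks <- detect_r_peaks(rec$signals[, lead], rec$fs)
  beats <- list()
  for (r in peaks) {
    fid <- tryCatch(delineate(rec, r), pronecg_edgebeat = function(e) NULL)
    if (!is.null(fid)) beats[[length(beats) + 1]] <- ecg_beat(rec, fid)
  }
  beats
}

#' A delineated beat
#'
#' Bundles a record reference with one beat's fiducials and segment windows.
#'
#' @param rec An [ecg_record()].
#' @param fid A [beat_fiducials()].
#' @return An `ecg_beat` object.
#' @export
ecg_beat <- function(rec, fid) {
  structure(list(rec = rec, fid = fid, windows = segment_windows(fid)),
            class = "ecg_beat")
}

#' Export delineation results as a table
#'
#' One row per (beat, lead) with fiducial indices and wave amplitudes,
#' suitable for `write.csv`.
#'
#' @param rec An [ecg_record()].
#' @param beats List of `ecg_beat` as from [delineate_record()].
#' @return A data frame.
#' @export
export_delineation <- function(rec, beats) {
  rows <- list()
  for (b in seq_along(beats)) {
    fid <- beats[[b]]$fid
    for (lead in colnames(rec$signals)) {
      amp <- measure_amplitudes(rec, lead, fid)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = rec$subject_id, beat = b, lead = lead,
        p_onset = fid$p_onset, qrs_onset = fid$qrs_onset,
        r_peak = fid$r_peak, qrs_offset = fid$qrs_offset,
        t_offset = fid$t_offset, p_present = fid$p_present,
        p_pos = amp$p_pos, p_neg = amp$p_neg, q = amp$q, r = amp$r,
        s = amp$s, st_level = amp$st_level, t_pos = amp$t_pos,
        t_neg = amp$t_neg, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
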