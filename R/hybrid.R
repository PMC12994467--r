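# Hybrid combiner: the tree-route conversion carries the best waveform
# morphology, the VCG route the best amplitudes. Each lead and segment of
# the tree-route beat is rescaled by the ratio of reference to tree-route
# peak-to-peak amplitude. Positive per-segment scaling provably preserves
# every morphology class (wave classes and QRS pattern letters depend only
# on sign structure and amplitude ratios), while the segment amplitude is
# transferred from the reference. The scale is clamped to [0.2, 5] and
# forced to 1 whenever either segment's peak-to-peak falls below a 0.05 mV
# floor, guarding degenerate segments.

segment_ptp <- function(x) {
  if (length(x) == 0) return(0)
  max(x) - min(x)
}

#' Rescale a converted beat to reference segment amplitudes
#'
#' @param rf_beat Converted beat ([ecg_record()]), typically the tree-route
#'   output.
#' @param ref_beat Reference beat ([ecg_record()]) on the same time base,
#'   typically the VCG-route output.
#' @param windows Segment windows (data frame from [segment_windows()])
#'   shared by both beats.
#' @param clamp Lower/upper bounds on the scale factor.
#' @param floor_mv Peak-to-peak floor below which the scale is forced to 1.
#' @param leads Leads to rescale (default: leads present in both records).
#' @return An [ecg_record()] with rescaled amplitudes.
#' @export
rescale_to_reference <- function(rf_beat, ref_beat, windows,
                                 clamp = c(0.2, 5), floor_mv = 0.05,
                                 leads = NULL) {
  if (!inherits(rf_beat, "ecg_record") || !inherits(ref_beat, "ecg_record"))
    abort_pronecg("WindowMismatch", "rf_beat and ref_beat must be ecg_record")
  if (nrow(rf_beat$signals) != nrow(ref_beat$signals) ||
      rf_beat$fs != ref_beat$fs)
    abort_pronecg("WindowMismatch", "beats are not on a shared time base")
  if (max(windows$end) - 1 > nrow(rf_beat$signals))
    abort_pronecg("WindowMismatch", "windows exceed record length")
  if (is.null(leads))
    leads <- intersect(colnames(rf_beat$signals), colnames(ref_beat$signals))
  out <- rf_beat$signals
  fs <- rf_beat$fs
  n <- nrow(out)
  w <- max(1, round(0.010 * fs))
  for (lead in leads) {
    # per-sample scale profile: the segment's scale inside each window,
    # with a 10 ms linear ramp across internal boundaries so identical
    # inputs pass through untouched and scale steps never jump
    scale_vec <- rep(1, n)
    seg_scale <- numeric(nrow(windows))
    for (k in seq_len(nrow(windows))) {
      idx <- windows$start[k]:(windows$end[k] - 1)
      ptp_rf <- segment_ptp(rf_beat$signals[idx, lead])
      ptp_ref <- segment_ptp(ref_beat$signals[idx, lead])
      seg_scale[k] <- if (ptp_rf < floor_mv || ptp_ref < floor_mv) 1
                      else min(max(ptp_ref / ptp_rf, clamp[1]), clamp[2])
      scale_vec[idx] <- seg_scale[k]
    }
    for (k in 2:nrow(windows)) {
      b <- windows$start[k]
      ramp_idx <- b:min(b + w - 1, n)
      alpha <- seq_along(ramp_idx) / (length(ramp_idx) + 1)
      scale_vec[ramp_idx] <- (1 - alpha) * seg_scale[k - 1] +
        alpha * seg_scale[k]
    }
    out[, lead] <- rf_beat$signals[, lead] * scale_vec
  }
  rec <- ecg_record(out, fs = fs, posture = "supine",
                    subject_id = rf_beat$subject_id)
  attr(rec, "truth") <- attr(rf_beat, "truth")
  rec
}

#' Convert a prone record with the hybrid model
#'
#' Runs the VCG route ([convert_approach2()]) and the tree route
#' ([predict_full_beat()] per delineated beat), then transfers the VCG
#' route's segment amplitudes onto the tree route's morphology with
#' [rescale_to_reference()]. Beats are assembled into a record that is zero
#' outside the beat windows for the modelled leads.
#'
#' @param bundle Fitted `segment_model_bundle` (tree route).
#' @param vcg_model Fitted `vcg_regression_model` (amplitude reference).
#' @param prone Complete prone [ecg_record()].
#' @param cov One-row [subject_covariates()].
#' @param ... Passed to [convert_approach2()] (e.g. `matrix_rule`).
#' @return List: `record` (converted [ecg_record()]) and `beats` (list of
#'   per-beat `ecg_beat`).
#' @export
convert_hybrid <- function(bundle, vcg_model, prone, cov, ...) {
  if (!inherits(bundle, "segment_model_bundle"))
    abort_pronecg("ModelNotFitted", "hybrid conversion needs a fitted tree bundle")
  ref_rec <- convert_approach2(vcg_model, prone, cov, ...)
  beats <- delineate_record(prone)
  if (length(beats) == 0)
    abort_pronecg("InsufficientData", "no delineable beats in prone record")
  n <- nrow(prone$signals)
  out <- matrix(0, n, 12, dimnames = list(NULL, ecg_leads()))
  pass <- setdiff(ecg_leads(), bundle$leads)
  conv_beats <- list()
  for (b in beats) {
    rf <- predict_full_beat(bundle, b, cov)
    hybrid <- rescale_to_reference(rf$rec, ref_rec, b$windows,
                                   leads = bundle$leads)
    span <- b$fid$p_onset:(b$fid$t_offset - 1)
    out[span, bundle$leads] <- hybrid$signals[span, bundle$leads]
    out[span, pass] <- prone$signals[span, pass]
    conv_beats[[length(conv_beats) + 1]] <- ecg_beat(hybrid, b$fid)
  }
  rec <- ecg_record(out, fs = prone$fs, posture = "supine",
                    subject_id = prone$subject_id)
  attr(rec, "truth") <- attr(prone, "truth")
  list(record = rec, beats = conv_beats)
}
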