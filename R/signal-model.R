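# Core signal containers: 12-lead ECG and orthogonal-lead VCG records, plus
# the subject covariate table shared by every conversion approach.

#' Canonical 12-lead order
#'
#' All `ecg_record` objects store their leads in this order: the six limb
#' leads followed by the six precordial leads.
#'
#' @return Character vector of the 12 lead names.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @rdname ecg_leads
#' @export
precordial_leads <- function() paste0("V", 1:6)

#' @rdname ecg_leads
#' @export
limb_leads <- function() c("I", "II", "III", "aVR", "aVL", "aVF")

vcg_leads <- function() c("X", "Y", "Z")

#' Construct a 12-lead ECG record
#'
#' Amplitudes are stored in millivolts at a single sampling rate. A record is
#' "complete" when all 12 canonical leads are present; most conversion
#' operations require completeness, readers canonicalize lead order on
#' ingest.
#'
#' @param signals Numeric matrix, one column per lead (columns named with
#'   lead names), amplitudes in millivolts.
#' @param fs Sampling rate in Hz.
#' @param posture `"supine"` or `"prone"`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `ecg_record` with elements `signals`, `fs`,
#'   `posture`, `subject_id`.
#' @export
ecg_record <- function(signals, fs, posture = c("supine", "prone"),
                       subject_id = "anonymous") {
  posture <- match.arg(posture)
  signals <- as.matrix(signals)
  if (is.null(colnames(signals)))
    abort_pronecg("FormatError", "lead matrix must have named columns")
  unknown <- setdiff(colnames(signals), ecg_leads())
  if (length(unknown) > 0)
    abort_pronecg("FormatError",
                  paste("unknown lead name(s):", paste(unknown, collapse = ", ")))
  # canonical order for whatever subset is present
  signals <- signals[, intersect(ecg_leads(), colnames(signals)), drop = FALSE]
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    abort_pronecg("FormatError", "fs must be a single positive number")
  if (!all(is.finite(signals)))
    abort_pronecg("FormatError", "non-finite amplitudes in ECG record")
  structure(
    list(signals = signals, fs = fs, posture = posture,
         subject_id = as.character(subject_id)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject=%s posture=%s fs=%g Hz, %d leads x %d samples (%.2f s)\n",
              x$subject_id, x$posture, x$fs, ncol(x$signals), nrow(x$signals),
              nrow(x$signals) / x$fs))
  invisible(x)
}

#' Duration of a record in seconds
#' @param rec An `ecg_record` or `vcg_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(rec) {
  n <- if (inherits(rec, "vcg_record")) nrow(rec$xyz) else nrow(rec$signals)
  n / rec$fs
}

is_complete_record <- function(rec) {
  all(ecg_leads() %in% colnames(rec$signals))
}

require_complete <- function(rec) {
  missing <- setdiff(ecg_leads(), colnames(rec$signals))
  if (length(missing) > 0)
    abort_pronecg("MissingLead",
                  paste("record lacks lead(s):", paste(missing, collapse = ", ")))
  invisible(rec)
}

#' Construct an orthogonal-lead VCG record
#'
#' Holds the three orthogonal (Frank-style X, Y, Z) dipole projections on the
#' same time base convention as [ecg_record()].
#'
#' @param xyz Numeric matrix with three columns `X`, `Y`, `Z`, millivolts.
#' @param fs Sampling rate in Hz.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `vcg_record`.
#' @export
vcg_record <- function(xyz, fs, subject_id = "anonymous") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3)
    abort_pronecg("FormatError", "VCG requires exactly three columns (X, Y, Z)")
  colnames(xyz) <- vcg_leads()
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    abort_pronecg("FormatError", "fs must be a single positive number")
  if (!all(is.finite(xyz)))
    abort_pronecg("FormatError", "non-finite amplitudes in VCG record")
  structure(list(xyz = xyz, fs = fs, subject_id = as.character(subject_id)),
            class = "vcg_record")
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf("<vcg_record> subject=%s fs=%g Hz, %d samples (%.2f s)\n",
              x$subject_id, x$fs, nrow(x$xyz), nrow(x$xyz) / x$fs))
  invisible(x)
}

#' Subject covariates
#'
#' The anthropometric and demographic covariates entering the conversion
#' models. `male` is a 0/1 indicator; lengths in cm, weight in kg.
#'
#' @param subject_id Identifier.
#' @param male 0/1 indicator of male sex.
#' @param age Years.
#' @param height Centimetres.
#' @param weight Kilograms.
#' @param chest Chest circumference, cm.
#' @param waist Waist circumference, cm.
#' @return A one-row `data.frame` of class `subject_covariates`.
#' @export
subject_covariates <- function(subject_id, male, age, height, weight,
                               chest, waist) {
  if (!male %in% c(0, 1))
    abort_pronecg("FormatError", "male must be 0 or 1")
  if (age < 0 || any(c(height, weight, chest, waist) <= 0))
    abort_pronecg("FormatError", "implausible covariate values")
  out <- data.frame(subject_id = as.character(subject_id), male = male,
                    age = age, height = height, weight = weight,
                    chest = chest, waist = waist,
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_covariates", class(out))
  out
}

covariate_fields <- function() c("male", "age", "height", "weight", "chest", "waist")

#' Diagnosis classes
#'
#' The closed set of ECG diagnosis classes used for cohort labels and
#' diagnostic evaluation.
#'
#' @return Character vector of class names.
#' @export
diagnosis_classes <- function() {
  c("Normal", "ST_elevation", "Old_MI", "ST_depression",
    "CLBBB", "CRBBB_RBBB", "LAH")
}
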