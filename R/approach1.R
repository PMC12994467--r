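# Approach 1: direct per-lead linear regression. The mirrored prone
# precordial geometry makes specific lead pairs inversely related: standard
# V1 pairs with prone V4, standard V4 with prone V1, and standard V2 with
# prone V2. Each of the targets V1, V2, V4 is regressed on its paired prone
# lead plus age and sex, fitting pooled time samples from healthy subjects.
# V3 and V5 are then derived as midpoints of their anatomical neighbours,
# and V6 plus the limb leads pass through unchanged (those electrodes sit at
# standard sites in the prone montage).

direct_pairing <- function() {
  c(V1 = "V4", V2 = "V2", V4 = "V1")
}

#' Elementwise midpoint of two lead series
#'
#' @param lead_a,lead_b Equal-length amplitude series.
#' @return `(lead_a + lead_b) / 2`.
#' @export
derive_midpoint_lead <- function(lead_a, lead_b) {
  if (length(lead_a) != length(lead_b))
    abort_pronecg("LengthMismatch", "lead series differ in length")
  (lead_a + lead_b) / 2
}

#' Fit the direct-lead conversion model
#'
#' Ordinary least squares per target lead (V1, V2, V4), each on its paired
#' prone lead plus the `male` indicator and `age`, pooled over the time
#' points of all beats of the eligible subjects.
#'
#' @param cohort An `ecg_cohort` (paired prone/supine records + covariates).
#' @param restrict Diagnosis classes eligible for fitting; default healthy
#'   (`"Normal"`) subjects only. Use `NULL` for all subjects.
#' @return A `direct_lead_model`: per-target intercept, coefficients, and
#'   goodness-of-fit R^2.
#' @export
fit_direct <- function(cohort, restrict = "Normal") {
  labels <- cohort_labels(cohort)
  eligible <- if (is.null(restrict)) cohort
              else cohort[labels %in% restrict]
  if (length(eligible) == 0)
    abort_pronecg("InsufficientData", "no eligible subjects after restriction")
  pooled <- pool_posture_pairs(eligible)
  cov <- cohort_covariates(eligible)
  cov_rows <- cov[match(pooled$subject_id, cov$subject_id), ]
  models <- list()
  for (target in names(direct_pairing())) {
    paired <- direct_pairing()[[target]]
    X <- cbind(prone = pooled$prone[, paired],
               male = cov_rows$male, age = cov_rows$age)
    colnames(X) <- c(paste0("prone_", paired), "male", "age")
    y <- pooled$supine[, target]
    if (nrow(X) < ncol(X) + 2)
      abort_pronecg("InsufficientData",
                    sprintf("%d samples for %d predictors", nrow(X), ncol(X)))
    models[[target]] <- ols_min_norm(X, y)
  }
  structure(list(models = models, pairing = direct_pairing(),
                 predictors = c("paired prone lead", "male", "age"),
                 n = nrow(pooled$prone)),
            class = "direct_lead_model")
}

#' @export
print.direct_lead_model <- function(x, ...) {
  cat("<direct_lead_model> targets:", paste(names(x$models), collapse = ", "),
      sprintf("(n = %d pooled samples)\n", x$n))
  for (target in names(x$models)) {
    m <- x$models[[target]]
    cat(sprintf("  %s ~ %s  R^2 = %.4f\n", target,
                paste(sprintf("%.3f*%s", m$coefficients,
                              names(m$coefficients)), collapse = " + "),
                m$r2))
  }
  invisible(x)
}

#' Convert a prone record with the direct-lead model
#'
#' V1, V2, V4 are regression outputs; V3 is the midpoint of converted V2 and
#' V4; V5 the midpoint of converted V4 and prone V6; V6 and the limb leads
#' pass through unchanged. The output is tagged supine.
#'
#' @param model A fitted [fit_direct()] model.
#' @param prone Complete prone [ecg_record()].
#' @param cov One-row [subject_covariates()] for the subject.
#' @return Converted [ecg_record()].
#' @export
convert_direct <- function(model, prone, cov) {
  if (!inherits(model, "direct_lead_model"))
    abort_pronecg("ModelNotFitted", "model is not a fitted direct_lead_model")
  require_complete(prone)
  out <- prone$signals
  for (target in names(model$models)) {
    m <- model$models[[target]]
    paired <- model$pairing[[target]]
    X <- cbind(prone$signals[, paired], cov$male, cov$age)
    out[, target] <- as.numeric(m$intercept + X %*% m$coefficients)
  }
  out[, "V3"] <- derive_midpoint_lead(out[, "V2"], out[, "V4"])
  out[, "V5"] <- derive_midpoint_lead(out[, "V4"], prone$signals[, "V6"])
  rec <- ecg_record(out, fs = prone$fs, posture = "supine",
                    subject_id = prone$subject_id)
  attr(rec, "truth") <- attr(prone, "truth")
  rec
}
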