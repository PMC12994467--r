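# Model-comparison metrics, Bland-Altman agreement, and diagnostic
# performance with subject-level bootstrap confidence intervals.

#' Regression metrics
#'
#' RMSE, MAE and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param y Observed series.
#' @param yhat Predicted series (same length, n >= 2).
#' @return A `metrics_report` list: `rmse`, `mae`, `r2`, `n`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat))
    abort_pronecg("LengthMismatch", "y and yhat differ in length")
  if (length(y) < 2)
    abort_pronecg("InsufficientData", "need n >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    abort_pronecg("DegenerateTarget", "constant y: R^2 undefined")
  err <- y - yhat
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 r2 = 1 - sum(err^2) / ss_tot, n = length(y)),
            class = "metrics_report")
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `a - b` (convention: converted minus original).
#' Limits of agreement are `bias ± 1.96 * sd(d)` with the sample (n-1) sd.
#'
#' @param a Measurements (e.g. model-predicted amplitudes).
#' @param b Paired measurements (e.g. measured amplitudes).
#' @return A `bland_altman_report`: `bias`, `loa_low`, `loa_high`, `sd_d`,
#'   `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    abort_pronecg("LengthMismatch", "a and b differ in length")
  if (length(a) < 2)
    abort_pronecg("InsufficientData", "need n >= 2")
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d, sd_d = sd_d, n = length(d)),
            class = "bland_altman_report")
}

# Rank-statistic AUC (Mann-Whitney) for numeric scores.
auc_scores <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

binary_counts <- function(truth_pos, pred_pos) {
  c(tp = sum(truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos),
    fp = sum(!truth_pos & pred_pos), tn = sum(!truth_pos & !pred_pos))
}

diag_point <- function(truth_pos, pred) {
  if (is.numeric(pred)) {
    pred_pos <- pred >= 0.5
    auc <- auc_scores(truth_pos, pred)
  } else {
    pred_pos <- as.logical(pred)
    auc <- NA_real_
  }
  ct <- binary_counts(truth_pos, pred_pos)
  sens <- ct["tp"] / (ct["tp"] + ct["fn"])
  spec <- ct["tn"] / (ct["tn"] + ct["fp"])
  if (is.na(auc)) auc <- (sens + spec) / 2  # single-threshold trapezoid
  f1 <- 2 * ct["tp"] / (2 * ct["tp"] + ct["fp"] + ct["fn"])
  c(sensitivity = unname(sens), specificity = unname(spec),
    auc = unname(auc), f1 = unname(f1))
}

#' Diagnostic performance for one class
#'
#' One-vs-rest binarization against `positive_class`. With hard label
#' predictions the AUC is the single-threshold trapezoid through
#' `(0,0) - (1-specificity, sensitivity) - (1,1)`, i.e.
#' `(sensitivity + specificity)/2`; with numeric scores it is the
#' Mann-Whitney rank statistic. Confidence intervals are percentile
#' bootstrap over subjects (falling back to observation-level resampling
#' when `subjects` is `NULL`).
#'
#' @param truth Character vector of true diagnosis labels.
#' @param predicted Character labels, or numeric scores for the positive
#'   class.
#' @param positive_class The class evaluated one-vs-rest.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param subjects Optional subject id per observation; resampling is done
#'   at the subject level to respect within-subject correlation.
#' @param conf Confidence level.
#' @return A `diagnostic_report`: point estimates and `ci_low`/`ci_high`
#'   for sensitivity, specificity, AUC and F1.
#' @export
diagnostic_metrics <- function(truth, predicted, positive_class,
                               n_boot = 1000, seed = 1, subjects = NULL,
                               conf = 0.95) {
  if (length(truth) != length(predicted))
    abort_pronecg("LengthMismatch", "truth and predicted differ in length")
  if (!positive_class %in% truth)
    abort_pronecg("MissingClass",
                  paste("positive class absent from truth:", positive_class))
  truth_pos <- truth == positive_class
  pred <- if (is.numeric(predicted)) predicted else predicted == positive_class
  point <- diag_point(truth_pos, pred)
  if (is.null(subjects)) subjects <- as.character(seq_along(truth))
  groups <- split(seq_along(truth), subjects)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      take <- unlist(groups[sample(length(groups), replace = TRUE)],
                     use.names = FALSE)
      tp <- truth_pos[take]
      if (!any(tp) || all(tp)) return(rep(NA_real_, 4))
      diag_point(tp, pred[take])
    }, numeric(4))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  structure(list(
    sensitivity = point["sensitivity"], specificity = point["specificity"],
    auc = point["auc"], f1 = point["f1"],
    ci_low = ci[1, ], ci_high = ci[2, ],
    positive_class = positive_class, n = length(truth), n_boot = n_boot
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> %s (n = %d)\n", x$positive_class, x$n))
  for (m in c("sensitivity", "specificity", "auc", "f1")) {
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m, x[[m]],
                x$ci_low[[m]], x$ci_high[[m]]))
  }
  invisible(x)
}
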