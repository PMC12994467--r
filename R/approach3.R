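# Approach 3: per-lead, per-segment tree-ensemble regression. Each row of a
# feature table is one (beat, normalized time point): the 12 prone-lead
# amplitudes at that point plus six subject covariates (18 features) predict
# the standard-lead amplitude at the matched normalized point. Segments are
# piecewise-linearly time-normalized to fixed lengths so rows align between
# the non-simultaneous prone and standard beats. Splitting and
# cross-validation are participant-level: all cycles of a subject fall on
# one side, never both.

#' Segment normalization lengths
#'
#' Number of normalized time points per segment at the canonical 500 Hz:
#' P-R 50, QRS 60, ST-T 200.
#'
#' @return Named integer vector.
#' @export
segment_lengths <- function() c(PR = 50L, QRS = 60L, STT = 200L)

target_leads <- function() paste0("V", 1:5)

# Interpolate all columns of `m` at `npt` evenly spaced positions across the
# half-open window [start, end).
normalize_window <- function(m, start, end, npt) {
  pos <- start + (seq_len(npt) - 1) / npt * (end - start)
  apply(m, 2, function(col) stats::approx(seq_len(nrow(m)), col, xout = pos)$y)
}

#' Build a feature table for one paired beat and one segment
#'
#' Both beats' segment windows are time-normalized to the fixed per-segment
#' length, aligning prone features with standard-lead targets row by row.
#'
#' @param prone_beat,standard_beat `ecg_beat` objects (delineated).
#' @param cov One-row [subject_covariates()].
#' @param segment `"PR"`, `"QRS"`, or `"STT"`.
#' @return Data frame with 18 feature columns (`prone_*`, covariates),
#'   target columns `target_V1` .. `target_V5`, and a `group` column
#'   (subject id).
#' @export
build_feature_table <- function(prone_beat, standard_beat, cov, segment) {
  if (!inherits(prone_beat, "ecg_beat") || !inherits(standard_beat, "ecg_beat"))
    abort_pronecg("UndelineatedBeat", "beats must be delineated (ecg_beat)")
  missing <- setdiff(covariate_fields(), names(cov))
  if (length(missing) > 0 || anyNA(cov[covariate_fields()]))
    abort_pronecg("MissingCovariate",
                  paste("covariates incomplete:", paste(missing, collapse = ", ")))
  stopifnot(segment %in% names(segment_lengths()))
  npt <- segment_lengths()[[segment]]
  wp <- prone_beat$windows[prone_beat$windows$kind == segment, ]
  ws <- standard_beat$windows[standard_beat$windows$kind == segment, ]
  feat <- normalize_window(prone_beat$rec$signals[, ecg_leads(), drop = FALSE],
                           wp$start, wp$end, npt)
  colnames(feat) <- paste0("prone_", ecg_leads())
  targ <- normalize_window(
    standard_beat$rec$signals[, target_leads(), drop = FALSE],
    ws$start, ws$end, npt)
  colnames(targ) <- paste0("target_", target_leads())
  out <- data.frame(feat, male = cov$male, age = cov$age, height = cov$height,
                    weight = cov$weight, chest = cov$chest, waist = cov$waist,
                    targ, group = cov$subject_id, stringsAsFactors = FALSE)
  out
}

feature_columns <- function() c(paste0("prone_", ecg_leads()), covariate_fields())

# Representative standard beat of a subject: the middle delineated beat.
representative_beat <- function(beats) {
  beats[[ceiling(length(beats) / 2)]]
}

#' Build pooled per-segment feature tables for a cohort
#'
#' Delineates the prone and standard records of every subject, pairs each
#' prone beat with the subject's representative (median) standard beat, and
#' pools the per-beat tables.
#'
#' @param cohort An `ecg_cohort`.
#' @return Named list of data frames, one per segment (`PR`, `QRS`, `STT`).
#' @export
build_cohort_tables <- function(cohort) {
  tabs <- list(PR = list(), QRS = list(), STT = list())
  for (s in cohort) {
    pb <- delineate_record(s$prone)
    sb <- delineate_record(s$supine)
    if (length(pb) == 0 || length(sb) == 0) next
    ref <- representative_beat(sb)
    for (seg in names(tabs)) {
      for (b in pb) {
        tabs[[seg]][[length(tabs[[seg]]) + 1]] <-
          build_feature_table(b, ref, s$covariates, seg)
      }
    }
  }
  lapply(tabs, function(l) {
    if (length(l) == 0)
      abort_pronecg("InsufficientData", "no delineated beats in cohort")
    do.call(rbind, l)
  })
}

#' Participant-level train/test split
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with disjoint, exhaustive `train` and `test` id vectors;
#'   `length(train) == round(ratio * n)`.
#' @export
participant_split <- function(subject_ids, ratio = 0.8, seed = 1) {
  if (ratio <= 0 || ratio >= 1)
    abort_pronecg("ConfigError", "ratio must be in (0, 1)")
  subject_ids <- unique(subject_ids)
  n_train <- round(ratio * length(subject_ids))
  train <- with_seed(seed, sample(subject_ids, n_train))
  list(train = sort(train), test = sort(setdiff(subject_ids, train)))
}

assert_no_leakage <- function(train_ids, test_ids) {
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap) > 0)
    abort_pronecg("LeakageError",
                  paste("subjects on both sides of the split:",
                        paste(overlap, collapse = ", ")))
  invisible(TRUE)
}

#' Default tree-ensemble hyperparameters
#'
#' The random-forest defaults are 500 trees with `mtry = 6` (the regression
#' default p/3 for the 18 features); the gradient-boosting defaults are
#' `eta = 0.1`, `max_depth = 2`, `gamma = 0.001`, `colsample_bytree = 0.4`,
#' with `nrounds` exposed (default 500).
#'
#' @return Named list of hyperparameters.
#' @export
rf_params <- function() list(ntree = 500, mtry = 6)

#' @rdname rf_params
#' @export
xgb_params <- function() {
  list(eta = 0.1, max_depth = 2, gamma = 0.001, colsample_bytree = 0.4,
       nrounds = 500)
}

fill_params <- function(algo, params) {
  defaults <- if (algo == "random_forest") rf_params() else xgb_params()
  utils::modifyList(defaults, if (is.null(params)) list() else params)
}

fit_one_model <- function(algo, params, X, y, seed) {
  if (algo == "random_forest") {
    fit <- ranger::ranger(
      x = X, y = y, num.trees = params$ntree, mtry = params$mtry,
      importance = "impurity", seed = seed, num.threads = 1,
      verbose = FALSE)
    list(engine = "ranger", fit = fit)
  } else {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
    fit <- xgboost::xgb.train(
      params = list(eta = params$eta, max_depth = params$max_depth,
                    gamma = params$gamma,
                    colsample_bytree = params$colsample_bytree,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
    list(engine = "xgboost", fit = fit)
  }
}

predict_one_model <- function(model, X) {
  if (model$engine == "ranger") {
    stats::predict(model$fit, data = X, num.threads = 1)$predictions
  } else {
    stats::predict(model$fit, newdata = xgboost::xgb.DMatrix(as.matrix(X)))
  }
}

#' Train the segment-model bundle
#'
#' Fits one model per (target lead V1-V5, segment), restricted to the
#' training subjects' rows; training/test leakage is guarded by asserting
#' the split is disjoint.
#'
#' @param tables Per-segment feature tables from [build_cohort_tables()].
#' @param algo `"random_forest"` or `"gradient_boosted_trees"`.
#' @param params Hyperparameter overrides (see [rf_params()], [xgb_params()]).
#' @param seed Integer seed.
#' @param train_ids Subjects to train on (default: all groups present).
#' @param test_ids Optional held-out subjects, checked for leakage.
#' @param leads Target leads (default V1-V5).
#' @param segments Segments to fit (default all three).
#' @return A `segment_model_bundle`.
#' @export
train_segment_models <- function(tables,
                                 algo = c("random_forest",
                                          "gradient_boosted_trees"),
                                 params = NULL, seed = 1,
                                 train_ids = NULL, test_ids = NULL,
                                 leads = target_leads(),
                                 segments = names(segment_lengths())) {
  algo <- match.arg(algo)
  params <- fill_params(algo, params)
  models <- list()
  for (seg in segments) {
    tab <- tables[[seg]]
    if (is.null(tab) || nrow(tab) == 0)
      abort_pronecg("EmptySlot", paste("no rows for segment", seg))
    if (is.null(train_ids)) train_ids <- unique(tab$group)
    if (!is.null(test_ids)) assert_no_leakage(train_ids, test_ids)
    tab <- tab[tab$group %in% train_ids, , drop = FALSE]
    if (nrow(tab) == 0)
      abort_pronecg("EmptySlot", paste("no training rows for segment", seg))
    X <- tab[, feature_columns()]
    models[[seg]] <- list()
    for (lead in leads) {
      models[[seg]][[lead]] <-
        fit_one_model(algo, params, X, tab[[paste0("target_", lead)]], seed)
    }
  }
  structure(list(models = models, algorithm = algo, params = params,
                 seed = seed, train_ids = sort(train_ids),
                 leads = leads, segments = segments),
            class = "segment_model_bundle")
}

#' @export
print.segment_model_bundle <- function(x, ...) {
  cat(sprintf("<segment_model_bundle> %s, %d models (%s x %s)\n",
              x$algorithm, length(x$segments) * length(x$leads),
              paste(x$leads, collapse = ","), paste(x$segments, collapse = ",")))
  cat("params:", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = " "), "\n")
  invisible(x)
}

bundle_model <- function(bundle, segment, lead) {
  m <- bundle$models[[segment]][[lead]]
  if (is.null(m))
    abort_pronecg("ModelNotFitted",
                  sprintf("no model for lead %s segment %s", lead, segment))
  m
}

#' Predict held-out rows of a feature table
#'
#' @param bundle A `segment_model_bundle`.
#' @param table A per-segment feature table.
#' @param segment,lead Which model to apply.
#' @return Numeric predictions for each row of `table`.
#' @export
predict_segment <- function(bundle, table, segment, lead) {
  m <- bundle_model(bundle, segment, lead)
  predict_one_model(m, table[, feature_columns()])
}

#' Grouped k-fold cross-validation
#'
#' Subjects are partitioned into k folds (all cycles of a subject in one
#' fold); per-fold RMSE, MAE and R^2 are reported per (lead, segment)
#' together with their mean and sd over folds.
#'
#' @param tables Per-segment feature tables.
#' @param algo,params,seed As in [train_segment_models()].
#' @param k Number of folds.
#' @param leads,segments Scope of the evaluation.
#' @return List with `folds` (long data frame) and `summary`
#'   (mean/sd over folds per lead, segment, metric).
#' @export
crossvalidate <- function(tables, algo = "random_forest", params = NULL,
                          k = 5, seed = 1, leads = target_leads(),
                          segments = names(segment_lengths())) {
  subjects <- unique(unlist(lapply(tables[segments], function(t) t$group)))
  if (k > length(subjects))
    abort_pronecg("TooManyFolds",
                  sprintf("k = %d exceeds %d subjects", k, length(subjects)))
  fold_of <- with_seed(seed, {
    stats::setNames(sample(rep(seq_len(k), length.out = length(subjects))),
                    sample(subjects))
  })
  rows <- list()
  for (fold in seq_len(k)) {
    test_ids <- names(fold_of)[fold_of == fold]
    train_ids <- setdiff(subjects, test_ids)
    assert_no_leakage(train_ids, test_ids)
    bundle <- train_segment_models(tables, algo, params, seed = seed,
                                   train_ids = train_ids, test_ids = test_ids,
                                   leads = leads, segments = segments)
    for (seg in segments) {
      held <- tables[[seg]][tables[[seg]]$group %in% test_ids, , drop = FALSE]
      for (lead in leads) {
        pred <- predict_segment(bundle, held, seg, lead)
        met <- regression_metrics(held[[paste0("target_", lead)]], pred)
        rows[[length(rows) + 1]] <- data.frame(
          fold = fold, lead = lead, segment = seg,
          rmse = met$rmse, mae = met$mae, r2 = met$r2)
      }
    }
  }
  folds <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(rmse, mae, r2) ~ lead + segment, folds,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- do.call(data.frame, agg)
  names(summary) <- c("lead", "segment", "rmse_mean", "rmse_sd",
                      "mae_mean", "mae_sd", "r2_mean", "r2_sd")
  list(folds = folds, summary = summary, k = k)
}

# Map predictions at normalized points back onto a native half-open window.
denormalize_window <- function(pred, start, end) {
  npt <- length(pred)
  pos <- start + (seq_len(npt) - 1) / npt * (end - start)
  stats::approx(pos, pred, xout = start:(end - 1), rule = 2)$y
}

# Linear cross-fade over `w` samples at the start of the right segment,
# ramping from the left segment's final value into the right prediction.
crossfade_boundary <- function(sig, boundary, w) {
  if (boundary - 1 < 1 || boundary + w - 1 > length(sig)) return(sig)
  left_last <- sig[boundary - 1]
  alpha <- seq_len(w) / (w + 1)
  idx <- boundary:(boundary + w - 1)
  sig[idx] <- (1 - alpha) * left_last + alpha * sig[idx]
  sig
}

#' Convert one prone beat with a segment-model bundle
#'
#' Per-segment predictions are mapped from normalized time back to the
#' beat's native windows, joined with a 10 ms linear cross-fade at segment
#' boundaries; outside `[p_onset, t_offset)` the baseline (0) is emitted.
#' Leads V1-V5 are model outputs; V6 and the limb leads pass through from
#' the prone record within the beat window.
#'
#' @param bundle A fitted `segment_model_bundle`.
#' @param prone_beat An `ecg_beat` of the prone record.
#' @param cov One-row [subject_covariates()].
#' @return An `ecg_beat` whose record holds the converted supine beat.
#' @export
predict_full_beat <- function(bundle, prone_beat, cov) {
  if (!inherits(prone_beat, "ecg_beat"))
    abort_pronecg("UndelineatedBeat", "prone beat must be delineated")
  rec <- prone_beat$rec
  fid <- prone_beat$fid
  wins <- prone_beat$windows
  n <- nrow(rec$signals)
  fs <- rec$fs
  out <- matrix(0, n, 12, dimnames = list(NULL, ecg_leads()))
  pass <- setdiff(ecg_leads(), bundle$leads)
  span <- fid$p_onset:(fid$t_offset - 1)
  out[span, pass] <- rec$signals[span, pass]
  w <- max(1, round(0.010 * fs))
  seg_tabs <- lapply(stats::setNames(nm = bundle$segments), function(seg)
    build_feature_table(prone_beat, prone_beat, cov, seg))
  for (lead in bundle$leads) {
    sig <- numeric(n)
    for (seg in bundle$segments) {
      pred <- predict_segment(bundle, seg_tabs[[seg]], seg, lead)
      wrow <- wins[wins$kind == seg, ]
      sig[wrow$start:(wrow$end - 1)] <-
        denormalize_window(pred, wrow$start, wrow$end)
    }
    sig <- crossfade_boundary(sig, fid$qrs_onset, w)
    sig <- crossfade_boundary(sig, fid$qrs_offset, w)
    out[, lead] <- sig
  }
  conv <- ecg_record(out, fs = fs, posture = "supine",
                     subject_id = rec$subject_id)
  ecg_beat(conv, fid)
}

#' Feature importances of a fitted bundle
#'
#' Native impurity (random forest) or gain (gradient boosting) importances,
#' ranked per (lead, segment); nonnegative and deterministic given the
#' training seed.
#'
#' @param bundle A fitted `segment_model_bundle`.
#' @return Long data frame: `lead`, `segment`, `feature`, `importance`,
#'   `rank`.
#' @export
feature_importance <- function(bundle) {
  rows <- list()
  for (seg in bundle$segments) {
    for (lead in bundle$leads) {
      m <- bundle_model(bundle, seg, lead)
      imp <- if (m$engine == "ranger") {
        m$fit$variable.importance
      } else {
        tab <- xgboost::xgb.importance(model = m$fit)
        v <- stats::setNames(rep(0, length(feature_columns())), feature_columns())
        v[tab$Feature] <- tab$Gain
        v
      }
      imp <- pmax(imp, 0)
      ord <- order(imp, decreasing = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        lead = lead, segment = seg, feature = names(imp)[ord],
        importance = as.numeric(imp[ord]), rank = seq_along(imp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
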