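# Sample pooling across beats and subjects. Prone and reference recordings
# are sequential, not simultaneous, so beats are paired by index after
# R-peak synchronization and cropped to a common window around each R peak.

beat_crop <- function(r, fs, n) {
  lo <- r - round(0.25 * fs)
  hi <- r + round(0.45 * fs) - 1
  if (lo < 1 || hi > n) return(NULL)
  lo:hi
}

# Pair prone and supine beats of every subject and pool their time samples.
# Returns matrices `prone` (n x 12) and `supine` (n x 12) plus per-sample
# subject ids.
pool_posture_pairs <- function(cohort) {
  prone_rows <- list(); supine_rows <- list(); ids <- list()
  for (s in cohort) {
    rp <- detect_r_peaks(s$prone$signals[, consensus_lead(s$prone)], s$prone$fs)
    rs <- detect_r_peaks(s$supine$signals[, consensus_lead(s$supine)], s$supine$fs)
    k <- min(length(rp), length(rs))
    if (k == 0) next
    for (b in seq_len(k)) {
      wp <- beat_crop(rp[b], s$prone$fs, nrow(s$prone$signals))
      ws <- beat_crop(rs[b], s$supine$fs, nrow(s$supine$signals))
      if (is.null(wp) || is.null(ws)) next
      prone_rows[[length(prone_rows) + 1]] <- s$prone$signals[wp, , drop = FALSE]
      supine_rows[[length(supine_rows) + 1]] <- s$supine$signals[ws, , drop = FALSE]
      ids[[length(ids) + 1]] <- rep(s$subject_id, length(wp))
    }
  }
  if (length(prone_rows) == 0)
    abort_pronecg("InsufficientData", "no pairable beats in cohort")
  list(prone = do.call(rbind, prone_rows),
       supine = do.call(rbind, supine_rows),
       subject_id = unlist(ids))
}

# Detect R peaks on the VCG via the dipole magnitude.
detect_r_peaks_vcg <- function(vcg) {
  mag <- sqrt(rowSums(vcg$xyz^2))
  detect_r_peaks(mag - stats::median(mag), vcg$fs)
}

# Pair prone beats with VCG beats (R-peak synchronized by index) and pool
# samples: prone 12-lead matrix against the orthogonal X, Y, Z targets.
pool_prone_vcg_pairs <- function(cohort) {
  prone_rows <- list(); vcg_rows <- list(); ids <- list()
  for (s in cohort) {
    rp <- detect_r_peaks(s$prone$signals[, consensus_lead(s$prone)], s$prone$fs)
    rv <- detect_r_peaks_vcg(s$vcg)
    k <- min(length(rp), length(rv))
    if (k == 0) next
    for (b in seq_len(k)) {
      wp <- beat_crop(rp[b], s$prone$fs, nrow(s$prone$signals))
      wv <- beat_crop(rv[b], s$vcg$fs, nrow(s$vcg$xyz))
      if (is.null(wp) || is.null(wv)) next
      prone_rows[[length(prone_rows) + 1]] <- s$prone$signals[wp, , drop = FALSE]
      vcg_rows[[length(vcg_rows) + 1]] <- s$vcg$xyz[wv, , drop = FALSE]
      ids[[length(ids) + 1]] <- rep(s$subject_id, length(wp))
    }
  }
  if (length(prone_rows) == 0)
    abort_pronecg("InsufficientData", "no pairable beats in cohort")
  list(prone = do.call(rbind, prone_rows),
       vcg = do.call(rbind, vcg_rows),
       subject_id = unlist(ids))
}

# Minimum-norm ordinary least squares with intercept. Rank deficiency is
# resolved by the SVD pseudoinverse (minimum-norm solution) with a warning.
ols_min_norm <- function(X, y, warn_rank = TRUE) {
  X1 <- cbind(`(Intercept)` = 1, X)
  sv <- svd(X1)
  tol <- max(dim(X1)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < ncol(X1) && warn_rank)
    warning("RankDeficient: design is rank deficient; minimum-norm solution used",
            call. = FALSE)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * crossprod(sv$u, y))
  fitted <- X1 %*% coef
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(intercept = coef[1], coefficients = stats::setNames(coef[-1], colnames(X)),
       r2 = r2, rank = rank, n = length(y))
}
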