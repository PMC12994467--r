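# Morphology nomenclature. Waveform windows are classified into the
# standard descriptor sets: P and T waves as upright / inverted / biphasic /
# flat (P additionally "absent" when no deflection was detected), the QRS
# as a polarity-ordered pattern string (e.g. "qRs", "QS", "RsR′"), and
# the ST segment as elevated / depressed / isoelectric. Thresholds follow
# conventional ECG reading: 0.05 mV (0.5 mm at standard gain) for a
# non-flat deflection, upper case for the dominant lobe and lobes strictly above half its
# amplitude, ST elevated at >= +0.1 mV and depressed at <= -0.05 mV.

#' Classify a single wave window
#'
#' `flat` if no sample reaches `flat_thresh` in magnitude; `biphasic` if
#' both polarities do; otherwise `upright`/`inverted` by the dominant
#' polarity.
#'
#' @param samples Baseline-referenced amplitudes (mV).
#' @param flat_thresh Flat threshold, mV.
#' @return One of `"upright"`, `"inverted"`, `"biphasic"`, `"flat"`.
#' @export
classify_wave <- function(samples, flat_thresh = 0.05) {
  if (length(samples) == 0)
    abort_pronecg("FormatError", "empty wave window")
  pos <- max(samples) >= flat_thresh
  neg <- -min(samples) >= flat_thresh
  if (pos && neg) "biphasic"
  else if (pos) "upright"
  else if (neg) "inverted"
  else "flat"
}

#' Classify a QRS complex into a pattern string
#'
#' Deflections are the zero-crossing-separated lobes whose peak magnitude
#' reaches `flat_thresh`. Letters follow polarity and temporal order:
#' initial negative lobes are Q, positive lobes R (a second positive lobe
#' gains a prime), negative lobes after a positive one are S. A lobe is
#' upper case iff it is the dominant lobe or strictly exceeds half its
#' peak magnitude. A
#' single all-negative deflection is reported as `"QS"`.
#'
#' @param samples Baseline-referenced QRS window (mV).
#' @param flat_thresh Lobe detection threshold, mV.
#' @return Pattern string over `{Q,q,R,r,S,s}` with prime suffixes, or
#'   `"QS"`.
#' @export
classify_qrs <- function(samples, flat_thresh = 0.05) {
  if (length(samples) == 0)
    abort_pronecg("EmptyQRS", "empty QRS window")
  sgn <- sign(samples)
  sgn[sgn == 0] <- NA
  # runs of constant polarity
  runs <- rle(ifelse(is.na(sgn), 0, sgn))
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  lobes <- data.frame(polarity = runs$values, peak = NA_real_)
  for (k in seq_len(nrow(lobes))) {
    seg <- samples[starts[k]:ends[k]]
    lobes$peak[k] <- max(abs(seg))
  }
  lobes <- lobes[lobes$polarity != 0 & lobes$peak >= flat_thresh, , drop = FALSE]
  # merge consecutive same-polarity lobes (zero-touching splits)
  if (nrow(lobes) > 1) {
    keep <- c(TRUE, diff(lobes$polarity) != 0)
    grp <- cumsum(keep)
    lobes <- do.call(rbind, lapply(split(lobes, grp), function(g)
      data.frame(polarity = g$polarity[1], peak = max(g$peak))))
  }
  if (nrow(lobes) == 0)
    abort_pronecg("EmptyQRS", "no deflection exceeds the flat threshold")
  if (all(lobes$polarity < 0)) return("QS")
  prime <- "′"
  biggest <- max(lobes$peak)
  letters_out <- character(nrow(lobes))
  n_pos <- 0; n_s <- 0; seen_pos <- FALSE
  for (k in seq_len(nrow(lobes))) {
    # upper case for the dominant lobe and any lobe strictly above half of it
    upper <- lobes$peak[k] >= biggest || lobes$peak[k] > 0.5 * biggest
    if (lobes$polarity[k] > 0) {
      n_pos <- n_pos + 1
      base <- if (upper) "R" else "r"
      letters_out[k] <- if (n_pos > 1) paste0(base, prime) else base
      seen_pos <- TRUE
    } else if (!seen_pos) {
      letters_out[k] <- if (upper) "Q" else "q"
    } else {
      n_s <- n_s + 1
      base <- if (upper) "S" else "s"
      letters_out[k] <- if (n_s > 1) paste0(base, prime) else base
    }
  }
  paste(letters_out, collapse = "")
}

classify_st <- function(st_level) {
  if (st_level >= 0.1) "elevated"
  else if (st_level <= -0.05) "depressed"
  else "isoelectric"
}

#' Morphology descriptor of one beat on one lead
#'
#' Combines the P class (with `"absent"` when no P deflection was
#' delineated), the QRS pattern string, the ST class (from the level at
#' J + 60 ms), and the T class.
#'
#' @param rec An [ecg_record()].
#' @param lead Lead name.
#' @param fid A [beat_fiducials()].
#' @param flat_thresh Flat/lobe threshold, mV.
#' @return A `morphology_descriptor`: list with `p_class`, `qrs_pattern`,
#'   `st_class`, `t_class`, `lead`.
#' @export
classify_beat_morphology <- function(rec, lead, fid, flat_thresh = 0.05) {
  x <- rec$signals[, lead]
  pr <- fid$p_onset:(fid$qrs_onset - 1)
  y <- x - mean(x[pr])
  p_class <- if (!fid$p_present) "absent"
             else classify_wave(y[pr], flat_thresh)
  qrs <- fid$qrs_onset:(fid$qrs_offset - 1)
  qrs_pattern <- tryCatch(classify_qrs(y[qrs], flat_thresh),
                          pronecg_emptyqrs = function(e) "QS")
  amp <- measure_amplitudes(rec, lead, fid)
  stt <- fid$qrs_offset:(fid$t_offset - 1)
  morphology_descriptor(p_class, qrs_pattern, classify_st(amp$st_level),
                        classify_wave(y[stt], flat_thresh), lead)
}

#' @rdname classify_beat_morphology
#' @param p_class,qrs_pattern,st_class,t_class,lead Descriptor fields.
#' @export
morphology_descriptor <- function(p_class, qrs_pattern, st_class, t_class,
                                  lead) {
  stopifnot(p_class %in% c("upright", "inverted", "biphasic", "flat", "absent"),
            nchar(qrs_pattern) > 0,
            st_class %in% c("elevated", "depressed", "isoelectric"),
            t_class %in% c("upright", "inverted", "biphasic", "flat"))
  structure(list(p_class = p_class, qrs_pattern = qrs_pattern,
                 st_class = st_class, t_class = t_class, lead = lead),
            class = "morphology_descriptor")
}

#' Descriptor agreement
#'
#' `descriptor_match()` is `TRUE` iff all four descriptor fields agree.
#' `morphology_similarity()` is the proportion of index-aligned descriptor
#' pairs in full agreement; restrict to one descriptor `field` or one
#' `lead` for the per-kind / per-lead breakdowns.
#'
#' @param a,b `morphology_descriptor` objects.
#' @return Logical.
#' @export
descriptor_match <- function(a, b) {
  a$p_class == b$p_class && a$qrs_pattern == b$qrs_pattern &&
    a$st_class == b$st_class && a$t_class == b$t_class
}

#' @rdname descriptor_match
#' @param A,B Index-aligned lists of `morphology_descriptor`.
#' @param field Optional single field (`"p_class"`, `"qrs_pattern"`,
#'   `"st_class"`, `"t_class"`) to compare instead of all four.
#' @param lead Optional lead name filter.
#' @return Proportion in `[0, 1]`.
#' @export
morphology_similarity <- function(A, B, field = NULL, lead = NULL) {
  if (length(A) != length(B))
    abort_pronecg("LengthMismatch", "descriptor sets differ in length")
  if (!is.null(lead)) {
    keep <- vapply(A, function(d) d$lead == lead, TRUE)
    A <- A[keep]; B <- B[keep]
  }
  if (length(A) == 0) return(NA_real_)
  hits <- mapply(function(a, b) {
    if (is.null(field)) descriptor_match(a, b)
    else identical(a[[field]], b[[field]])
  }, A, B)
  mean(hits)
}

#' Descriptor table for a record
#'
#' One row per (beat, lead) with the four descriptor fields; the CSV-ready
#' companion of [classify_beat_morphology()].
#'
#' @param rec An [ecg_record()].
#' @param beats List of `ecg_beat` (or `NULL` to delineate `rec`).
#' @param leads Leads to classify.
#' @return Data frame.
#' @export
morphology_table <- function(rec, beats = NULL, leads = colnames(rec$signals)) {
  if (is.null(beats)) beats <- delineate_record(rec)
  rows <- list()
  for (b in seq_along(beats)) {
    for (lead in leads) {
      d <- classify_beat_morphology(rec, lead, beats[[b]]$fid)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = rec$subject_id, beat = b, lead = lead,
        p_class = d$p_class, qrs_pattern = d$qrs_pattern,
        st_class = d$st_class, t_class = d$t_class,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
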