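# Readers and writers for the two on-disk dialects.
#
# CSV dialect: a metadata comment line
#   "# fs=<Hz> units=<mV|uV> posture=<supine|prone> subject=<id>"
# followed by an ordinary CSV with one column per lead. Amplitudes are
# converted to millivolts on read.
#
# WFDB dialect: a minimal header (.hea) / signal (.dat) pair, signal format
# 16 (interleaved little-endian 16-bit integers), physical units recovered as
# (adc - baseline) / gain. This covers the subset of the WFDB spec the
# toolkit emits; resolution is 1/gain mV (default gain 1000, i.e. 1 uV).

parse_meta_line <- function(line) {
  line <- sub("^#\\s*", "", line)
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(parts, "=")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  stats::setNames(as.list(vals), keys)
}

read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#"))
    abort_pronecg("FormatError",
                  paste0("CSV dialect requires a '# fs=... units=...' metadata line: ", path))
  meta <- parse_meta_line(first)
  if (is.null(meta$fs))
    abort_pronecg("FormatError", "metadata line lacks fs=<Hz>")
  dat <- utils::read.csv(path, skip = 1, check.names = FALSE)
  m <- as.matrix(dat)
  if (!is.numeric(m)) abort_pronecg("FormatError", "non-numeric sample values")
  units <- if (is.null(meta$units)) "mV" else meta$units
  if (units == "uV") m <- m / 1000
  else if (units != "mV") abort_pronecg("FormatError", paste("unknown units:", units))
  list(signals = m, fs = as.numeric(meta$fs),
       posture = meta$posture, subject = meta$subject)
}

#' Read a 12-lead ECG record
#'
#' @param path File path (for `wfdb`, the header path or the record basename).
#' @param dialect `"csv"` (self-describing single file) or `"wfdb"`
#'   (header/signal pair, format 16).
#' @param require_complete If `TRUE` (default) all 12 leads must be present.
#' @return An [ecg_record()] with amplitudes in millivolts and leads in
#'   canonical order.
#' @export
read_ecg <- function(path, dialect = c("csv", "wfdb"), require_complete = TRUE) {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "csv") read_signal_csv(path) else read_wfdb(path)
  leads <- colnames(raw$signals)
  if (require_complete) {
    missing <- setdiff(ecg_leads(), leads)
    if (length(missing) > 0)
      abort_pronecg("MissingLead",
                    paste("missing lead(s):", paste(missing, collapse = ", ")))
  }
  posture <- if (is.null(raw$posture)) "supine" else raw$posture
  subject <- if (is.null(raw$subject)) "anonymous" else raw$subject
  ecg_record(raw$signals, fs = raw$fs, posture = posture, subject_id = subject)
}

#' Write a 12-lead ECG record
#'
#' @param rec An [ecg_record()].
#' @param path Output path (for `wfdb`, basename; `.hea`/`.dat` are added).
#' @param dialect `"csv"` or `"wfdb"`.
#' @param units `"mV"` or `"uV"` (CSV dialect only).
#' @return `path`, invisibly.
#' @export
write_ecg <- function(rec, path, dialect = c("csv", "wfdb"), units = "mV") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    m <- rec$signals
    if (units == "uV") m <- m * 1000
    meta <- sprintf("# fs=%g units=%s posture=%s subject=%s",
                    rec$fs, units, rec$posture, rec$subject_id)
    write_csv_full_precision(m, path, meta)
  } else {
    write_wfdb(rec$signals, rec$fs, path,
               comment = sprintf("posture=%s subject=%s", rec$posture, rec$subject_id))
  }
  invisible(path)
}

#' Read / write orthogonal-lead VCG records
#'
#' Same dialects as [read_ecg()], with columns `X`, `Y`, `Z`.
#'
#' @inheritParams read_ecg
#' @return A [vcg_record()].
#' @export
read_vcg <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "csv") read_signal_csv(path) else read_wfdb(path)
  missing <- setdiff(vcg_leads(), colnames(raw$signals))
  if (length(missing) > 0)
    abort_pronecg("MissingLead",
                  paste("missing VCG lead(s):", paste(missing, collapse = ", ")))
  subject <- if (is.null(raw$subject)) "anonymous" else raw$subject
  vcg_record(raw$signals[, vcg_leads(), drop = FALSE], fs = raw$fs,
             subject_id = subject)
}

#' @rdname read_vcg
#' @inheritParams write_ecg
#' @param rec A [vcg_record()].
#' @export
write_vcg <- function(rec, path, dialect = c("csv", "wfdb"), units = "mV") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    m <- rec$xyz
    if (units == "uV") m <- m * 1000
    meta <- sprintf("# fs=%g units=%s subject=%s", rec$fs, units, rec$subject_id)
    write_csv_full_precision(m, path, meta)
  } else {
    write_wfdb(rec$xyz, rec$fs, path,
               comment = sprintf("subject=%s", rec$subject_id))
  }
  invisible(path)
}

# Write a numeric matrix as CSV with %.17g formatting so doubles round-trip
# bit-exactly through read.csv.
write_csv_full_precision <- function(m, path, meta_line) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_line, con)
  writeLines(paste(colnames(m), collapse = ","), con)
  body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  writeLines(do.call(paste, c(asplit(body, 2), sep = ",")), con)
  invisible(path)
}

# ---- minimal WFDB format-16 support -----------------------------------------

write_wfdb <- function(signals, fs, basename_path, gain = 1000, comment = NULL) {
  basename_path <- sub("\\.(hea|dat)$", "", basename_path)
  rec_name <- basename(basename_path)
  nsig <- ncol(signals)
  nsamp <- nrow(signals)
  adc <- round(signals * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  storage.mode(adc) <- "integer"
  checksums <- vapply(seq_len(nsig), function(j) {
    s <- sum(as.numeric(adc[, j])) %% 65536
    if (s >= 32768) s <- s - 65536
    as.integer(s)
  }, integer(1))
  hea <- c(
    sprintf("%s %d %g %d", rec_name, nsig, fs, nsamp),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
            rec_name, gain, adc[1, ], checksums, colnames(signals))
  )
  if (!is.null(comment)) hea <- c(hea, paste("#", comment))
  writeLines(hea, paste0(basename_path, ".hea"))
  con <- file(paste0(basename_path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(basename_path)
}

read_wfdb <- function(path) {
  base <- sub("\\.(hea|dat)$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path))
    abort_pronecg("FormatError", paste("no header file:", hea_path))
  lines <- readLines(hea_path)
  meta_lines <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_fields) < 4)
    abort_pronecg("FormatError", "malformed WFDB record line")
  nsig <- as.integer(head_fields[2])
  fs <- as.numeric(head_fields[3])
  nsamp <- as.integer(head_fields[4])
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (f[2] != "16")
      abort_pronecg("FormatError", paste("unsupported WFDB format:", f[2]))
    gain_spec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec)) else 0
    list(file = f[1], gain = gain, baseline = baseline,
         desc = if (length(f) >= 9) f[length(f)] else NA_character_)
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_path <- file.path(dirname(hea_path), sigs[[1]]$file)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  adc <- readBin(con, integer(), n = nsig * nsamp, size = 2,
                 endian = "little", signed = TRUE)
  m <- matrix(adc, ncol = nsig, byrow = TRUE)
  for (j in seq_len(nsig)) {
    m[, j] <- (m[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain
  }
  colnames(m) <- vapply(sigs, function(s) s$desc, "")
  meta <- list(signals = m, fs = fs)
  if (length(meta_lines) > 0) {
    kv <- parse_meta_line(meta_lines[1])
    meta$posture <- kv$posture
    meta$subject <- kv$subject
  }
  meta
}

# ---- covariates table -------------------------------------------------------

#' Read / write a subject covariates table
#'
#' Plain CSV keyed by `subject_id` with columns `male`, `age`, `height`,
#' `weight`, `chest`, `waist`.
#'
#' @param path CSV path.
#' @return Data frame of covariates, one row per subject.
#' @export
read_covariates <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", covariate_fields())
  missing <- setdiff(needed, names(dat))
  if (length(missing) > 0)
    abort_pronecg("MissingCovariate",
                  paste("covariates table lacks:", paste(missing, collapse = ", ")))
  dat$subject_id <- as.character(dat$subject_id)
  dat
}

#' @rdname read_covariates
#' @param covariates Data frame as returned by [read_covariates()].
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}
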