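# Band-limited (Fourier) resampling. The toolkit's canonical rate is 500 Hz;
# all pipelines resample on ingest so downstream window lengths in samples
# are comparable across sources.

fft_resample_vec <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  keep <- floor(min(n, n_out) / 2)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  if (keep > 0) Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
  if (min(n, n_out) %% 2 == 0 && n_out > n) {
    # upsampling across an even length: split the Nyquist bin symmetrically
    Y[keep + 1] <- X[keep + 1] / 2
    Y[n_out - keep + 1] <- X[keep + 1] / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a record to a target rate
#'
#' Fourier-domain band-limited resampling; waveform shape is preserved for
#' band-limited content, with ringing confined to the record edges.
#'
#' @param rec An [ecg_record()] or [vcg_record()].
#' @param fs_target Target sampling rate in Hz (> 0).
#' @return A record of the same class at `fs_target`.
#' @export
resample_record <- function(rec, fs_target) {
  if (!is.numeric(fs_target) || fs_target <= 0)
    abort_pronecg("FormatError", "fs_target must be positive")
  if (fs_target == rec$fs) return(rec)
  m <- if (inherits(rec, "vcg_record")) rec$xyz else rec$signals
  n_out <- round(nrow(m) * fs_target / rec$fs)
  out <- apply(m, 2, fft_resample_vec, n_out = n_out)
  if (inherits(rec, "vcg_record")) {
    vcg_record(out, fs = fs_target, subject_id = rec$subject_id)
  } else {
    ecg_record(out, fs = fs_target, posture = rec$posture,
               subject_id = rec$subject_id)
  }
}
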