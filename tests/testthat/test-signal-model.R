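make_rec <- function(n = 100, fs = 500, seed = 1) {
  withr::local_seed(seed)
  sig <- matrix(rnorm(n * 12, sd = 0.5), ncol = 12)
  colnames(sig) <- sample(ecg_leads())  # scrambled on purpose
  ecg_record(sig, fs = fs, posture = "prone", subject_id = "T01")
}

test_that("records canonicalize lead order and validate inputs", {
  rec <- make_rec()
  expect_identical(colnames(rec$signals), ecg_leads())
  expect_equal(record_duration(rec), 100 / 500)
  sig <- rec$signals
  sig[5, 3] <- NA
  expect_error(ecg_record(sig, 500), class = "pronecg_formaterror")
  expect_error(ecg_record(rec$signals, fs = 0), class = "pronecg_formaterror")
  bad <- rec$signals
  colnames(bad)[1] <- "W9"
  expect_error(ecg_record(bad, 500), class = "pronecg_formaterror")
})

test_that("CSV dialect round-trips bit-exactly and converts microvolts", {
  rec <- make_rec(n = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg(rec, path, "csv")
  back <- read_ecg(path, "csv")
  expect_identical(back$signals, rec$signals)
  expect_identical(back$posture, "prone")
  expect_identical(back$subject_id, "T01")
  expect_identical(back$fs, rec$fs)
  # microvolt files are normalized to millivolts on read
  write_ecg(rec, path, "csv", units = "uV")
  expect_equal(read_ecg(path, "csv")$signals, rec$signals, tolerance = 1e-12)
})

test_that("a CSV lacking a lead raises MissingLead naming it", {
  rec <- make_rec()
  path <- withr::local_tempfile(fileext = ".csv")
  partial <- rec$signals[, setdiff(ecg_leads(), "V3")]
  rec2 <- ecg_record(partial, 500, "prone")
  write_ecg(rec2, path, "csv")
  err <- expect_error(read_ecg(path, "csv"), class = "pronecg_missinglead")
  expect_match(conditionMessage(err), "V3")
  # partial records are readable when completeness is not required
  expect_silent(read_ecg(path, "csv", require_complete = FALSE))
})

test_that("WFDB format-16 pairs round-trip at 1 uV resolution", {
  rec <- make_rec(n = 150)
  base <- file.path(withr::local_tempdir(), "rec01")
  write_ecg(rec, base, "wfdb")
  expect_true(file.exists(paste0(base, ".hea")))
  back <- read_ecg(base, "wfdb")
  expect_equal(back$signals, rec$signals, tolerance = 1e-3)
  expect_identical(back$posture, "prone")
  # stability: a second write/read of the quantized record is exact
  write_ecg(back, base, "wfdb")
  again <- read_ecg(base, "wfdb")
  expect_identical(again$signals, back$signals)
})

test_that("VCG records round-trip in both dialects", {
  withr::local_seed(2)
  vcg <- vcg_record(matrix(rnorm(300), ncol = 3), fs = 500, subject_id = "T02")
  path <- withr::local_tempfile(fileext = ".csv")
  write_vcg(vcg, path, "csv")
  expect_identical(read_vcg(path, "csv")$xyz, vcg$xyz)
  base <- file.path(withr::local_tempdir(), "vcg01")
  write_vcg(vcg, base, "wfdb")
  expect_equal(read_vcg(base, "wfdb")$xyz, vcg$xyz, tolerance = 1e-3)
})

test_that("resampling preserves duration, identity, and band-limited shape", {
  rec <- make_rec(n = 1000, fs = 1000)
  expect_identical(resample_record(rec, 1000), rec)
  down <- resample_record(rec, 500)
  expect_equal(nrow(down$signals), 500)

  # analytic oracle: a 5 Hz sine resampled 1000 -> 500 Hz stays on the sine
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  sig <- matrix(rep(sin(2 * pi * 5 * t), 12), ncol = 12)
  colnames(sig) <- ecg_leads()
  rec <- ecg_record(sig, fs)
  out <- resample_record(rec, 500)
  t2 <- (0:(nrow(out$signals) - 1)) / 500
  mid <- 100:(nrow(out$signals) - 100)
  expect_lt(max(abs(out$signals[mid, "II"] - sin(2 * pi * 5 * t2[mid]))), 1e-3)
})

test_that("down-up resampling is near-lossless for band-limited signals", {
  vcg <- simulate_vcg(n_beats = 4, fs = 500, seed = 3)
  rec <- project_leads(vcg, lead_field("supine"))
  round_trip <- resample_record(resample_record(rec, 1000), 500)
  mid <- 50:(nrow(rec$signals) - 50)
  expect_lt(max(abs(round_trip$signals[mid, ] - rec$signals[mid, ])), 1e-3)
})

test_that("covariate tables round-trip and validate required columns", {
  cov <- rbind(dummy_covariates("S001"), dummy_covariates("S002"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_covariates(cov, path)
  back <- read_covariates(path)
  expect_equal(back$height, cov$height)
  broken <- cov[, setdiff(names(cov), "waist")]
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_covariates(path), class = "pronecg_missingcovariate")
})
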