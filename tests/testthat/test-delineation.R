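test_that("R detection returns nothing on flat signal and finds every beat", {
  expect_identical(detect_r_peaks(numeric(1000), 500), integer(0))

  fs <- 500
  times <- 0.5 + 0:9  # 10 beats at 1 Hz
  x <- gaussian_train(times, fs = fs)
  peaks <- detect_r_peaks(x, fs)
  expect_length(peaks, 10)
  expect_true(all(abs(peaks - (times * fs + 1)) <= 0.010 * fs))
  expect_true(all(diff(peaks) >= 0.2 * fs))

  # adaptive threshold: a halved beat is still detected
  amps <- rep(1, 10); amps[4] <- 0.5
  x2 <- gaussian_train(times, amps, fs = fs)
  expect_length(detect_r_peaks(x2, fs), 10)
})

test_that("detection sensitivity and PPV are 1.0 on noise-free trains", {
  for (seed in 1:3) {
    vcg <- simulate_vcg(n_beats = 6, fs = 500, seed = seed)
    rec <- project_leads(vcg, lead_field("supine"))
    truth <- attr(rec, "truth")$r_peaks
    det <- detect_r_peaks(rec$signals[, "II"], 500)
    expect_length(det, length(truth))           # sensitivity 1, PPV 1
    expect_true(all(abs(det - truth) <= 5))
  }
})

test_that("fiducials land within 20 ms of generator truth", {
  fs <- 500
  tol <- round(0.020 * fs)
  for (seed in c(2, 9)) {
    vcg <- simulate_vcg(n_beats = 6, fs = fs, seed = seed)
    rec <- project_leads(vcg, lead_field("supine"))
    truth <- attr(rec, "truth")$fiducials
    beats <- delineate_record(rec)
    expect_length(beats, nrow(truth))
    for (b in seq_along(beats)) {
      fid <- beats[[b]]$fid
      expect_true(fid$p_present)
      for (f in c("p_onset", "qrs_onset", "r_peak", "qrs_offset", "t_offset")) {
        expect_lte(abs(fid[[f]] - truth[[f]][b]), tol)
      }
      # ordering invariant
      v <- unlist(fid[c("p_onset", "qrs_onset", "r_peak", "qrs_offset",
                        "t_offset")])
      expect_true(all(diff(v) > 0))
    }
  }
})

test_that("a beat without P wave falls back to the fixed P-R span", {
  params <- default_beat_params()
  params <- params[params$wave != "P", ]
  vcg <- simulate_vcg(params, n_beats = 5, fs = 500, seed = 4)
  rec <- project_leads(vcg, lead_field("supine"))
  beats <- delineate_record(rec)
  expect_gt(length(beats), 0)
  for (b in beats) {
    expect_false(b$fid$p_present)
    expect_equal(b$fid$qrs_onset - b$fid$p_onset, round(0.12 * 500))
  }
})

test_that("beats too close to the record edge raise EdgeBeat", {
  vcg <- simulate_vcg(n_beats = 4, fs = 500, seed = 1)
  rec <- project_leads(vcg, lead_field("supine"))
  expect_error(delineate(rec, 25), class = "pronecg_edgebeat")
  expect_error(delineate(rec, nrow(rec$signals) - 10),
               class = "pronecg_edgebeat")
})

test_that("segment windows tile the beat exactly", {
  fid <- beat_fiducials(100, 200, 230, 260, 460)
  w <- segment_windows(fid)
  expect_equal(w$start, c(100, 200, 260))
  expect_equal(w$end, c(200, 260, 460))
  # no gaps, no overlaps: ends chain into starts
  expect_equal(w$end[-3], w$start[-1])
  expect_error(beat_fiducials(100, 90, 230, 260, 460),
               class = "pronecg_formaterror")
})

test_that("amplitudes are baseline-referenced and match construction", {
  # a flat P-R window gives a zero baseline, so the construction amplitudes
  # are read back directly
  hb <- handmade_beat(p_amp = 0)
  amp <- measure_amplitudes(hb$rec, "V2", hb$fid)
  expect_equal(amp$r, 1.0, tolerance = 0.02)
  expect_equal(amp$s, -0.3, tolerance = 0.02)
  expect_equal(amp$t_pos, 0.2, tolerance = 0.02)
  expect_equal(amp$t_neg, -0.1, tolerance = 0.02)
  expect_gte(amp$p_pos, 0); expect_lte(amp$p_neg, 0)
  expect_gte(amp$r, 0); expect_lte(amp$q, 0); expect_lte(amp$s, 0)
  # with a P wave present, the bidirectional P extremum is reported
  # (relative to the P-R mean, which includes the P wave itself)
  hb2 <- handmade_beat(p_amp = 0.1)
  amp2 <- measure_amplitudes(hb2$rec, "V2", hb2$fid)
  expect_gt(amp2$p_pos, 0.05)
})

test_that("amplitude measurement is DC-invariant and scale-equivariant", {
  hb <- handmade_beat()
  shifted <- handmade_beat(dc = 0.5)
  a0 <- measure_amplitudes(hb$rec, "V5", hb$fid)
  a1 <- measure_amplitudes(shifted$rec, "V5", shifted$fid)
  for (f in c("p_pos", "p_neg", "q", "r", "s", "st_level", "t_pos", "t_neg"))
    expect_equal(a1[[f]], a0[[f]], tolerance = 1e-9)
  doubled <- handmade_beat(scale = 2)
  a2 <- measure_amplitudes(doubled$rec, "V5", doubled$fid)
  for (f in c("p_pos", "q", "r", "s", "st_level", "t_pos", "t_neg"))
    expect_equal(a2[[f]], 2 * a0[[f]], tolerance = 1e-9)
})

test_that("delineation exports a per-beat, per-lead table", {
  coh <- small_cohort(n_subjects = 2, total_beats = 14, seed = 21)
  rec <- coh[[1]]$supine
  beats <- delineate_record(rec)
  tab <- export_delineation(rec, beats)
  expect_equal(nrow(tab), length(beats) * 12)
  expect_true(all(c("qrs_onset", "r", "st_level") %in% names(tab)))
})
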