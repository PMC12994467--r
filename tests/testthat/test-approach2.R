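test_that("the VCG regression recovers a known 16x3 map exactly", {
  withr::local_seed(42)
  n <- 400
  X <- matrix(rnorm(n * 16), n, 16,
              dimnames = list(NULL, pronecg:::vcg_predictor_schema()))
  B <- matrix(rnorm(48), 16, 3)
  icpt <- c(0.1, -0.2, 0.3)
  Y <- sweep(X %*% B, 2, icpt, `+`)
  model <- fit_vcg_model(X, Y)
  expect_lt(max(abs(model$B - B)), 1e-6)
  expect_lt(max(abs(model$intercept - icpt)), 1e-6)
  expect_equal(unname(model$r2), rep(1, 3), tolerance = 1e-9)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  withr::local_seed(8)
  n <- 300
  X <- matrix(rnorm(n * 16), n, 16)
  X[, 2] <- X[, 1]  # duplicated predictor
  colnames(X) <- pronecg:::vcg_predictor_schema()
  Y <- cbind(X[, 1], X[, 3], X[, 4])
  expect_warning(model <- fit_vcg_model(X, Y), "RankDeficient")
  # fit is still exact even though coefficients are not unique
  expect_equal(unname(model$r2), rep(1, 3), tolerance = 1e-9)
})

test_that("too few pooled samples raise InsufficientData", {
  X <- matrix(rnorm(10 * 16), 10, 16)
  expect_error(fit_vcg_model(X, matrix(rnorm(30), 10, 3)),
               class = "pronecg_insufficientdata")
})

test_that("the packaged cohort coefficient fixture matches its source", {
  m <- table2_model()
  expect_true(m$scale_unknown)
  expect_equal(m$B["prone_II", "X"], 1.123)
  expect_equal(m$B["prone_V3", "Z"], 2.185)
  expect_equal(m$B["age", "Y"], 0.333)
  expect_equal(unname(m$r2), c(0.968, 0.968, 0.845))
  expect_identical(rownames(m$B)[1:3], c("prone_I", "prone_II", "prone_III"))
})

test_that("applying the regression is a per-sample linear map", {
  s <- small_cohort(n_subjects = 4, total_beats = 32, noise_sd = 0,
                    seed = 9)[[1]]
  B <- matrix(0, 16, 3, dimnames = list(pronecg:::vcg_predictor_schema(),
                                        c("X", "Y", "Z")))
  B["prone_I", "X"] <- 1
  model <- structure(list(B = B, intercept = c(X = 0, Y = 0, Z = 0),
                          r2 = c(X = 1, Y = 1, Z = 1),
                          schema = rownames(B), scale_unknown = FALSE, n = 10),
                     class = "vcg_regression_model")
  out <- apply_prone_to_vcg(model, s$prone, s$covariates)
  expect_equal(out$xyz[, "X"], unname(s$prone$signals[, "I"]))
  # doubling the prone signals doubles the projection (covariate terms zero)
  doubled <- s$prone
  doubled$signals <- doubled$signals * 2
  out2 <- apply_prone_to_vcg(model, doubled, s$covariates)
  expect_equal(out2$xyz, 2 * out$xyz, tolerance = 1e-12)
})

test_that("fit-then-apply reproduces the generator VCG on noise-free data", {
  coh <- small_cohort(n_subjects = 10, total_beats = 85, noise_sd = 0, seed = 5)
  model <- suppressWarnings(fit_prone_to_vcg(coh))
  s <- coh[[6]]
  pred <- apply_prone_to_vcg(model, s$prone, s$covariates)
  for (k in 1:3) {
    expect_gte(regression_metrics(s$vcg$xyz[, k], pred$xyz[, k])$r2, 0.99)
  }
})

test_that("VCG-to-ECG projection is linear with exact limb identities", {
  dower <- transform_matrix("dower")
  zero <- vcg_record(matrix(0, 100, 3), 500)
  expect_equal(max(abs(vcg_to_ecg(zero, dower)$signals)), 0)

  # unit impulse on X reads out the matrix X-column
  imp <- matrix(0, 100, 3); imp[50, 1] <- 1
  out <- vcg_to_ecg(vcg_record(imp, 500), dower)
  expect_equal(unname(out$signals[50, c("I", "II", precordial_leads())]),
               unname(dower$rows[, "X"]))

  withr::local_seed(3)
  u <- vcg_record(matrix(rnorm(300), ncol = 3), 500)
  v <- vcg_record(matrix(rnorm(300), ncol = 3), 500)
  fu <- vcg_to_ecg(u, dower)$signals
  fv <- vcg_to_ecg(v, dower)$signals
  mix <- vcg_record(2 * u$xyz - 3 * v$xyz, 500)
  expect_equal(vcg_to_ecg(mix, dower)$signals, 2 * fu - 3 * fv,
               tolerance = 1e-12)
  # Einthoven / Goldberger identities hold on every output sample
  s <- vcg_to_ecg(u, transform_matrix("uijen"))$signals
  expect_lt(max(abs(s[, "III"] - (s[, "II"] - s[, "I"]))), 1e-12)
  expect_lt(max(abs(s[, "aVR"] + (s[, "I"] + s[, "II"]) / 2)), 1e-12)
  expect_lt(max(abs(s[, "aVL"] - (s[, "I"] - s[, "II"] / 2))), 1e-12)
  expect_lt(max(abs(s[, "aVF"] - (s[, "II"] - s[, "I"] / 2))), 1e-12)
})

test_that("the per-lead matrix selection uses Dower for V3, Uijen elsewhere", {
  coh <- small_cohort(n_subjects = 10, total_beats = 85, noise_sd = 0, seed = 5)
  model <- suppressWarnings(fit_prone_to_vcg(coh))
  s <- coh[[2]]
  conv <- convert_approach2(model, s$prone, s$covariates)
  vcg <- apply_prone_to_vcg(model, s$prone, s$covariates)
  d <- vcg_to_ecg(vcg, transform_matrix("dower"))$signals
  u <- vcg_to_ecg(vcg, transform_matrix("uijen"))$signals
  expect_equal(conv$signals[, "V3"], d[, "V3"])
  expect_equal(conv$signals[, "V4"], u[, "V4"])
  # all-Dower override changes exactly the leads where the matrices differ
  all_d <- convert_approach2(model, s$prone, s$covariates,
                             matrix_rule = "dower")
  expect_equal(all_d$signals[, "V3"], conv$signals[, "V3"])
  expect_gt(max(abs(all_d$signals[, "V4"] - conv$signals[, "V4"])), 1e-6)
})

test_that("the full VCG route reconstructs the supine 12-lead", {
  coh <- small_cohort(n_subjects = 10, total_beats = 85, noise_sd = 0, seed = 5)
  model <- suppressWarnings(fit_prone_to_vcg(coh))
  s <- coh[[8]]
  conv <- convert_approach2(model, s$prone, s$covariates)
  for (lead in ecg_leads()) {
    expect_gte(regression_metrics(s$supine$signals[, lead],
                                  conv$signals[, lead])$r2, 0.99)
  }
})
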