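fid_demo <- list(qrs_onset = 40, r_peak = 60, j_point = 100, t_end = 400)

test_that("registry enumerations are exact and ordered", {
  reg <- feature_registry()
  expect_equal(sum(reg$family == "MorphD"), 71)
  expect_equal(sum(reg$family == "MorphR"), 44)
  expect_equal(sum(reg$family == "SpectralD"), 24)
  expect_equal(sum(reg$family == "SpectralR"), 72)
  expect_false(any(duplicated(reg$name)))
  b <- generate_beat("ISM", default_config(), seed = 1)
  expect_identical(names(extract_morphD(b)),
                   feature_registry("MorphD")$name)
  expect_identical(names(extract_morphR(b)),
                   feature_registry("MorphR")$name)
})

test_that("area_under implements the trapezoid with exact decomposition", {
  fs <- 2000
  # constant 1 mV over 100 ms -> 0.1 mV.s (trapezoid over 201 samples)
  x <- rep(1, 201)
  expect_equal(area_under(x, fs, "signed"), 0.1, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(100)
    s <- area_under(v, fs, "signed"); p <- area_under(v, fs, "positive")
    n <- area_under(v, fs, "negative"); a <- area_under(v, fs, "absolute")
    expect_equal(s, p + n, tolerance = 1e-12)
    expect_equal(a, p - n, tolerance = 1e-12)
  }
})

test_that("AUC features agree with the oversampled Riemann oracle", {
  set.seed(8)
  fs <- 2000
  for (i in 1:10) {
    b <- generate_beat(sample(beat_classes(), 1), default_config(),
                       seed = 300 + i)
    v <- b$waveform[1, 101:220]
    o <- oracle_area_oversampled(v, fs)
    expect_lt(abs(area_under(v, fs, "signed") - o),
              0.01 * max(abs(o), 1e-6))
  }
})

test_that("loop features return the maximal vector and its angle", {
  expect_equal(loop_features(c(0, 1, 0), c(0, 0, 0)),
               c(length = 1, angle = 0))
  expect_equal(loop_features(c(0, 0), c(0, 2)),
               c(length = 2, angle = 90))
  expect_equal(loop_features(c(0, 0), c(0, 0)),
               c(length = 0, angle = 0))
  # noiseless NOR: QRS-loop angle equals the configured lead-amplitude ratio
  b <- generate_beat("NOR", config_clean(), seed = 4)
  v <- extract_morphD(b)
  expect_lt(abs(v[["QRSloop_ang"]] - atan2(1.2, 1.0) * 180 / pi), 1e-6)
})

test_that("zero waveforms give zero features with finite ratios", {
  z <- matrix(0, 2, 560)
  v <- extract_morphD(z, fiducials = fid_demo, fs = 2000)
  expect_length(v, 71)
  expect_true(all(is.finite(v)))
  regD <- feature_registry("MorphD")
  expect_true(all(v[regD$name[regD$units %in% c("mV", "mV.s")]] == 0))
  expect_true(all(v[grep("^(rel|ratio)AUC", names(v))] == 0))  # 0/0 -> 0
  vr <- extract_morphR(z, r_index = 60, fs = 2000)
  expect_length(vr, 44)
  regR <- feature_registry("MorphR")
  expect_true(all(vr[regR$name[regR$units %in% c("mV", "mV.s")]] == 0))
  expect_equal(unname(vr["Rmaxmin_dt_I"]), 0)
})

test_that("morphD recovers intervals and closed-form areas", {
  b <- generate_beat("NOR", default_config(noise_sd = 0), seed = 21)
  v <- extract_morphD(b)
  expect_lt(abs(v[["QRS_D"]] - b$params$qrs_ms), 0.5 + 1e-9)
  expect_equal(unname(v["QT"]),
               (b$fiducials$t_end - b$fiducials$qrs_onset) / b$fs * 1000)
  # rectangular pulse of height h, width w inside QRS: +AUC ~ h*w
  z <- matrix(0, 2, 560)
  z[, 61:100] <- 1.5                     # 40 samples tall 1.5 mV
  v2 <- extract_morphD(z, fiducials = fid_demo, fs = 2000)
  expect_lt(abs(v2[["AUC_qrs_pos_I"]] - 1.5 * 40 / 2000),
            1.5 / 2000)                  # within one-sample discretization
})

test_that("morphR is translation-invariant and matches triangle area", {
  fs <- 2000
  tri <- c(seq(0, 1, length.out = 41), seq(1, 0, length.out = 41)[-1])
  dip <- -0.3 * c(seq(0, 1, length.out = 8), seq(1, 0, length.out = 15)[-1])
  z <- matrix(0, 2, 560)
  z[, 211:291] <- rep(tri, each = 1)     # unit triangle, half-width 20 ms
  z[, 361:382] <- rep(dip, each = 1)     # unique minimum away from R
  z2 <- matrix(0, 2, 560)
  z2[, 218:298] <- rep(tri, each = 1)
  z2[, 368:389] <- rep(dip, each = 1)
  v1 <- extract_morphR(z, r_index = 250, fs = fs)
  v2 <- extract_morphR(z2, r_index = 257, fs = fs)
  expect_equal(unname(v1), unname(v2), tolerance = 1e-12)
  # AUC over t = 40 ms window covers the triangle: area = base*height/2
  expect_equal(unname(v1["AUC_t40_I"]), 80 / fs * 1 / 2, tolerance = 1e-9)
})

test_that("amplitude equivariance splits features correctly", {
  b <- generate_beat("ISE", default_config(noise_sd = 0), seed = 77)
  c0 <- 3.7
  bs <- b; bs$waveform <- b$waveform * c0
  for (fam in c("MorphD", "MorphR")) {
    v1 <- if (fam == "MorphD") extract_morphD(b) else extract_morphR(b)
    v2 <- if (fam == "MorphD") extract_morphD(bs) else extract_morphR(bs)
    reg <- feature_registry(fam)
    scaled <- reg$units %in% c("mV", "mV.s")
    unchanged <- reg$units %in% c("ms", "deg", "ratio")
    expect_equal(unname(v2[reg$name[scaled]]),
                 unname(c0 * v1[reg$name[scaled]]), tolerance = 1e-9)
    expect_equal(unname(v2[reg$name[unchanged]]),
                 unname(v1[reg$name[unchanged]]), tolerance = 1e-9)
  }
})

test_that("ST20 recovers the configured ST level with unit slope", {
  lv <- seq(0.05, 0.45, length.out = 25)
  meas <- vapply(seq_along(lv), function(i) {
    cfg <- config_clean()
    cfg$classes$ISE$st_level <- c(lv[i], 1.2 * lv[i])
    b <- generate_beat("ISE", cfg, seed = 500 + i)
    unname(extract_morphD(b)["ST20_I"])
  }, 0)
  fit <- stats::lm(meas ~ lv)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
})

test_that("invalid fiducials are rejected", {
  z <- matrix(0, 2, 560)
  bad <- list(qrs_onset = 100, r_peak = 60, j_point = 120, t_end = 400)
  expect_error(extract_morphD(z, fiducials = bad, fs = 2000), "order")
  far <- list(qrs_onset = 40, r_peak = 60, j_point = 100, t_end = 900)
  expect_error(extract_morphD(z, fiducials = far, fs = 2000), "window")
})
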