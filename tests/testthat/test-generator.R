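test_that("default configuration carries the study parameters", {
  cfg <- default_config()
  expect_equal(cfg$fs, 2000)
  expect_equal(cfg$classes$NOR$rr_mean_ms, 344)
  expect_equal(cfg$classes$NOR$rr_sd_ms, 46)
  expect_equal(cfg$classes$NOR$qrs_ms_mean, 24)
  expect_equal(cfg$classes$NOR$qrs_ms_sd, 4)
  expect_equal(cfg$classes$NOR$qt_ms_mean, 175)
  expect_equal(cfg$classes$NOR$qt_ms_sd, 22)
  expect_lt(cfg$baseline_freq, 0.5)
  # VPB wide by design: at least 2.5x the NOR QRS width
  expect_gte(cfg$classes$VPB$qrs_min_ms, 2.5 * cfg$classes$NOR$qrs_ms_mean)
})

test_that("degenerate configurations are rejected", {
  cfg <- default_config()
  cfg$classes$ISM$qrs_ms_mean <- 500      # QRS >= QT
  expect_error(validate_config(cfg), "degenerate")
  cfg2 <- default_config()
  cfg2$classes$NOR$rr_mean_ms <- 100      # RR <= QT
  expect_error(validate_config(cfg2), "degenerate")
})

test_that("beat windows have the specified geometry", {
  for (cls in beat_classes()) {
    b <- generate_beat(cls, default_config(), seed = 17)
    expect_equal(ncol(b$waveform), 560)          # 0.280 s at 2 kHz
    expect_equal(b$fiducials$r_peak, 60)         # 30 ms before R
    expect_equal(nrow(b$waveform), 2)
  }
  b <- generate_beat("NOR", default_config(fs = 1000), seed = 17)
  expect_equal(ncol(b$waveform), 280)
  expect_equal(b$fiducials$r_peak, 30)
})

test_that("fiducial ordering holds for every class over many draws", {
  cfg <- default_config()
  for (cls in beat_classes()) {
    for (i in 1:600) {
      f <- generate_beat(cls, cfg, seed = i)$fiducials
      expect_true(f$qrs_onset < f$r_peak && f$r_peak < f$j_point &&
                  f$j_point < f$t_end)
      expect_gte(f$qrs_onset, 0)
      expect_lt(f$t_end, 560)
    }
  }
})

test_that("ground-truth QRS duration equals the drawn parameter to one sample", {
  cfg <- default_config(noise_sd = 0)
  for (cls in beat_classes()) {
    for (i in 1:50) {
      b <- generate_beat(cls, cfg, seed = 100 + i)
      meas <- (b$fiducials$j_point - b$fiducials$qrs_onset) / b$fs * 1000
      expect_lt(abs(meas - b$params$qrs_ms), 1000 / b$fs + 1e-9)
    }
  }
})

test_that("noiseless ST20 reproduces the ST level exactly", {
  # NOR: no ST shift by construction
  b <- generate_beat("NOR", config_clean(), seed = 0)
  st20_i <- b$fiducials$j_point + round(0.020 * b$fs) + 1
  expect_equal(unname(b$waveform[, st20_i]), c(0, 0), tolerance = 1e-12)
  # ISE: measured deviation at J+20 ms equals the drawn per-lead level
  cfg <- default_config(noise_sd = 0)
  for (s in 1:10) {
    b <- generate_beat("ISE", cfg, seed = s)
    st20_i <- b$fiducials$j_point + round(0.020 * b$fs) + 1
    iso <- apply(b$waveform[, 1:20], 1, median)
    expect_equal(unname(b$waveform[, st20_i] - iso),
                 unname(b$params$st_level), tolerance = 1e-9)
  }
  # with all jitter disabled the drawn level is the configured one
  b <- generate_beat("ISE", config_clean(), seed = 1)
  st20_i <- b$fiducials$j_point + round(0.020 * b$fs) + 1
  expect_equal(unname(b$waveform[, st20_i]),
               default_config()$classes$ISE$st_level, tolerance = 1e-12)
})

test_that("VPB complexes are wide and premature", {
  cfg <- default_config()
  nor_mean <- cfg$classes$NOR$qrs_ms_mean
  for (s in 0:30) {
    b <- generate_beat("VPB", cfg, seed = s)
    expect_gte(b$params$qrs_ms, 2.5 * nor_mean)
    expect_equal(b$rr_prev_ms, 0.7 * b$params$rr_ms, tolerance = 1e-12)
  }
})

test_that("increasing the ISE ST level strictly increases noiseless ST20", {
  lv <- c(0.1, 0.2, 0.3, 0.45)
  meas <- vapply(lv, function(l) {
    cfg <- config_clean()
    cfg$classes$ISE$st_level <- c(l, 1.2 * l)
    b <- generate_beat("ISE", cfg, seed = 7)
    st20_i <- b$fiducials$j_point + round(0.020 * b$fs) + 1
    b$waveform[1, st20_i]
  }, 0)
  expect_true(all(diff(meas) > 0))
})

test_that("dataset generation honours counts, shuffling and determinism", {
  cfg <- default_config()
  ds <- generate_dataset(c(NOR = 20, ISM = 15, ISE = 10, VPB = 5), cfg,
                         seed = 3)
  expect_length(ds, 50)
  labs <- vapply(ds, function(b) b$label, "")
  expect_equal(unname(table(factor(labs, beat_classes()))[beat_classes()]),
               c(20L, 15L, 10L, 5L), ignore_attr = TRUE)
  # deterministically shuffled, not grouped by class
  expect_false(identical(labs, sort(labs)))
  ds2 <- generate_dataset(c(NOR = 20, ISM = 15, ISE = 10, VPB = 5), cfg,
                          seed = 3)
  expect_identical(lapply(ds, `[[`, "waveform"),
                   lapply(ds2, `[[`, "waveform"))
  expect_length(generate_dataset(c(NOR = 0), cfg, seed = 1), 0)
})

test_that("per-beat substreams are independent of other classes' counts", {
  cfg <- default_config()
  a <- generate_dataset(c(NOR = 5, VPB = 9), cfg, seed = 11)
  b <- generate_dataset(c(NOR = 5, VPB = 2), cfg, seed = 11)
  wav_nor <- function(ds) lapply(ds[vapply(ds, `[[`, "", "label") == "NOR"],
                                 `[[`, "waveform")
  norm_order <- function(ws) ws[order(vapply(ws, function(w) w[1, 100], 0))]
  expect_identical(norm_order(wav_nor(a)), norm_order(wav_nor(b)))
})

test_that("optional 16-bit quantization snaps samples to the step grid", {
  cfg <- default_config(quantize = TRUE)
  b <- generate_beat("NOR", cfg, seed = 2)
  steps <- b$waveform / cfg$quant_step
  expect_equal(steps, round(steps), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(
    b$waveform, generate_beat("NOR", default_config(), seed = 2)$waveform,
    tolerance = 1e-12)))
})

test_that("NOR calibration matches the stabilization statistics", {
  beats <- generate_dataset(c(NOR = 1000), default_config(noise_sd = 0),
                            seed = 42)
  rr <- vapply(beats, `[[`, 0, "rr_prev_ms")
  qrs <- vapply(beats, function(b)
    (b$fiducials$j_point - b$fiducials$qrs_onset) / b$fs * 1000, 0)
  qt <- vapply(beats, function(b)
    (b$fiducials$t_end - b$fiducials$qrs_onset) / b$fs * 1000, 0)
  n <- length(beats)
  for (chk in list(list(rr, 344, 46), list(qrs, 24, 4), list(qt, 175, 22))) {
    x <- chk[[1]]; mu <- chk[[2]]; sd0 <- chk[[3]]
    expect_lt(abs(mean(x) - mu), 3 * sd0 / sqrt(n))
    expect_lt(abs(sd(x) - sd0), 3 * sd0 / sqrt(2 * n))
  }
})

test_that("records carry correct annotations, RR structure and wander", {
  cfg <- default_config(noise_sd = 0, baseline_amp = 0)
  rec <- generate_record(rep("NOR", 40), cfg, seed = 5)
  expect_equal(nrow(rec$annotations), 40)
  expect_true(all(diff(rec$annotations$r_peak) >= 0.150 * rec$fs))
  # a VPB interrupts earlier than the sinus RR that preceded it
  rec2 <- generate_record(c("NOR", "NOR", "VPB", "NOR"), cfg, seed = 8)
  gaps <- diff(rec2$annotations$r_peak) / rec2$fs * 1000
  expect_lt(abs(gaps[2] - rec2$annotations$rr_prev_ms[3]), 1)
  expect_lt(gaps[2], cfg$classes$NOR$rr_mean_ms)
  # baseline wander amplitude recovered from the generated record
  cfgw <- default_config(noise_sd = 0, baseline_amp = 0.5,
                         baseline_freq = 0.2)
  rec3 <- generate_record(rep("NOR", 30), cfgw, seed = 5)
  t <- (0:(ncol(rec3$signal) - 1)) / rec3$fs
  X <- cbind(sin(2 * pi * 0.2 * t), cos(2 * pi * 0.2 * t))
  cf <- stats::lm.fit(X, rec3$signal[1, ])$coefficients
  expect_equal(sqrt(sum(cf^2)), 0.5, tolerance = 0.1)
})
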