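test_that("generate_rgb_trace obeys the stated sample-count and constancy contracts", {
  gen <- generate_rgb_trace(scene_config(fs = 30, duration_s = 10))
  expect_s3_class(gen$trace, "rgb_trace")
  expect_identical(gen$trace$n, 300L)

  flat <- generate_rgb_trace(scene_config(fs = 30, duration_s = 2,
                                          ac_rgb = c(0, 0, 0),
                                          noise_sd = 0, drift_amp = 0))
  expect_true(all(flat$trace$R == 150))
  expect_true(all(flat$trace$G == 110))
  expect_true(all(flat$trace$B == 90))
})

test_that("invalid scene configurations are rejected by name", {
  expect_error(scene_config(fs = 2, hr_hz = 1.3), class = "mv_config_error")
  expect_error(scene_config(duration_s = 0), class = "mv_config_error")
  expect_error(scene_config(noise_sd = -1), class = "mv_config_error")
  expect_error(scene_config(base_rgb = c(0, 110, 90)), class = "mv_config_error")
  expect_error(scene_config(ac_rgb = c(-1, 0, 0)), class = "mv_config_error")
  expect_error(scene_config(frame_shape = c(0, 8)), class = "mv_config_error")
})

test_that("identical configs (incl. seed) are bitwise reproducible; seeds differ", {
  cfg <- scene_config(duration_s = 3, seed = 11)
  a <- generate_rgb_trace(cfg); b <- generate_rgb_trace(cfg)
  expect_identical(a$trace$R, b$trace$R)
  expect_identical(a$trace$B, b$trace$B)
  c2 <- generate_rgb_trace(scene_config(duration_s = 3, seed = 12))
  expect_false(identical(a$trace$R, c2$trace$R))

  fa <- generate_frame_sequence(scene_config(duration_s = 0.5, seed = 5))
  fb <- generate_frame_sequence(scene_config(duration_s = 0.5, seed = 5))
  expect_identical(fa$frames, fb$frames)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_rgb_trace(scene_config(duration_s = 1)))
  expect_identical(rnorm(3), before)
})

test_that("spectral ground truth: in-band DFT maximum of a noiseless trace is at hr_hz", {
  for (hr in c(0.9, 1.3, 2.5)) {
    cfg <- scene_config(duration_s = 20, hr_hz = hr, noise_sd = 0, drift_amp = 0)
    tr <- generate_rgb_trace(cfg)$trace
    g <- tr$G - mean(tr$G)
    n <- length(g)
    amp <- Mod(stats::fft(g))[1:(n %/% 2)]
    freq <- (0:(n %/% 2 - 1)) * tr$fs / n
    inb <- freq >= 0.6 & freq <= 4
    fpeak <- freq[inb][which.max(amp[inb])]
    expect_lt(abs(fpeak - hr), tr$fs / n + 1e-12)   # within one bin
  }
})

test_that("SpO2 encoding consistency: analytic expectation matches the pipeline", {
  for (target in c(92, 96, 99)) {
    cfg <- scene_config_for_spo2(target, duration_s = 10,
                                 noise_sd = 0, drift_amp = 0)
    gen <- generate_rgb_trace(cfg)
    expect_equal(gen$ground_truth$spo2_expected, target, tolerance = 1e-9)
    est <- estimate_spo2(spo2_components(gen$trace))
    expect_lt(abs(est$spo2_pct - gen$ground_truth$spo2_expected), 0.5)
  }
})

test_that("ground truth fields are analytic functions of the config", {
  cfg <- scene_config(hr_hz = 1.1)
  gt <- generate_rgb_trace(cfg)$ground_truth
  expect_equal(gt$hr_bpm, 66)
  expect_equal(gt$ratio_of_ratios,
               (cfg$ac_rgb[1] / cfg$base_rgb[1]) / (cfg$ac_rgb[3] / cfg$base_rgb[3]))
  expect_gt(gt$ratio_of_ratios, 0)
})

test_that("frame sequences reproduce the trace model spatially", {
  cfg <- scene_config(duration_s = 1, noise_sd = 0, frame_shape = c(8, 8))
  sc <- generate_frame_sequence(cfg)
  t <- (0:(length(sc$frames) - 1)) / cfg$fs
  want_R <- cfg$base_rgb[1] + cfg$ac_rgb[1] * sin(2 * pi * cfg$hr_hz * t) +
    cfg$drift_amp * sin(2 * pi * cfg$drift_hz * t)
  got <- sapply(seq_along(sc$frames), function(k)
    spatial_average_frame(sc$frames[[k]], sc$rois[[k]])[["R"]])
  expect_equal(got, want_R, tolerance = 1e-12)
  expect_equal(sc$rois[[1]]$confidence, 1.0)
})

test_that("full frame pipeline recovers the configured heart rate", {
  cfg <- scene_config(duration_s = 10, hr_hz = 1.0, noise_sd = 0.1,
                      drift_amp = 0, frame_shape = c(8, 8))
  sc <- generate_frame_sequence(cfg)
  trace <- build_rgb_trace(sc$frames, sc$rois, fs = sc$fs)
  v <- estimate_vitals(trace)
  expect_lt(abs(v$hr_bpm - 60), 1)
})

test_that("reference series: constant at ground truth without jitter, grid-aligned", {
  cfg <- scene_config(duration_s = 40)
  ref <- generate_reference_series(cfg, jitter_sd = 0)
  expect_true(all(ref$bpm == 78))
  expect_equal(ref$time_s, seq(26, 40, by = 1))
  expect_error(generate_reference_series(cfg, jitter_sd = -1),
               class = "mv_config_error")
  refj <- generate_reference_series(cfg, jitter_sd = 2)
  expect_false(all(refj$bpm == 78))
  expect_identical(refj, generate_reference_series(cfg, jitter_sd = 2))
})
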