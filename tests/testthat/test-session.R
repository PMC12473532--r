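feed_trace <- function(session, trace, conf = NULL) {
  tt <- trace_times(trace)
  for (i in seq_len(trace$n)) {
    ci <- if (is.null(conf)) (if (trace$valid[i]) 1 else 0) else conf[i]
    push_frame(session, tt[i], trace$R[i], trace$G[i], trace$B[i], face = ci)
  }
  session
}

test_that("no estimate is emitted during the 26 s stabilization phase", {
  tr <- generate_rgb_trace(scene_config(duration_s = 26))$trace
  s <- feed_trace(rppg_session(), tr)
  expect_length(s$estimates, 0)
  expect_identical(s$phase, "stabilizing")
})

test_that("a clean 30 s stream yields >= 3 estimates at 78 +/- 1 bpm", {
  tr <- generate_rgb_trace(scene_config(duration_s = 30, noise_sd = 0,
                                        drift_amp = 0))$trace
  s <- feed_trace(rppg_session(), tr)
  df <- estimates_df(s$estimates)
  expect_gte(nrow(df), 3)
  expect_true(all(abs(df$hr_bpm - 78) <= 1))
  expect_identical(s$phase, "estimating")
})

test_that("low-confidence frames are masked invalid; timestamps must be sane", {
  s <- rppg_session()
  push_frame(s, 0.0, 100, 100, 100, face = 0.65)
  expect_false(s$valid[1])
  push_frame(s, 1 / 30, 100, 100, 100, face = face_observation(0, 0, 4, 4, 0.9))
  expect_true(s$valid[2])
  expect_error(push_frame(s, 1 / 30, 1, 1, 1), class = "mv_stream_error")

  # > 5% frame-interval jitter is a stream error, not silent resampling
  s2 <- rppg_session()
  jitter <- cumsum(c(0, rep(1 / 30, 20), 0.3, rep(1 / 30, 10)))
  expect_error(for (t in jitter) push_frame(s2, t, 1, 1, 1),
               class = "mv_stream_error")
})

test_that("streaming and batch runs produce identical estimate sequences", {
  tr <- generate_rgb_trace(scene_config(duration_s = 60, seed = 3))$trace
  s <- feed_trace(rppg_session(), tr)
  batch <- run_batch(tr)
  expect_identical(length(batch), length(s$estimates))
  for (i in seq_along(batch)) {
    expect_equal(batch[[i]]$hr_bpm, s$estimates[[i]]$hr_bpm, tolerance = 1e-12)
    expect_equal(batch[[i]]$snr, s$estimates[[i]]$snr, tolerance = 1e-12)
    expect_equal(batch[[i]]$spo2_pct, s$estimates[[i]]$spo2_pct, tolerance = 1e-12)
    expect_identical(batch[[i]]$valid, s$estimates[[i]]$valid)
  }
})

test_that("run_batch on a too-short trace warns and returns empty", {
  tr <- generate_rgb_trace(scene_config(duration_s = 10))$trace
  expect_warning(est <- run_batch(tr), "shorter than stabilization")
  expect_length(est, 0)
})

test_that("valid-second accrual respects the elapsed-time bound", {
  tr <- generate_rgb_trace(scene_config(duration_s = 40, noise_sd = 0,
                                        drift_amp = 0))$trace
  s <- rppg_session()
  tt <- trace_times(tr)
  for (i in seq_len(tr$n)) {
    push_frame(s, tt[i], tr$R[i], tr$G[i], tr$B[i], face = 1)
    elapsed <- i / tr$fs
    expect_lte(s$valid_seconds, max(0, elapsed - s$cfg$stabilization_s) + 1e-9)
  }
  expect_gt(s$valid_seconds, 0)
})

test_that("an invalid gap suspends validity, which resumes after the gap", {
  tr <- generate_rgb_trace(scene_config(duration_s = 60, noise_sd = 0,
                                        drift_amp = 0))$trace
  tt <- trace_times(tr)
  tr$valid[tt >= 35 & tt < 40] <- FALSE
  est <- run_batch(tr)
  df <- estimates_df(est)
  in_gap <- df$t_end > 35 & df$t_start < 40
  expect_true(all(!df$valid[in_gap]))
  expect_true(all(grepl("invalid_frames", df$reasons[in_gap])))
  expect_true(any(df$valid[df$t_start >= 44]))   # resumes after the gap
  clean <- run_batch(generate_rgb_trace(scene_config(duration_s = 60,
                                                     noise_sd = 0,
                                                     drift_amp = 0))$trace)
  gap_valid <- sum(vapply(est, function(e) e$counted, TRUE))
  clean_valid <- sum(vapply(clean, function(e) e$counted, TRUE))
  expect_lt(gap_valid, clean_valid)              # gap seconds are excluded
})

test_that("chatbot trigger logic follows the stated thresholds", {
  tr <- generate_rgb_trace(scene_config(duration_s = 60, noise_sd = 0,
                                        drift_amp = 0))$trace
  tt <- trace_times(tr)
  s <- rppg_session()
  expect_match(paste(gate_chatbot_trigger(s)$reasons, collapse = " "),
               "not_estimating")

  # feed until just short of 8 valid seconds: trigger must refuse
  for (i in which(tt < 33)) push_frame(s, tt[i], tr$R[i], tr$G[i], tr$B[i], 1)
  push_affect(s, 30, "happy", 0.8, "20s", 0.9)
  expect_lt(s$valid_seconds, 8)
  g <- gate_chatbot_trigger(s)
  expect_false(g$triggered)
  expect_true("insufficient_valid_seconds" %in% g$reasons)

  for (i in which(tt >= 33)) push_frame(s, tt[i], tr$R[i], tr$G[i], tr$B[i], 1)
  expect_gte(s$valid_seconds, 8)
  g2 <- gate_chatbot_trigger(s)
  expect_true(g2$triggered)
  expect_identical(s$phase, "triggered")

  # monotone: more valid input never flips the decision back
  s2 <- rppg_session()
  # (reuse the same stream shifted in time)
  for (i in seq_len(tr$n)) push_frame(s2, tt[i], tr$R[i], tr$G[i], tr$B[i], 1)
  push_affect(s2, 50, "neutral", 0.9)
  expect_true(gate_chatbot_trigger(s2)$triggered)
  expect_true(gate_chatbot_trigger(s2)$triggered)
})

test_that("trigger refuses without a confident affect label or with low SNR history", {
  tr <- generate_rgb_trace(scene_config(duration_s = 60, noise_sd = 0,
                                        drift_amp = 0))$trace
  s <- feed_trace(rppg_session(), tr)
  push_affect(s, 30, "happy", 0.4)             # below the 50% affect gate
  g <- gate_chatbot_trigger(s)
  expect_false(g$triggered)
  expect_identical(g$reasons, "no_confident_affect")

  # pure-noise scene: snr stays under the gate, so valid seconds never accrue
  noise <- generate_rgb_trace(scene_config(duration_s = 45, ac_rgb = c(0, 0, 0),
                                           noise_sd = 2, drift_amp = 0))$trace
  s2 <- feed_trace(rppg_session(), noise)
  push_affect(s2, 40, "neutral", 0.9)
  expect_equal(s2$valid_seconds, 0)
  g2 <- gate_chatbot_trigger(s2)
  expect_false(g2$triggered)
  expect_true("insufficient_valid_seconds" %in% g2$reasons)
})

test_that("session phases advance monotonically and stop is terminal", {
  s <- rppg_session()
  expect_identical(s$phase, "stabilizing")
  stop_session(s)
  expect_identical(s$phase, "stopped")
  expect_error(push_frame(s, 0, 1, 1, 1), class = "mv_stream_error")
})

test_that("session age vote pools the last 30 observations", {
  s <- rppg_session()
  for (i in 1:17) push_affect(s, i, "happy", 0.9, "20s", 0.8)
  expect_identical(session_age_vote(s)$status, "pending")
  for (i in 18:30) push_affect(s, i, "happy", 0.9, "30s", 0.8)
  v <- session_age_vote(s)
  expect_identical(v$status, "ok")
  expect_identical(v$label, "20s")
  expect_equal(v$confidence_fraction, 17 / 30)
})
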