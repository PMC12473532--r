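make_frame <- function(h, w, vals = NULL) {
  if (is.null(vals)) vals <- seq_len(h * w * 3)
  array(vals, dim = c(h, w, 3))
}

test_that("spatial_average_frame is the arithmetic ROI mean", {
  f <- array(0, dim = c(2, 2, 3))
  f[, , 1] <- c(10, 30, 20, 40)   # column-major: rows then cols
  f[, , 2] <- 5; f[, , 3] <- 7
  v <- spatial_average_frame(f, face_observation(0, 0, 2, 2))
  expect_equal(unname(v), c(25, 5, 7))

  uni <- array(rep(c(150, 110, 90), each = 36), dim = c(6, 6, 3))
  v <- spatial_average_frame(uni, face_observation(1, 2, 3, 2))
  expect_equal(unname(v), c(150, 110, 90))
})

test_that("spatial averaging matches a brute-force pixel loop, with box clipping", {
  set.seed(7)
  for (rep in 1:20) {
    f <- make_frame(16, 16, runif(16 * 16 * 3, 0, 255))
    v <- spatial_average_frame(f, face_observation(0, 0, 16, 16))
    expect_equal(unname(v), oracle_spatial_mean(f, 1:16, 1:16), tolerance = 1e-12)
    # partial out-of-frame box is clipped
    v2 <- spatial_average_frame(f, face_observation(10, 12, 10, 10))
    expect_equal(unname(v2), oracle_spatial_mean(f, 13:16, 11:16), tolerance = 1e-12)
  }
  f <- make_frame(4, 4)
  expect_error(spatial_average_frame(f, face_observation(10, 10, 2, 2)),
               class = "mv_signal_quality_error")
})

test_that("build_rgb_trace carries a validity mask and rejects empty input", {
  frames <- replicate(5, make_frame(4, 4, runif(48, 0, 255)), simplify = FALSE)
  rois <- rep(list(face_observation(0, 0, 4, 4)), 5)
  rois[3] <- list(NULL)
  tr <- build_rgb_trace(frames, rois, fs = 30)
  expect_identical(tr$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(tr$R[3]))
  expect_error(build_rgb_trace(frames, rep(list(NULL), 5), fs = 30),
               class = "mv_empty_input_error")
  expect_error(build_rgb_trace(list(), list(), fs = 30),
               class = "mv_empty_input_error")
})

test_that("chrominance transform: worked samples, oracle equivalence, linearity", {
  one <- chrominance_transform(list(R = 1, G = 1, B = 1))
  expect_equal(c(one$xs, one$ys), c(1, 1))
  two <- chrominance_transform(list(R = 2, G = 1, B = 0))
  expect_equal(c(two$xs, two$ys), c(4, 4))

  set.seed(21)
  for (rep in 1:20) {
    R <- runif(50, 0, 255); G <- runif(50, 0, 255); B <- runif(50, 0, 255)
    got <- chrominance_transform(list(R = R, G = G, B = B))
    want <- oracle_chrominance(R, G, B)
    expect_equal(got$xs, want$xs, tolerance = 1e-12)
    expect_equal(got$ys, want$ys, tolerance = 1e-12)
    # linearity
    a <- runif(1, 0.1, 5)
    sc <- chrominance_transform(list(R = a * R, G = a * G, B = a * B))
    expect_equal(sc$xs, a * got$xs, tolerance = 1e-9)
    expect_equal(sc$ys, a * got$ys, tolerance = 1e-9)
  }
})

test_that("bandpass design validates its spec and hits the documented response", {
  expect_error(bandpass_spec(2, 1), class = "mv_config_error")
  expect_error(bandpass_spec(0.6, 4, order = 151), class = "mv_config_error")
  expect_error(design_bandpass(7, bandpass_spec(0.6, 4)), class = "mv_config_error")

  filt <- design_bandpass(30, bandpass_spec())
  expect_equal(filt$order, 150)               # next even >= 3*30/0.6
  expect_equal(sum(filt$coef), 0, tolerance = 1e-14)  # exact DC zero

  t <- (0:599) / 30
  tone <- sin(2 * pi * 1.5 * t)
  y <- apply_bandpass(tone, filt, mode = "batch")
  expect_gt(max(abs(y[150:450])), 0.9)        # >= 90% passband amplitude
  dc <- apply_bandpass(rep(3, 600), filt, mode = "batch")
  expect_lt(max(abs(dc)), 0.03)               # <= 1% of DC level
})

test_that("batch filtering is zero-phase and rejects short series", {
  filt <- design_bandpass(30, bandpass_spec())
  t <- (0:899) / 30
  x <- sin(2 * pi * 1.5 * t)
  y <- apply_bandpass(x, filt, mode = "batch")
  mid <- 200:700
  lags <- -5:5
  cc <- vapply(lags, function(l) sum(x[mid] * y[mid + l]), 0)
  expect_identical(lags[which.max(cc)], 0L)
  expect_error(apply_bandpass(x[1:100], filt, mode = "batch"),
               class = "mv_signal_quality_error")
})

test_that("streaming filtering agrees with batch after group-delay compensation", {
  filt <- design_bandpass(30, bandpass_spec())
  t <- (0:899) / 30
  x <- 5 + sin(2 * pi * 1.5 * t) + 0.5 * sin(2 * pi * 0.9 * t)
  yb <- apply_bandpass(x, filt, mode = "batch")
  ys <- apply_bandpass(x, filt, mode = "streaming")
  d <- attr(ys, "delay_samples")
  expect_equal(d, 75)
  idx <- (filt$order + 2):(length(x) - d)     # after warm-up, before the tail
  diff <- ys[idx + d] - yb[idx]
  expect_lt(sqrt(mean(diff^2)) / sqrt(mean(yb[idx]^2)), 0.02)
})

test_that("pulse_signal: alpha ratio, degenerate rules, cancellation", {
  p <- pulse_signal(c(1, -1, 1, -1), c(2, -2, 2, -2))
  expect_equal(p$alpha, 0.5)
  expect_equal(p$s, rep(0, 4))

  p0 <- pulse_signal(c(1, 2, 3), c(0, 0, 0))
  expect_equal(p0$alpha, 0)
  expect_equal(p0$s, c(1, 2, 3))

  same <- rnorm(10)
  expect_equal(pulse_signal(same, same)$alpha, 1)
  expect_equal(pulse_signal(same, same)$s, rep(0, 10))

  expect_error(pulse_signal(1, 1), class = "mv_signal_quality_error")
  expect_error(pulse_signal(1:3, 1:4), class = "mv_config_error")
})

test_that("alpha-cancellation holds for randomized proportional pairs", {
  set.seed(4)
  for (rep in 1:100) {
    xf <- rnorm(40)
    k <- runif(1, 0.01, 100)
    p <- pulse_signal(xf, k * xf)
    expect_lt(max(abs(p$s)), 1e-9 * max(abs(xf)))
    expect_equal(p$alpha, 1 / k, tolerance = 1e-9)
  }
})
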