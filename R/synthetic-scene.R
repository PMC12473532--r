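# Synthetic facial-ROI scenes with known physiological ground truth, so every
# downstream stage is testable without cameras.

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene configuration
#'
#' Describes a skin-toned facial ROI whose mean R/G/B channels carry a
#' pulsatile component at a known cardiac frequency. Per-channel AC
#' amplitudes over the DC baseline encode a known ratio-of-ratios (hence a
#' known target SpO2); additive white noise, slow baseline drift and the
#' frame geometry complete the scene.
#'
#' Defaults emulate a consumer webcam watching a seated subject under office
#' lighting: 30 frames/s, a 78 bpm pulse, DC skin tone around (150, 110, 90)
#' on the 0-255 scale, AC amplitudes of 1-3% of DC with the green channel
#' strongest (haemoglobin absorption peaks in green), red/blue chosen so the
#' ratio-of-ratios maps to SpO2 = 98%, and sub-passband drift at 0.1 Hz.
#' The dominant green amplitude matters: it puts the pulse on the two
#' chrominance axes with opposite polarity, so the alpha combination
#' reinforces it; a scene whose chrominance axes are positively proportional
#' is self-cancelling by construction (that is the point of the alpha rule)
#' and carries no recoverable pulse.
#'
#' @param fs sampling rate, Hz (frames per second).
#' @param duration_s scene length, seconds, > 0.
#' @param hr_hz cardiac frequency, Hz; must satisfy `0 < hr_hz < fs/2`.
#' @param base_rgb DC triple (R, G, B), all > 0, 0-255 scale.
#' @param ac_rgb per-channel pulsatile amplitude triple, all >= 0.
#' @param noise_sd additive white-noise standard deviation per channel.
#' @param drift_amp baseline drift amplitude (shared across channels, like an
#'   illumination change).
#' @param drift_hz drift frequency, Hz; keep below the 0.6 Hz passband edge.
#' @param frame_shape `(height, width)` in pixels for frame rendering.
#' @param waveform `"sine"` (default) or `"harmonic"` (adds a second
#'   harmonic at 25% amplitude, for SNR tests).
#' @param seed integer RNG seed recorded in outputs.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(fs = 30, duration_s = 30, hr_hz = 1.3,
                         base_rgb = c(150, 110, 90),
                         ac_rgb = c(1.7308, 3.2, 1.0),
                         noise_sd = 0.3, drift_amp = 2, drift_hz = 0.1,
                         frame_shape = c(16L, 16L),
                         waveform = c("sine", "harmonic"),
                         seed = 1L) {
  waveform <- match.arg(waveform)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(hr_hz, "hr_hz", positive = TRUE)
  if (hr_hz >= fs / 2)
    abort_config(sprintf("Nyquist violated: hr_hz (%g) must be below fs/2 (%g)",
                         hr_hz, fs / 2))
  if (length(base_rgb) != 3L || any(base_rgb <= 0))
    abort_config("`base_rgb` must be three positive DC values")
  if (length(ac_rgb) != 3L || any(ac_rgb < 0))
    abort_config("`ac_rgb` must be three nonnegative amplitudes")
  stopifnot_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_number(drift_amp, "drift_amp", nonneg = TRUE)
  stopifnot_scalar_number(drift_hz, "drift_hz", nonneg = TRUE)
  if (length(frame_shape) != 2L || any(frame_shape < 1))
    abort_config("`frame_shape` must be positive (height, width)")
  structure(list(fs = fs, duration_s = duration_s, hr_hz = hr_hz,
                 base_rgb = as.numeric(base_rgb), ac_rgb = as.numeric(ac_rgb),
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_hz = drift_hz, frame_shape = as.integer(frame_shape),
                 waveform = waveform, seed = as.integer(seed)),
            class = "scene_config")
}

#' Scene configuration encoding a target SpO2
#'
#' Inverts the ratio-of-ratios calibration: given a target SpO2 the red AC
#' amplitude is set so `(AC_R/DC_R)/(AC_B/DC_B)` equals
#' `(A - spo2_target)/B`.
#'
#' @param spo2_target target SpO2 in percent (or directly a ratio via
#'   `ratio`).
#' @param ratio alternatively, the ratio-of-ratios to encode (overrides
#'   `spo2_target`).
#' @param cal an [spo2_calibration()].
#' @param ... passed to [scene_config()].
#' @return a `scene_config`.
#' @export
scene_config_for_spo2 <- function(spo2_target = 98, ratio = NULL,
                                  cal = spo2_calibration(), ...) {
  if (is.null(ratio)) ratio <- (cal$A - spo2_target) / cal$B
  if (ratio <= 0) abort_config("implied ratio-of-ratios must be positive")
  cfg <- scene_config(...)
  cfg$ac_rgb[1] <- ratio * cfg$base_rgb[1] * cfg$ac_rgb[3] / cfg$base_rgb[3]
  cfg
}

# Analytic ground truth implied by a config (no simulation involved).
scene_ground_truth <- function(config, cal = spo2_calibration()) {
  r <- if (config$ac_rgb[3] > 0)
    (config$ac_rgb[1] / config$base_rgb[1]) /
      (config$ac_rgb[3] / config$base_rgb[3])
  else NA_real_
  spo2 <- if (is.na(r)) NA_real_
          else min(max(cal$A - cal$B * r, cal$clamp[1]), cal$clamp[2])
  list(hr_bpm = 60 * config$hr_hz, ratio_of_ratios = r, spo2_expected = spo2,
       seed = config$seed)
}

scene_waveform <- function(config, t) {
  w <- sin(2 * pi * config$hr_hz * t)
  if (config$waveform == "harmonic")
    w <- w + 0.25 * sin(2 * pi * 2 * config$hr_hz * t)
  w
}

#' Generate a synthetic RGB trace with known ground truth
#'
#' Channel `c` is `base_c + ac_c * waveform(2 pi hr_hz t) + drift + noise`
#' with `N = round(fs * duration_s)` samples; exactly reproducible for a
#' fixed seed. Drift is a slow sinusoid shared by all channels (an
#' achromatic illumination change the bandpass must remove).
#'
#' @param config a [scene_config()].
#' @return list with `trace` (an [rgb_trace()]) and `ground_truth`
#'   (`hr_bpm`, `ratio_of_ratios`, `spo2_expected`, `seed`).
#' @export
generate_rgb_trace <- function(config) {
  if (!inherits(config, "scene_config"))
    abort_config("`config` must be a scene_config")
  n <- round(config$fs * config$duration_s)
  t <- (0:(n - 1)) / config$fs
  w <- scene_waveform(config, t)
  drift <- config$drift_amp * sin(2 * pi * config$drift_hz * t)
  ch <- with_seed(config$seed, lapply(1:3, function(i) {
    config$base_rgb[i] + config$ac_rgb[i] * w + drift +
      if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
  }))
  list(trace = rgb_trace(ch[[1]], ch[[2]], ch[[3]], fs = config$fs),
       ground_truth = scene_ground_truth(config))
}

#' Generate a synthetic frame sequence with ROI sidecar
#'
#' Each frame is a uniform patch at the scene's deterministic channel means
#' (base + pulse + drift) plus i.i.d. per-pixel noise, so spatial averaging
#' over the full-frame ROI reconstructs the trace within noise (exactly when
#' `noise_sd = 0`). The sidecar supplies a full-frame ROI with confidence 1.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (list of `H x W x 3` arrays), `rois` (list of
#'   [face_observation()]), `fs`, `ground_truth`, `config`.
#' @export
generate_frame_sequence <- function(config) {
  if (!inherits(config, "scene_config"))
    abort_config("`config` must be a scene_config")
  hw <- config$frame_shape
  if (prod(hw) == 0) abort_config("zero-area frame_shape")
  n <- round(config$fs * config$duration_s)
  t <- (0:(n - 1)) / config$fs
  w <- scene_waveform(config, t)
  drift <- config$drift_amp * sin(2 * pi * config$drift_hz * t)
  means <- sapply(1:3, function(i) config$base_rgb[i] + config$ac_rgb[i] * w + drift)
  frames <- with_seed(config$seed, lapply(seq_len(n), function(k) {
    f <- array(rep(means[k, ], each = prod(hw)), dim = c(hw[1], hw[2], 3L))
    if (config$noise_sd > 0)
      f <- f + array(stats::rnorm(prod(hw) * 3, 0, config$noise_sd),
                     dim = dim(f))
    f
  }))
  roi <- face_observation(0, 0, hw[2], hw[1], confidence = 1)
  list(frames = frames, rois = rep(list(roi), n), fs = config$fs,
       ground_truth = scene_ground_truth(config), config = config)
}

#' Synthetic reference heart-rate series
#'
#' Emulates a contact PPG reference (e.g. an ear-clip sensor): per estimate
#' window, the ground-truth bpm plus Gaussian jitter, aligned to the window
#' end times the streaming engine would emit.
#'
#' @param config a [scene_config()].
#' @param jitter_sd reference jitter standard deviation, bpm, >= 0.
#' @param times window end times (seconds); default = the stride grid of
#'   `session` over the scene duration.
#' @param session a [session_config()] supplying the default grid.
#' @return `data.frame(time_s, bpm)`.
#' @export
generate_reference_series <- function(config, jitter_sd = 0, times = NULL,
                                      session = session_config()) {
  if (!inherits(config, "scene_config"))
    abort_config("`config` must be a scene_config")
  if (!is.numeric(jitter_sd) || length(jitter_sd) != 1L || jitter_sd < 0)
    abort_config("`jitter_sd` must be a single number >= 0")
  gt <- scene_ground_truth(config)
  if (is.null(times)) {
    if (config$duration_s < session$stabilization_s)
      abort_config("scene shorter than the stabilization phase")
    times <- seq(session$stabilization_s, config$duration_s,
                 by = session$stride_s)
  }
  bpm <- gt$hr_bpm + if (jitter_sd > 0)
    with_seed(config$seed + 1L, stats::rnorm(length(times), 0, jitter_sd))
  else 0
  data.frame(time_s = times, bpm = bpm)
}
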