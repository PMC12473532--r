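# Real-time engine: rolling windows over a frame stream, stabilization phase,
# per-window validity gating, valid-second accrual, chatbot-trigger decision.

#' Streaming session configuration
#'
#' @param window_s analysis window length, seconds (rolling 2 s windows by
#'   default).
#' @param stride_s hop between window emissions, seconds; `0 < stride_s <=
#'   window_s`.
#' @param stabilization_s initial interval during which samples are buffered
#'   and no estimate is emitted (26 s default; deployments use 26-30 s).
#' @param min_valid_s seconds of valid windows required before chatbot
#'   feedback is allowed (8 s default).
#' @param snr_gate minimum pulse SNR for a window to count as valid rPPG
#'   (0.7 default).
#' @param face_conf_gate face-detection confidence gate (0.70 default):
#'   frames below it are masked invalid, and triggering requires the latest
#'   window's mean confidence to exceed it.
#' @param hr_band `(low_hz, high_hz)` cardiac search band.
#' @param affect_votes rolling sample count for the age majority vote (30).
#' @param spo2_cal an [spo2_calibration()].
#' @param fir a [bandpass_spec()]; the filter itself is designed once the
#'   stream's sampling rate is known.
#' @return object of class `session_config`.
#' @export
session_config <- function(window_s = 2.0, stride_s = 1.0,
                           stabilization_s = 26, min_valid_s = 8,
                           snr_gate = 0.7, face_conf_gate = 0.70,
                           hr_band = c(0.6, 4.0), affect_votes = 30L,
                           spo2_cal = spo2_calibration(),
                           fir = bandpass_spec()) {
  stopifnot_scalar_number(window_s, "window_s", positive = TRUE)
  stopifnot_scalar_number(stride_s, "stride_s", positive = TRUE)
  if (stride_s > window_s)
    abort_config("stride_s must not exceed window_s")
  stopifnot_scalar_number(stabilization_s, "stabilization_s", positive = TRUE)
  if (stabilization_s < window_s)
    abort_config("stabilization_s must be at least window_s")
  stopifnot_scalar_number(min_valid_s, "min_valid_s", positive = TRUE)
  stopifnot_scalar_number(snr_gate, "snr_gate", nonneg = TRUE)
  stopifnot_scalar_number(face_conf_gate, "face_conf_gate", nonneg = TRUE)
  if (face_conf_gate > 1) abort_config("face_conf_gate must lie in [0, 1]")
  structure(list(window_s = window_s, stride_s = stride_s,
                 stabilization_s = stabilization_s, min_valid_s = min_valid_s,
                 snr_gate = snr_gate, face_conf_gate = face_conf_gate,
                 hr_band = hr_band, affect_votes = as.integer(affect_votes),
                 spo2_cal = spo2_cal, fir = fir),
            class = "session_config")
}

#' Open a streaming rPPG session
#'
#' Returns a mutable session object (environment-backed). Feed it frame
#' samples with [push_frame()] and affect observations with [push_affect()];
#' query the chatbot gate with [gate_chatbot_trigger()]. Phases advance
#' monotonically `stabilizing -> estimating -> triggered -> stopped`.
#'
#' @param config a [session_config()].
#' @return object of class `rppg_session`.
#' @export
rppg_session <- function(config = session_config()) {
  s <- new.env(parent = emptyenv())
  s$cfg <- config
  s$t <- s$R <- s$G <- s$B <- s$conf <- numeric(0)
  s$valid <- logical(0)
  s$n <- 0L
  s$fs <- NA_real_
  s$filt <- NULL
  s$phase <- "stabilizing"
  s$valid_seconds <- 0
  s$next_emit <- config$stabilization_s + config$stride_s
  s$estimates <- list()
  s$affect <- list()
  s$trigger_log <- list()
  class(s) <- "rppg_session"
  s
}

#' @export
print.rppg_session <- function(x, ...) {
  cat(sprintf("<rppg_session> phase=%s, %d frames, %d estimates, %.1f valid s\n",
              x$phase, x$n, length(x$estimates), x$valid_seconds))
  invisible(x)
}

session_append <- function(s, t, R, G, B, conf, valid) {
  i <- s$n + 1L
  if (i > length(s$t)) {          # grow by doubling
    new <- max(256L, 2L * length(s$t))
    length(s$t) <- length(s$R) <- length(s$G) <- length(s$B) <-
      length(s$conf) <- new
    length(s$valid) <- new
  }
  s$t[i] <- t; s$R[i] <- R; s$G[i] <- G; s$B[i] <- B
  s$conf[i] <- conf; s$valid[i] <- valid
  s$n <- i
}

# Estimate for the window ending at `wend` (seconds). The pulse is extracted
# from a lookback segment long enough for the zero-phase filter plus an
# analysis span of >= 2 cardiac cycles at the band's lower edge; SpO2 and the
# validity mask use the window proper.
session_window_estimate <- function(s, wend) {
  cfg <- s$cfg
  fs <- s$fs
  analysis_s <- max(cfg$window_s, 2 / cfg$hr_band[1])
  look_s <- analysis_s + (s$filt$order + 2) / fs
  eps <- 1e-9
  idx_all <- seq_len(s$n)
  seg <- idx_all[s$t[idx_all] > wend - look_s - eps & s$t[idx_all] <= wend + eps]
  win <- idx_all[s$t[idx_all] > wend - cfg$window_s - eps & s$t[idx_all] <= wend + eps]
  ana <- idx_all[s$t[idx_all] > wend - analysis_s - eps & s$t[idx_all] <= wend + eps]
  reasons <- character(0)
  hr_bpm <- f_h <- spo2 <- NA_real_
  snr <- 0
  face_conf <- if (length(win)) mean(s$conf[win]) else 0
  if (length(win) == 0L || length(seg) <= s$filt$order + 1) {
    reasons <- c(reasons, "short_segment")
  } else {
    if (!all(s$valid[ana])) reasons <- c(reasons, "invalid_frames")
    # keep the filter running across masked samples via linear interpolation
    R <- s$R[seg]; G <- s$G[seg]; B <- s$B[seg]; v <- s$valid[seg]
    if (!all(v)) {
      if (sum(v) < 2L) {
        reasons <- c(reasons, "no_valid_samples")
        v <- NULL
      } else {
        tt <- s$t[seg]
        R <- stats::approx(tt[v], R[v], xout = tt, rule = 2)$y
        G <- stats::approx(tt[v], G[v], xout = tt, rule = 2)$y
        B <- stats::approx(tt[v], B[v], xout = tt, rule = 2)$y
      }
    }
    if (!("no_valid_samples" %in% reasons)) {
      xs <- 3 * R - 2 * G
      ys <- 1.5 * R + G - 1.5 * B
      xf <- apply_bandpass(xs, s$filt, mode = "batch")
      yf <- apply_bandpass(ys, s$filt, mode = "batch")
      keep <- which(s$t[seg] > wend - analysis_s - eps)
      pulse <- pulse_signal(xf[keep], yf[keep],
                            window = c(wend - cfg$window_s, wend))
      hr <- tryCatch(estimate_hr(pulse, fs, cfg$hr_band),
                     mv_signal_quality_error = function(e) {
                       list(valid = FALSE, reason = "short_segment",
                            f_h = NA_real_, hr_bpm = NA_real_)
                     })
      if (hr$valid) {
        f_h <- hr$f_h; hr_bpm <- hr$hr_bpm
        snr <- compute_snr(pulse, fs, f_h, cfg$hr_band)
      } else reasons <- c(reasons, hr$reason)
      wtr <- rgb_trace(s$R[win], s$G[win], s$B[win], fs = fs,
                       t0 = wend - cfg$window_s)
      sp <- estimate_spo2(spo2_components(wtr), cfg$spo2_cal)
      if (sp$valid) spo2 <- sp$spo2_pct else reasons <- c(reasons, sp$reason)
    }
  }
  valid <- length(reasons) == 0L
  counted <- valid && snr > cfg$snr_gate
  list(t_start = wend - cfg$window_s, t_end = wend, f_h = f_h,
       hr_bpm = hr_bpm, spo2_pct = spo2, snr = snr, face_conf = face_conf,
       valid = valid, counted = counted, reasons = reasons)
}

#' Push one frame sample into a session
#'
#' Appends the spatially averaged sample; frames whose face confidence falls
#' below the gate are masked invalid. The sampling rate is inferred from the
#' first 30 timestamps (5% jitter tolerance; beyond that is a stream error,
#' not silent resampling). No estimate is emitted during the stabilization
#' phase; afterwards every stride boundary emits a window estimate, and a
#' window adds `stride_s` to the accumulated valid seconds iff its estimate
#' is valid and its SNR exceeds the gate.
#'
#' @param session an [rppg_session()].
#' @param t timestamp, seconds; strictly increasing.
#' @param R,G,B spatially averaged channel intensities for the frame.
#' @param face a [face_observation()] or a bare confidence in `[0, 1]`;
#'   `NULL` marks a frame with no detected face.
#' @return invisibly, a list of the estimates emitted by this frame (usually
#'   empty or length 1).
#' @export
push_frame <- function(session, t, R, G, B, face = 1) {
  s <- session
  if (s$phase == "stopped") abort_stream("session is stopped")
  if (s$n > 0 && t <= s$t[s$n])
    abort_stream(sprintf("non-monotone timestamp %g after %g", t, s$t[s$n]))
  conf <- if (is.null(face)) 0
          else if (inherits(face, "face_observation")) face$confidence
          else as.numeric(face)
  ok <- conf >= s$cfg$face_conf_gate && all(is.finite(c(R, G, B)))
  session_append(s, t, R, G, B, conf, ok)
  if (is.na(s$fs) && s$n >= 30L) {
    dt <- diff(s$t[1:30])
    med <- stats::median(dt)
    if (any(abs(dt - med) / med > 0.05))
      abort_stream("frame-interval jitter exceeds 5%; cannot infer a stable fs")
    s$fs <- 1 / med
    s$filt <- design_bandpass(s$fs, s$cfg$fir)
  }
  out <- list()
  if (!is.na(s$fs)) {
    if (s$n > 30L) {
      dt <- s$t[s$n] - s$t[s$n - 1L]
      if (abs(dt - 1 / s$fs) * s$fs > 0.05)
        abort_stream(sprintf("frame interval %g s drifts > 5%% from 1/fs", dt))
    }
    elapsed <- s$n / s$fs
    while (elapsed >= s$next_emit - 1e-9) {
      wend <- s$next_emit
      est <- session_window_estimate(s, wend + s$t[1])
      if (s$phase == "stabilizing") s$phase <- "estimating"
      s$estimates[[length(s$estimates) + 1L]] <- est
      if (est$counted) s$valid_seconds <- s$valid_seconds + s$cfg$stride_s
      out[[length(out) + 1L]] <- est
      s$next_emit <- s$next_emit + s$cfg$stride_s
    }
  }
  invisible(out)
}

#' Push an affect observation (emotion + age) into a session
#'
#' @param session an [rppg_session()].
#' @param t timestamp, seconds.
#' @param emotion emotion label.
#' @param emotion_conf classifier confidence in `[0, 1]`.
#' @param age_bucket age-bucket label.
#' @param age_conf its confidence in `[0, 1]`.
#' @return invisibly the session.
#' @export
push_affect <- function(session, t, emotion, emotion_conf,
                        age_bucket = NA_character_, age_conf = NA_real_) {
  session$affect[[length(session$affect) + 1L]] <-
    list(t = t, emotion = emotion, emotion_conf = emotion_conf,
         age_bucket = age_bucket, age_conf = age_conf)
  invisible(session)
}

#' Rolling age estimate from a session's affect stream
#'
#' Majority vote over the last `affect_votes` age observations; `pending`
#' until that many have been seen.
#'
#' @param session an [rppg_session()].
#' @return see [majority_vote()].
#' @export
session_age_vote <- function(session) {
  labs <- vapply(session$affect, function(a) as.character(a$age_bucket), "")
  labs <- labs[!is.na(labs) & labs != "NA"]
  majority_vote(labs, n_required = session$cfg$affect_votes)
}

#' Chatbot trigger decision
#'
#' Feedback is allowed only when (i) at least `min_valid_s` seconds of valid
#' rPPG windows (SNR above the gate) have accumulated, (ii) the latest
#' window's mean face-detection confidence exceeds the gate, and (iii) at
#' least one affect label with confidence above 0.5 has been observed. The
#' returned reasons list every unmet condition. A positive decision advances
#' the session phase to `triggered`.
#'
#' @param session an [rppg_session()] in the estimating (or triggered) phase.
#' @return list with `triggered` (logical) and `reasons` (character).
#' @export
gate_chatbot_trigger <- function(session) {
  s <- session
  reasons <- character(0)
  if (!s$phase %in% c("estimating", "triggered"))
    reasons <- c(reasons, "not_estimating")
  if (s$valid_seconds < s$cfg$min_valid_s)
    reasons <- c(reasons, "insufficient_valid_seconds")
  last_conf <- if (length(s$estimates))
    s$estimates[[length(s$estimates)]]$face_conf else 0
  if (!(last_conf > s$cfg$face_conf_gate))
    reasons <- c(reasons, "low_face_confidence")
  has_affect <- any(vapply(s$affect, function(a)
    isTRUE(a$emotion_conf > 0.5) || isTRUE(a$age_conf > 0.5), logical(1)))
  if (!has_affect) reasons <- c(reasons, "no_confident_affect")
  triggered <- length(reasons) == 0L
  if (triggered && s$phase == "estimating") s$phase <- "triggered"
  s$trigger_log[[length(s$trigger_log) + 1L]] <-
    list(n_frames = s$n, valid_seconds = s$valid_seconds,
         triggered = triggered, reasons = reasons)
  list(triggered = triggered, reasons = reasons)
}

#' Stop a session
#' @param session an [rppg_session()].
#' @return invisibly the session (phase `stopped`).
#' @export
stop_session <- function(session) {
  session$phase <- "stopped"
  invisible(session)
}

#' Offline twin of the streaming engine
#'
#' Feeds a recorded trace sample-by-sample through the identical streaming
#' code path, so batch and live runs produce bit-identical estimate
#' sequences. Invalid trace samples are presented as frames with zero face
#' confidence.
#'
#' @param trace an [rgb_trace()].
#' @param config a [session_config()].
#' @return list of per-window estimates (each as in [push_frame()]); an
#'   empty list with a warning when the trace is shorter than
#'   `stabilization_s + window_s`.
#' @export
run_batch <- function(trace, config = session_config()) {
  dur <- trace$n / trace$fs
  if (dur < config$stabilization_s + config$window_s) {
    warning(sprintf("trace (%.1f s) shorter than stabilization + one window (%.1f s); no estimates",
                    dur, config$stabilization_s + config$window_s))
    return(list())
  }
  s <- rppg_session(config)
  tt <- trace_times(trace)
  for (i in seq_len(trace$n)) {
    push_frame(s, tt[i], trace$R[i], trace$G[i], trace$B[i],
               face = if (trace$valid[i]) 1 else 0)
  }
  s$estimates
}

#' Per-window estimates as a data frame
#' @param estimates list of window estimates from [run_batch()] or a
#'   session's `$estimates`.
#' @return data.frame with one row per window.
#' @export
estimates_df <- function(estimates) {
  if (length(estimates) == 0L)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      hr_bpm = numeric(0), spo2_pct = numeric(0),
                      snr = numeric(0), face_conf = numeric(0),
                      valid = logical(0), reasons = character(0)))
  data.frame(
    t_start = vapply(estimates, `[[`, 0, "t_start"),
    t_end = vapply(estimates, `[[`, 0, "t_end"),
    hr_bpm = vapply(estimates, `[[`, 0, "hr_bpm"),
    spo2_pct = vapply(estimates, `[[`, 0, "spo2_pct"),
    snr = vapply(estimates, `[[`, 0, "snr"),
    face_conf = vapply(estimates, `[[`, 0, "face_conf"),
    valid = vapply(estimates, `[[`, TRUE, "valid"),
    reasons = vapply(estimates, function(e) paste(e$reasons, collapse = ";"), "")
  )
}
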