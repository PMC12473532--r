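#' RGB trace container
#'
#' An `rgb_trace` holds the 3 x N matrix of spatially averaged channel
#' intensities sampled from a facial region of interest, one triple per video
#' frame, together with the sampling rate and a per-frame validity mask
#' (frames where face detection failed are kept in place but flagged).
#'
#' @param R,G,B numeric vectors of equal length: per-frame mean channel
#'   intensities (0-255 scale, but any consistent intensity unit works).
#' @param fs sampling rate in Hz (frames per second), > 0.
#' @param t0 start time of the first sample, seconds.
#' @param valid logical vector marking frames with a usable face observation;
#'   defaults to all `TRUE`.
#' @return An object of class `rgb_trace` with fields `fs`, `t0`, `R`, `G`,
#'   `B`, `valid` and `n`.
#' @export
rgb_trace <- function(R, G, B, fs, t0 = 0, valid = NULL) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- length(R)
  if (length(G) != n || length(B) != n)
    abort_config("R, G, B channels must have equal length")
  if (n < 1L) abort_empty_input("rgb_trace needs at least one sample")
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) abort_config("`valid` mask must match trace length")
  bad <- valid & !(is.finite(R) & is.finite(G) & is.finite(B))
  if (any(bad)) abort_config("valid samples must be finite")
  structure(
    list(R = as.numeric(R), G = as.numeric(G), B = as.numeric(B),
         fs = as.numeric(fs), t0 = as.numeric(t0),
         valid = as.logical(valid), n = n),
    class = "rgb_trace"
  )
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d samples @ %.6g Hz (%.2f s), %d invalid\n",
              x$n, x$fs, x$n / x$fs, sum(!x$valid)))
  invisible(x)
}

#' @export
length.rgb_trace <- function(x) x$n

#' Timestamps of an RGB trace
#' @param trace an [rgb_trace()].
#' @return numeric vector of per-sample times in seconds.
#' @export
trace_times <- function(trace) trace$t0 + (seq_len(trace$n) - 1L) / trace$fs

#' Face observation for one frame
#'
#' Bounding box convention: 0-based pixel coordinates, origin at the top-left
#' corner, half-open extent, i.e. the box covers columns `x .. x+w-1` and rows
#' `y .. y+h-1`.
#'
#' @param x,y top-left corner of the face box (pixels, 0-based).
#' @param w,h box width and height in pixels, > 0.
#' @param confidence detector confidence in `[0, 1]`.
#' @param landmarks optional named list of `(x, y)` pixel points; the
#'   alignment geometry expects at least `left_eye`, `right_eye`,
#'   `reference_point`.
#' @return An object of class `face_observation`.
#' @export
face_observation <- function(x, y, w, h, confidence = 1, landmarks = NULL) {
  stopifnot_scalar_number(w, "w", positive = TRUE)
  stopifnot_scalar_number(h, "h", positive = TRUE)
  stopifnot_scalar_number(confidence, "confidence")
  if (confidence < 0 || confidence > 1)
    abort_config("`confidence` must lie in [0, 1]")
  structure(list(x = x, y = y, w = w, h = h,
                 confidence = confidence, landmarks = landmarks),
            class = "face_observation")
}

#' Spatially average the channels of one frame over a face ROI
#'
#' Each returned value is the arithmetic mean of one colour channel over the
#' pixels in the intersection of the ROI box with the frame. Boxes partially
#' outside the frame are clipped; an empty intersection is a signal-quality
#' error (the caller marks the frame invalid rather than aborting a stream).
#'
#' @param frame numeric array `H x W x 3` of channel intensities (R, G, B).
#' @param roi a [face_observation()].
#' @return named numeric vector `c(R=, G=, B=)`.
#' @export
spatial_average_frame <- function(frame, roi) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    abort_config("`frame` must be an H x W x 3 array")
  if (!inherits(roi, "face_observation"))
    abort_config("`roi` must be a face_observation")
  # 0-based half-open box -> 1-based inclusive R indices, clipped to frame
  rows <- max(1L, floor(roi$y) + 1L):min(d[1], floor(roi$y + roi$h))
  cols <- max(1L, floor(roi$x) + 1L):min(d[2], floor(roi$x + roi$w))
  if (floor(roi$y) + 1L > d[1] || floor(roi$y + roi$h) < 1L ||
      floor(roi$x) + 1L > d[2] || floor(roi$x + roi$w) < 1L)
    abort_signal_quality("ROI does not intersect the frame")
  c(R = mean(frame[rows, cols, 1L]),
    G = mean(frame[rows, cols, 2L]),
    B = mean(frame[rows, cols, 3L]))
}

#' Build an RGB trace from a frame sequence
#'
#' Applies [spatial_average_frame()] per frame. Frames whose ROI is missing
#' (`NULL`) or does not intersect the frame are flagged invalid in the trace's
#' validity mask; their sample values are `NA`.
#'
#' @param frames list of `H x W x 3` arrays.
#' @param rois list of [face_observation()] (or `NULL` per missing face),
#'   one per frame.
#' @param fs sampling rate, Hz.
#' @param t0 start time, seconds.
#' @return an [rgb_trace()] carrying the validity mask.
#' @export
build_rgb_trace <- function(frames, rois, fs, t0 = 0) {
  n <- length(frames)
  if (length(rois) != n) abort_config("need exactly one ROI entry per frame")
  if (n == 0L) abort_empty_input("no frames supplied")
  R <- G <- B <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.null(rois[[i]])) next
    v <- tryCatch(spatial_average_frame(frames[[i]], rois[[i]]),
                  mv_signal_quality_error = function(e) NULL)
    if (is.null(v)) next
    R[i] <- v[["R"]]; G[i] <- v[["G"]]; B[i] <- v[["B"]]
    valid[i] <- TRUE
  }
  if (!any(valid)) abort_empty_input("no frame produced a valid face sample")
  rgb_trace(R, G, B, fs = fs, t0 = t0, valid = valid)
}

#' Chrominance transform of an RGB trace
#'
#' Projects the mean-channel traces onto two chrominance axes chosen to
#' suppress achromatic illumination changes while retaining blood-volume
#' pulsatility: `xs = 3 V_R - 2 V_G` and `ys = 1.5 V_R + V_G - 1.5 V_B`.
#'
#' @param trace an [rgb_trace()], or a list with numeric `R`, `G`, `B`.
#' @return list with numeric vectors `xs` and `ys`.
#' @export
chrominance_transform <- function(trace) {
  if (length(trace$R) == 0L) abort_empty_input("empty trace")
  list(xs = 3 * trace$R - 2 * trace$G,
       ys = 1.5 * trace$R + trace$G - 1.5 * trace$B)
}

#' Bandpass filter specification
#'
#' @param low_hz,high_hz passband edges in Hz. The default 0.6-4.0 Hz covers
#'   36-240 bpm; the narrower 0.7-3.5 Hz deployment preset is available as
#'   `bandpass_preset("tight")`.
#' @param order FIR order (tap count minus one); must be even so the filter
#'   is symmetric (linear phase) with integer group delay. `NULL` = choose at
#'   design time: the next even integer >= `3 * fs / low_hz`, capped at 10
#'   seconds of taps.
#' @param design filter design method identifier; only `"sinc-hamming"`
#'   (windowed sinc with a Hamming window) is implemented.
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 0.6, high_hz = 4.0, order = NULL,
                          design = "sinc-hamming") {
  stopifnot_scalar_number(low_hz, "low_hz", positive = TRUE)
  stopifnot_scalar_number(high_hz, "high_hz", positive = TRUE)
  if (low_hz >= high_hz)
    abort_config(sprintf("low_hz (%g) must be below high_hz (%g)", low_hz, high_hz))
  if (!is.null(order)) {
    stopifnot_scalar_number(order, "order", positive = TRUE)
    if (order < 2 || order %% 2 != 0)
      abort_config("`order` must be an even integer >= 2")
  }
  if (!identical(design, "sinc-hamming"))
    abort_config(sprintf("unknown filter design '%s'", design))
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 design = design),
            class = "bandpass_spec")
}

#' Named passband presets
#' @param name `"default"` (0.6-4.0 Hz) or `"tight"` (0.7-3.5 Hz).
#' @return a [bandpass_spec()].
#' @export
bandpass_preset <- function(name = c("default", "tight")) {
  switch(match.arg(name),
         default = bandpass_spec(0.6, 4.0),
         tight   = bandpass_spec(0.7, 3.5))
}

# Unit-DC windowed-sinc lowpass, M+1 taps (M even)
hamming_sinc_lowpass <- function(fc, fs, M) {
  n <- 0:M
  m <- n - M / 2
  h <- ifelse(m == 0, 2 * fc / fs, sin(2 * pi * fc / fs * m) / (pi * m))
  w <- 0.54 - 0.46 * cos(2 * pi * n / M)
  h <- h * w
  h / sum(h)          # exact unit DC gain
}

#' Design the FIR bandpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR, built as the difference of two
#' unit-DC lowpass kernels so the DC gain is exactly zero. Group delay is
#' `order/2` samples. With the default order rule the transition band is
#' narrow enough to attenuate sub-0.5 Hz baseline drift by well over 20 dB
#' while passing cardiac frequencies essentially unattenuated.
#'
#' @param fs sampling rate, Hz.
#' @param spec a [bandpass_spec()].
#' @return object of class `fir_filter`: `coef` (taps), `order`, `delay`
#'   (samples), `fs`, `spec`.
#' @export
design_bandpass <- function(fs, spec = bandpass_spec()) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (!inherits(spec, "bandpass_spec")) abort_config("`spec` must be a bandpass_spec")
  if (spec$high_hz >= fs / 2)
    abort_config(sprintf("high_hz (%g) must be below Nyquist (%g)", spec$high_hz, fs / 2))
  M <- spec$order
  if (is.null(M)) {
    M <- ceiling(3 * fs / spec$low_hz)
    if (M %% 2 != 0) M <- M + 1
    cap <- floor(10 * fs)
    if (cap %% 2 != 0) cap <- cap - 1
    M <- min(M, cap)
  }
  h <- hamming_sinc_lowpass(spec$high_hz, fs, M) -
       hamming_sinc_lowpass(spec$low_hz, fs, M)
  structure(list(coef = h, order = M, delay = M / 2, fs = fs, spec = spec),
            class = "fir_filter")
}

#' Apply the FIR bandpass to a series
#'
#' Two application modes:
#' \describe{
#'   \item{batch}{Offline, zero-phase. The series mean is removed, the series
#'     is reflect-padded by half the filter length at each end, and the
#'     symmetric kernel is applied centred, so a passband sinusoid comes out
#'     with zero lag. Requires `length(x) > length(coef)`.}
#'   \item{streaming}{Causal convolution with zero initial state, as a live
#'     engine would run it. Output sample `n` corresponds to input time
#'     `n - order/2` (the group delay); the delay in samples is attached as
#'     attribute `delay_samples` for timestamp compensation. The first
#'     `order` samples are filter warm-up.}
#' }
#' Both modes return a series of the same length as the input.
#'
#' @param x numeric series.
#' @param filt a `fir_filter` from [design_bandpass()].
#' @param mode `"batch"` or `"streaming"`.
#' @return filtered numeric series, same length as `x`.
#' @export
apply_bandpass <- function(x, filt, mode = c("batch", "streaming")) {
  mode <- match.arg(mode)
  if (!inherits(filt, "fir_filter")) abort_config("`filt` must be a fir_filter")
  h <- filt$coef
  L <- length(h)
  n <- length(x)
  if (mode == "batch") {
    if (n <= L)
      abort_signal_quality(sprintf(
        "series (%d samples) must be longer than the filter (%d taps) in batch mode", n, L))
    x <- x - mean(x)
    half <- filt$delay
    # reflect padding keeps full output length without ringing at the edges
    pad <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
    y <- stats::filter(pad, h, method = "convolution", sides = 2)
    as.numeric(y[(half + 1):(half + n)])
  } else {
    pad <- c(rep(0, L - 1), x)
    y <- stats::filter(pad, h, method = "convolution", sides = 1)
    y <- as.numeric(y[L:(L + n - 1)])
    attr(y, "delay_samples") <- filt$delay
    y
  }
}

# Population (divide-by-N) standard deviation; the estimator used throughout
# the signal path (alpha, AC components). Fixed for reproducibility.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Alpha-normalised pulse signal
#'
#' Combines the two filtered chrominance series into the blood-volume pulse
#' `s = xf - alpha * yf`, with the skin-tone normalisation factor
#' `alpha = sd(xf) / sd(yf)` (population standard deviations). Whatever noise
#' component the two chrominance axes share in proportion is cancelled
#' exactly. Degenerate rule: if `sd(yf) == 0`, `alpha = 0` and `s = xf`.
#'
#' @param xf,yf filtered chrominance series, equal length >= 2.
#' @param window optional `(start_s, end_s)` span covered by the series.
#' @param xs,ys optionally the raw (unfiltered) chrominance series, carried
#'   for inspection.
#' @return object of class `chrominance_pulse` with fields `xs`, `ys`, `xf`,
#'   `yf`, `alpha`, `s`, `window`.
#' @export
pulse_signal <- function(xf, yf, window = c(NA_real_, NA_real_),
                         xs = NULL, ys = NULL) {
  if (length(xf) != length(yf))
    abort_config("xf and yf must have equal length")
  if (length(xf) < 2L)
    abort_signal_quality("pulse extraction needs at least 2 samples")
  sy <- pop_sd(yf)
  if (sy == 0) {
    alpha <- 0
    s <- xf
  } else {
    alpha <- pop_sd(xf) / sy
    s <- xf - alpha * yf
  }
  structure(list(xs = xs, ys = ys, xf = xf, yf = yf,
                 alpha = alpha, s = s, window = window),
            class = "chrominance_pulse")
}

#' Full trace-to-pulse chain
#'
#' Convenience wrapper: chrominance transform, per-window mean removal,
#' zero-phase bandpass, alpha-normalised combination.
#'
#' @param trace an [rgb_trace()] (all samples assumed valid; interpolate or
#'   subset beforehand).
#' @param filt a `fir_filter`; defaults to the standard design for
#'   `trace$fs`.
#' @return a `chrominance_pulse`.
#' @export
extract_pulse <- function(trace, filt = NULL) {
  if (is.null(filt)) filt <- design_bandpass(trace$fs, bandpass_spec())
  ch <- chrominance_transform(trace)
  xf <- apply_bandpass(ch$xs, filt, mode = "batch")
  yf <- apply_bandpass(ch$ys, filt, mode = "batch")
  tt <- trace_times(trace)
  pulse_signal(xf, yf, window = c(tt[1], tt[length(tt)] + 1 / trace$fs),
               xs = ch$xs, ys = ch$ys)
}
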