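# Heart rate, SNR and SpO2 estimation from a windowed pulse / RGB trace.

# Hann-tapered, zero-padded magnitude spectrum. Zero padding brings the bin
# spacing to <= max_bin_hz (native resolution of a 2 s window is 0.5 Hz, far
# too coarse for bpm-level output); quadratic interpolation at the peak does
# the rest.
pulse_spectrum <- function(s, fs, max_bin_hz = 0.02) {
  n <- length(s)
  s <- s - mean(s)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  nfft <- 2^ceiling(log2(max(n, ceiling(fs / max_bin_hz))))
  sp <- stats::fft(c(s * w, rep(0, nfft - n)))
  k <- 0:(nfft %/% 2)
  list(freq = k * fs / nfft, amp = Mod(sp[k + 1]), nfft = nfft)
}

#' Heart rate from the pulse spectrum
#'
#' The pulse is Hann-tapered, zero-padded to a bin spacing of at most 0.02 Hz
#' and transformed with an FFT; the dominant in-band frequency `f_h` is the
#' magnitude argmax over the passband refined by quadratic interpolation
#' across the peak's neighbouring bins. Heart rate is `60 * f_h` bpm.
#'
#' @param pulse a `chrominance_pulse` or a numeric pulse series.
#' @param fs sampling rate, Hz.
#' @param band numeric `(low_hz, high_hz)` search band; defaults to the
#'   standard 0.6-4.0 Hz passband.
#' @return list with `f_h` (Hz), `hr_bpm`, `valid`, `reason`.
#'   A window shorter than two cardiac cycles at the band's lower edge is a
#'   signal-quality error; an all-constant pulse yields an invalid estimate
#'   with reason `"flat_spectrum"`.
#' @export
estimate_hr <- function(pulse, fs, band = c(0.6, 4.0)) {
  s <- if (inherits(pulse, "chrominance_pulse")) pulse$s else as.numeric(pulse)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    abort_config("invalid HR search band")
  need <- 2 * fs / band[1]
  if (length(s) < need - 1e-6)
    abort_signal_quality(sprintf(
      "window of %d samples covers < 2 cardiac cycles at %g Hz (need >= %d)",
      length(s), band[1], ceiling(need)))
  if (pop_sd(s) == 0)
    return(list(f_h = NA_real_, hr_bpm = NA_real_, valid = FALSE,
                reason = "flat_spectrum"))
  sp <- pulse_spectrum(s, fs)
  inb <- which(sp$freq >= band[1] & sp$freq <= band[2])
  a <- sp$amp[inb]
  if (all(a == 0))
    return(list(f_h = NA_real_, hr_bpm = NA_real_, valid = FALSE,
                reason = "flat_spectrum"))
  k <- inb[which.max(a)]
  df <- sp$freq[2] - sp$freq[1]
  f_h <- sp$freq[k]
  if (k > 1 && k < length(sp$freq)) {
    y1 <- sp$amp[k - 1]; y2 <- sp$amp[k]; y3 <- sp$amp[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den != 0) {
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 0.5) f_h <- f_h + delta * df
    }
  }
  f_h <- min(max(f_h, band[1]), band[2])
  list(f_h = f_h, hr_bpm = 60 * f_h, valid = TRUE, reason = NA_character_)
}

#' In-band signal-to-noise ratio of a pulse window
#'
#' A fundamental-plus-harmonic mask: the signal power is the spectral power
#' within 0.1 Hz of `f_h` and of `2 * f_h` (intersected with the band); the
#' noise power is the remaining in-band power. The ratio is dimensionless and
#' deterministic for a fixed input. The streaming validity gate requires
#' snr > 0.7 by default.
#'
#' @param pulse a `chrominance_pulse` or numeric pulse series.
#' @param fs sampling rate, Hz.
#' @param f_h fundamental frequency (Hz), inside `band`.
#' @param band `(low_hz, high_hz)` analysis band.
#' @param halfwidth half-width of the signal mask around each harmonic, Hz.
#' @return scalar snr >= 0 (0 when there is no in-band power, `Inf` when all
#'   in-band power sits under the mask).
#' @export
compute_snr <- function(pulse, fs, f_h, band = c(0.6, 4.0), halfwidth = 0.1) {
  s <- if (inherits(pulse, "chrominance_pulse")) pulse$s else as.numeric(pulse)
  if (!is.finite(f_h) || f_h < band[1] || f_h > band[2])
    abort_config("`f_h` must lie inside `band`")
  sp <- pulse_spectrum(s, fs)
  p <- sp$amp^2
  inb <- sp$freq >= band[1] & sp$freq <= band[2]
  total <- sum(p[inb])
  if (total == 0) return(0)
  mask <- inb & (abs(sp$freq - f_h) <= halfwidth |
                 abs(sp$freq - 2 * f_h) <= halfwidth)
  sig <- sum(p[mask])
  noise <- total - sig
  if (noise <= 0) return(Inf)
  sig / noise
}

#' SpO2 calibration constants
#'
#' Linear ratio-of-ratios calibration `spo2 = A - B * r`. The defaults
#' `A = 125`, `B = 26` are the published camera-oximetry constants for the
#' red/blue channel pair; the formula is unbounded, so estimates are clamped
#' to a physical range (flagged, not an error).
#'
#' @param A offset, percent.
#' @param B slope, percent per unit ratio; must be nonzero.
#' @param clamp `(min_pct, max_pct)` output clamp.
#' @return object of class `spo2_calibration`.
#' @export
spo2_calibration <- function(A = 125, B = 26, clamp = c(0, 100)) {
  stopifnot_scalar_number(A, "A")
  stopifnot_scalar_number(B, "B")
  if (B == 0) abort_config("`B` must be nonzero")
  if (length(clamp) != 2L || clamp[1] > clamp[2])
    abort_config("`clamp` must be an ordered (min, max) pair")
  structure(list(A = A, B = B, clamp = clamp), class = "spo2_calibration")
}

#' DC/AC decomposition of the red and blue channels
#'
#' Over one window, DC is the channel mean and AC the population standard
#' deviation of the raw red and blue traces. A filtered variant (AC from the
#' bandpassed channel) is available via `use_filtered`; raw is the default.
#'
#' @param trace an [rgb_trace()] window.
#' @param use_filtered if `TRUE`, compute AC on the bandpass-filtered
#'   channels (DC stays the raw mean).
#' @param filt optional `fir_filter` for the filtered variant.
#' @return object of class `spo2_components`: `dc_red`, `ac_red`, `dc_blue`,
#'   `ac_blue`, `valid`, `reason` (`"dark_frame"` when a DC is nonpositive).
#' @export
spo2_components <- function(trace, use_filtered = FALSE, filt = NULL) {
  if (trace$n < 1L) abort_empty_input("empty window")
  R <- trace$R; B <- trace$B
  dc_red <- mean(R); dc_blue <- mean(B)
  if (use_filtered) {
    if (is.null(filt)) filt <- design_bandpass(trace$fs, bandpass_spec())
    ac_red <- pop_sd(apply_bandpass(R, filt, mode = "batch"))
    ac_blue <- pop_sd(apply_bandpass(B, filt, mode = "batch"))
  } else {
    ac_red <- pop_sd(R)
    ac_blue <- pop_sd(B)
  }
  valid <- dc_red > 0 && dc_blue > 0
  structure(list(dc_red = dc_red, ac_red = ac_red,
                 dc_blue = dc_blue, ac_blue = ac_blue,
                 valid = valid,
                 reason = if (valid) NA_character_ else "dark_frame"),
            class = "spo2_components")
}

#' Ratio-of-ratios SpO2 estimate
#'
#' `spo2 = A - B * (ac_red/dc_red) / (ac_blue/dc_blue)`, clamped to the
#' calibration's physical range. Clamping is flagged rather than raised.
#'
#' @param components an [spo2_components()].
#' @param cal an [spo2_calibration()].
#' @return list with `spo2_pct`, `ratio`, `clamped`, `valid`, `reason`
#'   (`"no_blue_pulsatility"` when the blue AC is zero).
#' @export
estimate_spo2 <- function(components, cal = spo2_calibration()) {
  if (!inherits(components, "spo2_components"))
    abort_config("`components` must be spo2_components")
  if (!isTRUE(components$valid))
    return(list(spo2_pct = NA_real_, ratio = NA_real_, clamped = FALSE,
                valid = FALSE, reason = components$reason))
  if (components$ac_blue == 0)
    return(list(spo2_pct = NA_real_, ratio = NA_real_, clamped = FALSE,
                valid = FALSE, reason = "no_blue_pulsatility"))
  ratio <- (components$ac_red / components$dc_red) /
           (components$ac_blue / components$dc_blue)
  raw <- cal$A - cal$B * ratio
  spo2 <- min(max(raw, cal$clamp[1]), cal$clamp[2])
  list(spo2_pct = spo2, ratio = ratio, clamped = spo2 != raw,
       valid = TRUE, reason = NA_character_)
}

#' One-shot vitals estimate over a trace window
#'
#' Runs the full chain on a single window: chrominance pulse extraction,
#' FFT heart rate, harmonic-mask SNR, and ratio-of-ratios SpO2 (on the raw
#' channels). The `window` span and validity reasons are carried in the
#' result.
#'
#' @param trace an [rgb_trace()] covering one analysis window (valid samples
#'   only).
#' @param band HR search band `(low_hz, high_hz)`.
#' @param cal an [spo2_calibration()].
#' @param filt optional pre-designed `fir_filter` (saves re-design in loops).
#' @return object of class `vitals_estimate`: `f_h`, `hr_bpm`, `spo2_pct`,
#'   `snr`, `window`, `valid`, `reasons`.
#' @export
estimate_vitals <- function(trace, band = c(0.6, 4.0),
                            cal = spo2_calibration(), filt = NULL) {
  if (is.null(filt)) filt <- design_bandpass(trace$fs, bandpass_spec(band[1], band[2]))
  pulse <- extract_pulse(trace, filt)
  hr <- estimate_hr(pulse, trace$fs, band)
  snr <- if (hr$valid) compute_snr(pulse, trace$fs, hr$f_h, band) else 0
  sp <- estimate_spo2(spo2_components(trace), cal)
  reasons <- stats::na.omit(c(hr$reason, sp$reason))
  structure(list(f_h = hr$f_h, hr_bpm = hr$hr_bpm,
                 spo2_pct = sp$spo2_pct, snr = snr,
                 window = pulse$window,
                 valid = hr$valid && sp$valid,
                 reasons = as.character(reasons)),
            class = "vitals_estimate")
}

#' @export
print.vitals_estimate <- function(x, ...) {
  cat(sprintf("<vitals_estimate> [%.2f, %.2f) s: HR %.1f bpm, SpO2 %.1f%%, snr %.2f%s\n",
              x$window[1], x$window[2], x$hr_bpm, x$spo2_pct, x$snr,
              if (x$valid) "" else paste0(" INVALID (", paste(x$reasons, collapse = ","), ")")))
  invisible(x)
}
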