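# File formats: trace CSV, frame directories (plain-text PPM + JSON sidecar),
# session report JSON, application config.

#' Write an RGB trace as CSV
#'
#' Header `time_s,R,G,B`, one row per frame, full float precision (17
#' significant digits) so a write/read round trip is lossless. Invalid
#' samples are written as empty cells.
#'
#' @param trace an [rgb_trace()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  tt <- trace_times(trace)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
  lines <- c("time_s,R,G,B",
             paste(fmt(tt), fmt(trace$R), fmt(trace$G), fmt(trace$B), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an RGB trace from CSV
#'
#' Expects the `time_s,R,G,B` layout of [write_trace_csv()]. Malformed rows
#' raise a parse error naming the offending line. The sampling rate is
#' inferred from the median timestamp spacing; rows with empty channel cells
#' become invalid samples.
#'
#' @param path CSV file path.
#' @return an [rgb_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) abort_parse("trace CSV has no data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("time_s", "R", "G", "B")))
    abort_parse("line 1: expected header 'time_s,R,G,B'")
  n <- length(lines) - 1L
  tt <- R <- G <- B <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != 4L)
      abort_parse(sprintf("line %d: expected 4 cells, got %d", i + 1L, length(cells)))
    num <- suppressWarnings(as.numeric(cells))
    if (is.na(num[1]) || trimws(cells[1]) == "")
      abort_parse(sprintf("line %d: non-numeric time_s '%s'", i + 1L, cells[1]))
    bad <- which(is.na(num[2:4]) & trimws(cells[2:4]) != "")
    if (length(bad))
      abort_parse(sprintf("line %d: non-numeric cell '%s'", i + 1L, cells[1L + bad[1]]))
    tt[i] <- num[1]; R[i] <- num[2]; G[i] <- num[3]; B[i] <- num[4]
  }
  if (n < 2L) abort_parse("need at least 2 rows to infer the sampling rate")
  fs <- 1 / stats::median(diff(tt))
  valid <- is.finite(R) & is.finite(G) & is.finite(B)
  rgb_trace(R, G, B, fs = fs, t0 = tt[1], valid = valid)
}

# --- plain-text PPM (P3) frames ---------------------------------------------
# The frame-file format is ASCII PPM: portable, dependency-free, text-only.
# Channel values are rounded to integers on the 0-255 scale when written.

write_ppm <- function(frame, path) {
  d <- dim(frame)
  px <- round(pmin(pmax(frame, 0), 255))
  # interleave channels pixel by pixel, row-major
  m <- matrix(aperm(px, c(3, 2, 1)), nrow = 3)
  writeLines(c("P3", paste(d[2], d[1]), "255",
               paste(apply(m, 2, paste, collapse = " "), collapse = " ")),
             path)
  invisible(path)
}

read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(tok) < 4L || tok[1] != "P3") abort_parse(sprintf("%s: not an ASCII PPM", path))
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != 3L * w * h) abort_parse(sprintf("%s: truncated pixel data", path))
  aperm(array(vals, dim = c(3L, w, h)), c(3, 2, 1))
}

#' Write a synthetic frame sequence to a directory
#'
#' Frames become numbered ASCII PPM images (`frame_000000.ppm`, ...) and a
#' JSON sidecar `rois.json` records per-frame ROI and confidence plus the
#' sampling rate and the generating seed. PPM stores integer intensities, so
#' sub-unit channel detail is quantised; round trips are therefore exact only
#' at integer intensities.
#'
#' @param scene result of [generate_frame_sequence()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_frame_dir <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(scene$frames)
  for (k in seq_len(n))
    write_ppm(scene$frames[[k]], file.path(dir, sprintf("frame_%06d.ppm", k - 1L)))
  sidecar <- list(
    fs = scene$fs,
    seed = scene$config$seed,
    rois = lapply(seq_len(n), function(k) {
      r <- scene$rois[[k]]
      list(frame_index = k - 1L, x = r$x, y = r$y, w = r$w, h = r$h,
           confidence = r$confidence)
    }))
  jsonlite::write_json(sidecar, file.path(dir, "rois.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read frames (with timestamps) from a directory
#'
#' Reads numbered PPM frames and, when present, the `rois.json` sidecar.
#' Timestamps are `frame_index / fs`.
#'
#' @param path directory of numbered `.ppm` frames.
#' @param fs sampling rate to assume when no sidecar declares one.
#' @return list with `frames`, `rois`, `fs`, `times`.
#' @export
read_video_frames <- function(path, fs = 30) {
  if (!file.exists(path)) abort_io(sprintf("no such source: %s", path))
  if (!dir.exists(path))
    abort_io(paste("only frame directories are supported as video sources;",
                   "decode containers to numbered PPM frames first"))
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.ppm$", full.names = TRUE))
  if (length(files) == 0L) abort_empty_input(sprintf("no frames in %s", path))
  frames <- lapply(files, read_ppm)
  side <- file.path(path, "rois.json")
  rois <- NULL
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side)
    if (!is.null(sc$fs)) fs <- sc$fs
    rois <- lapply(sc$rois, function(r)
      face_observation(r$x, r$y, r$w, r$h, confidence = r$confidence))
  }
  if (is.null(rois)) {
    d <- dim(frames[[1]])
    rois <- rep(list(face_observation(0, 0, d[2], d[1], confidence = 1)),
                length(frames))
  }
  list(frames = frames, rois = rois, fs = fs,
       times = (seq_along(frames) - 1L) / fs)
}

# --- session reports ---------------------------------------------------------

#' Write a session report as JSON
#'
#' The report carries the config snapshot and seed for reproducibility, the
#' per-window estimates, and the trigger log.
#'
#' @param session an [rppg_session()] after streaming.
#' @param path output JSON path.
#' @param seed the seed the input was generated with (recorded only).
#' @return invisibly, the report list.
#' @export
write_session_report <- function(session, path, seed = NA) {
  cfg <- session$cfg
  report <- list(
    seed = seed,
    config = list(window_s = cfg$window_s, stride_s = cfg$stride_s,
                  stabilization_s = cfg$stabilization_s,
                  min_valid_s = cfg$min_valid_s, snr_gate = cfg$snr_gate,
                  face_conf_gate = cfg$face_conf_gate,
                  hr_band = cfg$hr_band,
                  spo2_A = cfg$spo2_cal$A, spo2_B = cfg$spo2_cal$B,
                  band_low_hz = cfg$fir$low_hz, band_high_hz = cfg$fir$high_hz),
    fs = session$fs,
    phase = session$phase,
    valid_seconds = session$valid_seconds,
    windows = lapply(session$estimates, function(e)
      list(t_start = e$t_start, t_end = e$t_end, hr_bpm = e$hr_bpm,
           spo2_pct = e$spo2_pct, snr = e$snr, valid = e$valid,
           reasons = as.list(e$reasons))),
    trigger_log = session$trigger_log
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(report)
}

#' Check a session report against the shipped field contract
#'
#' @param report a parsed report list (e.g. `jsonlite::read_json(path)`).
#' @return `TRUE`, or a parse error naming the missing field.
#' @export
validate_session_report <- function(report) {
  need <- c("seed", "config", "fs", "phase", "valid_seconds", "windows",
            "trigger_log")
  miss <- setdiff(need, names(report))
  if (length(miss)) abort_parse(paste("report missing fields:",
                                      paste(miss, collapse = ", ")))
  cfg_need <- c("window_s", "stride_s", "stabilization_s", "min_valid_s",
                "snr_gate", "face_conf_gate", "hr_band")
  miss <- setdiff(cfg_need, names(report$config))
  if (length(miss)) abort_parse(paste("report config missing:",
                                      paste(miss, collapse = ", ")))
  for (w in report$windows) {
    wm <- setdiff(c("t_start", "t_end", "hr_bpm", "spo2_pct", "snr", "valid"),
                  names(w))
    if (length(wm)) abort_parse(paste("window record missing:",
                                      paste(wm, collapse = ", ")))
  }
  TRUE
}

# --- application config ------------------------------------------------------

app_config_defaults <- function() {
  list(window_s = 2.0, stride_s = 1.0, stabilization_s = 26,
       min_valid_s = 8, snr_gate = 0.7, face_conf_gate = 0.70,
       band_low_hz = 0.6, band_high_hz = 4.0, fir_order = NA,
       spo2_A = 125, spo2_B = 26, spo2_clamp = c(0, 100),
       affect_votes = 30, seed = 1, language = "en")
}

#' Load an application config (JSON key-value file)
#'
#' Unknown keys are rejected with a message; missing keys take the
#' documented defaults.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return named list of validated settings.
#' @export
load_app_config <- function(path = NULL) {
  cfg <- app_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_io(sprintf("no such config: %s", path))
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      abort_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
    cfg[names(user)] <- user
  }
  cfg
}

app_session_config <- function(cfg) {
  session_config(
    window_s = cfg$window_s, stride_s = cfg$stride_s,
    stabilization_s = cfg$stabilization_s, min_valid_s = cfg$min_valid_s,
    snr_gate = cfg$snr_gate, face_conf_gate = cfg$face_conf_gate,
    hr_band = c(cfg$band_low_hz, cfg$band_high_hz),
    affect_votes = cfg$affect_votes,
    spo2_cal = spo2_calibration(cfg$spo2_A, cfg$spo2_B, cfg$spo2_clamp),
    fir = bandpass_spec(cfg$band_low_hz, cfg$band_high_hz,
                        order = if (is.na(cfg$fir_order)) NULL else cfg$fir_order))
}
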