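# Time alignment between the photo stream and the motion-sensor stream:
# each frame (or window center) gets a fixed-width sensor window centered on
# its timestamp, producing fixed-length 6-channel segments for the recurrent
# motion-state classifier. Windows are half-open [tc - tw/2, tc + tw/2) so
# that adjacent non-overlapping windows partition time.

SENSOR_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct a 6-channel motion-sensor stream
#'
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param channels numeric matrix with one row per sample and six columns
#'   (3-axis accelerometer in m/s^2, 3-axis gyroscope in rad/s), or a
#'   data.frame with columns `ax, ay, az, gx, gy, gz`.
#' @param fs sampling frequency in Hz (default 90, the device rate).
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(timestamps, channels, fs = 90) {
  timestamps <- as.numeric(timestamps)
  if (is.data.frame(channels)) channels <- as.matrix(channels[, SENSOR_CHANNELS])
  channels <- as.matrix(channels)
  if (length(timestamps) == 0L) stop_hf("empty stream", class = "hf_invalid")
  if (ncol(channels) != 6L) stop_hf("expected 6 channels", class = "hf_invalid")
  if (nrow(channels) != length(timestamps))
    stop_hf("channel length differs from timestamps", class = "hf_invalid")
  if (any(diff(timestamps) <= 0))
    stop_hf("timestamps must be strictly increasing", class = "hf_invalid")
  if (fs <= 0) stop_hf("fs must be positive", class = "hf_invalid")
  colnames(channels) <- SENSOR_CHANNELS
  structure(list(timestamps = timestamps, channels = channels, fs = fs),
            class = "sensor_stream")
}

#' Read a sensor stream from CSV
#'
#' Columns `t, ax, ay, az, gx, gy, gz` (header required; seconds, m/s^2,
#' rad/s).
#'
#' @param path CSV path.
#' @param fs sampling frequency in Hz.
#' @return a [sensor_stream()].
#' @export
read_sensor_csv <- function(path, fs = 90) {
  d <- utils::read.csv(path)
  need <- c("t", SENSOR_CHANNELS)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_hf("sensor CSV missing column(s): %s",
                            paste(miss, collapse = ", "), class = "hf_invalid")
  sensor_stream(d$t, d[, SENSOR_CHANNELS], fs = fs)
}

#' Write a sensor stream to CSV
#' @param stream a [sensor_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  utils::write.csv(data.frame(t = stream$timestamps, stream$channels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Time window centered on a frame timestamp
#'
#' @param t_c window center in seconds (a frame's shooting time).
#' @param t_w window width in seconds (default 3).
#' @return an object of class `time_window` with half-open span
#'   `[t_c - t_w/2, t_c + t_w/2)`.
#' @export
#' @examples
#' window_for_frame(10, 3) # span [8.5, 11.5)
window_for_frame <- function(t_c, t_w = 3) {
  if (!is.numeric(t_w) || t_w <= 0) stop_hf("t_w must be positive", class = "hf_invalid")
  structure(list(t_c = as.numeric(t_c), t_w = as.numeric(t_w),
                 start = t_c - t_w / 2, end = t_c + t_w / 2),
            class = "time_window")
}

#' Do two time windows overlap?
#'
#' Half-open spans: windows that merely touch do not overlap.
#'
#' @param w1,w2 [window_for_frame()] objects.
#' @return logical.
#' @export
windows_overlap <- function(w1, w2) {
  stopifnot(inherits(w1, "time_window"), inherits(w2, "time_window"))
  w1$start < w2$end && w2$start < w1$end
}

#' Extract a fixed-length sensor segment for a time window
#'
#' Always returns exactly `L = round(fs * t_w)` rows. Samples are addressed
#' by nearest-sample index computed from `fs` (deterministic under timestamp
#' jitter); rows falling outside the recorded stream are filled by edge
#' replication and flagged in `pad_flags`.
#'
#' @param stream a [sensor_stream()].
#' @param window a [window_for_frame()].
#' @return an object of class `sensor_segment`: list with `samples`
#'   (L x 6 matrix), `window`, `pad_flags` (logical length L), `fs`.
#' @export
extract_segment <- function(stream, window) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(window, "time_window"))
  fs <- stream$fs
  L <- as.integer(round(fs * window$t_w))
  t0 <- stream$timestamps[1L]
  n <- length(stream$timestamps)
  if (window$end <= t0 || window$start >= stream$timestamps[n] + 1 / fs)
    stop_hf("window [%g, %g) does not intersect stream", window$start,
            window$end, class = "hf_empty_extraction")
  # sample slots at the window's own grid, mapped to nearest stream indices
  slot_times <- window$start + (seq_len(L) - 0.5) / fs
  idx <- as.integer(floor((slot_times - t0) * fs + 1e-9)) + 1L
  pad <- idx < 1L | idx > n
  idx <- pmin(pmax(idx, 1L), n)
  seg <- stream$channels[idx, , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(samples = seg, window = window, pad_flags = pad, fs = fs),
            class = "sensor_segment")
}

#' Segment a continuous stream into fixed-width windows
#'
#' Window centers are placed at `(k + 0.5) * dc` for `k = 0 .. floor(D/dc) - 1`
#' where `D` is the stream duration, giving exactly `floor(D/dc)` segments
#' (15 for a 15 s stream at 1 s spacing). For `dc < t_w` adjacent windows
#' overlap; boundary windows are clipped and edge-padded.
#'
#' @param stream a [sensor_stream()].
#' @param t_w window width in seconds.
#' @param dc spacing of window centers in seconds.
#' @return list of [extract_segment()] results.
#' @export
segment_stream <- function(stream, t_w = 3, dc = 1) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (t_w <= 0 || dc <= 0) stop_hf("t_w and dc must be positive", class = "hf_invalid")
  n <- length(stream$timestamps)
  D <- stream$timestamps[n] - stream$timestamps[1L] + 1 / stream$fs
  k <- floor(D / dc + 1e-9)
  if (k < 1L) stop_hf("stream shorter than one spacing interval", class = "hf_invalid")
  centers <- stream$timestamps[1L] + (seq_len(k) - 0.5) * dc
  lapply(centers, function(tc)
    extract_segment(stream, window_for_frame(tc, t_w)))
}

#' Associate photo-stream frames with sensor segments
#'
#' For every frame in the manifest, extracts the sensor window centered on
#' its timestamp. Frames whose window does not intersect the stream are
#' skipped with a warning and counted.
#'
#' @param stream a [sensor_stream()].
#' @param manifest data.frame with columns `t` (frame timestamp, seconds),
#'   `payload` (opaque: image path, feature-row id, or a list column of
#'   feature vectors) and optionally `label`.
#' @param t_w window width in seconds.
#' @return list with `samples` (list of aligned samples, each a list with
#'   `segment`, `payload`, `label`, `t`) and `n_skipped`.
#' @export
associate_frames <- function(stream, manifest, t_w = 3) {
  stopifnot(inherits(stream, "sensor_stream"), is.data.frame(manifest))
  if (!"t" %in% names(manifest)) stop_hf("manifest needs a 't' column", class = "hf_invalid")
  out <- vector("list", nrow(manifest))
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    w <- window_for_frame(manifest$t[i], t_w)
    seg <- tryCatch(extract_segment(stream, w), hf_empty_extraction = function(e) NULL)
    if (is.null(seg)) { skipped <- skipped + 1L; next }
    out[[i]] <- list(segment = seg,
                     payload = if ("payload" %in% names(manifest)) manifest$payload[[i]] else NULL,
                     label = if ("label" %in% names(manifest)) manifest$label[[i]] else NA_character_,
                     t = manifest$t[i])
  }
  if (skipped > 0L)
    warning(sprintf("associate_frames: skipped %d frame(s) with no sensor coverage", skipped))
  list(samples = Filter(Negate(is.null), out), n_skipped = skipped)
}
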