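#' Construct an audio clip
#'
#' The in-memory representation of one mono recording: a dimensionless
#' amplitude series in `[-1, 1]` plus its sampling rate.
#'
#' @param samples Numeric vector of finite samples.
#' @param sample_rate Sampling rate in Hz.
#' @param source_id Label identifying the recording.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, source_id = "clip") {
  if (length(samples) == 0) stop("audio_clip: empty sample vector")
  if (!all(is.finite(samples))) stop("audio_clip: non-finite samples")
  if (sample_rate <= 0) stop("audio_clip: sample_rate must be positive")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 source_id = source_id),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Split a clip into fixed-length frames
#'
#' Frames are the atomic classification unit: 10 ms blocks by default,
#' non-overlapping (hop = frame length). The frame sample count is
#' `floor(frame_ms * sample_rate / 1000)`; a trailing remainder shorter than
#' one frame is discarded, so the frame count is
#' `floor((n - frame_len) / hop_len) + 1`.
#'
#' @param clip An [audio_clip].
#' @param frame_ms Frame length in milliseconds (default 10).
#' @param hop_ms Hop between frame starts in milliseconds (default =
#'   `frame_ms`, i.e. contiguous frames).
#' @param pre_emphasis Optional pre-emphasis coefficient (first-difference
#'   filter `x[n] - a*x[n-1]`); `0` (default) disables it.
#' @return An object of class `frame_series`: a list with `frames` (matrix,
#'   one row per frame), `frame_length_ms`, `hop_ms`, `sample_rate`,
#'   `n_frames` and `source_id`.
#' @export
frame_signal <- function(clip, frame_ms = 10, hop_ms = frame_ms,
                         pre_emphasis = 0) {
  stopifnot(inherits(clip, "audio_clip"), frame_ms > 0, hop_ms > 0)
  x <- clip$samples
  if (pre_emphasis > 0) x <- c(x[1], x[-1] - pre_emphasis * x[-length(x)])
  frame_len <- floor(frame_ms * clip$sample_rate / 1000)
  hop_len <- floor(hop_ms * clip$sample_rate / 1000)
  n <- length(x)
  if (n < frame_len)
    stop("frame_signal: clip shorter than one frame (", n, " < ", frame_len, " samples)")
  s <- (n - frame_len) %/% hop_len + 1L
  starts <- (seq_len(s) - 1L) * hop_len
  idx <- outer(starts, seq_len(frame_len), `+`)
  frames <- matrix(x[idx], nrow = s, ncol = frame_len)
  structure(list(frames = frames,
                 frame_length_ms = frame_ms,
                 hop_ms = hop_ms,
                 sample_rate = clip$sample_rate,
                 n_frames = s,
                 source_id = clip$source_id),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series '%s': %d frames of %g ms (hop %g ms) @ %g Hz>\n",
              x$source_id, x$n_frames, x$frame_length_ms, x$hop_ms,
              x$sample_rate))
  invisible(x)
}

#' Frame start times
#'
#' @param fs A `frame_series`.
#' @return Numeric vector of frame start times in seconds.
#' @export
frame_times <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  hop_len <- floor(fs$hop_ms * fs$sample_rate / 1000)
  (seq_len(fs$n_frames) - 1) * hop_len / fs$sample_rate
}
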