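# Beep trimming, 3 s segmentation, Butterworth band-pass filtering, z-score.

#' Remove the beep padding from a recording
#'
#' Drops `pad_s` seconds from both ends, leaving the central task block
#' (a 16 s recording at 256 Hz becomes 2560 x 14).
#'
#' @param recording A `bci_recording`.
#' @param pad_s Padding duration removed from each end, seconds.
#' @return The trimmed `bci_recording`.
#' @export
trim_beeps <- function(recording, pad_s = 3) {
  stopifnot(inherits(recording, "bci_recording"), pad_s >= 0)
  n <- nrow(recording$samples)
  pad <- round(pad_s * recording$fs)
  if (n < 2 * pad + 1)
    stop("recording too short: ", n, " samples cannot lose 2 x ", pad)
  if (pad > 0)
    recording$samples <- recording$samples[(pad + 1):(n - pad), , drop = FALSE]
  recording
}

#' Cut a task block into 3 s analysis segments
#'
#' Windows of `window_s` seconds at equally spaced starts with hop `hop_s`
#' (defaults 3 s / 1.75 s: a 10 s block at 256 Hz yields five 768-sample
#' segments starting at samples 0, 448, 896, 1344, 1792). Each segment keeps
#' its parent recording's metadata plus a 0-based `window_index` and
#' `start_sample`, so segmentation is lossless in provenance.
#'
#' @param recording A trimmed `bci_recording`.
#' @param window_s Window length, seconds.
#' @param hop_s Hop between window starts, seconds.
#' @return List of `bci_segment` objects (empty, with a warning, if the block
#'   is shorter than one window).
#' @export
segment_recording <- function(recording, window_s = 3, hop_s = 1.75) {
  stopifnot(inherits(recording, "bci_recording"))
  fs <- recording$fs
  win <- round(window_s * fs)
  hop <- round(hop_s * fs)
  n <- nrow(recording$samples)
  if (n < win) {
    warning("task block shorter than one analysis window; no segments")
    return(list())
  }
  starts <- seq(0L, n - win, by = hop)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    structure(list(samples = recording$samples[(s + 1):(s + win), , drop = FALSE],
                   fs = fs, window_index = i - 1L, start_sample = s,
                   meta = recording$meta),
              class = "bci_segment")
  })
}

#' @export
print.bci_segment <- function(x, ...) {
  cat(sprintf("<bci_segment> window %d (start %d), %d x %d @ %g Hz\n",
              x$window_index, x$start_sample, nrow(x$samples),
              ncol(x$samples), x$fs))
  invisible(x)
}

#' Band-pass filter specification
#'
#' A Butterworth band-pass of the given order. `mode = "causal"` applies a
#' single forward pass (as in the gate path); `mode = "zero_phase"` applies
#' forward-backward filtering with zero net phase (as in the trajectory
#' path). The packaged defaults are [stage1_filter()] (1-15 Hz, causal) and
#' [stage2_filter()] (1-45 Hz, zero-phase), both fifth order.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high`.
#' @param order Filter order.
#' @param mode `"causal"` or `"zero_phase"`.
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 5,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 mode = mode),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
stage1_filter <- function() filter_spec(1, 15, 5, "causal")

#' @rdname filter_spec
#' @export
stage2_filter <- function() filter_spec(1, 45, 5, "zero_phase")

#' Apply a Butterworth band-pass filter
#'
#' @param x A `bci_segment`, `bci_recording`, matrix (columns = channels),
#'   or numeric vector.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz (taken from `x` when it carries one).
#' @return The filtered object, same shape as the input.
#' @export
bandpass <- function(x, spec, fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, c("bci_segment", "bci_recording"))) {
    x$samples <- bandpass(x$samples, spec, fs = x$fs)
    return(x)
  }
  if (is.null(fs)) stop("'fs' is required for matrix or vector input")
  if (spec$high_hz >= fs / 2)
    stop("band edges must lie inside (0, fs/2)")
  bt <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  ff <- if (spec$mode == "zero_phase")
    # forward-backward pass over an odd-reflection extension of the signal,
    # so start-up transients decay inside the padding, not the data
    function(v) {
      n <- length(v)
      npad <- n - 1
      ext <- c(2 * v[1] - v[(npad + 1):2], v,
               2 * v[n] - v[(n - 1):(n - npad)])
      signal::filtfilt(bt, ext)[(npad + 1):(npad + n)]
    }
  else
    function(v) as.numeric(signal::filter(bt, v))
  if (is.matrix(x)) {
    out <- apply(x, 2, ff)
    dimnames(out) <- dimnames(x)
    out
  } else {
    ff(as.numeric(x))
  }
}

#' Z-score normalization
#'
#' Centers to mean zero and scales to unit standard deviation. A
#' zero-variance input returns all zeros with a warning, so degenerate
#' inputs do not abort batch runs.
#'
#' @param x Numeric vector with at least two values.
#' @return The standardized vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("zscore needs at least two values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance input to zscore; returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}
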