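# Welch PSD estimation and the five-band, eight-statistic feature bank.

#' Welch estimator configuration
#'
#' Defaults follow the analysis configuration: Hamming window of 637 samples
#' with 636-sample overlap (hop 1), so a 768-sample segment yields
#' K = 132 averaged periodograms at a frequency resolution of
#' fs / 637 (about 0.402 Hz at 256 Hz). `nfft` equals the window length
#' (no zero padding).
#'
#' @param fs Sampling rate in Hz.
#' @param window_len Window length L in samples.
#' @param noverlap Overlap between consecutive windows, samples (`< L`).
#' @param window Window function: `"hamming"` (DFT-even,
#'   `0.54 - 0.46 cos(2 pi n / L)`) or `"rect"`.
#' @return A list of class `"welch_config"`.
#' @export
welch_config <- function(fs, window_len = 637, noverlap = 636,
                         window = c("hamming", "rect")) {
  window <- match.arg(window)
  if (!(noverlap >= 0 && noverlap < window_len))
    stop("'noverlap' must be in [0, window_len)")
  structure(list(fs = fs, window_len = as.integer(window_len),
                 noverlap = as.integer(noverlap), window = window,
                 nfft = as.integer(window_len)),
            class = "welch_config")
}

# window sample values (DFT-even)
.welch_window <- function(cfg) {
  n <- 0:(cfg$window_len - 1)
  switch(cfg$window,
         hamming = 0.54 - 0.46 * cos(2 * pi * n / cfg$window_len),
         rect    = rep(1, cfg$window_len))
}

# frequency-domain taps (c0, c1) with w[n] = c0 + 2*c1*cos(2*pi*n/L)
.welch_taps <- function(cfg) {
  switch(cfg$window, hamming = c(0.54, -0.23), rect = c(1, 0))
}

# Batched Welch PSD over the columns of X (time x signals).
# Returns list(freq, power [nbins x ncol], df, K).
.welch_psd_matrix <- function(X, cfg) {
  X <- as.matrix(X)
  L <- cfg$window_len
  hop <- L - cfg$noverlap
  N <- nrow(X)
  if (L > N) stop("window_len exceeds data length (", N, " samples)")
  K <- (N - L) %/% hop + 1L
  nbins <- L %/% 2L + 1L
  Uk0 <- mvfft(X[1:L, , drop = FALSE])[1:(nbins + 1L), , drop = FALSE]
  acc <- .welch_accum(Uk0, X, L, as.integer(hop), as.integer(K),
                      .welch_taps(cfg))
  w <- .welch_window(cfg)
  U <- mean(w^2)
  P <- acc / (K * L * U * cfg$fs)
  scale <- rep(2, nbins)
  scale[1] <- 1
  if (L %% 2L == 0L) scale[nbins] <- 1   # Nyquist bin present for even L
  P <- P * scale
  list(freq = (0:(nbins - 1L)) * cfg$fs / L, power = P,
       df = cfg$fs / L, K = K)
}

#' Welch power spectral density of one channel
#'
#' Averaged modified periodograms over overlapping windows: with the default
#' configuration a 768-sample segment is covered by 132 sliding windows of
#' 637 samples (hop 1). The estimate is one-sided, scaled as a density
#' (power per Hz), so the df-weighted sum approximates the signal's mean
#' square power.
#'
#' @param x Numeric vector (one channel of a filtered segment).
#' @param cfg A [welch_config()].
#' @return A list of class `"bci_psd"` with `freq` (Hz), `power`
#'   (microvolt^2 per Hz), `df`, `K`, `fs`.
#' @export
welch_psd <- function(x, cfg) {
  stopifnot(inherits(cfg, "welch_config"))
  r <- .welch_psd_matrix(matrix(as.numeric(x), ncol = 1), cfg)
  structure(list(freq = r$freq, power = as.numeric(r$power), df = r$df,
                 K = r$K, fs = cfg$fs),
            class = "bci_psd")
}

#' @export
print.bci_psd <- function(x, ...) {
  cat(sprintf("<bci_psd> %d bins, df = %.4f Hz, K = %d windows\n",
              length(x$freq), x$df, x$K))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Contiguous half-open bands `[lo, hi)`; the upper band (gamma) closes at
#' 45 Hz inclusive.
#'
#' @return Data frame with columns `band`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo_hz = c(0, 4, 8, 13, 30),
             hi_hz = c(4, 8, 13, 30, 45),
             stringsAsFactors = FALSE)
}

#' Restrict a PSD to a frequency band
#'
#' Keeps bins with `lo_hz <= f < hi_hz` (or `<= hi_hz` when
#' `include_upper = TRUE`, used for the topmost band).
#'
#' @param psd A `bci_psd`.
#' @param lo_hz,hi_hz Band edges in Hz.
#' @param include_upper Close the band at the upper edge.
#' @return A `bci_psd` restricted to the band.
#' @export
band_slice <- function(psd, lo_hz, hi_hz, include_upper = FALSE) {
  stopifnot(inherits(psd, "bci_psd"))
  if (hi_hz <= lo_hz || lo_hz < 0 || lo_hz > max(psd$freq))
    stop("invalid band [", lo_hz, ", ", hi_hz, ")")
  keep <- psd$freq >= lo_hz & (if (include_upper) psd$freq <= hi_hz
                               else psd$freq < hi_hz)
  if (!any(keep)) stop("empty band [", lo_hz, ", ", hi_hz, ")")
  psd$freq <- psd$freq[keep]
  psd$power <- psd$power[keep]
  psd
}

#' Trapezoidal band power
#'
#' Composite trapezoid rule over the PSD bins of a band slice (step = the
#' Welch frequency resolution), giving band power in microvolt^2.
#'
#' @param psd A `bci_psd` (typically a [band_slice()]).
#' @return The area under the PSD over the band.
#' @export
band_trapz <- function(psd) {
  stopifnot(inherits(psd, "bci_psd"))
  if (length(psd$freq) < 2) {
    warning("fewer than two bins in band; trapezoidal area is zero")
    return(0)
  }
  pracma::trapz(psd$freq, psd$power)
}

.STATISTICS <- c("kurtosis", "mean", "skewness", "trapz", "entropy",
                 "variance", "mobility", "complexity")

# Hjorth mobility of a value sequence: sqrt(var(diff) / var)
.hjorth_mobility <- function(p) {
  v <- var(p)
  if (!is.finite(v) || v == 0) return(0)
  sqrt(var(diff(p)) / v)
}

#' The eight per-band statistics
#'
#' Computed on the PSD values of one band slice, in the canonical order
#' kurtosis, mean, skewness, trapz, entropy, variance, mobility, complexity.
#' Kurtosis is excess kurtosis; entropy is the Shannon entropy (natural log)
#' of the slice normalized to a probability vector; mobility and complexity
#' are the Hjorth difference-quotient parameters applied to the PSD value
#' sequence. Degenerate slices follow fixed conventions: zero-variance
#' slices have skewness and kurtosis 0, an all-zero slice has entropy 0.
#'
#' @param psd A `bci_psd` band slice with at least 3 bins.
#' @return Named numeric vector of length 8.
#' @export
band_features <- function(psd) {
  stopifnot(inherits(psd, "bci_psd"))
  p <- psd$power
  if (length(p) < 3) stop("band slice needs at least 3 bins")
  v <- var(p)
  degenerate <- !is.finite(v) || v == 0
  tot <- sum(p)
  ent <- if (tot <= 0) 0 else {
    q <- p / tot
    q <- q[q > 0]
    -sum(q * log(q))
  }
  mob <- .hjorth_mobility(p)
  cmpx <- if (mob == 0) 0 else .hjorth_mobility(diff(p)) / mob
  c(kurtosis   = if (degenerate) 0 else e1071::kurtosis(p),
    mean       = mean(p),
    skewness   = if (degenerate) 0 else e1071::skewness(p),
    trapz      = band_trapz(psd),
    entropy    = ent,
    variance   = if (is.finite(v)) v else 0,
    mobility   = mob,
    complexity = cmpx)
}

#' Feature index layout
#'
#' Feature ids are 1-based and channel-major:
#' `id = 40 * (channel_rank - 1) + 8 * (band_rank - 1) + statistic_rank`,
#' with channels in the order given (default AF3, F7, F8, AF4), bands
#' delta to gamma, and statistics in the canonical order of
#' [band_features()]. E.g. id 42 is F7/delta/mean and id 92 is
#' F8/theta/trapz.
#'
#' @param channels Active channels in layout order.
#' @return Data frame with columns `id`, `channel`, `band`, `statistic`.
#' @export
feature_id_map <- function(channels = ACTIVE_CHANNELS) {
  bands <- eeg_bands()$band
  grid <- expand.grid(statistic = .STATISTICS, band = bands,
                      channel = channels, stringsAsFactors = FALSE)
  data.frame(id = seq_len(nrow(grid)),
             channel = grid$channel, band = grid$band,
             statistic = grid$statistic, stringsAsFactors = FALSE)
}

#' @rdname feature_id_map
#' @param channel,band,statistic Coordinates of one feature.
#' @return `feature_id()`: the integer id.
#' @export
feature_id <- function(channel, band, statistic,
                       channels = ACTIVE_CHANNELS) {
  ci <- match(channel, channels)
  bi <- match(band, eeg_bands()$band)
  si <- match(statistic, .STATISTICS)
  if (any(is.na(c(ci, bi, si))))
    stop("unknown channel, band, or statistic")
  40L * (ci - 1L) + 8L * (bi - 1L) + si
}

# features for pre-computed PSD columns: P is nbins x nch, freq shared
.band_feature_block <- function(freq, P, df, fs, K) {
  bands <- eeg_bands()
  out <- numeric(ncol(P) * 40L)
  k <- 0L
  for (ch in seq_len(ncol(P))) {
    psd <- structure(list(freq = freq, power = P[, ch], df = df,
                          K = K, fs = fs), class = "bci_psd")
    for (b in seq_len(nrow(bands))) {
      sl <- band_slice(psd, bands$lo_hz[b], bands$hi_hz[b],
                       include_upper = b == nrow(bands))
      out[(k + 1L):(k + 8L)] <- band_features(sl)
      k <- k + 8L
    }
  }
  out
}

#' Spectral feature vector of one segment
#'
#' Welch PSD per active channel, five bands, eight statistics per band:
#' 40 features per channel, concatenated channel-major (160 over the four
#' active channels). The segment is expected to be filtered already (the
#' trajectory path uses the 1-45 Hz zero-phase filter).
#'
#' @param segment A `bci_segment` (or a `time x channel` matrix with channel
#'   column names).
#' @param channels Active channels, in feature-layout order.
#' @param cfg A [welch_config()] (defaults to the segment's sampling rate).
#' @return Named numeric vector (`feature_0001`, ...) of length
#'   `40 * length(channels)`.
#' @export
feature_vector <- function(segment, channels = ACTIVE_CHANNELS, cfg = NULL) {
  if (inherits(segment, "bci_segment")) {
    X <- segment$samples
    fs <- segment$fs
  } else {
    X <- as.matrix(segment)
    if (is.null(cfg)) stop("'cfg' is required for matrix input")
    fs <- cfg$fs
  }
  if (is.null(cfg)) cfg <- welch_config(fs)
  missing <- setdiff(channels, colnames(X))
  if (length(missing))
    stop("channel(s) not present in segment: ", paste(missing, collapse = ", "))
  r <- .welch_psd_matrix(X[, channels, drop = FALSE], cfg)
  out <- .band_feature_block(r$freq, r$power, r$df, cfg$fs, r$K)
  names(out) <- sprintf("feature_%04d", seq_along(out))
  out
}
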