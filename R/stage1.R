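# Stage 1: LED (SSVEP) gate from the normalized trapezoidal band-power ratio.

# shared metadata frame for a list of segments
.segment_meta <- function(segments) {
  data.frame(
    subject_id    = vapply(segments, function(s) as.integer(s$meta$subject_id), 1L),
    led_condition = vapply(segments, function(s) s$meta$led_condition, ""),
    trajectory    = vapply(segments, function(s) s$meta$trajectory, ""),
    repetition    = vapply(segments, function(s) as.integer(s$meta$repetition), 1L),
    window_index  = vapply(segments, function(s) as.integer(s$window_index), 1L),
    stringsAsFactors = FALSE)
}

# Filter the requested channels of every segment and estimate their PSDs in
# one batched sliding-DFT pass. Returns list(freq, df, K, power) with power
# nbins x (nseg * nch), segment-major.
.batch_segment_psd <- function(segments, channels, filt, cfg) {
  stopifnot(length(segments) > 0)
  fs <- segments[[1]]$fs
  if (is.null(cfg)) cfg <- welch_config(fs)
  nseg <- length(segments)
  nch <- length(channels)
  nr <- nrow(segments[[1]]$samples)
  X <- matrix(0, nr, nseg * nch)
  for (i in seq_len(nseg)) {
    sm <- segments[[i]]$samples
    missing <- setdiff(channels, colnames(sm))
    if (length(missing))
      stop("channel(s) not present in segment: ",
           paste(missing, collapse = ", "))
    X[, ((i - 1) * nch + 1):(i * nch)] <-
      bandpass(sm[, channels, drop = FALSE], filt, fs = fs)
  }
  r <- .welch_psd_matrix(X, cfg)
  r$fs <- fs
  r
}

# trapezoid areas over [lo, hi) for every column of a PSD matrix
# (uniform grid; equals pracma::trapz bin for bin)
.band_trapz_matrix <- function(freq, P, lo, hi, include_upper = FALSE) {
  keep <- which(freq >= lo & (if (include_upper) freq <= hi else freq < hi))
  if (length(keep) < 2) return(rep(0, ncol(P)))
  sub <- P[keep, , drop = FALSE]
  df <- freq[2] - freq[1]
  df * (colSums(sub) - 0.5 * sub[1, ] - 0.5 * sub[nrow(sub), ])
}

#' Normalized trapezoidal LED-gate feature
#'
#' The ratio z' = trapz(6-8 Hz) / trapz(1-10 Hz) of trapezoidal band powers
#' of one channel's Welch PSD. The 6-8 Hz band brackets the 7 Hz LED
#' response; the 1-10 Hz band is the normalizing reference, so z' is
#' invariant under amplitude scaling and (the numerator band being contained
#' in the denominator band) never exceeds 1 for a non-negative spectrum.
#'
#' @param x A filtered channel vector (stage-1 path: 1-15 Hz causal
#'   Butterworth) or a `bci_psd`.
#' @param cfg A [welch_config()] (required for vector input).
#' @return List of class `"led_ratio"` with `theta_area` (6-8 Hz),
#'   `rho_area` (1-10 Hz) and `ratio`.
#' @export
led_ratio <- function(x, cfg = NULL) {
  psd <- if (inherits(x, "bci_psd")) x else {
    if (is.null(cfg)) stop("'cfg' is required for vector input")
    welch_psd(x, cfg)
  }
  # closed intervals: [6, 8] and [1, 10] are integration ranges
  theta <- band_trapz(band_slice(psd, 6, 8, include_upper = TRUE))
  rho <- band_trapz(band_slice(psd, 1, 10, include_upper = TRUE))
  if (rho == 0) stop("undefined LED ratio: 1-10 Hz band power is zero")
  structure(list(theta_area = theta, rho_area = rho, ratio = theta / rho),
            class = "led_ratio")
}

#' @export
print.led_ratio <- function(x, ...) {
  cat(sprintf("<led_ratio> z' = %.4f (theta %.4g / rho %.4g)\n",
              x$ratio, x$theta_area, x$rho_area))
  invisible(x)
}

#' Gate feature table: one z' ratio per active channel per segment
#'
#' Applies the stage-1 path (1-15 Hz causal Butterworth, Welch PSD) to every
#' segment and extracts the [led_ratio()] of each active channel.
#'
#' @param segments List of raw `bci_segment`s.
#' @param channels Active channels (one feature column each).
#' @param filt Stage-1 [filter_spec()].
#' @param cfg A [welch_config()] (defaults to the segments' sampling rate).
#' @return List with `features` (`n_segments x length(channels)` matrix of
#'   ratios) and `meta` (per-segment metadata frame).
#' @export
stage1_features <- function(segments, channels = ACTIVE_CHANNELS,
                            filt = stage1_filter(), cfg = NULL) {
  r <- .batch_segment_psd(segments, channels, filt, cfg)
  theta <- .band_trapz_matrix(r$freq, r$power, 6, 8, include_upper = TRUE)
  rho <- .band_trapz_matrix(r$freq, r$power, 1, 10, include_upper = TRUE)
  if (any(rho == 0)) stop("undefined LED ratio: 1-10 Hz band power is zero")
  z <- matrix(theta / rho, ncol = length(channels), byrow = TRUE)
  colnames(z) <- channels
  list(features = z, meta = .segment_meta(segments))
}

#' Train and evaluate the LED gate by repeated stratified holdout
#'
#' Binary classification of illuminated vs non-illuminated segments from the
#' gate feature table: per repeat, a stratified `split` train fraction, a
#' classifier fit, and test-set predictions; per-class and overall accuracy
#' are averaged over repeats. Per-repeat partitions and decisions are stored
#' so the second stage can be evaluated on the same splits.
#'
#' @param features Gate feature matrix (segments x channels).
#' @param labels Two-level factor (conventionally `"illuminated"` /
#'   `"non_illuminated"`).
#' @param classifier `"rf"`, `"svm"`, `"lda"`, or `"knn"`.
#' @param split Training fraction of the holdout.
#' @param repeats Number of reshuffled holdout repetitions.
#' @param seed Integer seed driving all partitioning and classifier RNG.
#' @param strata Optional stratification factor (defaults to `labels`; the
#'   cascade stratifies by LED condition crossed with trajectory).
#' @param ... Passed to the underlying classifier.
#' @return An object of class `"bci_gate"`: averaged `accuracy`, `per_class`
#'   accuracies, `acc_by_repeat`, and `decisions` (per repeat: `train`
#'   logical, test predictions and truths).
#' @export
train_gate <- function(features, labels, classifier = "rf", split = 0.75,
                       repeats = 10, seed = 1, strata = NULL, ...) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    stop("gate training needs both classes present")
  if (is.null(strata)) strata <- labels
  seeds <- .repeat_seeds(seed, repeats)
  decisions <- vector("list", repeats)
  acc <- numeric(repeats)
  per_class <- matrix(0, repeats, nlevels(labels),
                      dimnames = list(NULL, levels(labels)))
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    train <- .stratified_split(strata, split)
    fit <- .fit_classifier(features[train, , drop = FALSE], labels[train],
                           classifier, ...)
    pred <- .predict_classifier(fit, features[!train, , drop = FALSE])
    truth <- factor(labels[!train], levels = levels(labels))
    acc[r] <- accuracy(pred, truth)
    pc <- per_class_accuracy(pred, truth)
    per_class[r, names(pc)] <- pc
    decisions[[r]] <- list(train = train, test_idx = which(!train),
                           pred = pred, truth = truth)
  }
  structure(list(classifier = classifier, split = split, repeats = repeats,
                 seed = seed, levels = levels(labels), labels = labels,
                 accuracy = mean(acc), acc_by_repeat = acc,
                 per_class = colMeans(per_class),
                 decisions = decisions, n = nrow(features)),
            class = "bci_gate")
}

#' @export
print.bci_gate <- function(x, ...) {
  cat(sprintf("<bci_gate> %s, %d repeats: accuracy %.4f\n",
              x$classifier, x$repeats, x$accuracy))
  for (lv in names(x$per_class))
    cat(sprintf("  %-16s %.4f\n", lv, x$per_class[lv]))
  invisible(x)
}
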