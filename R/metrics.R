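# Accuracy, information transfer rate, channel ranking, robustness report.

#' Classification accuracy
#'
#' Correct predictions divided by the total count; `per_class_accuracy()`
#' is the per-class recall (its class-size-weighted mean equals the overall
#' accuracy).
#'
#' @param predictions,truths Equal-length factors or vectors.
#' @return `accuracy()`: a fraction in `[0, 1]`.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths))
    stop("predictions and truths must be non-empty and of equal length")
  mean(as.character(predictions) == as.character(truths))
}

#' @rdname accuracy
#' @return `per_class_accuracy()`: named vector of per-class recalls.
#' @export
per_class_accuracy <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths))
    stop("predictions and truths must be non-empty and of equal length")
  truths <- as.factor(truths)
  vapply(levels(truths), function(lv) {
    idx <- truths == lv
    if (!any(idx)) return(NA_real_)
    mean(as.character(predictions)[idx] == lv)
  }, 1)
}

#' Information transfer rate (bits per minute)
#'
#' Wolpaw/Shannon formulation: bits per selection
#' `Bt = log2(K) + p log2(p) + (1 - p) log2((1 - p) / (K - 1))`, scaled to
#' `ITR = 60 Bt / T`. The `p = 1` case is the analytic limit (`Bt = log2 K`);
#' at chance (`p = 1/K`) the rate is zero; below chance a warning is issued
#' (negative-information regime) but the value is still returned.
#'
#' @param p Accuracy fraction in `(0, 1]` (vectorized).
#' @param K Number of choices available to the user.
#' @param T Seconds per selection (one 3 s analysis segment by default).
#' @return ITR in bits per minute.
#' @examples
#' itr(1, K = 4, T = 3)     # 40 bits/min
#' itr(0.25, K = 4, T = 3)  # 0: chance level for four choices
#' @export
itr <- function(p, K = 4, T = 3) {
  if (any(p <= 0 | p > 1)) stop("'p' must be in (0, 1]")
  if (K < 2 || T <= 0) stop("need K >= 2 and T > 0")
  if (any(p < 1 / K))
    warning("accuracy below chance (1/K): negative information rate")
  bt <- log2(K) +
    ifelse(p == 1, 0, p * log2(p)) +
    ifelse(p == 1, 0, (1 - p) * log2((1 - p) / (K - 1)))
  60 * bt / T
}

#' Per-channel feature tables for channel ranking
#'
#' Extracts, for every montage channel separately, the stage-1 gate feature
#' (the z' ratio) on all segments and the stage-2 trajectory features (40
#' per channel) on the illuminated segments, in one batched pass per path.
#'
#' @param segments List of raw `bci_segment`s.
#' @param channels Channels to evaluate (default: the whole montage).
#' @param filt1,filt2 Stage-1 and stage-2 [filter_spec()]s.
#' @param cfg A [welch_config()].
#' @return An object of class `"bci_channel_features"`: `gate` (segments x
#'   channels ratio matrix), `traj` (named list of per-channel 40-column
#'   matrices over illuminated segments), `meta`, `illuminated`.
#' @export
channel_feature_tables <- function(segments, channels = EMOTIV_CHANNELS,
                                   filt1 = stage1_filter(),
                                   filt2 = stage2_filter(), cfg = NULL) {
  meta <- .segment_meta(segments)
  s1 <- stage1_features(segments, channels, filt1, cfg)
  illuminated <- meta$led_condition == "on"
  r2 <- .batch_segment_psd(segments[illuminated], channels, filt2, cfg)
  blk <- .band_features_matrix(r2$freq, r2$power)     # 40 x (nseg_on * nch)
  nch <- length(channels)
  n_on <- sum(illuminated)
  traj <- lapply(seq_len(nch), function(ch) {
    cols <- (seq_len(n_on) - 1) * nch + ch
    t(blk[, cols, drop = FALSE])
  })
  names(traj) <- channels
  structure(list(gate = s1$features, traj = traj, meta = meta,
                 illuminated = illuminated),
            class = "bci_channel_features")
}

#' Rank channels by single-channel classification accuracy
#'
#' For each channel alone: the LED-gate accuracy (illuminated vs
#' non-illuminated, from that channel's z' ratio) and the four-class
#' trajectory accuracy (from that channel's 40 spectral features on
#' illuminated segments), each by repeated stratified holdout pooled over
#' subjects and averaged over repeats. The ranking score is the mean of the
#' two accuracies.
#'
#' @param x A `bci_channel_features` object (see [channel_feature_tables()])
#'   or a list of raw `bci_segment`s.
#' @param classifier,split,repeats,seed As in [train_gate()].
#' @param ... Passed to the underlying classifier.
#' @return An object of class `"bci_channel_ranking"`: a data frame with
#'   one row per channel (`gate_accuracy`, `trajectory_accuracy`, `score`),
#'   sorted by decreasing score.
#' @export
channel_ranking <- function(x, classifier = "rf", split = 0.75, repeats = 10,
                            seed = 1, ...) {
  if (!inherits(x, "bci_channel_features")) x <- channel_feature_tables(x)
  channels <- colnames(x$gate)
  led <- factor(ifelse(x$meta$led_condition == "on",
                       "illuminated", "non_illuminated"))
  traj_lab <- droplevels(as.factor(x$meta$trajectory[x$illuminated]))
  seeds <- .repeat_seeds(seed, repeats)
  gate_acc <- traj_acc <- matrix(0, repeats, length(channels))
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    tr_g <- .stratified_split(led, split)
    tr_t <- .stratified_split(traj_lab, split)
    for (ch in seq_along(channels)) {
      fg <- .fit_classifier(x$gate[tr_g, ch, drop = FALSE], led[tr_g],
                            classifier, ...)
      gate_acc[r, ch] <- accuracy(
        .predict_classifier(fg, x$gate[!tr_g, ch, drop = FALSE]), led[!tr_g])
      ft <- .fit_classifier(x$traj[[ch]][tr_t, , drop = FALSE],
                            traj_lab[tr_t], classifier, ...)
      traj_acc[r, ch] <- accuracy(
        .predict_classifier(ft, x$traj[[ch]][!tr_t, , drop = FALSE]),
        traj_lab[!tr_t])
    }
  }
  out <- data.frame(channel = channels,
                    gate_accuracy = colMeans(gate_acc),
                    trajectory_accuracy = colMeans(traj_acc),
                    stringsAsFactors = FALSE)
  out$score <- (out$gate_accuracy + out$trajectory_accuracy) / 2
  out <- out[order(out$score, decreasing = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("bci_channel_ranking", "data.frame")
  out
}

#' Single-subject robustness report
#'
#' Repeated holdout on one subject's gate features, reporting training and
#' test accuracy per trial and per classifier, with an over/under-fitting
#' flag when the averaged train-test gap exceeds a threshold.
#'
#' @param features One subject's feature matrix.
#' @param labels Class labels.
#' @param classifiers Classifiers to evaluate.
#' @param trials Number of holdout trials.
#' @param split,seed As in [train_gate()].
#' @param gap_threshold Flag threshold on the train-test gap, in accuracy
#'   percentage points.
#' @param ... Passed to the underlying classifiers.
#' @return An object of class `"bci_robustness"`: data frame with one row
#'   per classifier and trial (`train_accuracy`, `test_accuracy`, percent),
#'   with per-classifier averages and flags in `attr(, "summary")`.
#' @export
robustness_report <- function(features, labels,
                              classifiers = c("svm", "knn", "lda", "rf"),
                              trials = 10, split = 0.75, seed = 1,
                              gap_threshold = 10, ...) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  rows <- list()
  for (clf in classifiers) {
    seeds <- .repeat_seeds(seed, trials)   # same partitions per classifier
    for (tr in seq_len(trials)) {
      set.seed(seeds[tr])
      train <- .stratified_split(labels, split)
      fit <- .fit_classifier(features[train, , drop = FALSE], labels[train],
                             clf, ...)
      rows[[length(rows) + 1]] <- data.frame(
        classifier = clf, trial = tr,
        train_accuracy = 100 * accuracy(
          .predict_classifier(fit, features[train, , drop = FALSE]),
          labels[train]),
        test_accuracy = 100 * accuracy(
          .predict_classifier(fit, features[!train, , drop = FALSE]),
          labels[!train]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  avg <- aggregate(cbind(train_accuracy, test_accuracy) ~ classifier,
                   out, mean)
  avg$gap <- avg$train_accuracy - avg$test_accuracy
  avg$flagged <- abs(avg$gap) > gap_threshold
  attr(out, "summary") <- avg
  attr(out, "gap_threshold") <- gap_threshold
  class(out) <- c("bci_robustness", "data.frame")
  out
}

#' @export
print.bci_robustness <- function(x, ...) {
  cat("<bci_robustness> per-trial holdout accuracies (%)\n")
  print.data.frame(x, digits = 4)
  cat("\nAverages:\n")
  print.data.frame(attr(x, "summary"), digits = 4)
  invisible(x)
}
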