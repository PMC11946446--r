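# Stage 2: four-class trajectory classification on gate-passed illuminated
# segments, with ANOVA feature ranking and the consensus 16-feature set.

# Vectorized band statistics over the columns of a PSD matrix.
# Returns a (40 x ncol) matrix in the canonical feature order; agrees with
# band_features() column by column.
.band_features_matrix <- function(freq, P, bands = eeg_bands()) {
  nc <- ncol(P)
  out <- matrix(0, 8L * nrow(bands), nc)
  df <- freq[2] - freq[1]
  n1 <- function(v) ifelse(is.finite(v) & v > 0, v, NA)
  for (b in seq_len(nrow(bands))) {
    keep <- which(freq >= bands$lo_hz[b] &
                  (if (b == nrow(bands)) freq <= bands$hi_hz[b]
                   else freq < bands$hi_hz[b]))
    M <- P[keep, , drop = FALSE]
    n <- nrow(M)
    m <- colMeans(M)
    Mc <- M - rep(m, each = n)
    m2 <- colMeans(Mc^2)
    m3 <- colMeans(Mc^3)
    m4 <- colMeans(Mc^4)
    ok <- is.finite(m2) & m2 > 0
    skew <- ifelse(ok, m3 / m2^1.5 * ((1 - 1 / n))^1.5, 0)
    kurt <- ifelse(ok, (m4 / m2^2) * (1 - 1 / n)^2 - 3, 0)
    trapz <- df * (colSums(M) - 0.5 * M[1, ] - 0.5 * M[n, ])
    tot <- colSums(M)
    Q <- M / rep(ifelse(tot > 0, tot, 1), each = n)
    ent <- -colSums(ifelse(Q > 0, Q * log(Q), 0))
    ent[tot <= 0] <- 0
    vr <- m2 * n / (n - 1)
    D1 <- M[-1, , drop = FALSE] - M[-n, , drop = FALSE]
    v1 <- apply(D1, 2, var)
    mob <- ifelse(ok & is.finite(v1), sqrt(v1 / vr), 0)
    D2 <- D1[-1, , drop = FALSE] - D1[-(n - 1), , drop = FALSE]
    v2 <- apply(D2, 2, var)
    mob2 <- ifelse(v1 > 0 & is.finite(v2), sqrt(v2 / v1), 0)
    cmpx <- ifelse(mob > 0, mob2 / mob, 0)
    out[(8 * (b - 1) + 1):(8 * b), ] <-
      rbind(kurt, m, skew, trapz, ent, vr, mob, cmpx)
  }
  out
}

#' Trajectory feature table: 40 spectral features per active channel
#'
#' Applies the stage-2 path (1-45 Hz zero-phase Butterworth, Welch PSD,
#' five bands x eight statistics) to every segment, concatenating channels
#' in the canonical layout of [feature_id_map()] (160 columns over the four
#' active channels).
#'
#' @inheritParams stage1_features
#' @param filt Stage-2 [filter_spec()].
#' @return List with `features` (`n_segments x 40*length(channels)` matrix,
#'   columns `feature_0001`, ...), `meta`, and `id_map`.
#' @export
stage2_features <- function(segments, channels = ACTIVE_CHANNELS,
                            filt = stage2_filter(), cfg = NULL) {
  r <- .batch_segment_psd(segments, channels, filt, cfg)
  nch <- length(channels)
  nseg <- length(segments)
  blk <- .band_features_matrix(r$freq, r$power)   # 40 x (nseg*nch)
  feat <- matrix(0, nseg, 40L * nch)
  for (i in seq_len(nseg))
    feat[i, ] <- as.numeric(blk[, ((i - 1) * nch + 1):(i * nch)])
  colnames(feat) <- sprintf("feature_%04d", seq_len(ncol(feat)))
  list(features = feat, meta = .segment_meta(segments),
       id_map = feature_id_map(channels))
}

#' Rank features by one-way ANOVA F statistic
#'
#' For every feature column, the one-way F statistic of the between-group
#' to within-group mean-square ratio over the label groups (the classical
#' completion of the total sum-of-squares decomposition), ranked descending.
#' Features with zero within-group variance are skipped (NA) with a warning.
#'
#' @param features Feature matrix (rows = segments).
#' @param labels Grouping factor (at least 2 groups of at least 2).
#' @return An object of class `"bci_anova"`: a data frame with columns
#'   `feature_id`, `feature`, `F_statistic`, sorted by decreasing F, with
#'   the per-group feature means in `attr(, "group_means")`.
#' @export
anova_rank <- function(features, labels) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  if (k < 2) stop("ANOVA needs at least two groups")
  n_i <- as.numeric(table(labels))
  if (any(n_i < 2)) stop("every group needs at least two observations")
  N <- nrow(features)
  gsum <- rowsum(features, labels)
  gmean <- gsum / n_i
  grand <- colMeans(features)
  ssb <- colSums(n_i * (gmean - rep(grand, each = k))^2)
  sst <- colSums((features - rep(grand, each = N))^2)
  ssw <- pmax(sst - ssb, 0)
  F_stat <- (ssb / (k - 1)) / (ssw / (N - k))
  bad <- ssw == 0
  if (any(bad)) {
    warning(sum(bad), " feature(s) with zero within-group variance skipped")
    F_stat[bad] <- NA
  }
  nm <- colnames(features)
  if (is.null(nm)) nm <- sprintf("feature_%04d", seq_len(ncol(features)))
  ord <- order(F_stat, decreasing = TRUE, na.last = TRUE)
  out <- data.frame(feature_id = ord,
                    feature = nm[ord],
                    F_statistic = F_stat[ord],
                    stringsAsFactors = FALSE)
  attr(out, "group_means") <- gmean
  class(out) <- c("bci_anova", "data.frame")
  out
}

#' The packaged 16-feature consensus set
#'
#' Delta-band mean and skewness plus theta-band trapezoidal power and
#' entropy, on each of the four active channels: the feature subset that the
#' per-subject ANOVA rankings consistently place at the top.
#'
#' @param channels Active channels in layout order.
#' @return Sorted integer vector of 16 feature ids (e.g. 82/83 are the
#'   F8 delta mean/skewness in the default layout).
#' @export
consensus16 <- function(channels = ACTIVE_CHANNELS) {
  ids <- c(feature_id(rep(channels, each = 2), "delta",
                      c("mean", "skewness"), channels),
           feature_id(rep(channels, each = 2), "theta",
                      c("trapz", "entropy"), channels))
  sort(ids)
}

#' Consensus of per-subject feature rankings
#'
#' Counts how often each feature id occurs in the subjects' top-`top_n`
#' ANOVA rankings.
#'
#' @param rankings List of `bci_anova` objects (or integer id vectors), one
#'   per subject.
#' @param top_n Depth of each subject's list to scan.
#' @return List with `counts` (data frame `feature_id`, `count`, decreasing)
#'   and `consensus` (the packaged default set, [consensus16()]).
#' @export
consensus_features <- function(rankings, top_n = 20) {
  stopifnot(length(rankings) >= 1)
  tops <- lapply(rankings, function(r) {
    ids <- if (inherits(r, "bci_anova")) r$feature_id else as.integer(r)
    head(ids, top_n)
  })
  tab <- sort(table(unlist(tops)), decreasing = TRUE)
  counts <- data.frame(feature_id = as.integer(names(tab)),
                       count = as.integer(tab))
  list(counts = counts, consensus = consensus16())
}

#' Accuracy as a function of the number of top-ranked features
#'
#' Starting from the best-ranked feature and adding the next one
#' iteratively, evaluates repeated-holdout accuracy on each nested feature
#' set.
#'
#' @param features Feature matrix.
#' @param labels Class labels.
#' @param ranking A `bci_anova` object or integer id vector (best first).
#' @param classifier,split,repeats,seed As in [train_gate()].
#' @param k_max Largest feature-set size (truncated to the feature count).
#' @param ... Passed to the underlying classifier.
#' @return Data frame with columns `k` and `accuracy`.
#' @export
top_k_curve <- function(features, labels, ranking, classifier = "rf",
                        k_max = 20, split = 0.75, repeats = 5, seed = 1, ...) {
  features <- as.matrix(features)
  ids <- if (inherits(ranking, "bci_anova")) ranking$feature_id
         else as.integer(ranking)
  ids <- ids[!is.na(ids)]
  k_max <- min(k_max, length(ids))
  labels <- droplevels(as.factor(labels))
  acc <- vapply(seq_len(k_max), function(k) {
    sel <- ids[seq_len(k)]
    seeds <- .repeat_seeds(seed + k, repeats)
    mean(vapply(seq_len(repeats), function(r) {
      set.seed(seeds[r])
      train <- .stratified_split(labels, split)
      fit <- .fit_classifier(features[train, sel, drop = FALSE],
                             labels[train], classifier, ...)
      accuracy(.predict_classifier(fit, features[!train, sel, drop = FALSE]),
               labels[!train])
    }, 1))
  }, 1)
  data.frame(k = seq_len(k_max), accuracy = acc)
}

#' Train and evaluate the trajectory stage of the cascade
#'
#' Reuses the gate's per-repeat partitions: in each repeat the trajectory
#' classifier is trained on the illuminated training segments and tested
#' only on the illuminated test segments the gate predicted correctly (the
#' gate-passed set). The overall system accuracy divides the stage-2 correct
#' count by all segments the gate flagged illuminated in that repeat's test
#' set (false positives included), so it equals stage-2 accuracy exactly
#' when the gate is perfect.
#'
#' @param features Stage-2 feature matrix, aligned row-for-row with the
#'   segments the gate was evaluated on.
#' @param labels Trajectory factor (up_down, right_left, left_cross,
#'   right_cross); ignored (may be NA) for non-illuminated rows.
#' @param gate A `bci_gate` fitted on the same rows.
#' @param classifier One of `"rf"`, `"svm"`, `"lda"`, `"knn"`.
#' @param feature_set `"consensus16"`, `"all"`, or an integer id vector.
#' @param seed Integer seed.
#' @param itr_T Seconds per selection for the ITR (one analysis segment).
#' @param illuminated_level The gate label counting as illuminated.
#' @param ... Passed to the underlying classifier.
#' @return An object of class `"bci_stage2"` with averaged `accuracy`,
#'   `per_class`, `system_accuracy`, `itr` (bits/min at the averaged
#'   accuracy), and per-repeat detail in `per_repeat`.
#' @export
train_stage2 <- function(features, labels, gate, classifier = "rf",
                         feature_set = "consensus16", seed = 1, itr_T = 3,
                         illuminated_level = "illuminated", ...) {
  stopifnot(inherits(gate, "bci_gate"))
  features <- as.matrix(features)
  if (nrow(features) != gate$n)
    stop("feature rows (", nrow(features),
         ") do not match the gate's segment count (", gate$n, ")")
  sel <- if (is.numeric(feature_set)) as.integer(feature_set)
         else switch(match.arg(feature_set, c("consensus16", "all")),
                     consensus16 = consensus16(),
                     all = seq_len(ncol(features)))
  labels <- as.factor(labels)
  illum_all <- gate$labels == illuminated_level
  seeds <- .repeat_seeds(seed + 1L, gate$repeats)
  per_repeat <- vector("list", gate$repeats)
  for (r in seq_len(gate$repeats)) {
    d <- gate$decisions[[r]]
    illum <- d$truth == illuminated_level          # within test set
    train_idx <- which(d$train & illum_all & !is.na(labels))
    # gate-passed test set: truly illuminated and predicted illuminated
    passed <- d$test_idx[illum & d$pred == illuminated_level]
    detected <- sum(d$pred == illuminated_level)   # incl. false positives
    if (!length(passed))
      stop("empty gate-passed test set in repeat ", r)
    set.seed(seeds[r])
    fit <- .fit_classifier(features[train_idx, sel, drop = FALSE],
                           droplevels(labels[train_idx]), classifier, ...)
    pred <- .predict_classifier(fit, features[passed, sel, drop = FALSE])
    truth <- factor(as.character(labels[passed]), levels = fit$levels)
    n_corr <- sum(pred == truth)
    per_repeat[[r]] <- list(
      accuracy = n_corr / length(passed),
      per_class = per_class_accuracy(pred, truth),
      n_test = length(passed), n_detected = detected, n_correct = n_corr)
  }
  acc <- vapply(per_repeat, `[[`, 1, "accuracy")
  pc <- colMeans(do.call(rbind, lapply(per_repeat, `[[`, "per_class")))
  sys_acc <- vapply(per_repeat, function(p) p$n_correct / p$n_detected, 1)
  avg_acc <- mean(acc)
  structure(list(classifier = classifier, feature_ids = sel,
                 repeats = gate$repeats,
                 accuracy = avg_acc, acc_by_repeat = acc, per_class = pc,
                 system_accuracy = mean(sys_acc),
                 system_acc_by_repeat = sys_acc,
                 itr = itr(avg_acc, K = length(levels(droplevels(labels))),
                           T = itr_T),
                 itr_T = itr_T, per_repeat = per_repeat),
            class = "bci_stage2")
}

#' @export
print.bci_stage2 <- function(x, ...) {
  cat(sprintf(paste0("<bci_stage2> %s on %d features, %d repeats\n",
                     "  accuracy %.4f | system accuracy %.4f | ",
                     "ITR %.2f bits/min\n"),
              x$classifier, length(x$feature_ids), x$repeats,
              x$accuracy, x$system_accuracy, x$itr))
  invisible(x)
}

#' Overall system accuracy of a fitted cascade
#'
#' Correctly classified trajectory predictions divided by all segments the
#' gate flagged illuminated, averaged over holdout repeats.
#'
#' @param cascade A `bci_stage2` or `bci_cascade` object.
#' @return Fraction in `[0, 1]` (NA with a warning if the gate never fired).
#' @export
overall_system_accuracy <- function(cascade) {
  if (inherits(cascade, "bci_cascade"))
    return(cascade$average$system_accuracy)
  stopifnot(inherits(cascade, "bci_stage2"))
  det <- vapply(cascade$per_repeat, `[[`, 1, "n_detected")
  corr <- vapply(cascade$per_repeat, `[[`, 1, "n_correct")
  if (all(det == 0)) {
    warning("gate never flagged an illuminated segment; accuracy undefined")
    return(NA_real_)
  }
  mean(corr[det > 0] / det[det > 0])
}
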