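# The two-stage cascade: LED gate, then trajectory classification, evaluated
# per subject by repeated stratified holdout.

.TRAJ_LEVELS <- c("up_down", "right_left", "left_cross", "right_cross")

# recordings -> raw 3 s segments (trimming 16 s recordings first)
.cohort_segments <- function(recordings, pad_s = 3) {
  segs <- lapply(recordings, function(rec) {
    if (nrow(rec$samples) / rec$fs > 10 + 1e-9)
      rec <- trim_beeps(rec, pad_s)
    segment_recording(rec)
  })
  unlist(segs, recursive = FALSE)
}

#' Fit and evaluate the two-stage BCI cascade on a cohort
#'
#' The central model of the package. Every recording is trimmed and cut into
#' five 3 s segments; the gate feature (z' band-power ratio per frontal
#' channel, 1-15 Hz causal path) and the trajectory features (40 spectral
#' features per frontal channel, 1-45 Hz zero-phase path) are extracted; then,
#' per subject, the LED gate and the trajectory classifier are evaluated on
#' linked stratified 75/25 holdout splits repeated `repeats` times: the
#' trajectory stage trains on illuminated training segments and is tested
#' only on illuminated test segments the gate passed. Finally both stages
#' are refit on all data so the object can `predict()` new recordings.
#'
#' @param cohort A `bci_cohort` (or plain list of `bci_recording`s) with
#'   subject, LED-condition, and trajectory metadata.
#' @param classifier `"rf"` (default), `"svm"`, `"lda"`, or `"knn"`.
#' @param feature_set `"consensus16"` (the packaged 16-feature consensus
#'   set), `"all"` (all 160), or an integer feature-id vector.
#' @param split Training fraction of each holdout.
#' @param repeats Holdout repetitions averaged per subject.
#' @param seed Integer seed driving all partitioning and classifier RNG.
#' @param itr_T Seconds per selection for the ITR computation.
#' @param channels Active channels used for features.
#' @param filt1,filt2 Stage-1 and stage-2 [filter_spec()]s.
#' @param cfg A [welch_config()] (defaults to the cohort's sampling rate).
#' @param verbose Log stage boundaries with counts.
#' @param ... Passed to the underlying classifier.
#' @return An object of class `"bci_cascade"`; see [print.bci_cascade()],
#'   [summary.bci_cascade()], [predict.bci_cascade()].
#' @export
bci_cascade <- function(cohort, classifier = c("rf", "svm", "lda", "knn"),
                        feature_set = "consensus16", split = 0.75,
                        repeats = 10, seed = 1, itr_T = 3,
                        channels = ACTIVE_CHANNELS,
                        filt1 = stage1_filter(), filt2 = stage2_filter(),
                        cfg = NULL, verbose = FALSE, ...) {
  classifier <- match.arg(classifier)
  say <- function(...) if (verbose) message(sprintf(...))
  segments <- .cohort_segments(cohort)
  say("segmented %d recordings into %d segments", length(cohort),
      length(segments))
  s1 <- stage1_features(segments, channels, filt1, cfg)
  s2 <- stage2_features(segments, channels, filt2, cfg)
  meta <- s1$meta
  led <- factor(ifelse(meta$led_condition == "on",
                       "illuminated", "non_illuminated"),
                levels = c("illuminated", "non_illuminated"))
  traj <- factor(meta$trajectory, levels = .TRAJ_LEVELS)
  say("extracted %d gate features and %d trajectory features per segment",
      ncol(s1$features), ncol(s2$features))

  subjects <- sort(unique(meta$subject_id))
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max, length(subjects))
  gates <- stage2s <- vector("list", length(subjects))
  rows <- vector("list", length(subjects))
  counts <- c(segments_tested = 0, gate_passed = 0, gate_rejected = 0)
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    idx <- meta$subject_id == s
    strata <- interaction(led[idx], traj[idx], drop = TRUE)
    g <- train_gate(s1$features[idx, , drop = FALSE], led[idx], classifier,
                    split = split, repeats = repeats, seed = subj_seeds[i],
                    strata = strata, ...)
    st2 <- train_stage2(s2$features[idx, , drop = FALSE], traj[idx], g,
                        classifier, feature_set, seed = subj_seeds[i],
                        itr_T = itr_T, ...)
    gates[[i]] <- g
    stage2s[[i]] <- st2
    for (d in g$decisions) {
      counts["segments_tested"] <- counts["segments_tested"] + length(d$test_idx)
      counts["gate_passed"] <- counts["gate_passed"] + sum(d$pred == "illuminated")
      counts["gate_rejected"] <- counts["gate_rejected"] +
        sum(d$pred == "non_illuminated")
    }
    rows[[i]] <- data.frame(
      subject = s,
      gate_accuracy = g$accuracy,
      gate_illuminated = unname(g$per_class["illuminated"]),
      gate_non_illuminated = unname(g$per_class["non_illuminated"]),
      stage2_accuracy = st2$accuracy,
      up_down = unname(st2$per_class["up_down"]),
      right_left = unname(st2$per_class["right_left"]),
      left_cross = unname(st2$per_class["left_cross"]),
      right_cross = unname(st2$per_class["right_cross"]),
      itr = st2$itr,
      system_accuracy = st2$system_accuracy,
      system_itr = itr(max(st2$system_accuracy, 1e-12), K = 4, T = itr_T),
      stringsAsFactors = FALSE)
    say("subject %d: gate %.4f, stage2 %.4f, system %.4f", s,
        g$accuracy, st2$accuracy, st2$system_accuracy)
  }
  per_subject <- do.call(rbind, rows)
  average <- list(
    gate_accuracy = mean(per_subject$gate_accuracy),
    stage2_accuracy = mean(per_subject$stage2_accuracy),
    system_accuracy = mean(per_subject$system_accuracy),
    itr_mean_of_subjects = mean(per_subject$itr),
    itr_of_mean_accuracy = itr(mean(per_subject$stage2_accuracy), K = 4,
                               T = itr_T),
    system_itr = mean(per_subject$system_itr))

  # final models on all data, for predict()
  illum <- led == "illuminated"
  sel <- stage2s[[1]]$feature_ids
  set.seed(seed)
  gate_fit <- .fit_classifier(s1$features, led, classifier, ...)
  traj_fit <- .fit_classifier(s2$features[illum, sel, drop = FALSE],
                              traj[illum], classifier, ...)

  structure(list(call = match.call(),
                 classifier = classifier, feature_ids = sel,
                 split = split, repeats = repeats, seed = seed,
                 itr_T = itr_T, channels = channels,
                 per_subject = per_subject, average = average,
                 counts = as.list(counts),
                 n_recordings = length(cohort), n_segments = length(segments),
                 gates = gates, stage2s = stage2s,
                 final_fit = list(gate = gate_fit, trajectory = traj_fit,
                                  filt1 = filt1, filt2 = filt2, cfg = cfg)),
            class = "bci_cascade")
}

#' @export
print.bci_cascade <- function(x, ...) {
  cat("Two-stage SSVEP/EOG cascade\n")
  cat(sprintf("  classifier: %s | features: %d | %d subjects, %d repeats\n",
              x$classifier, length(x$feature_ids), nrow(x$per_subject),
              x$repeats))
  with(x$average, {
    cat(sprintf("  stage 1 (LED gate) accuracy:    %6.2f%%\n",
                100 * gate_accuracy))
    cat(sprintf("  stage 2 (trajectory) accuracy:  %6.2f%% | ITR %.2f bits/min\n",
                100 * stage2_accuracy, itr_mean_of_subjects))
    cat(sprintf("  overall system accuracy:        %6.2f%% | ITR %.2f bits/min\n",
                100 * system_accuracy, system_itr))
  })
  invisible(x)
}

#' Per-subject summary of a fitted cascade
#'
#' @param object A `bci_cascade`.
#' @param ... Unused.
#' @return The per-subject accuracy/ITR table (invisibly), after printing
#'   it together with the cohort averages.
#' @export
summary.bci_cascade <- function(object, ...) {
  cat("Per-subject results (accuracies as fractions):\n")
  print.data.frame(object$per_subject, digits = 4, row.names = FALSE)
  cat("\nCohort averages:\n")
  avg <- object$average
  cat(sprintf(paste0("  gate %.4f | stage2 %.4f | system %.4f\n",
                     "  ITR (mean of subjects) %.2f | ",
                     "ITR (of mean accuracy) %.2f bits/min\n"),
              avg$gate_accuracy, avg$stage2_accuracy, avg$system_accuracy,
              avg$itr_mean_of_subjects, avg$itr_of_mean_accuracy))
  invisible(object$per_subject)
}

#' @export
plot.bci_cascade <- function(x, ...) {
  m <- t(as.matrix(x$per_subject[, c("gate_accuracy", "stage2_accuracy",
                                     "system_accuracy")]))
  graphics::barplot(100 * m, beside = TRUE,
                    names.arg = x$per_subject$subject,
                    col = c("grey30", "steelblue", "orange"),
                    xlab = "subject", ylab = "accuracy (%)",
                    ylim = c(0, 115), ...)
  graphics::legend("top", horiz = TRUE, bty = "n",
                   fill = c("grey30", "steelblue", "orange"),
                   legend = c("LED gate", "trajectory", "overall system"))
  invisible(x)
}

#' Predict new recordings with a fitted cascade
#'
#' Applies the gate to every 3 s segment of the new data; segments the gate
#' predicts non-illuminated produce no trajectory prediction (the system
#' does not activate: `trajectory_pred` is `NA`).
#'
#' @param object A fitted `bci_cascade`.
#' @param newdata A `bci_cohort`, a list of `bci_recording`s or
#'   `bci_segment`s, or a single recording. Recordings longer than 10 s are
#'   beep-trimmed first.
#' @param ... Unused.
#' @return Data frame with one row per segment: the segment's metadata, the
#'   gate prediction, and the trajectory prediction (NA where the gate did
#'   not fire).
#' @export
predict.bci_cascade <- function(object, newdata, ...) {
  if (inherits(newdata, "bci_recording")) newdata <- list(newdata)
  segments <- if (all(vapply(newdata, inherits, TRUE, "bci_segment")))
    newdata
  else
    .cohort_segments(newdata)
  ff <- object$final_fit
  s1 <- stage1_features(segments, object$channels, ff$filt1, ff$cfg)
  gate_pred <- .predict_classifier(ff$gate, s1$features)
  out <- s1$meta
  out$gate_pred <- gate_pred
  out$trajectory_pred <- factor(rep(NA_character_, nrow(out)),
                                levels = .TRAJ_LEVELS)
  passed <- which(gate_pred == "illuminated")
  if (length(passed)) {
    s2 <- stage2_features(segments[passed], object$channels, ff$filt2,
                          ff$cfg)
    out$trajectory_pred[passed] <- .predict_classifier(
      ff$trajectory, s2$features[, object$feature_ids, drop = FALSE])
  }
  out
}
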