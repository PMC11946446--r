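test_that("one-way F matches the explicit sum-of-squares decomposition", {
  set.seed(61)
  x <- cbind(f1 = c(rnorm(50, 0), rnorm(50, 10)),
             f2 = rnorm(100),
             f3 = c(rnorm(50, 0, 2), rnorm(50, 1, 2)))
  g <- factor(rep(c("a", "b"), each = 50))
  r <- anova_rank(x, g)
  # explicit decomposition: SST = sum over groups/observations of
  # (y_ij - grand mean)^2, split into between and within parts
  oracle_F <- function(v, g) {
    grand <- mean(v)
    sst <- sum((v - grand)^2)
    ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - grand)^2))
    ssw <- sst - ssb
    k <- nlevels(g); n <- length(v)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  for (j in 1:3) {
    id <- which(r$feature_id == j)
    expect_equal(r$F_statistic[id], oracle_F(x[, j], g), tolerance = 1e-8)
    # independent library route
    expect_equal(r$F_statistic[id],
                 unname(stats::oneway.test(x[, j] ~ g, var.equal = TRUE)$statistic),
                 tolerance = 1e-8)
  }
  # the separated feature ranks first; the null feature's F is small
  expect_equal(r$feature_id[1], 1L)
  expect_lt(r$F_statistic[r$feature_id == 2], qf(0.95, 1, 98))
  # degenerate features are skipped with a warning
  xd <- cbind(x, dead = rep(c(1, 2), each = 50))
  expect_warning(rd <- anova_rank(xd, g), "zero within-group variance")
  expect_true(is.na(rd$F_statistic[rd$feature_id == 4]))
  expect_error(anova_rank(x, factor(rep("a", 100))), "two groups")
})

test_that("low-band frontal features outrank gamma features on synthetic cohorts", {
  s2 <- small_s2()
  on <- small_led() == "illuminated"
  r <- anova_rank(s2$features[on, ], factor(small_s1()$meta$trajectory[on]))
  m <- feature_id_map()
  rank_by_id <- integer(160)
  rank_by_id[r$feature_id] <- seq_len(160)
  low <- rank_by_id[m$id[m$band %in% c("delta", "theta")]]
  gamma <- rank_by_id[m$id[m$band == "gamma"]]
  expect_lt(median(low), median(gamma))
})

test_that("the consensus set is the documented 16 delta/theta features", {
  ids <- consensus16()
  expect_length(ids, 16)
  m <- feature_id_map()
  sel <- m[m$id %in% ids, ]
  expect_setequal(unique(sel$channel), ACTIVE_CHANNELS)
  expect_setequal(paste(sel$band, sel$statistic),
                  c("delta mean", "delta skewness", "theta trapz",
                    "theta entropy"))
  expect_true(all(c(82, 83, 92, 93, 42, 43, 52, 53) %in% ids))
  # occurrence counting over subject rankings
  cf <- consensus_features(list(1:20, c(1:10, 30:39)), top_n = 20)
  expect_equal(cf$counts$count[cf$counts$feature_id == 1], 2)
  expect_equal(cf$counts$count[cf$counts$feature_id == 30], 1)
  expect_equal(cf$consensus, consensus16())
  one <- consensus_features(list(1:20), top_n = 20)
  expect_true(all(one$counts$count == 1))
})

test_that("accuracy-vs-k curves behave over nested feature sets", {
  set.seed(62)
  n <- 40
  y <- factor(rep(letters[1:4], each = n))
  x <- cbind(sep = rep(c(0, 3, 6, 9), each = n) + rnorm(4 * n, 0, 0.3),
             matrix(rnorm(4 * n * 5), ncol = 5))
  r <- anova_rank(x, y)
  curve <- top_k_curve(x, y, r, classifier = "lda", k_max = 20, repeats = 2,
                       seed = 5)
  expect_equal(nrow(curve), 6)          # truncated to the feature count
  expect_equal(curve$k, 1:6)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  # the informative feature alone already classifies well, and adding
  # noise features does not destroy it
  expect_gt(curve$accuracy[1], 0.9)
  expect_gt(curve$accuracy[6], curve$accuracy[1] - 0.05)
})

test_that("the cascade links stage-2 testing to gate-passed segments", {
  set.seed(63)
  n <- 40   # per (led x trajectory) cell
  traj <- factor(rep(rep(c("up_down", "right_left", "left_cross",
                           "right_cross"), each = n), 2),
                 levels = c("up_down", "right_left", "left_cross",
                            "right_cross"))
  led <- factor(rep(c("illuminated", "non_illuminated"), each = 4 * n),
                levels = c("illuminated", "non_illuminated"))
  # gate feature: separable by construction
  gx <- cbind(ifelse(led == "illuminated", 1, 0) + rnorm(8 * n, 0, 0.05))
  # stage-2 features: separable 4-class clusters
  sx <- cbind(as.integer(traj) + rnorm(8 * n, 0, 0.05),
              as.integer(traj)^2 + rnorm(8 * n, 0, 0.05))
  g <- train_gate(gx, led, "lda", repeats = 4, seed = 9,
                  strata = interaction(led, traj))
  expect_equal(g$accuracy, 1)
  st2 <- train_stage2(sx, traj, g, classifier = "lda", feature_set = 1:2,
                      seed = 9)
  expect_equal(st2$accuracy, 1)
  # perfect gate: overall system accuracy equals stage-2 accuracy
  expect_equal(st2$system_accuracy, st2$accuracy)
  expect_equal(overall_system_accuracy(st2), 1)
  # stage-2 test sets contain only truly illuminated, gate-passed segments
  for (r in seq_len(g$repeats)) {
    d <- g$decisions[[r]]
    expect_equal(st2$per_repeat[[r]]$n_test,
                 sum(d$truth == "illuminated" & d$pred == "illuminated"))
  }
  # shuffled trajectory labels fall to 4-class chance
  set.seed(64)
  st2s <- train_stage2(sx, sample(traj), g, classifier = "lda",
                       feature_set = 1:2, seed = 10)
  expect_gt(st2s$accuracy, 0.1)
  expect_lt(st2s$accuracy, 0.45)
  # a gate that rejects everything cannot feed stage 2
  g_dead <- g
  for (r in seq_along(g_dead$decisions)) {
    g_dead$decisions[[r]]$pred[] <- "non_illuminated"
  }
  expect_error(train_stage2(sx, traj, g_dead, classifier = "lda",
                            feature_set = 1:2),
               "empty gate-passed")
})

test_that("overall system accuracy divides stage-2 correct by gate detections", {
  # hand-built cascade result: 100 detected, 97 correct
  fake <- structure(list(per_repeat = list(
    list(n_detected = 100, n_correct = 97),
    list(n_detected = 100, n_correct = 97))), class = "bci_stage2")
  expect_equal(overall_system_accuracy(fake), 0.97)
  dead <- structure(list(per_repeat = list(list(n_detected = 0, n_correct = 0))),
                    class = "bci_stage2")
  expect_warning(out <- overall_system_accuracy(dead), "never flagged")
  expect_true(is.na(out))
})

test_that("an imperfect gate caps overall accuracy at the stage-2 level", {
  set.seed(65)
  n <- 30
  traj <- factor(rep(rep(c("up_down", "right_left", "left_cross",
                           "right_cross"), each = n), 2),
                 levels = c("up_down", "right_left", "left_cross",
                            "right_cross"))
  led <- factor(rep(c("illuminated", "non_illuminated"), each = 4 * n),
                levels = c("illuminated", "non_illuminated"))
  gx <- cbind(ifelse(led == "illuminated", 1, 0) + rnorm(8 * n, 0, 0.45))
  sx <- cbind(as.integer(traj) + rnorm(8 * n, 0, 0.1))
  g <- train_gate(gx, led, "lda", repeats = 5, seed = 11,
                  strata = interaction(led, traj))
  expect_lt(g$accuracy, 1)   # noisy gate by construction
  st2 <- train_stage2(sx, traj, g, classifier = "lda", feature_set = 1,
                      seed = 11)
  expect_lte(st2$system_accuracy, st2$accuracy + 1e-12)
})
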