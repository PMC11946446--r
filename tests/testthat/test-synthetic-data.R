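test_that("gaze angles reproduce the setup geometry and a ray-geometry oracle", {
  expect_equal(gaze_angles(screen_geometry(61, 34, 120)),
               c(horizontal = 28.5, vertical = 16.1))
  # zero-width screen subtends nothing
  expect_equal(unname(gaze_angles(screen_geometry(0, 34, 120))["horizontal"]), 0)
  # 240 cm at 120 cm: 2*atan(1) = 90 degrees
  expect_equal(unname(gaze_angles(screen_geometry(240, 34, 120))["horizontal"]), 90)
  # brute-force oracle: angle between the rays to the two screen edges
  ray_angle <- function(extent, d) {
    a <- c(-extent / 2, d); b <- c(extent / 2, d)
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  }
  g <- gaze_angles(screen_geometry(61, 34, 120), digits = NULL)
  expect_lt(abs(g["horizontal"] - ray_angle(61, 120)), 0.05)
  expect_lt(abs(g["vertical"] - ray_angle(34, 120)), 0.05)
  expect_error(gaze_angles(screen_geometry(61, 34, 0)), "invalid geometry")
  expect_error(gaze_angles(screen_geometry(61, 34, -5)), "invalid geometry")
})

test_that("trajectory angle series have the table's peaks, period, and symmetries", {
  fs <- 256
  rl <- trajectory_angle_series("right_left", 2, fs)
  expect_equal(nrow(rl), 512)
  # periodic with period fs / cycle_rate = 256 samples
  expect_equal(rl[1:256, ], rl[257:512, ])
  # positive extremum of right_left is (+14.2, 0)
  i <- which.max(rl[, "x_deg"])
  expect_equal(unname(rl[i, "x_deg"]), 14.2)
  expect_equal(unname(rl[i, "y_deg"]), 0)
  expect_equal(range(rl[, "x_deg"]), c(-14.2, 14.2))
  # up_down never moves horizontally, peaks at +-8.1 vertically
  ud <- trajectory_angle_series("up_down", 1, fs)
  expect_true(all(ud[, "x_deg"] == 0))
  expect_equal(range(ud[, "y_deg"]), c(-8.1, 8.1))
  # left_cross is the x-mirror of right_cross
  rc <- trajectory_angle_series("right_cross", 1, fs)
  lc <- trajectory_angle_series("left_cross", 1, fs)
  expect_equal(lc[, "x_deg"], -rc[, "x_deg"])
  expect_equal(lc[, "y_deg"], rc[, "y_deg"])
  expect_error(trajectory_spec("circle"), "unknown trajectory")
  expect_error(trajectory_angle_series("up_down", 1.001, 256), "integer sample count")
})

test_that("EOG projection follows the corneoretinal dipole signs", {
  fs <- 256
  # pure rightward gaze: right-frontal sign opposite to left-frontal
  ang <- cbind(x_deg = rep(10, fs), y_deg = rep(0, fs))
  art <- synth_eog(ang, gain = 2, fs = fs)
  expect_true(all(art[, "AF4"] > 0) && all(art[, "F8"] > 0))
  expect_true(all(art[, "AF3"] < 0) && all(art[, "F7"] < 0))
  # vertical gaze is common mode on the frontal channels
  ud <- trajectory_angle_series("up_down", 1, fs)
  art_ud <- synth_eog(ud, gain = 2, fs = fs)
  expect_equal(art_ud[, "AF3"], art_ud[, "AF4"])
  expect_equal(art_ud[, "F7"], art_ud[, "F8"])
  # non-frontal leakage is attenuated
  expect_lt(max(abs(art_ud[, "O1"])), 0.2 * max(abs(art_ud[, "AF3"])))
  # zero gain gives an all-zero artifact
  expect_true(all(synth_eog(ud, gain = 0, fs = fs) == 0))
  expect_error(synth_eog(ud, gain = -1), "non-negative")
})

test_that("recordings have protocol dimensions and are seed-deterministic", {
  cfg <- sim_config(seed = 11)
  rec <- synth_recording(cfg)
  expect_equal(dim(rec$samples), c(4096, 14))          # 16 s at 256 Hz
  expect_equal(colnames(rec$samples), EMOTIV_CHANNELS)
  expect_equal(dim(trim_beeps(rec)$samples), c(2560, 14))
  rec2 <- synth_recording(cfg)
  expect_identical(rec$samples, rec2$samples)
  # different seed differs
  expect_false(identical(rec$samples,
                         synth_recording(sim_config(seed = 12))$samples))
})

test_that("cohort layout covers subjects x trajectories x conditions x reps", {
  tiny <- synth_cohort(1, 1, seed = 5)
  expect_length(tiny, 8)                               # 4 trajectories x 2 conditions
  coh <- small_cohort()
  expect_length(coh, 2 * 3 * 4 * 2)
  meta <- do.call(rbind, lapply(coh, function(r)
    data.frame(s = r$meta$subject_id, led = r$meta$led_condition,
               tr = r$meta$trajectory)))
  # per subject: reps x 4 recordings in each LED condition
  per <- table(meta$s, meta$led)
  expect_true(all(per == 3 * 4))
  expect_setequal(unique(meta$tr),
                  c("up_down", "right_left", "right_cross", "left_cross"))
  # bit-identical regeneration under the same seed
  coh2 <- synth_cohort(2, 3, seed = 301)
  expect_identical(coh[[7]]$samples, coh2[[7]]$samples)
})

test_that("LED-on recordings carry more 6-8 Hz power than LED-off on every channel", {
  cfg_on <- sim_config(led_on = TRUE)
  cfg_off <- sim_config(led_on = FALSE)
  wc <- welch_config(256)
  band_power <- function(cfg, seed) {
    cfg$seed <- seed
    rec <- trim_beeps(synth_recording(cfg))
    r <- gazebci:::.welch_psd_matrix(rec$samples[1:768, ], wc)
    keep <- r$freq >= 6 & r$freq <= 8
    colMeans(r$power[keep, , drop = FALSE])
  }
  on_mean <- rowMeans(vapply(1:10, function(s) band_power(cfg_on, 400 + s),
                             numeric(14)))
  off_mean <- rowMeans(vapply(1:10, function(s) band_power(cfg_off, 500 + s),
                              numeric(14)))
  expect_true(all(on_mean > off_mean))
})

test_that("AF3-AF4 difference tracks the horizontal angle at artifact extrema", {
  cfg <- sim_config(noise_amp_uv = 0, ssvep_amp_uv = 0,
                    trajectory = "right_left", seed = 1)
  rec <- trim_beeps(synth_recording(cfg))
  ang <- trajectory_angle_series("right_left", 10, 256)[, "x_deg"]
  d <- rec$samples[, "AF3"] - rec$samples[, "AF4"]
  pos <- which(ang == max(ang))
  neg <- which(ang == min(ang))
  # one consistent polarity: AF3 - AF4 = -2x under the dipole projection
  expect_true(all(sign(d[pos]) == -1))
  expect_true(all(sign(d[neg]) == +1))
})
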