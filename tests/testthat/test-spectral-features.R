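test_that("Welch estimate equals directly averaged modified periodograms", {
  cfg <- welch_config(256)
  set.seed(41)
  for (i in 1:3) {
    x <- rnorm(768) + sin(2 * pi * runif(1, 2, 40) * (0:767) / 256)
    p <- welch_psd(x, cfg)
    expect_equal(p$K, 132)
    expect_equal(p$df, 256 / 637)
    ref <- welch_direct(x, cfg)
    expect_lt(max(abs(p$power - ref) / pmax(ref, 1e-300)), 1e-10)
  }
  # also for a coarser, genuinely hopping configuration
  cfg2 <- welch_config(256, window_len = 256, noverlap = 128)
  x <- rnorm(1024)
  expect_lt(max(abs(welch_psd(x, cfg2)$power - welch_direct(x, cfg2))), 1e-12)
  expect_error(welch_psd(rnorm(500), cfg), "exceeds data length")
  expect_error(welch_config(256, 637, 637), "noverlap")
})

test_that("a 7 Hz sinusoid peaks at the bin nearest 7 Hz", {
  cfg <- welch_config(256)
  set.seed(42)
  x <- sin(2 * pi * 7 * (0:767) / 256) + 0.05 * rnorm(768)
  p <- welch_psd(x, cfg)
  expect_equal(which.max(p$power) - 1, round(7 / p$df))
})

test_that("white noise is flat when windows are independent", {
  set.seed(43)
  p <- welch_psd(rnorm(2048), welch_config(256, window_len = 128, noverlap = 0))
  cv <- sd(p$power[-1]) / mean(p$power[-1])
  expect_lt(cv, 0.5)
})

test_that("full-length rectangular Welch satisfies Parseval exactly", {
  set.seed(44)
  x <- rnorm(768)
  x <- x - mean(x)
  p <- welch_psd(x, welch_config(256, window_len = 768, noverlap = 0,
                                 window = "rect"))
  expect_equal(sum(p$power) * p$df, mean(x^2), tolerance = 1e-12)
})

test_that("band slicing uses half-open bins on the Welch grid", {
  cfg <- welch_config(256)
  p <- welch_psd(rnorm(768), cfg)
  delta <- band_slice(p, 0, 4)
  expect_length(delta$freq, 10)            # bins 0..9 at df ~ 0.402
  expect_lt(max(delta$freq), 4)
  # full-range slice is the identity
  full <- band_slice(p, 0, max(p$freq), include_upper = TRUE)
  expect_equal(full$power, p$power)
  # containment of nested bands
  expect_true(all(band_slice(p, 6, 8)$freq %in% band_slice(p, 1, 10)$freq))
  expect_error(band_slice(p, 8, 4), "invalid band")
})

test_that("trapezoidal band power matches closed-form integrals", {
  # constant power p over width w
  ps <- make_psd(seq(2, 6, by = 0.5), rep(3, 9))
  expect_equal(band_trapz(ps), 3 * 4)
  # exact for a linear ramp
  f <- seq(0, 1, by = 0.01)
  expect_equal(band_trapz(make_psd(f, 5 * f)), 2.5)
  # quadratic within 1e-4 of the analytic 1/3 on 100 intervals
  expect_lt(abs(band_trapz(make_psd(f, f^2)) - 1 / 3), 1e-4)
  single <- make_psd(c(1, 2), c(5, 5))
  single$freq <- 1; single$power <- 5
  expect_warning(expect_equal(band_trapz(single), 0), "fewer than two")
})

test_that("band statistics follow their defining conventions", {
  # constant slice: variance 0, skew/kurt 0, entropy log(n)
  ps <- make_psd(seq(0, 3.9, by = 0.1), rep(2, 40))
  bf <- band_features(ps)
  expect_named(bf, c("kurtosis", "mean", "skewness", "trapz", "entropy",
                     "variance", "mobility", "complexity"))
  expect_equal(unname(bf["variance"]), 0)
  expect_equal(unname(bf["skewness"]), 0)
  expect_equal(unname(bf["kurtosis"]), 0)
  expect_equal(unname(bf["entropy"]), log(40))
  expect_equal(unname(bf["mean"]), 2)
  # Hjorth parameters against a hand-coded difference-quotient oracle
  set.seed(45)
  v <- abs(rnorm(30))
  ps2 <- make_psd(seq_len(30) * 0.4, v)
  bf2 <- band_features(ps2)
  mob_oracle <- sqrt(var(diff(v)) / var(v))
  expect_equal(unname(bf2["mobility"]), mob_oracle, tolerance = 1e-12)
  expect_equal(unname(bf2["complexity"]),
               sqrt(var(diff(diff(v))) / var(diff(v))) / mob_oracle,
               tolerance = 1e-12)
  expect_equal(unname(bf2["variance"]), var(v))
  expect_equal(unname(bf2["trapz"]), pracma::trapz(ps2$freq, v))
})

test_that("amplitude scaling quadruples band power but not shape statistics", {
  cfg <- welch_config(256)
  set.seed(46)
  x <- rnorm(768)
  bands <- eeg_bands()
  p1 <- welch_psd(x, cfg)
  p2 <- welch_psd(2 * x, cfg)
  for (b in 1:5) {
    s1 <- band_slice(p1, bands$lo_hz[b], bands$hi_hz[b], b == 5)
    s2 <- band_slice(p2, bands$lo_hz[b], bands$hi_hz[b], b == 5)
    f1 <- band_features(s1); f2 <- band_features(s2)
    expect_equal(unname(f2["trapz"]), 4 * unname(f1["trapz"]))
    for (stat in c("skewness", "kurtosis", "entropy", "mobility", "complexity"))
      expect_equal(unname(f2[stat]), unname(f1[stat]), tolerance = 1e-10)
  }
})

test_that("feature ids resolve per the channel-major layout arithmetic", {
  m <- feature_id_map()
  expect_equal(nrow(m), 160)
  # the worked ids: F7 delta mean/skewness, F7 theta trapz/entropy,
  # F8 delta mean/skewness, F8 theta trapz/entropy
  expect_equal(feature_id("F7", "delta", "mean"), 42L)
  expect_equal(feature_id("F7", "delta", "skewness"), 43L)
  expect_equal(feature_id("F7", "theta", "trapz"), 52L)
  expect_equal(feature_id("F7", "theta", "entropy"), 53L)
  expect_equal(feature_id("F8", "delta", "mean"), 82L)
  expect_equal(feature_id("F8", "delta", "skewness"), 83L)
  expect_equal(feature_id("F8", "theta", "trapz"), 92L)
  expect_equal(feature_id("F8", "theta", "entropy"), 93L)
  # id arithmetic agrees with the map for every feature
  for (i in c(1, 42, 53, 83, 92, 160))
    expect_equal(feature_id(m$channel[i], m$band[i], m$statistic[i]), i)
  expect_error(feature_id("Cz", "delta", "mean"), "unknown")
})

test_that("feature vectors have the documented length and match by id", {
  seg <- small_segments()[[1]]
  fv <- feature_vector(seg)
  expect_length(fv, 160)
  expect_named(fv, sprintf("feature_%04d", 1:160))
  expect_length(feature_vector(seg, channels = "AF3"), 40)
  # id 42 is F7/delta/mean: recompute it directly from that channel's PSD
  cfg <- welch_config(seg$fs)
  p <- welch_psd(seg$samples[, "F7"], cfg)
  delta_mean <- unname(band_features(band_slice(p, 0, 4))["mean"])
  expect_equal(unname(fv[42]), delta_mean, tolerance = 1e-12)
  expect_error(feature_vector(seg, channels = c("AF3", "XX")), "XX")
})

test_that("the batched stage-2 extractor agrees with the per-segment reference", {
  segs <- small_segments()[1:4]
  filt <- stage2_filter()
  tab <- stage2_features(segs)
  for (i in c(1, 3)) {
    seg <- segs[[i]]
    seg$samples <- bandpass(seg$samples, filt, fs = seg$fs)
    expect_equal(unname(tab$features[i, ]), unname(feature_vector(seg)),
                 tolerance = 1e-10)
  }
})
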