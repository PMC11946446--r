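# Shared fixtures, built once per test run and cached for the session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 2 subjects x 3 reps x 4 trajectories x 2 conditions = 48 recordings
small_cohort <- function() cached("small_cohort", synth_cohort(2, 3, seed = 301))

small_segments <- function()
  cached("small_segments", gazebci:::.cohort_segments(small_cohort()))

small_s1 <- function() cached("small_s1", stage1_features(small_segments()))

small_s2 <- function() cached("small_s2", stage2_features(small_segments()))

small_led <- function()
  factor(ifelse(small_s1()$meta$led_condition == "on",
                "illuminated", "non_illuminated"),
         levels = c("illuminated", "non_illuminated"))

# the default study-scale cohort (10 subjects, 800 recordings), fixed seed
default_cohort <- function() cached("default_cohort", synth_cohort(seed = 101))

default_segments <- function()
  cached("default_segments", gazebci:::.cohort_segments(default_cohort()))

# a hand-built flat PSD on a grid aligned with integer band edges
flat_psd <- function(level = 1, df = 0.25, fmax = 12.75) {
  f <- seq(0, fmax, by = df)
  structure(list(freq = f, power = rep(level, length(f)), df = df,
                 K = 1, fs = 2 * fmax),
            class = "bci_psd")
}

# PSD object wrapper for arbitrary freq/power vectors
make_psd <- function(freq, power) {
  structure(list(freq = freq, power = power, df = freq[2] - freq[1],
                 K = 1, fs = 2 * max(freq)),
            class = "bci_psd")
}

# direct (oracle) Welch estimate: explicit windowing + mvfft periodograms
welch_direct <- function(x, cfg) {
  L <- cfg$window_len
  hop <- L - cfg$noverlap
  K <- (length(x) - L) %/% hop + 1
  w <- gazebci:::.welch_window(cfg)
  nb <- L %/% 2 + 1
  M <- vapply(seq_len(K), function(i) x[(1 + (i - 1) * hop):((i - 1) * hop + L)] * w,
              numeric(L))
  P <- rowMeans(Mod(mvfft(M)[1:nb, , drop = FALSE])^2) /
    (L * mean(w^2) * cfg$fs)
  sc <- rep(2, nb); sc[1] <- 1
  if (L %% 2 == 0) sc[nb] <- 1
  P * sc
}
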