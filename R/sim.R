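# Synthetic EEG/EOG cohort generator emulating the two-condition
# (LED on/off), four-trajectory recording protocol.

#' Screen geometry of the recording setup
#'
#' @param width_cm Screen width in cm.
#' @param height_cm Screen height in cm.
#' @param distance_cm Viewing distance in cm (must be positive).
#' @return A list of class `"screen_geometry"`.
#' @export
screen_geometry <- function(width_cm = 61, height_cm = 34, distance_cm = 120) {
  if (!is.numeric(distance_cm) || distance_cm <= 0)
    stop("invalid geometry: 'distance_cm' must be strictly positive")
  if (width_cm < 0 || height_cm < 0)
    stop("invalid geometry: screen extents must be non-negative")
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 distance_cm = distance_cm),
            class = "screen_geometry")
}

#' Maximum gaze angles subtended by the screen
#'
#' Full horizontal and vertical visual angles of a screen viewed centrally:
#' `2 * atan((extent / 2) / distance)`, in degrees.
#'
#' @param geometry A [screen_geometry()] object.
#' @param digits Decimal places to round to (the setup tables print one).
#'   Use `NULL` for unrounded values.
#' @return Named numeric vector `c(horizontal = , vertical = )` in degrees.
#' @examples
#' gaze_angles(screen_geometry(61, 34, 120))  # 28.5, 16.1
#' @export
gaze_angles <- function(geometry = screen_geometry(), digits = 1) {
  stopifnot(inherits(geometry, "screen_geometry"))
  full <- function(extent) 2 * atan((extent / 2) / geometry$distance_cm) * 180 / pi
  out <- c(horizontal = full(geometry$width_cm),
           vertical   = full(geometry$height_cm))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

.TRAJECTORIES <- c("up_down", "right_left", "right_cross", "left_cross")

#' Gaze-trajectory specification
#'
#' Peak gaze angles for the four moving-ball trajectories. The ball completes
#' one full cycle per second; peak angles come from the screen geometry:
#' horizontal half-range 14.2 degrees, vertical half-range 8.1 degrees.
#' `left_cross` mirrors `right_cross` in the horizontal axis.
#'
#' @param name One of `"up_down"`, `"right_left"`, `"right_cross"`,
#'   `"left_cross"`.
#' @param cycle_rate_hz Trajectory cycles per second.
#' @return A list of class `"trajectory_spec"` with fields `name`,
#'   `x_peak_deg`, `y_peak_deg`, `cycle_rate_hz`.
#' @export
trajectory_spec <- function(name, cycle_rate_hz = 1) {
  if (!is.character(name) || length(name) != 1 || !(name %in% .TRAJECTORIES))
    stop("unknown trajectory name: ", paste(name, collapse = ", "),
         " (expected one of ", paste(.TRAJECTORIES, collapse = ", "), ")")
  peaks <- switch(name,
    up_down     = c(x = 0,     y = 8.1),
    right_left  = c(x = 14.2,  y = 0),
    right_cross = c(x = 14.2,  y = 8.1),
    left_cross  = c(x = -14.2, y = 8.1))
  structure(list(name = name, x_peak_deg = unname(peaks["x"]),
                 y_peak_deg = unname(peaks["y"]),
                 cycle_rate_hz = cycle_rate_hz),
            class = "trajectory_spec")
}

#' Gaze-angle time series for a trajectory
#'
#' Sinusoidal pursuit of the moving ball: both axes follow
#' `peak * sin(2 * pi * rate * t)`, so the two axes move in phase for the
#' cross trajectories and the series is periodic with period
#' `1 / cycle_rate_hz`.
#'
#' @param spec A [trajectory_spec()] (or a trajectory name).
#' @param duration_s Duration in seconds; `duration_s * fs` must be integral.
#' @param fs Sampling rate in Hz.
#' @return Matrix with `duration_s * fs` rows and columns `x_deg`, `y_deg`.
#' @export
trajectory_angle_series <- function(spec, duration_s, fs) {
  if (is.character(spec)) spec <- trajectory_spec(spec)
  stopifnot(inherits(spec, "trajectory_spec"))
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-8)
    stop("duration_s * fs must be an integer sample count")
  n <- round(n)
  t <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * spec$cycle_rate_hz * t)
  cbind(x_deg = spec$x_peak_deg * s, y_deg = spec$y_peak_deg * s)
}

#' Project gaze angles onto EEG channels as an EOG artifact
#'
#' Dipole-style projection of the corneoretinal potential: a rightward gaze
#' rotation (positive horizontal angle) deflects the right-frontal channels
#' (AF4, F8) with sign opposite to the left-frontal ones (AF3, F7); a vertical
#' rotation deflects all four frontal channels with a common sign. Non-frontal
#' channels receive an attenuated leakage (hemisphere-signed horizontally).
#' The projected series is convolved with a short boxcar kernel to give the
#' deflections saccade-like edges.
#'
#' @param angle_series Matrix with columns `x_deg`, `y_deg` (degrees).
#' @param gain Artifact gain in microvolt per degree (non-negative).
#' @param channel_names Channels to project onto.
#' @param leakage Fraction of the artifact leaking into non-frontal channels.
#' @param fs Sampling rate (for the smoothing kernel length).
#' @param smooth_s Smoothing kernel duration in seconds.
#' @return Matrix `[time x channel]` in microvolt.
#' @export
synth_eog <- function(angle_series, gain, channel_names = EMOTIV_CHANNELS,
                      leakage = 0.1, fs = 256, smooth_s = 0.05) {
  if (gain < 0) stop("'gain' must be non-negative")
  x <- angle_series[, "x_deg"]
  y <- angle_series[, "y_deg"]
  frontal <- channel_names %in% ACTIVE_CHANNELS
  right <- !(channel_names %in% .LEFT_CHANNELS)
  sx <- ifelse(right, 1, -1) * ifelse(frontal, 1, leakage)
  sy <- ifelse(frontal, 1, leakage)
  out <- outer(x, sx) + outer(y, sy)
  out <- gain * out
  klen <- max(1L, round(smooth_s * fs))
  if (klen > 1L) {
    kern <- rep(1 / klen, klen)
    out <- apply(out, 2, function(col)
      as.numeric(stats::filter(col, kern, sides = 2, circular = TRUE)))
  }
  colnames(out) <- channel_names
  out
}

#' Simulation configuration
#'
#' Defaults reproduce the emulated study conditions: 256 Hz sampling,
#' 14 channels, 3 s beep padding around a 10 s task window, a 7 Hz LED
#' flicker driving the SSVEP, and a 1 Hz trajectory cycle. Amplitudes are in
#' microvolt; the background is 1/f^1.5 noise plus a white floor scaled so
#' band amplitudes are EEG-like. The SSVEP is strongest occipitally (O1/O2,
#' weight 1) and present at `ssvep_frontal_weight` on the frontal channels
#' so the frontal-channel gate is exercisable.
#'
#' @param sampling_rate_hz,n_channels,channel_names Montage parameters.
#' @param led_on Logical; is the 7 Hz LED flickering during the recording?
#' @param trajectory A [trajectory_spec()] or trajectory name.
#' @param ssvep_freq_hz LED flicker frequency.
#' @param ssvep_amp_uv SSVEP fundamental amplitude (microvolt, occipital).
#' @param ssvep_harmonic_weights Relative amplitudes of harmonics 1, 2, ...
#' @param ssvep_frontal_weight Relative SSVEP amplitude on AF3/F7/F8/AF4.
#' @param ssvep_other_weight Relative SSVEP amplitude on remaining channels.
#' @param eog_gain_uv_per_deg EOG artifact gain (microvolt per degree).
#' @param eog_leakage Non-frontal leakage fraction of the EOG artifact.
#' @param noise_spectral_exponent Exponent of the 1/f^a background.
#' @param noise_amp_uv Background noise RMS amplitude (microvolt).
#' @param noise_white_frac Fraction of noise power in the white floor.
#' @param beep_pad_s,task_s Beep padding and task durations (seconds).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(sampling_rate_hz = 256, n_channels = 14,
                       channel_names = EMOTIV_CHANNELS,
                       led_on = TRUE, trajectory = "right_left",
                       ssvep_freq_hz = 7, ssvep_amp_uv = 16,
                       ssvep_harmonic_weights = c(1, 0.25),
                       ssvep_frontal_weight = 0.4,
                       ssvep_other_weight = 0.15,
                       eog_gain_uv_per_deg = 2.5, eog_leakage = 0.1,
                       noise_spectral_exponent = 1.5, noise_amp_uv = 20,
                       noise_white_frac = 0.1,
                       beep_pad_s = 3, task_s = 10, seed = NULL) {
  if (is.character(trajectory)) trajectory <- trajectory_spec(trajectory)
  stopifnot(length(channel_names) == n_channels,
            ssvep_amp_uv >= 0, eog_gain_uv_per_deg >= 0, noise_amp_uv >= 0)
  if (abs(task_s * sampling_rate_hz - round(task_s * sampling_rate_hz)) > 1e-8)
    stop("task_s * sampling_rate_hz must be an integer sample count")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 n_channels = n_channels, channel_names = channel_names,
                 led_on = led_on, trajectory = trajectory,
                 ssvep_freq_hz = ssvep_freq_hz, ssvep_amp_uv = ssvep_amp_uv,
                 ssvep_harmonic_weights = ssvep_harmonic_weights,
                 ssvep_frontal_weight = ssvep_frontal_weight,
                 ssvep_other_weight = ssvep_other_weight,
                 eog_gain_uv_per_deg = eog_gain_uv_per_deg,
                 eog_leakage = eog_leakage,
                 noise_spectral_exponent = noise_spectral_exponent,
                 noise_amp_uv = noise_amp_uv,
                 noise_white_frac = noise_white_frac,
                 beep_pad_s = beep_pad_s, task_s = task_s, seed = seed),
            class = "sim_config")
}

# 1/f^a noise of unit RMS via spectral shaping of white Gaussian noise
.pink_noise <- function(n, exponent) {
  z <- stats::fft(rnorm(n))
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                      # two-sided frequency index
  w <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::fft(z * w, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize one labeled recording
#'
#' Background 1/f noise on every channel, plus (task window only) the EOG
#' artifact of the configured trajectory, plus (LED-on recordings only) the
#' 7 Hz SSVEP with its harmonics over the full recording. Identical
#' configurations (including `seed`) give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"bci_recording"` with elements `samples`
#'   (`time x channel` matrix, microvolt), `fs`, and `meta`.
#' @export
synth_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate_hz
  n_total <- round((2 * config$beep_pad_s + config$task_s) * fs)
  n_task <- round(config$task_s * fs)
  nch <- config$n_channels
  t <- (seq_len(n_total) - 1) / fs

  wf <- config$noise_white_frac
  samples <- vapply(seq_len(nch), function(ch) {
    config$noise_amp_uv * (sqrt(1 - wf) *
      .pink_noise(n_total, config$noise_spectral_exponent) +
      sqrt(wf) * rnorm(n_total))
  }, numeric(n_total))

  if (config$led_on && config$ssvep_amp_uv > 0) {
    frontal <- config$channel_names %in% ACTIVE_CHANNELS
    occipital <- config$channel_names %in% c("O1", "O2")
    topo <- ifelse(occipital, 1,
                   ifelse(frontal, config$ssvep_frontal_weight,
                          config$ssvep_other_weight))
    for (h in seq_along(config$ssvep_harmonic_weights)) {
      phase <- runif(1, 0, 2 * pi)
      carrier <- sin(2 * pi * h * config$ssvep_freq_hz * t + phase)
      samples <- samples + config$ssvep_amp_uv *
        config$ssvep_harmonic_weights[h] * outer(carrier, topo)
    }
  }

  if (config$eog_gain_uv_per_deg > 0) {
    ang <- trajectory_angle_series(config$trajectory, config$task_s, fs)
    art <- synth_eog(ang, config$eog_gain_uv_per_deg, config$channel_names,
                     leakage = config$eog_leakage, fs = fs)
    pad <- round(config$beep_pad_s * fs)
    samples[(pad + 1):(pad + n_task), ] <- samples[(pad + 1):(pad + n_task), ] + art
  }

  colnames(samples) <- config$channel_names
  structure(list(samples = samples, fs = fs,
                 meta = list(subject_id = NA_integer_,
                             led_condition = if (config$led_on) "on" else "off",
                             trajectory = config$trajectory$name,
                             repetition = NA_integer_,
                             seed = config$seed)),
            class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  subject %s, LED %s, trajectory %s, repetition %s\n",
              x$meta$subject_id, x$meta$led_condition, x$meta$trajectory,
              x$meta$repetition))
  invisible(x)
}

#' Simulate the full study cohort
#'
#' For each subject, every trajectory is recorded `reps_per_class` times in
#' both LED conditions (defaults: 10 subjects x 4 trajectories x 10 reps x
#' 2 conditions = 800 recordings of 16 s). Subject heterogeneity is a seeded
#' multiplicative jitter (+-20 percent) on the EOG gain, SSVEP amplitude and
#' noise amplitude.
#'
#' @param n_subjects Number of subjects.
#' @param reps_per_class Repetitions per trajectory per LED condition.
#' @param config Base [sim_config()]; per-recording condition/trajectory and
#'   jittered amplitudes override its fields.
#' @param seed Integer master seed (drives all randomness deterministically).
#' @return A list of `bci_recording` of class `"bci_cohort"`.
#' @export
synth_cohort <- function(n_subjects = 10, reps_per_class = 10,
                         config = sim_config(), seed = 1) {
  stopifnot(n_subjects >= 1, reps_per_class >= 1)
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(reps_per_class),
                      led = c(TRUE, FALSE),
                      trajectory = .TRAJECTORIES,
                      subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  jitter <- matrix(runif(n_subjects * 3, 0.8, 1.2), n_subjects, 3)
  rec_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- config
    cfg$led_on <- g$led
    cfg$trajectory <- trajectory_spec(g$trajectory,
                                      config$trajectory$cycle_rate_hz)
    cfg$eog_gain_uv_per_deg <- config$eog_gain_uv_per_deg * jitter[g$subject, 1]
    cfg$ssvep_amp_uv <- config$ssvep_amp_uv * jitter[g$subject, 2]
    cfg$noise_amp_uv <- config$noise_amp_uv * jitter[g$subject, 3]
    cfg$seed <- rec_seeds[i]
    rec <- synth_recording(cfg)
    rec$meta$subject_id <- g$subject
    rec$meta$repetition <- g$rep
    rec
  })
  structure(recs, class = "bci_cohort",
            n_subjects = n_subjects, reps_per_class = reps_per_class,
            seed = seed)
}

#' @export
print.bci_cohort <- function(x, ...) {
  cat(sprintf("<bci_cohort> %d recordings, %d subjects\n",
              length(x), attr(x, "n_subjects")))
  invisible(x)
}
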