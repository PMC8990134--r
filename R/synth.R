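# ---------------------------------------------------------------------------
# Synthetic-session generator: gait-periodic joint angles plus multichannel
# LFP whose band-limited components are amplitude-modulated by gait phase with
# known (ground-truth) per-channel coupling. Used throughout the test suite
# for parameter-recovery experiments.
# ---------------------------------------------------------------------------

#' Harmonic gait model for bilateral hindlimb joint angles
#'
#' Joint angles are modelled as truncated Fourier series of the gait phase
#' `phi(t) = 2*pi*cadence*t`: realistic hip/knee/ankle traces during treadmill
#' walking are periodic but clearly non-sinusoidal, so at least two harmonics
#' are kept by default. The right leg repeats the left-leg trajectory shifted
#' by `lr_lag` radians (pi = alternating gait).
#'
#' @param cadence Stepping rate in steps/second (must be > 0).
#' @param amplitudes 3 x H matrix of harmonic amplitudes in degrees; rows are
#'   hip, knee, ankle; columns are harmonics 1..H.
#' @param phases 3 x H matrix of harmonic phase offsets in radians.
#' @param baselines Length-3 vector of baseline angles in degrees (hip, knee,
#'   ankle).
#' @param lr_lag Left-right phase lag in radians (default `pi`).
#' @return An object of class `gait_model`.
#' @export
gait_model <- function(cadence = 0.72,
                       amplitudes = matrix(c(15, 6, 20, 8, 18, 5),
                                           nrow = 3, byrow = TRUE),
                       phases = matrix(c(0.0, 0.9, 2.0, 2.6, 4.0, 1.3),
                                       nrow = 3, byrow = TRUE),
                       baselines = c(hip = 100, knee = 110, ankle = 110),
                       lr_lag = pi) {
  if (!is.numeric(cadence) || length(cadence) != 1 || cadence <= 0)
    stop("cadence must be a single positive number (steps/second)")
  amplitudes <- as.matrix(amplitudes)
  phases <- as.matrix(phases)
  if (nrow(amplitudes) != 3 || nrow(phases) != 3)
    stop("amplitudes and phases need one row per joint type (hip, knee, ankle)")
  if (!all(dim(amplitudes) == dim(phases)))
    stop("amplitudes and phases must have matching dimensions")
  if (ncol(amplitudes) < 1)
    stop("at least one harmonic per joint is required")
  if (length(baselines) != 3)
    stop("baselines must have length 3")
  structure(list(cadence = cadence, amplitudes = amplitudes, phases = phases,
                 baselines = as.numeric(baselines), lr_lag = lr_lag),
            class = "gait_model")
}

#' Ground-truth gait-phase coupling of the LFP band components
#'
#' Each channel's band-limited component is multiplied by the instantaneous
#' gain `1 + m * cos(phi - psi)`, the simplest multiplicative model that
#' produces gait-locked ERD/ERS. `m` must satisfy `0 <= m < 1` so the gain
#' stays positive.
#'
#' @param n_channels Number of electrodes (default 8).
#' @param m `n_channels x 6` matrix of modulation depths in `[0, 1)`.
#' @param psi `n_channels x 6` matrix of modulation phases in radians (phase
#'   of the gait cycle at which the band envelope peaks).
#' @param amp `n_channels x 6` matrix of base band amplitudes (arbitrary LFP
#'   units). Defaults fall off with frequency as real LFP spectra do.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_channels = 8,
                          m = matrix(0.5, n_channels, 6),
                          psi = (outer(2 * pi * (seq_len(n_channels) - 1) /
                                         n_channels, rep(1, 6)) +
                                   outer(rep(1, n_channels),
                                         (0:5) * pi / 6)) %% (2 * pi),
                          amp = outer(rep(1, n_channels),
                                      c(1.0, 0.8, 0.5, 0.35, 0.25, 0.18))) {
  m <- as.matrix(m); psi <- as.matrix(psi); amp <- as.matrix(amp)
  dims <- c(n_channels, 6)
  for (nm in c("m", "psi", "amp")) {
    x <- get(nm)
    if (!all(dim(x) == dims))
      stop(sprintf("%s must be a %d x 6 matrix (channel x band)", nm, n_channels))
  }
  if (any(m < 0) || any(m >= 1))
    stop("modulation depth m must lie in [0, 1) so the envelope gain stays positive")
  if (any(amp < 0)) stop("base band amplitudes must be non-negative")
  structure(list(n_channels = n_channels, m = m, psi = psi, amp = amp),
            class = "coupling_spec")
}

#' Additive noise model for synthetic LFP
#'
#' @param line_amps Named amplitudes (LFP units) of mains interference at
#'   50/100/150 Hz, mirroring the harmonics the preprocessing notches out.
#' @param white_sd Standard deviation of broadband white noise.
#' @param pink_amp Standard deviation of 1/f ("pink") background activity.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(line_amps = c("50" = 0.25, "100" = 0.12, "150" = 0.08),
                       white_sd = 0.3, pink_amp = 0.3) {
  if (any(c(line_amps, white_sd, pink_amp) < 0))
    stop("noise amplitudes must be non-negative")
  structure(list(line_amps = line_amps, white_sd = white_sd,
                 pink_amp = pink_amp), class = "noise_spec")
}

#' Configuration of a synthetic recording session
#'
#' @param duration Session length in seconds (paper-scale sessions are
#'   2-3 minutes; the default is 120 s).
#' @param neural_fs Neural sampling rate in Hz (500).
#' @param kin_fs Kinematic sampling rate in Hz (50); must divide `neural_fs`.
#' @param n_channels Electrode count (8).
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bitwise-identical sessions.
#' @param gait A [gait_model()].
#' @param coupling A [coupling_spec()].
#' @param noise A [noise_spec()].
#' @param theta_cadence_link If `TRUE` (default), the theta-band base
#'   amplitude scales linearly with cadence, building in the band-power vs
#'   walking-speed effect the cadence analysis is designed to detect.
#' @param theta_cadence_coef Linear coefficient of that scaling per
#'   steps/second about the 0.70 steps/s reference (default 2, i.e. roughly
#'   +30% theta amplitude between the 0.59-0.67 and 0.73-0.80 cadence groups).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration = 120, neural_fs = 500, kin_fs = 50,
                         n_channels = 8, seed = 0, gait = gait_model(),
                         coupling = coupling_spec(n_channels),
                         noise = noise_spec(),
                         theta_cadence_link = TRUE, theta_cadence_coef = 2) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (neural_fs <= 0 || kin_fs <= 0) stop("sampling rates must be positive")
  if (neural_fs %% kin_fs != 0)
    stop("neural_fs must be an integer multiple of kin_fs")
  if (!inherits(gait, "gait_model")) stop("gait must be a gait_model")
  if (!inherits(coupling, "coupling_spec")) stop("coupling must be a coupling_spec")
  if (coupling$n_channels != n_channels)
    stop("coupling dimensions do not match n_channels")
  structure(list(duration = duration, neural_fs = neural_fs, kin_fs = kin_fs,
                 n_channels = n_channels, seed = as.integer(seed), gait = gait,
                 coupling = coupling, noise = noise,
                 theta_cadence_link = isTRUE(theta_cadence_link),
                 theta_cadence_coef = theta_cadence_coef),
            class = "synth_config")
}

joint_names <- function() {
  c("left_hip", "left_knee", "left_ankle",
    "right_hip", "right_knee", "right_ankle")
}

#' Generate bilateral joint-angle trajectories
#'
#' @param config A [synth_config()].
#' @return A list with `angles` (6 x T matrix, degrees; rows named as
#'   `left_hip` ... `right_ankle`), `t` (seconds) and the unwrapped
#'   ground-truth gait phase `phi` (radians) on the kinematic grid.
#' @export
generate_kinematics <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$gait
  n <- round(config$duration * config$kin_fs)
  t <- (seq_len(n) - 1) / config$kin_fs
  phi <- 2 * pi * g$cadence * t
  angles <- matrix(0, nrow = 6, ncol = n, dimnames = list(joint_names(), NULL))
  for (side in 0:1) {  # 0 = left, 1 = right
    ph <- phi + side * g$lr_lag
    for (jt in 1:3) {
      a <- g$baselines[jt]
      for (h in seq_len(ncol(g$amplitudes)))
        a <- a + g$amplitudes[jt, h] * cos(h * ph + g$phases[jt, h])
      angles[side * 3 + jt, ] <- a
    }
  }
  list(angles = angles, t = t, phi = phi)
}

# 1/f-amplitude noise by spectral shaping of white noise, unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  k <- 0:(n - 1)
  fold <- pmin(k, n - k)
  scale <- ifelse(fold == 0, 0, 1 / sqrt(fold))
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

effective_band_amp <- function(config) {
  amp <- config$coupling$amp
  if (config$theta_cadence_link) {
    gain <- 1 + config$theta_cadence_coef * (config$gait$cadence - 0.70)
    amp[, 2] <- amp[, 2] * max(gain, 0.05)
  }
  amp
}

#' Generate multichannel synthetic LFP from a ground-truth gait phase
#'
#' Each channel is a sum over the six canonical bands of band-limited Gaussian
#' noise whose amplitude is modulated by `1 + m * cos(phi - psi)`, plus mains
#' sinusoids at 50/100/150 Hz, pink background and white sensor noise. All
#' randomness is drawn under `config$seed`, so repeated calls are
#' bitwise-identical.
#'
#' @param config A [synth_config()].
#' @param phase Ground-truth unwrapped gait phase on the kinematic grid
#'   (radians), as returned by [generate_kinematics()]; it is upsampled to the
#'   neural grid by linear interpolation.
#' @return `n_channels x (neural_fs * duration)` matrix of LFP samples.
#' @export
generate_lfp <- function(config, phase) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$neural_fs
  n <- round(config$duration * fs)
  t_n <- (seq_len(n) - 1) / fs
  t_k <- (seq_along(phase) - 1) / config$kin_fs
  phi <- stats::approx(t_k, phase, xout = t_n, rule = 2)$y
  bands <- band_specs()
  cp <- config$coupling
  amp <- effective_band_amp(config)
  ns <- config$noise
  sos_list <- lapply(seq_len(nrow(bands)), function(b)
    butter_sos(4, c(bands$low[b], bands$high[b]), fs, "pass"))

  withr::with_seed(config$seed, {
    lfp <- matrix(0, nrow = config$n_channels, ncol = n)
    for (c_i in seq_len(config$n_channels)) {
      x <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        carrier <- sos_filtfilt(sos_list[[b]], stats::rnorm(n))
        carrier <- carrier / stats::sd(carrier)
        gain <- amp[c_i, b] * (1 + cp$m[c_i, b] * cos(phi - cp$psi[c_i, b]))
        x <- x + carrier * gain
      }
      for (fl in names(ns$line_amps)) {
        a <- ns$line_amps[[fl]]
        if (a > 0) x <- x + a * sin(2 * pi * as.numeric(fl) * t_n)
      }
      if (ns$pink_amp > 0) x <- x + ns$pink_amp * pink_noise(n)
      if (ns$white_sd > 0) x <- x + stats::rnorm(n, sd = ns$white_sd)
      lfp[c_i, ] <- x
    }
    lfp
  })
}

#' Default electrode map: dorsal/lateral column and body side per electrode
#'
#' Electrodes 1, 4, 5, 8 sit in the lateral columns and 2, 3, 6, 7 in the
#' dorsal columns; electrodes 3, 4, 7, 8 are on the left side of the cord and
#' 1, 2, 5, 6 on the right.
#'
#' @return A data frame with columns `electrode`, `column`, `side`.
#' @export
default_channel_map <- function() {
  data.frame(
    electrode = 1:8,
    column = c("lateral", "dorsal", "dorsal", "lateral",
               "lateral", "dorsal", "dorsal", "lateral"),
    side = c("right", "right", "left", "left",
             "right", "right", "left", "left"),
    stringsAsFactors = FALSE
  )
}

#' Classify a walking cadence into the lower/higher analysis groups
#'
#' Sessions slower than 0.67 steps/s belong to the lower-cadence group and
#' faster than 0.73 steps/s to the higher-cadence group; cadences in between
#' are excluded from the cadence analysis.
#'
#' @param cadence Cadence in steps/second.
#' @return `"lower"`, `"higher"` or `"excluded"`.
#' @export
cadence_group <- function(cadence) {
  ifelse(cadence < 0.67, "lower", ifelse(cadence > 0.73, "higher", "excluded"))
}

#' Generate a complete synthetic session
#'
#' Bundles LFP, kinematics, the default channel map and metadata (cadence,
#' cadence group, seed and the generator's ground truth) into a session
#' container.
#'
#' @param config A [synth_config()].
#' @return An object of class `lfp_session`; see [validate_session()] for the
#'   container contract.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  kin <- generate_kinematics(config)
  lfp <- generate_lfp(config, kin$phi)
  session <- structure(list(
    neural = lfp,
    neural_fs = config$neural_fs,
    kinematics = kin$angles,
    kin_fs = config$kin_fs,
    channel_map = default_channel_map()[seq_len(config$n_channels), ],
    meta = list(
      cadence = config$gait$cadence,
      cadence_group = cadence_group(config$gait$cadence),
      seed = config$seed,
      ground_truth = list(phi = kin$phi, coupling = config$coupling,
                          gait = config$gait,
                          band_amp = effective_band_amp(config)),
      notes = "synthetic session"
    )
  ), class = "lfp_session")
  validate_session(session)
  session
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf(
    "<lfp_session> %d channels x %d samples @ %g Hz | %d joints x %d samples @ %g Hz\n",
    nrow(x$neural), ncol(x$neural), x$neural_fs,
    nrow(x$kinematics), ncol(x$kinematics), x$kin_fs))
  cat(sprintf("  cadence %.3g steps/s (%s group)\n",
              x$meta$cadence, x$meta$cadence_group))
  invisible(x)
}
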