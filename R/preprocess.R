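# ---------------------------------------------------------------------------
# Preprocessing chain: notch -> six-band Butterworth bank -> rectified
# envelopes (4 Hz low-pass, resampled to 10 Hz) + windowed LFP amplitude
# (ALFP) -> lagged 3D feature tensors aligned with kinematic targets.
# All filtering is zero-phase (forward-backward), so features stay time-locked
# to the raw signal.
# ---------------------------------------------------------------------------

#' Canonical six-band specification
#'
#' delta (0.5-4 Hz), theta (6-12 Hz), beta (15-30 Hz), gamma (40-80 Hz),
#' high-gamma (80-120 Hz) and ripple (150-210 Hz).
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz).
#' @export
band_specs <- function() {
  data.frame(
    name = c("delta", "theta", "beta", "gamma", "high_gamma", "ripple"),
    low = c(0.5, 6, 15, 40, 80, 150),
    high = c(4, 12, 30, 80, 120, 210),
    stringsAsFactors = FALSE
  )
}

check_bands <- function(bands, fs) {
  if (!all(c("name", "low", "high") %in% names(bands)))
    stop("band specification needs columns name, low, high")
  if (any(bands$low <= 0) || any(bands$low >= bands$high))
    stop("band edges must satisfy 0 < low < high")
  if (any(bands$high >= fs / 2))
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 max(bands$high), fs / 2))
  invisible(bands)
}

#' Remove mains interference with Butterworth notch filters
#'
#' Applies 4th-order Butterworth band-stop filters (zero phase) centred at
#' each line frequency with a +/- `width` Hz stop band.
#'
#' @param x Signal vector or channels-by-samples matrix.
#' @param fs Sampling rate in Hz; must exceed twice the highest line frequency.
#' @param lines Line frequencies in Hz (default 50, 100, 150).
#' @param width Half-width of each stop band in Hz (default 2).
#' @return Filtered signal, same shape as `x`.
#' @export
remove_line_noise <- function(x, fs, lines = c(50, 100, 150), width = 2) {
  if (max(lines) + width >= fs / 2)
    stop(sprintf("notch at %g Hz requires fs > %g Hz", max(lines),
                 2 * (max(lines) + width)))
  for (f0 in lines) {
    sos <- butter_sos(4, c(f0 - width, f0 + width), fs, "stop")
    x <- sos_filtfilt(sos, x)
  }
  x
}

#' Band-pass filter bank
#'
#' Splits the signal into the canonical six bands (or a custom bank) with
#' 4th-order Butterworth band-pass filters applied zero-phase.
#'
#' @param x Signal vector or channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @param bands Band table as from [band_specs()].
#' @return Named list with one filtered signal (same shape as `x`) per band.
#' @export
bandpass_bank <- function(x, fs, bands = band_specs()) {
  check_bands(bands, fs)
  out <- lapply(seq_len(nrow(bands)), function(b) {
    sos <- butter_sos(4, c(bands$low[b], bands$high[b]), fs, "pass")
    sos_filtfilt(sos, x)
  })
  names(out) <- bands$name
  out
}

# 10 Hz analysis grid shared by envelopes, ALFP, tensors and targets:
# centres of 200 ms windows stepped every 100 ms.
feature_times <- function(n_samples, fs) {
  n_win <- floor((n_samples - 0.2 * fs) / (0.1 * fs)) + 1
  if (n_win < 1) stop("signal shorter than one 200 ms window")
  0.1 + 0.1 * (seq_len(n_win) - 1)
}

#' Band-limited envelope at 10 Hz
#'
#' Full-wave rectifies the band-limited signal, low-pass filters it at 4 Hz
#' (4th-order Butterworth, zero phase) and resamples it onto the shared 10 Hz
#' grid. The 4 Hz low-pass is itself the anti-alias filter for the 10 Hz
#' grid, so resampling reduces to sampling the filtered series at the grid
#' times.
#'
#' @param x Band-limited signal vector or channels-by-samples matrix at rate `fs`.
#' @param fs Sampling rate in Hz.
#' @return List with `values` (same leading shape as `x`, 10 Hz columns) and
#'   `t` (seconds). Values are clamped at zero (envelopes are non-negative).
#' @export
envelope <- function(x, fs) {
  sos <- butter_sos(4, 4, fs, "low")
  tt <- feature_times(if (is.matrix(x)) ncol(x) else length(x), fs)
  idx <- round(tt * fs) + 1
  sm <- sos_filtfilt(sos, abs(x))
  values <- if (is.matrix(sm)) sm[, idx, drop = FALSE] else sm[idx]
  values[values < 0] <- 0
  list(values = values, t = tt)
}

#' Windowed average LFP amplitude (ALFP) at 10 Hz
#'
#' Mean of the rectified broadband LFP within sliding 200 ms windows stepped
#' every 100 ms. The raw LFP is near zero-mean, so the signed mean would be
#' uninformative; the rectified mean is used (see the methods vignette).
#'
#' @param x Broadband (notched) LFP vector or channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @return List with `values` and `t` on the shared 10 Hz grid.
#' @export
compute_alfp <- function(x, fs) {
  one <- function(v) {
    n <- length(v)
    tt <- feature_times(n, fs)
    w <- round(0.2 * fs)
    step <- round(0.1 * fs)
    cs <- cumsum(c(0, abs(v)))
    starts <- (seq_along(tt) - 1) * step + 1
    (cs[starts + w] - cs[starts]) / w
  }
  if (is.matrix(x)) {
    tt <- feature_times(ncol(x), fs)
    values <- t(apply(x, 1, one))
  } else {
    tt <- feature_times(length(x), fs)
    values <- one(x)
  }
  list(values = values, t = tt)
}

#' Extract the full feature set from a session
#'
#' Notches line noise, runs the band bank, computes band envelopes and the
#' ALFP, all on the shared 10 Hz grid.
#'
#' @param session An `lfp_session`.
#' @param bands Band table (default the canonical six).
#' @return List with `env` (channel x band x time array), `alfp`
#'   (channel x time matrix), `t` (seconds), `bands`, and the session's
#'   channel map.
#' @export
extract_features <- function(session, bands = band_specs()) {
  validate_session(session)
  fs <- session$neural_fs
  clean <- remove_line_noise(session$neural, fs)
  bank <- bandpass_bank(clean, fs, bands)
  tt <- feature_times(ncol(session$neural), fs)
  env <- array(0, dim = c(nrow(session$neural), nrow(bands), length(tt)),
               dimnames = list(NULL, bands$name, NULL))
  for (b in seq_len(nrow(bands)))
    env[, b, ] <- envelope(bank[[b]], fs)$values
  alfp <- compute_alfp(clean, fs)
  list(env = env, alfp = alfp$values, t = tt, bands = bands,
       channel_map = session$channel_map)
}

#' Assemble lagged 3D feature tensors
#'
#' At each valid time point `t` builds the tensor
#' `T[c, l, f] = feature f of channel c at t - l*100 ms`, with features
#' ordered as the six band envelopes followed by the ALFP. Time points
#' without a complete lag history are dropped, so the first tensor sits
#' `(n_lags - 1) * 100` ms after the feature-series start.
#'
#' @param features Output of [extract_features()], or a list with `env`,
#'   `alfp`, `t`.
#' @param n_lags Number of 100 ms lags (default 10).
#' @return An object of class `feature_tensor_series`: array of dimension
#'   `(channel, lag, feature, time)` with a `t` attribute (seconds).
#' @export
build_feature_tensor <- function(features, n_lags = 10) {
  env <- features$env
  alfp <- features$alfp
  if (is.null(dim(alfp))) alfp <- matrix(alfp, nrow = 1)
  n_ch <- dim(env)[1]
  n_band <- dim(env)[2]
  n_t <- dim(env)[3]
  if (nrow(alfp) != n_ch || ncol(alfp) != n_t)
    stop("envelope and ALFP series are misaligned")
  if (n_t < n_lags) stop("feature series shorter than the lag history")
  feat <- array(0, dim = c(n_ch, n_band + 1, n_t))
  feat[, seq_len(n_band), ] <- env
  feat[, n_band + 1, ] <- alfp
  valid <- n_lags:n_t
  out <- array(0, dim = c(n_ch, n_lags, n_band + 1, length(valid)))
  for (l in seq_len(n_lags))
    out[, l, , ] <- feat[, , valid - (l - 1)]
  bnames <- dimnames(env)[[2]]
  if (is.null(bnames)) bnames <- paste0("band", seq_len(n_band))
  fnames <- c(bnames, "alfp")
  dimnames(out) <- list(NULL, NULL, fnames, NULL)
  structure(out, t = features$t[valid], class = "feature_tensor_series")
}

#' Time stamps of a feature tensor series
#' @param fts A `feature_tensor_series`.
#' @return Numeric vector of seconds.
#' @export
tensor_times <- function(fts) attr(fts, "t")

#' Align kinematic targets with the feature grid
#'
#' Anti-alias low-pass filters the joint angles (4 Hz, 4th-order Butterworth,
#' zero phase; gait content lies well below) and samples them at the feature
#' time stamps by linear interpolation.
#'
#' @param kinematics 6 x T matrix of joint angles (degrees) at rate `kin_fs`.
#' @param kin_fs Kinematic sampling rate in Hz.
#' @param times Feature time stamps in seconds.
#' @return Joints x length(times) matrix of targets.
#' @export
align_targets <- function(kinematics, kin_fs, times) {
  if (is.null(dim(kinematics))) kinematics <- matrix(kinematics, nrow = 1)
  t_k <- (seq_len(ncol(kinematics)) - 1) / kin_fs
  if (min(times) < min(t_k) - 1e-9 || max(times) > max(t_k) + 1e-9)
    stop("feature times fall outside the kinematic record")
  sos <- butter_sos(4, 4, kin_fs, "low")
  out <- matrix(0, nrow = nrow(kinematics), ncol = length(times))
  for (j in seq_len(nrow(kinematics))) {
    sm <- sos_filtfilt(sos, kinematics[j, ])
    out[j, ] <- stats::approx(t_k, sm, xout = times, rule = 2)$y
  }
  rownames(out) <- rownames(kinematics)
  out
}

#' Preprocess a session end to end
#'
#' Convenience wrapper: features, lagged tensors and aligned targets.
#'
#' @param session An `lfp_session`.
#' @param n_lags Number of 100 ms lags (default 10).
#' @param bands Band table.
#' @return List with `tensors` (`feature_tensor_series`), `targets`
#'   (joints x time), `features`, and `channel_map`.
#' @export
preprocess_session <- function(session, n_lags = 10, bands = band_specs()) {
  feats <- extract_features(session, bands)
  tensors <- build_feature_tensor(feats, n_lags)
  targets <- align_targets(session$kinematics, session$kin_fs,
                           tensor_times(tensors))
  list(tensors = tensors, targets = targets, features = feats,
       channel_map = session$channel_map)
}
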