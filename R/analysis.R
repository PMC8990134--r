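# ---------------------------------------------------------------------------
# Descriptive analyses: gait-cycle segmentation, gait-locked ERD/ERS
# time-frequency maps, mutual-information matrices, ANOVA/Tukey comparisons
# and the cadence band-power analysis.
# ---------------------------------------------------------------------------

#' Segment a recording into gait cycles
#'
#' For synthetic sessions the generator's ground-truth phase is used
#' directly. Otherwise cycle onsets are detected as local maxima of the hip
#' angle after low-pass filtering at twice the dominant stepping frequency.
#'
#' @param session An `lfp_session`; or `NULL` if `phase` is given.
#' @param phase Optional unwrapped gait phase (radians) at rate `fs`.
#' @param fs Sampling rate of `phase` (Hz); defaults to the session's
#'   kinematic rate.
#' @param hip_row Row of the kinematic matrix holding the hip angle used for
#'   event detection (default 1, the left hip).
#' @return An object of class `gait_cycle_set`: `boundaries` (cycle onset
#'   times, seconds, strictly increasing) plus the sample grid (`t`, `fs`)
#'   and per-sample normalized phase in `[0, 1)` (NA outside the covered
#'   span).
#' @export
segment_gait_cycles <- function(session = NULL, phase = NULL, fs = NULL,
                                hip_row = 1) {
  if (is.null(phase) && !is.null(session) &&
      !is.null(session$meta$ground_truth$phi)) {
    phase <- session$meta$ground_truth$phi
    fs <- session$kin_fs
  }
  if (!is.null(phase)) {
    if (is.null(fs)) stop("fs is required with an explicit phase vector")
    t <- (seq_along(phase) - 1) / fs
    if ((max(phase) - min(phase)) < 4 * pi)
      stop("fewer than two full gait cycles in the record")
    k <- seq(ceiling(phase[1] / (2 * pi)), floor(phase[length(phase)] / (2 * pi)))
    boundaries <- stats::approx(phase, t, xout = 2 * pi * k)$y
    norm_phase <- (phase %% (2 * pi)) / (2 * pi)
    return(structure(list(boundaries = boundaries, t = t, fs = fs,
                          phase = norm_phase), class = "gait_cycle_set"))
  }
  if (is.null(session)) stop("either a session or a phase vector is required")
  x <- session$kinematics[hip_row, ]
  fs <- session$kin_fs
  if (stats::sd(x) < 1e-9) stop("kinematics are constant; no gait cycles detectable")
  # dominant stepping frequency from the periodogram (ignore DC)
  sp <- stats::spec.pgram(x - mean(x), taper = 0, plot = FALSE, detrend = FALSE)
  f0 <- sp$freq[which.max(sp$spec)] * fs
  if (f0 <= 0 || max(sp$spec) < 1e-6)
    stop("no detectable periodicity in the kinematics")
  sm <- sos_filtfilt(butter_sos(4, min(2 * f0, 0.45 * fs), fs, "low"), x)
  mind <- max(1L, round(0.5 * fs / f0))
  n <- length(sm)
  peaks <- which(vapply(seq(2, n - 1), function(i)
    sm[i] > sm[i - 1] && sm[i] >= sm[i + 1], logical(1))) + 1
  # enforce minimum separation, keeping the larger peak
  keep <- c()
  for (p in peaks) {
    if (length(keep) == 0 || p - keep[length(keep)] >= mind) keep <- c(keep, p)
    else if (sm[p] > sm[keep[length(keep)]]) keep[length(keep)] <- p
  }
  if (length(keep) < 3) stop("fewer than two full gait cycles detected")
  t <- (seq_len(n) - 1) / fs
  boundaries <- t[keep]
  norm_phase <- rep(NA_real_, n)
  for (i in seq_len(length(keep) - 1)) {
    span <- keep[i]:(keep[i + 1] - 1)
    norm_phase[span] <- (span - keep[i]) / (keep[i + 1] - keep[i])
  }
  structure(list(boundaries = boundaries, t = t, fs = fs, phase = norm_phase),
            class = "gait_cycle_set")
}

#' Number of complete gait cycles in a cycle set
#' @param cycles A `gait_cycle_set`.
#' @return Integer count of complete cycles.
#' @export
n_cycles <- function(cycles) max(length(cycles$boundaries) - 1, 0)

#' Normalized gait phase at arbitrary times
#'
#' @param cycles A `gait_cycle_set`.
#' @param times Times in seconds.
#' @return Phase in `[0, 1)` per time; NA outside the segmented span.
#' @export
cycle_phase <- function(cycles, times) {
  b <- cycles$boundaries
  i <- findInterval(times, b)
  out <- rep(NA_real_, length(times))
  ok <- i >= 1 & i < length(b)
  out[ok] <- (times[ok] - b[i[ok]]) / (b[i[ok] + 1] - b[i[ok]])
  out
}

#' Gait-cycle-locked average envelope (ERD/ERS map)
#'
#' Assigns each envelope sample to a phase bin and averages per channel and
#' band; the percent change of each bin relative to the cycle mean quantifies
#' event-related synchronization (positive) and desynchronization (negative).
#'
#' @param env Channel x band x time envelope array (or channel x time matrix
#'   treated as one band).
#' @param times Envelope time stamps in seconds.
#' @param cycles A `gait_cycle_set` covering the envelope span.
#' @param bins Number of phase bins (default 100).
#' @return An object of class `tf_map`: `mean` and `pct_change` arrays of
#'   dimension channel x band x bin, plus `bins` and `n_cycles`.
#' @export
cycle_average <- function(env, times, cycles, bins = 100) {
  if (n_cycles(cycles) < 2) stop("need at least two complete gait cycles")
  if (is.matrix(env)) env <- array(env, dim = c(nrow(env), 1, ncol(env)))
  ph <- cycle_phase(cycles, times)
  ok <- !is.na(ph)
  if (!any(ok)) stop("envelope does not overlap the segmented cycles")
  bin <- pmin(floor(ph[ok] * bins), bins - 1) + 1
  d <- dim(env)
  mean_map <- array(NA_real_, dim = c(d[1], d[2], bins),
                    dimnames = c(dimnames(env)[1:2], list(NULL)))
  for (c_i in seq_len(d[1])) for (b in seq_len(d[2])) {
    v <- env[c_i, b, ok]
    mean_map[c_i, b, ] <- vapply(seq_len(bins), function(k)
      mean(v[bin == k]), numeric(1))
  }
  cyc_mean <- apply(mean_map, c(1, 2), mean)
  pct <- sweep(sweep(mean_map, c(1, 2), cyc_mean, "-"), c(1, 2), cyc_mean, "/") * 100
  structure(list(mean = mean_map, pct_change = pct, bins = bins,
                 n_cycles = n_cycles(cycles)), class = "tf_map")
}

#' Mutual information matrix of one session
#'
#' MI (bits) between every feature series (six band envelopes and the ALFP,
#' per channel) and every joint angle, both on the shared 10 Hz grid.
#'
#' @param features Output of [extract_features()].
#' @param kinematics Joints x samples matrix at rate `kin_fs`.
#' @param kin_fs Kinematic sampling rate (Hz).
#' @return Array `channel x feature(7) x joint(6)` of MI values in bits.
#' @export
mi_matrix <- function(features, kinematics, kin_fs) {
  targets <- align_targets(kinematics, kin_fs, features$t)
  n_ch <- dim(features$env)[1]
  n_band <- dim(features$env)[2]
  fnames <- c(dimnames(features$env)[[2]], "alfp")
  jn <- rownames(kinematics)
  if (is.null(jn)) jn <- paste0("joint", seq_len(nrow(kinematics)))
  out <- array(0, dim = c(n_ch, n_band + 1, nrow(targets)),
               dimnames = list(NULL, fnames, jn))
  for (c_i in seq_len(n_ch)) {
    for (b in seq_len(n_band))
      for (j in seq_len(nrow(targets)))
        out[c_i, b, j] <- mutual_information(features$env[c_i, b, ],
                                             targets[j, ])
    alfp <- if (is.matrix(features$alfp)) features$alfp[c_i, ] else features$alfp
    for (j in seq_len(nrow(targets)))
      out[c_i, n_band + 1, j] <- mutual_information(alfp, targets[j, ])
  }
  out
}

#' Mutual information analysis across sessions
#'
#' Computes per-session MI matrices and averages them, plus the band-level
#' summary (average over channels and joints per feature type) and the
#' channel-level summary (average over feature types and joints).
#'
#' @param sessions List of `lfp_session` objects.
#' @return List with `per_session` (list of arrays), `mean` (array),
#'   `by_feature` (named vector) and `by_channel` (vector).
#' @export
mi_analysis <- function(sessions) {
  if (length(sessions) < 1) stop("at least one session is required")
  mats <- lapply(sessions, function(s) {
    f <- extract_features(s)
    mi_matrix(f, s$kinematics, s$kin_fs)
  })
  mean_mat <- Reduce(`+`, mats) / length(mats)
  list(per_session = mats, mean = mean_mat,
       by_feature = apply(mean_mat, 2, mean),
       by_channel = apply(mean_mat, 1, mean))
}

#' ANOVA with Tukey HSD post hoc comparisons
#'
#' @param formula Model formula, e.g. `value ~ group` or `value ~ a * b`.
#' @param data Data frame with the response and factor columns.
#' @param alpha Significance level (default 0.05).
#' @return List with the `aov` fit, the ANOVA `table`, `tukey` results and
#'   `alpha`.
#' @export
compare_groups <- function(formula, data, alpha = 0.05) {
  vars <- all.vars(formula)[-1]
  for (v in vars) {
    data[[v]] <- as.factor(data[[v]])
    if (nlevels(data[[v]]) < 2)
      stop(sprintf("factor '%s' needs at least two levels", v))
  }
  counts <- table(data[vars])
  if (any(counts < 2))
    stop("each group needs at least two observations")
  fit <- stats::aov(formula, data = data)
  list(fit = fit, table = summary(fit), tukey = stats::TukeyHSD(fit),
       alpha = alpha)
}

#' Cadence band-power comparison
#'
#' Groups sessions into lower (< 0.67 steps/s) and higher (> 0.73 steps/s)
#' cadence; sessions in between are excluded. For each band the session-level
#' mean envelope amplitude during movement (samples inside detected gait
#' cycles, averaged over channels) is compared between groups with a Welch
#' t-test.
#'
#' @param sessions List of `lfp_session` objects.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `cadence_comparison`: data frame with columns
#'   `band`, `mean_lower`, `mean_higher`, `statistic`, `p_value`,
#'   `significant`, with the per-session band means as an attribute.
#' @export
cadence_analysis <- function(sessions, alpha = 0.05) {
  groups <- vapply(sessions, function(s)
    cadence_group(s$meta$cadence), character(1))
  used <- groups %in% c("lower", "higher")
  if (sum(groups == "lower") < 1 || sum(groups == "higher") < 1)
    stop("need at least one session in each cadence group")
  sessions <- sessions[used]
  groups <- groups[used]
  bands <- band_specs()$name
  per_session <- t(vapply(sessions, function(s) {
    f <- extract_features(s)
    cyc <- segment_gait_cycles(s)
    ph <- cycle_phase(cyc, f$t)
    moving <- !is.na(ph)
    vapply(seq_along(bands), function(b)
      mean(f$env[, b, moving]), numeric(1))
  }, numeric(length(bands))))
  colnames(per_session) <- bands
  res <- lapply(seq_along(bands), function(b) {
    lo <- per_session[groups == "lower", b]
    hi <- per_session[groups == "higher", b]
    tt <- stats::t.test(hi, lo)   # Welch
    data.frame(band = bands[b], mean_lower = mean(lo), mean_higher = mean(hi),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "per_session") <- per_session
  attr(out, "groups") <- groups
  class(out) <- c("cadence_comparison", class(out))
  out
}
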