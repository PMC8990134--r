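#' @useDynLib lfpdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Butterworth IIR design in zero-pole-gain form, realized as second-order
# sections and applied forward-backward (zero phase). The design route is the
# classical one: analog lowpass prototype -> frequency transform -> bilinear
# transform -> biquad cascade. No IIR design facility exists in the stack this
# package depends on, so it is implemented here and validated by
# frequency-response tests.
# ---------------------------------------------------------------------------

butter_prototype <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # force exact conjugate symmetry
  p[abs(Im(p)) < 1e-12] <- Re(p[abs(Im(p)) < 1e-12])
  list(z = complex(0), p = p, k = 1)
}

lp2lp_zpk <- function(zpk, wo) {
  degree <- length(zpk$p) - length(zpk$z)
  list(z = zpk$z * wo, p = zpk$p * wo, k = zpk$k * wo^degree)
}

lp2hp_zpk <- function(zpk, wo) {
  degree <- length(zpk$p) - length(zpk$z)
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = c(wo / zpk$z, rep(0 + 0i, degree)), p = wo / zpk$p, k = k)
}

.bp_roots <- function(r, wo, bw) {
  h <- r * bw / 2
  s <- sqrt(h^2 - wo^2 + 0i)
  c(h + s, h - s)
}

lp2bp_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  z <- c(.bp_roots(zpk$z, wo, bw), rep(0 + 0i, degree))
  p <- .bp_roots(zpk$p, wo, bw)
  list(z = z, p = p, k = zpk$k * bw^degree)
}

lp2bs_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zinv <- (bw / 2) / zpk$z
  pinv <- (bw / 2) / zpk$p
  z <- c(.bs_roots(zinv, wo), rep(1i * wo, degree), rep(-1i * wo, degree))
  p <- .bs_roots(pinv, wo)
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = z, p = p, k = k)
}

.bs_roots <- function(rinv, wo) {
  s <- sqrt(rinv^2 - wo^2 + 0i)
  c(rinv + s, rinv - s)
}

bilinear_zpk <- function(zpk, fs) {
  degree <- length(zpk$p) - length(zpk$z)
  fs2 <- 2 * fs
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  zd <- c(zd, rep(-1 + 0i, degree))
  k <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = zd, p = pd, k = k)
}

# Split a set of roots (closed under conjugation) into conjugate/real pairs.
.root_pairs <- function(r) {
  tol <- 1e-8
  cplx <- r[Im(r) > tol]
  real <- sort(Re(r[abs(Im(r)) <= tol]))
  pairs <- lapply(cplx, function(x) c(x, Conj(x)))
  if (length(real) %% 2 != 0)
    stop("internal: odd number of real roots; even filter order expected")
  if (length(real) > 0) {
    idx <- seq(1, length(real), by = 2)
    pairs <- c(pairs, lapply(idx, function(i) complex(real = real[c(i, i + 1)])))
  }
  pairs
}

# Pair poles and zeros into biquads: poles closest to the unit circle first,
# each taking its nearest available zero pair. Adequate for Butterworth banks.
zpk2sos <- function(zpk) {
  z <- zpk$z
  p <- zpk$p
  if (length(z) != length(p))
    stop("internal: zpk2sos expects equal zero and pole counts")
  pp <- .root_pairs(p)
  zp <- .root_pairs(z)
  ord <- order(vapply(pp, function(q) -max(Mod(q)), numeric(1)))
  pp <- pp[ord]
  sos <- matrix(0, nrow = length(pp), ncol = 6)
  for (i in seq_along(pp)) {
    d <- vapply(zp, function(q) sum(Mod(q - pp[[i]])), numeric(1))
    j <- which.min(d)
    zi <- zp[[j]]
    zp <- zp[-j]
    b <- c(1, -Re(zi[1] + zi[2]), Re(zi[1] * zi[2]))
    a <- c(1, -Re(pp[[i]][1] + pp[[i]][2]), Re(pp[[i]][1] * pp[[i]][2]))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' Designs an `n`-th order Butterworth prototype (band-pass and band-stop
#' designs therefore have `2n` poles, as in the usual `butter(n, ...)`
#' convention) via the bilinear transform, returned as a cascade of biquads.
#'
#' @param n Prototype order (4 throughout the canonical preprocessing chain).
#' @param w Corner frequency in Hz (scalar for `low`/`high`, length-2 for
#'   `pass`/`stop`). These are the -3 dB points of the single-pass response.
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return A `K x 6` matrix of second-order sections `(b0 b1 b2 1 a1 a2)`.
#' @export
butter_sos <- function(n, w, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= fs / 2))
    stop("filter corner frequencies must lie strictly inside (0, Nyquist)")
  proto <- butter_prototype(n)
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * (w / (fs / 2)) / fs2)
  zpk <- switch(type,
    low  = lp2lp_zpk(proto, warped),
    high = lp2hp_zpk(proto, warped),
    pass = {
      bw <- warped[2] - warped[1]
      wo <- sqrt(warped[1] * warped[2])
      lp2bp_zpk(proto, wo, bw)
    },
    stop = {
      bw <- warped[2] - warped[1]
      wo <- sqrt(warped[1] * warped[2])
      lp2bs_zpk(proto, wo, bw)
    }
  )
  zpk <- bilinear_zpk(zpk, fs2)
  zpk2sos(zpk)
}

#' Zero-phase filtering through second-order sections
#'
#' Applies the cascade forward and backward (square of the magnitude response,
#' zero phase), with odd extension padding and steady-state initial conditions
#' to suppress startup transients.
#'
#' @param sos Second-order-section matrix from [butter_sos()].
#' @param x Numeric vector, or a channels-by-samples matrix filtered row-wise.
#' @param padlen Extension length in samples (default caps at `length(x) - 1`).
#' @return Filtered signal, same shape as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = 3000L) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x)))
      out[i, ] <- .sosfiltfilt_cpp(sos, x[i, ], as.integer(padlen))
    return(out)
  }
  .sosfiltfilt_cpp(sos, x, as.integer(padlen))
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos Second-order-section matrix.
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response at each frequency (single pass; the zero-phase
#'   chain applies its squared magnitude).
#' @export
sos_freq_response <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  h <- rep(1 + 0i, length(w))
  for (k in seq_len(nrow(sos))) {
    e1 <- exp(-1i * w)
    e2 <- exp(-2i * w)
    num <- sos[k, 1] + sos[k, 2] * e1 + sos[k, 3] * e2
    den <- 1 + sos[k, 5] * e1 + sos[k, 6] * e2
    h <- h * num / den
  }
  h
}
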