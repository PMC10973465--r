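# Fourier synchrosqueezed transform (FSST) feature extraction.
#
# Filter-bank STFT at unit hop with a Kaiser window, instantaneous-frequency
# reassignment (synchrosqueezing) of each spectral bin, restricted to a
# frequency band; the real and imaginary parts of the squeezed spectrum are
# the per-sample feature channels.

#' FSST feature configuration
#'
#' @param window_length Kaiser window length in samples.
#' @param sidelobe_db Kaiser sidelobe attenuation (dB); 13.6 dB corresponds
#'   to a near-rectangular window (shape parameter beta about 0.5).
#' @param band c(lo, hi) frequency band (Hz) of bins kept as features;
#'   inclusive bounds.
#' @param raw if TRUE, bypass the transform: features are the raw waveform
#'   (one channel).
#' @param fs sampling rate (Hz).
#' @param max_analysis_hz highest STFT bin synchrosqueezed into the band
#'   (energy from far bins does not reassign into the passband).
#' @return list of class \code{cardiomag_fsst_config}.
#' @export
fsst_config <- function(window_length = 512, sidelobe_db = 13.6,
                        band = c(3.5, 12), raw = FALSE, fs = 1000,
                        max_analysis_hz = 50) {
  if (!raw) {
    if (band[2] > fs / 2 || band[1] < 0) stop("band outside [0, Nyquist]")
    stopifnot(band[1] < band[2])
  }
  beta <- .kaiser_beta(sidelobe_db)
  structure(list(window_length = window_length, sidelobe_db = sidelobe_db,
                 beta = beta, band = band, raw = raw, fs = fs,
                 max_analysis_hz = max_analysis_hz),
            class = "cardiomag_fsst_config")
}

# Kaiser shape parameter from sidelobe attenuation (standard design formula;
# below 21 dB the window approaches rectangular, beta -> 0; a small positive
# beta is retained for a smooth taper)
.kaiser_beta <- function(a_db) {
  if (a_db > 50) 0.1102 * (a_db - 8.7)
  else if (a_db >= 21) 0.5842 * (a_db - 21)^0.4 + 0.07886 * (a_db - 21)
  else 0.5
}

# band bin indices (0-based k, frequency k*fs/N)
.band_bins <- function(config) {
  N <- config$window_length
  k <- 0:(N %/% 2)
  f <- k * config$fs / N
  k[f >= config$band[1] & f <= config$band[2]]
}

#' Per-sample FSST features of a waveform
#'
#' Computes the synchrosqueezed short-time Fourier spectrum at every sample
#' (unit hop). Each STFT bin's energy is reassigned to the output bin nearest
#' its instantaneous frequency estimate (from the derivative-window
#' transform); output bins are restricted to the configured band. Returns a
#' channels x n matrix: real parts of the band bins, then imaginary parts.
#'
#' @param x numeric waveform, or a \code{cardiomag_field_record} (first
#'   non-NA axis used).
#' @param config a \code{\link{fsst_config}}.
#' @return numeric matrix (2 * n_bins) x length(x); for \code{raw} configs,
#'   1 x length(x).
#' @export
fsst_features <- function(x, config = fsst_config()) {
  if (inherits(x, "cardiomag_field_record")) {
    ax <- names(which(!vapply(x[c("Bx_pT", "By_pT", "Bz_pT")],
                              function(z) all(is.na(z)), logical(1))))[1]
    x <- x[[ax]]
  }
  n <- length(x)
  if (config$raw) return(matrix(x, nrow = 1))
  N <- config$window_length
  if (N > n) stop("record shorter than the analysis window")
  fs <- config$fs
  w <- .kaiser_window(N, config$beta)
  dw <- .window_derivative(w, fs)
  kmax <- min(N %/% 2, floor(config$max_analysis_hz * N / fs))
  bins <- .band_bins(config)
  if (!length(bins)) stop("no STFT bins inside the band")

  L <- stats::nextn(n + N, 2)
  xpad <- c(x, numeric(L - n))
  X <- fft(xpad)
  center <- N %/% 2
  out <- matrix(0 + 0i, length(bins), n)
  # STFT per analysis bin via FFT convolution with the time-reversed kernel:
  # (x * rev(g))[t] = sum_m x[t - (N-1) + m] g[m]; sampling at
  # t = i + (N-1) - center centers the window on sample i
  S <- Sd <- matrix(0 + 0i, kmax + 1, n)
  m <- 0:(N - 1)
  idx <- (seq_len(n) - 1) + (N - 1) - center + 1
  for (k in 0:kmax) {
    ph <- exp(-2i * pi * k * m / N)
    gk <- w * ph
    gdk <- dw * ph
    Grev <- fft(c(rev(gk), numeric(L - N)))
    Gdrev <- fft(c(rev(gdk), numeric(L - N)))
    conv <- fft(X * Grev, inverse = TRUE) / L
    convd <- fft(X * Gdrev, inverse = TRUE) / L
    S[k + 1, ] <- conv[idx]
    Sd[k + 1, ] <- convd[idx]
  }
  # instantaneous frequency (Hz) per bin/sample
  eps <- 1e-300
  omega <- matrix(rep((0:kmax) * fs / N, n), kmax + 1, n)
  corr <- Im(Sd / (S + eps)) / (2 * pi)
  finite <- is.finite(corr)
  omega[finite] <- omega[finite] - corr[finite]
  # reassign to nearest output bin
  target <- round(omega * N / fs)
  for (b in seq_along(bins)) {
    sel <- target == bins[b]
    if (any(sel)) {
      contrib <- S
      contrib[!sel] <- 0
      out[b, ] <- colSums(contrib)
    }
  }
  rbind(Re(out), Im(out))
}

.kaiser_window <- function(n, beta) {
  m <- seq(0, n - 1)
  r <- 2 * m / (n - 1) - 1
  besselI(beta * sqrt(pmax(0, 1 - r^2)), 0) / besselI(beta, 0)
}

# time derivative of the window (per second), centered differences
.window_derivative <- function(w, fs) {
  n <- length(w)
  d <- numeric(n)
  d[2:(n - 1)] <- (w[3:n] - w[1:(n - 2)]) / 2
  d[1] <- w[2] - w[1]
  d[n] <- w[n] - w[n - 1]
  d * fs
}
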