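# Synthetic background-noise generator emulating the shielded-box SQUID
# measurement environment, plus the acquisition filter chain.

#' Background-noise profile
#'
#' Describes the amplitude spectral density template of the measurement
#' environment: a white sensor floor, a 1/f rise below a corner frequency, an
#' elevated band around 12-20 Hz (building vibration / air conditioning), and
#' a residual power-line component at 60 Hz. The generated record is scaled
#' so that its expected 60 s standard deviation after the acquisition filters
#' equals \code{target_sd_pT}.
#'
#' Two profiles ship: \code{"y-cell"} reproduces the noise level measured on
#' the y axis with cell samples (0.146 pT) and \code{"x-wire"} the higher
#' x-axis level with the calibration wire present (0.218 pT).
#'
#' @param name profile name, or \code{"custom"}.
#' @param target_sd_pT 60 s standard deviation target (pT).
#' @param white_floor_fT white amplitude spectral density floor (fT/sqrt(Hz)).
#' @param one_over_f_corner_hz corner below which ASD rises as 1/sqrt(f).
#' @param bump_center_hz,bump_width_hz,bump_gain Gaussian band elevation
#'   (gain multiplies the floor at the center).
#' @param line_hz,line_gain residual power-line component (gain on the floor
#'   in a narrow band).
#' @return list of class \code{cardiomag_noise_profile}.
#' @export
noise_profile <- function(name = c("y-cell", "x-wire", "custom"),
                          target_sd_pT = NULL,
                          white_floor_fT = 15,
                          one_over_f_corner_hz = 5,
                          bump_center_hz = 16, bump_width_hz = 3,
                          bump_gain = 4,
                          line_hz = 60, line_gain = 10) {
  name <- match.arg(name)
  if (is.null(target_sd_pT))
    target_sd_pT <- switch(name, "y-cell" = 0.146, "x-wire" = 0.218,
                           custom = 0.15)
  stopifnot(target_sd_pT >= 0, white_floor_fT >= 0, bump_gain >= 0,
            line_gain >= 0)
  structure(list(name = name, target_sd_pT = target_sd_pT,
                 white_floor_fT = white_floor_fT,
                 one_over_f_corner_hz = one_over_f_corner_hz,
                 bump_center_hz = bump_center_hz,
                 bump_width_hz = bump_width_hz, bump_gain = bump_gain,
                 line_hz = line_hz, line_gain = line_gain),
            class = "cardiomag_noise_profile")
}

# amplitude spectral density template (relative units) at frequencies f (Hz)
.asd_template <- function(profile, f) {
  asd <- rep(1, length(f))
  pos <- f > 0
  asd[pos] <- sqrt(1 + profile$one_over_f_corner_hz / f[pos])
  asd <- asd * (1 + (profile$bump_gain - 1) *
                  exp(-0.5 * ((f - profile$bump_center_hz) /
                                profile$bump_width_hz)^2))
  asd <- asd * (1 + (profile$line_gain - 1) *
                  exp(-0.5 * ((f - profile$line_hz) / 0.5)^2))
  asd[f == 0] <- 0
  asd
}

#' Acquisition filter chain
#'
#' The digital filter cascade applied to every recorded channel: 4th-order
#' Butterworth high-pass at 3 Hz, 4th-order Butterworth low-pass at 100 Hz,
#' and a 2nd-order IIR notch at 60 Hz (Q = 30), each applied
#' forward-backward (zero phase) so peak shapes are not distorted.
#'
#' @param x numeric waveform at 1 kHz, or a \code{cardiomag_field_record}
#'   (all non-NA channels are filtered, labels/truth preserved).
#' @param fs sampling rate (Hz).
#' @param hpf_hz,lpf_hz,notch_hz,notch_q filter parameters.
#' @return filtered object of the same type.
#' @export
apply_acquisition_filters <- function(x, fs = 1000, hpf_hz = 3, lpf_hz = 100,
                                      notch_hz = 60, notch_q = 30) {
  if (inherits(x, "cardiomag_field_record")) {
    for (ch in c("Bx_pT", "By_pT", "Bz_pT"))
      if (!all(is.na(x[[ch]])))
        x[[ch]] <- apply_acquisition_filters(x[[ch]], fs, hpf_hz, lpf_hz,
                                             notch_hz, notch_q)
    return(x)
  }
  hp <- signal::butter(4, hpf_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, lpf_hz / (fs / 2), type = "low")
  # 2nd-order IIR notch: b = [1, -2 cos w0, 1] (normalized), poles at r
  w0 <- 2 * pi * notch_hz / fs
  bw <- notch_hz / notch_q
  r <- exp(-pi * bw / fs)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * (1 + a[2] + a[3]) / (1 + b[2] + b[3])  # unit DC gain
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  y <- signal::filtfilt(signal::Arma(b = b, a = a), y)
  y
}

# expected output SD (relative units) of a unit-scale template after the
# acquisition chain, from the template PSD integral over the filter response
.template_sd <- function(profile, fs = 1000, nfft = 2^16) {
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  asd <- .asd_template(profile, f)
  # filter magnitude responses
  hp <- signal::butter(4, 3 / (fs / 2), type = "high")
  lp <- signal::butter(4, 100 / (fs / 2), type = "low")
  H <- function(flt, f) abs(signal::freqz(flt$b, flt$a, 2 * pi * f / fs)$h)
  g <- H(hp, f)^2 * H(lp, f)^2   # filtfilt doubles the magnitude exponent
  # notch
  w0 <- 2 * pi * 60 / fs; r <- exp(-pi * 2 / fs)
  b <- c(1, -2 * cos(w0), 1); a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * (1 + a[2] + a[3]) / (1 + b[2] + b[3])
  g <- g * H(list(b = b, a = a), f)^2
  # unit white noise colored by asd and filtered has variance equal to the
  # two-sided spectral mean of (asd * gain)^2; the template is symmetric so
  # the one-sided mean equals it
  sqrt(mean((asd * g)^2))
}

#' Generate synthetic background noise
#'
#' Colors white Gaussian noise in the frequency domain with the profile's
#' amplitude spectral density template, passes it through the acquisition
#' filter chain, and scales it so the expected 60 s standard deviation equals
#' the profile target. Deterministic given the seed.
#'
#' @param profile a \code{\link{noise_profile}}.
#' @param duration_s record length (s).
#' @param seed integer seed.
#' @param axis which channel carries the noise (others NA).
#' @param fs sampling rate (Hz).
#' @return a \code{\link{field_record}}.
#' @export
generate_background <- function(profile, duration_s = 120, seed = 1,
                                axis = c("By_pT", "Bx_pT", "Bz_pT"),
                                fs = 1000) {
  stopifnot(duration_s > 0)
  axis <- match.arg(axis)
  n <- round(duration_s * fs)
  if (profile$target_sd_pT == 0) {
    z <- numeric(n)
  } else {
    rng_state <- .save_rng(); on.exit(.restore_rng(rng_state))
    set.seed(seed)
    nfft <- 2^ceiling(log2(n))
    f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
    asd <- .asd_template(profile, abs(f))
    wn <- rnorm(nfft)
    spec <- fft(wn) * asd
    z <- Re(fft(spec, inverse = TRUE)) / nfft
    z <- z[seq_len(n)]
    z <- apply_acquisition_filters(z, fs = fs)
    # scale: unit white noise colored by the template has expected SD
    # sqrt(mean(asd^2 * gain^2)); use the analytic template integral
    z <- z * profile$target_sd_pT / .template_sd_cached(profile)
  }
  args <- list(time_ms = seq_len(n) - 1)
  args[[axis]] <- z
  do.call(field_record, args)
}

# cache the template SD per profile (it is seed-independent)
.noise_cache <- new.env(parent = emptyenv())
.template_sd_cached <- function(profile) {
  key <- paste(unlist(profile), collapse = "|")
  if (is.null(.noise_cache[[key]]))
    .noise_cache[[key]] <- .template_sd(profile)
  .noise_cache[[key]]
}

#' Noise level of a field record
#'
#' The standard deviation of the magnetic flux density over the first 60 s
#' of the chosen axis.
#'
#' @param record a \code{cardiomag_field_record} (>= 60 s long).
#' @param axis channel name.
#' @param window_s averaging window (s).
#' @return noise level (pT).
#' @export
noise_level <- function(record, axis = "By_pT", window_s = 60) {
  n <- round(window_s * attr(record, "fs"))
  x <- record[[axis]]
  if (length(x) < n) stop("record shorter than ", window_s, " s")
  x <- x[seq_len(n)]
  sqrt(mean((x - mean(x))^2))
}
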