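# Scaled-template baseline detector and average-peak-waveform estimation.

#' Scaled-template event detection
#'
#' Slides the template along the record; at each offset fits
#' \code{y = scale * template + offset} by least squares and computes the
#' detection criterion scale / SE, where SE is the residual standard error
#' of the local fit. Detections are local maxima of the criterion above the
#' threshold, with a dead time of one template length.
#'
#' @param x numeric waveform (or \code{cardiomag_field_record}; first non-NA
#'   axis used).
#' @param template a \code{\link{peak_template}}.
#' @param threshold detection threshold on the criterion (\code{Inf} to only
#'   compute the criterion trace).
#' @return list of class \code{cardiomag_template_fit}: per-offset
#'   \code{scale}, \code{offset}, \code{se}, \code{criterion}, and
#'   \code{detections_ms} (template-center times of detections).
#' @export
scaled_template_detect <- function(x, template, threshold = Inf) {
  if (inherits(x, "cardiomag_field_record")) {
    ax <- names(which(!vapply(x[c("Bx_pT", "By_pT", "Bz_pT")],
                              function(z) all(is.na(z)), logical(1))))[1]
    x <- x[[ax]]
  }
  tpl <- template$waveform
  L <- length(tpl)
  n <- length(x)
  if (L >= n) stop("template must be shorter than the record")
  if (sd(tpl) == 0) stop("template has zero variance")
  st <- sum(tpl); stt <- sum(tpl^2)
  ones <- rep(1, L)
  # rolling sums via filter (moving window starting at each offset)
  roll <- function(v, k) {
    cs <- c(0, cumsum(v))
    cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]
  }
  sy <- roll(x, L)
  syy <- roll(x^2, L)
  # sum(template * window) at each offset: cross-correlation
  sty <- as.numeric(stats::convolve(x, tpl, conj = TRUE, type = "filter"))
  # convolve 'filter' returns sum_m x[t+m-1] tpl[m]? verify length n-L+1
  denom <- L * stt - st^2
  scale <- (L * sty - st * sy) / denom
  offset <- (sy - scale * st) / L
  sse <- pmax(0, syy + scale^2 * stt + L * offset^2 -
                2 * scale * sty - 2 * offset * sy + 2 * scale * offset * st)
  se <- sqrt(sse / max(L - 2, 1))
  # floor the residual SE so a numerically perfect fit yields a large finite
  # criterion rather than 0/0
  se_floor <- 1e-9 * sd(tpl)
  crit <- scale / pmax(se, se_floor)
  detections <- integer(0)
  if (is.finite(threshold)) {
    above <- which(crit > threshold)
    ord <- above[order(crit[above], decreasing = TRUE)]
    taken <- logical(length(crit))
    for (i in ord) {
      if (!taken[i]) {
        detections <- c(detections, i)
        lo <- max(1, i - L + 1); hi <- min(length(crit), i + L - 1)
        taken[lo:hi] <- TRUE
      }
    }
    detections <- sort(detections)
  }
  structure(list(scale = scale, offset = offset, se = se, criterion = crit,
                 template_length = L, threshold = threshold,
                 detections_ms = detections - 1 + floor(L / 2)),
            class = "cardiomag_template_fit")
}

#' Calibrate the template-detection threshold to a background rate
#'
#' Finds the smallest threshold whose mean detection rate over background
#' records does not exceed \code{target_rate} (peaks/min), by bisection over
#' the observed criterion range. Used to compare the baseline with the deep
#' detector without bias (equal background false-positive rates).
#'
#' @param background_records list of records (waveforms or field records).
#' @param template a \code{\link{peak_template}}.
#' @param target_rate peaks/min allowed on background.
#' @param iters bisection iterations.
#' @return threshold value.
#' @export
calibrate_template_threshold <- function(background_records, template,
                                         target_rate, iters = 25) {
  stopifnot(length(background_records) >= 1, target_rate >= 0)
  fits <- lapply(background_records, scaled_template_detect,
                 template = template)
  minutes <- vapply(fits, function(f)
    (length(f$criterion) + f$template_length) / 60000, numeric(1))
  rate_at <- function(th) {
    cnt <- vapply(fits, function(f) {
      d <- .pick_detections(f$criterion, th, f$template_length)
      length(d)
    }, numeric(1))
    sum(cnt) / sum(minutes)
  }
  hi <- max(vapply(fits, function(f) max(f$criterion), numeric(1))) + 1
  if (rate_at(hi) > target_rate) stop("target rate unreachable")
  lo <- 0
  if (rate_at(lo) <= target_rate) return(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) <= target_rate) hi <- mid else lo <- mid
  }
  hi
}

.pick_detections <- function(crit, threshold, L) {
  above <- which(crit > threshold)
  ord <- above[order(crit[above], decreasing = TRUE)]
  taken <- logical(length(crit))
  out <- integer(0)
  for (i in ord) {
    if (!taken[i]) {
      out <- c(out, i)
      lo <- max(1, i - L + 1); hi <- min(length(crit), i + L - 1)
      taken[lo:hi] <- TRUE
    }
  }
  sort(out)
}

#' Average peak waveform with adaptive correlation alignment
#'
#' Extracts segments of +/- \code{half_window_ms} around each region center,
#' averages them, then iteratively re-aligns each segment to maximize its
#' correlation with the current mean (integer shifts within
#' \code{max_shift_ms}, ties toward the smaller shift), repeating
#' \code{iterations} times.
#'
#' @param x waveform (or field record).
#' @param regions data.frame with \code{center_ms} (from
#'   \code{\link{detect_peak_regions}}).
#' @param half_window_ms half window length (ms).
#' @param iterations alignment iterations.
#' @param max_shift_ms per-iteration shift bound.
#' @param lpf_hz optional display low-pass (e.g. 12 Hz); NULL for none.
#' @return list of class \code{cardiomag_average_waveform}: \code{time_ms}
#'   (-half..+half), \code{mean_pT}, \code{n}, \code{iterations}.
#' @export
average_peak_waveform <- function(x, regions, half_window_ms = 175,
                                  iterations = 10, max_shift_ms = 50,
                                  lpf_hz = NULL) {
  if (inherits(x, "cardiomag_field_record")) {
    ax <- names(which(!vapply(x[c("Bx_pT", "By_pT", "Bz_pT")],
                              function(z) all(is.na(z)), logical(1))))[1]
    x <- x[[ax]]
  }
  ctr <- round(regions$center_ms) + 1L
  w <- half_window_ms
  ok <- ctr - w - max_shift_ms >= 1 & ctr + w + max_shift_ms <= length(x)
  ctr <- ctr[ok]
  if (!length(ctr)) stop("no region has a complete window inside the record")
  shifts <- rep(0L, length(ctr))
  grab <- function(c0) x[(c0 - w):(c0 + w)]
  segs <- vapply(ctr, grab, numeric(2 * w + 1))
  avg <- rowMeans(segs)
  for (it in seq_len(iterations)) {
    for (s in seq_along(ctr)) {
      cand <- (-max_shift_ms):max_shift_ms
      cors <- vapply(cand, function(dd) {
        seg <- grab(ctr[s] + shifts[s] + dd)
        if (sd(seg) == 0) -Inf else stats::cor(seg, avg)
      }, numeric(1))
      best <- cand[order(-cors, abs(cand))[1]]
      shifts[s] <- shifts[s] + best
    }
    segs <- vapply(ctr + shifts, grab, numeric(2 * w + 1))
    avg <- rowMeans(segs)
  }
  if (!is.null(lpf_hz)) {
    lp <- signal::butter(4, lpf_hz / 500, type = "low")
    avg <- signal::filtfilt(lp, avg)
  }
  structure(list(time_ms = -w:w, mean_pT = avg, n = length(ctr),
                 iterations = iterations, shifts = shifts),
            class = "cardiomag_average_waveform")
}
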