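# Construction of labeled training corpora: randomized simulated peaks
# assembled into 120 s records, superimposed on background noise.

# derived substream seed, kept inside 32-bit integer range
.sub_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(i) +
                104729 * as.numeric(salt)) %% 2147483647)
}

#' Randomize a peak template (stretch + scale)
#'
#' Draws a duration from a normal distribution with mean equal to the
#' template length and coefficient of variation \code{cv} (redrawing any
#' non-positive values, i.e. a truncated normal), resamples the waveform to
#' that duration by linear interpolation, and multiplies the amplitude by a
#' uniform draw from \code{amp_range}.
#'
#' @param template a \code{\link{peak_template}}.
#' @param seed integer seed.
#' @param cv coefficient of variation of the stretched duration (0.21,
#'   matching the beat-interval variability measured from field potentials).
#' @param amp_range amplitude multiplier range (uniform; 0.5-2.0 fold).
#' @return a \code{\link{peak_template}} with attributes
#'   \code{duration_ms} and \code{amplitude}.
#' @export
randomize_peak <- function(template, seed = NULL, cv = 0.21,
                           amp_range = c(0.5, 2.0)) {
  stopifnot(cv >= 0, amp_range[1] > 0, amp_range[1] <= amp_range[2])
  if (!is.null(seed)) {
    rng_state <- .save_rng(); on.exit(.restore_rng(rng_state))
    set.seed(seed)
  }
  n0 <- length(template$waveform)
  dur <- 0
  while (dur < 1) dur <- rnorm(1, n0, cv * n0)   # truncated-normal redraw
  dur <- round(dur)
  amp <- runif(1, amp_range[1], amp_range[2])
  wf <- approx(seq_len(n0), template$waveform,
               xout = seq(1, n0, length.out = dur))$y * amp
  out <- peak_template(wf, axis = template$axis)
  attr(out, "duration_ms") <- dur
  attr(out, "amplitude") <- amp
  out
}

#' Assemble randomized peaks into a labeled record
#'
#' Peak windows are placed at centers spaced by the nominal cycle length;
#' samples between adjacent windows are linearly interpolated between the
#' last sample of the preceding window and the first sample of the next.
#' Labels are P (TRUE) exactly inside peak windows. Negative polarity flips
#' the waveform sign.
#'
#' @param peaks list of (randomized) \code{\link{peak_template}}s; recycled
#'   if shorter than the number of cycle slots.
#' @param cycle_ms nominal peak spacing (ms); the rate is 1000/cycle_ms Hz.
#' @param duration_s record length (s).
#' @param polarity \code{"positive"}, \code{"negative"} or
#'   \code{"noise-only"} (flat record, all-N labels, empty truth).
#' @return list of class \code{cardiomag_labeled_record}: \code{waveform}
#'   (pT), \code{labels} (logical, TRUE = P), \code{truth_ms}, \code{polarity}.
#' @export
assemble_record <- function(peaks, cycle_ms = 1050, duration_s = 120,
                            polarity = c("positive", "negative",
                                         "noise-only")) {
  polarity <- match.arg(polarity)
  n <- round(duration_s * 1000)
  wf <- numeric(n)
  labels <- rep(FALSE, n)
  if (polarity == "noise-only") {
    return(structure(list(waveform = wf, labels = labels,
                          truth_ms = numeric(0), polarity = polarity),
                     class = "cardiomag_labeled_record"))
  }
  centers <- seq(cycle_ms / 2, n - cycle_ms / 2, by = cycle_ms)
  if (!length(centers)) stop("record too short for one cycle")
  sgn <- if (polarity == "negative") -1 else 1
  prev_end <- 1L; prev_val <- 0
  bounds <- matrix(0L, length(centers), 2)
  for (k in seq_along(centers)) {
    tpl <- peaks[[(k - 1L) %% length(peaks) + 1L]]
    len <- length(tpl$waveform)
    i0 <- round(centers[k]) - floor(len / 2)
    i1 <- i0 + len - 1L
    if (i0 <= prev_end || i1 > n)
      stop("stretched peak windows overlap; lower the rate or the stretch")
    wf[i0:i1] <- sgn * tpl$waveform
    labels[i0:i1] <- TRUE
    # linear interpolation across the preceding gap
    gap <- (prev_end):(i0)
    wf[gap] <- seq(prev_val, wf[i0], length.out = length(gap))
    prev_end <- i1; prev_val <- wf[i1]
    bounds[k, ] <- c(i0, i1)
  }
  if (prev_end < n) wf[prev_end:n] <- seq(prev_val, 0, length.out = n - prev_end + 1)
  structure(list(waveform = wf, labels = labels,
                 truth_ms = round(centers) - 1, polarity = polarity),
            class = "cardiomag_labeled_record")
}

#' Superimpose a signal record on background noise
#'
#' The signal is first passed through the acquisition filter chain (to be
#' consistent with the recorded noise), the noise is circularly shifted by a
#' seeded random offset, and the two waveforms are added. Labels and truth
#' are unchanged.
#'
#' @param signal a \code{cardiomag_labeled_record}.
#' @param noise a \code{cardiomag_field_record} at the same sampling rate,
#'   at least as long as the signal.
#' @param seed integer seed for the time shift.
#' @param axis which noise channel to use.
#' @param filter_signal apply the acquisition chain to the signal first
#'   (disable to emulate training on unfiltered simulation data).
#' @return the labeled record with noise added; attribute \code{shift}
#'   records the offset used.
#' @export
superimpose <- function(signal, noise, seed = 1, axis = NULL,
                        filter_signal = TRUE) {
  n <- length(signal$waveform)
  if (!is.null(noise)) {
    if (attr(noise, "fs") != 1000) stop("sampling rate mismatch")
    if (is.null(axis))
      axis <- names(which(!vapply(noise[c("Bx_pT", "By_pT", "Bz_pT")],
                                  function(z) all(is.na(z)), logical(1))))[1]
    nz <- noise[[axis]]
    if (length(nz) < n) stop("noise record shorter than signal")
  }
  sig <- signal$waveform
  if (filter_signal && any(sig != 0)) sig <- apply_acquisition_filters(sig)
  shift <- 0L
  if (!is.null(noise)) {
    rng_state <- .save_rng(); on.exit(.restore_rng(rng_state))
    set.seed(seed)
    shift <- sample.int(length(nz), 1) - 1L
    nz <- nz[((seq_len(n) - 1L + shift) %% length(nz)) + 1L]
    sig <- sig + nz
  }
  out <- signal
  out$waveform <- sig
  attr(out, "shift") <- shift
  out
}

#' Corpus specification
#'
#' @param n total number of records; must be divisible by 4 so the
#'   positive : negative : noise-only composition can be 1:1:2.
#' @param duration_s record length (s).
#' @param cycle_ms nominal peak spacing.
#' @param cv stretch coefficient of variation.
#' @param amp_range amplitude multiplier range.
#' @param intensity overall signal amplitude multiplier (fold of the
#'   estimated cell signal).
#' @param aug_sd_pT SD of the Gaussian augmentation noise added to every
#'   record (pT).
#' @param split train/validation/test fractions.
#' @param seed root seed; every record derives its own substream.
#' @param fixed_variability disable stretch and amplitude variation (the
#'   "no variability" ablation; random time shifts are retained).
#' @return list of class \code{cardiomag_corpus_spec}.
#' @export
corpus_spec <- function(n = 160, duration_s = 120, cycle_ms = 1050,
                        cv = 0.21, amp_range = c(0.5, 2.0), intensity = 1,
                        aug_sd_pT = 0.01, split = c(0.7, 0.1, 0.2),
                        seed = 1, fixed_variability = FALSE) {
  if (n %% 4 != 0) stop("n must be divisible by 4 for the 1:1:2 composition")
  stopifnot(abs(sum(split) - 1) < 1e-9)
  structure(list(n = n, duration_s = duration_s, cycle_ms = cycle_ms,
                 cv = cv, amp_range = amp_range, intensity = intensity,
                 aug_sd_pT = aug_sd_pT, split = split, seed = seed,
                 fixed_variability = fixed_variability),
            class = "cardiomag_corpus_spec")
}

#' Build a labeled corpus
#'
#' Generates \code{spec$n} records in composition positive : negative :
#' noise-only = 1:1:2, cycling the supplied noise records in equal
#' proportion, adds Gaussian augmentation noise (SD \code{aug_sd_pT}), and
#' assigns a stratified 70/10/20 train/validation/test split preserving the
#' composition. Pure function of (spec, template, noise records, seed).
#'
#' @param spec a \code{\link{corpus_spec}}.
#' @param noise_records list of \code{cardiomag_field_record} background
#'   records (or \code{NULL} for the no-noise ablation).
#' @param template a \code{\link{peak_template}}.
#' @return list of class \code{cardiomag_corpus}: \code{records} (each a
#'   labeled record with \code{$split} tag), \code{spec}.
#' @export
build_corpus <- function(spec, noise_records, template) {
  stopifnot(inherits(spec, "cardiomag_corpus_spec"))
  n4 <- spec$n / 4
  polarity <- rep(c("positive", "negative", "noise-only"), c(n4, n4, 2 * n4))
  tpl <- template
  tpl$waveform <- tpl$waveform * spec$intensity
  records <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    sseed <- .sub_seed(spec$seed, i)
    if (polarity[i] == "noise-only") {
      rec <- assemble_record(list(), spec$cycle_ms, spec$duration_s,
                             "noise-only")
    } else {
      n_slots <- length(seq(spec$cycle_ms / 2,
                            spec$duration_s * 1000 - spec$cycle_ms / 2,
                            by = spec$cycle_ms))
      peaks <- lapply(seq_len(n_slots), function(k) {
        if (spec$fixed_variability) tpl
        else randomize_peak(tpl, seed = .sub_seed(sseed, k), cv = spec$cv,
                            amp_range = spec$amp_range)
      })
      rec <- assemble_record(peaks, spec$cycle_ms, spec$duration_s,
                             polarity[i])
    }
    nz <- if (length(noise_records))
      noise_records[[(i - 1L) %% length(noise_records) + 1L]] else NULL
    rec <- superimpose(rec, nz, seed = .sub_seed(sseed, 0L, salt = 1L))
    # augmentation noise
    rng_state <- .save_rng()
    set.seed(.sub_seed(sseed, 0L, salt = 2L))
    rec$waveform <- rec$waveform +
      rnorm(length(rec$waveform), 0, spec$aug_sd_pT)
    .restore_rng(rng_state)
    rec$polarity <- polarity[i]
    records[[i]] <- rec
  }
  # stratified split preserving composition: largest-remainder quotas per
  # class, then a fix-up guaranteeing at least one train, validation and
  # test record overall
  rng_state <- .save_rng()
  set.seed(.sub_seed(spec$seed, 0L, salt = 3L))
  split_of <- character(spec$n)
  for (pol in unique(polarity)) {
    idx <- sample(which(polarity == pol))
    k <- length(idx)
    quota <- spec$split * k
    nn <- floor(quota)
    rem <- k - sum(nn)
    if (rem > 0) {
      extra <- order(quota - nn, c(3, 2, 1), decreasing = TRUE)[seq_len(rem)]
      nn[extra] <- nn[extra] + 1L
    }
    lab <- rep(c("train", "validation", "test"), nn)
    split_of[idx] <- lab
  }
  for (need in c("validation", "test")) {
    if (!any(split_of == need)) {
      donor <- which(split_of == "train")
      split_of[donor[length(donor)]] <- need
    }
  }
  # validation must carry at least one signal record, else early stopping
  # would reward the trivial all-N classifier on small corpora
  signal <- polarity != "noise-only"
  if (any(signal) && !any(signal & split_of == "validation")) {
    donor <- which(signal & split_of == "train")
    if (length(donor)) split_of[donor[length(donor)]] <- "validation"
  }
  .restore_rng(rng_state)
  for (i in seq_len(spec$n)) records[[i]]$split <- split_of[i]
  structure(list(records = records, spec = spec),
            class = "cardiomag_corpus")
}

#' @export
print.cardiomag_corpus <- function(x, ...) {
  pol <- vapply(x$records, function(r) r$polarity, character(1))
  spl <- vapply(x$records, function(r) r$split, character(1))
  cat(sprintf("<cardiomag_corpus> %d records (%s); split %s\n",
              length(x$records),
              paste(names(table(pol)), table(pol), collapse = " ", sep = ":"),
              paste(names(table(spl)), table(spl), collapse = " ", sep = ":")))
  invisible(x)
}

#' Subset a corpus by split
#' @param corpus a \code{cardiomag_corpus}.
#' @param split one of "train", "validation", "test".
#' @return list of labeled records.
#' @export
corpus_split <- function(corpus, split) {
  Filter(function(r) r$split == split, corpus$records)
}
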