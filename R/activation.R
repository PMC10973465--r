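# Activation-time maps from tissue recordings.

#' Activation-time map from membrane-potential snapshots
#'
#' First upward threshold crossing of each unit after \code{after_ms},
#' from the recorded V snapshots. Use \code{after_ms} past the initial
#' transient to map a propagating beat (the first beat after the uniform
#' initial condition activates near-synchronously and carries no wavefront
#' information).
#'
#' @param recording a \code{cardiomag_tissue_recording} with V snapshots.
#' @param after_ms map the first activation at or after this time.
#' @param threshold_mV crossing threshold.
#' @return nx x ny matrix of activation times (ms; NA if never crossed).
#' @export
activation_map <- function(recording, after_ms = 0, threshold_mV = -20) {
  t <- recording$time_v_ms
  V <- recording$V
  keep <- t >= after_ms
  t <- t[keep]; V <- V[keep, , drop = FALSE]
  nun <- ncol(V)
  act <- rep(NA_real_, nun)
  for (k in seq_len(nun)) {
    v <- V[, k]
    up <- which(v[-length(v)] < threshold_mV & v[-1] >= threshold_mV)
    if (length(up)) act[k] <- t[up[1] + 1L]
  }
  matrix(act, recording$geometry$nx, recording$geometry$ny)
}
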