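# FSST + LSTM per-sample peak classifier: training, inference, peak-region
# post-processing and evaluation metrics.

#' Network configuration
#'
#' @param hidden LSTM hidden units (study default 400; reduced sizes train
#'   much faster on small corpora).
#' @param bidirectional reserved; only the unidirectional network is shipped.
#' @return list of class \code{cardiomag_net_config}.
#' @export
net_config <- function(hidden = 400, bidirectional = FALSE) {
  stopifnot(hidden >= 1, !bidirectional)
  structure(list(hidden = hidden, n_classes = 2L,
                 bidirectional = bidirectional),
            class = "cardiomag_net_config")
}

#' Training configuration
#'
#' Adaptive moment estimation with initial learning rate 0.001 dropped by a
#' factor of 0.1 every 20 epochs, at most 60 epochs, mini-batches of 16
#' segments of 10 s, early stop once the validation loss has exceeded its
#' running minimum more than 10 times. The weights at the best validation
#' loss are returned.
#'
#' @param max_epochs,lr0,lr_drop_factor,lr_drop_every,patience,segment_s,batch_size,seed
#'   training hyperparameters.
#' @return list of class \code{cardiomag_train_config}.
#' @export
train_config <- function(max_epochs = 60, lr0 = 0.001, lr_drop_factor = 0.1,
                         lr_drop_every = 20, patience = 10, segment_s = 10,
                         batch_size = 16, seed = 1) {
  stopifnot(max_epochs >= 0, lr0 > 0, patience >= 1, segment_s > 0,
            batch_size >= 1)
  structure(list(max_epochs = max_epochs, lr0 = lr0,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_every = lr_drop_every, patience = patience,
                 segment_s = segment_s, batch_size = batch_size, seed = seed),
            class = "cardiomag_train_config")
}

# features + labels for one record, segmented
.record_segments <- function(rec, fsst_cfg, segment_len) {
  feats <- fsst_features(rec$waveform, fsst_cfg)
  labs <- as.integer(rec$labels)
  n <- ncol(feats)
  n_seg <- n %/% segment_len
  lapply(seq_len(max(n_seg, 1)), function(s) {
    i0 <- (s - 1) * segment_len + 1
    i1 <- min(s * segment_len, n)
    list(x = feats[, i0:i1, drop = FALSE], y = labs[i0:i1])
  })
}

#' Train the FSST + LSTM classifier on a corpus
#'
#' Extracts FSST features per record, standardizes each feature channel with
#' the mean and SD of the training split, segments records, and trains the
#' LSTM with Adam and validation-based early stopping.
#'
#' @param corpus a \code{cardiomag_corpus} (needs train and validation
#'   splits).
#' @param net a \code{\link{net_config}}.
#' @param train a \code{\link{train_config}}.
#' @param fsst_cfg a \code{\link{fsst_config}}.
#' @param verbose print per-epoch losses.
#' @return list of class \code{cardiomag_trained_model}: network weights,
#'   standardization statistics, configs and the training log.
#' @export
train_network <- function(corpus, net = net_config(), train = train_config(),
                          fsst_cfg = fsst_config(), verbose = FALSE) {
  recs <- corpus$records
  splits <- vapply(recs, function(r) r$split, character(1))
  if (!any(splits == "train") || !any(splits == "validation"))
    stop("corpus must contain train and validation splits")
  segment_len <- round(train$segment_s * 1000)
  segs <- list(); seg_split <- character(0)
  for (i in seq_along(recs)) {
    if (splits[i] == "test") next
    ss <- .record_segments(recs[[i]], fsst_cfg, segment_len)
    segs <- c(segs, ss)
    seg_split <- c(seg_split, rep(splits[i], length(ss)))
  }
  # standardization from training segments only
  tr_idx <- which(seg_split == "train")
  va_idx <- which(seg_split == "validation")
  allx <- do.call(cbind, lapply(segs[tr_idx], `[[`, "x"))
  mu <- rowMeans(allx)
  sdv <- apply(allx, 1, sd)
  sdv[sdv == 0] <- 1
  seq_x <- lapply(segs, function(s) (s$x - mu) / sdv)
  seq_y <- lapply(segs, `[[`, "y")

  fit <- cpp_lstm_train(seq_x, seq_y, as.integer(tr_idx), as.integer(va_idx),
                        net$hidden, train$batch_size, train$max_epochs,
                        train$lr0, train$lr_drop_factor, train$lr_drop_every,
                        train$patience, train$seed, verbose)
  structure(list(W = fit$W, b = fit$b, Wo = fit$Wo, bo = fit$bo,
                 mu = mu, sd = sdv, hidden = net$hidden,
                 fsst_config = fsst_cfg,
                 train_log = list(train = fit$train_loss,
                                  val = fit$val_loss,
                                  best_epoch = fit$best_epoch)),
            class = "cardiomag_trained_model")
}

#' Classify a record with a trained model
#'
#' @param model a \code{cardiomag_trained_model}.
#' @param record a \code{cardiomag_field_record}, labeled record, or bare
#'   numeric waveform (1 kHz).
#' @return data.frame with \code{prob_P} (per-sample class-P probability)
#'   and \code{label} (TRUE = P by argmax).
#' @export
classify <- function(model, record) {
  x <- if (is.numeric(record)) record
       else if (inherits(record, "cardiomag_labeled_record")) record$waveform
       else record
  feats <- fsst_features(x, model$fsst_config)
  feats <- (feats - model$mu) / model$sd
  p <- cpp_lstm_predict(model$W, matrix(model$b), model$Wo,
                        matrix(model$bo), feats)
  data.frame(prob_P = p, label = p >= 0.5)
}

#' Identify peak regions from a label sequence
#'
#' Maximal runs of P labels strictly longer than \code{min_duration_ms}
#' become peak regions; shorter runs are discarded as false positives.
#'
#' @param labels logical (or 0/1) per-sample label sequence at 1 kHz.
#' @param min_duration_ms region length threshold (strictly greater-than).
#' @return data.frame with \code{start_ms}, \code{end_ms}, \code{center_ms}
#'   (0-based sample times), possibly 0 rows.
#' @export
detect_peak_regions <- function(labels, min_duration_ms = 150) {
  lab <- as.logical(labels)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_duration_ms
  data.frame(start_ms = starts[keep] - 1,
             end_ms = ends[keep] - 1,
             center_ms = (starts[keep] + ends[keep]) / 2 - 1)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half (rank / Mann-Whitney formulation).
#'
#' @param scores numeric classifier scores.
#' @param truth logical (or 0/1) labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Match detected peak regions against ground-truth centers
#'
#' Greedy one-to-one matching by center distance: candidate pairs within
#' \code{tolerance_ms} are matched closest-first (ties toward the earlier
#' truth). Unmatched truth centers are undetected peaks; unmatched regions
#' are mis-detections.
#'
#' @param regions data.frame from \code{\link{detect_peak_regions}}.
#' @param truth_ms ground-truth peak-center times (ms).
#' @param tolerance_ms maximum center distance for a correct match (default
#'   one nominal peak width).
#' @param duration_s record length for the peaks/min rate (optional).
#' @return list of class \code{cardiomag_detection_result}: counts
#'   \code{correct}, \code{undetected}, \code{misdetected}, rate
#'   \code{peaks_per_min}, and the match table.
#' @export
match_peaks <- function(regions, truth_ms, tolerance_ms = 250,
                        duration_s = NULL) {
  stopifnot(tolerance_ms > 0)
  nr <- nrow(regions); nt <- length(truth_ms)
  matched_r <- rep(FALSE, nr); matched_t <- rep(FALSE, nt)
  pairs <- NULL
  if (nr > 0 && nt > 0) {
    dmat <- abs(outer(regions$center_ms, truth_ms, "-"))
    cand <- which(dmat <= tolerance_ms, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dmat[cand], cand[, 2])
      for (ci in ord) {
        i <- cand[ci, 1]; j <- cand[ci, 2]
        if (!matched_r[i] && !matched_t[j]) {
          matched_r[i] <- TRUE; matched_t[j] <- TRUE
          pairs <- rbind(pairs, c(region = unname(i), truth = unname(j)))
        }
      }
    }
  }
  res <- list(correct = sum(matched_t), undetected = sum(!matched_t),
              misdetected = sum(!matched_r),
              n_regions = nr, n_truth = nt,
              peaks_per_min = if (is.null(duration_s)) NA_real_
                              else nr / duration_s * 60,
              pairs = pairs)
  class(res) <- "cardiomag_detection_result"
  res
}

#' @export
print.cardiomag_detection_result <- function(x, ...) {
  cat(sprintf("<detection> %d/%d correct, %d undetected, %d mis-detected",
              x$correct, x$n_truth, x$undetected, x$misdetected))
  if (is.finite(x$peaks_per_min))
    cat(sprintf(", %.1f peaks/min", x$peaks_per_min))
  cat("\n")
  invisible(x)
}

#' Early-stopping rule on a validation-loss sequence
#'
#' The rule applied during training: iterate epochs, count every epoch whose
#' validation loss fails to improve the running minimum, and stop once that
#' count exceeds \code{patience}. Returns the epoch training stops after and
#' the epoch of the best (minimum) loss so far.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience allowed number of exceedances.
#' @return list(stop_epoch, best_epoch).
#' @export
early_stop_epoch <- function(val_losses, patience = 10) {
  best <- Inf; best_epoch <- 0L; exceed <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e
    } else {
      exceed <- exceed + 1L
      if (exceed > patience) return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}
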