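# FSST features, LSTM training/inference, peak regions, metrics.

test_that("FSST features have the declared shape and trivial cases", {
  cfg <- fsst_config()
  z <- fsst_features(numeric(2000), cfg)
  expect_equal(dim(z), c(10, 2000))  # 5 bins in 3.5-12 Hz, re + im
  expect_true(all(z == 0))
  raw <- fsst_features(sin(1:500 / 20), fsst_config(raw = TRUE))
  expect_equal(raw, matrix(sin(1:500 / 20), 1))
  expect_error(fsst_config(band = c(3.5, 600)), "Nyquist")
  expect_error(fsst_features(numeric(100), cfg), "shorter")
})

test_that("a pure tone concentrates in its nearest FSST bin", {
  cfg <- fsst_config()
  x <- sin(2 * pi * 8 * (0:19999) / 1000)
  F <- fsst_features(x, cfg)
  nb <- nrow(F) / 2
  energy <- rowMeans(F[1:nb, ]^2 + F[nb + 1:nb, ]^2)
  bins_hz <- cardiomag:::.band_bins(cfg) * 1000 / 512
  nearest <- which.min(abs(bins_hz - 8))
  expect_gt(energy[nearest] / sum(energy), 0.8)
})

test_that("AUROC matches brute-force pair counting and its invariances", {
  expect_identical(auroc(c(5, 4, 3), c(TRUE, TRUE, FALSE)), 1.0)
  # hand case: concordant pairs 3 of 4
  expect_identical(auroc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)),
                   0.75)
  set.seed(8)
  sc <- runif(2e4); tr <- rep(c(TRUE, FALSE), 1e4)
  expect_equal(auroc(sc, tr), 0.5, tolerance = 0.02)
  # invariant under strictly increasing transforms
  expect_equal(auroc(qnorm(sc), tr), auroc(sc, tr))
  # ties count one half
  expect_equal(auroc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)))
  # independent cross-check against the ROC reference implementation
  set.seed(13)
  sc2 <- rnorm(400) + rep(c(0, 0.8), 200)
  tr2 <- rep(c(FALSE, TRUE), 200)
  expect_equal(auroc(sc2, tr2),
               as.numeric(pROC::auc(pROC::roc(tr2, sc2, quiet = TRUE,
                                              direction = "<"))))
})

test_that("peak regions are maximal P-runs strictly longer than threshold", {
  expect_equal(nrow(detect_peak_regions(rep(FALSE, 1000))), 0)
  lab <- c(rep(FALSE, 100), rep(TRUE, 100), rep(FALSE, 100),
           rep(TRUE, 200), rep(FALSE, 100))
  r <- detect_peak_regions(lab, 150)
  expect_equal(nrow(r), 1)
  expect_equal(r$start_ms, 300); expect_equal(r$end_ms, 499)
  # exactly 150 ms is discarded (strict inequality)
  lab150 <- c(rep(FALSE, 10), rep(TRUE, 150), rep(FALSE, 10))
  expect_equal(nrow(detect_peak_regions(lab150, 150)), 0)
  lab151 <- c(rep(FALSE, 10), rep(TRUE, 151), rep(FALSE, 10))
  expect_equal(nrow(detect_peak_regions(lab151, 150)), 1)
  # count is monotone non-increasing in the threshold
  set.seed(2)
  lab_r <- runif(5000) < 0.4
  counts <- vapply(c(0, 5, 20, 50), function(th)
    nrow(detect_peak_regions(lab_r, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak matching is greedy one-to-one with the stated tie-break", {
  reg <- data.frame(start_ms = c(90, 1090), end_ms = c(110, 1110),
                    center_ms = c(100, 1100))
  res <- match_peaks(reg, c(100, 1100), tolerance_ms = 250)
  expect_equal(res$correct, 2); expect_equal(res$undetected, 0)
  expect_equal(res$misdetected, 0)
  # no regions: all truth undetected
  res0 <- match_peaks(reg[0, ], c(100, 200), tolerance_ms = 250,
                      duration_s = 60)
  expect_equal(res0$correct, 0); expect_equal(res0$undetected, 2)
  expect_equal(res0$peaks_per_min, 0)
  # one region midway between two truths: matched to the nearer; the tie
  # case goes to the earlier truth
  reg1 <- data.frame(start_ms = 190, end_ms = 210, center_ms = 200)
  res1 <- match_peaks(reg1, c(120, 290), tolerance_ms = 250)
  expect_equal(res1$correct, 1)
  expect_equal(res1$pairs[1, "truth"], c(truth = 1))  # 80 ms < 90 ms
  res2 <- match_peaks(reg1, c(150, 250), tolerance_ms = 250)
  expect_equal(res2$pairs[1, "truth"], c(truth = 1))  # tie -> earlier
  expect_equal(res2$undetected, 1)
})

test_that("the early-stopping rule fires on the scripted loss sequence", {
  losses <- c(1.0, 0.9, rep(0.95, 11))
  res <- early_stop_epoch(losses, patience = 10)
  expect_equal(res$stop_epoch, 13)  # stops after the 11th exceedance of 0.9
  expect_equal(res$best_epoch, 2)
  # monotone improvement never stops early
  res2 <- early_stop_epoch(seq(1, 0.1, length.out = 30), patience = 10)
  expect_equal(res2$stop_epoch, 30)
})

test_that("zero training epochs returns the untrained initial network", {
  corp <- tiny_corpus(n = 8, duration_s = 2, cycle_ms = 500)
  m <- train_network(corp, net_config(hidden = 8),
                     train_config(max_epochs = 0, segment_s = 1),
                     fsst_config())
  expect_equal(length(m$train_log$train), 0)
  expect_equal(m$train_log$best_epoch, 0)
  p <- classify(m, corp$records[[1]])
  expect_true(all(p$prob_P >= 0 & p$prob_P <= 1))
})

test_that("training on an easy corpus yields a discriminative classifier", {
  # peak amplitude 10x the noise SD, small network, short records
  corp <- tiny_corpus(n = 8, duration_s = 10, intensity = 1,
                      noise_sd = 0.015, seed = 11)
  m <- train_network(corp, net_config(hidden = 16),
                     train_config(max_epochs = 30, lr0 = 0.003,
                                  segment_s = 5, batch_size = 4, seed = 2),
                     fsst_config())
  test_recs <- corpus_split(corp, "test")
  # validation loss decreased during training
  expect_lt(min(m$train_log$val), m$train_log$val[1])
  rec <- Filter(function(r) r$polarity != "noise-only",
                corp$records)[[1]]
  cl <- classify(m, rec)
  expect_gt(auroc(cl$prob_P, rec$labels), 0.95)
  # determinism of inference
  cl2 <- classify(m, rec)
  expect_identical(cl$prob_P, cl2$prob_P)
  # noise-only record: few P labels
  nz <- Filter(function(r) r$polarity == "noise-only", corp$records)[[1]]
  cln <- classify(m, nz)
  expect_lt(mean(cln$label), 0.1)
})
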