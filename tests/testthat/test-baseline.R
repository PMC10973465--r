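# Scaled-template baseline and peak-waveform averaging.

test_that("a perfectly embedded template is detected at its position", {
  tpl <- toy_template()
  x <- numeric(8000)
  x[3001:3250] <- 0.7 * tpl$waveform + 0.05  # scaled + offset
  fit <- scaled_template_detect(x, tpl, threshold = 50)
  expect_equal(which.max(fit$criterion), 3001)
  expect_equal(fit$scale[3001], 0.7, tolerance = 1e-9)
  expect_equal(fit$offset[3001], 0.05, tolerance = 1e-9)
  expect_equal(fit$detections_ms, 3000 + floor(250 / 2))
  expect_error(scaled_template_detect(x, peak_template(rep(1, 100) * 0 + 2)),
               "variance")
})

test_that("dead time prevents double counting of one event", {
  tpl <- toy_template()
  x <- numeric(6000)
  for (c0 in c(1000, 3000, 5000)) x[c0:(c0 + 249)] <- tpl$waveform
  fit <- scaled_template_detect(x + rnorm(6000, 0, 1e-4), tpl, threshold = 20)
  expect_equal(length(fit$detections_ms), 3)
})

test_that("threshold calibration inverts the empirical rate curve", {
  set.seed(21)
  tpl <- toy_template()
  bg <- lapply(1:2, function(i) rnorm(60000, 0, 0.1))
  # pick an achievable target from an actual fit
  f <- scaled_template_detect(bg[[1]], tpl)
  th0 <- quantile(f$criterion, 0.999)
  d0 <- cardiomag:::.pick_detections(f$criterion, th0, f$template_length)
  target <- length(d0) / 1  # per minute (60 s record)
  th <- calibrate_template_threshold(bg[1], tpl, target_rate = target)
  expect_equal(th, unname(th0), tolerance = 0.1 * th0)
  # monotonicity: a higher allowed rate gives a lower threshold
  th_lo <- calibrate_template_threshold(bg, tpl, target_rate = 2)
  th_hi <- calibrate_template_threshold(bg, tpl, target_rate = 20)
  expect_gt(th_lo, th_hi)
  # a zero target sits above every criterion value
  th0r <- calibrate_template_threshold(bg, tpl, target_rate = 0)
  expect_gt(th0r, max(f$criterion))
})

test_that("averaging identical clean peaks returns the peak itself", {
  tpl <- toy_template()
  x <- numeric(20000)
  ctrs <- c(3000, 8000, 13000, 18000)
  for (c0 in ctrs) x[(c0 - 124):(c0 + 125)] <- tpl$waveform
  regions <- data.frame(center_ms = ctrs - 1)
  avg <- average_peak_waveform(x, regions, half_window_ms = 175)
  expect_equal(avg$n, 4)
  seg <- x[(ctrs[1] - 175):(ctrs[1] + 175)]
  expect_equal(avg$mean_pT, seg, tolerance = 1e-12)
  # single region: the average equals that segment
  avg1 <- average_peak_waveform(x, regions[1, , drop = FALSE])
  expect_equal(avg1$mean_pT, seg)
  expect_error(average_peak_waveform(x, data.frame(center_ms = 10)),
               "complete window")
})

test_that("adaptive alignment recovers jittered peaks", {
  set.seed(31)
  tpl <- toy_template(amp = 1)
  x <- rnorm(40000, 0, 0.15)
  true_ctrs <- seq(2000, 38000, by = 2000)
  jit <- sample(-20:20, length(true_ctrs), replace = TRUE)
  for (i in seq_along(true_ctrs)) {
    c0 <- true_ctrs[i] + jit[i]
    x[(c0 - 124):(c0 + 125)] <- x[(c0 - 124):(c0 + 125)] + tpl$waveform
  }
  regions <- data.frame(center_ms = true_ctrs - 1)
  clean <- numeric(351); clean[(176 - 124):(176 + 125)] <- tpl$waveform
  avg0 <- average_peak_waveform(x, regions, iterations = 0)
  avg10 <- average_peak_waveform(x, regions, iterations = 10)
  expect_gt(cor(avg10$mean_pT, clean), cor(avg0$mean_pT, clean))
  expect_gt(cor(avg10$mean_pT, clean), 0.97)
  # alignment shifts stay within the configured bound
  expect_true(all(abs(avg10$shifts) <= 10 * 50))
})

test_that("averaging n noisy copies shrinks residual noise like 1/sqrt(n)", {
  set.seed(5)
  tpl <- toy_template(amp = 1)
  mk_avg <- function(n) {
    x <- rnorm(n * 1000 + 1000, 0, 0.2)
    ctrs <- seq(800, by = 1000, length.out = n)
    for (c0 in ctrs) x[(c0 - 124):(c0 + 125)] <- x[(c0 - 124):(c0 + 125)] +
        tpl$waveform
    avg <- average_peak_waveform(x, data.frame(center_ms = ctrs - 1),
                                 iterations = 0)
    clean <- numeric(351); clean[(176 - 124):(176 + 125)] <- tpl$waveform
    sd(avg$mean_pT - clean)
  }
  r4 <- mean(replicate(4, mk_avg(4)))
  r36 <- mean(replicate(4, mk_avg(36)))
  expect_equal(r4 / r36, 3, tolerance = 0.8)  # sqrt(36/4) = 3
})
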