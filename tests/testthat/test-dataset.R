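# Labeled-corpus construction: peak randomization, record assembly,
# superposition, composition and splits.

test_that("randomize_peak is the identity at zero variability", {
  tpl <- toy_template()
  out <- randomize_peak(tpl, seed = 1, cv = 0, amp_range = c(1, 1))
  expect_equal(out$waveform, tpl$waveform, tolerance = 1e-12)
})

test_that("stretch durations reproduce the configured variation", {
  tpl <- toy_template()
  set.seed(0)
  durs <- amps <- numeric(2000)
  for (i in seq_along(durs)) {
    p <- randomize_peak(tpl, seed = i, cv = 0.21)
    durs[i] <- attr(p, "duration_ms")
    amps[i] <- attr(p, "amplitude")
  }
  expect_equal(sd(durs) / mean(durs), 0.21, tolerance = 0.015)
  expect_equal(mean(durs), 250, tolerance = 0.02 * 250)
  # uniform amplitude moments on [0.5, 2]
  expect_gte(min(amps), 0.5); expect_lte(max(amps), 2)
  expect_equal(mean(amps), 1.25, tolerance = 0.03)
})

test_that("record assembly places, labels and interpolates peaks", {
  # no peaks: flat record, all-N labels
  r0 <- assemble_record(list(), polarity = "noise-only", duration_s = 5)
  expect_true(all(r0$waveform == 0) && !any(r0$labels))
  expect_length(r0$truth_ms, 0)

  tpl <- toy_template()
  r <- assemble_record(list(tpl), cycle_ms = 1050, duration_s = 120)
  expect_length(r$waveform, 120000)
  expect_equal(length(r$truth_ms), floor((120000 - 1050) / 1050) + 1)
  expect_equal(length(r$truth_ms), 114, tolerance = 1)
  # every maximal P-run contains exactly one truth center
  runs <- rle(r$labels)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  pruns <- which(runs$values)
  hits <- vapply(pruns, function(i)
    sum(r$truth_ms >= starts[i] - 1 & r$truth_ms <= ends[i] - 1), numeric(1))
  expect_true(all(hits == 1))
  expect_equal(length(pruns), length(r$truth_ms))
  # P fraction ~ n_peaks * width / duration
  expect_equal(mean(r$labels), length(r$truth_ms) * 250 / 120000,
               tolerance = 0.05)
  # negative polarity flips the waveform
  rn <- assemble_record(list(tpl), cycle_ms = 1050, duration_s = 10,
                        polarity = "negative")
  rp <- assemble_record(list(tpl), cycle_ms = 1050, duration_s = 10,
                        polarity = "positive")
  expect_equal(rn$waveform, -rp$waveform)
})

test_that("superposition is additive and preserves labels", {
  tpl <- toy_template()
  sig <- assemble_record(list(tpl), cycle_ms = 1000, duration_s = 10)
  prof <- noise_profile("custom", target_sd_pT = 0.1)
  nz <- generate_background(prof, duration_s = 12, seed = 3)
  s1 <- superimpose(sig, nz, seed = 17)
  # zero signal with the same shift gives the shifted noise alone
  zero <- sig; zero$waveform <- numeric(length(sig$waveform))
  s0 <- superimpose(zero, nz, seed = 17)
  filt <- apply_acquisition_filters(sig$waveform)
  expect_equal(s1$waveform - s0$waveform, filt, tolerance = 1e-10)
  expect_identical(s1$labels, sig$labels)
  expect_identical(s1$truth_ms, sig$truth_ms)
  # zero noise: the filtered signal alone
  s2 <- superimpose(sig, NULL, seed = 1)
  expect_equal(s2$waveform, filt)
  # sampling-rate mismatch is an error
  bad <- nz; attr(bad, "fs") <- 500
  expect_error(superimpose(sig, bad), "mismatch")
})

test_that("corpus composition, splits and augmentation follow the spec", {
  expect_error(corpus_spec(n = 6), "divisible by 4")
  sp <- corpus_spec(n = 160)
  ns <- round(sp$split * 160)
  expect_equal(ns, c(112, 16, 32))

  tpl <- toy_template()
  prof <- noise_profile("custom", target_sd_pT = 0.05)
  nz <- lapply(1:2, function(i) generate_background(prof, 10, seed = i))
  spec <- corpus_spec(n = 8, duration_s = 10, cycle_ms = 1000, seed = 5)
  corp <- build_corpus(spec, nz, tpl)
  pol <- vapply(corp$records, `[[`, character(1), "polarity")
  expect_equal(sum(pol == "positive"), 2)
  expect_equal(sum(pol == "negative"), 2)
  expect_equal(sum(pol == "noise-only"), 4)
  spl <- vapply(corp$records, `[[`, character(1), "split")
  expect_true(all(c("train", "validation", "test") %in% spl))
  # noise-only records have all-N labels and empty truth
  for (r in corp$records[pol == "noise-only"]) {
    expect_false(any(r$labels))
    expect_length(r$truth_ms, 0)
  }
  # determinism: identical spec regenerates identical records
  corp2 <- build_corpus(spec, nz, tpl)
  expect_identical(corp$records[[1]]$waveform, corp2$records[[1]]$waveform)
  expect_identical(vapply(corp2$records, `[[`, character(1), "split"), spl)
})

test_that("augmentation noise alone has the configured 0.01 pT SD", {
  spec <- corpus_spec(n = 4, duration_s = 120, seed = 2)
  # no background noise, zero-amplitude template: only augmentation remains
  tpl0 <- peak_template(numeric(250))
  corp <- build_corpus(spec, list(), tpl0)
  nz_only <- corp$records[[3]]  # a noise-only record
  expect_lt(abs(sd(nz_only$waveform) - 0.01), 0.001)
})
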