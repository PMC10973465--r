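# Ionic cell models: integration rule, AP simulation, feature extraction.

test_that("forward-Euler step follows the definition and respects clamps", {
  vm <- cell_model("ventricular", fixed = c("Ki", "CaSR"))
  s1 <- euler_step(vm, vm$state0, dt = 0.01)
  dy <- cell_derivs(vm, vm$state0)
  free <- setdiff(vm$state_names, vm$fixed)
  expect_equal(s1[free], (vm$state0 + 0.01 * dy)[free])
  expect_identical(s1[["Ki"]], vm$state0[["Ki"]])
  expect_identical(s1[["CaSR"]], vm$state0[["CaSR"]])
})

test_that("Euler integration of y' = -y matches the exponential closed form", {
  # rate per second, dt = 0.01 ms: 1e5 steps reach t = 1 s
  y <- euler_integrate(function(t, y) -y * 1e-3, 1, dt = 0.01, n_steps = 1e5)
  expect_equal(y, exp(-1), tolerance = 1e-3)
  # fixed point: zero derivative leaves the state unchanged
  expect_identical(euler_integrate(function(t, y) 0 * y, c(3, 4), 0.01, 100),
                   c(3, 4))
  # non-finite derivative is an integration error naming the component
  expect_error(euler_integrate(function(t, y) c(0, NaN), c(1, 1), 0.01, 5),
               "component 2")
})

test_that("a current-free model holds its membrane potential", {
  vm <- cell_model("ventricular",
                   scalings = setNames(rep(0, 8), c("sNa", "sCaL", "sto",
                                                    "sKr", "sK1", "sf",
                                                    "sNaCa", "sNaK")),
                   overrides = c(sKs = 0, gpCa = 0, gbNa = 0, gbCa = 0))
  tr <- simulate_ap(vm, duration_s = 0.5)
  expect_true(all(abs(tr$V_mV - tr$V_mV[1]) < 1e-9))
  feats <- extract_ap_features(tr, "ventricular", analysis_window_s = 0.5)
  expect_false(feats$beating)
})

test_that("a leak-only membrane relaxes exponentially to the reversal", {
  g_leak <- 0.1  # A/F per mV -> 1/ms rate
  vm <- cell_model("ventricular",
                   scalings = setNames(rep(0, 8), c("sNa", "sCaL", "sto",
                                                    "sKr", "sK1", "sf",
                                                    "sNaCa", "sNaK")),
                   overrides = c(sKs = 0, gpCa = 0, gbCa = 0, gbNa = g_leak),
                   fixed = "Nai")
  tr <- simulate_ap(vm, duration_s = 0.2, record_stride_ms = 1)
  rtf <- 8314.472 * (37 + 273.15) / 96485.3415
  ena <- rtf * log(151 / vm$state0[["Nai"]])
  v_th <- ena + (vm$state0[["V"]] - ena) * exp(-g_leak * tr$time_ms)
  expect_equal(tr$V_mV, v_th, tolerance = 1e-3)
  expect_true(all(diff(tr$V_mV) > 0))  # monotone approach from below
})

test_that("both fitted models beat spontaneously with plausible features", {
  vm <- cell_model("ventricular", use_optimized = TRUE)
  tr <- simulate_ap(vm, duration_s = 20)
  f <- extract_ap_features(tr, "ventricular", analysis_window_s = 12)
  expect_true(f$beating)
  expect_lt(f$MDP, -50)
  expect_gt(f$Peak, f$MDP + 40)  # full depolarization above threshold
  expect_gt(f$BF, 10); expect_lt(f$BF, 200)
  expect_gte(f$APD90_50, 1)

  pm <- cell_model("pacemaker", use_optimized = TRUE)
  trp <- simulate_ap(pm, duration_s = 10)
  fp <- extract_ap_features(trp, "pacemaker", analysis_window_s = 6)
  expect_true(fp$beating)
  expect_lt(fp$MDP, -50); expect_gt(fp$Peak, 0)
})

test_that("gating variables remain in [0, 1] through a long integration", {
  for (id in c("ventricular", "pacemaker")) {
    m <- cell_model(id, use_optimized = TRUE)
    st <- simulate_states(m, duration_s = 60, dt_ms = 0.01,
                          record_stride_ms = 20)
    gates <- setdiff(m$state_names, c("V", "Nai", "Cai", "CaSR", "Ki"))
    g <- st$states[, gates]
    expect_true(all(g >= -1e-12 & g <= 1 + 1e-12),
                label = paste(id, "gates within [0,1]"))
  }
})

test_that("halving the time step changes ventricular AP features by < 1%", {
  vm <- cell_model("ventricular", use_optimized = TRUE)
  f1 <- extract_ap_features(simulate_ap(vm, 60, dt_ms = 0.01), "ventricular")
  f2 <- extract_ap_features(simulate_ap(vm, 60, dt_ms = 0.005), "ventricular")
  for (k in c("MDP", "APD90", "BF")) {
    expect_lt(abs(f1[[k]] - f2[[k]]) / abs(f2[[k]]), 0.01, label = k)
  }
})

test_that("feature extraction matches the triangular-AP closed form", {
  tr <- triangle_trace(n_beats = 5, period_ms = 1000, mdp = -70, peak = 40,
                       up_ms = 2, down_ms = 300)
  f <- extract_ap_features(tr, "ventricular", analysis_window_s = 5)
  expect_true(f$beating)
  expect_equal(f$MDP, -70)
  expect_equal(f$Peak, 40)
  expect_equal(f$Vmax, 55)            # 110 mV over 2 ms
  expect_equal(f$BF, 60)              # beats exactly 1000 ms apart
  # ramp geometry: crossing sample at +1 ms, APD90 at 90% repolarization
  expect_equal(f$APD90, 271, tolerance = 1e-6)
  expect_equal(f$APD50, 151, tolerance = 1e-6)
  expect_equal(f$APD90_50, 271 / 151, tolerance = 1e-6)
})

test_that("feature extraction ignores a constant time offset", {
  tr <- triangle_trace()
  tr2 <- tr; tr2$time_ms <- tr2$time_ms + 12345
  f1 <- extract_ap_features(tr, "ventricular")
  f2 <- extract_ap_features(tr2, "ventricular")
  expect_equal(f1[c("MDP", "Vmax", "APD90", "BF")],
               f2[c("MDP", "Vmax", "APD90", "BF")])
})

test_that("constant traces are flagged non-beating, not errors", {
  tr <- structure(data.frame(time_ms = 0:999, V_mV = rep(-70, 1000)),
                  class = c("cardiomag_ap_trace", "data.frame"))
  f <- extract_ap_features(tr, "ventricular")
  expect_false(f$beating)
  expect_true(is.na(f$APD90))
})

test_that("Q10 temperature scaling follows the power law", {
  expect_identical(apply_q10(5, 2.5, 37, 37), 5)
  expect_identical(apply_q10(5, 1, 12, 37), 5)
  expect_equal(apply_q10(8, 2, 27, 37), 4)   # 10 degrees below: halved
  expect_equal(apply_q10(1, 3, 57, 37), 9)
  expect_error(apply_q10(1, -1, 20, 37))
  expect_equal(bpm_to_hz(60), 1)
})
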