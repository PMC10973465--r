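# Shared fixtures: small synthetic templates and corpora built in code.

# a smooth biphasic test peak (pT), 250 ms at 1 kHz
toy_template <- function(amp = 0.15, len = 250) {
  t <- seq_len(len)
  w <- amp * sin(2 * pi * (t - 1) / len) * exp(-((t - len / 2)^2) / (2 * (len / 5)^2))
  peak_template(w)
}

# tiny corpus for fast detector tests: short records, clean peaks
tiny_corpus <- function(n = 8, duration_s = 10, intensity = 1,
                        noise_sd = 0.05, seed = 7, cycle_ms = 1000) {
  prof <- noise_profile("custom", target_sd_pT = noise_sd)
  noise <- lapply(1:2, function(i)
    generate_background(prof, duration_s = duration_s, seed = seed + i))
  spec <- corpus_spec(n = n, duration_s = duration_s, cycle_ms = cycle_ms,
                      intensity = intensity, seed = seed)
  build_corpus(spec, noise, toy_template())
}

# triangular AP trace with known geometry for feature-extraction oracles
triangle_trace <- function(n_beats = 5, period_ms = 1000, mdp = -70,
                           peak = 40, up_ms = 2, down_ms = 300) {
  dt <- 1
  t_all <- numeric(0); v_all <- numeric(0)
  for (b in seq_len(n_beats)) {
    t0 <- (b - 1) * period_ms
    tt <- seq(0, period_ms - dt, by = dt)
    v <- ifelse(tt < up_ms, mdp + (peak - mdp) * tt / up_ms,
         ifelse(tt < up_ms + down_ms,
                peak - (peak - mdp) * (tt - up_ms) / down_ms, mdp))
    t_all <- c(t_all, t0 + tt); v_all <- c(v_all, v)
  }
  structure(data.frame(time_ms = t_all, V_mV = v_all),
            class = c("cardiomag_ap_trace", "data.frame"))
}
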