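#!/usr/bin/env Rscript

# Regenerates inst/extdata/peak_template_sim.csv: the 250 ms peak template
# cut from the y-axis magnetometer waveform of the monodomain sheet
# simulation (fitted models, room temperature, full-size pacemaker cluster
# on a reduced ventricular margin), normalized to the full-geometry peak
# amplitude estimate. Deterministic; takes a few minutes.
#
#   Rscript scripts/generate_template.R [--out inst/extdata/peak_template_sim.csv]

suppressPackageStartupMessages({
  library(optparse)
  library(cardiomag)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", default = "inst/extdata/peak_template_sim.csv"),
  make_option("--nx", type = "integer", default = 42),
  make_option("--duration", type = "double", default = 4),
  make_option("--dt", type = "double", default = 0.02)
)))

geom <- build_geometry(nx = opts$nx, ny = opts$nx, pacemaker_units = 1440,
                       cluster_shape = c(36, 40))
cfg <- tissue_config(duration_s = opts$duration, dt_ms = opts$dt)
models <- list(
  ventricular = cell_model("ventricular", use_optimized = TRUE,
                           overrides = c(T_degC = 24)),
  pacemaker = cell_model("pacemaker", use_optimized = TRUE,
                         overrides = c(T_degC = 24)))
wts <- link_weight_matrices(geom, sensor_assembly())
rec <- simulate_tissue(geom, cfg, models, weights = wts)
fr <- field_record(rec$time_i_ms, rec$B[, 1] * 1e12, rec$B[, 2] * 1e12,
                   rec$B[, 3] * 1e12)
# skip the initial synchronized transient before cutting
late <- fr[fr$time_ms > 1500, ]
tpl <- cut_peak_template(field_record(late$time_ms, late$Bx_pT, late$By_pT,
                                      late$Bz_pT), axis = "By_pT")
tpl$waveform <- tpl$waveform * 0.153 / max(abs(tpl$waveform))
write_template(tpl, opts$out)
cat("template ->", opts$out, "  cycle", rec$cycle_length_ms, "ms\n")
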