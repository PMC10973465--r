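# File formats, configuration and the end-to-end pipeline driver.

#' Write a field record to columnar text
#'
#' CSV with header \code{time_ms,Bx_pT,By_pT,Bz_pT} at 9 significant digits,
#' plus optional sidecar files: \code{<path>.truth} (one peak-center time in
#' ms per line) and \code{<path>.labels} (one P/N character per sample).
#'
#' @param record a \code{cardiomag_field_record} (labels taken from
#'   \code{attr(record, "labels")} if present).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_record <- function(record, path) {
  df <- as.data.frame(record)[c("time_ms", "Bx_pT", "By_pT", "Bz_pT")]
  for (cc in names(df)) df[[cc]] <- signif(df[[cc]], 9)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  truth <- attr(record, "truth_ms")
  if (!is.null(truth))
    writeLines(format(truth, trim = TRUE), paste0(path, ".truth"))
  labels <- attr(record, "labels")
  if (!is.null(labels))
    writeLines(paste(ifelse(labels, "P", "N"), collapse = ""),
               paste0(path, ".labels"))
  invisible(path)
}

#' Read a field record written by \code{\link{write_record}}
#'
#' @param path file path; sidecar \code{.truth} / \code{.labels} files are
#'   picked up automatically.
#' @return a \code{cardiomag_field_record}; label and truth sidecars are
#'   attached as attributes.
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  need <- c("time_ms", "Bx_pT", "By_pT", "Bz_pT")
  if (!all(need %in% names(df)))
    stop("malformed header: expected columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty record: ", path)
  rec <- field_record(df$time_ms, df$Bx_pT, df$By_pT, df$Bz_pT)
  tp <- paste0(path, ".truth")
  if (file.exists(tp))
    attr(rec, "truth_ms") <- as.numeric(readLines(tp))
  lp <- paste0(path, ".labels")
  if (file.exists(lp)) {
    lab <- strsplit(readLines(lp, n = 1), "")[[1]]
    if (length(lab) != nrow(df))
      stop("labels file length ", length(lab),
           " does not match record length ", nrow(df), " (line 1)")
    attr(rec, "labels") <- lab == "P"
  }
  rec
}

#' Read/write a peak template as two-column CSV
#' @param template a \code{\link{peak_template}} (for writing).
#' @param path file path.
#' @export
write_template <- function(template, path) {
  df <- data.frame(time_ms = seq_along(template$waveform) - 1,
                   B_pT = signif(template$waveform, 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  df <- read.csv(path)
  peak_template(df[[2]])
}

#' Run the full pipeline on a demonstration scale
#'
#' Chains the stages end-to-end: tissue simulation -> magnetometer forward
#' model -> peak template -> synthetic noise -> labeled corpus -> FSST+LSTM
#' training -> detection -> evaluation. Stage sizes are configurable; the
#' defaults are a desk-scale demonstration (reduced grid, short records,
#' small network), not the full study conditions.
#'
#' @param seed root seed; every stage derives a named substream.
#' @param nx,ny,sim_duration_s tissue stage.
#' @param n_records,record_s corpus stage.
#' @param hidden,max_epochs detector stage.
#' @param intensity signal amplitude multiplier.
#' @param out_dir optional directory for artifacts (CSV records + JSON
#'   manifest); NULL writes nothing.
#' @param template optional precomputed \code{\link{peak_template}}; skips
#'   the simulation stages.
#' @param verbose print stage progress.
#' @return list with the per-stage artifacts and the evaluation summary.
#' @export
run_pipeline <- function(seed = 1, nx = 21, ny = 21, sim_duration_s = 4,
                         n_records = 16, record_s = 60, hidden = 64,
                         max_epochs = 12, intensity = 1, out_dir = NULL,
                         template = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(template)) {
    say("[1/5] tissue simulation (%dx%d, %g s)", nx, ny, sim_duration_s)
    template <- simulated_peak_template(nx = nx, ny = ny,
                                        duration_s = sim_duration_s)
  } else say("[1/5] using supplied peak template")

  say("[2/5] synthetic background noise")
  prof <- noise_profile("y-cell")
  noise <- lapply(seq_len(4), function(i)
    generate_background(prof, duration_s = record_s,
                        seed = .sub_seed(seed, i, salt = 11L)))

  say("[3/5] corpus (%d records of %g s)", n_records, record_s)
  spec <- corpus_spec(n = n_records, duration_s = record_s,
                      intensity = intensity,
                      seed = .sub_seed(seed, 0L, salt = 12L))
  corpus <- build_corpus(spec, noise, template)

  say("[4/5] training (hidden %d)", hidden)
  model <- train_network(corpus, net_config(hidden = hidden),
                         train_config(max_epochs = max_epochs,
                                      seed = .sub_seed(seed, 0L, salt = 13L)),
                         fsst_config())

  say("[5/5] detection on held-out records")
  test_recs <- corpus_split(corpus, "test")
  eval_one <- function(rec) {
    cl <- classify(model, rec)
    regions <- detect_peak_regions(cl$label, 150)
    match_peaks(regions, rec$truth_ms, tolerance_ms = 250,
                duration_s = length(rec$waveform) / 1000)
  }
  evals <- lapply(test_recs, eval_one)
  signal_idx <- vapply(test_recs, function(r) r$polarity != "noise-only",
                       logical(1))
  sens <- {
    cor_ <- sum(vapply(evals[signal_idx], `[[`, numeric(1), "correct"))
    tot <- sum(vapply(evals[signal_idx], `[[`, numeric(1), "n_truth"))
    if (tot > 0) cor_ / tot else NA_real_
  }
  fp_rate <- {
    e <- evals[!signal_idx]
    if (length(e))
      mean(vapply(e, `[[`, numeric(1), "peaks_per_min")) else NA_real_
  }
  summary <- list(sensitivity = sens, noise_fp_per_min = fp_rate,
                  n_test = length(test_recs),
                  elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  say("done: sensitivity %.2f, background false positives %.1f /min",
      sens, fp_rate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_template(template, file.path(out_dir, "peak_template.csv"))
    jsonlite::write_json(
      list(seed = seed, stages = list(nx = nx, ny = ny,
                                      n_records = n_records,
                                      hidden = hidden),
           summary = summary),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(template = template, corpus = corpus, model = model,
       evaluations = evals, summary = summary)
}

#' Peak template from a reduced tissue simulation
#'
#' Runs the monodomain sheet with the fitted models at room temperature on a
#' (by default reduced) grid, applies the magnetometer forward model online,
#' and cuts the 250 ms peak template from the y-axis waveform. The template
#' amplitude is rescaled to the amplitude estimated for the full-size sheet
#' (\code{full_scale_pT}), since a reduced grid carries proportionally fewer
#' current-carrying links.
#'
#' @param nx,ny,duration_s,dt_ms simulation size.
#' @param full_scale_pT peak amplitude the template is normalized to; NULL
#'   keeps the raw reduced-grid amplitude.
#' @return a \code{\link{peak_template}} with attribute \code{cycle_ms}.
#' @export
simulated_peak_template <- function(nx = 21, ny = 21, duration_s = 4,
                                    dt_ms = 0.02, full_scale_pT = 0.153) {
  geom <- build_geometry(nx = nx, ny = ny,
                         pacemaker_units = round(0.2 * nx * ny))
  cfg <- tissue_config(duration_s = duration_s, dt_ms = dt_ms)
  models <- list(
    ventricular = cell_model("ventricular", use_optimized = TRUE,
                             overrides = c(T_degC = 24)),
    pacemaker = cell_model("pacemaker", use_optimized = TRUE,
                           overrides = c(T_degC = 24)))
  wts <- link_weight_matrices(geom, sensor_assembly())
  rec <- simulate_tissue(geom, cfg, models, weights = wts, record_v = TRUE)
  fr <- field_record(rec$time_i_ms, rec$B[, 1] * 1e12, rec$B[, 2] * 1e12,
                     rec$B[, 3] * 1e12)
  tpl <- cut_peak_template(fr, axis = "By_pT")
  if (!is.null(full_scale_pT))
    tpl$waveform <- tpl$waveform * full_scale_pT / max(abs(tpl$waveform))
  attr(tpl, "cycle_ms") <- rec$cycle_length_ms
  tpl
}
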