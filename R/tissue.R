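# 2D monodomain tissue simulation of the cultured cardiomyocyte sheet.

#' Build the sheet geometry with a pacemaker cluster
#'
#' The default reproduces the study geometry: an 84 x 84 grid of 60 um units
#' with a contiguous lower-left cluster of exactly 1440 pacemaker-like units
#' (the remaining 5616 are ventricular-type). The cluster is a w x h
#' rectangle with w * h = \code{pacemaker_units}; among the divisor pairs
#' that fit the grid the most nearly square is chosen, tie broken toward
#' taller-than-wide (so 1440 becomes 36 x 40 and 8 on a 4 x 4 grid becomes
#' 2 x 4).
#'
#' @param nx,ny grid size in units.
#' @param dx_um spatial step (um); dy = dx.
#' @param pacemaker_units number of pacemaker-like units (0 for none).
#' @param placement corner for the cluster (only \code{"lower-left"} is
#'   shipped; the magnetometer convention expects it).
#' @param cluster_shape optional c(w, h) overriding the automatic rectangle.
#' @return Object of class \code{cardiomag_geometry} with the integer type
#'   map (\code{0} = ventricular, \code{1} = pacemaker) as an nx x ny matrix
#'   indexed \code{[i, j]} with x the first index and the cluster at low i, j.
#' @export
build_geometry <- function(nx = 84, ny = 84, dx_um = 60,
                           pacemaker_units = 1440,
                           placement = "lower-left", cluster_shape = NULL) {
  stopifnot(nx >= 1, ny >= 1, pacemaker_units >= 0,
            pacemaker_units <= nx * ny, placement == "lower-left")
  type <- matrix(0L, nx, ny)
  if (pacemaker_units > 0) {
    if (is.null(cluster_shape)) {
      divs <- which(pacemaker_units %% seq_len(pacemaker_units) == 0)
      cand <- lapply(divs, function(w) c(w, pacemaker_units / w))
      cand <- Filter(function(p) p[1] <= nx && p[2] <= ny, cand)
      sq <- vapply(cand, function(p) abs(p[1] - p[2]), numeric(1))
      # prefer the most nearly square exact rectangle, tie toward taller
      ok <- length(cand) && min(sq) <= max(2, 0.2 * sqrt(pacemaker_units))
      if (ok) {
        tall <- vapply(cand, function(p) p[1] <= p[2], logical(1))
        cluster_shape <- cand[[order(sq, !tall)[1]]]
      } else {
        # no usable exact rectangle: near-square block, partial last row
        w <- min(nx, ceiling(sqrt(pacemaker_units)))
        h <- ceiling(pacemaker_units / w)
        if (h > ny) stop("pacemaker cluster cannot fit the grid")
        cluster_shape <- c(w, h)
      }
    }
    w <- cluster_shape[1]; h <- cluster_shape[2]
    if (w * h < pacemaker_units || w > nx || h > ny)
      stop("cluster shape does not fit or does not match unit count")
    full_rows <- pacemaker_units %/% w
    type[seq_len(w), seq_len(full_rows)] <- 1L
    rem <- pacemaker_units - full_rows * w
    if (rem > 0) type[seq_len(rem), full_rows + 1L] <- 1L
  }
  structure(list(nx = nx, ny = ny, dx_um = dx_um, type = type,
                 pacemaker_units = pacemaker_units),
            class = "cardiomag_geometry")
}

#' @export
print.cardiomag_geometry <- function(x, ...) {
  cat(sprintf("<cardiomag_geometry> %d x %d units, dx = %g um, %d pacemaker / %d ventricular\n",
              x$nx, x$ny, x$dx_um, sum(x$type == 1L), sum(x$type == 0L)))
  invisible(x)
}

#' Tissue solver configuration
#'
#' Electrical and numerical parameters of the monodomain sheet. Isotropy is
#' the default (\code{rho_y = rho_x}, \code{S_y = S_x}). The effective sheet
#' thickness sets the cross-section of the inter-unit conduction path and is
#' the main knob scaling absolute magnetic amplitude. The default resistivity
#' reproduces a conduction velocity of about 0.02 m/s on a 1D strand of the
#' fitted ventricular model (see \code{\link{calibrate_resistivity}}).
#'
#' @param rho_x,rho_y averaged cellular resistivity (Ohm m).
#' @param S_x,S_y surface-to-volume ratio (1/m).
#' @param Cm_area membrane capacitance per unit area (F/m^2).
#' @param thickness_um effective sheet thickness (um) for the link-current
#'   cross-section.
#' @param dt_ms integration step (ms).
#' @param duration_s simulated time (s).
#' @param v_stride_ms membrane-potential snapshot stride (ms).
#' @param i_stride_ms link-current / field sampling stride (ms; 1 ms gives
#'   the 1 kHz magnetometer rate).
#' @param act_threshold_mV activation-time detection threshold (mV).
#' @return list of class \code{cardiomag_tissue_config}.
#' @export
tissue_config <- function(rho_x = 1860, rho_y = rho_x, S_x = 2e5, S_y = S_x,
                          Cm_area = 0.01, thickness_um = 1100,
                          dt_ms = 0.01, duration_s = 60,
                          v_stride_ms = 10, i_stride_ms = 1,
                          act_threshold_mV = -20) {
  stopifnot(rho_x > 0, rho_y > 0, S_x > 0, S_y > 0, Cm_area > 0, dt_ms > 0)
  structure(list(rho_x = rho_x, rho_y = rho_y, S_x = S_x, S_y = S_y,
                 Cm_area = Cm_area, thickness_um = thickness_um,
                 dt_ms = dt_ms, duration_s = duration_s,
                 v_stride_ms = v_stride_ms, i_stride_ms = i_stride_ms,
                 act_threshold_mV = act_threshold_mV),
            class = "cardiomag_tissue_config")
}

# diffusion coefficients on the grid, 1/ms
.grid_diffusion <- function(geometry, config) {
  dx_m <- geometry$dx_um * 1e-6
  Dx <- 1 / (config$rho_x * config$S_x * config$Cm_area)  # m^2/s
  Dy <- 1 / (config$rho_y * config$S_y * config$Cm_area)
  c(Dx = Dx / dx_m^2 / 1000, Dy = Dy / dx_m^2 / 1000)
}

# link resistance (Ohm): rho * dx / (dx * thickness) = rho / thickness
.link_resistance <- function(geometry, config) {
  th_m <- config$thickness_um * 1e-6
  c(Rx = config$rho_x / th_m, Ry = config$rho_y / th_m)
}

#' Inter-unit link currents for one membrane-potential frame
#'
#' Current on each x-link is (V[i,j] - V[i+1,j]) / R_link (in A, V converted
#' from mV), positive toward increasing index; similarly for y-links.
#'
#' @param V_frame nx x ny matrix of membrane potential (mV).
#' @param geometry a \code{cardiomag_geometry}.
#' @param config a \code{cardiomag_tissue_config}.
#' @return list with matrices \code{Ix} ((nx-1) x ny) and \code{Iy}
#'   (nx x (ny-1)) in amperes.
#' @export
link_currents <- function(V_frame, geometry, config) {
  stopifnot(nrow(V_frame) == geometry$nx, ncol(V_frame) == geometry$ny)
  R <- .link_resistance(geometry, config)
  nx <- geometry$nx; ny <- geometry$ny
  Ix <- (V_frame[-nx, , drop = FALSE] - V_frame[-1, , drop = FALSE]) * 1e-3 / R["Rx"]
  Iy <- (V_frame[, -ny, drop = FALSE] - V_frame[, -1, drop = FALSE]) * 1e-3 / R["Ry"]
  list(Ix = Ix, Iy = Iy)
}

#' Advance a passive (I_ion = 0) field by Crank-Nicolson diffusion
#'
#' Exposes the solver's ADI Crank-Nicolson diffusion core with zero-flux
#' boundaries, for verification against heat-equation closed forms.
#'
#' @param V_frame nx x ny matrix (mV).
#' @inheritParams link_currents
#' @param n_steps number of dt-length steps.
#' @return nx x ny matrix after diffusion.
#' @export
diffuse_field <- function(V_frame, geometry, config, n_steps = 1) {
  D <- .grid_diffusion(geometry, config)
  out <- cpp_diffuse(as.numeric(V_frame), geometry$nx, geometry$ny,
                     config$dt_ms, D["Dx"], D["Dy"], as.integer(n_steps))
  matrix(out, geometry$nx, geometry$ny)
}

#' Simulate the 2D cardiomyocyte sheet
#'
#' Operator-split monodomain integration: per-unit ionic forward-Euler update
#' followed by an ADI Crank-Nicolson diffusion step each dt. Records membrane
#' potential snapshots, link currents at the magnetometer rate (optional; the
#' arrays are large) and/or the projected magnetometer channels when a weight
#' matrix from \code{\link{link_weight_matrices}} is supplied.
#'
#' @param geometry a \code{\link{build_geometry}} result.
#' @param config a \code{\link{tissue_config}}.
#' @param models list with elements \code{ventricular} and \code{pacemaker}
#'   (\code{\link{cell_model}} objects, typically at 24 degrees C with the
#'   fitted scalings).
#' @param weights optional list with matrices \code{wx}, \code{wy} projecting
#'   link currents onto field channels (tesla per ampere).
#' @param record_links record raw link currents (memory heavy; short runs).
#' @param record_v record V snapshots.
#' @param stim optional list(idx, start_ms, dur_ms, amp) for an external
#'   stimulus (A/F) applied to 1-based unit indices.
#' @return Object of class \code{cardiomag_tissue_recording}: snapshot times
#'   and V matrix (frames x units), link-current sample times, optional
#'   \code{Ix}/\code{Iy}, optional projected field \code{B} (frames x
#'   channels, tesla), per-unit activation times (ms) and the estimated
#'   dominant cycle length (ms).
#' @export
simulate_tissue <- function(geometry, config, models, weights = NULL,
                            record_links = FALSE, record_v = TRUE,
                            stim = NULL) {
  stopifnot(inherits(geometry, "cardiomag_geometry"),
            inherits(config, "cardiomag_tissue_config"))
  vm <- models$ventricular; pm <- models$pacemaker
  stopifnot(inherits(vm, "cardiomag_cell_model"),
            inherits(pm, "cardiomag_cell_model"))
  D <- .grid_diffusion(geometry, config)
  R <- .link_resistance(geometry, config)
  wx <- wy <- NULL
  if (!is.null(weights)) { wx <- weights$wx; wy <- weights$wy }
  if (is.null(stim)) stim <- list(idx = integer(0), start_ms = 0,
                                  dur_ms = 0, amp = 0)
  # type map transposed to k = j*nx + i linear order (x fastest)
  res <- cpp_simulate_tissue(
    geometry$nx, geometry$ny, as.integer(geometry$type),
    vm$params, pm$params,
    matrix(as.numeric(vm$state0), ncol = 1), as.numeric(pm$state0),
    .vent_pool_fixed(vm$fixed),
    config$duration_s * 1000, config$dt_ms,
    D[["Dx"]], D[["Dy"]], R[["Rx"]], R[["Ry"]],
    config$v_stride_ms, config$i_stride_ms,
    wx, wy, record_links, record_v,
    as.integer(stim$idx) - 1L, stim$start_ms, stim$dur_ms, stim$amp,
    config$act_threshold_mV)
  rec <- structure(list(
    geometry = geometry, config = config,
    time_v_ms = res$time_v_ms, V = res$V,
    time_i_ms = res$time_i_ms, Ix = res$Ix, Iy = res$Iy, B = res$B,
    activation_ms = res$activation_ms,
    cycle_length_ms = NA_real_),
    class = "cardiomag_tissue_recording")
  if (record_v && nrow(res$V) > 3)
    rec$cycle_length_ms <- .dominant_cycle(res$time_v_ms, rowMeans(res$V),
                                           config$act_threshold_mV)
  rec
}

# pool indices (0-based) of clamped ventricular state variables in the
# tissue solver's per-unit layout; only concentrations are clampable there
.vent_pool_fixed <- function(fixed) {
  map <- c(Nai = 13L, Cai = 14L, CaSR = 15L, Ki = 16L)
  unname(map[intersect(fixed, names(map))])
}

# dominant activation cycle length from the spatial-mean potential:
# mean interval between upward threshold crossings
.dominant_cycle <- function(t, vbar, threshold = -20) {
  up <- which(vbar[-length(vbar)] < threshold & vbar[-1] >= threshold)
  if (length(up) < 2) return(NA_real_)
  mean(diff(t[up]))
}

#' @export
print.cardiomag_tissue_recording <- function(x, ...) {
  cat(sprintf("<tissue_recording> %d x %d units, %.1f s, cycle %.0f ms\n",
              x$geometry$nx, x$geometry$ny,
              max(x$time_i_ms, 0) / 1000, x$cycle_length_ms))
  invisible(x)
}

#' Planar conduction velocity on a 1D strand
#'
#' Stimulates one end of an all-ventricular strand and fits activation time
#' against distance over the central units.
#'
#' @param model ventricular \code{cell_model}. The probe protocol makes the
#'   strand stably quiescent until stimulated (spontaneous firing would
#'   otherwise mask slow propagation): the funny current is suppressed, the
#'   inward rectifier is scaled up threefold, and the strand starts from a
#'   pre-equilibrated resting state of that quiescent membrane.
#' @param config \code{tissue_config} (its \code{rho_x} is the value probed).
#' @param n_units strand length.
#' @param dx_um spatial step.
#' @param stim_amp stimulus amplitude (A/F) on the first three units.
#' @return conduction velocity (m/s), or NA if the wave failed to propagate.
#' @export
measure_cv <- function(model, config, n_units = 50, dx_um = 60,
                       stim_amp = 40) {
  geom <- build_geometry(nx = n_units, ny = 1, dx_um = dx_um,
                         pacemaker_units = 0)
  cfg <- config
  cfg$duration_s <- min(config$duration_s, 1.0)
  cfg$v_stride_ms <- 1000; cfg$i_stride_ms <- 1000
  quiet <- model
  quiet$params[["sf"]] <- 0
  quiet$params[["sK1"]] <- 3 * quiet$params[["sK1"]]
  rest <- simulate_ap(quiet, duration_s = 3, dt_ms = 0.05)
  quiet$state0 <- attr(rest, "final_state")
  pm <- cell_model("pacemaker") # unused by an all-ventricular strand
  rec <- simulate_tissue(geom, cfg, list(ventricular = quiet, pacemaker = pm),
                         record_v = FALSE,
                         stim = list(idx = 1:3, start_ms = 5, dur_ms = 2,
                                     amp = stim_amp))
  act <- rec$activation_ms
  mid <- seq(ceiling(n_units * 0.3), floor(n_units * 0.8))
  if (any(is.na(act[mid]))) return(NA_real_)
  fit <- stats::lm(act[mid] ~ mid)
  slope <- unname(coef(fit)[2])         # ms per unit
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  (dx_um * 1e-6) / (slope * 1e-3)       # m/s
}

#' Calibrate resistivity to a conduction-velocity target
#'
#' Bisection on log(rho) using the empirical monotone decrease of conduction
#' velocity with resistivity, until the strand conduction velocity of the
#' ventricular model matches \code{target_cv} within \code{tol}.
#'
#' @param target_cv target conduction velocity (m/s).
#' @param config base \code{tissue_config}.
#' @param model ventricular model (default: registry fitted model at the
#'   configured temperature).
#' @param bracket c(lo, hi) resistivity bracket (Ohm m).
#' @param tol relative tolerance on the conduction velocity.
#' @param max_iter bisection iterations.
#' @return calibrated resistivity (Ohm m) with attribute \code{cv}.
#' @export
calibrate_resistivity <- function(target_cv, config,
                                  model = NULL,
                                  bracket = c(0.05, 200), tol = 0.02,
                                  max_iter = 30) {
  stopifnot(target_cv > 0)
  if (is.null(model))
    model <- cell_model("ventricular", use_optimized = TRUE,
                        overrides = c(T_degC = 24))
  cv_at <- function(rho) {
    cfg <- config; cfg$rho_x <- cfg$rho_y <- rho
    measure_cv(model, cfg)
  }
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- cv_at(lo); cv_hi <- cv_at(hi)
  if (is.na(cv_lo) || cv_lo < target_cv)
    stop("target conduction velocity unreachable: too fast for bracket")
  if (!is.na(cv_hi) && cv_hi > target_cv)
    stop("target conduction velocity unreachable: too slow for bracket")
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    cv <- cv_at(mid)
    if (!is.na(cv) && abs(cv - target_cv) / target_cv < tol) {
      return(structure(mid, cv = cv))
    }
    if (is.na(cv) || cv < target_cv) hi <- mid else lo <- mid
  }
  mid <- sqrt(lo * hi)
  structure(mid, cv = cv_at(mid))
}
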