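# Biot-Savart forward model: tissue link currents (or a calibration wire)
# -> average flux density through three orthogonal first-order gradiometric
# pickup coils.

MU0 <- 4 * pi * 1e-7  # T m / A, exact

#' Field magnitude of an infinite straight wire
#'
#' @param I current (A).
#' @param r distance from the wire (m), > 0.
#' @return field magnitude mu0 I / (2 pi r) in tesla.
#' @export
wire_field <- function(I, r) {
  if (any(r <= 0)) stop("distance from wire must be > 0")
  MU0 * I / (2 * pi * r)
}

#' Magnetic field of a finite straight current segment
#'
#' Standard finite-segment Biot-Savart closed form. Points may be given as a
#' matrix (one row per observation point).
#'
#' @param p1,p2 segment endpoints (m), numeric length-3.
#' @param I current (A), positive from p1 to p2.
#' @param points n x 3 matrix (or length-3 vector) of observation points (m).
#' @return n x 3 matrix of field vectors (tesla).
#' @export
segment_field <- function(p1, p2, I, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  a <- p2 - p1
  r1 <- sweep(points, 2, p1)                      # point - p1
  r2 <- sweep(points, 2, p2)
  cx <- cbind(a[2] * r1[, 3] - a[3] * r1[, 2],
              a[3] * r1[, 1] - a[1] * r1[, 3],
              a[1] * r1[, 2] - a[2] * r1[, 1])    # a x r1
  c2 <- rowSums(cx^2)
  n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
  if (any(c2 == 0 & (n1 * n2 == 0 | abs(n1 + n2 - sqrt(sum(a^2))) < 1e-300)))
    stop("observation point lies on the segment")
  d1 <- drop(r1 %*% a); d2 <- drop(r2 %*% a)
  fac <- MU0 * I / (4 * pi) * (d1 / n1 - d2 / n2) / c2
  fac[c2 == 0] <- 0  # on-axis points: zero field off the wire line
  cx * fac
}

#' Pickup-coil specification
#'
#' @param kind \code{"axial"} (circular loops, axial baseline) or
#'   \code{"planar"} (rectangular loops, in-plane baseline).
#' @param axis sensing axis: \code{"x"}, \code{"y"} or \code{"z"}.
#' @param diameter_mm circle diameter (axial kind).
#' @param width_mm,height_mm rectangle dimensions (planar kind); height runs
#'   along the bobbin (z) axis.
#' @param baseline_mm gradiometer baseline.
#' @param n_quad quadrature resolution (Gauss-Legendre nodes per dimension).
#' @return list of class \code{cardiomag_coil}.
#' @export
coil_spec <- function(kind = c("axial", "planar"), axis = c("z", "x", "y"),
                      diameter_mm = 15.5, width_mm = 9, height_mm = 15.5,
                      baseline_mm = 50, n_quad = 8) {
  kind <- match.arg(kind); axis <- match.arg(axis)
  stopifnot(baseline_mm > 0, n_quad >= 2)
  structure(list(kind = kind, axis = axis, diameter_mm = diameter_mm,
                 width_mm = width_mm, height_mm = height_mm,
                 baseline_mm = baseline_mm, n_quad = n_quad),
            class = "cardiomag_coil")
}

#' Three-axis gradiometric sensor assembly
#'
#' The assembly mirrors the magnetometer used for the measurements: an axial
#' circular first-order gradiometer (diameter 15.5 mm) sensing Bz and two
#' planar rectangular first-order gradiometers (9 x 15.5 and 11 x 15.5 mm^2)
#' sensing Bx and By, all with 50 mm baselines. Coordinates: z is vertical
#' (axial coil axis), the sample sheet lies in the plane z = -standoff. Every
#' bottom loop's lowest point sits at z = 0.
#'
#' @param standoff_mm sample distance below the bottom coil edge.
#' @param lateral_offset_mm length-2 (x, y) sample displacement.
#' @param n_quad quadrature nodes per dimension per loop.
#' @return list of class \code{cardiomag_assembly}.
#' @export
sensor_assembly <- function(standoff_mm = 3, lateral_offset_mm = c(0, 0),
                            n_quad = 8) {
  structure(list(
    coils = list(
      x = coil_spec("planar", "x", width_mm = 9, height_mm = 15.5,
                    n_quad = n_quad),
      y = coil_spec("planar", "y", width_mm = 11, height_mm = 15.5,
                    n_quad = n_quad),
      z = coil_spec("axial", "z", diameter_mm = 15.5, n_quad = n_quad)),
    standoff_mm = standoff_mm,
    lateral_offset_mm = lateral_offset_mm),
    class = "cardiomag_assembly")
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via eigen)
.gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2, weights = (b - a) / 2 * w[ord])
}

# quadrature points (n x 3), weights (sum = area) and unit normal for the two
# loops of a gradiometer; loop 2 enters with opposite sign downstream.
.coil_loops <- function(coil) {
  m <- 1e-3
  n <- coil$n_quad
  if (coil$kind == "axial") {
    R <- coil$diameter_mm / 2 * m
    gr <- .gauss_legendre(n, 0, R)
    nth <- max(8, 2 * n)
    th <- (seq_len(nth) - 0.5) * 2 * pi / nth
    wth <- rep(2 * pi / nth, nth)
    r <- rep(gr$nodes, each = nth); wr <- rep(gr$weights, each = nth)
    tt <- rep(th, n); wt <- rep(wth, n)
    pts <- cbind(r * cos(tt), r * sin(tt), 0)
    w <- wr * wt * r
    loop1 <- list(points = pts, weights = w, normal = c(0, 0, 1))
    pts2 <- pts; pts2[, 3] <- coil$baseline_mm * m
    loop2 <- list(points = pts2, weights = w, normal = c(0, 0, 1))
  } else {
    gu <- .gauss_legendre(n, -coil$width_mm / 2 * m, coil$width_mm / 2 * m)
    gv <- .gauss_legendre(n, 0, coil$height_mm * m)
    u <- rep(gu$nodes, each = n); wu <- rep(gu$weights, each = n)
    v <- rep(gv$nodes, n); wv <- rep(gv$weights, n)
    w <- wu * wv
    if (coil$axis == "x") {        # plane x = 0, u along y, v along z
      pts <- cbind(0, u, v); normal <- c(1, 0, 0)
    } else {                       # plane y = 0, u along x, v along z
      pts <- cbind(u, 0, v); normal <- c(0, 1, 0)
    }
    loop1 <- list(points = pts, weights = w, normal = normal)
    pts2 <- pts; pts2[, 3] <- pts2[, 3] + coil$baseline_mm * m
    loop2 <- list(points = pts2, weights = w, normal = normal)
  }
  list(loop1 = loop1, loop2 = loop2)
}

#' Average flux density of a field source through a gradiometric coil
#'
#' Computes (1/Area) * integral of B . n over each loop by Gauss-Legendre
#' quadrature; the gradiometer output is the bottom-loop average minus the
#' top-loop average.
#'
#' @param field_fn function(points n x 3) -> n x 3 field matrix (tesla).
#' @param coil a \code{\link{coil_spec}}.
#' @return scalar average flux density (tesla).
#' @export
coil_average_flux_density <- function(field_fn, coil) {
  lp <- .coil_loops(coil)
  avg <- function(loop) {
    B <- field_fn(loop$points)
    sum((B %*% loop$normal) * loop$weights) / sum(loop$weights)
  }
  avg(lp$loop1) - avg(lp$loop2)
}

# positions (m) of link-current segments for a geometry placed under the
# assembly: grid centered at (0,0), sheet at z = -standoff, unit (i,j) at
# x = (i - (nx+1)/2) dx, y = (j - (ny+1)/2) dy. The pacemaker cluster (low
# i, j) therefore sits toward the -x, -y corner.
.link_segments <- function(geometry, assembly) {
  m <- 1e-3
  dx <- geometry$dx_um * 1e-6
  nx <- geometry$nx; ny <- geometry$ny
  x0 <- assembly$lateral_offset_mm[1] * m
  y0 <- assembly$lateral_offset_mm[2] * m
  z <- -assembly$standoff_mm * m
  xc <- (seq_len(nx) - (nx + 1) / 2) * dx + x0
  yc <- (seq_len(ny) - (ny + 1) / 2) * dx + y0
  # x-links between (i,j) and (i+1,j), i fastest (matches solver indexing)
  gx <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny))
  xl <- list(p1 = cbind(xc[gx$i], yc[gx$j], z),
             p2 = cbind(xc[gx$i + 1], yc[gx$j], z))
  gy <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1))
  yl <- list(p1 = cbind(xc[gy$i], yc[gy$j], z),
             p2 = cbind(xc[gy$i], yc[gy$j + 1], z))
  list(x = xl, y = yl)
}

#' Magnetometer weight matrices for a tissue geometry
#'
#' For each inter-unit link and each coil axis, the gradiometer-averaged
#' flux density produced by a unit current (1 A) through that link segment.
#' The forward model is then the linear map B(t) = wx Ix(t) + wy Iy(t),
#' which \code{\link{simulate_tissue}} can apply online.
#'
#' @param geometry a \code{cardiomag_geometry}.
#' @param assembly a \code{\link{sensor_assembly}}.
#' @return list of matrices \code{wx} (3 x n_xlinks), \code{wy}
#'   (3 x n_ylinks) in tesla per ampere, rows ordered x, y, z.
#' @export
link_weight_matrices <- function(geometry, assembly) {
  segs <- .link_segments(geometry, assembly)
  w_for <- function(sg) {
    nl <- nrow(sg$p1)
    out <- matrix(0, 3, nl)
    for (axn in 1:3) {
      coil <- assembly$coils[[c("x", "y", "z")[axn]]]
      lp <- .coil_loops(coil)
      for (sgn_loop in list(c(1, "loop1"), c(-1, "loop2"))) {
        loop <- lp[[sgn_loop[2]]]
        sgn <- as.numeric(sgn_loop[1])
        wsum <- sum(loop$weights)
        acc <- numeric(nl)
        a <- sg$p2 - sg$p1                       # nl x 3 (constant per set)
        for (qp in seq_len(nrow(loop$points))) {
          p <- loop$points[qp, ]
          r1 <- cbind(p[1] - sg$p1[, 1], p[2] - sg$p1[, 2], p[3] - sg$p1[, 3])
          r2 <- cbind(p[1] - sg$p2[, 1], p[2] - sg$p2[, 2], p[3] - sg$p2[, 3])
          cx <- cbind(a[, 2] * r1[, 3] - a[, 3] * r1[, 2],
                      a[, 3] * r1[, 1] - a[, 1] * r1[, 3],
                      a[, 1] * r1[, 2] - a[, 2] * r1[, 1])
          c2 <- rowSums(cx^2)
          n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
          d1 <- rowSums(r1 * a); d2 <- rowSums(r2 * a)
          fac <- MU0 / (4 * pi) * (d1 / n1 - d2 / n2) / c2
          fac[c2 == 0 | !is.finite(fac)] <- 0
          Bn <- drop(cx %*% loop$normal) * fac
          acc <- acc + sgn * loop$weights[qp] / wsum * Bn
        }
        out[axn, ] <- out[axn, ] + acc
      }
    }
    out
  }
  list(wx = w_for(segs$x), wy = w_for(segs$y))
}

#' Project recorded link currents onto the magnetometer
#'
#' Computes the three-axis average flux density time series from a tissue
#' recording that stored raw link currents (superposition of finite-segment
#' Biot-Savart fields, coil-averaged per axis). Extracellular return
#' currents are neglected.
#'
#' @param recording a \code{cardiomag_tissue_recording} with \code{Ix},
#'   \code{Iy} recorded.
#' @param assembly a \code{\link{sensor_assembly}}.
#' @param weights optional precomputed \code{\link{link_weight_matrices}}.
#' @return a \code{\link{field_record}} in pT at the recording's current
#'   sampling rate.
#' @export
forward_magnetometer <- function(recording, assembly, weights = NULL) {
  if (is.null(recording$Ix) || !length(recording$Ix))
    stop("recording did not store link currents; rerun with record_links = TRUE")
  if (is.null(weights)) weights <- link_weight_matrices(recording$geometry, assembly)
  Bt <- recording$Ix %*% t(weights$wx) + recording$Iy %*% t(weights$wy)  # T
  field_record(time_ms = recording$time_i_ms,
               Bx_pT = Bt[, 1] * 1e12, By_pT = Bt[, 2] * 1e12,
               Bz_pT = Bt[, 3] * 1e12)
}

#' Construct a three-axis field record
#'
#' @param time_ms sample times (ms, 1 kHz convention: sample i at i ms).
#' @param Bx_pT,By_pT,Bz_pT channel waveforms (pT); missing axes may be NA.
#' @param truth_ms optional ground-truth peak-center times (ms).
#' @return data.frame of class \code{cardiomag_field_record}.
#' @export
field_record <- function(time_ms, Bx_pT = NA_real_, By_pT = NA_real_,
                         Bz_pT = NA_real_, truth_ms = NULL) {
  out <- data.frame(time_ms = time_ms, Bx_pT = Bx_pT, By_pT = By_pT,
                    Bz_pT = Bz_pT)
  attr(out, "truth_ms") <- truth_ms
  attr(out, "fs") <- 1000
  class(out) <- c("cardiomag_field_record", "data.frame")
  out
}

#' Cut the peak template out of a simulated field waveform
#'
#' Extracts a window (default 250 ms) centered on the largest-magnitude
#' excursion of the chosen axis.
#'
#' @param record a \code{cardiomag_field_record} from the forward model.
#' @param axis which channel to cut.
#' @param length_ms template length.
#' @return a \code{\link{peak_template}}.
#' @export
cut_peak_template <- function(record, axis = "By_pT", length_ms = 250) {
  x <- record[[axis]]
  ctr <- which.max(abs(x))
  half <- floor(length_ms / 2)
  i0 <- ctr - half; i1 <- i0 + length_ms - 1
  if (i0 < 1 || i1 > length(x)) stop("peak too close to record edge")
  peak_template(x[i0:i1] - mean(x[c(i0, i1)]), axis = axis)
}

#' Peak template container
#'
#' @param waveform numeric waveform (pT) sampled at 1 kHz; nominal length
#'   250 samples.
#' @param axis source axis label.
#' @return list of class \code{cardiomag_peak_template}.
#' @export
peak_template <- function(waveform, axis = "By_pT") {
  stopifnot(all(is.finite(waveform)))
  structure(list(waveform = as.numeric(waveform), fs = 1000, axis = axis),
            class = "cardiomag_peak_template")
}

#' Artificial magnetic signal from the calibration wire
#'
#' Emulates the validation setup: a long straight wire along the y axis under
#' the sensor carries a current whose waveform repeats the peak template at a
#' fixed rate; the x-axis gradiometer output is the wire field (infinite
#' straight-wire law) integrated over the pickup coil. The current amplitude
#' is chosen so the coil-averaged field reproduces the template amplitude
#' times \code{intensity} times \code{snr_factor} (the enhancement that
#' matches the wire experiment's signal-to-noise ratio to the cell
#' experiment).
#'
#' @param template a \code{\link{peak_template}}.
#' @param intensity fold multiplier on the estimated cell signal (0.5, 1, 5
#'   in the validation experiments).
#' @param duration_s record length (s).
#' @param rate_hz peak repetition rate.
#' @param wire_depth_mm wire distance below z = 0 (bottom coil edge).
#' @param snr_factor enhancement factor applied to emulate the wire setup.
#' @param noise optional \code{cardiomag_field_record} of background noise to
#'   add (x axis).
#' @return a \code{\link{field_record}} with ground-truth peak centers; the
#'   x channel carries the signal.
#' @export
generate_artificial_signal <- function(template, intensity = 1,
                                       duration_s = 120, rate_hz = 1,
                                       wire_depth_mm = 3, snr_factor = 2.74,
                                       noise = NULL) {
  if (rate_hz * duration_s < 1) stop("duration too short for one peak")
  n <- round(duration_s * 1000)
  tpl <- template$waveform
  # coil transfer: average Bx over the x gradiometer per ampere in the wire
  coil <- sensor_assembly()$coils$x
  wire_fn <- function(points) {
    # wire along y at (0, z = -wire_depth); B = mu0 I/(2 pi r^2) (yhat x r)
    rz <- points[, 3] + wire_depth_mm * 1e-3
    rx <- points[, 1]
    r2 <- rx^2 + rz^2
    cbind(MU0 / (2 * pi) * rz / r2, 0, -MU0 / (2 * pi) * rx / r2)
  }
  k <- coil_average_flux_density(wire_fn, coil)    # T per A
  amp <- intensity * snr_factor
  period <- round(1000 / rate_hz)
  centers <- seq(period / 2, n - period / 2, by = period)
  sig <- numeric(n)
  half <- floor(length(tpl) / 2)
  for (ctr in centers) {
    i0 <- round(ctr) - half
    idx <- seq(i0, i0 + length(tpl) - 1)
    ok <- idx >= 1 & idx <= n
    sig[idx[ok]] <- sig[idx[ok]] + tpl[ok]
  }
  I_t <- amp * (sig * 1e-12) / k                   # A through the wire
  bx <- k * I_t * 1e12                             # back to pT, == amp * sig
  if (!is.null(noise)) {
    stopifnot(nrow(noise) >= n)
    bx <- bx + noise$Bx_pT[seq_len(n)]
  }
  field_record(time_ms = seq_len(n) - 1, Bx_pT = bx,
               truth_ms = centers - 1)
}
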