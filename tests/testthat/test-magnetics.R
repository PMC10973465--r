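# Biot-Savart forward model and gradiometric pickup coils.

test_that("the infinite-wire law holds exactly", {
  expect_equal(wire_field(1, 1), 2e-7)
  expect_equal(wire_field(1, 2), wire_field(1, 1) / 2)
  expect_equal(wire_field(3, 0.5), 3 * wire_field(1, 0.5))
  expect_error(wire_field(1, 0))
})

test_that("finite-segment field matches the textbook closed form", {
  # perpendicular bisector of a segment of length 2L at distance d:
  # B = mu0 I / (4 pi d) * 2 L / sqrt(L^2 + d^2), perpendicular to the plane
  L <- 0.3; d <- 0.2; I <- 2
  B <- segment_field(c(0, -L, 0), c(0, L, 0), I, c(d, 0, 0))
  Bth <- 1e-7 * I / d * 2 * L / sqrt(L^2 + d^2)
  expect_equal(B[1, 3], -Bth, tolerance = 1e-12)
  expect_equal(B[1, 1], 0); expect_equal(B[1, 2], 0)

  # two equal co-directed segments mirror-placed about the point cancel
  B2 <- segment_field(c(-0.1, -1, 0), c(-0.1, 1, 0), 1, c(0, 0, 0)) +
        segment_field(c(0.1, -1, 0), c(0.1, 1, 0), 1, c(0, 0, 0))
  expect_equal(max(abs(B2)), 0, tolerance = 1e-22)
  # reversing the current flips the field exactly
  Bf <- segment_field(c(0, -1, 0), c(0, 1, 0), 1, c(0.2, 0, 0.1))
  Bb <- segment_field(c(0, 1, 0), c(0, -1, 0), 1, c(0.2, 0, 0.1))
  expect_equal(Bb, -Bf)

  # long segment tends to the infinite-wire law
  r <- 0.01
  B3 <- segment_field(c(0, -5, 0), c(0, 5, 0), 1, c(r, 0, 0))
  expect_equal(sqrt(sum(B3^2)), wire_field(1, r), tolerance = 1e-3)

  expect_error(segment_field(c(0, -1, 0), c(0, 1, 0), 1, c(0, 0, 0)),
               "on the segment")
})

test_that("a first-order gradiometer rejects a uniform field exactly", {
  for (kind in c("axial", "planar")) {
    coil <- coil_spec(kind, axis = if (kind == "axial") "z" else "x")
    n <- if (kind == "axial") c(0, 0, 1) else c(1, 0, 0)
    g <- coil_average_flux_density(function(p)
      matrix(rep(n * 3e-12, each = nrow(p)), ncol = 3), coil)
    expect_identical(g, 0)
  }
})

test_that("a field confined to the bottom loop passes through unattenuated", {
  coil <- coil_spec("axial", "z")
  fld <- function(p) cbind(0, 0, ifelse(p[, 3] < 0.025, 1e-12, 0))
  g <- coil_average_flux_density(fld, coil)
  expect_equal(g, 1e-12)
})

test_that("coil-averaged wire flux matches the analytic log integral", {
  # wire along y at depth d below the x-sensing planar coil (plane x = 0,
  # width w along y, height h along z): average of mu0 I/(2 pi (z+d)) over
  # the loop = mu0 I/(2 pi h) ln((d+h)/d); subtract the top loop term
  coil <- coil_spec("planar", "x", width_mm = 9, height_mm = 15.5,
                    baseline_mm = 50, n_quad = 12)
  d <- 0.003; I <- 1
  fld <- function(p) {
    rz <- p[, 3] + d; rx <- p[, 1]
    r2 <- rx^2 + rz^2
    cbind(2e-7 * I * rz / r2, 0, -2e-7 * I * rx / r2)
  }
  g <- coil_average_flux_density(fld, coil)
  h <- 0.0155; base <- 0.050
  a1 <- 2e-7 * I / h * log((d + h) / d)
  a2 <- 2e-7 * I / h * log((d + base + h) / (d + base))
  expect_equal(g, a1 - a2, tolerance = 0.005)
})

test_that("coil average approaches the point value for a distant source", {
  coil <- coil_spec("axial", "z", n_quad = 10)
  d <- 1.0 # 1 m away; coil is 15.5 mm
  fld <- function(p) {
    rz <- p[, 3] + d
    cbind(0, 0, 2e-7 / rz)
  }
  g <- coil_average_flux_density(fld, coil)
  pointv <- 2e-7 / d - 2e-7 / (d + 0.05)
  expect_equal(g, pointv, tolerance = 0.01 * abs(pointv))
})

test_that("quadrature refinement changes the link weights by < 0.1%", {
  geom <- build_geometry(nx = 6, ny = 6, pacemaker_units = 0)
  w8 <- link_weight_matrices(geom, sensor_assembly(n_quad = 8))
  w16 <- link_weight_matrices(geom, sensor_assembly(n_quad = 16))
  rel <- max(abs(w8$wx - w16$wx)) / max(abs(w16$wx))
  expect_lt(rel, 1e-3)
})

test_that("the forward magnetometer map is linear and mirror-antisymmetric", {
  geom <- build_geometry(nx = 8, ny = 8, pacemaker_units = 0)
  asm <- sensor_assembly()
  w <- link_weight_matrices(geom, asm)
  set.seed(3)
  Ix <- matrix(rnorm(2 * 7 * 8, sd = 1e-9), 2)  # 2 frames
  Iy <- matrix(rnorm(2 * 8 * 7, sd = 1e-9), 2)
  rec <- structure(list(geometry = geom, time_i_ms = 0:1, Ix = Ix, Iy = Iy),
                   class = "cardiomag_tissue_recording")
  fr <- forward_magnetometer(rec, asm, weights = w)
  rec2 <- rec; rec2$Ix <- 3 * Ix; rec2$Iy <- 3 * Iy
  fr2 <- forward_magnetometer(rec2, asm, weights = w)
  expect_equal(fr2$Bx_pT, 3 * fr$Bx_pT)
  expect_equal(fr2$By_pT, 3 * fr$By_pT)

  # mirror the currents across the x-z plane (y -> -y). The field is a
  # pseudovector and the sensor is symmetric under this mirror, so the
  # in-plane outputs (x and z axes) flip sign while the y-axis output is
  # preserved. Mirroring maps the x-link at (i,j) to (i, ny+1-j) keeping its
  # sign, and the y-link at (i,j) to (i, ny-j) with reversed current.
  mir_x <- function(I) {
    m <- array(I, c(nrow(I), 7, 8))[, , 8:1, drop = FALSE]
    matrix(m, nrow(I))
  }
  mir_y <- function(I) {
    m <- array(I, c(nrow(I), 8, 7))[, , 7:1, drop = FALSE]
    -matrix(m, nrow(I))
  }
  rec3 <- rec; rec3$Ix <- mir_x(Ix); rec3$Iy <- mir_y(Iy)
  fr3 <- forward_magnetometer(rec3, asm, weights = w)
  expect_equal(fr3$Bx_pT, -fr$Bx_pT, tolerance = 1e-10)
  expect_equal(fr3$Bz_pT, -fr$Bz_pT, tolerance = 1e-10)
  expect_equal(fr3$By_pT, fr$By_pT, tolerance = 1e-10)
})

test_that("lateral sample displacement of 2 mm changes amplitude modestly", {
  geom <- build_geometry(nx = 8, ny = 8, pacemaker_units = 0)
  w0 <- link_weight_matrices(geom, sensor_assembly())
  w2 <- link_weight_matrices(geom, sensor_assembly(lateral_offset_mm = c(2, 0)))
  set.seed(4)
  Ix <- matrix(rnorm(7 * 8, sd = 1e-9), 1)
  Iy <- matrix(rnorm(8 * 7, sd = 1e-9), 1)
  rec <- structure(list(geometry = geom, time_i_ms = 0, Ix = Ix, Iy = Iy),
                   class = "cardiomag_tissue_recording")
  b0 <- forward_magnetometer(rec, sensor_assembly(), weights = w0)$By_pT
  b2 <- forward_magnetometer(rec, sensor_assembly(), weights = w2)$By_pT
  expect_lt(abs(b2 - b0) / abs(b0), 0.35)  # small fractional change
})

test_that("artificial signals carry the stated truth and scale linearly", {
  tpl <- toy_template()
  a1 <- generate_artificial_signal(tpl, intensity = 1, duration_s = 120,
                                   rate_hz = 1)
  expect_equal(length(attr(a1, "truth_ms")), 120)
  expect_equal(nrow(a1), 120000)
  a5 <- generate_artificial_signal(tpl, intensity = 5, duration_s = 120,
                                   rate_hz = 1)
  expect_equal(a5$Bx_pT, 5 * a1$Bx_pT, tolerance = 1e-12)
  # degenerate zero intensity still lists truth centers
  a0 <- generate_artificial_signal(tpl, intensity = 0, duration_s = 10,
                                   rate_hz = 1)
  expect_equal(length(attr(a0, "truth_ms")), 10)
  expect_true(all(a0$Bx_pT == 0))
  expect_error(generate_artificial_signal(tpl, duration_s = 0.2, rate_hz = 1))
})
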