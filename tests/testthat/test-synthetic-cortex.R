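test_that("angular gain is area preserving and hits the wedge targets", {
  # no asymmetry: identity profile
  expect_equal(angular_gain(seq(0, 359), 0, 0), rep(1, 360))
  # full-circle integral is 360 for any amplitudes (closed form)
  for (amps in list(c(80, 52), c(80, 0), c(40, -30))) {
    expect_equal(gain_cumulative(360, amps[1], amps[2]), 360,
                 tolerance = 1e-9)
    # quadrature oracle agrees with the closed-form cumulative
    got <- gain_window_integral(0, 360, amps[1], amps[2])
    expect_equal(got, 360, tolerance = 1e-5)
  }
  # +/-25 degree wedge integrals reproduce the requested indices
  # (the group-level magnitudes: HVA about 80, adult VMA 52)
  H <- gain_window_integral(-25, 25, 80, 52) +
    gain_window_integral(155, 205, 80, 52)
  V <- gain_window_integral(65, 115, 80, 52) +
    gain_window_integral(245, 295, 80, 52)
  expect_equal((H - V) / ((H + V) / 2) * 100, 80, tolerance = 1e-4)
  L <- gain_window_integral(245, 295, 80, 52)
  U <- gain_window_integral(65, 115, 80, 52)
  expect_equal((L - U) / ((L + U) / 2) * 100, 52, tolerance = 1e-4)
  # unreachable amplitudes are refused with the feasibility condition
  expect_error(angular_gain(0, 190, 0), "non-positive")
})

test_that("mesh area bookkeeping is exact and the mesh is connected", {
  h <- sym_left()
  m <- h$mesh
  tri <- cortmag:::triangle_areas(
    as.matrix(m$vertices[, c("x_mm", "y_mm", "z_mm")]), m$faces)
  expect_equal(sum(m$vertices$area_midgray), sum(tri),
               tolerance = 1e-9)
  expect_true(all(m$vertices$area_midgray > 0))
  expect_equal(igraph::components(cortmag:::mesh_graph(m))$no, 1)
  # depth scaling
  expect_equal(m$vertices$area_pial, 1.2 * m$vertices$area_midgray)
  expect_equal(m$vertices$area_white, 0.85 * m$vertices$area_midgray)
  expect_error(ground_truth_config(mesh_density = 400), "allowed range")
})

test_that("hemispheres are mirror images with equal V1 areas", {
  s <- sym_subject()
  a_l <- map_surface_area(s$left$mesh, v1_of(s$left))
  a_r <- map_surface_area(s$right$mesh, v1_of(s$right))
  expect_equal(a_l, a_r, tolerance = 0.005)
  # reflection: same vertex areas, opposite y
  expect_equal(s$left$mesh$vertices$area_midgray,
               s$right$mesh$vertices$area_midgray, tolerance = 1e-9)
  expect_equal(s$left$mesh$vertices$y_mm,
               -s$right$mesh$vertices$y_mm, tolerance = 1e-9)
})

test_that("mesh areal magnification follows the Horton-Hoyt law", {
  h <- sym_left()
  ret <- h$retinotopy
  v1 <- v1_of(h)
  # cumulative area profile: integral of M(E) over the hemifield disc
  k <- 17.3; e0 <- 0.75
  anti <- function(E) log(E + e0) + e0 / (E + e0)
  in_v1 <- ret$vertex %in% v1
  # snap window edges to midpoints between adjacent distinct vertex
  # eccentricities so the cut bisects surface cells (no quantization bias)
  ecc_vals <- sort(unique(round(ret$ecc[in_v1], 9)))
  snap <- function(E) {
    i <- max(which(ecc_vals <= E))
    mean(ecc_vals[c(i, min(i + 1, length(ecc_vals)))])
  }
  area_to <- function(E) sum(h$mesh$vertices$area_midgray[in_v1 &
                                                           ret$ecc <= E])
  for (E in 2:7) {
    lo <- snap(1); hi <- snap(E)
    got <- area_to(hi) - area_to(lo)
    want <- pi * k^2 * (anti(hi) - anti(lo))
    expect_equal(got, want, tolerance = 0.05)
  }
  # differential check on a wide central ring where many columns fall
  sel <- ret$vertex %in% v1 & ret$ecc >= 2 & ret$ecc <= 5
  ring_area <- pi * k^2 * (anti(5) - anti(2))
  expect_equal(sum(h$mesh$vertices$area_midgray[sel]), ring_area,
               tolerance = 0.05)
})

test_that("central 7 degrees is 38% of a full-field V1 map", {
  h <- build_hemisphere(ground_truth_config(ecc_range = c(0, 90),
                                            mesh_density = 6000), "left")
  v1 <- v1_of(h)
  frac <- map_surface_area(h$mesh, v1, retinotopy = h$retinotopy,
                           ecc_window = c(0, 7)) /
    map_surface_area(h$mesh, v1)
  expect_equal(frac, 0.38, tolerance = 0.05)
})

test_that("built wedge areas match the analytic gain integrals", {
  s <- asym_subject()
  # ground-truth angular masks, both hemispheres, 1-7 degrees
  area_in <- function(hemi, lo, hi) {
    ret <- hemi$retinotopy
    d <- cortmag:::angle_diff(ret$angle, (lo + hi) / 2)
    sel <- ret$visual_area == "V1" & abs(d) <= (hi - lo) / 2 &
      ret$ecc >= 1 & ret$ecc <= 7
    sum(hemi$mesh$vertices$area_midgray[sel])
  }
  band <- function(hemi) {
    ret <- hemi$retinotopy
    sel <- ret$visual_area == "V1" & ret$ecc >= 1 & ret$ecc <= 7
    sum(hemi$mesh$vertices$area_midgray[sel])
  }
  got_H <- area_in(s$left, -25, 25) + area_in(s$right, 155, 205)
  tot <- band(s$left) + band(s$right)
  want_H <- (gain_window_integral(-25, 25, 80, 52) +
               gain_window_integral(155, 205, 80, 52)) / 360 * tot
  expect_equal(got_H, want_H, tolerance = 0.02)
  # each hemisphere holds one half of each vertical wedge; summed they
  # cover the full +/-25 window. Compare the lower/upper ratio, where the
  # shared border-vertex area cancels.
  got_L <- area_in(s$left, 245, 295) + area_in(s$right, 245, 295)
  got_U <- area_in(s$left, 65, 115) + area_in(s$right, 65, 115)
  want_ratio <- gain_window_integral(245, 295, 80, 52) /
    gain_window_integral(65, 115, 80, 52)
  expect_equal(got_L / got_U, want_ratio, tolerance = 0.02)
  want_L <- gain_window_integral(245, 295, 80, 52) / 360 * tot
  expect_equal(got_L, want_L, tolerance = 0.06)
})

test_that("simulated BOLD is reproducible and respects the noise contract", {
  h <- build_hemisphere(ground_truth_config(mesh_density = 1000), "left")
  mov <- small_movie_tr()
  vs <- head(v1_of(h), 5)
  b1 <- simulate_bold(h$retinotopy, mov, noise_sd = 0.3, seed = 7,
                      vertices = vs)
  b2 <- simulate_bold(h$retinotopy, mov, noise_sd = 0.3, seed = 7,
                      vertices = vs)
  expect_identical(b1, b2)
  b3 <- simulate_bold(h$retinotopy, mov, noise_sd = 0.3, seed = 8,
                      vertices = vs)
  expect_false(identical(b1, b3))
  expect_error(simulate_bold(h$retinotopy, mov, noise_sd = -1), ">= 0")
  # zero noise equals the forward prediction
  b0 <- simulate_bold(h$retinotopy, mov, noise_sd = 0, seed = 1,
                      vertices = vs[1])
  ret1 <- h$retinotopy[h$retinotopy$vertex == vs[1], ]
  expect_equal(as.numeric(b0),
               predict_timeseries(as.list(ret1[, c("x", "y", "sigma")]),
                                  mov),
               tolerance = 1e-12)
})

test_that("motion traces put FD exceedances exactly at the spikes", {
  quiet <- simulate_motion(50, jitter_sd = 0)
  expect_true(all(framewise_displacement(quiet)$fd == 0))
  spiky <- simulate_motion(200, spike_frames = seq(20, 200, by = 20),
                           spike_mm = 0.6, jitter_sd = 0)
  fd <- framewise_displacement(spiky)
  expect_equal(count_exceedances(fd, 0.5), 10)
  expect_equal(fd$fd[fd$frame %in% seq(20, 200, by = 20)], rep(0.6, 10))
  # seeded jitter below threshold: exceedances still equal spike count
  jit <- simulate_motion(200, spike_frames = c(30, 90, 150),
                         spike_mm = 0.6, jitter_sd = 0.02, seed = 12)
  expect_equal(count_exceedances(framewise_displacement(jit), 0.5), 3)
  expect_error(simulate_motion(10, spike_frames = 11), "2..n_frames")
})

test_that("perturbed retinotopy matches the requested noise regime", {
  h <- sym_left()
  ret <- perturb_retinotopy(h$retinotopy, angle_sd = 10, seed = 3)
  err <- cortmag:::angle_diff(ret$angle, h$retinotopy$angle)
  expect_equal(sd(err), 10, tolerance = 0.05)
  # simulated variance explained is high, median near the observed 0.6
  expect_equal(median(ret$r2), 0.61, tolerance = 0.05)
  # x, y stay consistent with (ecc, angle)
  expect_equal(ret$x, ret$ecc * cos(ret$angle * pi / 180), tolerance = 1e-9)
})
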