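#' Ground-truth configuration for a synthetic hemisphere
#'
#' Parameters of the synthetic cortical hemisphere generator. Areal
#' magnification follows the Horton-Hoyt law
#' `M(E) = (hh_scale / (E + hh_e0))^2` (mm^2 per deg^2), multiplied by a
#' smooth angular gain profile that injects a chosen horizontal-vertical
#' (HVA) and vertical-meridian (VMA) surface-area asymmetry. pRF size grows
#' linearly with eccentricity.
#'
#' @param hh_scale Horton-Hoyt scale constant (mm).
#' @param hh_e0 Horton-Hoyt eccentricity offset (degrees, > 0).
#' @param ecc_range Eccentricity extent of the map (degrees).
#' @param hva_amp Target cortical HVA index (0-200 scale of the
#'   mean-normalized difference; see [hva_index()]).
#' @param vma_amp Target cortical VMA index (-200 to 200; see
#'   [vma_index()]).
#' @param sigma_slope,sigma_intercept Linear pRF size law
#'   `sigma = sigma_intercept + sigma_slope * eccentricity` (degrees).
#' @param mesh_density Approximate number of vertices per hemisphere
#'   (>= 500).
#' @param depth_scale Named vector of pial and white per-vertex area factors
#'   relative to midgray.
#' @param v2_scale,v3_scale Total V2 (and V3) surface area as a fraction of
#'   V1 area.
#' @param wedge_width Wedge half-width (degrees) at which the injected
#'   asymmetry indices are defined (the index-defining wedge).
#' @param lobe_width Half-width (degrees) of the raised-cosine meridian
#'   gain lobes.
#' @return An object of class `ground_truth_config`.
#' @export
ground_truth_config <- function(hh_scale = 17.3, hh_e0 = 0.75,
                                ecc_range = c(0, 8), hva_amp = 0,
                                vma_amp = 0, sigma_slope = 0.2,
                                sigma_intercept = 0.5, mesh_density = 10000,
                                depth_scale = c(pial = 1.2, white = 0.85),
                                v2_scale = 0.97, v3_scale = 0.79,
                                wedge_width = 25, lobe_width = 45) {
  check_positive(hh_scale, "hh_scale")
  check_positive(hh_e0, "hh_e0")
  if (length(ecc_range) != 2 || ecc_range[1] < 0 ||
      ecc_range[2] <= ecc_range[1]) {
    abort("`ecc_range` must be an increasing pair of non-negative degrees.")
  }
  check_number(hva_amp, "hva_amp", lower = -200 + 1e-9, upper = 200 - 1e-9)
  check_number(vma_amp, "vma_amp", lower = -200 + 1e-9, upper = 200 - 1e-9)
  check_number(sigma_slope, "sigma_slope", lower = 0)
  check_positive(sigma_intercept, "sigma_intercept")
  check_number(mesh_density, "mesh_density", lower = 500)
  # fail early if the requested asymmetries are not representable
  gain_amplitudes(hva_amp, vma_amp, wedge_width, lobe_width)
  structure(
    list(hh_scale = hh_scale, hh_e0 = hh_e0, ecc_range = ecc_range,
         hva_amp = hva_amp, vma_amp = vma_amp, sigma_slope = sigma_slope,
         sigma_intercept = sigma_intercept,
         mesh_density = as.integer(mesh_density),
         depth_scale = depth_scale, v2_scale = v2_scale,
         v3_scale = v3_scale, wedge_width = wedge_width,
         lobe_width = lobe_width),
    class = "ground_truth_config"
  )
}

# ---- angular gain profile --------------------------------------------------

# Closed-form raised-cosine lobe amplitudes (horizontal, upper, lower) that
# reproduce the requested HVA/VMA indices for +/- `wedge_width` wedges while
# keeping the full-circle gain integral at 360 (area preserving). The two
# horizontal lobes share one amplitude, and amplitudes satisfy
# 2 a_h + a_u + a_l = 0.
gain_amplitudes <- function(hva_amp, vma_amp, wedge_width = 25,
                            lobe_width = 45) {
  W <- wedge_width
  w <- lobe_width
  if (W > w) abort("`wedge_width` must not exceed `lobe_width`.")
  L <- W + (w / pi) * sin(pi * W / w) # lobe mass inside a +/- W wedge
  a_h <- hva_amp / (4 * L)
  denom <- 50 - a_h * L # mean(lower, upper) wedge gain integral
  if (denom <= 0) {
    abort("`hva_amp` too large: the vertical wedge integral would be <= 0.")
  }
  d <- vma_amp * denom / (100 * L)
  a_u <- (-2 * a_h - d) / 2
  a_l <- (-2 * a_h + d) / 2
  amps <- c(horizontal = a_h, upper = a_u, lower = a_l)
  if (any(amps <= -1)) {
    abort(paste0(
      "Requested (hva_amp, vma_amp) make the angular gain non-positive at ",
      "a meridian; reduce the amplitudes (each lobe amplitude must exceed ",
      "-1, got ", paste(sprintf("%.3f", amps), collapse = ", "), ")."))
  }
  amps
}

# raised-cosine lobe, half-width w, evaluated at wrapped angular offset
gain_lobe <- function(delta, w) {
  ifelse(abs(delta) <= w, (1 + cos(pi * delta / w)) / 2, 0)
}

#' Angular magnification gain profile
#'
#' Multiplicative angular gain applied to the Horton-Hoyt areal law:
#' raised-cosine lobes centered on the four polar-angle meridians, with
#' amplitudes solved in closed form so that (a) the gain integrates to 360
#' over the full circle (total map area is preserved) and (b) the
#' `+/- wedge_width` wedge integrals reproduce the requested HVA and VMA
#' indices exactly.
#'
#' @param theta Polar angle(s) in degrees; 0 = right horizontal, 90 = upper
#'   vertical, counterclockwise.
#' @param hva_amp,vma_amp Target asymmetry indices (see
#'   [ground_truth_config()]).
#' @param wedge_width,lobe_width Wedge half-width defining the indices and
#'   lobe half-width of the gain profile (degrees).
#' @return Numeric vector of unitless gains, mean 1 over the circle.
#' @export
#' @examples
#' angular_gain(c(0, 90, 180, 270), hva_amp = 80, vma_amp = 52)
angular_gain <- function(theta, hva_amp, vma_amp, wedge_width = 25,
                         lobe_width = 45) {
  a <- gain_amplitudes(hva_amp, vma_amp, wedge_width, lobe_width)
  theta <- wrap_angle(theta)
  1 +
    a[["horizontal"]] * gain_lobe(angle_diff(theta, 0), lobe_width) +
    a[["upper"]] * gain_lobe(angle_diff(theta, 90), lobe_width) +
    a[["horizontal"]] * gain_lobe(angle_diff(theta, 180), lobe_width) +
    a[["lower"]] * gain_lobe(angle_diff(theta, 270), lobe_width)
}

# antiderivative of the raised-cosine lobe (offset so F(-w) = 0)
lobe_antideriv <- function(delta, w) {
  delta <- pmin(pmax(delta, -w), w)
  (delta + w) / 2 + (w / (2 * pi)) * sin(pi * delta / w)
}

#' Cumulative angular gain
#'
#' `G(theta) = integral of the angular gain from 0 to theta` (degrees of
#' gain-weighted angle). `G(360) = 360` exactly.
#'
#' @inheritParams angular_gain
#' @return Cumulative gain in degrees.
#' @export
gain_cumulative <- function(theta, hva_amp, vma_amp, wedge_width = 25,
                            lobe_width = 45) {
  a <- gain_amplitudes(hva_amp, vma_amp, wedge_width, lobe_width)
  w <- lobe_width
  centers <- c(0, 90, 180, 270, 360)
  amps <- c(a[["horizontal"]], a[["upper"]], a[["horizontal"]],
            a[["lower"]], a[["horizontal"]])
  acc <- theta
  for (i in seq_along(centers)) {
    acc <- acc + amps[i] * (lobe_antideriv(theta - centers[i], w) -
                              lobe_antideriv(0 - centers[i], w))
  }
  acc
}

# ---- Horton-Hoyt radial map ------------------------------------------------

# cortical distance coordinate u(E) whose derivative is
# hh_scale * E / (E + e0)^2, so that du dv = M(E) * E dE dtheta with
# dv/dtheta_rad = hh_scale * gain(theta)
hh_u <- function(E, scale, e0) {
  scale * (log(E + e0) + e0 / (E + e0))
}

# numeric inverse of hh_u on [0, ~1.1 E_max]
hh_u_inverse <- function(scale, e0, E_max) {
  Es <- seq(0, 1.1 * E_max + 0.5, length.out = 4096)
  us <- hh_u(Es, scale, e0)
  function(u) approx(us, Es, xout = u, rule = 2)$y
}

# ---- hemisphere construction ----------------------------------------------

# visual polar angle of a field-elevation phi (degrees in [-90, 90]) for a
# hemisphere: the left hemisphere maps the right hemifield (centered on
# theta = 0), the right hemisphere the left hemifield (centered on 180)
elevation_to_angle <- function(phi, hemisphere) {
  if (hemisphere == "left") wrap_angle(phi) else wrap_angle(180 - phi)
}

# signed cumulative gain along the hemifield, from the horizontal meridian
hemifield_cumgain <- function(phi, hemisphere, cfg) {
  G <- function(th) gain_cumulative(th, cfg$hva_amp, cfg$vma_amp,
                                    cfg$wedge_width, cfg$lobe_width)
  if (hemisphere == "left") {
    ifelse(phi >= 0, G(wrap_angle(phi)), G(phi + 360) - 360)
  } else {
    G(180) - G(180 - phi)
  }
}

#' Build a synthetic cortical hemisphere with known retinotopy
#'
#' Constructs a triangulated flat hemisphere mesh whose local areal
#' magnification equals `gain(theta) * (hh_scale / (E + hh_e0))^2` by
#' mapping the visual field through a closed-form log-eccentricity map. V1
#' occupies a full hemifield; dorsal and ventral V2 and V3 quarterfields
#' adjoin it at the polar-angle reversals, mirror-mapped and scaled to the
#' configured area fractions. Per-vertex surface areas are one third of the
#' summed incident-triangle areas (midgray), scaled by the configured depth
#' factors for the pial and white surfaces.
#'
#' @param config A [ground_truth_config()].
#' @param hemisphere `"left"` (represents the right visual hemifield) or
#'   `"right"`.
#' @return An object of class `cortical_hemisphere`: list with `mesh` (a
#'   `cortical_mesh`: `vertices` tibble with mm coordinates and per-depth
#'   areas, integer `faces` matrix), `retinotopy` (tibble: `vertex`,
#'   `visual_area`, `ecc`, `angle`, `x`, `y`, `sigma`, `r2`), the row
#'   `layout`, and the `config`.
#' @export
build_hemisphere <- function(config, hemisphere = c("left", "right")) {
  if (!inherits(config, "ground_truth_config")) {
    abort("`config` must be created by `ground_truth_config()`.")
  }
  hemisphere <- match.arg(hemisphere)
  k <- config$hh_scale
  e0 <- config$hh_e0
  s2 <- config$v2_scale
  s3 <- config$v3_scale

  # grid size: rows across V1+V2+V3 ~ 3 * n1; rows are laid about twice as
  # densely as columns because wedge boundaries are resolved along the
  # angular (row) direction
  row_aspect <- 2
  u_lo <- hh_u(config$ecc_range[1], k, e0)
  u_hi <- hh_u(config$ecc_range[2], k, e0)
  v1_extent <- k * deg2rad(1) *
    (hemifield_cumgain(90, hemisphere, config) -
       hemifield_cumgain(-90, hemisphere, config))
  n1_raw <- sqrt(config$mesh_density / 3 * v1_extent / (u_hi - u_lo) *
                   row_aspect)
  n1 <- 2L * floor(n1_raw / 2) + 1L # odd so the horizontal row exists
  if (n1 < 15) abort("`mesh_density` too low to resolve the map.")
  n_c <- max(8L, round(config$mesh_density / (3 * n1)))
  n2 <- max(4L, (n1 - 1L) %/% 2L + 1L)
  n3 <- n2
  if (n_c < 8 || n1 < 15) abort("`mesh_density` too low to resolve the map.")

  v1_of <- function(phi) k * deg2rad(1) *
    hemifield_cumgain(phi, hemisphere, config)
  v_b <- v1_of(-90); v_t <- v1_of(90)
  h_d <- v1_of(0) - v_b # dorsal half extent
  h_v <- v_t - v1_of(0) # ventral half extent

  phi_v3d <- seq(-90, 0, length.out = n3)
  phi_v2d <- seq(0, -90, length.out = n2)
  phi_v1 <- seq(-90, 90, length.out = n1)
  phi_v2v <- seq(90, 0, length.out = n2)
  phi_v3v <- seq(0, 90, length.out = n3)

  rows <- dplyr::bind_rows(
    tibble(region = "V3", phi = phi_v3d[-n3],
           v = v_b - s2 * h_d - s3 * (h_d - (v1_of(phi_v3d[-n3]) - v_b))),
    tibble(region = "V2", phi = phi_v2d[-n2],
           v = v_b - s2 * (v1_of(phi_v2d[-n2]) - v_b)),
    tibble(region = "V1", phi = phi_v1, v = v1_of(phi_v1)),
    tibble(region = "V2", phi = phi_v2v[-1],
           v = v_t + s2 * (v_t - v1_of(phi_v2v[-1]))),
    tibble(region = "V3", phi = phi_v3v[-1],
           v = v_t + s2 * h_v + s3 * (v1_of(phi_v3v[-1]) - v1_of(0)))
  )
  rows <- rows[order(rows$v), ]
  rows$row <- seq_len(nrow(rows))

  us <- seq(u_lo, u_hi, length.out = n_c)
  inv_u <- hh_u_inverse(k, e0, config$ecc_range[2])
  eccs <- inv_u(us)

  n_r <- nrow(rows)
  vert <- tidyr::expand_grid(row = seq_len(n_r), col = seq_len(n_c))
  vert$vertex <- seq_len(nrow(vert))
  vert$region <- rows$region[vert$row]
  vert$phi <- rows$phi[vert$row]
  vert$v <- rows$v[vert$row]
  # stagger alternate rows by half a column so vertex eccentricities are
  # quasi-continuous, as on a native surface, rather than column-aligned;
  # the pattern is anchored at the horizontal-meridian row so the dorsal
  # and ventral halves stay exact mirrors
  du <- us[2] - us[1]
  row_h <- rows$row[rows$region == "V1" & abs(rows$phi) < 1e-9][1]
  vert$u <- us[vert$col] + ifelse((vert$row - row_h) %% 2 == 0, du / 2, 0)
  vert$ecc <- inv_u(vert$u)

  # mirror the right hemisphere so the pair is a true reflection
  y_mm <- if (hemisphere == "left") vert$v else -vert$v

  # faces: two triangles per grid quad; the diagonal orientation flips at
  # the horizontal-meridian row so the edge graph (hence edge-graph
  # geodesics) is mirror-symmetric between the dorsal and ventral halves
  quad_r <- rep(seq_len(n_r - 1L), each = n_c - 1L)
  quad_c <- rep(seq_len(n_c - 1L), times = n_r - 1L)
  idx <- function(r, c) (r - 1L) * n_c + c
  lower_half <- quad_r < row_h
  anti <- cbind(idx(quad_r, quad_c), idx(quad_r, quad_c + 1L),
                idx(quad_r + 1L, quad_c),
                idx(quad_r, quad_c + 1L), idx(quad_r + 1L, quad_c + 1L),
                idx(quad_r + 1L, quad_c))
  main <- cbind(idx(quad_r, quad_c), idx(quad_r, quad_c + 1L),
                idx(quad_r + 1L, quad_c + 1L),
                idx(quad_r, quad_c), idx(quad_r + 1L, quad_c + 1L),
                idx(quad_r + 1L, quad_c))
  tris <- ifelse(matrix(lower_half, nrow = length(quad_r), ncol = 6),
                 anti, main)
  faces <- rbind(tris[, 1:3, drop = FALSE], tris[, 4:6, drop = FALSE])

  coords <- cbind(vert$u, y_mm, 0)
  tri_area <- triangle_areas(coords, faces)
  va <- vertex_areas(tri_area, faces, nrow(vert))

  vertices <- tibble(
    vertex = vert$vertex,
    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
    area_midgray = va,
    area_pial = va * config$depth_scale[["pial"]],
    area_white = va * config$depth_scale[["white"]]
  )
  mesh <- structure(list(vertices = vertices, faces = faces,
                         hemisphere = hemisphere),
                    class = "cortical_mesh")

  angle <- elevation_to_angle(vert$phi, hemisphere)
  retinotopy <- tibble(
    vertex = vert$vertex,
    visual_area = vert$region,
    ecc = vert$ecc,
    angle = angle,
    x = vert$ecc * cos(deg2rad(angle)),
    y = vert$ecc * sin(deg2rad(angle)),
    sigma = config$sigma_intercept + config$sigma_slope * vert$ecc,
    r2 = 1
  )

  structure(
    list(mesh = mesh, retinotopy = retinotopy,
         layout = list(rows = rows, n_rows = n_r, n_cols = n_c,
                       u = us, ecc = eccs, grid = vert[, c("vertex", "row",
                                                          "col", "phi")]),
         hemisphere = hemisphere, config = config),
    class = "cortical_hemisphere"
  )
}

#' @export
print.cortical_hemisphere <- function(x, ...) {
  cat(sprintf(
    "<cortical_hemisphere> %s, %d vertices (%d x %d grid), ecc %g-%g deg\n",
    x$hemisphere, nrow(x$mesh$vertices), x$layout$n_rows, x$layout$n_cols,
    x$config$ecc_range[1], x$config$ecc_range[2]))
  invisible(x)
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %s hemisphere, %d vertices, %d faces, %.0f mm^2\n",
              x$hemisphere, nrow(x$vertices), nrow(x$faces),
              sum(x$vertices$area_midgray)))
  invisible(x)
}

# unsigned triangle areas from a coordinate matrix and face index matrix
triangle_areas <- function(coords, faces) {
  a <- coords[faces[, 1], , drop = FALSE]
  b <- coords[faces[, 2], , drop = FALSE]
  c_ <- coords[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# barycentric share: each vertex receives one third of incident triangles
vertex_areas <- function(tri_area, faces, n_vertices) {
  acc <- numeric(n_vertices)
  for (j in 1:3) {
    t <- tapply(tri_area, faces[, j], sum)
    acc[as.integer(names(t))] <- acc[as.integer(names(t))] + t
  }
  acc / 3
}

#' Build a two-hemisphere synthetic subject
#'
#' @param config A [ground_truth_config()].
#' @return Named list with `left` and `right` [build_hemisphere()] results.
#' @export
build_subject <- function(config) {
  list(left = build_hemisphere(config, "left"),
       right = build_hemisphere(config, "right"))
}

#' Ground-truth meridian and area boundaries of a synthetic hemisphere
#'
#' @param hemi A [build_hemisphere()] result.
#' @return Tibble with `vertex` and `boundary` in
#'   `"v1_v2_dorsal"` (lower vertical meridian), `"v1_v2_ventral"` (upper
#'   vertical meridian), `"v1_horizontal"`, and `"v2_v3_dorsal"`,
#'   `"v2_v3_ventral"`.
#' @export
ground_truth_boundaries <- function(hemi) {
  g <- hemi$layout$grid
  rows <- hemi$layout$rows
  lab <- function(rowsel, name) {
    tibble(vertex = g$vertex[g$row %in% rowsel], boundary = name)
  }
  v1 <- rows$row[rows$region == "V1"]
  dplyr::bind_rows(
    lab(min(v1), "v1_v2_dorsal"),
    lab(max(v1), "v1_v2_ventral"),
    lab(rows$row[rows$region == "V1" & abs(rows$phi) < 1e-9],
        "v1_horizontal"),
    lab(rows$row[rows$region == "V2" & abs(rows$phi) < 1e-9 &
                   rows$row < min(v1)], "v2_v3_dorsal"),
    lab(rows$row[rows$region == "V2" & abs(rows$phi) < 1e-9 &
                   rows$row > max(v1)], "v2_v3_ventral")
  )
}

# ---- measurement noise and BOLD simulation ---------------------------------

#' Add measurement noise to a ground-truth retinotopy
#'
#' Perturbs polar angle and eccentricity with Gaussian noise and replaces
#' the ground-truth variance explained with Beta-distributed values,
#' emulating fitted-map noise without simulating time series.
#'
#' @param retinotopy Retinotopy tibble from [build_hemisphere()].
#' @param angle_sd Angular noise SD (degrees).
#' @param ecc_sd Eccentricity noise SD (degrees); eccentricities stay
#'   non-negative.
#' @param r2_shape Two Beta shape parameters for simulated variance
#'   explained (default centered near 0.6, the typical fitted-map median).
#' @param seed Integer seed.
#' @return Retinotopy tibble with perturbed `angle`, `ecc`, `x`, `y`, `r2`.
#' @export
perturb_retinotopy <- function(retinotopy, angle_sd = 0, ecc_sd = 0,
                               r2_shape = c(6, 4), seed = 1L) {
  withr::with_seed(seed, {
    n <- nrow(retinotopy)
    out <- retinotopy
    out$angle <- wrap_angle(out$angle + rnorm(n, 0, angle_sd))
    out$ecc <- pmax(0, out$ecc + rnorm(n, 0, ecc_sd))
    out$x <- out$ecc * cos(deg2rad(out$angle))
    out$y <- out$ecc * sin(deg2rad(out$angle))
    out$r2 <- stats::rbeta(n, r2_shape[1], r2_shape[2])
    out
  })
}

#' Noise level matching a target variance explained
#'
#' Gaussian noise with this SD added to `signal` yields an expected fitted
#' variance explained of about `target_r2`.
#'
#' @param signal Noise-free predicted series.
#' @param target_r2 Desired variance explained in (0, 1).
#' @return Noise standard deviation (percent signal units).
#' @export
calibrate_noise_sd <- function(signal, target_r2 = 0.6) {
  check_number(target_r2, "target_r2", lower = 1e-6, upper = 1 - 1e-6)
  sd(signal) * sqrt((1 - target_r2) / target_r2)
}

#' Simulate per-vertex BOLD series from ground-truth pRFs
#'
#' Runs the pRF forward model ([predict_timeseries()]) for every requested
#' vertex and adds seeded Gaussian noise.
#'
#' @param retinotopy Retinotopy tibble (needs `x`, `y`, `sigma`).
#' @param movie An `aperture_movie`.
#' @param hrf [hrf_parameters()] used as generator.
#' @param noise_sd Gaussian noise SD in the units of the prediction
#'   (>= 0).
#' @param seed Integer seed; fixed seeds give bit-identical output.
#' @param vertices Optional vertex ids to simulate (default all).
#' @return Numeric matrix (TR x vertex), column names the vertex ids, with
#'   attribute `noise_sd`.
#' @export
simulate_bold <- function(retinotopy, movie, hrf = hrf_parameters(),
                          noise_sd = 0, seed = 1L, vertices = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (movie$frame_rate * movie$tr > 1 + 1e-9) movie <- downsample_to_tr(movie)
  if (!is.null(vertices)) {
    retinotopy <- retinotopy[retinotopy$vertex %in% vertices, ]
  }
  mm <- movie_matrix(movie)
  kernel <- two_gamma_hrf(hrf, dt = movie$tr)
  n_tr <- ncol(mm)
  gmat <- vapply(seq_len(nrow(retinotopy)),
                 function(i) prf_gaussian(movie, retinotopy$x[i],
                                          retinotopy$y[i],
                                          retinotopy$sigma[i]),
                 numeric(nrow(mm)))
  neural <- crossprod(mm, gmat)
  pred <- convolve_hrf(neural, kernel)
  out <- withr::with_seed(seed, {
    pred + matrix(rnorm(length(pred), 0, noise_sd), nrow = n_tr)
  })
  colnames(out) <- as.character(retinotopy$vertex)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Simulate a six-parameter rigid motion trace
#'
#' Baseline jitter is a Gaussian random walk in all six rigid-body
#' parameters; spikes are persistent level shifts of the x translation, so
#' framewise displacement exceeds its threshold exactly once per spike.
#'
#' @param n_frames Number of volumes.
#' @param spike_frames Frame indices (2..n_frames) at which spikes occur.
#' @param spike_mm Net framewise displacement of each spike (mm).
#' @param jitter_sd Per-frame random-walk step SD (mm for translations,
#'   degrees for rotations).
#' @param seed Integer seed.
#' @return Tibble with `frame`, translations `trans_x`, `trans_y`,
#'   `trans_z` (mm) and rotations `rot_x`, `rot_y`, `rot_z` (degrees).
#' @export
simulate_motion <- function(n_frames, spike_frames = integer(),
                            spike_mm = 0.6, jitter_sd = 0, seed = 1L) {
  if (length(spike_frames) > 0 &&
      (any(spike_frames < 2) || any(spike_frames > n_frames))) {
    abort("`spike_frames` must lie in 2..n_frames.")
  }
  withr::with_seed(seed, {
    walk <- function() cumsum(rnorm(n_frames, 0, jitter_sd))
    tr <- tibble(
      frame = seq_len(n_frames),
      trans_x = walk(), trans_y = walk(), trans_z = walk(),
      rot_x = walk(), rot_y = walk(), rot_z = walk()
    )
    for (f in spike_frames) {
      tr$trans_x[f:n_frames] <- tr$trans_x[f:n_frames] + spike_mm
    }
    tr
  })
}
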