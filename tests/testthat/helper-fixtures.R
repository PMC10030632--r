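# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- build()
  }
  .fixture_cache[[name]]
}

# coarse default-geometry movie (all 8 sweeps, 31 px grid)
small_movie <- function() {
  fixture("small_movie", function() {
    make_bar_aperture(aperture_config(grid_resolution = 31))
  })
}

small_movie_tr <- function() {
  fixture("small_movie_tr", function() downsample_to_tr(small_movie()))
}

# finer movie for fitting-accuracy checks
fit_movie_tr <- function() {
  fixture("fit_movie_tr", function() {
    downsample_to_tr(make_bar_aperture(aperture_config(grid_resolution = 51)))
  })
}

# symmetric hemisphere (no injected asymmetry)
sym_left <- function() {
  fixture("sym_left", function() {
    build_hemisphere(ground_truth_config(), "left")
  })
}

sym_subject <- function() {
  fixture("sym_subject", function() build_subject(ground_truth_config()))
}

# adult-like asymmetric subject (HVA 80, VMA 52)
asym_subject <- function() {
  fixture("asym_subject", function() {
    build_subject(ground_truth_config(hva_amp = 80, vma_amp = 52))
  })
}

v1_of <- function(hemi) {
  hemi$retinotopy$vertex[hemi$retinotopy$visual_area == "V1"]
}

# regular flat grid mesh (n x n, unit spacing) for geometry oracles
flat_grid_mesh <- function(n = 25) {
  xy <- expand.grid(col = seq_len(n), row = seq_len(n))
  coords <- cbind(xy$col - 1, xy$row - 1, 0)
  qr <- rep(seq_len(n - 1), each = n - 1)
  qc <- rep(seq_len(n - 1), times = n - 1)
  idx <- function(r, c) (r - 1L) * n + c
  faces <- rbind(cbind(idx(qr, qc), idx(qr, qc + 1L), idx(qr + 1L, qc)),
                 cbind(idx(qr, qc + 1L), idx(qr + 1L, qc + 1L),
                       idx(qr + 1L, qc)))
  vertices <- tibble::tibble(
    vertex = seq_len(n * n),
    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = 0,
    area_midgray = 1, area_pial = 1.2, area_white = 0.85)
  structure(list(vertices = vertices, faces = faces, hemisphere = "left"),
            class = "cortical_mesh")
}

# independent trapezoid quadrature of the angular gain over [a, b] degrees,
# handling windows that wrap below 0
gain_window_integral <- function(a, b, hva, vma, n = 20001) {
  quad <- function(lo, hi) {
    th <- seq(lo, hi, length.out = n)
    g <- angular_gain(th %% 360, hva, vma)
    sum((g[-1] + g[-n]) * diff(th) / 2)
  }
  if (a < 0) quad(a + 360, 360) + quad(0, b) else quad(a, b)
}
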