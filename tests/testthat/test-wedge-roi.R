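test_that("log-spaced bands have the closed-form geometric edges", {
  e <- log_bands(1, 7, 7)
  expect_equal(e[1], 1)
  expect_equal(e[8], 7)
  expect_equal(e[2], 7^(1 / 7))
  expect_equal(round(e[2], 4), 1.3205)
  ratios <- e[-1] / e[-8]
  expect_true(all(abs(ratios - ratios[1]) < 1e-12))
  expect_error(log_bands(0, 7), "0 < lo < hi")
})

test_that("edge-graph geodesics match flat-grid geometry", {
  mesh <- flat_grid_mesh(25)
  # straight line source: the bottom row
  line <- which(mesh$vertices$y_mm == 0)
  d <- geodesic_distance(mesh, line)
  expect_true(all(d[line] == 0))
  # within the documented edge-graph metric error of the true
  # perpendicular distance
  expect_true(all(d <= mesh$vertices$y_mm * 1.08 + 1e-9))
  expect_true(all(d >= mesh$vertices$y_mm - 1e-9))
  # Lipschitz along edges
  ed <- cortmag:::mesh_edges(mesh)
  gap <- abs(d[ed$edges[, 1]] - d[ed$edges[, 2]])
  expect_true(all(gap <= ed$lengths + 1e-9))
  expect_error(geodesic_distance(mesh, integer()), "nonempty")
})

test_that("iso-angle distances average the qualifying vertices", {
  expect_equal(iso_angle_distance(rep(5, 4), c(44, 46, 40, 50), rep(1, 4),
                                  45), 5)
  expect_equal(iso_angle_distance(c(2, 4), c(44, 46), c(1, 1), 45), 3)
  # r2 threshold and angular window both filter
  expect_equal(iso_angle_distance(c(2, 4), c(44, 46), c(0.05, 1), 45), 4)
  expect_true(is.na(iso_angle_distance(c(2, 4), c(10, 20), c(1, 1), 45)))
})

test_that("angle cleaning is a fixed point away from reversals", {
  h <- sym_left()
  cleaned <- clean_angles(h$retinotopy, h$mesh)
  chg <- abs(cortmag:::angle_diff(cleaned$angle_clean,
                                  h$retinotopy$angle))
  # interior: away from reversal rows and from the open mesh edge, where
  # neighborhoods are truncated
  rows <- h$layout$rows
  border_rows <- c(rows$row[abs(abs(rows$phi) - 90) < 1e-9],
                   rows$row[abs(rows$phi) < 1e-9 & rows$region != "V1"])
  near_border <- h$layout$grid$row %in%
    unique(as.vector(outer(border_rows, -2:2, `+`)))
  adj <- cortmag:::mesh_neighbors(h$mesh)
  bv <- cortmag:::mesh_boundary_vertices(h$mesh)
  near_edge <- logical(nrow(cleaned))
  near_edge[unique(c(bv, unlist(adj[bv])))] <- TRUE
  expect_lt(max(chg[!near_border & !near_edge]), 0.5)
})

test_that("angle cleaning denoises without crossing reversals", {
  h <- sym_left()
  noisy <- perturb_retinotopy(h$retinotopy, angle_sd = 10, seed = 5)
  cleaned <- clean_angles(noisy, h$mesh)
  err <- cortmag:::angle_diff(cleaned$angle_clean, h$retinotopy$angle)
  expect_lt(sqrt(mean(err^2)), 3)
  # boundary preservation: cleaning never pushes additional V1 angles
  # across a vertical meridian; on noisy input the count of
  # out-of-hemifield V1 angles can only shrink
  gt <- ground_truth_boundaries(h)
  border <- gt$vertex[gt$boundary %in% c("v1_v2_dorsal", "v1_v2_ventral")]
  v1_in <- setdiff(v1_of(h), border)
  crossings <- function(angles) {
    e <- cortmag:::angle_diff(angles, 0)[v1_in]
    sum(e < -90 - 1e-9 | e > 90 + 1e-9)
  }
  expect_lte(crossings(cleaned$angle_clean), crossings(noisy$angle))
  # and on a noiseless map no angle crosses at all
  clean0 <- clean_angles(h$retinotopy, h$mesh)
  expect_equal(crossings(clean0$angle_clean), 0)
  # the dorsal V1/V2 border row remains extremal relative to the map
  # interior: its mean cleaned elevation stays below every interior row
  dorsal <- gt$vertex[gt$boundary == "v1_v2_dorsal"]
  elev_c <- cortmag:::angle_diff(cleaned$angle_clean, 0)
  row_of <- h$layout$grid$row[match(seq_len(nrow(cleaned)),
                                    h$layout$grid$vertex)]
  v1_rows <- sort(unique(row_of[v1_of(h)]))
  row_means <- vapply(v1_rows, function(r) {
    mean(elev_c[v1_of(h)[row_of[v1_of(h)] == r]])
  }, numeric(1))
  dorsal_row <- unique(row_of[dorsal])
  expect_equal(which.min(row_means), match(dorsal_row, v1_rows))
})

test_that("wedges nest monotonically and order across depths", {
  s <- asym_subject()
  hemi <- s$left
  roi <- v1_of(hemi)
  cfg <- wedge_config()
  line <- trace_meridian_line(hemi$retinotopy, roi, "right_horizontal")
  dists <- geodesic_distance(hemi$mesh, line$vertex)
  prev <- NULL
  for (w in cfg$widths) {
    wr <- wedge_roi(hemi, "right_horizontal", w, cfg, roi = roi,
                    line = line, distances = dists)
    if (!is.null(prev)) {
      expect_true(all(prev %in% wr$vertex_ids))
    }
    prev <- wr$vertex_ids
  }
  w25 <- wedge_roi(hemi, "right_horizontal", 25, cfg, roi = roi,
                   line = line, distances = dists)
  a_mid <- wedge_area(w25, hemi$mesh, "midgray")
  expect_gte(wedge_area(w25, hemi$mesh, "pial"), a_mid)
  expect_gte(a_mid, wedge_area(w25, hemi$mesh, "white"))
})

test_that("the four 45-degree wedges tile the 1-7 degree V1 band", {
  s <- sym_subject()
  cfg <- wedge_config()
  for (hemi in s) {
    roi <- v1_of(hemi)
    mers <- cortmag:::hemisphere_meridians(hemi$mesh$hemisphere)
    wedges <- lapply(mers, function(m) {
      wedge_roi(hemi, m, 45, cfg, roi = roi)$vertex_ids
    })
    ret <- hemi$retinotopy
    band <- ret$vertex[ret$vertex %in% roi & ret$ecc >= 1 & ret$ecc <= 7]
    area_of <- function(v) {
      if (length(v) == 0) return(0)
      map_surface_area(hemi$mesh, v)
    }
    union_area <- area_of(unique(unlist(wedges)))
    band_area <- area_of(band)
    expect_equal(union_area, band_area, tolerance = 0.05)
    # pairwise overlaps below 2% of the band
    for (i in 1:2) {
      for (j in (i + 1):3) {
        ov <- intersect(wedges[[i]], wedges[[j]])
        expect_lt(area_of(ov) / band_area, 0.02)
      }
    }
  }
})

test_that("vertical wedges are symmetric on a symmetric subject", {
  s <- sym_subject()
  areas <- meridian_surface_areas(s, widths = 25)
  up <- areas$area[areas$meridian == "upper_vertical"]
  lo <- areas$area[areas$meridian == "lower_vertical"]
  expect_equal(up, lo, tolerance = 0.02)
})

test_that("centers-only areas respect thresholds and symmetry", {
  s <- sym_subject()
  hemi <- s$left
  ret <- hemi$retinotopy
  roi <- v1_of(hemi)
  # a full-hemifield range recovers the above-threshold band area
  full <- centers_only_area(ret, hemi$mesh, "right_horizontal", 90)
  band <- ret$vertex[ret$vertex %in% roi & ret$ecc >= 1 & ret$ecc <= 7 &
                       ret$r2 >= 0.10]
  expect_equal(full, map_surface_area(hemi$mesh, band), tolerance = 1e-9)
  # horizontal +/-15 matches the two 15-degree vertical half-ranges; the
  # vertical ranges include the V1/V2 border rows, whose vertex areas
  # carry a share of adjacent V2 triangles, so equality is approximate
  horiz <- centers_only_area(ret, hemi$mesh, "right_horizontal", 15)
  vert <- centers_only_area(ret, hemi$mesh, "upper_vertical", 15) +
    centers_only_area(ret, hemi$mesh, "lower_vertical", 15)
  expect_equal(horiz, vert, tolerance = 0.06)
})

test_that("wedge and centers-only methods agree on the HVA index", {
  s <- asym_subject()
  aw <- asymmetry_indices(meridian_surface_areas(s, widths = 25), 25)
  ac <- asymmetry_indices(meridian_surface_areas(s, widths = 25,
                                                 method = "centers"), 25)
  expect_lt(abs(aw$hva - ac$hva), 15)
  expect_lt(abs(aw$vma - ac$vma), 15)
})

test_that("injected asymmetries are recovered by the wedge analysis", {
  for (amps in list(c(80, 52), c(80, 0), c(0, 0))) {
    subj <- if (amps[1] == 80 && amps[2] == 52) {
      asym_subject()
    } else if (amps[1] == 0) {
      sym_subject()
    } else {
      build_subject(ground_truth_config(hva_amp = 80, vma_amp = 0))
    }
    idx <- asymmetry_indices(meridian_surface_areas(subj, widths = 25), 25)
    expect_lt(abs(idx$hva - amps[1]), 8)
    expect_lt(abs(idx$vma - amps[2]), 8)
  }
})
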