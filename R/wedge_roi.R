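#' Wedge-ROI configuration
#'
#' @param widths Wedge half-widths in degrees of polar angle.
#' @param ecc_window Eccentricity window (degrees); the central 1 degree is
#'   excluded because foveal polar-angle estimates are noisy.
#' @param n_bands Number of log-spaced eccentricity bands.
#' @param angle_tolerance Half-width (degrees) of the polar-angle window
#'   around an iso-angle line used to estimate its cortical distance.
#' @param r2_min Variance-explained threshold for boundary estimation
#'   (areas themselves are summed over all vertices).
#' @return An object of class `wedge_config`.
#' @export
wedge_config <- function(widths = c(15, 25, 35, 45, 55),
                         ecc_window = c(1, 7), n_bands = 7,
                         angle_tolerance = 8, r2_min = 0.10) {
  if (is.unsorted(widths)) abort("`widths` must be ascending.")
  if (n_bands < 1) abort("`n_bands` must be >= 1.")
  structure(list(widths = widths, ecc_window = ecc_window,
                 n_bands = as.integer(n_bands),
                 angle_tolerance = angle_tolerance, r2_min = r2_min),
            class = "wedge_config")
}

# polar angle of each meridian in visual-field coordinates
meridian_angle <- function(meridian) {
  switch(meridian,
         right_horizontal = 0, upper_vertical = 90,
         left_horizontal = 180, lower_vertical = 270,
         abort("Unknown meridian."))
}

# meridians represented in a hemisphere's (contralateral) hemifield
hemisphere_meridians <- function(hemisphere) {
  if (hemisphere == "left") {
    c("right_horizontal", "upper_vertical", "lower_vertical")
  } else {
    c("left_horizontal", "upper_vertical", "lower_vertical")
  }
}

#' Log-spaced eccentricity band edges
#'
#' `n + 1` edges `lo * (hi/lo)^(k/n)`, geometrically spaced so bands are
#' roughly equally wide on the cortex.
#'
#' @param lo,hi Eccentricity limits (degrees, `0 < lo < hi`).
#' @param n Number of bands.
#' @return Numeric vector of `n + 1` edges.
#' @export
#' @examples
#' log_bands(1, 7, 7)
log_bands <- function(lo = 1, hi = 7, n = 7) {
  if (lo <= 0 || hi <= lo) abort("Need 0 < lo < hi.")
  lo * (hi / lo)^(seq(0, n) / n)
}

#' Multi-source geodesic distance on the mesh edge graph
#'
#' Shortest-path distance from a set of source vertices (a meridian
#' line-ROI) to every vertex, using Euclidean edge weights — the edge-graph
#' approximation to the polyhedral geodesic.
#'
#' @param mesh A `cortical_mesh`.
#' @param line Source vertex ids (nonempty).
#' @return Numeric vector of distances (mm), 0 at the sources, `Inf` for
#'   vertices disconnected from all sources.
#' @export
geodesic_distance <- function(mesh, line) {
  if (length(line) == 0) abort("`line` must be nonempty.")
  g <- mesh_graph(mesh)
  n <- nrow(mesh$vertices)
  g <- igraph::add_vertices(g, 1)
  virtual <- n + 1L
  g <- igraph::add_edges(g, as.vector(rbind(virtual, line)),
                         weight = rep(0, length(line)))
  d <- igraph::distances(g, v = virtual, weights = igraph::E(g)$weight)
  as.numeric(d)[seq_len(n)]
}

#' Smooth a polar-angle map by r2-weighted circular averaging
#'
#' An iterative, anchored neighborhood smoother standing in for
#' template-based map cleaning: each vertex's angle is repeatedly replaced
#' by the circular mean of its own raw angle (weight `r2`) and its current
#' neighbors' angles (weights `lambda * r2`), until the largest update falls
#' below `tol`. The anchor to the raw data keeps smooth maps (linear angle
#' fields) fixed in the map interior, and because the circular mean of
#' angles on one side of a meridian stays on that side, cleaning never moves
#' an angle across a reversal boundary.
#'
#' @param retinotopy Retinotopy tibble with `vertex`, `angle`, `r2`.
#' @param mesh The `cortical_mesh`.
#' @param lambda Neighbor weight multiplier (smoothing strength).
#' @param tol Convergence tolerance (degrees, maximum per-iteration
#'   change).
#' @param max_iter Iteration cap.
#' @return The retinotopy tibble with an added `angle_clean` column.
#' @export
clean_angles <- function(retinotopy, mesh, lambda = 1, tol = 0.1,
                         max_iter = 100) {
  n <- nrow(mesh$vertices)
  ord <- match(mesh$vertices$vertex, retinotopy$vertex)
  if (any(is.na(ord))) abort("Retinotopy must cover all mesh vertices.")
  raw <- deg2rad(retinotopy$angle[ord])
  r2 <- pmax(retinotopy$r2[ord], 1e-6)
  ed <- mesh_edges(mesh)$edges
  # sparse neighbor-weight matrix W[i, j] = lambda * r2[j]
  W <- Matrix::sparseMatrix(
    i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
    x = lambda * r2[c(ed[, 2], ed[, 1])], dims = c(n, n))
  cur <- raw
  anchor_c <- r2 * cos(raw)
  anchor_s <- r2 * sin(raw)
  for (it in seq_len(max_iter)) {
    zc <- anchor_c + as.numeric(W %*% cos(cur))
    zs <- anchor_s + as.numeric(W %*% sin(cur))
    nxt <- atan2(zs, zc)
    delta <- abs(angle_diff(nxt * 180 / pi, cur * 180 / pi))
    cur <- nxt
    if (max(delta) < tol) break
  }
  out <- retinotopy
  out$angle_clean <- wrap_angle(cur * 180 / pi)[match(retinotopy$vertex,
                                                     mesh$vertices$vertex)]
  out
}

#' Trace a meridian line-ROI on the map
#'
#' Automated replacement for hand-drawn line-ROIs: within the ROI the map
#' is split into fine eccentricity bins and, in each bin, the vertex whose
#' (cleaned) polar angle is closest to the meridian is taken as a line
#' vertex.
#'
#' @param retinotopy Retinotopy tibble (`angle_clean` used when present).
#' @param roi Vertex ids of the map (V1).
#' @param meridian One of `"right_horizontal"`, `"left_horizontal"`,
#'   `"upper_vertical"`, `"lower_vertical"`.
#' @param ecc_window Eccentricity range to trace over (degrees).
#' @param n_bins Number of (log-spaced) eccentricity bins; log spacing
#'   matches the roughly uniform cortical sampling of eccentricity.
#' @param r2_min Variance-explained threshold for candidate vertices.
#' @return Tibble with `vertex`, `ecc`, `angle` of the line vertices.
#' @export
trace_meridian_line <- function(retinotopy, roi, meridian,
                                ecc_window = c(1, 7), n_bins = 16,
                                r2_min = 0.10) {
  ang_col <- if ("angle_clean" %in% names(retinotopy)) "angle_clean" else "angle"
  target <- meridian_angle(meridian)
  rr <- retinotopy[retinotopy$vertex %in% roi &
                     retinotopy$ecc >= ecc_window[1] &
                     retinotopy$ecc <= ecc_window[2] &
                     retinotopy$r2 >= r2_min, ]
  if (nrow(rr) == 0) abort("No ROI vertices available to trace the line.")
  edges <- log_bands(ecc_window[1], ecc_window[2], n_bins)
  bin <- cut(rr$ecc, edges, include.lowest = TRUE, labels = FALSE)
  dev <- abs(angle_diff(rr[[ang_col]], target))
  picks <- vapply(split(seq_len(nrow(rr)), bin), function(ix) {
    ix[which.min(dev[ix])]
  }, integer(1))
  tibble(vertex = rr$vertex[picks], ecc = rr$ecc[picks],
         angle = rr[[ang_col]][picks])
}

#' Mean cortical distance of an iso-angle line
#'
#' The cortical distance of the iso-angle line bounding a wedge is
#' estimated as the mean geodesic distance of the vertices whose (cleaned)
#' polar angle lies within `tolerance` of the target angle and whose
#' variance explained passes `r2_min`.
#'
#' @param distances Geodesic distances (mm) of the candidate vertices.
#' @param angles Cleaned polar angles (degrees) of the same vertices.
#' @param r2 Variance explained of the same vertices.
#' @param target_angle Iso-angle line polar angle (degrees).
#' @param tolerance Angular half-window (degrees).
#' @param r2_min Threshold on `r2`.
#' @return Mean distance (mm), or `NA` if no vertex qualifies.
#' @export
iso_angle_distance <- function(distances, angles, r2, target_angle,
                               tolerance = 8, r2_min = 0.10) {
  sel <- abs(angle_diff(angles, target_angle)) <= tolerance & r2 >= r2_min
  if (!any(sel)) return(NA_real_)
  mean(distances[sel])
}

#' Assemble a meridian-centered wedge-ROI
#'
#' Builds one wedge-ROI on one hemisphere: traces the meridian line,
#' computes the geodesic distance map, divides the eccentricity window into
#' log-spaced bands, estimates the iso-angle boundary distance per band and
#' side, and takes the union over bands of the vertices closer to the
#' meridian than the band's boundary distance. Bands with no qualifying
#' boundary vertices get their distance interpolated from neighboring bands
#' (linear in log eccentricity).
#'
#' @param hemi A [build_hemisphere()] result, or a list with `mesh` and
#'   `retinotopy`.
#' @param meridian Meridian name (see [trace_meridian_line()]).
#' @param half_width Wedge half-width (degrees of polar angle).
#' @param cfg A [wedge_config()].
#' @param roi Vertex ids of the map carrying the wedge (default: the
#'   ground-truth V1 label if `visual_area` is present).
#' @param line Optional pre-traced meridian line (tibble with `vertex`).
#' @param distances Optional precomputed geodesic distances.
#' @return Object of class `wedge_roi`: list with `vertex_ids`, `meridian`,
#'   `half_width`, and `iso` (per band and side: target angle, boundary
#'   distance, interpolation flag).
#' @export
wedge_roi <- function(hemi, meridian, half_width, cfg = wedge_config(),
                      roi = NULL, line = NULL, distances = NULL) {
  mesh <- hemi$mesh
  ret <- hemi$retinotopy
  ang_col <- if ("angle_clean" %in% names(ret)) "angle_clean" else "angle"
  if (is.null(roi)) {
    if (!"visual_area" %in% names(ret)) {
      abort("Provide `roi` or a retinotopy with a `visual_area` column.")
    }
    roi <- ret$vertex[ret$visual_area == "V1"]
  }
  if (is.null(line)) {
    line <- trace_meridian_line(ret, roi, meridian, cfg$ecc_window,
                                r2_min = cfg$r2_min)
  }
  if (is.null(distances)) {
    distances <- geodesic_distance(mesh, line$vertex)
  }
  target0 <- meridian_angle(meridian)
  edges <- log_bands(cfg$ecc_window[1], cfg$ecc_window[2], cfg$n_bands)
  idx <- match(ret$vertex, mesh$vertices$vertex)
  dist_v <- distances[idx]
  in_roi <- ret$vertex %in% roi
  band_of <- cut(ret$ecc, edges, include.lowest = TRUE, labels = FALSE)
  side_of <- sign(angle_diff(ret[[ang_col]], target0))
  side_of[side_of == 0] <- 1

  iso <- tidyr::expand_grid(band = seq_len(cfg$n_bands), side = c(-1, 1))
  iso$target <- wrap_angle(target0 + iso$side * half_width)
  iso$mid_ecc <- sqrt(edges[iso$band] * edges[iso$band + 1])
  iso$distance <- purrr::pmap_dbl(iso, function(band, side, target, ...) {
    sel <- in_roi & !is.na(band_of) & band_of == band
    if (!any(sel)) return(NA_real_)
    iso_angle_distance(dist_v[sel], ret[[ang_col]][sel], ret$r2[sel],
                       target, cfg$angle_tolerance, cfg$r2_min)
  })
  # a side participates only if at least one band yields a boundary
  # estimate (for the vertical meridians only one side lies in the map);
  # missing bands on a participating side are interpolated
  side_ok <- vapply(c(-1, 1), function(s) {
    any(!is.na(iso$distance[iso$side == s]))
  }, logical(1))
  if (!any(side_ok)) {
    abort(sprintf("All bands missing for %s.", meridian))
  }
  iso$interpolated <- FALSE
  for (s in c(-1, 1)[side_ok]) {
    rows <- which(iso$side == s)
    miss <- rows[is.na(iso$distance[rows])]
    have <- rows[!is.na(iso$distance[rows])]
    if (length(miss) > 0) {
      iso$distance[miss] <- approx(log(iso$mid_ecc[have]),
                                   iso$distance[have],
                                   xout = log(iso$mid_ecc[miss]),
                                   rule = 2)$y
      iso$interpolated[miss] <- TRUE
    }
  }
  # vertices on an absent side (angle noise scattering them just across
  # the meridian) inherit the opposite side's boundary distance
  eff_dist <- function(band, side) {
    s_use <- if (side_ok[(side + 3) / 2]) side else -side
    iso$distance[iso$band == band & iso$side == s_use]
  }

  keep <- rep(FALSE, nrow(ret))
  for (b in seq_len(cfg$n_bands)) {
    for (s in c(-1, 1)) {
      d_ok <- eff_dist(b, s)
      if (is.na(d_ok)) next
      # small absolute slack so vertices exactly on the boundary are
      # included regardless of floating-point noise
      sel <- in_roi & !is.na(band_of) & band_of == b &
        side_of == s & dist_v <= d_ok + 1e-9
      keep <- keep | sel
    }
  }
  # meridian-line vertices inside the window always belong to the wedge
  keep <- keep | (in_roi & !is.na(band_of) & dist_v == 0)

  structure(
    list(vertex_ids = ret$vertex[keep], meridian = meridian,
         half_width = half_width, iso = iso, line = line,
         hemisphere = mesh$hemisphere),
    class = "wedge_roi"
  )
}

#' @export
print.wedge_roi <- function(x, ...) {
  cat(sprintf("<wedge_roi> %s +/-%g deg, %s hemisphere, %d vertices\n",
              x$meridian, x$half_width, x$hemisphere,
              length(x$vertex_ids)))
  invisible(x)
}

#' Surface area of a wedge-ROI
#'
#' Sums per-vertex surface areas over the wedge at the chosen depth. All
#' wedge vertices count, with no variance-explained filtering.
#'
#' @param wedge A [wedge_roi()] result.
#' @param mesh The `cortical_mesh`.
#' @param depth Cortical depth (`"midgray"`, `"pial"`, `"white"`).
#' @return Surface area (mm^2).
#' @export
wedge_area <- function(wedge, mesh, depth = "midgray") {
  if (length(wedge$vertex_ids) == 0) abort("Wedge is empty.")
  map_surface_area(mesh, wedge$vertex_ids, depth = depth)
}

#' Centers-only wedge surface area
#'
#' The computationally simple alternative to the wedge-ROI construction:
#' sums the surface area of the vertices whose fitted pRF centers fall
#' within the angular range around the meridian and the eccentricity
#' window, after thresholding by variance explained.
#'
#' @param retinotopy Retinotopy tibble (fitted `angle`, `ecc`, `r2`).
#' @param mesh The `cortical_mesh`.
#' @param meridian Meridian name.
#' @param half_width Angular half-range (degrees).
#' @param ecc_window Eccentricity window (degrees).
#' @param r2_min Variance-explained threshold (default 0.10).
#' @param roi Optional vertex ids (default: ground-truth V1 when present).
#' @param depth Cortical depth.
#' @return Surface area (mm^2).
#' @export
centers_only_area <- function(retinotopy, mesh, meridian, half_width,
                              ecc_window = c(1, 7), r2_min = 0.10,
                              roi = NULL, depth = "midgray") {
  target <- meridian_angle(meridian)
  if (is.null(roi)) {
    roi <- if ("visual_area" %in% names(retinotopy)) {
      retinotopy$vertex[retinotopy$visual_area == "V1"]
    } else retinotopy$vertex
  }
  sel <- retinotopy$vertex %in% roi &
    abs(angle_diff(retinotopy$angle, target)) <= half_width &
    retinotopy$ecc >= ecc_window[1] & retinotopy$ecc <= ecc_window[2] &
    retinotopy$r2 >= r2_min
  if (!any(sel)) return(0)
  map_surface_area(mesh, retinotopy$vertex[sel], depth = depth)
}

#' Meridian surface areas for a two-hemisphere subject
#'
#' Runs the wedge-ROI analysis on both hemispheres and combines them the
#' way the asymmetry indices require: left- and right-horizontal wedge
#' areas are summed into `horizontal`; the upper-vertical (and
#' lower-vertical) wedges of the two hemispheres are summed into
#' `upper_vertical` (`lower_vertical`); `vertical` is their sum.
#'
#' @param subject A [build_subject()] result (or list with `left`, `right`
#'   hemispheres whose retinotopies carry `angle_clean` if cleaning is
#'   wanted).
#' @param widths Wedge half-widths (degrees).
#' @param cfg A [wedge_config()].
#' @param depth Cortical depth.
#' @param method `"wedge"` (geodesic wedge-ROIs) or `"centers"`
#'   (centers-only).
#' @return Tibble with `meridian`, `half_width`, `area` (mm^2).
#' @export
meridian_surface_areas <- function(subject, widths = c(15, 25, 35, 45, 55),
                                   cfg = wedge_config(widths = widths),
                                   depth = "midgray",
                                   method = c("wedge", "centers")) {
  method <- match.arg(method)
  per_hemi <- purrr::map(subject[c("left", "right")], function(hemi) {
    mers <- hemisphere_meridians(hemi$mesh$hemisphere)
    purrr::map(mers, function(mer) {
      if (method == "centers") {
        areas <- purrr::map_dbl(widths, function(w) {
          centers_only_area(hemi$retinotopy, hemi$mesh, mer, w,
                            cfg$ecc_window, cfg$r2_min, depth = depth)
        })
        return(tibble(meridian = mer, half_width = widths, area = areas))
      }
      roi <- hemi$retinotopy$vertex[hemi$retinotopy$visual_area == "V1"]
      line <- trace_meridian_line(hemi$retinotopy, roi, mer,
                                  cfg$ecc_window, r2_min = cfg$r2_min)
      dists <- geodesic_distance(hemi$mesh, line$vertex)
      areas <- purrr::map_dbl(widths, function(w) {
        wr <- wedge_roi(hemi, mer, w, cfg, roi = roi, line = line,
                        distances = dists)
        wedge_area(wr, hemi$mesh, depth)
      })
      tibble(meridian = mer, half_width = widths, area = areas)
    }) |> dplyr::bind_rows()
  })
  both <- dplyr::bind_rows(per_hemi)
  both$group_meridian <- dplyr::case_when(
    both$meridian %in% c("left_horizontal", "right_horizontal") ~
      "horizontal",
    TRUE ~ both$meridian
  )
  combined <- both |>
    group_by(.data$group_meridian, .data$half_width) |>
    summarise(area = sum(.data$area), .groups = "drop") |>
    dplyr::rename(meridian = "group_meridian")
  vertical <- combined |>
    filter(.data$meridian %in% c("upper_vertical", "lower_vertical")) |>
    group_by(.data$half_width) |>
    summarise(area = sum(.data$area), .groups = "drop") |>
    mutate(meridian = "vertical")
  dplyr::bind_rows(combined, vertical) |>
    arrange(.data$meridian, .data$half_width)
}
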