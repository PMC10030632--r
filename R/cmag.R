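#' Horton-Hoyt areal cortical magnification law
#'
#' `M(E) = (scale / (E + e0))^2` mm^2 of cortex per deg^2 of visual field.
#'
#' @param E Eccentricity (degrees, >= 0); vectorized.
#' @param scale Scale constant (mm), default 17.3.
#' @param e0 Eccentricity offset (degrees), default 0.75.
#' @return Areal magnification (mm^2/deg^2).
#' @export
#' @examples
#' horton_hoyt_areal(3)
horton_hoyt_areal <- function(E, scale = 17.3, e0 = 0.75) {
  if (any(E + e0 <= 0)) abort("`E + e0` must be positive.")
  (scale / (E + e0))^2
}

#' Fraction of V1 within a central eccentricity
#'
#' Integrates the Horton-Hoyt areal law over the visual-field disc:
#' `A(E) = integral of M(e) 2 pi e de` has the closed form
#' `2 pi scale^2 [ln(E + e0) + e0/(E + e0)]` (up to a constant), and the
#' fraction is `A(E_max) / A(E_full)`.
#'
#' @param E_max Central eccentricity limit (degrees, > 0).
#' @param E_full Full map extent (degrees, >= `E_max`), default 90.
#' @param scale,e0 Law constants, as in [horton_hoyt_areal()].
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' fraction_within(7, 90) # about 0.38
fraction_within <- function(E_max, E_full = 90, scale = 17.3, e0 = 0.75) {
  check_positive(E_max, "E_max")
  if (E_full < E_max) abort("`E_full` must be >= `E_max`.")
  antideriv <- function(E) log(E + e0) + e0 / (E + e0)
  (antideriv(E_max) - antideriv(0)) / (antideriv(E_full) - antideriv(0))
}

#' Areal cortical magnification as a function of eccentricity
#'
#' For each sample eccentricity `r`, finds the adaptive half-width
#' `delta_r` such that a fixed fraction (default 20%) of the ROI's vertices
#' have eccentricity within `r +/- delta_r`, sums their surface area, and
#' divides by the visual-field area of the annulus (scaled by the hemifield
#' fraction the hemisphere represents). Annuli extending below 0 degrees
#' are clipped with a warning.
#'
#' @param mesh A `cortical_mesh`.
#' @param retinotopy Retinotopy tibble (`vertex`, `ecc`).
#' @param roi Vertex ids of the ROI (e.g. V1).
#' @param r_grid Sample eccentricities (degrees), default 1-7.
#' @param vertex_frac Fraction of ROI vertices captured per annulus.
#' @param hemifield_fraction Fraction of the full annulus represented by
#'   this map (0.5 for a single-hemisphere hemifield map).
#' @param depth Cortical depth of the vertex areas.
#' @return Tibble of class `cmag_curve` with `r`, `delta_r`, `n_vertices`,
#'   `area_mm2`, `m` (mm^2/deg^2).
#' @export
areal_cmag <- function(mesh, retinotopy, roi,
                       r_grid = seq(1, 7, by = 0.25), vertex_frac = 0.2,
                       hemifield_fraction = 0.5, depth = "midgray") {
  if (length(roi) == 0) abort("ROI is empty.")
  depth_col <- switch(depth,
                      midgray = "area_midgray", pial = "area_pial",
                      white = "area_white",
                      abort("`depth` must be midgray, pial, or white."))
  rr <- retinotopy[retinotopy$vertex %in% roi, ]
  areas <- mesh$vertices[[depth_col]][match(rr$vertex,
                                            mesh$vertices$vertex)]
  clipped <- FALSE
  n_roi <- nrow(rr)
  k_cap <- max(1L, ceiling(vertex_frac * n_roi))
  out <- purrr::map(r_grid, function(r) {
    dev <- sort(abs(rr$ecc - r))
    # smallest half-width capturing the target vertex fraction: the k-th
    # order statistic of the absolute deviations (ties included), with the
    # ring edge placed halfway to the next-further vertex so the annulus
    # covers the included vertices' surface cells without overreach
    d_k <- dev[k_cap]
    d_next <- dev[dev > d_k][1]
    delta_r <- if (is.na(d_next)) d_k else (d_k + d_next) / 2
    dev <- abs(rr$ecc - r)
    inside <- dev <= d_k
    lo <- r - delta_r
    if (lo < 0) {
      clipped <<- TRUE
      lo <- 0
    }
    ring_deg2 <- pi * ((r + delta_r)^2 - lo^2) * hemifield_fraction
    tibble(r = r, delta_r = delta_r, n_vertices = sum(inside),
           area_mm2 = sum(areas[inside]), m = sum(areas[inside]) / ring_deg2)
  })
  if (clipped) warn("Some annuli extended below 0 degrees and were clipped.")
  structure(dplyr::bind_rows(out), class = c("cmag_curve", "tbl_df", "tbl",
                                             "data.frame"))
}
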