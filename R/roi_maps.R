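# mesh edge list (unique undirected edges with Euclidean lengths)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  xyz <- as.matrix(mesh$vertices[, c("x_mm", "y_mm", "z_mm")])
  len <- sqrt(rowSums((xyz[e[, 1], , drop = FALSE] -
                         xyz[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

# vertices on the open boundary of the mesh (incident to an edge that
# belongs to a single face)
mesh_boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_edges <- e[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  sort(unique(as.vector(open_edges)))
}

mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(ed$edges))
  igraph::E(g)$weight <- ed$lengths
  g
}

# adjacency list of the vertex graph
mesh_neighbors <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  sp1 <- split(ed[, 2], ed[, 1])
  sp2 <- split(ed[, 1], ed[, 2])
  for (k in names(sp1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp1[[k]])
  for (k in names(sp2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp2[[k]])
  adj
}

#' Detect polar-angle reversals delineating V1, V2, and V3
#'
#' Map boundaries are the centers of the polar-angle reversals at the
#' vertical and horizontal meridians. On the vertex graph, a reversal vertex
#' is a local extremum of field elevation across its neighborhood: the
#' elevation angle reaches +/-90 degrees at the V1/V2 borders (vertical
#' meridians) and returns through 0 at the V2/V3 borders (horizontal
#' meridian). Only vertices with `r2 >= r2_min` participate.
#'
#' @param retinotopy Retinotopy tibble with `vertex`, `angle`, `r2` (uses
#'   `angle_clean` instead of `angle` when present).
#' @param mesh The `cortical_mesh` the map lives on.
#' @param r2_min Variance-explained threshold (default 0.10).
#' @param meridian_tol How close (degrees) a candidate's angle must be to a
#'   meridian to be labeled.
#' @param min_cluster Reversals are curvilinear ridges: candidates of a
#'   meridian are grouped by proximity (within two mesh edges) and groups
#'   smaller than `min_cluster` are discarded as isolated noise extrema.
#' @param slack Extremum tolerance (degrees): a vertex counts as a local
#'   extremum when no neighbor exceeds it by more than `slack`, absorbing
#'   ties along the ridge and residual map noise.
#' @return Tibble with `vertex`, `meridian` (`"upper_vertical"`,
#'   `"lower_vertical"`, `"horizontal"`), and `angle`; zero rows (with a
#'   message) if no reversal is found.
#' @export
detect_reversals <- function(retinotopy, mesh, r2_min = 0.10,
                             meridian_tol = 15, min_cluster = 3,
                             slack = 1) {
  ang_col <- if ("angle_clean" %in% names(retinotopy)) "angle_clean" else "angle"
  keep <- retinotopy$r2 >= r2_min
  if (!any(keep)) {
    rlang::inform("No vertices at or above `r2_min`; no reversals found.")
    return(tibble(vertex = integer(), meridian = character(),
                  angle = numeric()))
  }
  hemisphere <- mesh$hemisphere
  ang <- retinotopy[[ang_col]]
  # signed field elevation in [-90, 90] relative to the hemifield center
  center <- if (hemisphere == "left") 0 else 180
  elev <- angle_diff(ang, center)
  if (hemisphere == "right") elev <- -elev
  elev[!keep] <- NA_real_

  adj <- mesh_neighbors(mesh)
  n <- length(elev)
  # extrema on or next to the open mesh boundary are edge artifacts (their
  # neighborhoods are truncated), not reversals
  on_boundary <- logical(n)
  bv <- mesh_boundary_vertices(mesh)
  on_boundary[bv] <- TRUE
  on_boundary[unique(unlist(adj[bv]))] <- TRUE
  is_max <- logical(n); is_min <- logical(n)
  for (v in seq_len(n)) {
    if (is.na(elev[v]) || on_boundary[v]) next
    nb <- elev[adj[[v]]]
    nb <- nb[!is.na(nb)]
    if (length(nb) < 2) next
    if (all(elev[v] >= nb - slack)) is_max[v] <- TRUE
    if (all(elev[v] <= nb + slack)) is_min[v] <- TRUE
  }
  res <- dplyr::bind_rows(
    tibble(vertex = which(is_max & abs(elev - 90) <= meridian_tol),
           meridian = "upper_vertical"),
    tibble(vertex = which(is_min & abs(elev + 90) <= meridian_tol),
           meridian = "lower_vertical"),
    tibble(vertex = which((is_max | is_min) & abs(elev) <= meridian_tol),
           meridian = "horizontal")
  )
  if (nrow(res) > 0 && min_cluster > 1) {
    g2 <- igraph::connect(mesh_graph(mesh), 2)
    res <- dplyr::bind_rows(lapply(split(res, res$meridian), function(r) {
      sub <- igraph::induced_subgraph(g2, r$vertex)
      comp <- igraph::components(sub)
      keep <- comp$membership %in% which(comp$csize >= min_cluster)
      r[keep, ]
    }))
  }
  if (nrow(res) == 0) {
    rlang::inform("No polar-angle reversal detected.")
    return(tibble(vertex = integer(), meridian = character(),
                  angle = numeric()))
  }
  res$angle <- ang[res$vertex]
  res
}

#' Surface area of an ROI at a cortical depth
#'
#' Sums per-vertex surface areas over the ROI vertices whose eccentricity
#' falls inside the window. Hemispheres are summed by the caller.
#'
#' @param mesh A `cortical_mesh`.
#' @param vertices Vertex ids of the ROI.
#' @param depth `"midgray"` (default), `"pial"`, or `"white"`.
#' @param retinotopy Optional retinotopy tibble; needed when `ecc_window`
#'   is finite.
#' @param ecc_window Eccentricity window in degrees (closed interval).
#' @return Total surface area (mm^2).
#' @export
map_surface_area <- function(mesh, vertices, depth = "midgray",
                             retinotopy = NULL, ecc_window = c(0, Inf)) {
  depth_col <- switch(depth,
                      midgray = "area_midgray", pial = "area_pial",
                      white = "area_white",
                      abort("`depth` must be midgray, pial, or white."))
  if (length(vertices) == 0) abort("ROI is empty.")
  sel <- mesh$vertices$vertex %in% vertices
  if (is.finite(ecc_window[2]) || ecc_window[1] > 0) {
    if (is.null(retinotopy)) {
      abort("`retinotopy` is required for a finite eccentricity window.")
    }
    ecc <- retinotopy$ecc[match(mesh$vertices$vertex, retinotopy$vertex)]
    sel <- sel & !is.na(ecc) & ecc >= ecc_window[1] & ecc <= ecc_window[2]
  }
  sum(mesh$vertices[[depth_col]][sel])
}

#' Coefficient of variation
#'
#' `sd(x) / mean(x)` with the sample (n - 1) standard deviation; the
#' dispersion of map surface area relative to its mean.
#'
#' @param values Numeric vector, `n >= 2`, positive mean.
#' @return Unitless CV.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 3))
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("Need at least 2 values.")
  m <- mean(values)
  if (m <= 0) abort("Mean must be positive.")
  sd(values) / m
}

#' Bootstrap the percent difference of two group means
#'
#' Resamples each group with replacement and reports the difference of
#' means as a percentage of the second group's mean, with a percentile
#' confidence interval.
#'
#' @param values_a,values_b Numeric vectors (group A and reference group B).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return Tibble with `pct_diff` (point estimate from the observed means),
#'   `boot_mean`, `conf_low`, `conf_high`, `n_boot`.
#' @export
group_mean_bootstrap <- function(values_a, values_b, n_boot = 1000,
                                 seed = 1L, conf = 0.95) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("Both groups must be nonempty.")
  }
  pct <- function(a, b) (mean(a) - mean(b)) / mean(b) * 100
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      pct(sample(values_a, replace = TRUE),
          sample(values_b, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble(pct_diff = pct(values_a, values_b), boot_mean = mean(boots),
         conf_low = qs[1], conf_high = qs[2], n_boot = n_boot)
}
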