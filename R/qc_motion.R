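#' Framewise displacement from a rigid motion trace
#'
#' Summarizes head motion per frame transition as the sum of absolute
#' framewise differences of the three translations plus the three rotations
#' converted to arc length on a sphere approximating the distance from the
#' head center to the cortex (`head_radius`, default 50 mm). Rotations given
#' in degrees are converted with the factor `head_radius * pi / 180`;
#' rotations already in radians are multiplied by `head_radius` alone.
#'
#' @param trace Data frame with one row per volume and columns `trans_x`,
#'   `trans_y`, `trans_z` (mm) and `rot_x`, `rot_y`, `rot_z`.
#' @param head_radius Rotation arc-length radius (mm).
#' @param rotation_units `"degrees"` (default) or `"radians"`.
#' @return Tibble with `frame` (2..n) and `fd` (mm); zero rows for a
#'   single-frame trace.
#' @export
#' @examples
#' tr <- simulate_motion(10, spike_frames = 5, spike_mm = 0.6)
#' framewise_displacement(tr)
framewise_displacement <- function(trace, head_radius = 50,
                                   rotation_units = c("degrees", "radians")) {
  rotation_units <- match.arg(rotation_units)
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(cols %in% names(trace))) {
    abort(paste("`trace` needs columns", paste(cols, collapse = ", ")))
  }
  if (any(!is.finite(as.matrix(trace[cols])))) {
    abort("Motion trace contains non-finite values.")
  }
  n <- nrow(trace)
  if (n < 2) return(tibble(frame = integer(), fd = numeric()))
  rot_factor <- if (rotation_units == "degrees") {
    head_radius * pi / 180
  } else {
    head_radius
  }
  d <- apply(as.matrix(trace[cols]), 2, diff)
  d <- matrix(d, ncol = 6, dimnames = list(NULL, cols))
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    rowSums(abs(rot_factor * d[, 4:6, drop = FALSE]))
  tibble(frame = 2:n, fd = as.numeric(fd))
}

#' Count framewise-displacement threshold exceedances
#'
#' Number of frame transitions whose FD strictly exceeds the threshold.
#'
#' @param fd A tibble from [framewise_displacement()] or a numeric vector.
#' @param threshold Exceedance threshold (mm, > 0).
#' @return Integer count.
#' @export
count_exceedances <- function(fd, threshold = 0.5) {
  check_positive(threshold, "threshold")
  v <- if (is.data.frame(fd)) fd$fd else fd
  sum(v > threshold)
}

#' Median variance explained over an ROI
#'
#' @param retinotopy Retinotopy tibble with `vertex` and `r2`.
#' @param vertices Optional vertex ids restricting the ROI; default all.
#' @return Median R^2 (fraction).
#' @export
median_map_r2 <- function(retinotopy, vertices = NULL) {
  if (!is.null(vertices)) {
    retinotopy <- retinotopy[retinotopy$vertex %in% vertices, ]
  }
  if (nrow(retinotopy) == 0) abort("ROI is empty.")
  median(retinotopy$r2)
}

#' Left-right hemisphere surface-area symmetry
#'
#' Two-tailed Pearson correlation between paired per-subject left- and
#' right-hemisphere map surface areas, a whole-pipeline data-quality check:
#' high symmetry indicates map definitions good enough for area estimates.
#'
#' @param areas Data frame with one row per subject.
#' @param lh,rh Column names holding the left and right hemisphere areas.
#' @return Tibble with `r`, `p`, `n`, `conf_low`, `conf_high`.
#' @export
hemisphere_symmetry <- function(areas, lh = "lh_area", rh = "rh_area") {
  x <- areas[[lh]]
  y <- areas[[rh]]
  if (is.null(x) || is.null(y)) abort("Columns `lh`/`rh` not found.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in one hemisphere.")
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
}
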