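#' Configuration for the sweeping-bar contrast aperture
#'
#' Describes the bar-aperture retinotopic mapping stimulus: a high-contrast
#' bar that sweeps across a circular field, used as the contrast aperture of
#' the pRF forward model. Defaults correspond to a 7 degree-radius field with
#' a 3 x 14 degree bar drifting at 0.30 deg/s, updated twice per second, and
#' eight sweeps (four cardinal full-diameter sweeps and four diagonal sweeps
#' that traverse half the field, the second half replaced by blanks).
#'
#' @param field_radius Radius of the circular aperture (degrees of visual
#'   angle).
#' @param bar_width Width of the bar along its direction of motion (degrees).
#' @param bar_length Length of the bar orthogonal to motion (degrees).
#' @param n_sweeps Number of sweeps; the first four are cardinal, the
#'   remainder diagonal.
#' @param drift_speed Bar drift velocity (degrees/second).
#' @param frame_rate Stimulus update rate (frames/second).
#' @param tr Repetition time of the accompanying BOLD acquisition (seconds).
#'   `frame_rate * tr` must be a whole number so that frames align to TRs.
#' @param grid_resolution Pixels per side of the square sampling grid.
#' @param n_volumes Optional fixed number of TRs. When given, the movie is
#'   padded with blank frames (at the end) or truncated to exactly this many
#'   volumes; when `NULL` the movie length follows from the sweep geometry.
#' @return An object of class `aperture_config`.
#' @export
#' @examples
#' cfg <- aperture_config(grid_resolution = 41)
#' cfg$field_radius
aperture_config <- function(field_radius = 7, bar_width = 3, bar_length = 14,
                            n_sweeps = 8, drift_speed = 0.30, frame_rate = 2,
                            tr = 2, grid_resolution = 101, n_volumes = NULL) {
  check_positive(field_radius, "field_radius")
  check_number(bar_width, "bar_width", lower = 0)
  if (bar_width >= 2 * field_radius) {
    abort("`bar_width` must be smaller than the aperture diameter.")
  }
  check_positive(bar_length, "bar_length")
  check_positive(drift_speed, "drift_speed")
  check_positive(frame_rate, "frame_rate")
  check_positive(tr, "tr")
  fpt <- frame_rate * tr
  if (abs(fpt - round(fpt)) > 1e-9) {
    abort("`frame_rate * tr` must be a whole number of frames per TR.")
  }
  if (!is.numeric(grid_resolution) || grid_resolution < 2) {
    abort("`grid_resolution` must be an integer >= 2.")
  }
  if (!is.numeric(n_sweeps) || n_sweeps < 1) {
    abort("`n_sweeps` must be a positive integer.")
  }
  if (!is.null(n_volumes)) check_positive(n_volumes, "n_volumes")
  structure(
    list(field_radius = field_radius, bar_width = bar_width,
         bar_length = bar_length, n_sweeps = as.integer(n_sweeps),
         drift_speed = drift_speed, frame_rate = frame_rate, tr = tr,
         grid_resolution = as.integer(grid_resolution),
         n_volumes = if (is.null(n_volumes)) NULL else as.integer(n_volumes)),
    class = "aperture_config"
  )
}

# canonical sweep motion directions (degrees, direction the bar travels):
# L->R, bottom->top, R->L, top->bottom, then four diagonals 45 deg apart
sweep_directions <- function(n_sweeps) {
  cardinal <- c(0, 90, 180, 270)
  diagonal <- c(45, 135, 225, 315)
  c(cardinal, diagonal)[seq_len(n_sweeps)]
}

#' Build the sweeping-bar aperture movie
#'
#' Generates the binary contrast-aperture movie frame by frame from the sweep
#' geometry. Cardinal sweeps traverse the full aperture diameter; diagonal
#' sweeps traverse from the edge to the center of the field, with the second
#' half of the sweep replaced by blank (all-zero) frames. Each sweep is
#' padded to a whole number of TRs with positions beyond the aperture edge
#' (which render as blanks), so an integer number of frames falls in each TR.
#'
#' @param config An [aperture_config()].
#' @return An object of class `aperture_movie`: a list with `frames` (a
#'   `resolution x resolution x n_frames` array of 0/1 values), pixel-center
#'   coordinates `px`, `py` (degrees), `pixel_scale` (degrees/pixel),
#'   `timestamps` (frame onsets, seconds), per-frame `sweep` index and
#'   `blank` flag, and the acquisition geometry.
#' @export
#' @examples
#' mov <- make_bar_aperture(aperture_config(grid_resolution = 31))
#' dim(mov$frames)
make_bar_aperture <- function(config) {
  if (!inherits(config, "aperture_config")) {
    abort("`config` must be created by `aperture_config()`.")
  }
  R <- config$field_radius
  res <- config$grid_resolution
  px <- seq(-R, R, length.out = res)
  pixel_scale <- 2 * R / (res - 1)
  fpt <- as.integer(round(config$frame_rate * config$tr))
  step <- config$drift_speed / config$frame_rate

  # frames needed to traverse the full diameter, rounded up to whole TRs
  n_geom <- ceiling(2 * R / step)
  n_per_sweep <- fpt * ceiling(n_geom / fpt)
  dirs <- sweep_directions(config$n_sweeps)
  is_diag <- dirs %% 90 != 0

  disc <- outer(px, px, function(x, y) x^2 + y^2 <= R^2)
  frames_list <- vector("list", config$n_sweeps)
  sweep_id <- integer(0)
  blank <- logical(0)
  for (s in seq_len(config$n_sweeps)) {
    pos <- -R + step * (seq_len(n_per_sweep) - 1L)
    active <- rep(TRUE, n_per_sweep)
    if (is_diag[s]) {
      # bar stops at the field center; remainder of the sweep is blank
      active <- pos <= 0
    }
    d <- deg2rad(dirs[s])
    u <- outer(px, px, function(x, y) x * cos(d) + y * sin(d))
    v <- outer(px, px, function(x, y) -x * sin(d) + y * cos(d))
    base <- abs(v) <= config$bar_length / 2 & disc
    arr <- array(0, dim = c(res, res, n_per_sweep))
    if (config$bar_width > 0) {
      for (j in which(active)) {
        arr[, , j] <- (abs(u - pos[j]) <= config$bar_width / 2 & base) * 1
      }
    }
    frames_list[[s]] <- arr
    sweep_id <- c(sweep_id, rep(s, n_per_sweep))
    blank <- c(blank, !active)
  }
  frames <- array(unlist(frames_list, use.names = FALSE),
                  dim = c(res, res, n_per_sweep * config$n_sweeps))

  if (!is.null(config$n_volumes)) {
    target <- config$n_volumes * fpt
    n_now <- dim(frames)[3]
    if (target <= n_now) {
      frames <- frames[, , seq_len(target), drop = FALSE]
      sweep_id <- sweep_id[seq_len(target)]
      blank <- blank[seq_len(target)]
    } else {
      pad <- array(0, dim = c(res, res, target - n_now))
      frames <- array(c(frames, pad), dim = c(res, res, target))
      sweep_id <- c(sweep_id, rep(NA_integer_, target - n_now))
      blank <- c(blank, rep(TRUE, target - n_now))
    }
  }
  n_frames <- dim(frames)[3]
  # frames with no bar pixels are blanks regardless of provenance
  blank <- blank | apply(frames, 3, sum) == 0

  structure(
    list(frames = frames, px = px, py = px, pixel_scale = pixel_scale,
         timestamps = (seq_len(n_frames) - 1L) / config$frame_rate,
         frame_rate = config$frame_rate, tr = config$tr,
         field_radius = R, sweep = sweep_id, blank = blank,
         config = config),
    class = "aperture_movie"
  )
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf(
    "<aperture_movie> %d x %d px, %d frames (%.0f TRs), %.3g deg/px\n",
    dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
    dim(x$frames)[3] / (x$frame_rate * x$tr), x$pixel_scale))
  cat(sprintf("  field radius %.3g deg, %d blank frames\n",
              x$field_radius, sum(x$blank)))
  invisible(x)
}

#' Average an aperture movie down to TR resolution
#'
#' Averages frames within each TR so the movie has one (possibly fractional,
#' in `[0, 1]`) frame per BOLD volume, the temporal resolution at which the
#' pRF forward model operates.
#'
#' @param movie An [make_bar_aperture()] movie.
#' @param tr Target repetition time (seconds); must be a whole multiple of
#'   the movie's frame interval. Defaults to the movie's own `tr`.
#' @return An `aperture_movie` with `frame_rate = 1/tr` and values in
#'   `[0, 1]`.
#' @export
downsample_to_tr <- function(movie, tr = movie$tr) {
  if (!inherits(movie, "aperture_movie")) {
    abort("`movie` must be an `aperture_movie`.")
  }
  check_positive(tr, "tr")
  fpt <- movie$frame_rate * tr
  if (abs(fpt - round(fpt)) > 1e-9 || fpt < 1) {
    abort("`tr` must be a whole multiple of the movie frame interval.")
  }
  fpt <- as.integer(round(fpt))
  n_frames <- dim(movie$frames)[3]
  n_tr <- n_frames %/% fpt
  if (n_tr * fpt != n_frames) {
    warn("Movie length is not a whole number of TRs; trailing frames dropped.")
  }
  res <- dim(movie$frames)[1]
  idx <- rep(seq_len(n_tr), each = fpt)
  mat <- matrix(movie$frames[, , seq_len(n_tr * fpt)], nrow = res * res)
  agg <- sapply(seq_len(n_tr), function(k) {
    rowMeans(mat[, idx == k, drop = FALSE])
  })
  out <- movie
  out$frames <- array(agg, dim = c(res, res, n_tr))
  out$frame_rate <- 1 / tr
  out$tr <- tr
  out$timestamps <- (seq_len(n_tr) - 1L) * tr
  out$sweep <- movie$sweep[seq(1, n_tr * fpt, by = fpt)]
  out$blank <- apply(out$frames, 3, sum) == 0
  out
}

# movie frames as an (n_pixels x n_frames) matrix for fast projection
movie_matrix <- function(movie) {
  d <- dim(movie$frames)
  matrix(movie$frames, nrow = d[1] * d[2], ncol = d[3])
}
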