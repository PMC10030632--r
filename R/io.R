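#' Write an aperture movie as NIfTI with a JSON sidecar
#'
#' Frames become the 4th NIfTI dimension; pixel scale, timestamps and
#' acquisition geometry go to `<path>.json`.
#'
#' @param movie An `aperture_movie`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_aperture_nifti <- function(movie, path) {
  arr <- array(movie$frames,
               dim = c(dim(movie$frames)[1], dim(movie$frames)[2], 1,
                       dim(movie$frames)[3]))
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  sidecar <- list(pixel_scale = movie$pixel_scale,
                  field_radius = movie$field_radius,
                  frame_rate = movie$frame_rate, tr = movie$tr,
                  timestamps = movie$timestamps,
                  blank = movie$blank)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an aperture movie written by [write_aperture_nifti()]
#'
#' @param path The `.nii` / `.nii.gz` path (sidecar expected at
#'   `<path>.json`).
#' @return An `aperture_movie`.
#' @export
read_aperture_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(img)
  frames <- array(as.numeric(img), dim = c(d[1], d[2], d[4]))
  R <- side$field_radius
  structure(
    list(frames = frames, px = seq(-R, R, length.out = d[1]),
         py = seq(-R, R, length.out = d[2]),
         pixel_scale = side$pixel_scale,
         timestamps = side$timestamps, frame_rate = side$frame_rate,
         tr = side$tr, field_radius = R,
         sweep = rep(NA_integer_, d[4]), blank = side$blank,
         config = NULL),
    class = "aperture_movie"
  )
}

#' Read a six-column rigid-motion confound table
#'
#' Whitespace- or tab-separated, one row per volume: three translations
#' (mm) then three rotations (degrees or radians, see
#' [framewise_displacement()]). A header row is detected and skipped.
#'
#' @param path File path.
#' @return Tibble with `frame` plus the six motion columns.
#' @export
read_motion_confounds <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                           "\\s+")[[1]][1])))
  df <- utils::read.table(path, header = has_header)
  if (ncol(df) != 6) abort("Expected 6 motion columns.")
  names(df) <- c("trans_x", "trans_y", "trans_z",
                 "rot_x", "rot_y", "rot_z")
  dplyr::bind_cols(tibble(frame = seq_len(nrow(df))), as_tibble(df))
}

#' Write a vertex set as a FreeSurfer label file
#'
#' Plain-text label format: a comment line, a vertex count, then one line
#' per vertex with the 0-based vertex index, its coordinates (mm) and a
#' value column.
#'
#' @param vertices 1-based vertex ids.
#' @param mesh The `cortical_mesh` providing coordinates.
#' @param path Output path.
#' @param values Optional per-vertex values (default 0).
#' @return Invisibly, `path`.
#' @export
write_label <- function(vertices, mesh, path, values = 0) {
  sel <- match(vertices, mesh$vertices$vertex)
  if (any(is.na(sel))) abort("Some vertices are not in the mesh.")
  values <- rep_len(values, length(vertices))
  lines <- c(
    "#!ascii label, synthetic surface",
    as.character(length(vertices)),
    sprintf("%d  %.6f  %.6f  %.6f %.10f",
            vertices - 1L, mesh$vertices$x_mm[sel],
            mesh$vertices$y_mm[sel], mesh$vertices$z_mm[sel], values)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a FreeSurfer label file
#'
#' @param path Label file path.
#' @return Tibble with 1-based `vertex`, coordinates, and `value`.
#' @export
read_label <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[2])
  df <- utils::read.table(text = lines[3:(2 + n)])
  names(df) <- c("vertex", "x_mm", "y_mm", "z_mm", "value")
  df$vertex <- df$vertex + 1L
  as_tibble(df)
}

#' Write per-vertex pRF fits as CSV
#'
#' @param fit A `prf_fit` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_prf_fits <- function(fit, path) {
  readr::write_csv(tidy(fit), path)
  invisible(path)
}
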