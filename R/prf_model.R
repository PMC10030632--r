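#' Parameters of the two-gamma hemodynamic response function
#'
#' The HRF is modeled as a difference of two gamma densities: a positive
#' response lobe minus a scaled undershoot lobe. The five parameters are the
#' response and undershoot delays (the gamma means, seconds), the response
#' and undershoot dispersions (seconds), and the undershoot-to-response
#' amplitude ratio. Defaults are the conventional double-gamma first-pass
#' values (6, 16, 1, 1, 1/6).
#'
#' @param response_delay,undershoot_delay Gamma peak delays (seconds, > 0).
#' @param response_dispersion,undershoot_dispersion Gamma dispersions
#'   (seconds, > 0).
#' @param ratio Undershoot:response amplitude ratio (>= 0).
#' @return An object of class `hrf_parameters`.
#' @export
#' @examples
#' hrf_parameters()
hrf_parameters <- function(response_delay = 6, undershoot_delay = 16,
                           response_dispersion = 1,
                           undershoot_dispersion = 1, ratio = 1 / 6) {
  check_positive(response_delay, "response_delay")
  check_positive(undershoot_delay, "undershoot_delay")
  check_positive(response_dispersion, "response_dispersion")
  check_positive(undershoot_dispersion, "undershoot_dispersion")
  check_number(ratio, "ratio", lower = 0)
  structure(
    list(response_delay = response_delay,
         undershoot_delay = undershoot_delay,
         response_dispersion = response_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         ratio = ratio),
    class = "hrf_parameters"
  )
}

#' Sample the two-gamma HRF kernel
#'
#' Evaluates the difference-of-gammas hemodynamic response at a fixed
#' sampling interval and normalizes the kernel so its peak equals 1.
#'
#' @param params An [hrf_parameters()] object.
#' @param dt Sampling interval (seconds, > 0).
#' @param duration Kernel length (seconds).
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...`.
#' @export
#' @examples
#' k <- two_gamma_hrf(hrf_parameters(), dt = 1)
#' which.max(k) # peak near the 6 s response delay
two_gamma_hrf <- function(params = hrf_parameters(), dt, duration = 32) {
  if (!inherits(params, "hrf_parameters")) params <- do.call(hrf_parameters, params)
  check_positive(dt, "dt")
  check_positive(duration, "duration")
  t <- seq(0, duration, by = dt)
  g1 <- dgamma(t, shape = params$response_delay / params$response_dispersion,
               scale = params$response_dispersion)
  g2 <- dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
               scale = params$undershoot_dispersion)
  h <- g1 - params$ratio * g2
  peak <- max(h)
  if (peak <= 0) abort("HRF has a non-positive peak; check parameters.")
  h / peak
}

#' pRF parameters
#'
#' Center coordinates and size of a circular 2D-Gaussian population
#' receptive field, in degrees of visual angle.
#'
#' @param x,y Center of the Gaussian in the visual field (degrees; positive
#'   x rightward, positive y upward).
#' @param sigma Standard deviation of the Gaussian (degrees, > 0).
#' @return An object of class `prf_parameters`.
#' @export
prf_parameters <- function(x, y, sigma) {
  check_number(x, "x")
  check_number(y, "y")
  check_positive(sigma, "sigma")
  structure(list(x = x, y = y, sigma = sigma), class = "prf_parameters")
}

# pRF Gaussian sampled on the movie pixel grid, as a vector over pixels,
# scaled so it integrates to 1 over the continuous plane (overlap with an
# all-ones aperture is then the in-field Gaussian mass)
prf_gaussian <- function(movie, x, y, sigma) {
  gx <- exp(-(movie$px - x)^2 / (2 * sigma^2))
  gy <- exp(-(movie$py - y)^2 / (2 * sigma^2))
  as.vector(outer(gx, gy)) * movie$pixel_scale^2 / (2 * pi * sigma^2)
}

# convolve each column of `neural` (time x k) with kernel, truncated to the
# input length
convolve_hrf <- function(neural, kernel) {
  n <- nrow(neural)
  apply(neural, 2, function(v) {
    convolve(v, rev(kernel), type = "open")[seq_len(n)]
  })
}

#' Predict a BOLD time series from a pRF and an aperture movie
#'
#' The model is linear: the Gaussian pRF is multiplied pointwise by each
#' stimulus contrast-aperture frame and summed over pixels to give a neural
#' drive per TR, which is convolved with the two-gamma HRF and truncated to
#' the movie length. Movies at a finer temporal resolution are first
#' averaged down to TR resolution.
#'
#' @param prf A [prf_parameters()] object (or list with `x`, `y`, `sigma`).
#' @param movie An `aperture_movie`.
#' @param hrf An [hrf_parameters()] object.
#' @return Numeric vector, one predicted value per TR (arbitrary units;
#'   amplitude and baseline are fit separately).
#' @export
predict_timeseries <- function(prf, movie, hrf = hrf_parameters()) {
  if (!inherits(movie, "aperture_movie")) {
    abort("`movie` must be an `aperture_movie`.")
  }
  if (!inherits(prf, "prf_parameters")) prf <- do.call(prf_parameters, prf[c("x", "y", "sigma")])
  if (movie$frame_rate * movie$tr > 1 + 1e-9) {
    movie <- downsample_to_tr(movie)
  }
  g <- prf_gaussian(movie, prf$x, prf$y, prf$sigma)
  neural <- as.vector(crossprod(movie_matrix(movie), g))
  kernel <- two_gamma_hrf(hrf, dt = movie$tr)
  as.vector(convolve_hrf(matrix(neural, ncol = 1), kernel))
}

#' Variance explained of a prediction
#'
#' `1 - RSS/TSS`, with the total sum of squares taken about the data mean,
#' clamped to `[0, 1]`. Zero-variance data yield 0 with attribute
#' `degenerate = TRUE` and a warning.
#'
#' @param pred,data Numeric vectors of equal length.
#' @return Fraction of variance explained in `[0, 1]`.
#' @export
#' @examples
#' variance_explained(c(1, 2, 3), c(1, 2, 3))
variance_explained <- function(pred, data) {
  if (length(pred) != length(data)) {
    abort("`pred` and `data` must have equal length.")
  }
  tss <- sum((data - mean(data))^2)
  if (tss == 0) {
    warn("Zero-variance data; variance explained defined as 0.")
    return(structure(0, degenerate = TRUE))
  }
  r2 <- 1 - sum((data - pred)^2) / tss
  min(max(r2, 0), 1)
}

#' Convert a raw series to percent signal change
#'
#' Divides by the series mean, subtracts 1, and multiplies by 100.
#'
#' @param y Numeric vector with a nonzero mean.
#' @return Percent signal change series.
#' @export
percent_signal_change <- function(y) {
  m <- mean(y)
  if (m == 0) abort("Series mean is zero; cannot convert to percent signal.")
  (y / m - 1) * 100
}

# ---- fitting ---------------------------------------------------------------

# RSS of data against prediction with free non-negative amplitude and free
# baseline; returns list(rss, beta, intercept)
scaled_rss <- function(pred, data) {
  pc <- pred - mean(pred)
  dc <- data - mean(data)
  vp <- sum(pc^2)
  beta <- if (vp > 0) max(0, sum(pc * dc) / vp) else 0
  resid <- dc - beta * pc
  list(rss = sum(resid^2), beta = beta,
       intercept = mean(data) - beta * mean(pred))
}

# average adjacent pairs (boxcar anti-alias) along time
decimate_by_2 <- function(y) {
  n <- 2L * (length(y) %/% 2L)
  y <- y[seq_len(n)]
  (y[seq(1, n, by = 2)] + y[seq(2, n, by = 2)]) / 2
}

#' Search grid for the coarse pRF stage
#'
#' Centers on an `n_xy x n_xy` grid spanning `+/- grid_span` times the field
#' radius, and sizes log-spaced over `sigma_range`.
#'
#' @param field_radius Aperture radius (degrees).
#' @param n_xy Grid points per spatial axis.
#' @param grid_span Spatial half-extent as a multiple of `field_radius`.
#' @param sigma_range Range of Gaussian SDs (degrees).
#' @param n_sigma Number of log-spaced sizes.
#' @return Tibble with columns `x`, `y`, `sigma`.
#' @export
prf_search_grid <- function(field_radius, n_xy = 11, grid_span = 1.25,
                            sigma_range = c(0.1, 6), n_sigma = 10) {
  xs <- seq(-grid_span * field_radius, grid_span * field_radius,
            length.out = n_xy)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_sigma))
  tidyr::expand_grid(x = xs, y = xs, sigma = sigmas)
}

# neural drive courses (n_tr x n_prf) for a table of pRFs
neural_courses <- function(grid, movie) {
  mm <- movie_matrix(movie)
  gmat <- vapply(seq_len(nrow(grid)),
                 function(i) prf_gaussian(movie, grid$x[i], grid$y[i],
                                          grid$sigma[i]),
                 numeric(nrow(mm)))
  crossprod(mm, gmat)
}

# Nelder-Mead over (x, y, log sigma) with box penalties; objective is the
# amplitude/baseline-profiled RSS; never returns a worse point than start
refine_prf <- function(start, data, movie, kernel, bounds, mm) {
  obj <- function(par) {
    x <- par[1]; y <- par[2]; sigma <- exp(par[3])
    if (x < bounds$x[1] || x > bounds$x[2] ||
        y < bounds$y[1] || y > bounds$y[2] ||
        sigma < bounds$sigma[1] || sigma > bounds$sigma[2]) {
      return(1e12)
    }
    g <- prf_gaussian(movie, x, y, sigma)
    neural <- as.vector(crossprod(mm, g))
    pred <- as.vector(convolve_hrf(matrix(neural, ncol = 1), kernel))
    scaled_rss(pred, data)$rss
  }
  p0 <- c(start$x, start$y, log(start$sigma))
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-8))
  if (fit$value <= obj(p0)) {
    list(x = fit$par[1], y = fit$par[2], sigma = exp(fit$par[3]),
         rss = fit$value)
  } else {
    list(x = start$x, y = start$y, sigma = start$sigma, rss = obj(p0))
  }
}

#' Fit pRF models with a multi-stage coarse-to-fine procedure
#'
#' Stage 1 temporally decimates the data by a factor of two (averaging
#' adjacent TR pairs) and brute-force grid-searches the pRF center and size.
#' Stage 2 refines each vertex by a derivative-free local search at full
#' temporal resolution. Stage 3 holds the pRF parameters fixed and fits the
#' five HRF parameters by a search minimizing the error averaged across
#' vertices. Stage 4 refits the pRF parameters with the HRF held fixed.
#' Amplitude and baseline are profiled out by least squares at every step
#' (amplitude constrained non-negative).
#'
#' @param bold BOLD data in percent signal change: a numeric matrix
#'   (TR x vertex), a numeric vector (one vertex), or a long tibble with
#'   columns `vertex`, `t`, `bold`.
#' @param movie An `aperture_movie` (any frame rate; used at TR resolution).
#' @param hrf Starting [hrf_parameters()].
#' @param grid Coarse search grid, as from [prf_search_grid()].
#' @param fit_hrf Run stages 3-4? When `FALSE` the starting HRF is kept.
#' @param hrf_vertices Maximum number of best-fitting vertices used for the
#'   HRF stage.
#' @param r2_min_hrf Minimum stage-2 variance explained for a vertex to
#'   inform the HRF stage.
#' @return An object of class `prf_fit`: list with `fits` (tibble: `vertex`,
#'   `x`, `y`, `sigma`, `r2`, `beta`, `intercept`, `degenerate`), the fitted
#'   `hrf`, per-stage summed RSS in `stages`, and the search `grid` used.
#' @export
fit_prf <- function(bold, movie, hrf = hrf_parameters(),
                    grid = prf_search_grid(movie$field_radius),
                    fit_hrf = TRUE, hrf_vertices = 50, r2_min_hrf = 0.2) {
  if (is.data.frame(bold)) {
    need <- c("vertex", "t", "bold")
    if (!all(need %in% names(bold))) {
      abort("Long-format `bold` needs columns `vertex`, `t`, `bold`.")
    }
    wide <- tidyr::pivot_wider(bold[need], names_from = "vertex",
                               values_from = "bold")
    wide <- wide[order(wide$t), ]
    bold <- as.matrix(wide[, -1, drop = FALSE])
  }
  if (is.vector(bold)) bold <- matrix(bold, ncol = 1)
  movie <- if (movie$frame_rate * movie$tr > 1 + 1e-9) {
    downsample_to_tr(movie)
  } else movie
  n_tr <- dim(movie$frames)[3]
  if (nrow(bold) != n_tr) {
    abort(sprintf("`bold` has %d TRs but the movie has %d.",
                  nrow(bold), n_tr))
  }
  n_vert <- ncol(bold)
  vert_ids <- colnames(bold) %||% as.character(seq_len(n_vert))
  degenerate <- apply(bold, 2, function(v) all(v == 0) || sd(v) == 0)

  R <- movie$field_radius
  bounds <- list(x = c(-1.5 * R, 1.5 * R), y = c(-1.5 * R, 1.5 * R),
                 sigma = c(0.05, 3 * R))

  # stage 1: decimated grid search
  neural <- neural_courses(grid, movie)
  kernel0 <- two_gamma_hrf(hrf, dt = movie$tr)
  preds <- convolve_hrf(neural, kernel0)
  preds_dec <- apply(preds, 2, decimate_by_2)
  bold_dec <- apply(bold, 2, decimate_by_2)
  pc <- sweep(preds_dec, 2, colMeans(preds_dec))
  pnorm2 <- colSums(pc^2)
  stage1 <- integer(n_vert)
  stage1_rss <- numeric(n_vert)
  for (v in seq_len(n_vert)) {
    dc <- bold_dec[, v] - mean(bold_dec[, v])
    num <- as.vector(crossprod(pc, dc))
    beta <- pmax(0, num / pmax(pnorm2, 1e-12))
    rss <- sum(dc^2) - 2 * beta * num + beta^2 * pnorm2
    stage1[v] <- which.min(rss)
    stage1_rss[v] <- min(rss)
  }

  # stage 2: continuous refinement at full resolution
  mm <- movie_matrix(movie)
  run_refine <- function(start_tbl, kernel) {
    purrr::map(seq_len(n_vert), function(v) {
      if (degenerate[v]) {
        return(list(x = 0, y = 0, sigma = 1, rss = 0))
      }
      refine_prf(as.list(start_tbl[v, ]), bold[, v], movie, kernel, bounds,
                 mm)
    })
  }
  start2 <- grid[stage1, ]
  fits2 <- run_refine(start2, kernel0)
  stage2_rss <- map_dbl(fits2, "rss")

  hrf_out <- hrf
  fits_final <- fits2
  stage3_rss <- NA_real_
  stage4_rss <- NA_real_
  if (fit_hrf) {
    # stage 3: HRF search with pRFs fixed, error averaged across vertices
    tss <- apply(bold, 2, function(v) sum((v - mean(v))^2))
    r2_2 <- ifelse(tss > 0, 1 - stage2_rss / tss, 0)
    cand <- order(r2_2, decreasing = TRUE)
    cand <- cand[r2_2[cand] >= r2_min_hrf & !degenerate[cand]]
    cand <- head(cand, hrf_vertices)
    if (length(cand) > 0) {
      fit_tbl <- dplyr::bind_rows(lapply(fits2, function(f) {
        tibble(x = f$x, y = f$y, sigma = f$sigma)
      }))
      neural_fix <- neural_courses(fit_tbl[cand, , drop = FALSE], movie)
      tss_cand <- tss[cand]
      hrf_obj <- function(par) {
        if (any(par[1:4] <= 0) || par[5] < 0) return(1e12)
        p <- hrf_parameters(par[1], par[2], par[3], par[4], par[5])
        k <- tryCatch(two_gamma_hrf(p, dt = movie$tr),
                      error = function(e) NULL)
        if (is.null(k)) return(1e12)
        pr <- convolve_hrf(neural_fix, k)
        err <- vapply(seq_along(cand), function(i) {
          scaled_rss(pr[, i], bold[, cand[i]])$rss / tss_cand[i]
        }, numeric(1))
        mean(err)
      }
      p0 <- unlist(hrf, use.names = FALSE)
      hfit <- optim(p0, hrf_obj, method = "Nelder-Mead",
                    control = list(maxit = 400, reltol = 1e-8))
      if (hfit$value <= hrf_obj(p0)) {
        hrf_out <- hrf_parameters(hfit$par[1], hfit$par[2], hfit$par[3],
                                  hfit$par[4], hfit$par[5])
      }
      stage3_rss <- min(hfit$value, hrf_obj(p0))
      # stage 4: refit pRFs with the fitted HRF fixed
      kernel4 <- two_gamma_hrf(hrf_out, dt = movie$tr)
      start4 <- dplyr::bind_rows(lapply(fits2, function(f) {
        tibble(x = f$x, y = f$y, sigma = f$sigma)
      }))
      fits_final <- run_refine(start4, kernel4)
      stage4_rss <- sum(map_dbl(fits_final, "rss")[!degenerate])
    }
  }

  kernel_final <- two_gamma_hrf(hrf_out, dt = movie$tr)
  rows <- purrr::imap(fits_final, function(f, v) {
    if (degenerate[v]) {
      return(tibble(vertex = vert_ids[v], x = NA_real_, y = NA_real_,
                    sigma = NA_real_, r2 = 0, beta = 0, intercept = 0,
                    degenerate = TRUE))
    }
    g <- prf_gaussian(movie, f$x, f$y, f$sigma)
    neural_v <- as.vector(crossprod(mm, g))
    pred <- as.vector(convolve_hrf(matrix(neural_v, ncol = 1), kernel_final))
    sc <- scaled_rss(pred, bold[, v])
    r2 <- variance_explained(sc$beta * pred + sc$intercept, bold[, v])
    tibble(vertex = vert_ids[v], x = f$x, y = f$y, sigma = f$sigma,
           r2 = as.numeric(r2), beta = sc$beta, intercept = sc$intercept,
           degenerate = FALSE)
  })
  structure(
    list(fits = dplyr::bind_rows(rows), hrf = hrf_out,
         stages = tibble(
           stage = c("grid", "refine", "hrf", "final"),
           objective = c(sum(stage1_rss[!degenerate]),
                         sum(stage2_rss[!degenerate]),
                         stage3_rss, stage4_rss)),
         grid = grid, movie_tr = movie$tr, n_tr = n_tr),
    class = "prf_fit"
  )
}

#' @export
print.prf_fit <- function(x, ...) {
  cat(sprintf("<prf_fit> %d vertices, %d TRs, median R2 = %.3f\n",
              nrow(x$fits), x$n_tr, median(x$fits$r2)))
  invisible(x)
}

#' @rdname fit_prf
#' @param x A `prf_fit` object.
#' @param ... Unused.
#' @export
tidy.prf_fit <- function(x, ...) x$fits

#' @rdname fit_prf
#' @export
glance.prf_fit <- function(x, ...) {
  tibble(n_vertices = nrow(x$fits), n_tr = x$n_tr,
         median_r2 = median(x$fits$r2),
         n_degenerate = sum(x$fits$degenerate),
         hrf_response_delay = x$hrf$response_delay,
         hrf_undershoot_delay = x$hrf$undershoot_delay,
         hrf_ratio = x$hrf$ratio)
}
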