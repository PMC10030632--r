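test_that("two-gamma HRF has the right shape and normalization", {
  k <- two_gamma_hrf(hrf_parameters(), dt = 0.1)
  expect_equal(max(k), 1)
  # default parameters: exactly one sign change (positive lobe, then
  # undershoot), peak near the 6 s response delay
  signs <- sign(k[k != 0])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_equal((which.max(k) - 1) * 0.1, 6, tolerance = 0.3)
  # no undershoot when the amplitude ratio is 0
  k0 <- two_gamma_hrf(hrf_parameters(ratio = 0), dt = 0.1)
  expect_true(all(k0 >= 0))
  # closed-form oracle: normalized difference of gamma densities
  p <- hrf_parameters(5, 12, 0.9, 1.1, 0.4)
  t <- seq(0, 32, by = 0.1)
  want <- dgamma(t, shape = 5 / 0.9, scale = 0.9) -
    0.4 * dgamma(t, shape = 12 / 1.1, scale = 1.1)
  expect_equal(two_gamma_hrf(p, dt = 0.1), want / max(want))
  expect_error(two_gamma_hrf(hrf_parameters(response_dispersion = -1),
                             dt = 0.1))
})

test_that("predictions behave at the edges of the stimulated field", {
  mov <- small_movie_tr()
  # pRF far outside the 7-degree aperture drives nothing
  far <- predict_timeseries(list(x = 20, y = 0, sigma = 0.5), mov)
  expect_lt(max(abs(far)), 1e-8)
  # constant full-field drive gives a constant prediction after the
  # HRF transient
  const <- mov
  const$frames <- array(1, dim = dim(mov$frames))
  pred <- predict_timeseries(list(x = 1, y = -2, sigma = 2), const)
  settled <- pred[20:length(pred)]
  expect_lt(diff(range(settled)) / mean(settled), 1e-6)
  expect_error(predict_timeseries(list(x = 0, y = 0, sigma = -1), mov),
               "positive")
})

test_that("a huge pRF tracks per-frame aperture area (overlap oracle)", {
  mov <- small_movie_tr()
  pred <- predict_timeseries(list(x = 0, y = 0, sigma = 10), mov)
  # independent oracle: per-frame Gaussian-weighted aperture integral,
  # computed directly from the frames, convolved with the same kernel
  gx <- exp(-mov$px^2 / (2 * 10^2))
  w <- outer(gx, gx) * mov$pixel_scale^2 / (2 * pi * 10^2)
  drive <- apply(mov$frames, 3, function(f) sum(f * w))
  kernel <- two_gamma_hrf(hrf_parameters(), dt = mov$tr)
  want <- stats::convolve(drive, rev(kernel),
                          type = "open")[seq_along(drive)]
  expect_equal(pred, want, tolerance = 1e-10)
})

test_that("the forward model is linear in disjoint apertures", {
  mov <- small_movie_tr()
  a <- mov; b <- mov
  n <- dim(mov$frames)[3]
  half <- seq_len(n %/% 2)
  a$frames[, , -half] <- 0
  b$frames[, , half] <- 0
  prf <- list(x = 1, y = 1, sigma = 1.5)
  expect_equal(predict_timeseries(prf, a) + predict_timeseries(prf, b),
               predict_timeseries(prf, mov), tolerance = 1e-12)
})

test_that("variance explained follows the RSS/TSS decomposition", {
  y <- sin(seq(0, 6 * pi, length.out = 96))
  expect_equal(variance_explained(y, y), 1)
  expect_equal(variance_explained(rep(mean(y), 96), y), 0)
  # orthogonal noise at half the signal SD gives exactly R^2 = 0.8
  set.seed(11)
  e <- rnorm(96)
  e <- e - mean(e)
  yc <- y - mean(y)
  e <- e - sum(e * yc) / sum(yc^2) * yc # orthogonalize
  e <- e * (sd(y) / 2) / sd(e)
  expect_equal(variance_explained(y, y + e), 0.8, tolerance = 1e-12)
  expect_warning(r <- variance_explained(rep(1, 5), rep(2, 5)),
                 "Zero-variance")
  expect_equal(as.numeric(r), 0)
})

test_that("noiseless fits recover distinct ground truths without swapping", {
  mov <- fit_movie_tr()
  truths <- list(list(x = 2, y = 1, sigma = 1),
                 list(x = -3, y = -2, sigma = 0.6))
  bold <- sapply(truths, predict_timeseries, movie = mov)
  fit <- fit_prf(bold, mov, fit_hrf = FALSE)
  for (i in 1:2) {
    expect_equal(fit$fits$x[i], truths[[i]]$x, tolerance = 0.01)
    expect_equal(fit$fits$y[i], truths[[i]]$y, tolerance = 0.01)
    expect_equal(fit$fits$sigma[i], truths[[i]]$sigma, tolerance = 0.01)
    expect_gt(fit$fits$r2[i], 0.999)
  }
  # stage monotonicity on the shared objective: the continuous refinement
  # never does worse than its grid-search start
  expect_lte(fit$stages$objective[2], fit$stages$objective[1])
})

test_that("HRF stages recover a non-default generating HRF", {
  mov <- fit_movie_tr()
  true_hrf <- hrf_parameters(response_delay = 5.5, undershoot_delay = 14,
                             ratio = 0.35)
  set.seed(2)
  prfs <- tibble::tibble(x = runif(6, -4, 4), y = runif(6, -4, 4),
                         sigma = runif(6, 0.5, 2))
  bold <- sapply(seq_len(6), function(i) {
    predict_timeseries(as.list(prfs[i, ]), mov, true_hrf)
  })
  fit <- fit_prf(bold, mov, fit_hrf = TRUE)
  expect_gt(min(fit$fits$r2), 0.99)
  expect_equal(fit$hrf$response_delay, 5.5, tolerance = 0.2)
  expect_equal(fit$hrf$ratio, 0.35, tolerance = 0.2)
  expect_equal(fit$fits$x, prfs$x, tolerance = 0.02)
})

test_that("degenerate and pure-noise data stay below the map threshold", {
  mov <- small_movie_tr()
  zero <- matrix(0, nrow = dim(mov$frames)[3], ncol = 1)
  fit0 <- fit_prf(zero, mov, fit_hrf = FALSE)
  expect_true(fit0$fits$degenerate[1])
  expect_equal(fit0$fits$r2[1], 0)
  # seeded pure-noise vertices: fitted variance explained stays below the
  # 0.10 delineation threshold in > 95% of replicates
  set.seed(9)
  noise <- matrix(rnorm(dim(mov$frames)[3] * 60), ncol = 60)
  fit <- fit_prf(noise, mov, fit_hrf = FALSE)
  expect_gt(mean(fit$fits$r2 < 0.10), 0.95)
})

test_that("prf_fit tidiers expose fits and fit summary", {
  mov <- small_movie_tr()
  pred <- predict_timeseries(list(x = 0, y = 2, sigma = 1), mov)
  fit <- fit_prf(pred, mov, fit_hrf = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("vertex", "x", "y", "sigma", "r2", "beta",
                     "intercept", "degenerate"))
  gl <- glance(fit)
  expect_equal(gl$n_vertices, 1)
  expect_gt(gl$median_r2, 0.99)
})
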