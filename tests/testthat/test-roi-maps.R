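test_that("reversal detection finds the constructed boundaries exactly", {
  h <- fixture("rev_hemi", function() {
    build_hemisphere(ground_truth_config(mesh_density = 3000), "left")
  })
  gt <- ground_truth_boundaries(h)
  rev <- detect_reversals(h$retinotopy, h$mesh)
  g <- cortmag:::mesh_graph(h$mesh)
  check_close <- function(detected, reference, max_rings = 2) {
    d <- igraph::distances(g, v = detected, to = reference, weights = NA)
    expect_lte(max(apply(d, 1, min)), max_rings) # precision
    expect_lte(max(apply(d, 2, min)), max_rings) # recall
  }
  check_close(rev$vertex[rev$meridian == "lower_vertical"],
              gt$vertex[gt$boundary == "v1_v2_dorsal"])
  check_close(rev$vertex[rev$meridian == "upper_vertical"],
              gt$vertex[gt$boundary == "v1_v2_ventral"])
  check_close(rev$vertex[rev$meridian == "horizontal"],
              gt$vertex[grepl("v2_v3", gt$boundary)])
})

test_that("reversal detection survives noise below the reversal contrast", {
  h <- fixture("rev_hemi", function() {
    build_hemisphere(ground_truth_config(mesh_density = 3000), "left")
  })
  gt <- ground_truth_boundaries(h)
  g <- cortmag:::mesh_graph(h$mesh)
  # 4-degree angular noise: after cleaning, residual noise sits below the
  # row-to-row elevation contrast of this mesh, the regime in which the
  # reversal ridge is identifiable
  for (seed in c(5, 23)) {
    noisy <- clean_angles(perturb_retinotopy(h$retinotopy, angle_sd = 4,
                                             seed = seed), h$mesh)
    rev <- detect_reversals(noisy, h$mesh)
    for (pair in list(c("lower_vertical", "v1_v2_dorsal"),
                      c("upper_vertical", "v1_v2_ventral"))) {
      det <- rev$vertex[rev$meridian == pair[1]]
      ref <- gt$vertex[gt$boundary == pair[2]]
      d <- igraph::distances(g, v = det, to = ref, weights = NA)
      expect_gt(mean(apply(d, 1, min) <= 2), 0.9) # precision
      expect_lte(max(apply(d, 2, min)), 5)        # recall
    }
  }
})

test_that("an empty map below threshold yields an empty diagnostic result", {
  h <- fixture("rev_hemi", function() {
    build_hemisphere(ground_truth_config(mesh_density = 3000), "left")
  })
  low <- h$retinotopy
  low$r2 <- 0.05
  expect_message(out <- detect_reversals(low, h$mesh), "No vertices")
  expect_equal(nrow(out), 0)
})

test_that("surface areas are conserved and additive over windows", {
  h <- sym_left()
  all_v <- h$mesh$vertices$vertex
  expect_equal(map_surface_area(h$mesh, all_v),
               sum(h$mesh$vertices$area_midgray))
  v1 <- v1_of(h)
  a1 <- map_surface_area(h$mesh, v1, retinotopy = h$retinotopy,
                         ecc_window = c(0, 3))
  a2 <- map_surface_area(h$mesh, v1, retinotopy = h$retinotopy,
                         ecc_window = c(3 + 1e-12, 7))
  a12 <- map_surface_area(h$mesh, v1, retinotopy = h$retinotopy,
                          ecc_window = c(0, 7))
  expect_equal(a1 + a2, a12)
  expect_gt(a1, 0)
  expect_error(map_surface_area(h$mesh, v1, depth = "nope"), "depth")
  expect_error(map_surface_area(h$mesh, integer()), "empty")
})

test_that("coefficient of variation matches hand arithmetic", {
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(13)
  x <- rlnorm(40, 0, 0.2)
  expect_equal(coefficient_of_variation(3 * x),
               coefficient_of_variation(x)) # scale invariance
  expect_error(coefficient_of_variation(c(-2, 1)), "positive")
  expect_error(coefficient_of_variation(1), "at least 2")
})

test_that("CV estimates from n = 25 concentrate near the true value", {
  # lognormal with CV 0.2: sdlog = sqrt(log(1 + 0.2^2))
  sdlog <- sqrt(log(1 + 0.04))
  set.seed(17)
  cvs <- replicate(300, coefficient_of_variation(rlnorm(25, 0, sdlog)))
  expect_gt(mean(cvs >= 0.13 & cvs <= 0.27), 0.90)
})

test_that("group-mean bootstrap reports exact and covering intervals", {
  b <- c(100, 100, 100)
  a <- b * 1.055
  out <- group_mean_bootstrap(a, b, n_boot = 200, seed = 1)
  expect_equal(out$pct_diff, 5.5)
  expect_equal(out$conf_low, 5.5)
  expect_equal(out$conf_high, 5.5)
  same <- group_mean_bootstrap(c(1, 2, 3, 4), c(1, 2, 3, 4), seed = 2)
  expect_lte(same$conf_low, 0)
  expect_gte(same$conf_high, 0)
  # reproducibility
  r1 <- group_mean_bootstrap(rnorm(10, 10), rnorm(10, 9), seed = 3)
  r2 <- group_mean_bootstrap(rnorm(10, 10), rnorm(10, 9), seed = 3)
  expect_false(identical(r1$conf_low, r2$conf_low)) # different data
  x <- rnorm(10, 10); y <- rnorm(10, 9)
  expect_identical(group_mean_bootstrap(x, y, seed = 4),
                   group_mean_bootstrap(x, y, seed = 4))
})

test_that("bootstrap CI covers a known mean offset at the nominal rate", {
  set.seed(19)
  hits <- replicate(120, {
    b <- rnorm(25, 100, 20)
    a <- rnorm(25, 105, 21)
    out <- group_mean_bootstrap(a, b, n_boot = 300,
                                seed = sample.int(1e6, 1))
    out$conf_low <= 5 && out$conf_high >= 5
  })
  expect_gt(mean(hits), 0.85)
})
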