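#' Configuration for a full synthetic-study run
#'
#' Describes a two-group (or any number of groups) simulated study: each
#' group injects its own HVA/VMA asymmetry into the synthetic hemispheres,
#' subjects vary in overall map scale and in measurement noise, and the
#' wedge-ROI analysis recovers per-subject meridian areas and asymmetry
#' indices.
#'
#' @param groups Named list; each element a list with `n_subjects`,
#'   `hva_amp`, `vma_amp`.
#' @param seed Global integer seed; all per-subject randomness derives from
#'   it.
#' @param mesh_density Vertices per hemisphere.
#' @param ecc_range Map eccentricity extent (degrees).
#' @param scale_cv Between-subject coefficient of variation of the map
#'   scale constant (lognormal jitter of `hh_scale`).
#' @param angle_noise_sd Per-vertex polar-angle measurement noise SD
#'   (degrees) applied before map cleaning.
#' @param r2_shape Beta shape parameters of simulated variance explained.
#' @param index_width Wedge half-width defining the asymmetry indices.
#' @param widths Wedge half-widths measured per subject.
#' @param clean Logical; run [clean_angles()] before the wedge analysis.
#' @param ... Further arguments passed to [ground_truth_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = list(
                              adult_like = list(n_subjects = 10,
                                                hva_amp = 80, vma_amp = 52),
                              child_like = list(n_subjects = 10,
                                                hva_amp = 80, vma_amp = 0)),
                            seed = 1L, mesh_density = 4000,
                            ecc_range = c(0, 8), scale_cv = 0.1,
                            angle_noise_sd = 10, r2_shape = c(6, 4),
                            index_width = 25,
                            widths = c(15, 25, 35, 45, 55),
                            clean = TRUE, ...) {
  if (length(groups) == 0 ||
      any(vapply(groups, function(g) g$n_subjects, numeric(1)) < 1)) {
    abort("Every group needs at least one subject.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list.")
  }
  structure(
    list(groups = groups, seed = as.integer(seed),
         mesh_density = mesh_density, ecc_range = ecc_range,
         scale_cv = scale_cv, angle_noise_sd = angle_noise_sd,
         r2_shape = r2_shape, index_width = index_width, widths = widths,
         clean = clean, gt_args = list(...)),
    class = "pipeline_config"
  )
}

# simulate + analyze one subject; returns indices and the area table
simulate_subject <- function(config, group, subject_seed) {
  g <- config$groups[[group]]
  jitter <- withr::with_seed(subject_seed, {
    exp(rnorm(1, -config$scale_cv^2 / 2, config$scale_cv))
  })
  gt <- do.call(ground_truth_config, c(
    list(hh_scale = 17.3 * jitter, ecc_range = config$ecc_range,
         hva_amp = g$hva_amp, vma_amp = g$vma_amp,
         mesh_density = config$mesh_density),
    config$gt_args))
  subject <- build_subject(gt)
  for (h in c("left", "right")) {
    ret <- perturb_retinotopy(subject[[h]]$retinotopy,
                              angle_sd = config$angle_noise_sd,
                              r2_shape = config$r2_shape,
                              seed = subject_seed + match(h, c("left",
                                                               "right")))
    # band windows use the noise-free eccentricities (template-denoised
    # eccentricity stand-in); angles carry the measurement noise
    ret$ecc <- subject[[h]]$retinotopy$ecc
    if (config$clean) {
      ret <- clean_angles(ret, subject[[h]]$mesh)
    }
    subject[[h]]$retinotopy <- ret
  }
  cfg <- wedge_config(widths = config$widths)
  areas <- meridian_surface_areas(subject, config$widths, cfg)
  idx <- asymmetry_indices(areas, config$index_width)
  list(areas = areas, indices = idx)
}

#' Run the full synthetic study pipeline
#'
#' Builds every subject's hemispheres with the group's injected
#' asymmetries, adds measurement noise, cleans the polar-angle maps, runs
#' the wedge-ROI analysis, computes per-subject HVA/VMA indices, and
#' compares the groups with pooled-variance t-tests. Deterministic for a
#' fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `subjects`
#'   (per-subject indices), `areas` (per-subject meridian area table),
#'   `group_summary`, `tests` (HVA and VMA group t-tests when two or more
#'   groups), `manifest`, and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by `pipeline_config()`.")
  }
  plan <- purrr::imap(config$groups, function(g, label) {
    tibble(group = label, subject = seq_len(g$n_subjects))
  }) |> dplyr::bind_rows()
  seeds <- withr::with_seed(config$seed, {
    sample.int(.Machine$integer.max - 10L, nrow(plan))
  })
  plan$subject_seed <- seeds
  runs <- purrr::pmap(plan, function(group, subject, subject_seed) {
    simulate_subject(config, group, subject_seed)
  })
  subjects <- purrr::map2(runs, seq_len(nrow(plan)), function(r, i) {
    dplyr::bind_cols(plan[i, c("group", "subject")], r$indices)
  }) |> dplyr::bind_rows()
  areas <- purrr::map2(runs, seq_len(nrow(plan)), function(r, i) {
    dplyr::bind_cols(plan[i, c("group", "subject")], r$areas)
  }) |> dplyr::bind_rows()
  group_summary <- subjects |>
    group_by(.data$group) |>
    summarise(n = n(), mean_hva = mean(.data$hva), sd_hva = sd(.data$hva),
              mean_vma = mean(.data$vma), sd_vma = sd(.data$vma),
              .groups = "drop")
  tests <- NULL
  if (length(config$groups) >= 2) {
    labs <- names(config$groups)[1:2]
    g1 <- subjects[subjects$group == labs[1], ]
    g2 <- subjects[subjects$group == labs[2], ]
    tests <- dplyr::bind_rows(
      dplyr::bind_cols(tibble(index = "hva"),
                       group_ttest(g1$hva, g2$hva)),
      dplyr::bind_cols(tibble(index = "vma"),
                       group_ttest(g1$vma, g2$vma))
    )
    tests$contrast <- paste(labs[1], "vs", labs[2])
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cortmag")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    subjects_hash = rlang::hash(subjects),
    areas_hash = rlang::hash(areas)
  )
  structure(list(subjects = subjects, areas = areas,
                 group_summary = group_summary, tests = tests,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects in %d group(s), seed %d\n",
              nrow(x$subjects), length(x$config$groups), x$config$seed))
  print(x$group_summary)
  if (!is.null(x$tests)) {
    cat("Group comparisons:\n")
    print(x$tests[, c("index", "t", "df", "p", "cohens_d")])
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @export
tidy.pipeline_result <- function(x, ...) x$subjects

#' @rdname run_pipeline
#' @export
glance.pipeline_result <- function(x, ...) {
  out <- tibble(n_subjects = nrow(x$subjects),
                n_groups = length(x$config$groups),
                seed = x$config$seed)
  if (!is.null(x$tests)) {
    out$p_hva <- x$tests$p[x$tests$index == "hva"]
    out$p_vma <- x$tests$p[x$tests$index == "vma"]
  }
  out
}

#' Write deterministic fixture files for examples and tests
#'
#' `tiny` writes one small synthetic subject (mesh and retinotopy CSVs, a
#' motion-confound table, and a coarse aperture movie as NIfTI + JSON);
#' `paper_scale` additionally runs the two-group pipeline (10 subjects per
#' group) and writes its per-subject index table and group tests.
#'
#' @param preset `"tiny"` or `"paper_scale"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a character vector of the written file paths.
#' @export
generate_fixtures <- function(preset = c("tiny", "paper_scale"), seed = 1L,
                              dir = tempfile("cortmag-fixtures-")) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  gt <- ground_truth_config(mesh_density = 2000, hva_amp = 80,
                            vma_amp = 52)
  hemi <- build_hemisphere(gt, "left")
  p_mesh <- file.path(dir, "tiny_lh_mesh_vertices.csv")
  readr::write_csv(hemi$mesh$vertices, p_mesh)
  p_ret <- file.path(dir, "tiny_lh_retinotopy.csv")
  readr::write_csv(hemi$retinotopy, p_ret)
  motion <- simulate_motion(96, spike_frames = c(20, 60), spike_mm = 0.6,
                            jitter_sd = 0.01, seed = seed)
  p_mot <- file.path(dir, "tiny_motion.tsv")
  readr::write_tsv(motion[, -1], p_mot, col_names = FALSE)
  movie <- make_bar_aperture(aperture_config(grid_resolution = 31,
                                             n_volumes = 96))
  p_mov <- file.path(dir, "tiny_aperture.nii.gz")
  write_aperture_nifti(movie, p_mov)
  paths <- c(p_mesh, p_ret, p_mot, p_mov, paste0(p_mov, ".json"))
  if (preset == "paper_scale") {
    res <- run_pipeline(pipeline_config(seed = seed))
    p_sub <- file.path(dir, "group_indices.csv")
    readr::write_csv(res$subjects, p_sub)
    p_tests <- file.path(dir, "group_tests.csv")
    readr::write_csv(res$tests, p_tests)
    p_json <- file.path(dir, "group_summary.json")
    jsonlite::write_json(list(group_summary = res$group_summary,
                              tests = res$tests,
                              manifest = res$manifest),
                         p_json, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_sub, p_tests, p_json)
  }
  invisible(paths)
}
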