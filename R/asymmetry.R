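#' Horizontal-vertical asymmetry (HVA) index
#'
#' `(horizontal - vertical) / mean(horizontal, vertical) * 100`: the
#' mean-normalized percent difference between the V1 surface area
#' representing the horizontal and the vertical meridian. 0 means no
#' asymmetry; positive values mean more area for the horizontal meridian.
#' Bounded in (-200, 200) for positive areas.
#'
#' @param horizontal,vertical Surface areas (mm^2, > 0); vectorized.
#' @return Unitless index.
#' @export
#' @examples
#' hva_index(200, 100)
hva_index <- function(horizontal, vertical) {
  if (any(horizontal <= 0) || any(vertical <= 0)) {
    abort("Areas must be positive.")
  }
  (horizontal - vertical) / ((horizontal + vertical) / 2) * 100
}

#' Vertical-meridian asymmetry (VMA) index
#'
#' `(lower - upper) / mean(lower, upper) * 100`: the mean-normalized
#' percent difference between the V1 surface area representing the lower
#' and the upper vertical meridian. Negative values indicate an inverted
#' VMA (more area for the upper vertical meridian).
#'
#' @param lower,upper Surface areas (mm^2, > 0); vectorized.
#' @return Unitless index.
#' @export
#' @examples
#' vma_index(80, 120)
vma_index <- function(lower, upper) {
  if (any(lower <= 0) || any(upper <= 0)) abort("Areas must be positive.")
  (lower - upper) / ((lower + upper) / 2) * 100
}

#' Asymmetry indices from a meridian surface-area table
#'
#' @param areas Tibble from [meridian_surface_areas()].
#' @param width Wedge half-width at which the indices are computed
#'   (default 25 degrees, the index-defining wedge).
#' @return Tibble with `half_width`, `horizontal`, `vertical`,
#'   `lower_vertical`, `upper_vertical`, `hva`, `vma`.
#' @export
asymmetry_indices <- function(areas, width = 25) {
  w <- areas[areas$half_width == width, ]
  if (nrow(w) == 0) abort("Requested width not present in `areas`.")
  get <- function(m) w$area[w$meridian == m]
  tibble(half_width = width,
         horizontal = get("horizontal"), vertical = get("vertical"),
         lower_vertical = get("lower_vertical"),
         upper_vertical = get("upper_vertical"),
         hva = hva_index(get("horizontal"), get("vertical")),
         vma = vma_index(get("lower_vertical"), get("upper_vertical")))
}

#' Bootstrapped linear fit of wedge area against wedge width
#'
#' Resamples subjects with replacement; for each resample fits a
#' least-squares line to the group-mean area as a function of wedge width,
#' and reports the pointwise mean fit with a percentile band (default the
#' 16th-84th percentiles, a 68% interval).
#'
#' @param data Tibble with columns `subject`, `half_width`, `area`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (fixed seeds give identical bands).
#' @param conf Band coverage (default 0.68).
#' @return Object of class `wedge_fit`: list with `band` (tibble:
#'   `half_width`, `mean_area`, `fit`, `conf_low`, `conf_high`), `slopes`
#'   (bootstrap slope draws), `n_subjects`, `n_boot`.
#' @export
bootstrap_linear_fit <- function(data, n_boot = 10000, seed = 1L,
                                 conf = 0.68) {
  need <- c("subject", "half_width", "area")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns subject, half_width, area.")
  }
  subs <- unique(data$subject)
  widths <- sort(unique(data$half_width))
  if (length(widths) < 2) abort("Need at least 2 widths.")
  if (length(subs) < 3) abort("Need at least 3 subjects.")
  # subject x width matrix of areas
  m <- tapply(data$area, list(data$subject, data$half_width), mean)
  m <- m[match(subs, rownames(m)), as.character(widths), drop = FALSE]
  X <- cbind(1, widths)
  XtXinvXt <- solve(crossprod(X), t(X))
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(length(subs), replace = TRUE)
      ybar <- colMeans(m[take, , drop = FALSE])
      as.numeric(XtXinvXt %*% ybar) # intercept, slope
    }, numeric(2))
  })
  fits <- X %*% draws # width x n_boot fitted lines
  alpha <- (1 - conf) / 2
  band <- tibble(
    half_width = widths,
    mean_area = colMeans(m),
    fit = rowMeans(fits),
    conf_low = apply(fits, 1, quantile, alpha, names = FALSE),
    conf_high = apply(fits, 1, quantile, 1 - alpha, names = FALSE)
  )
  structure(list(band = band, slopes = draws[2, ],
                 intercepts = draws[1, ], n_subjects = length(subs),
                 n_boot = n_boot, conf = conf),
            class = "wedge_fit")
}

#' @export
print.wedge_fit <- function(x, ...) {
  cat(sprintf(
    "<wedge_fit> %d subjects, %d bootstraps, slope %.2f [%.2f, %.2f]\n",
    x$n_subjects, x$n_boot, mean(x$slopes),
    quantile(x$slopes, (1 - x$conf) / 2),
    quantile(x$slopes, 1 - (1 - x$conf) / 2)))
  invisible(x)
}

#' @rdname bootstrap_linear_fit
#' @param x A `wedge_fit` object.
#' @param ... Unused.
#' @export
tidy.wedge_fit <- function(x, ...) x$band

#' @rdname bootstrap_linear_fit
#' @export
glance.wedge_fit <- function(x, ...) {
  alpha <- (1 - x$conf) / 2
  tibble(slope = mean(x$slopes),
         slope_low = quantile(x$slopes, alpha, names = FALSE),
         slope_high = quantile(x$slopes, 1 - alpha, names = FALSE),
         n_subjects = x$n_subjects, n_boot = x$n_boot)
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Two-tailed independent-samples t-test assuming homogeneity of variance
#' (`df = n_a + n_b - 2`), with the standardized mean difference
#' `d = (mean_a - mean_b) / pooled SD` and a confidence interval on the
#' mean difference.
#'
#' @param a,b Numeric vectors of per-subject indices.
#' @param conf Confidence level.
#' @return Tibble with `estimate` (mean difference a - b), `t`, `df`, `p`,
#'   `cohens_d`, `conf_low`, `conf_high`, `n_a`, `n_b`.
#' @export
#' @examples
#' group_ttest(c(1, 2, 3), c(4, 5, 6))
group_ttest <- function(a, b, conf = 0.95) {
  na <- length(a); nb <- length(b)
  if (na + nb < 4 || na < 2 || nb < 2) {
    abort("Need at least 2 observations per group and 4 in total.")
  }
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (sp2 == 0) abort("Zero pooled variance.")
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  est <- mean(a) - mean(b)
  tval <- est / se
  p <- 2 * pt(-abs(tval), df)
  crit <- qt(1 - (1 - conf) / 2, df)
  tibble(estimate = est, t = tval, df = df, p = p,
         cohens_d = est / sqrt(sp2),
         conf_low = est - crit * se, conf_high = est + crit * se,
         n_a = na, n_b = nb)
}
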