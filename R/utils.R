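# internal validation helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                  name, x, lower, upper))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

# circular helpers: angles in degrees, convention 0 = right horizontal,
# 90 = upper vertical, counterclockwise, stored in [0, 360)
wrap_angle <- function(theta) theta %% 360

# signed angular difference a - b in (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(x) x * pi / 180

# weighted circular mean of angles (degrees)
circ_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(deg2rad(theta)))
  c_ <- sum(w * cos(deg2rad(theta)))
  wrap_angle(atan2(s, c_) * 180 / pi)
}
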