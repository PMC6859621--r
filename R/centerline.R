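# Smoothed centerlines and the tortuosity metrics computed from them.

#' Smooth a centerline chain with a penalized cubic spline
#'
#' Fits `x(u)` and `y(u)` independently with cubic smoothing splines, where
#' `u` is chordal arc length normalized to \[0, 1\], using the given penalty
#' weight on the integrated squared second derivative. The fitted curve is
#' resampled at approximately 1 px arc-length steps; tangent angle
#' `theta(s)` and signed curvature `kappa(s)` come from the first and second
#' spline derivatives. Because both coordinates use the same linear
#' smoother, the fit is exactly equivariant under rigid transformations.
#'
#' @param chain A tibble/data frame with columns `x`, `y` (ordered points),
#'   at least 4 distinct points.
#' @param regularization Smoothing penalty weight on the unit-normalized
#'   arclength domain (default `3e-5`).
#' @param step Resampling step in pixels.
#' @return An object of class `oxy_centerline`: list with `points` (tibble
#'   `s`, `x`, `y`, `theta` degrees, `kappa` 1/px), `la` (arc length, px),
#'   `lc` (chord length, px), `chord_angle` (degrees).
#' @export
smooth_centerline <- function(chain, regularization = 3e-5, step = 1) {
  chain <- as.data.frame(chain)
  dup <- c(FALSE, diff(chain$x) == 0 & diff(chain$y) == 0)
  chain <- chain[!dup, ]
  n <- nrow(chain)
  if (n < 4) {
    abort("Centerline needs at least 4 distinct points.",
          class = "oxy_too_short")
  }
  s <- c(0, cumsum(sqrt(diff(chain$x)^2 + diff(chain$y)^2)))
  u <- s / s[n]
  fx <- smooth.spline(u, chain$x, lambda = regularization, all.knots = TRUE)
  fy <- smooth.spline(u, chain$y, lambda = regularization, all.knots = TRUE)

  # dense arclength table, then resample uniformly in arc length
  ug <- seq(0, 1, length.out = max(6 * n, 240))
  xg <- predict(fx, ug)$y
  yg <- predict(fy, ug)$y
  sg <- c(0, cumsum(sqrt(diff(xg)^2 + diff(yg)^2)))
  la <- sg[length(sg)]
  s_out <- seq(0, la, length.out = max(ceiling(la / step) + 1, 8))
  u_out <- approx(sg, ug, xout = s_out, ties = "ordered")$y

  x0 <- predict(fx, u_out)$y
  y0 <- predict(fy, u_out)$y
  dx <- predict(fx, u_out, deriv = 1)$y
  dy <- predict(fy, u_out, deriv = 1)$y
  ddx <- predict(fx, u_out, deriv = 2)$y
  ddy <- predict(fy, u_out, deriv = 2)$y
  theta <- atan2(dy, dx) * 180 / pi
  kappa <- (dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5

  lc <- sqrt((x0[length(x0)] - x0[1])^2 + (y0[length(y0)] - y0[1])^2)
  if (!(lc > 0)) abort("Degenerate centerline: zero chord length.")
  structure(
    list(
      points = tibble(s = s_out, x = x0, y = y0, theta = theta,
                      kappa = kappa),
      la = la, lc = lc,
      chord_angle = atan2(y0[length(y0)] - y0[1],
                          x0[length(x0)] - x0[1]) * 180 / pi,
      regularization = regularization
    ),
    class = "oxy_centerline"
  )
}

#' @export
print.oxy_centerline <- function(x, ...) {
  cat(sprintf(
    "<oxy_centerline> %d points, arc %.1f px, chord %.1f px\n",
    nrow(x$points), x$la, x$lc))
  invisible(x)
}

#' Count critical points of a centerline
#'
#' Critical points are locations where the first derivative of the
#' centerline vanishes. The curve is rotated so its chord lies along the
#' +x axis (which makes the count invariant to rigid transformations) and
#' the number of sign changes of dy/ds along the rotated curve is counted;
#' zeros touched without crossing are not counted.
#'
#' @param centerline An `oxy_centerline`.
#' @param eps Values of |dy/ds| below this are treated as exactly zero, so
#'   numerically straight segments yield zero critical points.
#' @return Integer count `N`.
#' @export
count_critical_points <- function(centerline, eps = 1e-6) {
  stopifnot(inherits(centerline, "oxy_centerline"))
  rel <- (centerline$points$theta - centerline$chord_angle) * pi / 180
  dyds <- sin(rel)
  sign_changes(dyds, eps = eps)$count
}

#' Count inflection points (vessel inflection index)
#'
#' The vessel inflection index (VII) is the number of sign changes of the
#' signed curvature along the centerline — points where the second
#' derivative of the centerline vanishes with a change of bending
#' direction. Curvatures with magnitude below `kappa_eps` are treated as
#' zero (a crossing requires opposite signs across the sub-threshold gap),
#' and crossings within `endpoint_buffer` samples of either end are
#' ignored to suppress boundary artifacts of the spline fit.
#'
#' @param centerline An `oxy_centerline`.
#' @param kappa_eps Curvature zero tolerance, 1/px.
#' @param endpoint_buffer Number of end samples excluded from counting.
#' @return A list with `vii` (integer count) and `locations` (tibble with
#'   `s`, `x`, `y` of each inflection).
#' @export
count_inflections <- function(centerline, kappa_eps = 1e-6,
                              endpoint_buffer = 2) {
  stopifnot(inherits(centerline, "oxy_centerline"))
  p <- centerline$points
  k <- p$kappa
  n <- length(k)
  sc <- sign_changes(k, eps = kappa_eps)
  if (sc$count == 0) {
    return(list(vii = 0L,
                locations = tibble(s = numeric(), x = numeric(),
                                   y = numeric())))
  }
  lo <- sc$at[, 1]
  hi <- sc$at[, 2]
  ok <- lo > endpoint_buffer & hi <= n - endpoint_buffer
  lo <- lo[ok]; hi <- hi[ok]
  if (length(lo) == 0) {
    return(list(vii = 0L,
                locations = tibble(s = numeric(), x = numeric(),
                                   y = numeric())))
  }
  # linear interpolation of the zero crossing between the bracketing samples
  frac <- abs(k[lo]) / (abs(k[lo]) + abs(k[hi]))
  s_inf <- p$s[lo] + frac * (p$s[hi] - p$s[lo])
  list(
    vii = length(lo),
    locations = tibble(
      s = s_inf,
      x = approx(p$s, p$x, xout = s_inf, ties = "ordered")$y,
      y = approx(p$s, p$y, xout = s_inf, ties = "ordered")$y
    )
  )
}

#' Mean arc/chord ratio between inflection points
#'
#' Partitions the centerline at its inflection points (plus both endpoints)
#' into consecutive sub-segments and returns the mean over sub-segments of
#' sub-arc length / sub-chord length. With no inflection points the whole
#' curve forms a single sub-segment. Always >= 1.
#'
#' @param centerline An `oxy_centerline`.
#' @param inflection_s Arc-length positions of the inflection points
#'   (e.g. from [count_inflections()]).
#' @return Numeric `M >= 1`.
#' @export
mean_arc_chord_ratio <- function(centerline, inflection_s = numeric()) {
  stopifnot(inherits(centerline, "oxy_centerline"))
  p <- centerline$points
  smax <- p$s[nrow(p)]
  bounds <- sort(unique(c(0, inflection_s[inflection_s > 0 &
                                            inflection_s < smax], smax)))
  xb <- approx(p$s, p$x, xout = bounds, ties = "ordered")$y
  yb <- approx(p$s, p$y, xout = bounds, ties = "ordered")$y
  arcs <- diff(bounds)
  chords <- sqrt(diff(xb)^2 + diff(yb)^2)
  ok <- chords > .Machine$double.eps
  mean(pmax(arcs[ok] / chords[ok], 1))
}

#' Vessel tortuosity index of a smoothed centerline
#'
#' Computes the components of the vessel tortuosity index
#' `VTI = 0.1 * SDtheta * N * M * LA / LC`:
#' `SDtheta` is the standard deviation (degrees) of the tangent angles
#' measured in the chord-aligned frame at every resampled centerline point;
#' `N` the number of critical points ([count_critical_points()]); `M` the
#' mean arc/chord ratio between inflection points
#' ([mean_arc_chord_ratio()]); `LA`, `LC` the centerline arc and chord
#' lengths. A straight segment has `N = 0` and hence `VTI = 0` exactly.
#'
#' @param centerline An `oxy_centerline`.
#' @param kappa_eps,endpoint_buffer Passed to [count_inflections()].
#' @param crit_eps Zero tolerance for the chord-frame dy/ds in
#'   [count_critical_points()].
#' @param sd_mode `"angles"` (standard deviation of chord-frame tangent
#'   angles, the default) or `"differences"` (standard deviation of
#'   consecutive tangent-angle differences).
#' @return A one-row tibble with `sd_theta`, `n_critical`, `m_ratio`, `la`,
#'   `lc`, `vti`.
#' @export
compute_vti <- function(centerline, kappa_eps = 1e-6, endpoint_buffer = 2,
                        crit_eps = 1e-6,
                        sd_mode = c("angles", "differences")) {
  stopifnot(inherits(centerline, "oxy_centerline"))
  sd_mode <- match.arg(sd_mode)
  rel <- wrap_angle(centerline$points$theta - centerline$chord_angle)
  sd_theta <- if (sd_mode == "angles") sd(rel) else sd(diff(rel))
  n_crit <- count_critical_points(centerline, eps = crit_eps)
  infl <- count_inflections(centerline, kappa_eps, endpoint_buffer)
  m <- mean_arc_chord_ratio(centerline, infl$locations$s)
  tibble(
    sd_theta = sd_theta,
    n_critical = as.integer(n_crit),
    m_ratio = m,
    la = centerline$la,
    lc = centerline$lc,
    vti = 0.1 * sd_theta * n_crit * m * centerline$la / centerline$lc
  )
}
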