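# Shared fixtures: analytic curves, small renders, and the independent
# dense finite-difference tortuosity oracle.

# Analytic sinusoid chain y = A sin(2 pi k t / L), optionally rigidly
# transformed, sampled once per pixel of axial length.
sinusoid_chain <- function(A, k, L, angle = 0, shift = c(0, 0),
                           density = 1) {
  p <- make_vessel_path(
    vessel_spec("sinusoid", length = L, amplitude = A, periods = k,
                start = shift, orientation = angle),
    samples_per_px = density)
  p[, c("x", "y")]
}

straight_chain <- function(n = 100, y = 5) {
  tibble::tibble(x = seq(0, n - 1), y = rep(y, n))
}

# Independent oracle for the tortuosity components of a sinusoid:
# dense sampling, uniform arc-length resampling, central finite
# differences for tangents and curvature -- no splines, no package code.
vti_oracle_sinusoid <- function(A, k, L, n_dense = 40000) {
  t <- seq(0, L, length.out = n_dense)
  x <- t
  y <- A * sin(2 * pi * k * t / L)
  sg <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  la <- sg[n_dense]
  s_u <- seq(0, la, length.out = n_dense)
  xu <- stats::approx(sg, x, s_u)$y
  yu <- stats::approx(sg, y, s_u)$y
  h <- la / (n_dense - 1)
  dx <- (xu[3:n_dense] - xu[1:(n_dense - 2)]) / (2 * h)
  dy <- (yu[3:n_dense] - yu[1:(n_dense - 2)]) / (2 * h)
  theta <- atan2(dy, dx) * 180 / pi
  ddx <- diff(xu, differences = 2) / h^2
  ddy <- diff(yu, differences = 2) / h^2
  kap <- (dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
  chord <- sqrt((xu[n_dense] - xu[1])^2 + (yu[n_dense] - yu[1])^2)
  nz_dy <- dy[abs(dy) > 1e-9]
  n_crit <- sum(abs(diff(sign(nz_dy))) > 0)
  sgn <- sign(kap)
  sgn[abs(kap) < 1e-9] <- 0
  nz <- which(sgn != 0)
  flip <- nz[which(sgn[nz][-1] != sgn[nz][-length(nz)])]
  s_inf <- s_u[2:(n_dense - 1)][flip]
  bounds <- c(0, s_inf, la)
  xb <- stats::approx(s_u, xu, bounds)$y
  yb <- stats::approx(s_u, yu, bounds)$y
  m <- mean(diff(bounds) / sqrt(diff(xb)^2 + diff(yb)^2))
  list(sd_theta = stats::sd(theta), n_critical = n_crit, m_ratio = m,
       la = la, lc = chord, vii = length(s_inf),
       vti = 0.1 * stats::sd(theta) * n_crit * m * la / chord)
}

# Small noiseless circumpapillary render shared by imaging tests.
# Vessels sit radially with the given per-vessel geometry.
demo_render <- function(specs_fun, onh_radius = 30, image_size = 320,
                        noise_sd = 0, seed = 1) {
  cfg <- render_config(image_size = image_size, onh_radius = onh_radius,
                       noise_sd = noise_sd, seed = seed)
  render_pair(specs_fun(cfg), cfg, calibration_params())
}

# Radial vessel helper: start near the ONH rim, run outward.
radial_spec <- function(cfg, angle, so2, diam, kind = "sinusoid",
                        periods = 3, amp = 2, r0 = 1.1, len = 4.1) {
  th <- angle * pi / 180
  vessel_spec(kind, length = len * cfg$onh_radius, amplitude = amp,
              periods = periods, diameter = diam, so2_true = so2,
              start = cfg$onh_center + r0 * cfg$onh_radius *
                c(cos(th), sin(th)),
              orientation = angle)
}

# Match measured segments to ground-truth vessels by angular position.
match_truth <- function(res, truth) {
  i <- vapply(res$angle, function(a) {
    which.min(abs(((truth$base_angle - a + 180) %% 360) - 180))
  }, integer(1))
  truth[i, ]
}
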