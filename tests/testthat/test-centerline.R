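# Spline smoothing, critical points, inflections, arc/chord ratios, VTI.

test_that("smoothing reproduces straight lines and resists jitter", {
  cl <- smooth_centerline(straight_chain(80))
  expect_lt(max(abs(cl$points$kappa)), 1e-6)
  resid <- abs(cl$points$y - 5)
  expect_lt(max(resid), 1e-3)
  expect_equal(cl$la, cl$lc, tolerance = 1e-9)

  set.seed(42)
  ch <- sinusoid_chain(10, 2, 200)
  jit <- ch
  jit$x <- jit$x + rnorm(nrow(ch), 0, 0.3)
  jit$y <- jit$y + rnorm(nrow(ch), 0, 0.3)
  cl2 <- smooth_centerline(jit)
  truth <- sinusoid_chain(10, 2, 200, density = 16)
  rmse <- sqrt(mean(vapply(seq_len(nrow(cl2$points)), function(i) {
    min((truth$x - cl2$points$x[i])^2 + (truth$y - cl2$points$y[i])^2)
  }, numeric(1))))
  expect_lt(rmse, 0.3)

  expect_error(smooth_centerline(straight_chain(3)),
               class = "oxy_too_short")
})

test_that("critical points follow the chord-frame first derivative", {
  expect_identical(count_critical_points(smooth_centerline(
    straight_chain(100))), 0L)
  one_period <- smooth_centerline(sinusoid_chain(10, 1, 150))
  expect_identical(count_critical_points(one_period), 2L)
  # rigid transformation leaves the count unchanged
  rot <- smooth_centerline(sinusoid_chain(10, 1, 150, angle = 37,
                                          shift = c(40, -17)))
  expect_identical(count_critical_points(rot), 2L)
})

test_that("inflection counting matches the analytic ground truth", {
  expect_identical(count_inflections(smooth_centerline(
    straight_chain(100)))$vii, 0L)
  th <- seq(0, 2, length.out = 150)
  arc <- tibble::tibble(x = 100 * cos(th), y = 100 * sin(th))
  expect_identical(count_inflections(smooth_centerline(arc))$vii, 0L)
  for (k in 1:4) {
    cl <- smooth_centerline(sinusoid_chain(8, k, 200))
    expect_identical(count_inflections(cl)$vii, 2L * k - 1L)
  }
  # inflection locations sit at the sinusoid's zero crossings
  cl2 <- smooth_centerline(sinusoid_chain(10, 2, 200))
  locs <- count_inflections(cl2)$locations
  expect_equal(nrow(locs), 3)
  expect_equal(sort(locs$x), c(50, 100, 150), tolerance = 0.02)
})

test_that("mean arc/chord ratio is 1 for lines, >= 1 always, and matches
           quadrature", {
  cl <- smooth_centerline(straight_chain(100))
  expect_equal(mean_arc_chord_ratio(cl), 1, tolerance = 1e-9)

  set.seed(7)
  for (i in 1:5) {
    a <- runif(1, 2, 12)
    k <- sample(1:3, 1)
    cl_i <- smooth_centerline(sinusoid_chain(a, k, 180, angle = runif(1, 0, 360)))
    infl <- count_inflections(cl_i)
    expect_gte(mean_arc_chord_ratio(cl_i, infl$locations$s), 1)
  }

  # one sine period, amplitude L/10: against the dense quadrature oracle
  o <- vti_oracle_sinusoid(20, 1, 200)
  cl2 <- smooth_centerline(sinusoid_chain(20, 1, 200))
  infl2 <- count_inflections(cl2)
  expect_equal(mean_arc_chord_ratio(cl2, infl2$locations$s), o$m_ratio,
               tolerance = 1e-3)
})

test_that("VTI is zero for straight segments and oracle-consistent", {
  v <- compute_vti(smooth_centerline(straight_chain(100)))
  expect_identical(v$vti, 0)
  expect_identical(v$n_critical, 0L)

  o <- vti_oracle_sinusoid(10, 2, 200)
  v2 <- compute_vti(smooth_centerline(sinusoid_chain(10, 2, 200)))
  expect_equal(v2$vti, o$vti, tolerance = 0.02)
  expect_equal(v2$sd_theta, o$sd_theta, tolerance = 0.02)
  expect_identical(v2$n_critical, o$n_critical)
  expect_equal(v2$m_ratio, o$m_ratio, tolerance = 0.01)
})

test_that("VTI is invariant to rigid motion and scale", {
  base <- compute_vti(smooth_centerline(sinusoid_chain(10, 2, 200)))
  rot <- compute_vti(smooth_centerline(
    sinusoid_chain(10, 2, 200, angle = 37, shift = c(120.3, -55.7))))
  expect_lt(abs(rot$vti - base$vti) / base$vti, 1e-6)
  expect_lt(abs(rot$sd_theta - base$sd_theta) / base$sd_theta, 1e-6)
  expect_identical(rot$n_critical, base$n_critical)

  # uniform magnification: every factor in the index is dimensionless
  ch <- sinusoid_chain(10, 2, 200)
  ch3 <- tibble::tibble(x = 3 * ch$x, y = 3 * ch$y)
  sc <- compute_vti(smooth_centerline(ch3, step = 3))
  expect_lt(abs(sc$vti - base$vti) / base$vti, 1e-3)
  expect_lt(abs(sc$sd_theta - base$sd_theta) / base$sd_theta, 1e-3)
  expect_equal(sc$la / sc$lc, base$la / base$lc, tolerance = 1e-6)
  # at a fixed 1 px resampling step the difference is pure sampling jitter
  sc1 <- compute_vti(smooth_centerline(ch3))
  expect_lt(abs(sc1$vti - base$vti) / base$vti, 0.01)
})

test_that("VTI grows with sinusoid amplitude", {
  amps <- c(2, 4, 6, 8, 10)
  vti <- vapply(amps, function(a) {
    compute_vti(smooth_centerline(sinusoid_chain(a, 2, 200)))$vti
  }, numeric(1))
  expect_true(all(diff(vti) > 0))
})
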