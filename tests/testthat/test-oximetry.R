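# Profiles, FWHM boundaries, optical density, SO2 and O2 content.

test_that("profiles are perpendicular and spaced every 5 px", {
  cl <- smooth_centerline(tibble::tibble(x = seq(5, 57), y = rep(30, 53)))
  img <- matrix(0.5, 60, 70)
  pr <- extract_profiles(cl, img, half_width = 10)
  expect_equal(nrow(pr), 11)  # floor(52/5) + 1
  # horizontal centerline: every profile line is vertical
  expect_true(all(abs(pr$theta) < 1))

  # a centerline approaching the frame edge loses profiles with a warning
  cl_edge <- smooth_centerline(tibble::tibble(
    x = seq(5, 57), y = seq(40, 6, length.out = 53)))
  expect_warning(pr2 <- extract_profiles(cl_edge, img, half_width = 10),
                 "dropped")
  expect_lt(nrow(pr2), nrow(extract_profiles(cl_edge, img,
                                             half_width = 4)))

  # fully outside: no profiles at all
  cl_out <- smooth_centerline(tibble::tibble(x = seq(5, 57),
                                             y = rep(1, 53)))
  expect_error(suppressWarnings(extract_profiles(cl_out, img,
                                                 half_width = 10)),
               class = "oxy_no_profiles")
})

test_that("fwhm_bounds locates sub-pixel half-maximum crossings", {
  pos <- seq(-20, 20, 0.5)
  gauss <- 0.8 * (1 - 0.6 * exp(-pos^2 / (2 * 16)))
  b <- fwhm_bounds(pos, gauss)
  expect_equal(unname(diff(b)), 2 * sqrt(2 * log(2)) * 4, tolerance = 0.02)
  expect_equal(unname(b[1]), -unname(b[2]), tolerance = 1e-6)

  box <- ifelse(abs(pos) <= 5, 0.3, 0.8)
  bb <- fwhm_bounds(pos, box)
  expect_equal(unname(diff(bb)), 10, tolerance = 0.1)

  expect_error(fwhm_bounds(pos, rep(0.8, length(pos))),
               class = "oxy_no_vessel")
  expect_error(fwhm_bounds(pos, 0.8 - 0.01 * pos),
               class = "oxy_no_vessel")
})

make_flat_profiles <- function(inside, outside, n = 5, half_width = 20) {
  pos <- seq(-half_width, half_width, 0.5)
  ity <- ifelse(abs(pos) <= 3, inside, outside)
  tibble::tibble(
    profile_id = seq_len(n), s = 5 * (seq_len(n) - 1),
    x = 30 + 5 * (seq_len(n) - 1), y = 30, theta = 0,
    pos = replicate(n, pos, simplify = FALSE),
    intensity = replicate(n, ity, simplify = FALSE)
  )
}

test_that("optical density follows the inside/outside definition", {
  bounds <- tibble::tibble(profile_id = 1:5, left = -3, right = 3)
  same <- make_flat_profiles(0.8, 0.8)
  expect_equal(optical_density(same, bounds)$od, 1)
  half <- make_flat_profiles(0.4, 0.8)
  expect_equal(optical_density(half, bounds)$od, 0.5)
  expect_equal(optical_density(half, bounds, od_mode = "log")$od,
               log10(2), tolerance = 1e-12)
  # fewer than 3 usable profiles excludes the segment
  expect_error(optical_density(half[1:2, ], bounds),
               class = "oxy_segment_excluded")
})

test_that("optical density equals a brute-force per-sample recomputation", {
  set.seed(31)
  pos <- seq(-20, 20, 0.5)
  profs <- list(); n <- 6
  for (i in 1:n) {
    depth <- runif(1, 0.2, 0.5)
    sig <- runif(1, 2, 4)
    profs[[i]] <- 0.7 * (1 - depth * exp(-pos^2 / (2 * sig^2))) +
      rnorm(length(pos), 0, 0.002)
  }
  profiles <- tibble::tibble(
    profile_id = 1:n, s = 5 * (0:(n - 1)), x = 40, y = 40, theta = 0,
    pos = replicate(n, pos, simplify = FALSE), intensity = profs)
  bounds <- purrr::list_rbind(purrr::imap(profs, function(ity, i) {
    b <- fwhm_bounds(pos, ity)
    tibble::tibble(profile_id = i, left = b[["left"]],
                   right = b[["right"]])
  }))
  od <- optical_density(profiles, bounds)$od

  # independent loop: direct masking, no shared code path
  vals <- numeric(0)
  for (i in 1:n) {
    l <- bounds$left[i]; r <- bounds$right[i]; w <- r - l
    ins <- out <- numeric(0)
    for (j in seq_along(pos)) {
      p <- pos[j]
      if (p >= l && p <= r) ins <- c(ins, profs[[i]][j])
      if ((p >= l - 2 * w && p <= l - w) ||
          (p >= r + w && p <= r + 2 * w)) out <- c(out, profs[[i]][j])
    }
    vals <- c(vals, mean(ins) / mean(out))
  }
  expect_equal(od, mean(vals), tolerance = 1e-6)
})

test_that("SO2, hemoglobin and O2 content transforms are exact", {
  cal <- calibration_params(a = 110, b = -70)
  expect_equal(so2_from_odr(0.5, cal), 75)
  expect_equal(suppressMessages(so2_from_odr(0.05, cal)), 100)
  expect_message(so2_from_odr(0.05, cal), "clamped")
  expect_error(so2_from_odr(NaN, cal), class = "oxy_invalid_measurement")
  expect_error(so2_from_odr(-1, cal), class = "oxy_invalid_measurement")

  expect_equal(hgb_from_hct(45), 15)
  expect_equal(hgb_from_hct(30), 10)
  expect_error(hgb_from_hct(0), class = "oxy_invalid_subject")
  expect_error(hgb_from_hct(101), class = "oxy_invalid_subject")

  expect_equal(o2_content(100, 15, 1.34), 20.1)
  expect_equal(o2_content(0, 15), 0)
  expect_equal(o2_content(50, 10, 1.34), 6.7)
  expect_error(o2_content(-5, 15), class = "oxy_invalid_measurement")

  # round trip through the calibration inverse
  for (so2 in c(5, 40, 75, 99)) {
    cal2 <- calibration_params()
    expect_equal(so2_from_odr((so2 - cal2$a) / cal2$b, cal2), so2)
  }
})

test_that("o2_content is linear and monotone in each argument", {
  so2 <- seq(10, 90, 20)
  expect_true(all(diff(o2_content(so2, 14)) > 0))
  expect_equal(o2_content(so2, 14), so2 * o2_content(1, 14),
               tolerance = 1e-12)
  hgb <- seq(8, 16, 2)
  expect_true(all(diff(o2_content(50, hgb)) > 0))
  expect_equal(o2_content(50, 14, 1.34) + o2_content(50, 14, 0.5),
               o2_content(50, 14, 1.84), tolerance = 1e-12)
})

test_that("noiseless renders invert to the encoded SO2 and caliber", {
  cal <- calibration_params()
  r <- demo_render(function(cfg) list(
    radial_spec(cfg, 10, 95, 60),
    radial_spec(cfg, 82, 60, 70, periods = 2),
    radial_spec(cfg, 154, 80, 50),
    radial_spec(cfg, 226, 40, 80, amp = 1.5)))
  res <- suppressMessages(suppressWarnings(
    measure_oximetry(r$pair, cal, hct = 45,
                     ground_truth = r$ground_truth)))
  expect_gte(nrow(res), 4)
  truth <- match_truth(res, r$ground_truth)
  expect_lt(max(abs(res$so2 - truth$so2_true)), 2)
  expect_lt(max(abs(res$diameter_um / truth$diameter - 1)), 0.10)
  expect_true(all(res$odr == res$od_633 / res$od_532))
  expect_true(all(res$so2 >= 0 & res$so2 <= 100))
  # o2 content respects its ceiling O2max * HgB
  expect_true(all(res$o2_content >= 0 &
                    res$o2_content <= cal$o2max * hgb_from_hct(45)))
  # artery/vein labels come from the angular ground-truth match
  expect_true(all(res$vessel_type %in% c("artery", "vein")))
})
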