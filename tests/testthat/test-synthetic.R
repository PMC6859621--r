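# Synthetic fundus generator: paths, renders, cohorts.

test_that("make_vessel_path traces the requested parametric curve", {
  p <- make_vessel_path(vessel_spec("straight", length = 100), 4)
  expect_gte(nrow(p), 400)
  # collinear: all cross products vanish
  v1 <- c(diff(p$x)[1], diff(p$y)[1])
  cross <- diff(p$x) * v1[2] - diff(p$y) * v1[1]
  expect_lt(max(abs(cross)), 1e-12)
  chord <- sqrt(diff(range(p$x))^2 + diff(range(p$y))^2)
  expect_equal(chord, 100)

  # sinusoid, 2 periods: analytic curvature ~ -sin(2 pi k t / L) changes
  # sign at the 2k - 1 = 3 interior zeros
  p2 <- make_vessel_path(vessel_spec("sinusoid", length = 200,
                                     amplitude = 10, periods = 2), 2)
  curv2 <- -sin(2 * pi * 2 * p2$t / 200)
  interior <- curv2[p2$t > 1 & p2$t < 199]
  flips <- sum(diff(sign(interior[abs(interior) > 1e-9])) != 0)
  expect_identical(flips, 3L)

  # zero periods degenerates to a straight line
  p3 <- make_vessel_path(vessel_spec("sinusoid", length = 150,
                                     amplitude = 10, periods = 0), 1)
  expect_lt(max(abs(p3$y - p3$y[1])), 1e-12)
})

test_that("invalid vessel specs are rejected", {
  expect_error(vessel_spec("straight", length = -5))
  expect_error(vessel_spec("straight", length = 100, so2_true = 130))
  expect_error(vessel_spec("sinusoid", length = 100, periods = -1))
  expect_error(make_vessel_path(vessel_spec("straight", length = 5)),
               "at least 10")
  expect_error(make_vessel_path(vessel_spec("straight", length = 100),
                                samples_per_px = 0))
})

test_that("render_pair is seed-deterministic and validates invertibility", {
  cfg <- render_config(image_size = 128, onh_radius = 12, noise_sd = 0.01,
                       seed = 99)
  sp <- vessel_spec("straight", length = 40, diameter = 60, so2_true = 80,
                    start = c(20, 30), orientation = 15)
  r1 <- render_pair(list(sp), cfg)
  r2 <- render_pair(list(sp), cfg)
  expect_identical(r1$pair$image_532, r2$pair$image_532)
  expect_identical(r1$pair$image_633, r2$pair$image_633)
  expect_identical(r1$ground_truth, r2$ground_truth)

  # a calibration whose inverse maps so2 to an OD >= 1 cannot be rendered
  bad_cal <- calibration_params(a = 50, b = 10)
  expect_error(render_pair(list(sp), cfg, bad_cal), "non-invertible")
})

test_that("an empty vessel list renders background and yields no segments", {
  cfg <- render_config(image_size = 160, onh_radius = 15, noise_sd = 0)
  r <- render_pair(list(), cfg)
  expect_equal(nrow(r$ground_truth), 0)
  res <- suppressWarnings(suppressMessages(
    measure_oximetry(r$pair, calibration_params())))
  expect_equal(nrow(res), 0)
})

test_that("rendered intensities encode the configured optical densities", {
  # vessel center transmittance is pre-compensated so the FWHM-window mean
  # equals the nominal OD; check the dip bottom against the closed form
  cfg <- render_config(image_size = 128, onh_radius = 12, noise_sd = 0)
  cal <- calibration_params()
  so2 <- 90
  sp <- vessel_spec("straight", length = 60, diameter = 80, so2_true = so2,
                    start = c(30, 90), orientation = 0)
  r <- render_pair(list(sp), cfg, cal)
  g <- sqrt(pi) * (2 * pnorm(sqrt(log(2)) * sqrt(2)) - 1) /
    (2 * sqrt(log(2)))
  mid <- r$pair$image_532[90, 60]
  expect_equal(mid, cfg$background * (1 - (1 - cfg$od532_base) / g),
               tolerance = 1e-3)
  odr <- (so2 - cal$a) / cal$b
  mid6 <- r$pair$image_633[90, 60]
  expect_equal(mid6,
               cfg$background * (1 - (1 - cfg$od532_base * odr) / g),
               tolerance = 1e-3)
})

test_that("generate_cohort is deterministic and carries the group structure", {
  s1 <- generate_cohort(4, 4, seed = 11)
  s2 <- generate_cohort(4, 4, seed = 11)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_cohort(4, 4, seed = 12)
  expect_false(identical(s1$segments, s3$segments))

  big <- generate_cohort(30, 30, seed = 5)
  sub <- big$subjects
  expect_true(all(sub$map == (sub$sbp + 2 * sub$dbp) / 3))
  # MAP centers near 93 (NC) and 82 (SCR) mmHg
  expect_equal(mean(sub$map[sub$diagnosis == "NC"]), 93, tolerance = 0.05)
  expect_equal(mean(sub$map[sub$diagnosis == "SCR"]), 82, tolerance = 0.05)
  # SCR oxygen deficit and inflection shift have the imposed signs
  seg <- dplyr::left_join(big$segments,
                          sub[, c("subject_id", "diagnosis")],
                          by = "subject_id")
  by_dx <- dplyr::summarise(
    dplyr::group_by(seg, .data$diagnosis),
    o2 = mean(.data$o2_content), vii = mean(.data$vii))
  expect_gt(by_dx$o2[by_dx$diagnosis == "NC"],
            by_dx$o2[by_dx$diagnosis == "SCR"])
  expect_lt(by_dx$vii[by_dx$diagnosis == "NC"],
            by_dx$vii[by_dx$diagnosis == "SCR"])
  expect_error(generate_cohort(0, 4), "counts")
})

test_that("arterial-venous SO2 contrast keeps its sign in every seed", {
  for (seed in 1:6) {
    sim <- generate_cohort(3, 3, seed = seed)
    gt <- sim$ground_truth
    gap <- mean(gt$so2_true[gt$vessel_type == "artery"]) -
      mean(gt$so2_true[gt$vessel_type == "vein"])
    expect_gt(gap, 0)
  }
})

test_that("rendered cohorts write images and tables to disk", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(1, 1, seed = 3, render = TRUE, out_dir = dir,
                         render_cfg = render_config(image_size = 256,
                                                    onh_radius = 24))
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  eye_dirs <- list.dirs(file.path(dir, "images"), recursive = FALSE)
  expect_length(eye_dirs, 4)
  pair <- read_fundus_pair(eye_dirs[1])
  expect_s3_class(pair, "fundus_pair")
  expect_equal(dim(pair$image_532), c(256, 256))
  expect_equal(pair$onh_radius, 24)
  # 16-bit TIFF round trip is exact to quantization
  key <- basename(eye_dirs[1])
  expect_equal(pair$image_532, unclass(sim$pairs[[key]]$image_532),
               tolerance = 2 / 65535, ignore_attr = TRUE)
  # rendered vii ground truth is odd (2k - 1 for k periods)
  expect_true(all(sim$ground_truth$vii_true %% 2 == 1))
})
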