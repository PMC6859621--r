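# Aggregation, outlier screening, mixed models, entropy and MI.

test_that("mean arterial pressure follows (SBP + 2 DBP) / 3", {
  expect_equal(map_from_bp(120, 80), 280 / 3)
  expect_equal(map_from_bp(90, 90), 90)
  expect_error(map_from_bp(80, 100), class = "oxy_invalid_vitals")
  set.seed(3)
  sbp <- runif(50, 95, 180)
  dbp <- sbp - runif(50, 5, 60)
  expect_equal(map_from_bp(sbp, dbp), (sbp + 2 * dbp) / 3,
               tolerance = 1e-12)
})

fake_tables <- function() {
  subjects <- tibble::tibble(
    subject_id = c("A", "B"), diagnosis = c("NC", "SCR"),
    age = c(40, 50), map = c(93, 82), hct = c(42, 28))
  oxi <- tibble::tibble(
    segment_id = paste0("s", 1:5),
    subject_id = c("A", "A", "A", "A", "B"),
    eye = c("OD", "OD", "OD", "OD", "OS"),
    vessel_type = c("artery", "artery", "artery", "vein", "vein"),
    o2_content = c(10, 12, 14, 9, 7))
  tor <- dplyr::mutate(oxi, vti = c(0.1, 0.2, 0.3, 0.15, 0.2),
                       vii = c(8, 9, 10, 7, 8))
  list(subjects = subjects, oxi = oxi, tor = tor)
}

test_that("aggregation averages per eye and vessel type", {
  ft <- fake_tables()
  tb <- aggregate_cohort(ft$oxi, ft$tor, ft$subjects)
  art <- tb[tb$subject_id == "A" & tb$vessel_type == "artery", ]
  expect_equal(art$o2_content, 12)
  expect_equal(art$vti, 0.2)
  expect_equal(art$n_segments_o2, 3L)
  # eye with veins only has no artery row
  expect_equal(sum(tb$subject_id == "B" & tb$vessel_type == "artery"), 0)
  # at most 4 rows per subject
  expect_true(all(table(tb$subject_id) <= 4))
})

test_that("aggregation enforces table integrity", {
  ft <- fake_tables()
  dup <- dplyr::bind_rows(ft$oxi, ft$oxi[1, ])
  expect_error(aggregate_cohort(dup, ft$tor, ft$subjects),
               class = "oxy_integrity")
  orphan <- dplyr::mutate(ft$oxi,
                          subject_id = replace(subject_id, 1, "ZZ"))
  expect_error(aggregate_cohort(orphan, ft$tor, ft$subjects),
               class = "oxy_integrity")
})

test_that("outlier screening removes only rows outside the stratum band", {
  set.seed(5)
  sim <- generate_cohort(10, 10, seed = 9)
  tb <- suppressMessages(
    aggregate_cohort(sim$segments, sim$segments, sim$subjects))
  clean <- remove_outliers(tb)
  expect_equal(nrow(clean), nrow(tb))  # all within 3 SD: no-op

  spiked <- tb
  i <- which(spiked$diagnosis == "NC" & spiked$vessel_type == "artery")[1]
  grp <- spiked$diagnosis == "NC" & spiked$vessel_type == "artery"
  spiked$o2_content[i] <- mean(spiked$o2_content[grp]) +
    5 * sd(spiked$o2_content[grp])
  filt <- remove_outliers(spiked)
  expect_equal(nrow(filt), nrow(spiked) - 1)
  lg <- outlier_log(filt)
  expect_equal(lg$subject_id[lg$action == "removed"], spiked$subject_id[i])

  # small strata are skipped and logged
  tiny <- tb[tb$diagnosis == "NC", ][1:3, ]
  tiny$o2_content[1] <- 1000
  filt2 <- remove_outliers(tiny)
  expect_equal(nrow(filt2), 3)
  expect_match(outlier_log(filt2)$action[1], "skipped")
})

test_that("the group mixed model recovers imposed effects", {
  sim <- generate_cohort(12, 12, seed = 101)
  tb <- remove_outliers(suppressMessages(
    aggregate_cohort(sim$segments, sim$segments, sim$subjects)))
  m <- fit_group_lmm(tb, "o2_content")
  td <- tidy(m)
  scr <- td[td$term == "diagnosisSCR", ]
  expect_lt(scr$estimate, 0)
  expect_lt(scr$p_value, 0.05)
  g <- glance(m)
  expect_equal(g$n_subjects, 24)
  expect_gte(g$n_obs, g$n_subjects)
  expect_true(all(td$std_error > 0))

  m_vii <- suppressWarnings(fit_group_lmm(tb, "vii"))
  scr_vii <- tidy(m_vii)[tidy(m_vii)$term == "diagnosisSCR", ]
  expect_gt(scr_vii$estimate, 0)  # imposed +2 inflection shift

  expect_error(fit_group_lmm(tb[tb$subject_id == "S001", ]),
               "2 subjects")
})

test_that("fixed-effect CIs cover the simulation truth at nominal rate", {
  # The population group difference implied by the generator defaults:
  # hemoglobin gap (HCT 42 vs 28), SO2 deficit of 3 points, and the
  # VII-mediated path (-0.5 mLO2/dL per inflection x +2 inflections).
  eff <- cohort_effects()
  truth <- 1.34 * (28 / 3) * ((92 - eff$so2_deficit) +
                                (58 - eff$so2_deficit)) / 2 / 100 -
    1.34 * (42 / 3) * (92 + 58) / 2 / 100 +
    eff$vii_slope * eff$vii_shift
  hits <- 0
  n_seeds <- 30
  for (seed in seq_len(n_seeds)) {
    sim <- generate_cohort(12, 12, seed = 300 + seed)
    tb <- remove_outliers(suppressMessages(
      aggregate_cohort(sim$segments, sim$segments, sim$subjects)))
    td <- tidy(suppressWarnings(fit_group_lmm(tb, "o2_content")))
    scr <- td[td$term == "diagnosisSCR", ]
    if (scr$conf_low <= truth && truth <= scr$conf_high) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.85)  # nominal 95% within 10 points
})

test_that("o2-tortuosity regression flags degenerate designs", {
  sim <- generate_cohort(6, 6, seed = 77)
  tb <- suppressMessages(
    aggregate_cohort(sim$segments, sim$segments, sim$subjects))
  tb$vii <- 8
  expect_error(relate_o2_tortuosity(tb, "vii"),
               class = "oxy_rank_deficient")
})

test_that("entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(3.7, 50)), 0)
  expect_equal(shannon_entropy(1:16, n_bins = 16), 4)
  expect_equal(shannon_entropy(c(rep(0, 8), rep(1, 8)), n_bins = 2), 1)
  expect_error(shannon_entropy(numeric(0)))
  # bounds: 0 <= H <= log2(bins)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(60)
    h <- shannon_entropy(x)
    expect_gte(h, 0)
    expect_lte(h, log2(ceiling(sqrt(60))))
  }
})

test_that("mutual information matches its defining formula", {
  px <- c(0.1, 0.2, 0.3, 0.4)
  py <- c(0.25, 0.25, 0.4, 0.1)
  expect_equal(mutual_information_joint(outer(px, py)), 0,
               tolerance = 1e-12)
  expect_equal(mutual_information_joint(matrix(c(0.5, 0, 0, 0.5), 2)), 1)
  expect_error(mutual_information_joint(matrix(c(0.9, 0, 0, 0.3), 2)))

  set.seed(13)
  x <- rnorm(200)
  expect_equal(mutual_information(x, x), shannon_entropy(x),
               tolerance = 1e-12)
  # 0 <= MI <= min(H(x), H(y)) on arbitrary paired data
  for (i in 1:8) {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100)
    mi <- mutual_information(x, y)
    expect_gte(mi, -1e-9)
    expect_lte(mi, min(shannon_entropy(x), shannon_entropy(y)) + 1e-9)
  }
  expect_error(mutual_information(1:5, 1:4), "equal length")
})

test_that("cohort summary mirrors the diagnosis x eye x vessel-type layout", {
  sim <- generate_cohort(5, 5, seed = 15)
  tb <- suppressMessages(
    aggregate_cohort(sim$segments, sim$segments, sim$subjects))
  sm <- cohort_summary(tb)
  expect_equal(nrow(sm), 8)  # 2 dx x 2 eyes x 2 types
  expect_true(all(c("o2_content_mean", "o2_content_sd", "vti_mean",
                    "vii_mean") %in% names(sm)))
  dem <- compare_demographics(sim$subjects)
  expect_true(all(c("age", "map", "hct") %in% dem$variable))
  expect_true(all(dem$p_value >= 0 & dem$p_value <= 1))
})
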