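# Cohort-level aggregation and linear mixed models.

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' `MAP = (SBP + 2 * DBP) / 3` mmHg.
#'
#' @param sbp,dbp Systolic and diastolic blood pressure, mmHg;
#'   `sbp >= dbp > 0`.
#' @return MAP in mmHg.
#' @export
map_from_bp <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) || any(dbp <= 0) ||
      any(dbp > sbp)) {
    abort("Require sbp >= dbp > 0.", class = "oxy_invalid_vitals")
  }
  (sbp + 2 * dbp) / 3
}

#' Aggregate per-segment records to the cohort table
#'
#' Averages oxygen content, VTI and VII per subject, eye and vessel type
#' (arithmetic means over segments), and joins the subject covariates.
#' Strata with no segments are omitted; each subject contributes at most
#' four rows (2 eyes x 2 vessel types).
#'
#' @param oximetry Tibble with `subject_id`, `eye`, `vessel_type`,
#'   `segment_id`, `o2_content`.
#' @param tortuosity Tibble with `subject_id`, `eye`, `vessel_type`,
#'   `segment_id`, `vti`, `vii`. May be the same table as `oximetry` when
#'   segments carry all three metrics.
#' @param subjects Tibble with `subject_id`, `diagnosis`, `age`, `map`
#'   (and typically `hct`, `sbp`, `dbp`).
#' @return A tibble with one row per subject x eye x vessel type:
#'   `o2_content`, `vti`, `vii` means, `n_segments_o2`, `n_segments_tort`,
#'   and subject covariates.
#' @export
aggregate_cohort <- function(oximetry, tortuosity, subjects) {
  for (tb in list(oximetry, tortuosity)) {
    if (anyDuplicated(tb$segment_id)) {
      abort(sprintf("Duplicate segment id(s): %s",
                    paste(unique(tb$segment_id[duplicated(tb$segment_id)]),
                          collapse = ", ")),
            class = "oxy_integrity")
    }
  }
  bad <- setdiff(unique(c(oximetry$subject_id, tortuosity$subject_id)),
                 subjects$subject_id)
  if (length(bad)) {
    abort(sprintf("Segment tables reference unknown subject id(s): %s",
                  paste(bad, collapse = ", ")), class = "oxy_integrity")
  }
  keys <- c("subject_id", "eye", "vessel_type")
  o2 <- oximetry |>
    filter(!is.na(.data$vessel_type)) |>
    group_by(across(all_of(keys))) |>
    summarise(o2_content = mean(.data$o2_content),
              n_segments_o2 = dplyr::n(), .groups = "drop")
  tort <- tortuosity |>
    filter(!is.na(.data$vessel_type)) |>
    group_by(across(all_of(keys))) |>
    summarise(vti = mean(.data$vti), vii = mean(.data$vii),
              n_segments_tort = dplyr::n(), .groups = "drop")
  out <- dplyr::full_join(o2, tort, by = keys) |>
    dplyr::inner_join(
      select(subjects, any_of(c("subject_id", "diagnosis", "age", "map",
                                "hct", "sbp", "dbp"))),
      by = "subject_id") |>
    arrange(.data$subject_id, .data$eye, .data$vessel_type)
  dropped <- sum(is.na(out$o2_content) & is.na(out$vti))
  if (dropped > 0) {
    inform(sprintf("%d stratum rows had no segments and were dropped.",
                   dropped))
  }
  out
}

#' Remove outliers within diagnosis x vessel-type strata
#'
#' Flags rows whose `o2_content`, `vti` or `vii` falls outside
#' `mean +/- k * SD` of its diagnosis x vessel-type stratum and removes
#' them. Strata with fewer than `min_stratum` rows are left untouched (and
#' noted in the log).
#'
#' @param table Cohort table from [aggregate_cohort()].
#' @param k Band half-width in standard deviations (default 3).
#' @param min_stratum Minimum rows per stratum for the rule to apply.
#' @param metrics Columns screened.
#' @return The filtered tibble, with the removal log attached as
#'   `attr(, "outlier_log")` (a tibble with row id, metric, value, band).
#' @export
remove_outliers <- function(table, k = 3, min_stratum = 5,
                            metrics = c("o2_content", "vti", "vii")) {
  metrics <- intersect(metrics, names(table))
  log_rows <- list()
  drop <- rep(FALSE, nrow(table))
  strata <- table |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$diagnosis, .data$vessel_type)
  for (grp in dplyr::group_split(strata)) {
    if (nrow(grp) < min_stratum) {
      log_rows[[length(log_rows) + 1]] <- tibble(
        subject_id = NA_character_, eye = NA_character_,
        diagnosis = grp$diagnosis[1], vessel_type = grp$vessel_type[1],
        metric = NA_character_, value = NA_real_,
        lower = NA_real_, upper = NA_real_,
        action = sprintf("stratum skipped (n = %d < %d)", nrow(grp),
                         min_stratum))
      next
    }
    for (m in metrics) {
      v <- grp[[m]]
      mu <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      out <- which(!is.na(v) & (v < mu - k * s | v > mu + k * s))
      for (i in out) {
        drop[grp$.row[i]] <- TRUE
        log_rows[[length(log_rows) + 1]] <- tibble(
          subject_id = grp$subject_id[i], eye = grp$eye[i],
          diagnosis = grp$diagnosis[1], vessel_type = grp$vessel_type[1],
          metric = m, value = v[i], lower = mu - k * s, upper = mu + k * s,
          action = "removed")
      }
    }
  }
  out <- table[!drop, , drop = FALSE]
  attr(out, "outlier_log") <- if (length(log_rows)) list_rbind(log_rows) else
    tibble(subject_id = character(), eye = character(),
           diagnosis = character(), vessel_type = character(),
           metric = character(), value = numeric(), lower = numeric(),
           upper = numeric(), action = character())
  out
}

#' Outlier removal log
#'
#' @param table A tibble returned by [remove_outliers()].
#' @return The removal-log tibble.
#' @export
outlier_log <- function(table) {
  attr(table, "outlier_log") %||%
    abort("No outlier log attached; run remove_outliers() first.")
}

new_lmm_result <- function(fit, response, term_of_interest = NULL) {
  ct <- as.data.frame(summary(fit)$coefficients)
  coef_tb <- tibble(
    term = rownames(ct),
    estimate = ct[["Estimate"]],
    std_error = ct[["Std. Error"]],
    df = ct[["df"]],
    statistic = ct[["t value"]],
    p_value = ct[["Pr(>|t|)"]]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fit = fit,
      response = response,
      term_of_interest = term_of_interest,
      coefficients = coef_tb,
      ranef_variance = vc$vcov[vc$grp == "subject_id"][1],
      residual_variance = vc$vcov[vc$grp == "Residual"][1],
      n_obs = stats::nobs(fit),
      n_subjects = lme4::ngrps(fit)[["subject_id"]],
      singular = lme4::isSingular(fit),
      method = if (lme4::isREML(fit)) "REML" else "ML"
    ),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %s ~ fixed effects + (1 | subject_id)\n",
              x$response))
  cat(sprintf("  %d observations, %d subjects, %s fit%s\n", x$n_obs,
              x$n_subjects, x$method,
              if (x$singular) " (singular)" else ""))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model result
#'
#' @param x An `lmm_result`.
#' @param conf_level Confidence level for the t-based intervals.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: estimate, standard
#'   error, Satterthwaite df, t statistic, p-value, confidence bounds.
#' @export
tidy.lmm_result <- function(x, conf_level = 0.95, ...) {
  q <- qt(1 - (1 - conf_level) / 2, df = x$coefficients$df)
  x$coefficients |>
    mutate(conf_low = .data$estimate - q * .data$std_error,
           conf_high = .data$estimate + q * .data$std_error)
}

#' One-row model summary of a mixed-model result
#'
#' @param x An `lmm_result`.
#' @param ... Unused.
#' @return A one-row tibble: response, n, subjects, variance components,
#'   fit method, singularity flag.
#' @export
glance.lmm_result <- function(x, ...) {
  tibble(
    response = x$response,
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    ranef_variance = x$ranef_variance,
    residual_variance = x$residual_variance,
    method = x$method,
    singular = x$singular
  )
}

fit_lmm_formula <- function(table, formula, response) {
  need <- all.vars(formula)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    abort(sprintf("Cohort table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- tidyr::drop_na(table, any_of(need))
  if (length(unique(data$subject_id)) < 2 ||
      length(unique(data$diagnosis)) < 1) {
    abort("Need at least 2 subjects to fit a mixed model.")
  }
  for (v in setdiff(need, c("subject_id", response))) {
    if (is.numeric(data[[v]]) && sd(data[[v]]) == 0) {
      abort(sprintf("Term `%s` is constant: rank-deficient design.", v),
            class = "oxy_rank_deficient")
    }
  }
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE))
  if (lme4::isSingular(fit)) {
    warn("Singular random-effect fit; refitting by maximum likelihood.")
    fit <- suppressMessages(lmerTest::lmer(formula, data = data,
                                           REML = FALSE))
  }
  fit
}

#' Fit the group-difference linear mixed model
#'
#' Random-intercept model per subject with diagnosis, eye and vessel type
#' as fixed effects, adjusted for age and mean arterial pressure:
#' `response ~ diagnosis + eye + vessel_type + age + map +
#' (1 | subject_id)`, fit by REML with Satterthwaite t-tests (two-sided;
#' significance at p <= 0.05). Using both eyes with a subject random
#' intercept controls the correlation between fellow eyes.
#'
#' @param table Cohort table from [aggregate_cohort()] (after
#'   [remove_outliers()]).
#' @param response One of `"o2_content"`, `"vti"`, `"vii"`.
#' @return An `lmm_result`; see [tidy.lmm_result()] and
#'   [glance.lmm_result()].
#' @export
fit_group_lmm <- function(table,
                          response = c("o2_content", "vti", "vii")) {
  response <- match.arg(response)
  if (length(unique(table$subject_id)) < 2) {
    abort("Need at least 2 subjects per diagnosis.")
  }
  f <- stats::as.formula(paste(
    response, "~ diagnosis + eye + vessel_type + age + map",
    "+ (1 | subject_id)"))
  fit <- fit_lmm_formula(table, f, response)
  new_lmm_result(fit, response, term_of_interest = "diagnosisSCR")
}

#' Relate oxygen content to a tortuosity metric
#'
#' Mixed-model regression of O2 content on VTI or VII, accounting for
#' vessel type and fellow eyes and adjusted for age and MAP:
#' `o2_content ~ metric + vessel_type + eye + age + map +
#' (1 | subject_id)`. The coefficient of the metric term is the reported
#' association (mL O2/dL per metric unit).
#'
#' @param table Cohort table.
#' @param metric `"vti"` or `"vii"`.
#' @return An `lmm_result` with `term_of_interest` set to the metric.
#' @export
relate_o2_tortuosity <- function(table, metric = c("vii", "vti")) {
  metric <- match.arg(metric)
  if (metric %in% names(table) && is.numeric(table[[metric]]) &&
      sd(table[[metric]], na.rm = TRUE) == 0) {
    abort(sprintf("`%s` is constant: rank-deficient design.", metric),
          class = "oxy_rank_deficient")
  }
  f <- stats::as.formula(paste(
    "o2_content ~", metric, "+ vessel_type + eye + age + map",
    "+ (1 | subject_id)"))
  fit <- fit_lmm_formula(table, f, "o2_content")
  new_lmm_result(fit, "o2_content", term_of_interest = metric)
}

#' Summary table of cohort means by diagnosis, eye and vessel type
#'
#' Mean and standard deviation of O2 content, VTI and VII in each
#' diagnosis x eye x vessel-type cell (the layout used to report cohort
#' oximetry/tortuosity results).
#'
#' @param table Cohort table.
#' @return A tibble with one row per cell and `mean`/`sd` columns per
#'   metric.
#' @export
cohort_summary <- function(table) {
  table |>
    group_by(.data$diagnosis, .data$vessel_type, .data$eye) |>
    summarise(
      n = dplyr::n(),
      across(any_of(c("o2_content", "vti", "vii")),
             list(mean = ~mean(.x, na.rm = TRUE),
                  sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
}

#' Compare demographics between diagnosis groups
#'
#' Convenience wrapper: Welch t-tests for numeric covariates and a
#' chi-square test for sex.
#'
#' @param subjects Subject table with `diagnosis` and covariates.
#' @param numeric_vars Numeric covariates to compare.
#' @return A tibble with variable, group means (or counts) and p-value.
#' @export
compare_demographics <- function(subjects,
                                 numeric_vars = c("age", "map", "hct")) {
  numeric_vars <- intersect(numeric_vars, names(subjects))
  rows <- map(numeric_vars, function(v) {
    tt <- t.test(subjects[[v]] ~ subjects$diagnosis)
    tibble(variable = v,
           nc = unname(tt$estimate[1]), scr = unname(tt$estimate[2]),
           test = "t", p_value = tt$p.value)
  })
  if ("sex" %in% names(subjects) &&
      length(unique(subjects$sex)) > 1) {
    ct <- suppressWarnings(chisq.test(table(subjects$diagnosis,
                                            subjects$sex)))
    rows[[length(rows) + 1]] <- tibble(
      variable = "sex", nc = NA_real_, scr = NA_real_,
      test = "chi-square", p_value = ct$p.value)
  }
  list_rbind(rows)
}
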