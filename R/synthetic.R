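#' Calibration parameters for the optical density ratio to SO2 transform
#'
#' Holds the linear calibration `SO2 = a + b * ODR` together with the optical
#' density convention and the constants of the oxygen content formula
#' `O2 content = O2max * HgB * SO2 / 100`.
#'
#' The calibration coefficients are instrument-specific and must be supplied
#' by the user for real data; the defaults here are the ones used by the
#' synthetic forward model, chosen so that SO2 in \[0, 100\] maps to an ODR in
#' \[0.75, 1.25\] and every render stays invertible.
#'
#' @param a Intercept of the linear SO2 transform, percent.
#' @param b Slope, percent per unit ODR. Must be non-zero.
#' @param od_mode `"ratio"` (optical density as the mean inside/outside
#'   intensity ratio) or `"log"` (mean `log10(outside/inside)`).
#' @param o2max Oxygen-binding capacity of hemoglobin, mL O2 per g
#'   (default 1.34).
#' @param hgb_per_hct Hemoglobin concentration per hematocrit percent,
#'   g/dL per % (default 1/3, the standard clinical rule).
#' @return A list of class `oxy_calibration`.
#' @export
calibration_params <- function(a = -150, b = 200, od_mode = c("ratio", "log"),
                               o2max = 1.34, hgb_per_hct = 1 / 3) {
  od_mode <- match.arg(od_mode)
  stopifnot_scalar_num(a, "a")
  stopifnot_scalar_num(b, "b")
  if (b == 0) abort("Calibration slope `b` must be non-zero.")
  stopifnot_scalar_num(o2max, "o2max", positive = TRUE)
  stopifnot_scalar_num(hgb_per_hct, "hgb_per_hct", positive = TRUE)
  structure(
    list(a = a, b = b, od_mode = od_mode, o2max = o2max,
         hgb_per_hct = hgb_per_hct),
    class = "oxy_calibration"
  )
}

# Inverse of the SO2 calibration: the ODR that encodes a given saturation.
odr_from_so2 <- function(so2, cal) {
  (so2 - cal$a) / cal$b
}

#' Specify one synthetic vessel
#'
#' Parametric description of a single vessel used by the forward renderer.
#' A sinusoid with `periods = k` full periods has exactly `2k - 1` interior
#' curvature sign changes, which is the analytic ground truth for the vessel
#' inflection index.
#'
#' @param path_kind `"straight"`, `"sinusoid"` or `"composite"` (sinusoid
#'   plus a one-third-amplitude third harmonic).
#' @param length Axial length of the vessel in pixels (the chord of the
#'   undulation envelope).
#' @param amplitude Lateral undulation amplitude in pixels.
#' @param periods Integer number of full undulation periods (0 degenerates
#'   to a straight vessel).
#' @param diameter Vessel caliber in micrometers (the rendered FWHM).
#' @param vessel_type `"artery"` or `"vein"`.
#' @param so2_true True hemoglobin oxygen saturation encoded in the render,
#'   percent in \[0, 100\].
#' @param start Numeric `c(x, y)` start point in pixels.
#' @param orientation Direction of the vessel axis in degrees
#'   (0 = +x, counterclockwise... measured in the y-down image frame).
#' @return A list of class `vessel_spec`.
#' @export
vessel_spec <- function(path_kind = c("straight", "sinusoid", "composite"),
                        length, amplitude = 0, periods = 0L, diameter = 60,
                        vessel_type = c("artery", "vein"), so2_true = 90,
                        start = c(0, 0), orientation = 0) {
  path_kind <- match.arg(path_kind)
  vessel_type <- match.arg(vessel_type)
  stopifnot_scalar_num(length, "length", positive = TRUE)
  stopifnot_scalar_num(diameter, "diameter", positive = TRUE)
  stopifnot_scalar_num(so2_true, "so2_true")
  if (so2_true < 0 || so2_true > 100) {
    abort("`so2_true` must lie in [0, 100].")
  }
  if (periods < 0 || periods != round(periods)) {
    abort("`periods` must be a non-negative integer.")
  }
  structure(
    list(path_kind = path_kind, length = length, amplitude = amplitude,
         periods = as.integer(periods), diameter = diameter,
         vessel_type = vessel_type, so2_true = so2_true,
         start = start, orientation = orientation),
    class = "vessel_spec"
  )
}

#' Rendering configuration for synthetic fundus pairs
#'
#' @param image_size Side of the square image in pixels.
#' @param onh_center Numeric `c(x, y)` center of the optic nerve head disc;
#'   defaults to the image center.
#' @param onh_radius ONH radius in pixels. `5 * onh_radius` must fit inside
#'   the frame so the outer tortuosity annulus is imaged.
#' @param um_per_px Pixel scale in micrometers per pixel.
#' @param background Background intensity in \[0, 1\].
#' @param onh_intensity Intensity of the bright ONH disc.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param od532_base Inside/outside intensity ratio of every vessel at
#'   532 nm (near-isosbestic, oxygenation-insensitive).
#' @param seed Integer seed for the render noise.
#' @return A list of class `render_config`.
#' @export
render_config <- function(image_size = 256, onh_center = NULL,
                          onh_radius = 24, um_per_px = 10,
                          background = 0.65, onh_intensity = 0.95,
                          noise_sd = 0, od532_base = 0.55, seed = 1L) {
  stopifnot_scalar_num(image_size, "image_size", positive = TRUE)
  stopifnot_scalar_num(onh_radius, "onh_radius", positive = TRUE)
  stopifnot_scalar_num(um_per_px, "um_per_px", positive = TRUE)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (od532_base <= 0 || od532_base >= 1) {
    abort("`od532_base` must lie in (0, 1).")
  }
  onh_center <- onh_center %||% rep((image_size + 1) / 2, 2)
  if (min(onh_center) - 5 * onh_radius < 1 ||
      max(onh_center) + 5 * onh_radius > image_size) {
    abort("5 * onh_radius must fit inside the image frame.")
  }
  structure(
    list(image_size = as.integer(image_size), onh_center = onh_center,
         onh_radius = onh_radius, um_per_px = um_per_px,
         background = background, onh_intensity = onh_intensity,
         noise_sd = noise_sd, od532_base = od532_base,
         seed = as.integer(seed)),
    class = "render_config"
  )
}

#' Sample the parametric path of a synthetic vessel
#'
#' @param spec A [vessel_spec()].
#' @param samples_per_px Sampling density along the axis (points per pixel).
#' @return A tibble with columns `t` (axial parameter, px), `x`, `y`
#'   (pixel coordinates).
#' @examples
#' p <- make_vessel_path(vessel_spec("sinusoid", length = 200,
#'                                   amplitude = 10, periods = 2))
#' @export
make_vessel_path <- function(spec, samples_per_px = 4) {
  if (!inherits(spec, "vessel_spec")) abort("`spec` must be a vessel_spec.")
  if (spec$length < 10) abort("Vessel `length` must be at least 10 px.")
  stopifnot_scalar_num(samples_per_px, "samples_per_px", positive = TRUE)
  L <- spec$length
  n <- ceiling(L * samples_per_px) + 1
  t <- seq(0, L, length.out = n)
  lat <- switch(spec$path_kind,
    straight = rep(0, n),
    sinusoid = if (spec$periods == 0) rep(0, n) else {
      spec$amplitude * sin(2 * pi * spec$periods * t / L)
    },
    composite = if (spec$periods == 0) rep(0, n) else {
      spec$amplitude * sin(2 * pi * spec$periods * t / L) +
        (spec$amplitude / 3) * sin(2 * pi * 3 * spec$periods * t / L + pi / 7)
    }
  )
  th <- spec$orientation * pi / 180
  tibble(
    t = t,
    x = spec$start[1] + t * cos(th) - lat * sin(th),
    y = spec$start[2] + t * sin(th) + lat * cos(th)
  )
}

# Analytic/numeric ground truth for one spec: interior curvature sign
# changes and arc length. Sinusoids use the closed form 2k - 1; composite
# paths fall back to dense finite differences.
vessel_truth <- function(spec) {
  path <- make_vessel_path(spec, samples_per_px = 8)
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  arc <- sum(seg)
  n_inf <- if (spec$path_kind == "straight" || spec$periods == 0) {
    0L
  } else if (spec$path_kind == "sinusoid") {
    2L * spec$periods - 1L
  } else {
    dx <- diff(path$x); dy <- diff(path$y)
    ddx <- diff(dx); ddy <- diff(dy)
    kap <- dx[-1] * ddy - dy[-1] * ddx
    sign_changes(kap, eps = max(abs(kap)) * 1e-9)$count
  }
  list(arc_length = arc, inflections = as.integer(n_inf))
}

# Mean of exp(-d^2 / (2 sigma^2)) over the FWHM window [-w, w],
# w = sigma * sqrt(2 log 2). The renderer divides the dip depth by this so
# that the FWHM-window mean transmittance equals the nominal OD.
fwhm_mean_factor <- local({
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  sqrt(pi) * erf(sqrt(log(2))) / (2 * sqrt(log(2)))
})

# Paint one vessel's Gaussian attenuation profile onto an accumulator
# matrix: at each pixel, att = exp(-dmin^2 / (2 sigma^2)) where dmin is the
# distance to the vessel path. Computed as a running pixelwise max over
# dense path points (exact up to the 0.2 px path sampling).
paint_attenuation <- function(att, path, sigma) {
  n <- nrow(att)
  hw <- ceiling(4 * sigma)
  offs <- -hw:hw
  for (i in seq_len(nrow(path))) {
    px <- path$x[i]; py <- path$y[i]
    cx <- round(px); cy <- round(py)
    xs <- cx + offs; ys <- cy + offs
    okx <- xs >= 1 & xs <= n
    oky <- ys >= 1 & ys <= n
    if (!any(okx) || !any(oky)) next
    xs <- xs[okx]; ys <- ys[oky]
    d2 <- outer((ys - py)^2, (xs - px)^2, `+`)
    w <- exp(-d2 / (2 * sigma^2))
    att[ys, xs] <- pmax(att[ys, xs], w)
  }
  att
}

# Evaluate an expression with a temporary RNG state so callers' streams are
# untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render a two-wavelength synthetic fundus pair
#'
#' Forward model for dual-wavelength oximetry. Each vessel is drawn as an
#' inverted Gaussian cross-profile whose FWHM equals its nominal diameter.
#' The dip depth is set so that the mean transmittance across the FWHM
#' window equals the target optical density: `od532_base` at 532 nm and
#' `od532_base * ODR(so2_true)` at 633 nm, with the ODR given by the inverse
#' of the linear SO2 calibration. Running [measure_oximetry()] on a noiseless
#' render therefore recovers `so2_true` and the nominal caliber.
#'
#' @param vessels List of [vessel_spec()] objects (may be empty).
#' @param cfg A [render_config()].
#' @param cal A [calibration_params()]; the same calibration must be used to
#'   invert the render.
#' @return A list with elements `pair` (a `fundus_pair`: matrices
#'   `image_532`, `image_633` in \[0, 1\], `onh_center`, `onh_radius`,
#'   `um_per_px`) and `ground_truth` (one tibble row per vessel).
#' @export
render_pair <- function(vessels, cfg = render_config(),
                        cal = calibration_params()) {
  n <- cfg$image_size
  base <- matrix(cfg$background, n, n)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  d_onh <- sqrt((xs - cfg$onh_center[1])^2 + (ys - cfg$onh_center[2])^2)
  base[d_onh <= cfg$onh_radius] <- cfg$onh_intensity
  img532 <- base
  img633 <- base

  gt <- vector("list", length(vessels))
  for (i in seq_along(vessels)) {
    v <- vessels[[i]]
    odr <- odr_from_so2(v$so2_true, cal)
    od633 <- cfg$od532_base * odr
    if (!is.finite(odr) || odr <= 0 || od633 <= 0 || od633 >= 1) {
      abort(sprintf(
        "so2_true = %.1f maps to a non-invertible render (ODR %.3f).",
        v$so2_true, odr))
    }
    fwhm_px <- v$diameter / cfg$um_per_px
    sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
    path <- make_vessel_path(v, samples_per_px = 5)
    if (min(path$x, path$y) < 1 || max(path$x, path$y) > n) {
      abort(sprintf("Vessel %d extends outside the frame.", i))
    }
    att <- paint_attenuation(matrix(0, n, n), path, sigma)
    d532 <- (1 - cfg$od532_base) / fwhm_mean_factor
    d633 <- (1 - od633) / fwhm_mean_factor
    img532 <- img532 * (1 - d532 * att)
    img633 <- img633 * (1 - d633 * att)

    truth <- vessel_truth(v)
    mid <- path[ceiling(nrow(path) / 2), ]
    gt[[i]] <- tibble(
      vessel_id = i,
      vessel_type = v$vessel_type,
      so2_true = v$so2_true,
      diameter = v$diameter,
      inflection_count_true = truth$inflections,
      arc_length_true = truth$arc_length,
      base_angle = atan2(mid$y - cfg$onh_center[2],
                         mid$x - cfg$onh_center[1]) * 180 / pi
    )
  }

  if (cfg$noise_sd > 0) {
    with_local_seed(cfg$seed, {
      img532 <- img532 + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
      img633 <- img633 + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
    })
  }
  img532 <- pmin(pmax(img532, 0), 1)
  img633 <- pmin(pmax(img633, 0), 1)

  pair <- structure(
    list(image_532 = img532, image_633 = img633,
         onh_center = cfg$onh_center, onh_radius = cfg$onh_radius,
         um_per_px = cfg$um_per_px),
    class = "fundus_pair"
  )
  list(
    pair = pair,
    ground_truth = if (length(gt)) list_rbind(gt) else tibble(
      vessel_id = integer(), vessel_type = character(),
      so2_true = numeric(), diameter = numeric(),
      inflection_count_true = integer(), arc_length_true = numeric(),
      base_angle = numeric())
  )
}

#' @export
print.fundus_pair <- function(x, ...) {
  cat(sprintf(
    "<fundus_pair> %d x %d px, ONH center (%.1f, %.1f), radius %.1f px, %.1f um/px\n",
    nrow(x$image_532), ncol(x$image_532), x$onh_center[1], x$onh_center[2],
    x$onh_radius, x$um_per_px))
  invisible(x)
}

#' Group-level effects imposed on a synthetic cohort
#'
#' @param so2_deficit SO2 reduction (percentage points) applied to every
#'   vessel of SCR subjects.
#' @param vii_slope Change in O2 content per additional inflection point,
#'   mL O2/dL (the true coefficient recovered by
#'   [relate_o2_tortuosity()]).
#' @param vii_shift Additional inflection points in SCR vessels.
#' @param vti_shift Additive VTI shift in SCR vessels.
#' @param o2_noise_sd Per-segment O2 content measurement noise, mL O2/dL.
#' @param subject_sd SD of the subject-level random intercept on O2 content.
#' @param vti_noise_sd Per-segment VTI noise.
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(so2_deficit = 3, vii_slope = -0.5, vii_shift = 2,
                           vti_shift = 0.03, o2_noise_sd = 1.2,
                           subject_sd = 1.5, vti_noise_sd = 0.02) {
  structure(
    list(so2_deficit = so2_deficit, vii_slope = vii_slope,
         vii_shift = vii_shift, vti_shift = vti_shift,
         o2_noise_sd = o2_noise_sd, subject_sd = subject_sd,
         vti_noise_sd = vti_noise_sd),
    class = "cohort_effects"
  )
}

round_to_odd <- function(x) {
  k <- pmax(round((x + 1) / 2), 1)
  2 * k - 1
}

#' Simulate a two-group cohort with known effects
#'
#' Generates subjects (normal controls, `NC`, and sickle cell retinopathy,
#' `SCR`), two eyes each, with vitals drawn from documented defaults: mean
#' arterial pressure centered near 93 mmHg (NC) and 82 mmHg (SCR), ages
#' 46 +/- 4 and 41 +/- 15 years, hematocrit 42 +/- 3 and 28 +/- 4 %.
#' Per-vessel oxygen content is linked to the vessel inflection index with
#' the configured slope, so the mixed-model regression of O2 content on VII
#' has a known true coefficient.
#'
#' With `render = FALSE` the function returns per-segment measurement tables
#' directly (ground truth plus configured noise), suitable for statistical
#' simulations. With `render = TRUE` each eye is also rendered as a
#' two-wavelength image pair carrying the same ground truth, and optionally
#' written to `out_dir` (TIFF pairs, `subjects.csv`, `ground_truth.csv` and
#' per-eye `annotations.json`).
#'
#' @param n_nc,n_scr Number of subjects per group (>= 1).
#' @param effects A [cohort_effects()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param render Render image pairs for each eye?
#' @param out_dir Directory to write rendered images and tables to
#'   (created if needed). Ignored unless `render = TRUE`.
#' @param render_cfg A [render_config()] template for rendering.
#' @param cal A [calibration_params()].
#' @param vessels_per_type Vessels of each type rendered per eye.
#' @return A list of class `cohort_sim` with `subjects`, `ground_truth`,
#'   `segments` (per-segment measurements; table mode only), and when
#'   rendering, `pairs` (named list of `fundus_pair`).
#' @export
generate_cohort <- function(n_nc = 12, n_scr = 12,
                            effects = cohort_effects(), seed = 1L,
                            render = FALSE, out_dir = NULL,
                            render_cfg = render_config(image_size = 320,
                                                       onh_radius = 30),
                            cal = calibration_params(),
                            vessels_per_type = 4) {
  if (n_nc < 1 || n_scr < 1) abort("Subject counts must be >= 1.")
  set.seed(seed)
  n_sub <- n_nc + n_scr
  diagnosis <- c(rep("NC", n_nc), rep("SCR", n_scr))
  nc <- diagnosis == "NC"
  draw2 <- function(m_nc, s_nc, m_scr, s_scr, lo, hi) {
    ifelse(nc, rnorm_trunc(n_sub, m_nc, s_nc, lo, hi),
           rnorm_trunc(n_sub, m_scr, s_scr, lo, hi))
  }
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    diagnosis = diagnosis,
    sex = sample(c("M", "F"), n_sub, replace = TRUE),
    age = round(draw2(46, 4, 41, 15, 18, 80), 1),
    hct = round(draw2(42, 3, 28, 4, 15, 55), 1),
    sbp = round(draw2(120, 10, 105, 9, 85, 180)),
    dbp = round(draw2(80, 8, 70, 7, 45, 110))
  )
  subjects$dbp <- pmin(subjects$dbp, subjects$sbp - 5)
  subjects$map <- map_from_bp(subjects$sbp, subjects$dbp)
  subj_intercept <- rnorm(n_sub, 0, effects$subject_sd)

  seg_rows <- list()
  gt_rows <- list()
  pairs <- list()
  eyes <- c("OD", "OS")
  eye_idx <- 0L

  for (si in seq_len(n_sub)) {
    sub <- subjects[si, ]
    scr <- sub$diagnosis == "SCR"
    hgb <- sub$hct * cal$hgb_per_hct
    for (eye in eyes) {
      eye_idx <- eye_idx + 1L
      n_v <- 2 * vessels_per_type
      vtype <- rep(c("artery", "vein"), vessels_per_type)
      so2_mean <- ifelse(vtype == "artery", 92, 58) -
        if (scr) effects$so2_deficit else 0
      vii_true <- round_to_odd(rnorm(
        n_v, 8 + if (scr) effects$vii_shift else 0, 1.5))
      o2_base <- cal$o2max * hgb * so2_mean / 100
      o2_true <- o2_base + effects$vii_slope * (vii_true - 8) +
        subj_intercept[si]
      o2_true <- pmin(pmax(o2_true, 0.5), cal$o2max * hgb)
      so2_vessel <- pmin(pmax(100 * o2_true / (cal$o2max * hgb), 5), 99)
      vti_true <- pmax(rnorm(
        n_v, 0.16 + if (scr) effects$vti_shift else 0, 0.04), 0.02)
      diam <- round(runif(n_v, 50, 80))

      gt_eye <- tibble(
        subject_id = sub$subject_id, eye = eye,
        diagnosis = sub$diagnosis,
        vessel_id = seq_len(n_v), vessel_type = vtype,
        so2_true = so2_vessel, o2_true = o2_true,
        vti_true = vti_true, vii_true = as.integer(vii_true),
        diameter = diam
      )
      gt_rows[[eye_idx]] <- gt_eye

      seg_rows[[eye_idx]] <- gt_eye |>
        mutate(
          segment_id = sprintf("%s_%s_V%02d", .data$subject_id, .data$eye,
                               .data$vessel_id),
          o2_content = .data$o2_true + rnorm(n_v, 0, effects$o2_noise_sd),
          vti = pmax(.data$vti_true + rnorm(n_v, 0, effects$vti_noise_sd),
                     0.001),
          vii = .data$vii_true
        ) |>
        select("segment_id", "subject_id", "eye", "vessel_type",
               "o2_content", "vti", "vii", "diameter")

      if (render) {
        cfg <- render_cfg
        cfg$seed <- (abs(seed) %% 100000L) * 10000L + eye_idx
        angles <- seq(0, 360, length.out = n_v + 2)[seq_len(n_v + 1)] +
          runif(1, 0, 360 / (n_v + 1))
        specs <- vector("list", n_v)
        r0 <- 1.1 * cfg$onh_radius
        len <- 4.1 * cfg$onh_radius
        for (vi in seq_len(n_v)) {
          th <- angles[vi] * pi / 180
          specs[[vi]] <- vessel_spec(
            "sinusoid",
            length = len,
            amplitude = runif(1, 1.5, 2.5) +
              if (scr) 10 * effects$vti_shift else 0,
            periods = (vii_true[vi] + 1) / 2,
            diameter = diam[vi],
            vessel_type = vtype[vi],
            so2_true = so2_vessel[vi],
            start = cfg$onh_center + r0 * c(cos(th), sin(th)),
            orientation = angles[vi]
          )
        }
        # one sub-caliber capillary to exercise the 25 um filter
        thc <- angles[n_v + 1] * pi / 180
        specs[[n_v + 1]] <- vessel_spec(
          "straight", length = len, diameter = 15, vessel_type = "vein",
          so2_true = 60,
          start = cfg$onh_center + r0 * c(cos(thc), sin(thc)),
          orientation = angles[n_v + 1]
        )
        rp <- render_pair(specs, cfg, cal)
        gt_eye$base_angle <- rp$ground_truth$base_angle[seq_len(n_v)]
        gt_rows[[eye_idx]] <- gt_eye
        key <- sprintf("%s_%s", sub$subject_id, eye)
        pairs[[key]] <- rp$pair
        if (!is.null(out_dir)) {
          dir <- file.path(out_dir, "images", key)
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
          write_fundus_pair(rp$pair, dir,
                            meta = list(subject_id = sub$subject_id,
                                        eye = eye))
        }
      }
    }
  }

  ground_truth <- list_rbind(gt_rows)
  segments <- list_rbind(seg_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(subjects, file.path(out_dir, "subjects.csv"))
    readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"))
  }
  structure(
    list(subjects = subjects, ground_truth = ground_truth,
         segments = segments,
         pairs = if (render) pairs else NULL,
         effects = effects, seed = seed, calibration = cal),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d subjects (%d NC, %d SCR), %d segments%s\n",
    nrow(x$subjects), sum(x$subjects$diagnosis == "NC"),
    sum(x$subjects$diagnosis == "SCR"), nrow(x$segments),
    if (!is.null(x$pairs)) sprintf(", %d rendered eyes", length(x$pairs))
    else ""))
  invisible(x)
}
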