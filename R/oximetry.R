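# Per-vessel oximetry: perpendicular profiles, FWHM boundaries, optical
# densities at both wavelengths, SO2 and O2 content.

#' Extract perpendicular intensity profiles along a centerline
#'
#' Samples the image along lines perpendicular to the local tangent, one
#' profile every `spacing` pixels of arc length starting at the first
#' centerline point. Profiles whose support would leave the image frame are
#' dropped with a single warning.
#'
#' @param centerline An [smooth_centerline()] result.
#' @param image Intensity matrix.
#' @param spacing Arc-length spacing between profiles, px (default 5).
#' @param half_width Half-extent of each profile, px; must exceed the
#'   expected vessel radius plus the flanking background windows.
#' @param step Sample step along the profile, px (gives an odd, centered
#'   sample count).
#' @return A tibble with one row per profile: `profile_id`, `s`, `x`, `y`,
#'   `theta`, and list-columns `pos`, `intensity`.
#' @export
extract_profiles <- function(centerline, image, spacing = 5,
                             half_width = 20, step = 0.5) {
  stopifnot(inherits(centerline, "oxy_centerline"))
  p <- centerline$points
  if (nrow(p) < 2) abort("Centerline has fewer than 2 points.")
  s_targets <- seq(0, p$s[nrow(p)], by = spacing)
  idx <- map_int(s_targets, function(st) which.min(abs(p$s - st)))
  idx <- unique(idx)
  pos <- seq(-half_width, half_width, by = step)
  nr <- nrow(image); nc <- ncol(image)

  rows <- list()
  dropped <- 0
  for (j in seq_along(idx)) {
    i <- idx[j]
    th <- p$theta[i] * pi / 180
    nx <- -sin(th); ny <- cos(th)
    xs <- p$x[i] + pos * nx
    ys <- p$y[i] + pos * ny
    if (min(xs) < 1 || max(xs) > nc || min(ys) < 1 || max(ys) > nr) {
      dropped <- dropped + 1
      next
    }
    rows[[length(rows) + 1]] <- tibble(
      profile_id = j, s = p$s[i], x = p$x[i], y = p$y[i],
      theta = p$theta[i],
      pos = list(pos),
      intensity = list(sample_bicubic(image, xs, ys))
    )
  }
  if (dropped > 0) {
    warn(sprintf("%d profile(s) extended outside the frame and were dropped.",
                 dropped))
  }
  if (length(rows) == 0) {
    abort("No profile lies inside the image frame.",
          class = "oxy_no_profiles")
  }
  list_rbind(rows)
}

#' Full width at half maximum of a vessel intensity dip
#'
#' Locates the sub-pixel crossings of the half level
#' `background - depth / 2` flanking the interior intensity minimum of a
#' perpendicular profile, by linear interpolation. The background level is
#' the median of the outer quarter of samples on each side.
#'
#' @param pos Sample positions along the profile (px, centered on the
#'   centerline).
#' @param intensity Intensities at those positions.
#' @param min_depth Minimum dip depth (intensity units) below background for
#'   the profile to count as a vessel.
#' @return Numeric `c(left, right)` sub-pixel edge positions;
#'   `right - left` is the FWHM width.
#' @export
fwhm_bounds <- function(pos, intensity, min_depth = 0.05) {
  n <- length(pos)
  if (n < 7) abort("Profile too short.", class = "oxy_no_vessel")
  q <- max(3, floor(n / 4))
  bg <- median(c(intensity[seq_len(q)], intensity[seq(n - q + 1, n)]))
  imin <- which.min(intensity)
  depth <- bg - intensity[imin]
  if (imin <= 2 || imin >= n - 1 || depth < min_depth) {
    abort("No vessel dip in profile.", class = "oxy_no_vessel")
  }
  half <- bg - depth / 2

  cross <- function(i0, i1) {
    # linear interpolation between samples i0 (below half) and i1 (above)
    f <- (half - intensity[i0]) / (intensity[i1] - intensity[i0])
    pos[i0] + f * (pos[i1] - pos[i0])
  }
  left <- NA_real_
  for (i in seq(imin, 2)) {
    if (intensity[i - 1] >= half && intensity[i] < half) {
      left <- cross(i, i - 1)
      break
    }
  }
  right <- NA_real_
  for (i in seq(imin, n - 1)) {
    if (intensity[i + 1] >= half && intensity[i] < half) {
      right <- cross(i, i + 1)
      break
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    abort("Profile does not recross the half level on both sides.",
          class = "oxy_no_vessel")
  }
  c(left = left, right = right)
}

#' Optical density of a vessel segment at one wavelength
#'
#' For each profile, the inside intensity is the mean between the FWHM
#' edges and the outside intensity the mean over two flanking windows, each
#' one vessel-width wide and one vessel-width away from the respective
#' edge. The segment optical density is the mean over usable profiles of
#' inside/outside (`od_mode = "ratio"`, the default) or of
#' `log10(outside/inside)` (`od_mode = "log"`).
#'
#' Profiles whose outside windows touch other vessels (per `exclude_mask`)
#' or retain too few samples are skipped; fewer than 3 usable profiles is an
#' error of class `oxy_segment_excluded`.
#'
#' @param profiles Profile tibble from [extract_profiles()].
#' @param bounds Tibble with `profile_id`, `left`, `right` (FWHM edges, px).
#' @param od_mode `"ratio"` or `"log"`.
#' @param exclude_mask Optional logical matrix marking pixels of *other*
#'   vessels; outside windows sampling it invalidate the profile.
#' @return A list with `od`, `n_used`, and `per_profile` (tibble of
#'   per-profile inside/outside means).
#' @export
optical_density <- function(profiles, bounds, od_mode = c("ratio", "log"),
                            exclude_mask = NULL) {
  od_mode <- match.arg(od_mode)
  b <- dplyr::inner_join(profiles, bounds, by = "profile_id")
  vals <- list()
  for (i in seq_len(nrow(b))) {
    pos <- b$pos[[i]]
    ity <- b$intensity[[i]]
    l <- b$left[i]; r <- b$right[i]
    w <- r - l
    if (!(w > 0)) next
    ins <- pos >= l & pos <= r
    out <- (pos >= l - 2 * w & pos <= l - w) |
      (pos >= r + w & pos <= r + 2 * w)
    if (sum(ins) < 3 || sum(pos < l - w & out) < 2 ||
        sum(pos > r + w & out) < 2) next
    if (!is.null(exclude_mask)) {
      th <- b$theta[i] * pi / 180
      ox <- round(b$x[i] + pos[out] * (-sin(th)))
      oy <- round(b$y[i] + pos[out] * cos(th))
      ok <- ox >= 1 & ox <= ncol(exclude_mask) &
        oy >= 1 & oy <= nrow(exclude_mask)
      if (any(exclude_mask[cbind(oy[ok], ox[ok])])) next
    }
    vals[[length(vals) + 1]] <- tibble(
      profile_id = b$profile_id[i],
      inside = mean(ity[ins]),
      outside = mean(ity[out])
    )
  }
  if (length(vals) < 3) {
    abort("Fewer than 3 usable profiles; segment excluded.",
          class = "oxy_segment_excluded")
  }
  pp <- list_rbind(vals)
  od <- if (od_mode == "ratio") {
    mean(pp$inside / pp$outside)
  } else {
    mean(log10(pp$outside / pp$inside))
  }
  list(od = od, n_used = nrow(pp), per_profile = pp)
}

#' Convert an optical density ratio to hemoglobin oxygen saturation
#'
#' Applies the linear calibration `SO2 = a + b * ODR` and clamps the result
#' to \[0, 100\] percent (measurement noise can overshoot the physiologic
#' range); clamping is reported via a message.
#'
#' @param odr Optical density ratio(s), `OD633 / OD532`; finite and > 0.
#' @param cal A [calibration_params()].
#' @return SO2 in percent.
#' @export
so2_from_odr <- function(odr, cal = calibration_params()) {
  if (any(!is.finite(odr)) || any(odr <= 0)) {
    abort("`odr` must be finite and > 0.", class = "oxy_invalid_measurement")
  }
  raw <- cal$a + cal$b * odr
  n_clamp <- sum(raw < 0 | raw > 100)
  if (n_clamp > 0) {
    inform(sprintf("SO2 clamped to [0, 100] for %d value(s).", n_clamp))
  }
  pmin(pmax(raw, 0), 100)
}

#' Hemoglobin concentration from hematocrit
#'
#' @param hct Hematocrit, volume percent, in (0, 100).
#' @param hgb_per_hct Conversion factor, g/dL per percent (default 1/3,
#'   the standard clinical rule).
#' @return Hemoglobin concentration, g/dL.
#' @export
hgb_from_hct <- function(hct, hgb_per_hct = 1 / 3) {
  if (any(!is.finite(hct)) || any(hct <= 0) || any(hct >= 100)) {
    abort("`hct` must lie in (0, 100) percent.", class = "oxy_invalid_subject")
  }
  hct * hgb_per_hct
}

#' Vascular oxygen content
#'
#' `O2 content = O2max * HgB * SO2 / 100` (mL O2 per dL of blood), with
#' `O2max` the oxygen-binding capacity of hemoglobin (mL O2 per g) and
#' `HgB` the hemoglobin concentration (g/dL).
#'
#' @param so2 Oxygen saturation, percent in \[0, 100\].
#' @param hgb Hemoglobin concentration, g/dL, > 0.
#' @param o2max Oxygen-binding capacity, mL O2/g (default 1.34).
#' @return Oxygen content, mL O2/dL.
#' @export
o2_content <- function(so2, hgb, o2max = 1.34) {
  if (any(!is.finite(so2)) || any(so2 < 0) || any(so2 > 100) ||
      any(hgb <= 0) || any(o2max <= 0)) {
    abort("so2 must be in [0, 100]; hgb and o2max must be > 0.",
          class = "oxy_invalid_measurement")
  }
  o2max * hgb * so2 / 100
}

# Assign each measured segment the vessel type of the ground-truth vessel
# with the nearest angular position around the ONH.
match_vessel_type <- function(angle, ground_truth) {
  if (is.null(ground_truth) || nrow(ground_truth) == 0 ||
      !"base_angle" %in% names(ground_truth)) {
    return(rep(NA_character_, length(angle)))
  }
  vapply(angle, function(a) {
    d <- abs(wrap_angle(ground_truth$base_angle - a))
    ground_truth$vessel_type[which.min(d)]
  }, character(1))
}

#' Measure per-segment oximetry on a fundus image pair
#'
#' Full oximetry chain for one eye: vessels are segmented on the 532 nm
#' image with the Frangi filter, restricted to the circumpapillary annulus
#' (default 1-2 ONH radii), and thinned to centerline segments.
#' Perpendicular profiles every `spacing` pixels give FWHM vessel
#' boundaries (on the higher-contrast 532 nm image) and per-wavelength
#' optical densities; the optical density ratio `OD633 / OD532` is
#' converted to SO2 with the linear calibration, and, when a hematocrit is
#' supplied, to oxygen content.
#'
#' @param pair A `fundus_pair` (from [render_pair()] or
#'   [read_fundus_pair()]).
#' @param cal A [calibration_params()].
#' @param annulus Annulus bounds in ONH radii, `c(inner, outer)`.
#' @param hct Optional subject hematocrit (percent) to compute O2 content.
#' @param ground_truth Optional ground-truth tibble (with `base_angle`,
#'   `vessel_type`) used to label segments as artery/vein.
#' @param scales,threshold,min_diameter Passed to [segment_vessels()].
#' @param spacing,half_width Passed to [extract_profiles()].
#' @param min_chain Minimum centerline length in px for a segment.
#' @param onh_margin Extra pixels beyond the inner annulus bound excluded
#'   around the ONH rim (suppresses the disc-edge response).
#' @param regularization Spline penalty for the profile-geometry
#'   centerline. Stiffer than the tortuosity default: profile extraction
#'   needs stable tangents, and the short chains of the inner annulus carry
#'   pixel-level skeleton jitter that a light penalty would follow.
#' @return A tibble with one row per retained segment: `segment_id`,
#'   `vessel_type`, `diameter_um`, `od_532`, `od_633`, `odr`, `so2`,
#'   optional `o2_content`, `n_profiles`, `x`, `y`, `angle`.
#' @export
measure_oximetry <- function(pair, cal = calibration_params(),
                             annulus = c(1, 2), hct = NULL,
                             ground_truth = NULL,
                             scales = c(1.5, 2.5, 3.5), threshold = 0.25,
                             min_diameter = 25, spacing = 5,
                             half_width = 20, min_chain = 10,
                             onh_margin = 3, regularization = 0.01) {
  stopifnot(inherits(pair, "fundus_pair"))
  img5 <- pair$image_532
  img6 <- pair$image_633
  dims <- dim(img5)
  ann <- annulus_mask(pair$onh_center, pair$onh_radius,
                      annulus[1], annulus[2], dims)
  if (onh_margin > 0) {
    rim <- annulus_mask(pair$onh_center, pair$onh_radius,
                        annulus[1],
                        annulus[1] + onh_margin / pair$onh_radius, dims)
    ann <- ann & !rim
  }
  roi <- radial_band(pair$onh_center,
                     annulus[1] * pair$onh_radius + onh_margin,
                     annulus[2] * pair$onh_radius + 8, dims)
  seg_img <- suppress_onh(img5, pair$onh_center, pair$onh_radius)
  mask <- segment_vessels(seg_img, scales = scales, threshold = threshold,
                          min_diameter = min_diameter,
                          um_per_px = pair$um_per_px, roi = roi)
  labels <- EBImage::bwlabel(mask)
  chains <- extract_centerlines(mask, ann, min_length = min_chain)
  rows <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    res <- tryCatch({
      cl <- smooth_centerline(ch, regularization = regularization)
      own <- labels[cbind(round(ch$y), round(ch$x))]
      own <- own[own > 0]
      own_label <- if (length(own)) as.integer(names(sort(
        table(own), decreasing = TRUE))[1]) else 0L
      other_mask <- mask & labels != own_label
      prof5 <- extract_profiles(cl, img5, spacing = spacing,
                                half_width = half_width)
      prof6 <- extract_profiles(cl, img6, spacing = spacing,
                                half_width = half_width)
      bounds <- list()
      for (i in seq_len(nrow(prof5))) {
        bd <- tryCatch(
          fwhm_bounds(prof5$pos[[i]], prof5$intensity[[i]]),
          oxy_no_vessel = function(e) NULL)
        if (!is.null(bd)) {
          bounds[[length(bounds) + 1]] <- tibble(
            profile_id = prof5$profile_id[i],
            left = bd[["left"]], right = bd[["right"]])
        }
      }
      if (length(bounds) < 3) {
        abort("Fewer than 3 profiles with a measurable vessel dip.",
              class = "oxy_segment_excluded")
      }
      bounds <- list_rbind(bounds)
      od5 <- optical_density(prof5, bounds, od_mode = cal$od_mode,
                             exclude_mask = other_mask)
      od6 <- optical_density(prof6, bounds, od_mode = cal$od_mode,
                             exclude_mask = other_mask)
      odr <- od6$od / od5$od
      so2 <- so2_from_odr(odr, cal)
      mid <- ch[ceiling(nrow(ch) / 2), ]
      ang <- atan2(mid$y - pair$onh_center[2],
                   mid$x - pair$onh_center[1]) * 180 / pi
      tibble(
        segment_id = sprintf("seg%02d", ci),
        vessel_type = match_vessel_type(ang, ground_truth),
        diameter_um = mean(bounds$right - bounds$left) * pair$um_per_px,
        od_532 = od5$od, od_633 = od6$od, odr = odr, so2 = so2,
        n_profiles = min(od5$n_used, od6$n_used),
        x = mid$x, y = mid$y, angle = ang
      )
    },
    oxy_segment_excluded = function(e) {
      inform(sprintf("Segment %d excluded: %s", ci, conditionMessage(e)))
      NULL
    },
    oxy_no_profiles = function(e) NULL,
    oxy_too_short = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- if (length(rows)) list_rbind(rows) else tibble(
    segment_id = character(), vessel_type = character(),
    diameter_um = numeric(), od_532 = numeric(), od_633 = numeric(),
    odr = numeric(), so2 = numeric(), n_profiles = integer(),
    x = numeric(), y = numeric(), angle = numeric())
  if (!is.null(hct) && nrow(out) > 0) {
    out$o2_content <- o2_content(out$so2, hgb_from_hct(hct, cal$hgb_per_hct),
                                 cal$o2max)
  }
  out
}
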