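# Per-segment tortuosity measurement on the 532 nm image.

#' Refine a pixel chain to sub-pixel ridge positions
#'
#' Skeleton chains carry up to half-pixel lattice jitter which, on gently
#' curved vessels, survives light spline smoothing and produces phantom
#' curvature sign changes. This refinement snaps each chain point to the
#' vessel's intensity valley: local tangents come from a stiff auxiliary
#' spline fit, the image is sampled along each normal, and the minimum is
#' located to sub-pixel precision by a quadratic fit around the deepest
#' sample.
#'
#' @param chain Tibble with `x`, `y` (ordered skeleton chain).
#' @param image Intensity matrix (vessels dark).
#' @param half_window Search half-extent along the normal, px.
#' @param step Sampling step along the normal, px.
#' @return A tibble with refined `x`, `y`.
#' @export
refine_chain_subpixel <- function(chain, image, half_window = 4,
                                  step = 0.25) {
  cl <- smooth_centerline(chain, regularization = 0.01, step = 1)
  p <- cl$points
  pos <- seq(-half_window, half_window, by = step)
  nr <- nrow(image); nc <- ncol(image)
  out_x <- p$x
  out_y <- p$y
  for (i in seq_len(nrow(p))) {
    th <- p$theta[i] * pi / 180
    nx <- -sin(th); ny <- cos(th)
    xs <- p$x[i] + pos * nx
    ys <- p$y[i] + pos * ny
    ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
    if (sum(ok) < 5) next
    v <- sample_bicubic(image, xs[ok], ys[ok])
    pk <- pos[ok]
    j <- which.min(v)
    if (j == 1 || j == length(v)) next
    # quadratic vertex through the three samples around the minimum
    denom <- v[j - 1] - 2 * v[j] + v[j + 1]
    delta <- if (abs(denom) > .Machine$double.eps) {
      0.5 * (v[j - 1] - v[j + 1]) / denom * step
    } else 0
    d <- pk[j] + max(min(delta, step), -step)
    out_x[i] <- p$x[i] + d * nx
    out_y[i] <- p$y[i] + d * ny
  }
  # The normal offsets vary smoothly along a true vessel; a short running
  # mean removes the sub-pixel estimation jitter without touching the
  # geometry (the offsets, not the positions, are filtered).
  dx <- out_x - p$x
  dy <- out_y - p$y
  if (length(dx) >= 7) {
    kern <- rep(1 / 5, 5)
    pad <- function(v) c(rep(v[1], 2), v, rep(v[length(v)], 2))
    dx <- as.numeric(stats::filter(pad(dx), kern, sides = 2))[3:(length(dx) + 2)]
    dy <- as.numeric(stats::filter(pad(dy), kern, sides = 2))[3:(length(dy) + 2)]
  }
  tibble(x = p$x + dx, y = p$y + dy)
}

#' Measure vessel tortuosity on a fundus image
#'
#' Segments vessels on the 532 nm image (higher vessel/tissue contrast),
#' restricts them to the outer circumpapillary annulus (default 1.5-5 ONH
#' radii), extracts branch-free centerline chains via thinning, smooths
#' each with a penalized cubic spline (regularization `3e-5`), and computes
#' the vessel tortuosity index and vessel inflection index per segment.
#' Vessels narrower than `min_diameter` (default 25 um) are excluded by the
#' caliber filter of [segment_vessels()].
#'
#' @param pair A `fundus_pair`, or a bare intensity matrix plus `onh_center`,
#'   `onh_radius`, `um_per_px` supplied via `pair` being a list with those
#'   fields.
#' @param annulus Annulus bounds in ONH radii.
#' @param regularization Spline smoothing penalty (see
#'   [smooth_centerline()]).
#' @param min_chain Minimum centerline length, px.
#' @param kappa_eps,endpoint_buffer Passed to [count_inflections()].
#' @param crit_eps Chord-frame dy/ds zero tolerance for
#'   [count_critical_points()]. Both tolerances default well above the
#'   sub-pixel centerline noise floor and well below the curvature and
#'   slope scales of real undulations.
#' @param scales,threshold,min_diameter Passed to [segment_vessels()].
#' @param ground_truth Optional ground-truth tibble for artery/vein labels.
#' @return A tibble with one row per segment: `segment_id`, `vessel_type`,
#'   `sd_theta`, `n_critical`, `m_ratio`, `la`, `lc`, `vti`, `vii`,
#'   `x`, `y`, `angle`.
#' @export
measure_tortuosity <- function(pair, annulus = c(1.5, 5),
                               regularization = 3e-5, min_chain = 20,
                               kappa_eps = 4e-3, endpoint_buffer = 2,
                               crit_eps = 0.01,
                               scales = c(1.5, 2.5, 3.5), threshold = 0.25,
                               min_diameter = 25, ground_truth = NULL) {
  stopifnot(inherits(pair, "fundus_pair"))
  img <- pair$image_532
  ann <- annulus_mask(pair$onh_center, pair$onh_radius,
                      annulus[1], annulus[2], dim(img))
  roi <- radial_band(pair$onh_center,
                     max(annulus[1] * pair$onh_radius - 8,
                         pair$onh_radius + 3),
                     annulus[2] * pair$onh_radius + 8, dim(img))
  seg_img <- suppress_onh(img, pair$onh_center, pair$onh_radius)
  mask <- segment_vessels(seg_img, scales = scales, threshold = threshold,
                          min_diameter = min_diameter,
                          um_per_px = pair$um_per_px, roi = roi)
  chains <- extract_centerlines(mask, ann, min_length = min_chain)
  rows <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    res <- tryCatch({
      ch_ref <- refine_chain_subpixel(ch, img)
      cl <- smooth_centerline(ch_ref, regularization = regularization)
      rec <- compute_vti(cl, kappa_eps = kappa_eps,
                         endpoint_buffer = endpoint_buffer,
                         crit_eps = crit_eps)
      infl <- count_inflections(cl, kappa_eps, endpoint_buffer)
      mid <- ch[ceiling(nrow(ch) / 2), ]
      ang <- atan2(mid$y - pair$onh_center[2],
                   mid$x - pair$onh_center[1]) * 180 / pi
      mutate(rec,
             segment_id = sprintf("seg%02d", ci),
             vessel_type = match_vessel_type(ang, ground_truth),
             vii = infl$vii,
             x = mid$x, y = mid$y, angle = ang,
             .before = 1)
    },
    oxy_too_short = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows)) list_rbind(rows) else tibble(
    segment_id = character(), vessel_type = character(),
    vii = integer(), sd_theta = numeric(), n_critical = integer(),
    m_ratio = numeric(), la = numeric(), lc = numeric(), vti = numeric(),
    x = numeric(), y = numeric(), angle = numeric())
}
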