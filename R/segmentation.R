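# Vessel segmentation: multiscale Frangi vesselness + caliber filtering.

# Radial band mask in absolute pixel radii around a center point.
radial_band <- function(center, rmin_px, rmax_px, dim) {
  xs <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]), dim[1], dim[2])
  d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  d >= rmin_px & d < rmax_px
}

# Replace the bright ONH disc by the median intensity of the immediately
# surrounding band, so the disc's step edge produces no spurious ridge
# response in the vesselness filter. The ONH geometry is given by the
# annotation, never detected.
suppress_onh <- function(img, center, radius, pad = 2) {
  xs <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  ys <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  band <- d >= radius + pad & d < radius + pad + 6
  img[d < radius + pad] <- median(img[band])
  img
}

# Shift a matrix by (dy, dx) with zero padding.
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Frangi vesselness for dark tubular structures on a bright background.
# For each scale sigma the image is Gaussian-smoothed, the scale-normalized
# Hessian eigenvalues (|l1| <= |l2|) are computed, and
#   V = exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2))),  l2 > 0
# with Rb = l1/l2 (blob suppression) and S = sqrt(l1^2 + l2^2) (structure
# strength, c defaulting to half its per-scale maximum). The response is the
# pixelwise maximum over scales.
#
# @param img Numeric matrix.
# @param scales Gaussian scales (px); roughly vessel radius / sqrt(2).
# @param beta Blob-suppression sensitivity.
# @param c Structure-strength sensitivity; NULL = half max(S) per scale.
#' @noRd
frangi_vesselness <- function(img, scales = c(1.5, 2.5, 3.5), beta = 0.5,
                              c = NULL, roi = NULL) {
  v <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- EBImage::gblur(img, sigma = s)
    ixx <- (shift_mat(sm, 0, 1) - 2 * sm + shift_mat(sm, 0, -1)) * s^2
    iyy <- (shift_mat(sm, 1, 0) - 2 * sm + shift_mat(sm, -1, 0)) * s^2
    ixy <- (shift_mat(sm, 1, 1) - shift_mat(sm, 1, -1) -
              shift_mat(sm, -1, 1) + shift_mat(sm, -1, -1)) / 4 * s^2
    half_tr <- (ixx + iyy) / 2
    rad <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
    mu1 <- half_tr + rad
    mu2 <- half_tr - rad
    swap <- abs(mu1) > abs(mu2)
    l1 <- ifelse(swap, mu2, mu1)  # smaller magnitude
    l2 <- ifelse(swap, mu1, mu2)
    s2 <- l1^2 + l2^2
    cc <- if (is.null(c)) {
      sqrt(max(if (is.null(roi)) s2 else s2[roi])) / 2
    } else c
    if (cc == 0) next
    rb2 <- (l1 / l2)^2
    vs <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    vs[l2 <= 0 | !is.finite(vs)] <- 0
    v <- pmax(v, vs)
  }
  if (!is.null(roi)) v[!roi] <- 0
  v
}

#' Circumpapillary annulus mask
#'
#' Marks pixels whose distance `d` from the optic nerve head center satisfies
#' `inner_factor * r <= d < outer_factor * r`. The oximetry annulus uses
#' factors (1, 2); tortuosity uses (1.5, 5).
#'
#' @param onh_center Numeric `c(x, y)` in pixels.
#' @param onh_radius ONH radius in pixels.
#' @param inner_factor,outer_factor Annulus bounds in ONH radii,
#'   `0 < inner < outer`.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return A logical matrix.
#' @export
annulus_mask <- function(onh_center, onh_radius, inner_factor, outer_factor,
                         dim) {
  if (!(inner_factor > 0 && inner_factor < outer_factor)) {
    abort("Require 0 < inner_factor < outer_factor.",
          class = "oxy_invalid_geometry")
  }
  stopifnot_scalar_num(onh_radius, "onh_radius", positive = TRUE)
  xs <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]), dim[1], dim[2])
  d <- sqrt((xs - onh_center[1])^2 + (ys - onh_center[2])^2)
  d >= inner_factor * onh_radius & d < outer_factor * onh_radius
}

#' Segment vessels with a multiscale Frangi filter
#'
#' Computes the Frangi vesselness response (dark vessels on bright
#' background), thresholds it relative to its maximum, and removes connected
#' components whose median local width (twice the median distance-transform
#' value along the component skeleton) falls below `min_diameter`. This
#' caliber filter excludes capillaries below the 25 um analysis cutoff.
#'
#' @param image Numeric intensity matrix.
#' @param scales Frangi Gaussian scales in pixels.
#' @param threshold Relative vesselness threshold in (0, 1).
#' @param min_diameter Minimum vessel caliber to keep, micrometers.
#' @param um_per_px Pixel scale.
#' @param min_component_px Minimum component size in pixels.
#' @param roi Optional logical matrix restricting detection (and the
#'   vesselness normalization) to a region of interest, e.g. the analysis
#'   annulus with the bright ONH disc excluded so the disc-edge response
#'   does not dominate the response normalization.
#' @return A logical mask matrix. An all-constant image yields an empty mask.
#' @export
segment_vessels <- function(image, scales = c(1.5, 2.5, 3.5),
                            threshold = 0.25, min_diameter = 25,
                            um_per_px = 10, min_component_px = 20,
                            roi = NULL) {
  if (length(image) == 0) abort("`image` is empty.")
  if (min_diameter < 0) abort("`min_diameter` must be >= 0.")
  v <- frangi_vesselness(image, scales, roi = roi)
  vmax <- max(v)
  if (vmax <= .Machine$double.eps) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  mask <- v > threshold * vmax
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask & FALSE)
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  skel <- thin_mask(mask)
  keep <- logical(max(lab))
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    if (sum(comp) < min_component_px) next
    sk_idx <- which(comp & skel)
    wpx <- component_width_px(image, sk_idx, nrow(image))
    if (!is.finite(wpx)) {
      # no measurable intensity dip: fall back to the mask half-width
      wpx <- if (length(sk_idx)) 2 * median(dm[sk_idx]) else
        2 * max(dm[comp])
    }
    keep[l] <- wpx * um_per_px >= min_diameter
  }
  matrix(lab %in% which(keep), nrow(image), ncol(image))
}

# Median FWHM width (px) of a component, measured on the image itself at
# up to 7 skeleton points. The mask width floors at the smallest filter
# scale, so sub-caliber vessels would otherwise evade the diameter filter;
# the image profile keeps the true caliber. Local tangents come from a PCA
# of the surrounding skeleton points.
component_width_px <- function(image, sk_idx, nr) {
  if (length(sk_idx) < 5) return(NA_real_)
  ys <- (sk_idx - 1) %% nr + 1
  xs <- (sk_idx - 1) %/% nr + 1
  take <- unique(round(seq(1, length(sk_idx),
                           length.out = min(7, length(sk_idx)))))
  pos <- seq(-12, 12, by = 0.5)
  widths <- numeric(0)
  for (i in take) {
    nb <- which(abs(xs - xs[i]) <= 5 & abs(ys - ys[i]) <= 5)
    if (length(nb) < 3) next
    cc <- cbind(xs[nb] - mean(xs[nb]), ys[nb] - mean(ys[nb]))
    ev <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
    nxv <- -ev[2]; nyv <- ev[1]
    px <- xs[i] + pos * nxv
    py <- ys[i] + pos * nyv
    ok <- px >= 1 & px <= ncol(image) & py >= 1 & py <= nr
    if (sum(ok) < 15) next
    w <- tryCatch({
      b <- fwhm_bounds(pos[ok], sample_bicubic(image, px[ok], py[ok]))
      b[["right"]] - b[["left"]]
    }, oxy_no_vessel = function(e) NA_real_)
    if (is.finite(w)) widths <- c(widths, w)
  }
  if (length(widths) >= 3) median(widths) else NA_real_
}
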