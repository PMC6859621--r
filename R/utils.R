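# Internal numeric helpers shared across modules.

# Bilinear interpolation of a matrix image at continuous (x, y) positions.
# x indexes columns, y rows, both 1-based. Positions must lie inside
# [1, ncol] x [1, nrow]; callers are responsible for bounds checks.
sample_bilinear <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1), nc - 1)
  y0 <- pmin(pmax(floor(y), 1), nr - 1)
  fx <- x - x0
  fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Catmull-Rom bicubic interpolation at continuous (x, y) positions.
# Sharper than bilinear: narrow vessel dips (FWHM ~ 2-3 px) keep their
# depth, which the FWHM/optical-density estimators rely on. Positions must
# lie inside the image; border pixels are clamp-padded.
sample_bicubic <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1), nc - 1)
  y0 <- pmin(pmax(floor(y), 1), nr - 1)
  fx <- x - x0
  fy <- y - y0
  kcr <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  out <- numeric(length(x))
  for (j in -1:2) {
    yy <- pmin(pmax(y0 + j, 1), nr)
    wy <- kcr(fy - j)
    row_acc <- numeric(length(x))
    for (i in -1:2) {
      xx <- pmin(pmax(x0 + i, 1), nc)
      row_acc <- row_acc + kcr(fx - i) * img[cbind(yy, xx)]
    }
    out <- out + wy * row_acc
  }
  out
}

# Wrap angles (degrees) to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Count sign changes in a numeric sequence, treating |v| < eps as zero.
# A change requires opposite signs across any run of sub-threshold values.
# Returns the count and the index pairs (last index of the old sign, first
# index of the new sign) bracketing each crossing.
sign_changes <- function(v, eps = 0) {
  s <- sign(v)
  s[abs(v) < eps] <- 0
  idx <- which(s != 0)
  if (length(idx) < 2) {
    return(list(count = 0L, at = matrix(numeric(0), ncol = 2)))
  }
  sv <- s[idx]
  flips <- which(sv[-1] != sv[-length(sv)])
  list(
    count = length(flips),
    at = cbind(idx[flips], idx[flips + 1])
  )
}

# Truncated normal draw by resampling (light tails only; used for vitals).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
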