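# Shannon entropy and mutual information of tortuosity metrics.

# Equal-width histogram bin assignment over the data range.
bin_values <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

entropy_from_probs <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base)) + 0  # "+ 0" normalizes -0 to 0
}

#' Shannon entropy of a sample
#'
#' Bins the values into an equal-width histogram over the data range
#' (default `ceiling(sqrt(n))` bins) and returns
#' `H = -sum p_i log2 p_i` over non-empty bins. A degenerate sample whose
#' values all fall in one bin has entropy 0; the maximum is `log2(n_bins)`
#' for equal occupancy.
#'
#' @param x Numeric vector with at least one finite value.
#' @param n_bins Number of histogram bins; default `ceiling(sqrt(n))`.
#' @param base Logarithm base (2 gives bits).
#' @return Entropy in bits (for base 2).
#' @export
shannon_entropy <- function(x, n_bins = NULL, base = 2) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("`x` has no finite values.")
  n_bins <- n_bins %||% ceiling(sqrt(length(x)))
  bins <- bin_values(x, n_bins)
  entropy_from_probs(tabulate(bins) / length(x), base = base)
}

#' Mutual information between two samples
#'
#' Bins each variable with its own equal-width histogram (default
#' `ceiling(sqrt(n))` bins), forms the joint histogram, and evaluates
#' `MI(x, y) = sum_ij p(x_i, y_j) * log( p(x_i, y_j) / (p(x_i) p(y_j)) )`
#' in base 2. MI is 0 for independent variables and at most
#' `min(H(x), H(y))`; `MI(x, x) = H(x)`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param n_bins Bins per variable; default `ceiling(sqrt(n))`.
#' @param base Logarithm base.
#' @return Mutual information in bits (for base 2).
#' @export
mutual_information <- function(x, y, n_bins = NULL, base = 2) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("Need at least 2 paired finite values.")
  n_bins <- n_bins %||% ceiling(sqrt(length(x)))
  bx <- bin_values(x, n_bins)
  by <- bin_values(y, n_bins)
  joint <- table(factor(bx, levels = seq_len(max(bx))),
                 factor(by, levels = seq_len(max(by))))
  mutual_information_joint(joint / sum(joint), base = base)
}

#' Mutual information of a joint probability table
#'
#' Direct evaluation of the mutual information formula on a joint
#' distribution matrix: `MI = sum_ij p_ij log(p_ij / (p_i. p_.j))`. A table
#' that factorizes exactly into its marginals gives 0.
#'
#' @param joint Non-negative matrix summing to 1 (within 1e-6).
#' @param base Logarithm base.
#' @return Mutual information (bits for base 2); >= 0 up to rounding.
#' @export
mutual_information_joint <- function(joint, base = 2) {
  joint <- as.matrix(joint)
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-6) {
    abort("`joint` must be a probability table summing to 1.")
  }
  px <- rowSums(joint)
  py <- colSums(joint)
  prod <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / prod[nz], base = base))
}
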