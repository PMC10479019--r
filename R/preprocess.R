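#' Z-score outlier removal on a point set
#'
#' Keeps the points whose x and y coordinates both lie within
#' \code{threshold} standard deviations of the respective coordinate mean,
#' with means and standard deviations computed over the input set. An axis
#' with zero standard deviation filters nothing. Order is preserved.
#'
#' @param points n x 2 numeric matrix (x, y).
#' @param threshold positive z-score cut-off; default 3.
#' @return the retained subset, in input order.
#' @export
zscoreFilter <- function(points, threshold = 3) {
  .assertPoints(points)
  if (nrow(points) < 3) stop("too few points (need >= 3)", call. = FALSE)
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be positive", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  keep <- rep(TRUE, nrow(points))
  for (axis in 1:2) {
    v <- points[, axis]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) next
    keep <- keep & (abs(v - mean(v)) / s <= threshold)
  }
  if (!any(keep)) stop("all points rejected as outliers", call. = FALSE)
  points[keep, , drop = FALSE]
}

#' Histogram equalization of an 8-bit image
#'
#' Classic 256-bin cumulative-histogram equalization:
#' out = round(255 * (cdf(g) - cdf_min) / (N - cdf_min)) with cdf counted in
#' pixels and cdf_min the count of the first occupied level. The level
#' mapping is monotone, so pixel rank order is preserved; a constant image
#' maps to a constant image.
#'
#' @param image integer matrix, gray levels 0-255.
#' @return equalized image (integer matrix, 0-255).
#' @export
histEqualize <- function(image) {
  .assertImage(image)
  g <- as.integer(round(image))
  counts <- tabulate(g + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdfMin <- cdf[which(counts > 0)[1L]]
  N <- length(g)
  if (N == cdfMin) return(matrix(g, nrow = nrow(image)))  # constant image
  lut <- as.integer(round(255 * (cdf - cdfMin) / (N - cdfMin)))
  lut <- pmax(0L, lut)
  matrix(lut[g + 1L], nrow = nrow(image))
}
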