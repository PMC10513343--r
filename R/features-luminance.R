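#' RGB to grayscale (ITU-R 601-2 luma)
#'
#' `L = 0.299 R + 0.587 G + 0.114 B`, on the 0..255 scale.
#'
#' @param img `h x w x 3` array with channels in \[0, 255\].
#' @return `h x w` numeric matrix of luminance values.
#' @export
to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' RMS contrast
#'
#' Population standard deviation of the grayscale pixel intensities.
#'
#' @param g grayscale matrix.
#' @return nonnegative scalar.
#' @export
rms_contrast <- function(g) {
  stopifnot(length(g) > 0)
  m <- mean(g)
  sqrt(mean((g - m)^2))
}

#' Luminance-histogram skewness and kurtosis
#'
#' Third and fourth standardized moments of the pixel-intensity
#' distribution; kurtosis is reported as excess kurtosis by default.
#'
#' @param g grayscale matrix with nonzero contrast.
#' @param excess if `TRUE` (default) subtract 3 from the fourth moment.
#' @return named vector `c(skewness = , kurtosis = )`.
#' @export
luminance_moments <- function(g, excess = TRUE) {
  m <- mean(g)
  dev <- g - m
  s2 <- mean(dev^2)
  if (s2 <= .Machine$double.eps)
    stop("moments are undefined for a constant image")
  skew <- mean(dev^3) / s2^1.5
  kurt <- mean(dev^4) / s2^2 - if (excess) 3 else 0
  c(skewness = skew, kurtosis = kurt)
}

#' Center-of-mass balance
#'
#' Intensity-weighted centroid of the image, normalized by canvas size.
#' Pixel centers sit at `+0.5` in 0-based coordinates, so a uniform image
#' has CoM exactly `(0.5, 0.5)`. The deviation from the central axes
#' (`CoM = 0.5`) is left to downstream analysis.
#'
#' @param g grayscale matrix with positive total intensity.
#' @return named vector `c(horizontal = , vertical = )` of normalized CoM
#'   coordinates (horizontal measured from the left edge, vertical from the
#'   top edge).
#' @export
balance_com <- function(g) {
  tot <- sum(g)
  if (tot <= 0) stop("center of mass is undefined for an all-black image")
  h <- nrow(g); w <- ncol(g)
  xs <- (seq_len(w) - 0.5) / w   # column centers, normalized
  ys <- (seq_len(h) - 0.5) / h
  c(horizontal = sum(colSums(g) * xs) / tot,
    vertical = sum(rowSums(g) * ys) / tot)
}
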