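#' sRGB to CIELAB
#'
#' Closed-form, vectorized sRGB (D65) to CIELAB conversion: inverse sRGB
#' gamma, the sRGB RGB-to-XYZ matrix, then the CIE f() cube-root map.
#'
#' @param rgb numeric matrix with columns R, G, B in \[0, 255\].
#' @return matrix with columns L, a, b.
#' @export
rgb_to_lab <- function(rgb) {
  srgb <- rgb / 255
  lin <- ifelse(srgb <= 0.04045, srgb / 12.92, ((srgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.0, 1.08883)
  xyz <- sweep(xyz, 2, white, "/")
  d <- 6 / 29
  f <- ifelse(xyz > d^3, xyz^(1 / 3), xyz / (3 * d^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

# h x w x 3 RGB array -> h x w x 3 Lab array
.img_to_lab <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  lab <- rgb_to_lab(cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3])))
  array(lab, dim = c(h, w, 3))
}

# separable binomial blur (the small Gaussian of the frequency-tuned
# construction), replicated borders
.binomial_blur <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  blur1 <- function(x) {  # along rows (first dim)
    n <- nrow(x)
    idx <- function(d) pmin(pmax(seq_len(n) + d, 1L), n)
    k[1] * x[idx(-2L), , drop = FALSE] + k[2] * x[idx(-1L), , drop = FALSE] +
      k[3] * x + k[4] * x[idx(1L), , drop = FALSE] +
      k[5] * x[idx(2L), , drop = FALSE]
  }
  t(blur1(t(blur1(m))))
}

#' Frequency-tuned saliency map
#'
#' Per-pixel Euclidean distance in Lab space between the image's mean Lab
#' vector and the Gaussian-blurred image's Lab values, rescaled to
#' \[0, 255\].
#'
#' @param img `h x w x 3` RGB array in \[0, 255\].
#' @return `saliency_map`: matrix of the image's shape with values in
#'   \[0, 255\].
#' @export
ft_saliency <- function(img) {
  lab <- .img_to_lab(img)
  mu <- c(mean(lab[, , 1]), mean(lab[, , 2]), mean(lab[, , 3]))
  d2 <- (.binomial_blur(lab[, , 1]) - mu[1])^2 +
        (.binomial_blur(lab[, , 2]) - mu[2])^2 +
        (.binomial_blur(lab[, , 3]) - mu[3])^2
  .rescale_255(sqrt(d2))
}

.rescale_255 <- function(m) {
  lo <- min(m); hi <- max(m)
  out <- if (hi - lo > 1e-12) (m - lo) / (hi - lo) * 255 else m * 0
  structure(out, class = c("saliency_map", class(out)))
}

#' Graph-based manifold-ranking saliency map
#'
#' Two-stage manifold ranking over superpixels: the image is segmented into
#' about `n_superpixels` SLIC superpixels; a k-regular graph joins spatial
#' neighbors, neighbors-of-neighbors and all boundary superpixels, with
#' edge weights `exp(-||c_i - c_j|| / sigma2)` on mean (normalized) Lab
#' colors. Stage one ranks against each of the four boundary-seed
#' indicators and combines the complements by product; stage two re-ranks
#' with the mean-thresholded stage-one map as foreground seeds. The
#' closed-form ranking is `f = (D - alpha W)^{-1} y`.
#'
#' @param img `h x w x 3` RGB array in \[0, 255\].
#' @param n_superpixels target superpixel count (default 200).
#' @param alpha ranking balance parameter (default 0.99).
#' @param sigma2 edge-weight bandwidth (default 0.1).
#' @return `saliency_map`: matrix of the image's shape, values in
#'   \[0, 255\].
#' @export
gbmr_saliency <- function(img, n_superpixels = 200L, alpha = 0.99,
                          sigma2 = 0.1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  lab <- .img_to_lab(img)
  labels <- slic_cpp(as.numeric(lab), h, w, as.integer(n_superpixels),
                     10.0, 10L)
  ns <- max(labels)
  if (ns < 4) stop("segmentation yielded fewer than 4 superpixels")
  # mean normalized Lab per superpixel
  nf <- cbind(as.vector(lab[, , 1]) / 100,
              (as.vector(lab[, , 2]) + 128) / 255,
              (as.vector(lab[, , 3]) + 128) / 255)
  lv <- as.vector(labels)
  cols <- vapply(seq_len(3), function(ch)
    as.vector(tapply(nf[, ch], lv, mean)), numeric(ns))
  # adjacency from 4-neighborhood label transitions
  adj <- matrix(FALSE, ns, ns)
  a <- labels[-h, ]; b <- labels[-1, ]
  sel <- a != b; adj[cbind(a[sel], b[sel])] <- TRUE
  a <- labels[, -w]; b <- labels[, -1]
  sel <- a != b; adj[cbind(a[sel], b[sel])] <- TRUE
  adj <- adj | t(adj)
  # neighbors-of-neighbors + boundary closure
  adj2 <- adj | ((adj %*% adj) > 0)
  boundary <- sort(unique(c(labels[1, ], labels[h, ], labels[, 1],
                            labels[, w])))
  adj2[boundary, boundary] <- TRUE
  diag(adj2) <- FALSE
  dist <- as.matrix(stats::dist(cols))
  W <- exp(-dist / sigma2) * adj2
  D <- diag(rowSums(W))
  Ainv <- solve(D - alpha * W)
  rank_norm <- function(y) {
    f <- as.vector(Ainv %*% y)
    lo <- min(f); hi <- max(f)
    if (hi - lo > 1e-12) (f - lo) / (hi - lo) else f * 0
  }
  sides <- list(unique(labels[1, ]), unique(labels[h, ]),
                unique(labels[, 1]), unique(labels[, w]))
  s_bg <- rep(1, ns)
  for (side in sides) {
    y <- numeric(ns); y[side] <- 1
    s_bg <- s_bg * (1 - rank_norm(y))
  }
  y_fg <- as.numeric(s_bg >= mean(s_bg))
  sal <- rank_norm(y_fg)
  .rescale_255(matrix(sal[lv], h, w))
}

#' Mean and standard deviation of a saliency map
#'
#' The mean measures the strength of the saliency; the standard deviation
#' its spatial extent.
#'
#' @param m saliency map (matrix in \[0, 255\]).
#' @return named vector `c(mean = , std = )`.
#' @export
saliency_stats <- function(m) {
  mu <- mean(m)
  c(mean = mu, std = sqrt(mean((m - mu)^2)))
}
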