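#' Sobel gradients
#'
#' 3x3 Sobel operators with replicated borders. Returns the gradient
#' magnitude and orientation (over `[0, 2*pi)`).
#'
#' @param g grayscale matrix.
#' @return list with matrices `gx`, `gy`, `magnitude`, `orientation`.
#' @export
sobel_gradients <- function(g) {
  h <- nrow(g); w <- ncol(g)
  pad <- function(m) {  # replicate borders
    m <- rbind(m[1, , drop = FALSE], m, m[h, , drop = FALSE])
    cbind(m[, 1, drop = FALSE], m, m[, w, drop = FALSE])
  }
  p <- pad(g)
  sh <- function(dy, dx) p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  # x increases with column index, y downward with row index
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% (2 * pi)
  list(gx = gx, gy = gy, magnitude = mag, orientation = ori)
}

# magnitude-weighted orientation histogram over [0, 2*pi), n_bins bins
.hog_hist <- function(mag, ori, n_bins) {
  bin <- pmin(floor(ori / (2 * pi) * n_bins) + 1L, n_bins)
  h <- vapply(seq_len(n_bins), function(b) sum(mag[bin == b]), numeric(1))
  h
}

#' PHOG-based anisotropy, complexity and self-similarity
#'
#' Gradient magnitude and orientation come from Sobel operators; HOG
#' histograms (magnitude-weighted, 16 bins over `[0, 360)` degrees) are
#' built for the whole image (ground level) and for every cell of a
#' quad-tree pyramid. At the analysis level (default 3, an 8x8 grid):
#' * `complexity_gs` -- mean gradient magnitude of the image;
#' * `anisotropy` -- standard deviation of the normalized cell-histogram
#'   bin values pooled over all cells at the level;
#' * `self_similarity` -- mean histogram-intersection kernel between each
#'   cell histogram and the ground histogram (both normalized to sum 1).
#'
#' @param g grayscale matrix.
#' @param levels pyramid depth (default 3); reduced with a warning if the
#'   image has fewer than `2^levels` pixels per side.
#' @param n_bins orientation bins (default 16).
#' @return named vector `c(anisotropy = , complexity_gs = ,
#'   self_similarity = )`.
#' @export
phog_features <- function(g, levels = 3L, n_bins = 16L) {
  stopifnot(levels >= 1)
  h <- nrow(g); w <- ncol(g)
  while (2^levels > min(h, w)) {
    warning("image too small for requested pyramid level; reducing")
    levels <- levels - 1L
  }
  gr <- sobel_gradients(g)
  complexity <- mean(gr$magnitude)
  ground <- .hog_hist(gr$magnitude, gr$orientation, n_bins)
  gtot <- sum(ground)
  if (gtot <= 1e-12) {
    # featureless image: no edge structure at any level
    return(c(anisotropy = 0, complexity_gs = complexity, self_similarity = 1))
  }
  ground <- ground / gtot
  ncell <- 2^levels
  ri <- cut(seq_len(h), ncell, labels = FALSE)
  ci <- cut(seq_len(w), ncell, labels = FALSE)
  hists <- matrix(0, ncell * ncell, n_bins)
  idx <- 1L
  for (i in seq_len(ncell)) {
    for (j in seq_len(ncell)) {
      sel_r <- ri == i; sel_c <- ci == j
      m <- gr$magnitude[sel_r, sel_c]
      o <- gr$orientation[sel_r, sel_c]
      hh <- .hog_hist(m, o, n_bins)
      tot <- sum(hh)
      if (tot > 1e-12) hists[idx, ] <- hh / tot
      idx <- idx + 1L
    }
  }
  nonzero <- rowSums(hists) > 0
  hik <- apply(hists[nonzero, , drop = FALSE], 1,
               function(hh) sum(pmin(hh, ground)))
  c(anisotropy = stats::sd(as.vector(hists[nonzero, , drop = FALSE])),
    complexity_gs = complexity,
    self_similarity = mean(hik))
}
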