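# Oriented even/odd (complex Gabor) filter bank, applied by FFT (circular
# convolution). Filter FFTs are cached per image size so a whole stimulus
# set pays the filter setup once.

.genart_cache <- new.env(parent = emptyenv())

# complex Gabor kernel sampled on a symmetric grid (-r..r), DC-free even part
.gabor_kernel <- function(wavelength, theta, sigma = 0.5 * wavelength,
                          gamma = 0.5) {
  r <- ceiling(3 * sigma / min(1, gamma))
  xs <- -r:r
  X <- matrix(xs, 2 * r + 1, 2 * r + 1, byrow = TRUE)   # column = x
  Y <- matrix(xs, 2 * r + 1, 2 * r + 1)                 # row = y
  xp <- X * cos(theta) + Y * sin(theta)
  yp <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xp^2 + (gamma * yp)^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xp / wavelength)
  odd <- env * sin(2 * pi * xp / wavelength)
  even <- even - mean(even)  # zero DC: constant images give zero response
  complex(real = even, imaginary = odd) |>
    matrix(2 * r + 1, 2 * r + 1)
}

# place a small centered kernel into an h x w matrix with wraparound so its
# center sits at index (1, 1); FFT of that gives the circular-conv transfer
.embed_kernel_fft <- function(kern, h, w) {
  # crop oversized kernels centrally (small images only); the grid stays
  # symmetric so mirror/rotation response identities are preserved
  r_max <- (min(h, w) - 1L) %/% 2L
  r0 <- (nrow(kern) - 1L) %/% 2L
  if (r0 > r_max) {
    keep <- (r0 + 1L - r_max):(r0 + 1L + r_max)
    kern <- kern[keep, keep]
    kern <- kern - mean(Re(kern))  # re-zero the DC of the even part
  }
  kh <- nrow(kern); kw <- ncol(kern)
  r <- (kh - 1L) / 2L
  big <- matrix(0 + 0i, h, w)
  ri <- ((-r:r) %% h) + 1L
  ci <- ((-r:r) %% w) + 1L
  big[ri, ci] <- kern
  stats::fft(big)
}

#' Oriented filter bank for an image size
#'
#' 24 orientations over `[0, 180)` degrees at two spatial scales
#' (wavelengths 8 and 16 px by default), as complex even/odd pairs. Cached
#' per `(h, w, parameters)`.
#'
#' @param h,w image size in pixels.
#' @param n_orientations number of orientations (default 24).
#' @param wavelengths filter wavelengths in pixels.
#' @return list with the orientation angles and the per-filter transfer
#'   functions (FFTs).
#' @keywords internal
gabor_bank <- function(h, w, n_orientations = 24L, wavelengths = c(8, 16)) {
  key <- paste("gabor", h, w, n_orientations,
               paste(wavelengths, collapse = "_"), sep = ":")
  if (!is.null(.genart_cache[[key]])) return(.genart_cache[[key]])
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  ffts <- vector("list", n_orientations * length(wavelengths))
  idx <- 1L
  for (s in seq_along(wavelengths)) {
    for (k in seq_len(n_orientations)) {
      ffts[[idx]] <- .embed_kernel_fft(.gabor_kernel(wavelengths[s], thetas[k]),
                                       h, w)
      idx <- idx + 1L
    }
  }
  bank <- list(thetas = thetas, n_orientations = n_orientations,
               n_scales = length(wavelengths), ffts = ffts)
  .genart_cache[[key]] <- bank
  bank
}

# energy (modulus of complex response) maps for every filter in the bank.
# Returns per-filter total mass and, optionally, full maps for a subset of
# orientations (used by the symmetry scores).
.gabor_energy <- function(g, bank, keep_orientations = integer(0)) {
  h <- nrow(g); w <- ncol(g)
  Fg <- stats::fft(g)
  n_filt <- length(bank$ffts)
  mass <- matrix(0, bank$n_orientations, bank$n_scales)
  keep <- array(0, dim = c(h, w, length(keep_orientations), bank$n_scales))
  npix <- h * w
  for (s in seq_len(bank$n_scales)) {
    for (k in seq_len(bank$n_orientations)) {
      idx <- (s - 1L) * bank$n_orientations + k
      resp <- stats::fft(Fg * bank$ffts[[idx]], inverse = TRUE) / npix
      e <- Mod(resp)
      mass[k, s] <- sum(e)
      ki <- match(k, keep_orientations)
      if (!is.na(ki)) keep[, , ki, s] <- e
    }
  }
  list(mass = mass, maps = keep)
}

#' Edge-orientation histogram
#'
#' Total rectified response mass of the oriented even/odd filter bank per
#' orientation, normalized to sum 1. Bin `k` indexes the filter's
#' luminance-modulation direction `(k-1) * 180 / n` degrees, i.e. the
#' normal of the edges it responds to (bin 1 collects vertical edges).
#'
#' @param g grayscale matrix.
#' @param n_orientations number of orientation bins (default 24).
#' @return numeric vector of length `n_orientations` summing to 1.
#' @export
orientation_histogram <- function(g, n_orientations = 24L) {
  if (n_orientations < 2) stop("need at least 2 orientations")
  bank <- gabor_bank(nrow(g), ncol(g), n_orientations)
  mass <- rowSums(.gabor_energy(g, bank)$mass)
  tot <- sum(mass)
  if (tot <= 1e-12) stop("empty orientation histogram (all-zero image)")
  mass / tot
}

#' First-order entropy of an orientation histogram
#'
#' Shannon entropy `-sum p log2 p`; maximal (`log2 n`) for a uniform
#' distribution of edge orientations.
#'
#' @param h normalized histogram (nonnegative, sums to 1).
#' @return entropy in bits.
#' @export
first_order_entropy <- function(h) {
  p <- h[h > 0]
  -sum(p * log2(p))
}

#' Gabor edge density
#'
#' Mean over pixels of the summed rectified filter responses, normalized by
#' the bank size. Zero for a constant image.
#'
#' @param g grayscale matrix.
#' @param n_orientations number of orientations (default 24).
#' @return nonnegative scalar.
#' @export
edge_density <- function(g, n_orientations = 24L) {
  bank <- gabor_bank(nrow(g), ncol(g), n_orientations)
  mass <- .gabor_energy(g, bank)$mass
  sum(mass) / (length(g) * length(bank$ffts))
}

#' Mirror-symmetry scores from oriented filter responses
#'
#' Energy maps of a fixed bank of oriented even/odd filters (8 orientations
#' x 2 scales) are max-pooled to a coarse grid; each score is
#' `1 - L1(P, P') / sum(P + P')` where `P'` is the pooled map stack of the
#' mirrored image. Mirror responses are obtained exactly from the original
#' responses (a horizontal flip maps the energy map at orientation `theta`
#' to the flipped map at `pi - theta`), so a mirror-symmetric image scores
#' exactly 1. Scores lie in `[0, 1]`.
#'
#' @param img `h x w x 3` RGB array in \[0, 255\] (a grayscale matrix is
#'   also accepted).
#' @param pool_grid pooling grid size (default 8, i.e. 8 x 8 cells).
#' @return named vector `c(lr = , ud = , lrud = )` for left-right mirror,
#'   up-down mirror, and 180-degree rotation symmetry.
#' @export
symmetry_scores <- function(img, pool_grid = 8L) {
  g <- if (length(dim(img)) == 3) to_gray(img) else img
  n_orient <- 24L
  sym_orients <- seq(1L, n_orient, by = 3L)  # 8 orientations, multiples of pi/8
  bank <- gabor_bank(nrow(g), ncol(g), n_orient)
  en <- .gabor_energy(g, bank, keep_orientations = sym_orients)$maps
  n_so <- length(sym_orients)
  # orientation index of pi - theta within the symmetry subset
  mirr <- vapply(seq_len(n_so), function(i) {
    k <- sym_orients[i]
    km <- ((n_orient - (k - 1L)) %% n_orient) + 1L
    match(km, sym_orients)
  }, integer(1))
  pool <- function(m) .max_pool(m, pool_grid)
  P <- array(0, dim = c(pool_grid, pool_grid, n_so, dim(en)[4]))
  for (s in seq_len(dim(en)[4]))
    for (i in seq_len(n_so)) P[, , i, s] <- pool(en[, , i, s])
  flip_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  flip_rows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  P_lr <- P; P_ud <- P; P_ro <- P
  for (s in seq_len(dim(en)[4]))
    for (i in seq_len(n_so)) {
      P_lr[, , i, s] <- pool(flip_cols(en[, , mirr[i], s]))
      P_ud[, , i, s] <- pool(flip_rows(en[, , mirr[i], s]))
      P_ro[, , i, s] <- pool(flip_rows(flip_cols(en[, , i, s])))
    }
  score <- function(A, B) {
    denom <- sum(A) + sum(B)
    if (denom <= 1e-12) return(1)  # featureless image: trivially symmetric
    1 - sum(abs(A - B)) / denom
  }
  c(lr = score(P, P_lr), ud = score(P, P_ud), lrud = score(P, P_ro))
}

# max-pool a matrix onto a grid x grid summary (blocks as equal as possible)
.max_pool <- function(m, grid) {
  ri <- cut(seq_len(nrow(m)), grid, labels = FALSE)
  ci <- cut(seq_len(ncol(m)), grid, labels = FALSE)
  out <- matrix(-Inf, grid, grid)
  rmax <- vapply(seq_len(grid), function(i)
    apply(m[ri == i, , drop = FALSE], 2, max), numeric(ncol(m)))
  # rmax: ncol(m) x grid; now pool columns
  for (j in seq_len(grid))
    out[, j] <- apply(rmax[ci == j, , drop = FALSE], 2, max)
  out
}
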