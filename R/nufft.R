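#' Gridding configuration
#'
#' Parameters of the Kaiser-Bessel gridding interpolator: oversampling
#' ratio, kernel width in (oversampled) grid cells and the kernel shape
#' parameter beta. The default beta follows the standard minimal-aliasing
#' prescription for the chosen width/oversampling pair,
#' `beta = pi * sqrt((w/os)^2 * (os - 0.5)^2 - 0.8)`.
#'
#' @param matrix Nominal image matrix size (per dimension, even).
#' @param os Oversampling ratio (>= 1; default 2).
#' @param width Kernel full width in oversampled grid cells (default 4).
#' @param beta Kernel shape parameter; default from `width`/`os`.
#' @return An object of class `gridding_config`.
#' @export
gridding_config <- function(matrix, os = 2, width = 4, beta = NULL) {
  if (os < 1 || width < 2) abort("need os >= 1 and width >= 2.",
                                 class = "utecine_invalid_argument")
  m <- as.integer(matrix)
  if (m %% 2 != 0) abort("`matrix` must be even.", class = "utecine_invalid_argument")
  G <- as.integer(round(m * os))
  if (G %% 2 != 0) abort("oversampled grid must be even.", class = "utecine_invalid_argument")
  if (is.null(beta)) beta <- kb_beta(width, os)
  structure(list(matrix = m, os = os, grid = G, width = as.integer(width),
                 beta = beta),
            class = "gridding_config")
}

#' Kaiser-Bessel shape parameter for a width/oversampling pair
#' @param width Kernel full width in grid cells.
#' @param os Oversampling ratio.
#' @return beta.
#' @export
kb_beta <- function(width, os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

# Circular shift putting index dim/2 (0-based) at the origin; for even
# dimensions fftshift and its inverse coincide.
fftshift3 <- function(x) {
  d <- dim(x)
  stopifnot(all(d %% 2 == 0))
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Centered forward/inverse 3D DFT: origin of both image and k-space at
# 0-based index dim/2.
ft3c <- function(x) fftshift3(fft(fftshift3(x)))
ift3c <- function(x) fftshift3(fft(fftshift3(x), inverse = TRUE)) / length(x)

# Analytic image-domain apodization of the KB kernel: the continuous
# Fourier transform of the width-`width` kernel evaluated at pixel offset
# n - G/2 of the oversampled grid.
kb_apod1d <- function(G, width, beta) {
  nu <- ((0:(G - 1)) - G / 2) / G
  g2 <- beta^2 - (pi * width * nu)^2
  a <- ifelse(g2 > 0,
              sinh(sqrt(pmax(g2, 0))) / sqrt(pmax(g2, 1e-300)),
              sinc_safe(sqrt(pmax(-g2, 0))))
  width * a
}

sinc_safe <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

kb_apod3 <- function(cfg) {
  a <- kb_apod1d(cfg$grid, cfg$width, cfg$beta)
  outer(outer(a, a), a)
}

# Map k-space coordinates (cycles/FOV) to oversampled grid units.
k_to_grid <- function(kmat, cfg) {
  kmat * cfg$os + cfg$grid / 2
}

#' NUFFT-style forward model (image to non-Cartesian k-space)
#'
#' Approximates the continuous Fourier transform of an image sampled at
#' arbitrary k-space locations: the image is deapodized, zero-padded onto
#' the oversampled grid, FFT'd, and interpolated at the sample locations
#' with the Kaiser-Bessel kernel. Positions follow the FOV-centered
#' convention of [rasterize_frame()].
#'
#' @param img Real or complex `matrix^3` array.
#' @param kmat n x 3 matrix of k-space locations in cycles/FOV.
#' @param cfg A [gridding_config()] with matching `matrix`.
#' @return Complex vector of n samples.
#' @export
nufft_forward <- function(img, kmat, cfg) {
  stopifnot(inherits(cfg, "gridding_config"))
  m <- cfg$matrix
  if (!all(dim(img) == m)) abort("image does not match config matrix.",
                                 class = "utecine_invalid_argument")
  G <- cfg$grid
  apod <- kb_apod3(cfg)
  pad <- array(0 + 0i, dim = c(G, G, G))
  idx <- (G / 2 - m / 2 + 1):(G / 2 + m / 2)
  pad[idx, idx, idx] <- img / apod[idx, idx, idx]
  K <- ft3c(pad)
  cpp_kb_interp(as.vector(K), k_to_grid(kmat, cfg), G, cfg$width, cfg$beta)
}

#' Direct discrete Fourier transform at arbitrary k-space locations
#'
#' Brute-force evaluation of `S(k) = sum_j img_j exp(-2 pi i k . x_j)` with
#' voxel positions on the FOV-centered grid. Serves as the slow exact
#' reference for [nufft_forward()]; only practical for small matrices.
#'
#' @inheritParams nufft_forward
#' @return Complex vector of samples.
#' @export
dft_forward <- function(img, kmat, cfg = NULL) {
  m <- dim(img)[1]
  pos <- ((0:(m - 1)) - m / 2) / m
  idx <- as.matrix(expand.grid(x = pos, y = pos, z = pos))
  v <- as.vector(img)
  keep <- v != 0
  idx <- idx[keep, , drop = FALSE]
  v <- v[keep]
  out <- complex(length.out = nrow(kmat))
  for (s in seq_len(nrow(kmat))) {
    ph <- -2 * pi * (idx %*% kmat[s, ])
    out[s] <- sum(v * complex(real = cos(ph), imaginary = sin(ph)))
  }
  out
}
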