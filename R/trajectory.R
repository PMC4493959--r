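#' Spiral distribution of radial half-projection directions
#'
#' Generates `n` unit vectors distributed on a spiral that starts at the
#' north pole of the unit sphere and winds down to the south pole, so that
#' the polar coordinate is uniformly spaced in `z` and the azimuth advances
#' with an approximately constant arc-length step. Together with their
#' antipodes the directions cover the sphere nearly uniformly, which is the
#' standard way to distribute center-out (half-projection) radial spokes.
#'
#' The construction is fully deterministic: repeated calls with the same `n`
#' are bitwise identical.
#'
#' @param n Number of directions (positive integer).
#' @return A tibble with columns `index` (0-based spoke index), `x`, `y`,
#'   `z` (components of the unit direction vector). `z` is non-increasing
#'   with `index`.
#' @examples
#' spiral_directions(4)
#' @export
spiral_directions <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    abort("`n` must be a single integer >= 1.", class = "utecine_invalid_argument")
  }
  n <- as.integer(n)
  if (n == 1L) {
    return(tibble(index = 0L, x = 0, y = 0, z = 1))
  }
  z <- seq(1, -1, length.out = n)
  # Arc-length-uniform azimuth increment (Archimedean spiral on the sphere);
  # the increment is undefined at the poles, where the azimuth is arbitrary.
  s2 <- pmax(1 - z^2, 0)
  dphi <- ifelse(s2 > 0, 3.6 / sqrt(n * s2), 0)
  phi <- cumsum(dphi)
  tibble(
    index = 0:(n - 1L),
    x = sqrt(s2) * cos(phi),
    y = sqrt(s2) * sin(phi),
    z = z
  )
}

#' Radial k-space sample locations along one spoke
#'
#' Center-out readout: the first sample sits exactly at the k-space origin
#' (this is what makes the echo time ultra short) and samples are uniformly
#' spaced out to `k_max`.
#'
#' @param direction Unit 3-vector (or a one-row tibble with `x`, `y`, `z`).
#' @param n_readout Number of samples along the spoke (>= 2).
#' @param k_max Maximum sampled spatial frequency in cycles per field of
#'   view (matrix/2 for Nyquist sampling of the nominal matrix).
#' @return A numeric `n_readout` x 3 matrix of k-space coordinates
#'   (cycles/FOV).
#' @examples
#' spoke_samples(c(0, 0, 1), n_readout = 4, k_max = 64)
#' @export
spoke_samples <- function(direction, n_readout, k_max) {
  if (is.data.frame(direction)) {
    direction <- c(direction$x[1], direction$y[1], direction$z[1])
  }
  if (length(direction) != 3L || any(!is.finite(direction))) {
    abort("`direction` must be a finite 3-vector.", class = "utecine_invalid_argument")
  }
  if (length(n_readout) != 1L || n_readout < 2) {
    abort("`n_readout` must be >= 2.", class = "utecine_invalid_argument")
  }
  r <- spoke_radii(n_readout, k_max)
  outer(r, direction)
}

spoke_radii <- function(n_readout, k_max) {
  seq(0, k_max, length.out = n_readout)
}

#' Construct a full radial spoke set
#'
#' Bundles the spiral directions with the radial sampling of each spoke.
#'
#' @param n_spokes Number of half-projections.
#' @param n_readout Samples per spoke (>= 2).
#' @param k_max Maximum spatial frequency in cycles/FOV (typically
#'   matrix/2).
#' @return An object of class `spoke_set`: list with `directions` (tibble
#'   from [spiral_directions()]), `n_readout`, `k_max` and `radii`.
#' @export
spoke_set <- function(n_spokes, n_readout, k_max) {
  if (n_readout < 2) abort("`n_readout` must be >= 2.", class = "utecine_invalid_argument")
  if (k_max <= 0) abort("`k_max` must be positive.", class = "utecine_invalid_argument")
  structure(
    list(
      directions = spiral_directions(n_spokes),
      n_spokes = as.integer(n_spokes),
      n_readout = as.integer(n_readout),
      k_max = k_max,
      radii = spoke_radii(n_readout, k_max)
    ),
    class = "spoke_set"
  )
}

#' @export
print.spoke_set <- function(x, ...) {
  cat("<spoke_set>", x$n_spokes, "half-projections,", x$n_readout,
      "samples/spoke, k_max =", x$k_max, "cycles/FOV\n")
  invisible(x)
}

#' k-space coordinates of a subset of spokes
#'
#' Expands spokes into a flat matrix of 3D sample locations, readout index
#' varying fastest, in the spoke order given.
#'
#' @param spokes A [spoke_set()].
#' @param which 0-based spoke indices (default: all spokes in order).
#' @return Numeric (length(which) * n_readout) x 3 matrix, cycles/FOV.
#' @export
kspace_coords <- function(spokes, which = NULL) {
  stopifnot(inherits(spokes, "spoke_set"))
  d <- spokes$directions
  if (!is.null(which)) {
    d <- d[match(which, d$index), , drop = FALSE]
    if (anyNA(d$index)) abort("unknown spoke index", class = "utecine_invalid_argument")
  }
  u <- cbind(d$x, d$y, d$z)
  r <- spokes$radii
  # (n_readout x 3) blocks stacked per spoke
  nr <- length(r)
  ns <- nrow(u)
  out <- matrix(0, nr * ns, 3)
  for (a in 1:3) {
    out[, a] <- as.vector(outer(r, u[, a]))
  }
  out
}

#' @method tidy spoke_set
#' @export
tidy.spoke_set <- function(x, ...) x$directions
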