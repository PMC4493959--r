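#' Radial density-compensation weights
#'
#' 3D center-out radial sampling concentrates samples near the k-space
#' origin; before gridding, each sample is weighted by the k-space volume
#' it represents: the spherical shell between the radial midpoints of its
#' neighbours, divided by the number of spokes sharing the sphere. The
#' origin sample receives the volume of the innermost half-shell.
#'
#' @param radii Strictly non-decreasing sample radii (cycles/FOV).
#' @param n_spokes Number of spokes the shell volume is shared by
#'   (default 1; used for absolute normalization only).
#' @return Numeric weights, one per radius; their sum is the covered
#'   k-space ball volume divided by `n_spokes`.
#' @export
density_compensation <- function(radii, n_spokes = 1) {
  if (any(radii < 0)) abort("radii must be >= 0.", class = "utecine_invalid_argument")
  n <- length(radii)
  if (n == 1L || all(radii == radii[1])) {
    return(rep(1 / n, n))
  }
  mid <- (radii[-n] + radii[-1]) / 2
  lo <- c(radii[1], mid)
  hi <- c(mid, radii[n] + (radii[n] - mid[n - 1]))
  (4 * pi / 3) * (hi^3 - lo^3) / n_spokes
}

#' Grid non-Cartesian samples onto the oversampled Cartesian grid
#'
#' The adjoint of Kaiser-Bessel interpolation: each (optionally
#' density-weighted) sample is spread onto the `os * matrix` grid with the
#' separable kernel. Out-of-range frequencies wrap periodically, matching
#' the FFT convention.
#'
#' @param samples Complex samples (vector).
#' @param kmat n x 3 k-space locations in cycles/FOV.
#' @param cfg A [gridding_config()].
#' @param weights Optional per-sample density-compensation weights.
#' @return Complex 3D array of side `cfg$grid`.
#' @export
grid_adjoint <- function(samples, kmat, cfg, weights = NULL) {
  stopifnot(inherits(cfg, "gridding_config"))
  if (nrow(kmat) != length(samples)) {
    abort("samples and trajectory length differ.", class = "utecine_invalid_argument")
  }
  if (any(abs(kmat) > cfg$matrix / 2 + 1e-9)) {
    abort("sample outside the oversampled grid bounds.",
          class = "utecine_invalid_argument")
  }
  s <- if (is.null(weights)) samples else samples * weights
  g <- cpp_kb_spread(as.complex(s), k_to_grid(kmat, cfg), cfg$grid,
                     cfg$width, cfg$beta)
  array(g, dim = rep(cfg$grid, 3))
}

#' Interpolate an oversampled grid at non-Cartesian locations
#'
#' Forward counterpart of [grid_adjoint()] (exact adjoint pair); exposed
#' for adjoint testing and iterative extensions.
#'
#' @param grid Complex 3D array of side `cfg$grid`.
#' @inheritParams grid_adjoint
#' @return Complex sample vector.
#' @export
grid_interpolate <- function(grid, kmat, cfg) {
  stopifnot(inherits(cfg, "gridding_config"))
  cpp_kb_interp(as.vector(grid), k_to_grid(kmat, cfg), cfg$grid,
                cfg$width, cfg$beta)
}

#' Finalize one coil image from the gridded k-space
#'
#' Centered inverse FFT of the oversampled grid, division by the kernel's
#' analytic image-domain apodization, central crop to the nominal matrix,
#' and magnitude.
#'
#' @param grid Complex oversampled 3D array from [grid_adjoint()].
#' @param cfg A [gridding_config()].
#' @param deapodize Set `FALSE` to skip apodization correction (ablation).
#' @return Real non-negative `matrix^3` array.
#' @export
finalize_image <- function(grid, cfg, deapodize = TRUE) {
  stopifnot(inherits(cfg, "gridding_config"))
  G <- cfg$grid
  m <- cfg$matrix
  img <- ift3c(grid)
  if (deapodize) img <- img / kb_apod3(cfg)
  idx <- (G / 2 - m / 2 + 1):(G / 2 + m / 2)
  Mod(img[idx, idx, idx])
}

#' Sum-of-squares coil combination
#'
#' Voxelwise root-sum-of-squares of per-coil magnitude images.
#'
#' @param vols A list of equal-size real 3D arrays, or a 4D array with
#'   coils along the last dimension.
#' @return Combined real 3D array.
#' @export
coil_combine_sos <- function(vols) {
  if (is.array(vols) && length(dim(vols)) == 4) {
    vols <- lapply(seq_len(dim(vols)[4]), function(i) vols[, , , i])
  }
  stopifnot(is.list(vols), length(vols) >= 1)
  d <- dim(vols[[1]])
  if (!all(vapply(vols, function(v) identical(dim(v), d), TRUE))) {
    abort("coil volumes differ in shape.", class = "utecine_invalid_argument")
  }
  sqrt(Reduce(`+`, lapply(vols, function(v) v^2)))
}

#' Reconstruct a single frame from selected projections
#'
#' Density compensation, Kaiser-Bessel gridding, inverse FFT with
#' deapodization and crop, magnitude per coil, then sum-of-squares.
#'
#' @param samples Complex array `n_readout x n_proj_selected x n_coils`
#'   (a 2D array is treated as single-coil).
#' @param kmat Matching k-space locations (readout fastest).
#' @param cfg A [gridding_config()].
#' @param radii Sample radii of one spoke (for density compensation).
#' @param n_spokes_norm Spoke count used to normalize the weights.
#' @return Real `matrix^3` array.
#' @export
reconstruct_frame <- function(samples, kmat, cfg, radii, n_spokes_norm = NULL) {
  if (length(dim(samples)) == 2) dim(samples) <- c(dim(samples), 1L)
  n_sp <- dim(samples)[2]
  if (is.null(n_spokes_norm)) n_spokes_norm <- n_sp
  w <- rep(density_compensation(radii, n_spokes_norm), times = n_sp)
  vols <- lapply(seq_len(dim(samples)[3]), function(c_i) {
    g <- grid_adjoint(as.vector(samples[, , c_i]), kmat, cfg, weights = w)
    finalize_image(g, cfg)
  })
  coil_combine_sos(vols)
}

#' Reconstruct a cine volume from raw data
#'
#' Bins the acquired projections into HSR or HTR frames, reconstructs each
#' frame per coil and combines coils by sum of squares. HSR uses every
#' projection for each of the `n_hsr` frames; HTR splits each block into
#' its `block_size` slots, giving `block_size` times more frames with
#' `block_size` times fewer projections each.
#'
#' @param raw A [acquire()] result (gated).
#' @param mode `"hsr"` or `"htr"`.
#' @param cfg Optional [gridding_config()]; defaults to the sequence
#'   matrix with oversampling 2, width 4.
#' @return Object of class `cine_volume`: list with `data` (4D array
#'   `x, y, z, frame`), `frame_times` (s after trigger), `voxel_size_um`,
#'   `mode`, `fov`, `matrix`.
#' @export
reconstruct_cine <- function(raw, mode = c("hsr", "htr"), cfg = NULL) {
  stopifnot(inherits(raw, "raw_dataset"))
  mode <- match.arg(tolower(mode), c("hsr", "htr"))
  if (is.null(raw$schedule)) {
    abort("raw dataset is non-gated; cine binning undefined.",
          class = "utecine_invalid_argument")
  }
  if (is.null(cfg)) cfg <- gridding_config(raw$seq$matrix)
  bins <- bin_frames(raw$schedule, mode)
  bs <- raw$seq$block_size
  n_coils <- dim(raw$samples)[4]
  m <- cfg$matrix
  out <- array(0, dim = c(m, m, m, nrow(bins)))
  for (i in seq_len(nrow(bins))) {
    proj <- bins$projections[[i]]
    hsr_frame <- if (mode == "hsr") bins$frame[i] else bins$frame[i] %/% bs
    kmat <- kspace_coords(raw$spokes, which = proj)
    sel <- raw$samples[, proj + 1L, hsr_frame + 1L, , drop = FALSE]
    dim(sel) <- c(dim(sel)[1:2], n_coils)
    out[, , , i] <- reconstruct_frame(sel, kmat, cfg, raw$spokes$radii)
  }
  structure(
    list(data = out, frame_times = bins$time,
         voxel_size_um = 1000 * raw$seq$fov / m, mode = mode,
         fov = raw$seq$fov, matrix = m),
    class = "cine_volume"
  )
}

#' @export
print.cine_volume <- function(x, ...) {
  cat(sprintf("<cine_volume> %s: %d frames of %d^3 voxels (%.4g um isotropic)\n",
              toupper(x$mode), dim(x$data)[4], x$matrix, x$voxel_size_um))
  invisible(x)
}

#' @method tidy cine_volume
#' @export
tidy.cine_volume <- function(x, ...) {
  nf <- dim(x$data)[4]
  tibble(
    frame = 0:(nf - 1L),
    time = x$frame_times,
    mean = vapply(seq_len(nf), function(i) mean(x$data[, , , i]), numeric(1)),
    sd = vapply(seq_len(nf), function(i) sd(x$data[, , , i]), numeric(1)),
    max = vapply(seq_len(nf), function(i) max(x$data[, , , i]), numeric(1))
  )
}

#' @method glance cine_volume
#' @export
glance.cine_volume <- function(x, ...) {
  tibble(mode = x$mode, n_frames = dim(x$data)[4], matrix = x$matrix,
         fov_mm = x$fov, voxel_size_um = x$voxel_size_um)
}
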