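#' Region-of-interest helpers
#'
#' `roi_box()` returns the linear voxel indices of a cube anchored at a
#' corner of the volume (the conventional noise ROI "outside the body").
#' `roi_from_labels()` returns the indices of one label of a rasterized
#' phantom, optionally eroded so partial-volume boundary voxels are
#' excluded.
#'
#' @param matrix Volume side length in voxels.
#' @param size Box edge length in voxels.
#' @param corner 3-vector of 1-based corner coordinates (default the
#'   (1,1,1) corner).
#' @return Integer vector of linear voxel indices.
#' @export
roi_box <- function(matrix, size = 12, corner = c(1, 1, 1)) {
  m <- as.integer(matrix)
  rng <- lapply(corner, function(c0) {
    if (c0 + size - 1 <= m) c0:(c0 + size - 1) else (c0 - size + 1):c0
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  as.integer(g[, 1] + (g[, 2] - 1L) * m + (g[, 3] - 1L) * m * m)
}

#' @rdname roi_box
#' @param labels Integer 3D label array from [rasterize_frame()].
#' @param value Label value to extract.
#' @param erode Number of 6-neighbourhood erosion passes (default 1).
#' @export
roi_from_labels <- function(labels, value, erode = 1) {
  mask <- labels == value
  for (i in seq_len(erode)) mask <- erode6(mask)
  which(mask)
}

erode6 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) {
      idx_dst[[ax]] <- (1 + by):n
      idx_src[[ax]] <- 1:(n - by)
    } else {
      idx_dst[[ax]] <- 1:(n + by)
      idx_src[[ax]] <- (1 - by):n
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- mask
  for (ax in 1:3) {
    out <- out & shift(mask, ax, 1) & shift(mask, ax, -1)
  }
  out
}

roi_indices <- function(vol, roi) {
  if (is.logical(roi)) roi <- which(roi)
  if (length(roi) == 0) abort("empty ROI.", class = "utecine_invalid_argument")
  roi
}

#' Apparent signal-to-noise ratio
#'
#' Mean signal over the ROI divided by the standard deviation (sample,
#' n - 1) of the signal in a noise ROI placed outside the object. Called
#' "apparent" because the spatial covariance of phased-array noise is not
#' accounted for.
#'
#' @param vol Real 3D array.
#' @param roi,noise_roi Linear voxel indices (or logical arrays).
#' @return SNR (dimensionless).
#' @export
apparent_snr <- function(vol, roi, noise_roi) {
  roi <- roi_indices(vol, roi)
  noise_roi <- roi_indices(vol, noise_roi)
  s <- sd(vol[noise_roi])
  if (!is.finite(s) || s == 0) {
    abort("noise ROI has zero standard deviation (noiseless input).",
          class = "utecine_degenerate_noise")
  }
  mean(vol[roi]) / s
}

#' Contrast-to-noise ratio between blood and a reference tissue
#'
#' `CNR = SNR(blood) - SNR(tissue)`; negative pre-contrast (long-T1 blood
#' is darker than myocardium/muscle in a spoiled gradient echo), positive
#' after USPIO injection at ultra-short TE.
#'
#' @param vol Real 3D array.
#' @param blood_roi,tissue_roi,noise_roi Linear voxel indices.
#' @return CNR (dimensionless, may be negative).
#' @export
cnr <- function(vol, blood_roi, tissue_roi, noise_roi) {
  apparent_snr(vol, blood_roi, noise_roi) -
    apparent_snr(vol, tissue_roi, noise_roi)
}

#' Blood-signal homogeneity across the cardiac cycle
#'
#' Standard deviation (sample, n - 1) over cine frames of the per-frame
#' mean ROI signal.
#'
#' @param cine A [reconstruct_cine()] result, or a 4D array.
#' @param roi Linear voxel indices within one frame, or a list of
#'   per-frame index vectors.
#' @return Standard deviation of the frame means.
#' @export
homogeneity <- function(cine, roi) {
  data <- if (inherits(cine, "cine_volume")) cine$data else cine
  nf <- dim(data)[4]
  if (nf < 2) abort("homogeneity needs at least 2 frames.",
                    class = "utecine_invalid_argument")
  if (!is.list(roi)) roi <- rep(list(roi), nf)
  means <- vapply(seq_len(nf), function(i) {
    fr <- data[, , , i]
    mean(fr[roi_indices(fr, roi[[i]])])
  }, numeric(1))
  sd(means)
}

#' Threshold-based chamber segmentation
#'
#' Thresholds the volume at `threshold * reference` (reference defaults to
#' the intensity at the seed voxel) and returns the 6-connected component
#' containing the seed.
#'
#' @param vol Real 3D array.
#' @param seed 3-vector of 1-based voxel coordinates inside the chamber.
#' @param threshold Fraction of the blood-pool reference intensity, in
#'   (0, 1).
#' @param reference Blood-pool reference intensity; default `vol[seed]`.
#' @return Integer vector of linear voxel indices of the segmented
#'   chamber.
#' @export
segment_chamber <- function(vol, seed, threshold = 0.5, reference = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1).", class = "utecine_invalid_argument")
  }
  d <- dim(vol)
  seed_lin <- seed[1] + (seed[2] - 1L) * d[1] + (seed[3] - 1L) * d[1] * d[2]
  if (is.null(reference)) reference <- vol[seed_lin]
  mask <- vol > threshold * reference
  if (!mask[seed_lin]) {
    abort("seed voxel is below threshold; empty segmentation.",
          class = "utecine_empty_segmentation")
  }
  comp <- cpp_flood_fill6(as.vector(mask), as.integer(d), as.integer(seed_lin))
  which(array(comp, dim = d))
}

#' Per-frame segmented chamber volumes
#'
#' Segments every cine frame from the same seed and converts voxel counts
#' to microliters.
#'
#' @param cine A [reconstruct_cine()] result.
#' @param seed 1-based voxel coordinates of the chamber seed.
#' @param threshold Threshold fraction for [segment_chamber()].
#' @param reference Optional fixed reference intensity applied to all
#'   frames; default: per-frame seed intensity.
#' @return Tibble with `frame`, `time`, `n_voxels`, `volume_ul`.
#' @export
chamber_volumes <- function(cine, seed, threshold = 0.5, reference = NULL) {
  stopifnot(inherits(cine, "cine_volume"))
  voxel_ul <- (cine$voxel_size_um / 1000)^3  # mm^3 == uL
  nf <- dim(cine$data)[4]
  nv <- vapply(seq_len(nf), function(i) {
    length(segment_chamber(cine$data[, , , i], seed, threshold, reference))
  }, numeric(1))
  tibble(frame = 0:(nf - 1L), time = cine$frame_times,
         n_voxels = as.integer(nv), volume_ul = nv * voxel_ul)
}

#' Ventricular function from end-diastolic and end-systolic volumes
#'
#' @param edv_ul,esv_ul Volumes in microliters (`esv_ul <= edv_ul`).
#' @param chamber Chamber name.
#' @return One-row tibble with `chamber`, `edv_ul`, `esv_ul`, `sv_ul`,
#'   `ef_pct`.
#' @export
ventricular_function <- function(edv_ul, esv_ul, chamber = "lv") {
  if (esv_ul > edv_ul) {
    abort("ESV exceeds EDV; end-diastole/systole identification failed.",
          class = "utecine_invalid_argument")
  }
  if (edv_ul <= 0) abort("EDV must be positive.", class = "utecine_invalid_argument")
  tibble(chamber = chamber, edv_ul = edv_ul, esv_ul = esv_ul,
         sv_ul = edv_ul - esv_ul, ef_pct = 100 * (1 - esv_ul / edv_ul))
}

#' Ventricular function report from a cine reconstruction
#'
#' Segments the chamber on every frame, identifies end-diastole and
#' end-systole as the frames of maximal and minimal segmented volume, and
#' derives stroke volume and ejection fraction.
#'
#' @inheritParams chamber_volumes
#' @param chamber Chamber name for the report.
#' @return One-row tibble (see [ventricular_function()]) with the
#'   additional columns `ed_frame` and `es_frame`.
#' @export
function_report <- function(cine, seed, threshold = 0.5, reference = NULL,
                            chamber = "lv") {
  cv <- chamber_volumes(cine, seed, threshold, reference)
  ed <- which.max(cv$volume_ul)
  es <- which.min(cv$volume_ul)
  out <- ventricular_function(cv$volume_ul[ed], cv$volume_ul[es], chamber)
  out$ed_frame <- cv$frame[ed]
  out$es_frame <- cv$frame[es]
  out
}
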