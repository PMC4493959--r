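#' Plot a cine frame slice
#'
#' @param object A [reconstruct_cine()] result.
#' @param frame 0-based frame index.
#' @param slice 1-based slice index along the chosen axis (default:
#'   middle).
#' @param plane `"axial"` (xy), `"coronal"` (xz) or `"sagittal"` (yz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cine_volume
#' @export
autoplot.cine_volume <- function(object, frame = 0, slice = NULL,
                                 plane = c("axial", "coronal", "sagittal"),
                                 ...) {
  plane <- match.arg(plane)
  vol <- object$data[, , , frame + 1L]
  m <- dim(vol)[1]
  if (is.null(slice)) slice <- m %/% 2
  sl <- switch(plane,
               axial = vol[, , slice],
               coronal = vol[, slice, ],
               sagittal = vol[slice, , ])
  df <- tibble(
    i = rep(seq_len(nrow(sl)), times = ncol(sl)),
    j = rep(seq_len(ncol(sl)), each = nrow(sl)),
    intensity = as.vector(sl)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d, %s slice %d", frame, plane, slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the spiral spoke distribution
#'
#' Shows the end points of the half-projections on the unit sphere,
#' projected on the kx-ky plane and coloured by kz, the standard way to
#' inspect pole-to-pole spiral coverage.
#'
#' @param object A [spoke_set()] or the tibble from [spiral_directions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spoke_set
#' @export
autoplot.spoke_set <- function(object, ...) {
  d <- if (inherits(object, "spoke_set")) object$directions else object
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$z)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "kx / kmax", y = "ky / kmax", colour = "kz") +
    ggplot2::theme_minimal()
}

#' Blood signal versus echo time, pre and post contrast
#'
#' Evaluates the steady-state signal model for blood before and after
#' USPIO loading over a range of echo times, illustrating why ultra-short
#' echo times are required for positive contrast: the T1-driven signal
#' gain survives only while `exp(-TE * r2 * C)` is still close to one.
#'
#' @param field Field strength in tesla.
#' @param dose Dose in micromoles Fe/kg.
#' @param te_range Echo-time range in seconds.
#' @param tr,flip Sequence timing/flip.
#' @param n Number of TE samples.
#' @return A tibble with `te`, `condition`, `signal`.
#' @export
signal_vs_te <- function(field = 7, dose = 200,
                         te_range = c(0.00001, 0.012),
                         tr = 0.0035, flip = 15, n = 200) {
  te <- seq(te_range[1], te_range[2], length.out = n)
  pre <- tissue_signals(field, 0, tr, te = 0, flip = flip)
  post <- tissue_signals(field, dose, tr, te = 0, flip = flip)
  b_pre <- pre[pre$tissue == "blood", ]
  b_post <- post[post$tissue == "blood", ]
  dplyr::bind_rows(
    tibble(te = te, condition = "pre-contrast",
           signal = spgr_signal(b_pre$m0, b_pre$t1, b_pre$t2s, tr, te, flip)),
    tibble(te = te, condition = sprintf("post %g umol Fe/kg", dose),
           signal = spgr_signal(b_post$m0, b_post$t1, b_post$t2s, tr, te, flip))
  )
}

#' @rdname signal_vs_te
#' @param ... Passed to [signal_vs_te()].
#' @export
plot_signal_vs_te <- function(...) {
  df <- signal_vs_te(...)
  ggplot2::ggplot(df, ggplot2::aes(.data$te * 1000, .data$signal,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TE (ms)", y = "blood signal (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}
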