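#' Sequence configuration
#'
#' Bundles the acquisition parameters of one experiment: timing, geometry,
#' projection count, gating, field preset and contrast dose.
#'
#' @param tr,te Repetition/echo time, seconds.
#' @param flip Flip angle, degrees.
#' @param fov Field of view, mm (isotropic).
#' @param matrix Image matrix per dimension.
#' @param n_projections Total number of half-projections (per cine for a
#'   gated scan).
#' @param field Field strength in tesla (4.7, 7 or 9.4).
#' @param dose USPIO dose in micromoles Fe/kg (0 = pre-contrast).
#' @param gated Logical; ECG-triggered cine or free-running static scan.
#' @param rr_interval R-R interval, seconds (used when gated).
#' @param block_size Projections per gated block.
#' @param n_coils 1 (volume coil) or 4 (2x2 phased array).
#' @param n_readout Samples per spoke; default `matrix` (two-fold readout
#'   oversampling of the `matrix/2` radial extent).
#' @param bandwidth Readout bandwidth, Hz/pixel (metadata only).
#' @return Object of class `sequence_config`.
#' @export
sequence_config <- function(tr = 0.0035, te = 0.000031, flip = 15,
                            fov = 20, matrix = 128, n_projections = 18144,
                            field = 7, dose = 200, gated = TRUE,
                            rr_interval = 0.150, block_size = 4L,
                            n_coils = 1L, n_readout = NULL,
                            bandwidth = NA_real_) {
  if (is.null(n_readout)) n_readout <- as.integer(matrix)
  structure(list(tr = tr, te = te, flip = flip, fov = fov,
                 matrix = as.integer(matrix),
                 n_projections = as.integer(n_projections),
                 field = field, dose = dose, gated = isTRUE(gated),
                 rr_interval = rr_interval, block_size = as.integer(block_size),
                 n_coils = as.integer(n_coils),
                 n_readout = as.integer(n_readout), bandwidth = bandwidth),
            class = "sequence_config")
}

#' @export
print.sequence_config <- function(x, ...) {
  cat(sprintf(
    "<sequence_config> TR/TE %.4g/%.4g ms, FA %g deg, FOV %g mm, matrix %d, %d proj, %.1f T, dose %g umol Fe/kg, %s\n",
    x$tr * 1e3, x$te * 1e3, x$flip, x$fov, x$matrix, x$n_projections,
    x$field, x$dose, if (x$gated) "gated" else "non-gated"))
  invisible(x)
}

#' @method glance sequence_config
#' @export
glance.sequence_config <- function(x, ...) {
  tibble(tr = x$tr, te = x$te, flip = x$flip, fov = x$fov,
         matrix = x$matrix, n_projections = x$n_projections,
         field = x$field, dose = x$dose, gated = x$gated,
         resolution_um = 1000 * x$fov / x$matrix)
}

#' @rdname sequence_config
#' @export
gating_of <- function(x) {
  stopifnot(inherits(x, "sequence_config"))
  gating_params(x$rr_interval, x$tr, x$block_size, x$gated)
}

#' Simulated receive-coil sensitivity maps
#'
#' `n_coils = 1` models a homogeneous volume coil (unit sensitivity).
#' `n_coils = 4` models a 2x2 phased surface array on the anterior face of
#' the FOV: each element has a smooth Gaussian sensitivity profile centered
#' on its quadrant, plus a small uniform floor so the sum-of-squares
#' sensitivity is positive everywhere. A gentle per-element linear phase
#' makes the maps complex, as real coil fields are.
#'
#' @param n_coils 1 or 4.
#' @param matrix Grid size per dimension.
#' @param fov Field of view, mm.
#' @return Complex array `matrix^3 x n_coils`.
#' @export
simulate_coil_maps <- function(n_coils, matrix, fov = 20) {
  m <- as.integer(matrix)
  if (!n_coils %in% c(1L, 4L)) {
    abort("`n_coils` must be 1 or 4.", class = "utecine_invalid_argument")
  }
  if (n_coils == 1L) {
    return(array(1 + 0i, dim = c(m, m, m, 1L)))
  }
  ax <- ((0:(m - 1)) - m / 2) / m * fov
  X <- array(rep(ax, times = m * m), dim = c(m, m, m))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  centers <- rbind(
    c(-fov / 4, -fov / 2, -fov / 4),
    c(fov / 4, -fov / 2, -fov / 4),
    c(-fov / 4, -fov / 2, fov / 4),
    c(fov / 4, -fov / 2, fov / 4)
  )
  sigma <- fov / 2.5
  out <- array(0 + 0i, dim = c(m, m, m, 4L))
  for (c_i in 1:4) {
    d2 <- (X - centers[c_i, 1])^2 + (Y - centers[c_i, 2])^2 +
      (Z - centers[c_i, 3])^2
    mag <- exp(-d2 / (2 * sigma^2)) + 0.05
    phase <- 0.1 * pi * (X * centers[c_i, 1] + Z * centers[c_i, 3]) / fov
    out[, , , c_i] <- mag * complex(real = cos(phase), imaginary = sin(phase))
  }
  out
}

#' Simulate a raw k-space acquisition
#'
#' For every HSR frame the phantom is frozen at the frame's mid-time
#' (quasi-static approximation), multiplied by each coil sensitivity, and
#' its Fourier transform is evaluated at all scheduled spoke sample
#' locations via the oversampled-FFT + Kaiser-Bessel interpolation forward
#' model. I.i.d. complex Gaussian noise of standard deviation
#' `noise_sigma` is then added per coil (seeded, reproducible).
#'
#' For a non-gated configuration a single frame at t = 0 is produced.
#'
#' @param ph A [dynamic_phantom()].
#' @param seq A [sequence_config()]; its FOV must match the phantom's.
#' @param spokes A [spoke_set()] with `n_spokes == seq$n_projections`.
#' @param schedule Optional [build_schedule()]; built from `seq` when
#'   omitted (gated case).
#' @param coils Optional coil maps from [simulate_coil_maps()].
#' @param noise_sigma Complex-noise standard deviation (arbitrary units,
#'   same scale as the k-space samples).
#' @param seed Integer seed for the noise stream.
#' @return Object of class `raw_dataset`: list with `samples` (complex
#'   array `n_readout x n_projections x n_frames x n_coils`), `spokes`,
#'   `schedule` (NULL if non-gated), `seq`, `frame_times`, `noise_sigma`,
#'   `seed`, `config_hash`.
#' @export
acquire <- function(ph, seq, spokes, schedule = NULL, coils = NULL,
                    noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(ph, "dynamic_phantom"), inherits(seq, "sequence_config"),
            inherits(spokes, "spoke_set"))
  if (!isTRUE(all.equal(ph$fov, seq$fov))) {
    abort("phantom and sequence FOV disagree.", class = "utecine_invalid_argument")
  }
  if (spokes$n_spokes != seq$n_projections) {
    abort("spoke set and sequence projection count disagree.",
          class = "utecine_invalid_argument")
  }
  if (seq$gated && is.null(schedule)) {
    schedule <- build_schedule(seq$n_projections, gating_of(seq))
  }
  n_frames <- if (seq$gated) schedule$n_hsr else 1L
  frame_times <- if (seq$gated) {
    (0:(n_frames - 1L) + 0.5) * seq$block_size * seq$tr
  } else 0
  if (is.null(coils)) coils <- simulate_coil_maps(seq$n_coils, seq$matrix, seq$fov)
  n_coils <- dim(coils)[4]
  cfg <- gridding_config(seq$matrix)
  kmat <- kspace_coords(spokes)
  samples <- array(0 + 0i,
                   dim = c(seq$n_readout, seq$n_projections, n_frames, n_coils))
  for (f in seq_len(n_frames)) {
    ras <- rasterize_frame(ph, frame_times[f], matrix = seq$matrix,
                           field = seq$field, dose = seq$dose,
                           tr = seq$tr, te = seq$te, flip = seq$flip)
    for (c_i in seq_len(n_coils)) {
      img <- ras$signal * coils[, , , c_i]
      samples[, , f, c_i] <- nufft_forward(img, kmat, cfg)
    }
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    n <- length(samples)
    samples <- samples + complex(real = rnorm(n, sd = noise_sigma),
                                 imaginary = rnorm(n, sd = noise_sigma))
  }
  raw <- structure(
    list(samples = samples, spokes = spokes, schedule = schedule, seq = seq,
         frame_times = frame_times, noise_sigma = noise_sigma,
         seed = as.integer(seed), config_hash = NA_character_),
    class = "raw_dataset"
  )
  raw$config_hash <- config_hash(raw["seq"])
  raw
}

#' @export
print.raw_dataset <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<raw_dataset> %d readout x %d proj x %d frames x %d coils, sigma %g, seed %d\n",
              d[1], d[2], d[3], d[4], x$noise_sigma, x$seed))
  invisible(x)
}

#' @method glance raw_dataset
#' @export
glance.raw_dataset <- function(x, ...) {
  d <- dim(x$samples)
  tibble(n_readout = d[1], n_projections = d[2], n_frames = d[3],
         n_coils = d[4], noise_sigma = x$noise_sigma, seed = x$seed,
         config_hash = x$config_hash)
}
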