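# Shared fixtures, built in code at test time.

# Partial-volume (supersampled) rasterization of a centered sphere of
# radius R (in FOV fractions) on an m^3 grid; reduces voxelization error
# when comparing against the continuous sphere Fourier transform.
supersampled_sphere <- function(m, R, ss = 4) {
  pos <- ((0:(m - 1)) - m / 2) / m
  off <- (seq_len(ss) - (ss + 1) / 2) / (ss * m)
  sph <- array(0, dim = c(m, m, m))
  for (ox in off) for (oy in off) for (oz in off) {
    X <- array(rep(pos + ox, m * m), dim = c(m, m, m))
    Y <- aperm(array(rep(pos + oy, m * m), dim = c(m, m, m)), c(2, 1, 3))
    Z <- aperm(array(rep(pos + oz, m * m), dim = c(m, m, m)), c(3, 2, 1))
    sph <- sph + (X^2 + Y^2 + Z^2 <= R^2)
  }
  sph / ss^3
}

# Closed-form Fourier transform of a unit-amplitude sphere of radius R
# (FOV fractions), scaled to match a voxel-sum DFT on an m^3 grid.
sphere_ft <- function(kmat, R, m) {
  kr <- sqrt(rowSums(kmat^2))
  kappa <- 2 * pi * kr * R
  ifelse(kappa < 1e-8, 4 / 3 * pi * R^3,
         4 * pi * R^3 * (sin(kappa) - kappa * cos(kappa)) / kappa^3) * m^3
}

# Brute-force nearest-neighbour great-circle distances between unit vectors.
nn_great_circle <- function(u) {
  g <- u %*% t(u)
  g[g > 1] <- 1
  g[g < -1] <- -1
  d <- acos(g)
  diag(d) <- Inf
  apply(d, 1, min)
}

# A single-primitive phantom: one blood sphere centered in the FOV.
blood_sphere_phantom <- function(radius_mm = 3, fov = 20) {
  dynamic_phantom(
    list(phantom_primitive("pool", "blood", c(0, 0, 0), rep(radius_mm, 3))),
    fov = fov
  )
}

# Small gated raw dataset on a beating single-chamber phantom.
tiny_gated_raw <- function(matrix = 16, n_proj = 64, rr = 0.150, tr = 0.0035,
                           noise_sigma = 0, seed = 1, ef = 0.6,
                           n_coils = 1) {
  ph <- dynamic_phantom(
    list(
      phantom_primitive("shell", "myocardium", c(0, 0, 0), c(6, 6, 7)),
      phantom_primitive("cavity", "blood", c(0, 0, 0), c(3.4, 3.4, 4.2),
                        ef = ef, chamber = "lv")
    ),
    fov = 20, rr = rr
  )
  seq <- sequence_config(tr = tr, fov = 20, matrix = matrix,
                         n_projections = n_proj, gated = TRUE,
                         rr_interval = rr, n_coils = n_coils)
  spokes <- spoke_set(n_proj, seq$n_readout, matrix / 2)
  list(ph = ph, seq = seq, spokes = spokes,
       raw = acquire(ph, seq, spokes, noise_sigma = noise_sigma, seed = seed))
}
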