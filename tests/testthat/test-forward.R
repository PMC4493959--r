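test_that("coil maps: volume coil is uniform, array covers the FOV", {
  m1 <- simulate_coil_maps(1, 12)
  expect_true(all(m1 == 1 + 0i))
  m4 <- simulate_coil_maps(4, 16, fov = 20)
  sos <- sqrt(apply(Mod(m4)^2, 1:3, sum))
  expect_true(all(sos > 0))
  # each element peaks in its assigned quadrant (x/z sign pattern, anterior y)
  centers_sign <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  pos <- ((0:15) - 8) / 16 * 20
  for (c_i in 1:4) {
    am <- which(Mod(m4[, , , c_i]) == max(Mod(m4[, , , c_i])), arr.ind = TRUE)[1, ]
    expect_equal(sign(pos[am[1]]) , centers_sign[c_i, 1])
    expect_equal(sign(pos[am[3]]) , centers_sign[c_i, 2])
    expect_lt(pos[am[2]], 0)
  }
  expect_error(simulate_coil_maps(3, 8), class = "utecine_invalid_argument")
})

test_that("forward model matches the direct DFT on a small grid", {
  set.seed(11)
  m <- 12
  img <- array(rnorm(m^3), dim = c(m, m, m))
  cfg <- gridding_config(m)
  km <- kspace_coords(spoke_set(30, 10, m / 2))
  expect_lt(max(Mod(nufft_forward(img, km, cfg) - dft_forward(img, km))) /
              max(Mod(dft_forward(img, km))), 5e-3)
})

test_that("k = 0 sample equals the image sum (DC theorem)", {
  m <- 12
  img <- array(1, dim = c(m, m, m))
  cfg <- gridding_config(m)
  dc <- nufft_forward(img, matrix(0, 1, 3), cfg)
  expect_equal(Mod(dc), m^3, tolerance = 1e-3)
})

test_that("simulated sphere samples match the closed-form transform within 1%", {
  m <- 32
  sph <- supersampled_sphere(m, 0.25, ss = 4)
  cfg <- gridding_config(m)
  sp <- spoke_set(60, 2 * m + 1, m / 2)
  km <- kspace_coords(sp)
  s_hat <- nufft_forward(sph, km, cfg)
  truth <- sphere_ft(km, 0.25, m)
  keep <- sqrt(rowSums(km^2)) <= m / 4
  expect_lt(max(Mod(s_hat - truth)[keep]) / max(Mod(truth)), 0.01)
})

test_that("continuous transform of a real object is Hermitian-symmetric", {
  m <- 16
  sph <- supersampled_sphere(m, 0.3, ss = 2)
  cfg <- gridding_config(m)
  set.seed(4)
  kpos <- matrix(runif(60, -m / 4, m / 4), 20, 3)
  s_pos <- nufft_forward(sph, kpos, cfg)
  s_neg <- nufft_forward(sph, -kpos, cfg)
  expect_lt(max(Mod(s_neg - Conj(s_pos))) / max(Mod(s_pos)), 1e-3)
})

test_that("acquisition is linear in the object and reproducible under a seed", {
  fx <- tiny_gated_raw(matrix = 16, n_proj = 16, noise_sigma = 0.5, seed = 7)
  fx2 <- tiny_gated_raw(matrix = 16, n_proj = 16, noise_sigma = 0.5, seed = 7)
  expect_identical(fx$raw$samples, fx2$raw$samples)
  fx3 <- tiny_gated_raw(matrix = 16, n_proj = 16, noise_sigma = 0.5, seed = 8)
  expect_false(identical(fx$raw$samples, fx3$raw$samples))

  # linearity at zero noise: doubling every tissue's M0 doubles the samples
  ph1 <- blood_sphere_phantom(3)
  seq1 <- sequence_config(matrix = 16, n_projections = 12, gated = FALSE, fov = 20)
  sp <- spoke_set(12, 16, 8)
  r1 <- acquire(ph1, seq1, sp)
  cfg <- gridding_config(16)
  km <- kspace_coords(sp)
  ras <- rasterize_frame(ph1, 0, matrix = 16)
  s_img <- nufft_forward(2 * ras$signal, km, cfg)
  expect_equal(as.vector(s_img), 2 * as.vector(r1$samples[, , 1, 1]),
               tolerance = 1e-10)
})

test_that("acquisition DC samples equal the weighted object sum per spoke", {
  ph <- blood_sphere_phantom(3)
  seq1 <- sequence_config(matrix = 16, n_projections = 10, gated = FALSE, fov = 20)
  sp <- spoke_set(10, 16, 8)
  raw <- acquire(ph, seq1, sp)
  ras <- rasterize_frame(ph, 0, matrix = 16)
  dc <- raw$samples[1, , 1, 1]  # first readout point of every spoke is k = 0
  expect_equal(Mod(dc), rep(sum(ras$signal), 10), tolerance = 5e-3)
})

test_that("added noise is calibrated complex Gaussian", {
  ph <- blood_sphere_phantom(3)
  n_proj <- 3200
  seq1 <- sequence_config(matrix = 16, n_projections = n_proj, gated = FALSE,
                          fov = 20, n_readout = 32)
  sp <- spoke_set(n_proj, 32, 8)
  clean <- acquire(ph, seq1, sp, noise_sigma = 0)
  noisy <- acquire(ph, seq1, sp, noise_sigma = 2.5, seed = 123)
  resid <- noisy$samples - clean$samples
  expect_gt(length(resid), 1e5)
  expect_equal(sd(Re(resid)), 2.5, tolerance = 0.05)
  expect_equal(sd(Im(resid)), 2.5, tolerance = 0.05)
})

test_that("geometry mismatches are rejected", {
  ph <- blood_sphere_phantom(3, fov = 30)
  seq1 <- sequence_config(matrix = 16, n_projections = 8, gated = FALSE, fov = 20)
  sp <- spoke_set(8, 16, 8)
  expect_error(acquire(ph, seq1, sp), class = "utecine_invalid_argument")
  sp_bad <- spoke_set(9, 16, 8)
  ph2 <- blood_sphere_phantom(3, fov = 20)
  expect_error(acquire(ph2, seq1, sp_bad), class = "utecine_invalid_argument")
})
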