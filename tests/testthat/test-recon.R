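test_that("density compensation weights follow 3D shell volumes", {
  w <- density_compensation(c(0, 1))
  # shells [0, 0.5] and [0.5, 1.5] around the two samples
  expect_equal(w[2] / w[1], (1.5^3 - 0.5^3) / 0.5^3, tolerance = 1e-12)
  w <- density_compensation(seq(0, 16, length.out = 33))
  expect_true(all(diff(w) > 0))
  expect_equal(density_compensation(c(0, 0, 0)), rep(1 / 3, 3))
  # spoke weights sum to the covered k-ball volume divided by the spoke count
  r <- seq(0, 16, length.out = 33)
  w <- density_compensation(r, n_spokes = 100)
  dr <- r[2] - r[1]
  expect_equal(sum(w), 4 / 3 * pi * (16 + dr / 2)^3 / 100, tolerance = 1e-12)
  expect_error(density_compensation(c(-1, 1)), class = "utecine_invalid_argument")
})

test_that("gridding and interpolation are exact adjoints", {
  cfg <- gridding_config(16)
  for (seed in 1:3) {
    set.seed(seed)
    n <- 150
    km <- matrix(runif(n * 3, -8, 8), n, 3)
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    y <- array(complex(real = rnorm(cfg$grid^3), imaginary = rnorm(cfg$grid^3)),
               dim = rep(cfg$grid, 3))
    ip1 <- sum(Conj(y) * grid_adjoint(x, km, cfg))
    ip2 <- sum(Conj(grid_interpolate(y, km, cfg)) * x)
    expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)
  }
})

test_that("a single DC sample concentrates its kernel mass at the grid center", {
  cfg <- gridding_config(8)
  g <- grid_adjoint(1 + 0i, matrix(0, 1, 3), cfg)
  ctr <- cfg$grid / 2 + 1
  expect_equal(which(Mod(g) == max(Mod(g)), arr.ind = TRUE)[1, ],
               c(dim1 = ctr, dim2 = ctr, dim3 = ctr), ignore_attr = TRUE)
  expect_gt(Re(g[ctr, ctr, ctr]), 0)
  expect_error(grid_adjoint(1 + 0i, matrix(20, 1, 3), cfg),
               class = "utecine_invalid_argument")
})

test_that("deapodized gridding reproduces smooth-object samples within 1%", {
  m <- 16
  pos <- ((0:(m - 1)) - m / 2) / m
  X <- array(rep(pos, m * m), dim = c(m, m, m))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  img <- exp(-(X^2 + Y^2 + Z^2) / (2 * 0.15^2))
  cfg <- gridding_config(m)
  km <- kspace_coords(spoke_set(40, 12, m / 2))
  s <- nufft_forward(img, km, cfg)
  truth <- dft_forward(img, km)
  expect_lt(max(Mod(s - truth)) / max(Mod(truth)), 0.01)
})

test_that("point-spread function peaks at center with >10:1 sidelobe suppression", {
  m <- 32
  cfg <- gridding_config(m)
  sp <- spoke_set(400, m + 1, m / 2)
  km <- kspace_coords(sp)
  w <- rep(density_compensation(sp$radii, 400), times = 400)
  psf <- finalize_image(grid_adjoint(rep(1 + 0i, nrow(km)), km, cfg, weights = w), cfg)
  ctr <- m / 2 + 1
  expect_equal(which(psf == max(psf), arr.ind = TRUE)[1, ],
               c(dim1 = ctr, dim2 = ctr, dim3 = ctr), ignore_attr = TRUE)
  main <- psf[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)]
  side <- psf
  side[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)] <- 0
  expect_gt(max(main) / max(side), 10)
  # all-zero input gives an all-zero image
  z <- finalize_image(array(0 + 0i, dim = rep(cfg$grid, 3)), cfg)
  expect_true(all(z == 0))
})

test_that("sum-of-squares combination is Pythagorean and monotone", {
  a <- array(3, dim = c(2, 2, 2))
  b <- array(4, dim = c(2, 2, 2))
  expect_equal(coil_combine_sos(list(a)), a)
  expect_equal(coil_combine_sos(list(a, b)), array(5, dim = c(2, 2, 2)))
  expect_true(all(coil_combine_sos(list(a, b)) >= coil_combine_sos(list(a))))
  expect_error(coil_combine_sos(list(a, array(4, dim = c(2, 2, 3)))),
               class = "utecine_invalid_argument")
})

test_that("noiseless uniform sphere reconstructs with at least 20:1 contrast", {
  m <- 32
  ph <- blood_sphere_phantom(radius_mm = 3, fov = 20)
  seq1 <- sequence_config(matrix = m, n_projections = 2048, gated = FALSE, fov = 20)
  sp <- spoke_set(2048, m, m / 2)
  raw <- acquire(ph, seq1, sp)
  cfg <- gridding_config(m)
  vol <- reconstruct_frame(raw$samples[, , 1, ], kspace_coords(sp), cfg, sp$radii)
  pos <- ((0:(m - 1)) - m / 2) / m * 20
  X <- array(rep(pos, m * m), dim = c(m, m, m))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  expect_gt(mean(vol[r < 2.1]) / mean(vol[r > 4.5]), 20)
})

test_that("multi-coil combination flattens the object", {
  fx <- tiny_gated_raw(matrix = 24, n_proj = 288, ef = 0, n_coils = 4)
  cine <- reconstruct_cine(fx$raw, "hsr")
  ras <- rasterize_frame(fx$ph, 0, matrix = 24)
  obj <- roi_from_labels(ras$labels, 1L, erode = 1)
  cv <- function(v) sd(v[obj]) / mean(v[obj])
  coils <- simulate_coil_maps(4, 24, 20)
  cfg <- gridding_config(24)
  km <- kspace_coords(fx$spokes)
  single <- vapply(1:4, function(c_i) {
    w <- rep(density_compensation(fx$spokes$radii, 288), times = 288)
    cv(finalize_image(grid_adjoint(as.vector(fx$raw$samples[, , 1, c_i]),
                                   km, cfg, weights = w), cfg))
  }, numeric(1))
  expect_lt(cv(cine$data[, , , 1]), min(single))
})

test_that("cine reconstruction: frame counts, HSR/HTR consistency and partitioned data", {
  fx <- tiny_gated_raw(matrix = 24, n_proj = 640, ef = 0)
  hsr <- reconstruct_cine(fx$raw, "hsr")
  htr <- reconstruct_cine(fx$raw, "htr")
  expect_equal(dim(hsr$data)[4], 10L)
  expect_equal(dim(htr$data)[4], 40L)
  expect_equal(hsr$voxel_size_um, 20 / 24 * 1000)

  # static object: mean of the 4 HTR children correlates with the HSR frame
  child_mean <- (htr$data[, , , 1] + htr$data[, , , 2] +
                   htr$data[, , , 3] + htr$data[, , , 4]) / 4
  expect_gt(cor(as.vector(child_mean), as.vector(hsr$data[, , , 1])), 0.95)

  # quarter-sampled HTR frames carry more background streak energy
  ras <- rasterize_frame(fx$ph, 0, matrix = 24)
  bg <- which(ras$labels == 0L)
  expect_gt(mean(htr$data[, , , 1][bg]^2), mean(hsr$data[, , , 1][bg]^2))

  # gridding the 4 disjoint HTR children with HSR weights sums to the HSR grid
  cfg <- gridding_config(24)
  sched <- fx$raw$schedule
  bins_htr <- bin_frames(sched, "htr")
  w_spoke <- density_compensation(fx$spokes$radii, 640)
  grid_children <- 0
  for (s in 0:3) {
    proj <- bins_htr$projections[[s + 1]]
    km_c <- kspace_coords(fx$spokes, which = proj)
    w <- rep(w_spoke, times = length(proj))
    grid_children <- grid_children +
      grid_adjoint(as.vector(fx$raw$samples[, proj + 1L, 1, 1]), km_c, cfg,
                   weights = w)
  }
  km_all <- kspace_coords(fx$spokes)
  grid_full <- grid_adjoint(as.vector(fx$raw$samples[, , 1, 1]), km_all, cfg,
                            weights = rep(w_spoke, times = 640))
  expect_lt(max(Mod(grid_children - grid_full)) / max(Mod(grid_full)), 1e-12)
  expect_equal(finalize_image(grid_children, cfg), hsr$data[, , , 1],
               tolerance = 1e-10)

  expect_error(reconstruct_cine(fx$raw, "other"))
})

test_that("a beating chamber is largest at end-diastole and smallest near end-systole", {
  fx <- tiny_gated_raw(matrix = 24, n_proj = 512, ef = 0.6)
  cine <- reconstruct_cine(fx$raw, "hsr")
  ctr <- 24 / 2 + 1
  areas <- vapply(1:10, function(f) {
    sl <- cine$data[, , ctr, f]
    sum(sl > 0.5 * max(sl))
  }, numeric(1))
  expect_equal(which.max(areas), 1L)
  expect_true(which.min(areas) %in% 3:5)  # end-systole configured at 35% of R-R
})
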