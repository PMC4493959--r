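test_that("relaxivity model shortens T1/T2* and is the identity at zero dose", {
  ag7 <- contrast_agent(7)
  expect_equal(relax_with_contrast(1.8, 0.025, ag7, 0),
               tibble::tibble(t1 = 1.8, t2s = 0.025))
  r <- relax_with_contrast(2.0, 0.030, ag7, 1)
  expect_equal(r$t1, 1 / (1 / 2 + 1.13), tolerance = 1e-12)
  r94 <- relax_with_contrast(2.0, 0.030, contrast_agent(9.4), 1)
  expect_equal(r94$t2s, 1 / (1 / 0.030 + 86.23), tolerance = 1e-12)
  expect_equal(r94$t2s * 1000, 8.364, tolerance = 1e-4)
  expect_error(relax_with_contrast(-1, 0.03, ag7, 1),
               class = "utecine_invalid_argument")
  expect_true(contrast_agent(4.7)$r2 > contrast_agent(4.7)$r1)
})

test_that("spoiled gradient-echo signal has the correct limits", {
  # heavy saturation: T1 >> TR gives nearly no signal
  expect_lt(spgr_signal(1, 1e6, Inf, 0.0035, 0, 15), 1e-3)
  # full recovery: TR >> T1, 90 degrees, no decay -> M0
  expect_equal(spgr_signal(1, 0.001, Inf, 10, 0, 90), 1, tolerance = 1e-9)
  # monotone decreasing in TE
  te <- seq(0, 0.01, length.out = 20)
  s <- spgr_signal(1, 1, 0.005, 0.0035, te, 15)
  expect_true(all(diff(s) < 0))
  expect_error(spgr_signal(1, 1, 1, -1, 0, 15), class = "utecine_invalid_argument")
})

test_that("USPIO-loaded blood gains at least threefold at ultra-short TE", {
  conc <- dose_to_blood_conc(200)
  expect_equal(conc, 200 / 77, tolerance = 1e-12)
  ts0 <- tissue_signals(7, 0, tr = 0.0035, te = 0.000031, flip = 15)
  ts200 <- tissue_signals(7, 200, tr = 0.0035, te = 0.000031, flip = 15)
  pre <- ts0$signal[ts0$tissue == "blood"]
  post <- ts200$signal[ts200$tissue == "blood"]
  expect_gt(post / pre, 3)
})

test_that("positive-contrast regime holds at all fields and doses 200/500", {
  for (field in c(4.7, 7, 9.4)) {
    for (dose in c(200, 500)) {
      ts <- tissue_signals(field, dose, tr = 0.0035, te = 0.000031, flip = 15)
      blood <- ts$signal[ts$tissue == "blood"]
      expect_gt(blood, ts$signal[ts$tissue == "myocardium"])
      expect_gt(blood, ts$signal[ts$tissue == "muscle"])
    }
    # pre-contrast ordering is reversed (long-T1 blood is darker)
    ts0 <- tissue_signals(field, 0, tr = 0.0035, te = 0.000031, flip = 15)
    expect_lt(ts0$signal[ts0$tissue == "blood"],
              ts0$signal[ts0$tissue == "myocardium"])
  }
})

test_that("dose raises the blood-muscle signal difference", {
  diff_at <- function(dose, field) {
    ts <- tissue_signals(field, dose, tr = 0.0035, te = 0.000031, flip = 15)
    ts$signal[ts$tissue == "blood"] - ts$signal[ts$tissue == "muscle"]
  }
  for (field in c(4.7, 7, 9.4)) {
    expect_gt(diff_at(500, field), diff_at(200, field))
  }
})

test_that("post/pre blood signal ratio decays with TE and crosses unity beyond the UTE regime", {
  ratio_at <- function(te) {
    pre <- tissue_signals(7, 0, tr = 0.0035, te = te, flip = 15)
    post <- tissue_signals(7, 200, tr = 0.0035, te = te, flip = 15)
    post$signal[post$tissue == "blood"] / pre$signal[pre$tissue == "blood"]
  }
  te <- c(0.000031, 0.001, 0.003, 0.008, 0.015, 0.030)
  r <- vapply(te, ratio_at, numeric(1))
  expect_true(all(diff(r) < 0))     # T2* cost grows with TE
  expect_gt(r[1], 1)                # positive contrast at ultra-short TE
  expect_lt(r[length(r)], 1)        # reversal at long conventional TE
  cross <- stats::uniroot(function(x) ratio_at(x) - 1, c(0.001, 0.05))$root
  expect_gt(cross, 0.003)           # crossover sits above 3 ms in this model
})

test_that("rasterized sphere volume matches the closed form within 2% at matrix 128", {
  ph <- blood_sphere_phantom(radius_mm = 3, fov = 20)
  ras <- rasterize_frame(ph, 0, matrix = 128)
  vox_ul <- (20 / 128)^3
  v_vox <- sum(ras$labels == 1L) * vox_ul
  expect_equal(v_vox, 4 / 3 * pi * 3^3, tolerance = 0.02)
})

test_that("rasterization paints blood brighter than myocardium post contrast", {
  ph <- mouse_thorax_phantom()
  ras <- rasterize_frame(ph, 0, matrix = 48, field = 7, dose = 200)
  labs <- vapply(ph$primitives, `[[`, "", "label")
  blood <- ras$signal[ras$labels == which(labs == "lv_cavity")]
  myo <- ras$signal[ras$labels == which(labs == "myocardium")]
  expect_true(all(blood > max(myo)))
  # time wraps modulo the cardiac period
  ras2 <- rasterize_frame(ph, ph$rr * 3, matrix = 48)
  expect_identical(ras2$labels, ras$labels)
})

test_that("an empty phantom rasterizes to zero and has no chambers", {
  ph <- dynamic_phantom(list(), fov = 20)
  ras <- rasterize_frame(ph, 0, matrix = 16)
  expect_true(all(ras$signal == 0))
  expect_true(all(ras$labels == 0L))
  expect_error(ground_truth_volumes(ph), class = "utecine_invalid_argument")
})

test_that("analytic chamber volumes follow the configured cycle exactly", {
  sph <- dynamic_phantom(
    list(phantom_primitive("c", "blood", c(0, 0, 0), c(1, 1, 1),
                           ef = 0, chamber = "lv")),
    fov = 20
  )
  expect_equal(ground_truth_volumes(sph)$volume_ul, 4 / 3 * pi, tolerance = 1e-12)

  ph <- mouse_thorax_phantom(lv_ef = 0.641, rv_ef = 0.618)
  gt <- ground_truth_function(ph)
  expect_equal(gt$ef_pct[gt$chamber == "lv"], 64.1, tolerance = 1e-12)
  expect_equal(gt$ef_pct[gt$chamber == "rv"], 61.8, tolerance = 1e-12)
  expect_equal(gt$edv_ul[gt$chamber == "lv"], 42.3, tolerance = 1e-9)
  expect_equal(gt$sv_ul[gt$chamber == "lv"], 42.3 * 0.641, tolerance = 1e-9)
  # periodicity and end-systole at the configured phase
  v <- function(t) ground_truth_volumes(ph, t, "lv")$volume_ul
  expect_equal(v(0), v(ph$rr), tolerance = 1e-12)
  ts <- seq(0, ph$rr, length.out = 101)
  expect_equal(ts[which.min(vapply(ts, v, numeric(1)))], ph$es_phase * ph$rr,
               tolerance = 0.02)
  expect_error(ground_truth_volumes(ph, 0, "la"), class = "utecine_invalid_argument")
})
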