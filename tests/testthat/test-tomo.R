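test_that("frame stack re-indexes to sinograms and back exactly", {
  ph <- make_phantom(shape_spec("bean", radius = 3), 48, 0.25)
  st <- simulate_rotation_series(ph, 60)
  sinos <- frames_to_sinograms(st)
  expect_length(sinos, 48)
  expect_equal(dim(sinos[[1]]$values), c(60, 48))
  expect_equal(sinos[[10]]$values[7, ], st$frames[10, , 7])
  rt <- sinograms_to_stack(sinos, fps = st$fps)
  expect_equal(rt$frames, st$frames)
  # insufficient angular coverage is rejected
  short <- frame_stack(st$frames[, , 1:20], st$fps, st$pixel_size,
                       st$angles[1:20])
  expect_error(frames_to_sinograms(short), "180")
})

test_that("ramp filter reproduces the closed-form Ram-Lak kernel", {
  imp <- numeric(64); imp[33] <- 1
  f <- ramp_filter(imp, spacing = 1)
  n <- -8:8
  expected <- ifelse(n == 0, 0.25,
                     ifelse(n %% 2 == 0, 0, -1 / (n * pi)^2))
  expect_equal(f[33 + n], expected, tolerance = 1e-3)
  expect_lt(max(abs(f[33 + n] - expected)), 2e-5)
  # detector-spacing scaling of the center sample
  f2 <- ramp_filter(imp, spacing = 0.5)
  expect_equal(f2[33] / f[33], 2, tolerance = 1e-3)  # h(0) = 1/(4 d^2), x d
  # DC removal and linearity
  expect_lt(max(abs(ramp_filter(rep(3, 64)))), 1e-10 * 3)
  x <- rnorm(64)
  expect_equal(ramp_filter(5 * x), 5 * ramp_filter(x), tolerance = 1e-12)
})

test_that("backprojection recovers an analytic disk at unit amplitude", {
  nd <- 96; na <- 180; Rd <- 25
  x <- (1:nd) - (nd + 1) / 2
  chord <- ifelse(abs(x) < Rd, 2 * sqrt(pmax(Rd^2 - x^2, 0)), 0)
  sino <- sinogram(matrix(rep(chord, each = na), na, nd),
                   (0:(na - 1)) * 360 / na, 1)
  sl <- backproject(sino)
  rr <- sqrt(outer(x^2, x^2, `+`))
  expect_equal(mean(sl[rr < 0.8 * Rd]), 1, tolerance = 0.05)
  expect_lt(mean(abs(sl[rr > 1.3 * Rd])), 0.05)
  # zero sinogram -> zero slice
  z <- backproject(sinogram(matrix(0, 16, 32), (0:15) * 360 / 16, 1))
  expect_equal(max(abs(z)), 0)
})

test_that("off-center point backprojects to the rotated position", {
  # a point 10 px along +x seen at 0 deg must map to t = +10 cos(theta);
  # reconstruct and confirm the peak sits at (+10, 0), and that a 90 deg
  # angle-offset acquisition moves it to (0, -10) under this convention
  nd <- 64
  x <- (1:nd) - (nd + 1) / 2
  na <- 120
  ang <- (0:(na - 1)) * 360 / na
  sino_vals <- t(vapply(ang, function(a) {
    t0 <- 10 * cos(a * pi / 180)
    exp(-0.5 * (x - t0)^2)   # narrow Gaussian "point"
  }, numeric(nd)))
  sl <- backproject(sinogram(sino_vals, ang, 1))
  pk <- which(sl == max(sl), arr.ind = TRUE)
  expect_equal(as.numeric(pk), c((nd + 1) / 2 + 10, (nd + 1) / 2),
               tolerance = 0.11)
  sl90 <- backproject(sinogram(sino_vals, ang + 90, 1))
  pk90 <- which(sl90 == max(sl90), arr.ind = TRUE)
  expect_equal(as.numeric(pk90), c((nd + 1) / 2, (nd + 1) / 2 - 10),
               tolerance = 0.11)
})

test_that("backprojection agrees with an independent textbook inverse Radon", {
  nd <- 48; na <- 60
  x <- (1:nd) - (nd + 1) / 2
  ang <- (0:(na - 1)) * 180 / na
  shape <- function(t0, w) exp(-0.5 * ((x - t0) / w)^2)
  sino_vals <- t(vapply(ang, function(a)
    3 * shape(6 * cos(a * pi / 180) + 3 * sin(a * pi / 180), 3) +
      shape(-8 * cos(a * pi / 180), 2), numeric(nd)))
  sn <- sinogram(sino_vals, ang, 1)
  mine <- backproject(sn)
  oracle <- naive_iradon(sino_vals, ang, 1)
  expect_lt(sqrt(sum((mine - oracle)^2) / sum(oracle^2)), 1e-2)
})

test_that("volume reconstruction recovers phantoms row-wise", {
  ph <- make_phantom(shape_spec("grooved", radius = 4,
                                groove_depth_frac = 0.35), 64, 0.25)
  st <- simulate_rotation_series(ph, 200)
  rv <- reconstruct_volume(st, normalize = "unit-max")
  expect_gt(cor(as.vector(rv$intensity), as.vector(ph$intensity)), 0.95)
  expect_equal(max(rv$intensity), 1)
  # groove survives reconstruction: downstream concavity is positive
  mesh <- extract_isosurface(rv, 0.32)
  expect_true(attr(mesh, "genus_zero"))
  fit <- fit_spharm(mesh, 8)
  expect_gt(concave_fraction(fit, 6), 0.02)
  # sampling monotonicity where it bites: a heavily undersampled series
  # reconstructs strictly worse than an adequately sampled one
  st40 <- simulate_rotation_series(ph, 40)
  rv40 <- reconstruct_volume(st40, normalize = "unit-max")
  expect_gt(cor(as.vector(rv$intensity), as.vector(ph$intensity)),
            cor(as.vector(rv40$intensity), as.vector(ph$intensity)))
})

test_that("axis translation only shifts which sinograms are occupied", {
  g <- 48
  ph <- make_phantom(shape_spec("spherical", radius = 2.2), g, 0.25)
  sh <- ph
  sh$intensity <- ph$intensity[, c((g - 5):g, 1:(g - 6)), ]  # shift along axis
  st1 <- simulate_rotation_series(ph, 24)
  st2 <- simulate_rotation_series(sh, 24)
  s1 <- frames_to_sinograms(st1); s2 <- frames_to_sinograms(st2)
  occ1 <- vapply(s1, function(s) sum(s$values), numeric(1))
  occ2 <- vapply(s2, function(s) sum(s$values), numeric(1))
  expect_equal(occ2, occ1[c((g - 5):g, 1:(g - 6))], tolerance = 1e-9)
})

test_that("rotation period is recovered to sub-frame precision", {
  sp <- shape_spec("amorphous", radius = 4, perturbation_degrees = c(4, 12),
                   perturbation_amplitude_frac = 0.1, seed = 3)
  ph <- make_phantom(sp, 64, 0.25)
  one <- simulate_rotation_series(ph, 300, fps = 50)  # 6 s per turn
  fr <- array(0, c(64, 64, 600))
  fr[, , 1:300] <- one$frames; fr[, , 301:600] <- one$frames
  est <- estimate_rotation_period(fr, fps = 50)
  expect_equal(est$period, 6, tolerance = 1 / 300)   # within one frame
  expect_equal(max(est$angles) - est$angles[1], 360 * (599 / 50) / 6,
               tolerance = 0.01)
  # invariant to global intensity scaling
  expect_equal(estimate_rotation_period(fr * 37.5, fps = 50)$period,
               est$period)
  # static footage has no period
  static <- array(rep(ph$intensity[, , 32], 200), c(64, 64, 200))
  static <- static + array(rnorm(length(static), 0, 0.01), dim(static))
  expect_error(estimate_rotation_period(static, fps = 50), "period not found")
})

test_that("center-offset search recovers a known shift", {
  nd <- 64; na <- 90
  x <- (1:nd) - (nd + 1) / 2
  ang <- (0:(na - 1)) * 360 / na
  off <- 1.7   # detector samples
  sino_vals <- t(vapply(ang, function(a) {
    t0 <- 6 * cos(a * pi / 180) - 2 * sin(a * pi / 180) - off
    exp(-0.5 * ((x - t0) / 2.5)^2)
  }, numeric(nd)))
  est <- estimate_center_offset(sinogram(sino_vals, ang, 1))
  expect_equal(est, -off, tolerance = 0.15)
})
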