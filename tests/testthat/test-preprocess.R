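test_that("directional filter passes the requested direction and rejects the other", {
  wr <- plane_wavefield(600, 3, "right", taper = TRUE)
  wl <- plane_wavefield(600, 3, "left", taper = TRUE)
  e <- function(w) sum(w$v^2)
  mid <- function(w) sum(w$v[, 25:72, 25:72]^2)   # away from edges
  # pass: >= 95% energy
  expect_gt(e(directional_filter(wr, "left_to_right")) / e(wr), 0.95)
  expect_gt(e(directional_filter(wl, "right_to_left")) / e(wl), 0.95)
  # reject: < 1e-3 of input energy away from edges
  expect_lt(mid(directional_filter(wl, "left_to_right")) / mid(wl), 1e-3)
  expect_lt(mid(directional_filter(wr, "right_to_left")) / mid(wr), 1e-3)
  # relative L2 error of the passed wave away from edges < 0.05
  out <- directional_filter(wr, "left_to_right")
  rel <- sqrt(sum((out$v[, 25:72, 25:72] - wr$v[, 25:72, 25:72])^2) /
                sum(wr$v[, 25:72, 25:72]^2))
  expect_lt(rel, 0.05)
})

test_that("the two directional outputs partition the input", {
  set.seed(3)
  v <- array(stats::rnorm(16 * 48 * 48), c(16, 48, 48))
  w <- wavefield(v, 1.54e-4, 1.54e-4, 1 / 4167)
  l <- directional_filter(w, "left_to_right")
  r <- directional_filter(w, "right_to_left")
  expect_equal(l$v + r$v, w$v, tolerance = 1e-10)
})

test_that("directional filtering is idempotent on propagating waves", {
  # grid-periodic wave (single Fourier bin, clear of the kx ~ 0 ramp): the
  # half-plane mask is exactly 1 there, so filtering twice equals once
  nx <- 96; nt <- 96; nz <- 8; dx <- 1.54e-4; dt <- 1 / 4167
  k0 <- 2 * pi * 5 / (nx * dx)
  f0 <- 14 / (nt * dt)
  x <- (0:(nx - 1)) * dx; tt <- (0:(nt - 1)) * dt
  v <- array(0, c(nz, nx, nt))
  for (it in 1:nt)
    v[, , it] <- matrix(rep(cos(2 * pi * f0 * tt[it] - k0 * x), each = nz),
                        nz, nx)
  w <- wavefield(v, dx, dx, dt)
  once <- directional_filter(w, "left_to_right", pad = 0, equalize = FALSE)
  twice <- directional_filter(once, "left_to_right", pad = 0,
                              equalize = FALSE)
  expect_gt(sum(once$v^2) / sum(w$v^2), 0.999)   # fully in the kept region
  rel <- sqrt(sum((twice$v - once$v)^2) / sum(once$v^2))
  expect_lt(rel, 1e-10)
})

test_that("k-filter keeps in-band waves and attenuates out-of-band waves", {
  v0 <- 3; dv <- 1
  win <- plane_wavefield(600, v0, "right", nz = 12, nx = 64, nt = 64,
                         taper = TRUE)
  wout <- plane_wavefield(600, 8, "right", nz = 12, nx = 64, nt = 64,
                          taper = TRUE)
  gin <- sum(k_bandpass(win, v0, dv)$v^2) / sum(win$v^2)
  gout <- sum(k_bandpass(wout, v0, dv)$v^2) / sum(wout$v^2)
  expect_gt(sqrt(gin), 1 / sqrt(2))
  expect_lt(gout, gin)
  # independent check of the order-1 Butterworth magnitude at the off-band k
  f <- 600
  klo <- 2 * pi * f / (v0 + dv); khi <- 2 * pi * f / (v0 - dv)
  kof <- 2 * pi * f / 8
  gref <- useweb:::butterworth_bp_gain(kof, klo, khi)
  expect_lt(sqrt(gout), min(3 * gref, 0.9))
  z <- wavefield(array(0, c(8, 16, 16)), 1e-4, 1e-4, 1e-4)
  expect_true(all(k_bandpass(z, 3)$v == 0))
  expect_error(k_bandpass(win, 0.5, 1), "v0 - dv")
})

test_that("DC removal zeroes every trace mean and keeps zero-mean signals", {
  set.seed(5)
  v <- array(stats::rnorm(8 * 12 * 64, mean = 2), c(8, 12, 64))
  w <- wavefield(v, 1e-4, 1e-4, 1e-4)
  out <- remove_dc(w)
  means <- apply(out$v, c(1, 2), mean)
  expect_lt(max(abs(means)), 1e-12 * sqrt(mean(v^2)))
  zm <- plane_wavefield(600, 3, nz = 4, nx = 16, nt = 64)
  zm$v <- zm$v - rep(apply(zm$v, c(1, 2), mean), times = 64)
  expect_equal(remove_dc(zm)$v, zm$v, tolerance = 1e-10)
})

test_that("depth averaging obeys its arithmetic identities", {
  nz <- 21
  v <- array(0, c(nz, 8, 16))
  for (iz in 1:nz) v[iz, , ] <- iz          # linear in depth row index
  w <- wavefield(v, 1e-4, 1e-4, 1e-4, z0 = 0)
  # symmetric span around the center row equals the center-row value
  m <- depth_average(w, center_z = 10 * 1e-4, span = 8e-4)
  expect_equal(unname(m[1, 1]), 11)
  # span below dz extracts a single row
  m1 <- depth_average(w, center_z = 4 * 1e-4, span = 1e-5)
  expect_equal(unname(m1[1, 1]), 5)
  # depth-constant field: any span gives the same result
  vconst <- wavefield(array(7, c(nz, 8, 16)), 1e-4, 1e-4, 1e-4)
  expect_equal(unname(depth_average(vconst, 1e-3, 1.5e-3)[3, 4]), 7)
  expect_error(depth_average(w, 1, 1e-3), "outside")
})

test_that("directional filter and k-filter commute as Fourier masks", {
  w <- plane_wavefield(600, 3, "right", nz = 12, nx = 48, nt = 48,
                       t_arr = 0.003, taper = TRUE)
  a <- k_bandpass(directional_filter(w, "left_to_right", pad = 0,
                                     equalize = FALSE), 3, 1, pad = 0)
  b <- directional_filter(k_bandpass(w, 3, 1, pad = 0), "left_to_right",
                          pad = 0, equalize = FALSE)
  expect_equal(a$v, b$v, tolerance = 1e-8)
})

test_that("preprocessing preserves shape and grid metadata", {
  w <- plane_wavefield(600, 3, nz = 8, nx = 32, nt = 32)
  for (out in list(directional_filter(w, "left_to_right"),
                   k_bandpass(w, 3, 1), remove_dc(w))) {
    expect_identical(dim(out$v), dim(w$v))
    expect_identical(out$dx, w$dx)
    expect_identical(out$dt, w$dt)
  }
})
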