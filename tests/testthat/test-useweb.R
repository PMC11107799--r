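test_that("window extraction applies the Tukey taper and edge policy", {
  set.seed(8)
  v <- array(stats::rnorm(32 * 48 * 20), c(32, 48, 20))
  w <- wavefield(v, 1.54e-4, 1.54e-4, 1 / 4167)
  H <- decompose(w, 600, tau_len = 20)
  # rectangular window equals plain restriction
  ew <- extract_window(H, c(16 * H$dz, 24 * H$dx), 2e-3, taper = 0)
  expect_equal(ew$Hw, H$H[ew$zidx, ew$xidx, , drop = FALSE],
               tolerance = 1e-12)
  # full taper on a constant volume reproduces the taper profile
  Hc <- H; Hc$H[] <- 1 + 0i
  ew2 <- extract_window(Hc, c(16 * H$dz, 24 * H$dx), 2e-3, taper = 1)
  expect_equal(Re(ew2$Hw[, , 1]), ew2$taper, tolerance = 1e-12)
  # corner window: trim policy keeps the intersection, strict errors
  expect_error(extract_window(H, c(0, 0), 2e-3, policy = "strict"),
               "exceeds")
  ew3 <- extract_window(H, c(0, 0), 2e-3, policy = "trim")
  expect_equal(length(ew3$zidx), 7)          # half of a 13-sample window
  expect_equal(length(ew3$xidx), 7)
})

test_that("slant slices obey their limiting identities", {
  set.seed(9)
  Hw <- array(complex(real = stats::rnorm(6 * 8 * 30),
                      imaginary = stats::rnorm(6 * 8 * 30)), c(6, 8, 30))
  dx <- 1.54e-4; dt <- 1 / 4167
  # u -> Inf picks the tau = 0 slice
  expect_equal(slant_slice(Hw, 1e9, dx, dt), Hw[, , 1], tolerance = 1e-6)
  # all-zero volume -> all-zero slice
  expect_true(all(slant_slice(array(0i, c(4, 4, 8)), 1, dx, dt) == 0))
  expect_error(slant_slice(Hw, -1, dx, dt), "positive")
  # interpolation: constructed volume linear in tau index
  Hl <- array(0i, c(2, 4, 10))
  for (it in 1:10) Hl[, , it] <- it
  SF <- slant_slice(Hl, u = dx / dt, dx, dt)  # tau = x index step
  expect_equal(Re(SF[1, ]), c(1, 2, 3, 4))
})

test_that("spectral amplitude has the exponential-peak, Parseval and symmetry properties", {
  dz <- dx <- 1.54e-4
  nx <- 24; nz <- 16
  k0 <- 900                                  # rad/m
  SF <- matrix(exp(-1i * k0 * (0:(nx - 1)) * dx), nz, nx, byrow = TRUE)
  sp <- spectral_amplitude(SF, dz, dx, pad = c(32, 256))
  pk <- which(sp$K == max(sp$K), arr.ind = TRUE)[1, ]
  expect_equal(sp$kz[pk[1]], 0)
  expect_lt(abs(abs(sp$kx[pk[2]]) - k0), 2 * pi / (256 * dx))
  # Parseval with no padding
  sp0 <- spectral_amplitude(SF, dz, dx, pad = c(nz, nx))
  lhs <- sum(abs(SF)^2) * dz * dx
  rhs <- sum(sp0$K^2) * (1 / (nz * dz)) * (1 / (nx * dx))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # real input -> symmetric amplitude
  spr <- spectral_amplitude(matrix(stats::rnorm(nz * nx), nz, nx), dz, dx,
                            pad = c(16, 32))
  expect_equal(spr$K[2:16, 2:32],
               spr$K[16:2, 32:2], tolerance = 1e-10)
})

test_that("steering maximum behaves as an element-wise max", {
  dz <- dx <- 1e-4
  mk <- function(seed) {
    set.seed(seed)
    spectral_amplitude(matrix(complex(real = stats::rnorm(32),
                                      imaginary = stats::rnorm(32)), 4, 8),
                       dz, dx, pad = c(4, 8))
  }
  a <- mk(1); b <- mk(2)
  expect_equal(max_over_steering(list(a)), a)
  expect_equal(max_over_steering(list(a, a, b)),
               max_over_steering(list(a, b)))
  K <- max_over_steering(list(a, b))$K
  expect_true(all(K >= a$K) && all(K >= b$K))
  expect_error(max_over_steering(list()), "empty")
})

test_that("wavenumber picking respects the annulus and tie-breaks", {
  kz <- 2 * pi * useweb:::fft_freqs(8, 1e-4)
  kx <- 2 * pi * useweb:::fft_freqs(64, 1e-4)
  K <- matrix(0, 8, 64)
  spec <- structure(list(K = K, kz = kz, kx = kx), class = "swe_kspec")
  f0 <- 500
  # single nonzero bin inside the annulus wins
  i <- which.min(abs(kx - 2 * pi * f0 / 3))
  K1 <- K; K1[1, i] <- 1
  spec$K <- K1
  pk <- pick_wavenumber(spec, f0, c(0.5, 10), refine = FALSE)
  expect_equal(pk$kx, kx[i])
  expect_equal(pk$c, 2 * pi * f0 / abs(kx[i]))
  # two equal maxima: the smaller |k| one is chosen, reproducibly
  j <- which.min(abs(kx - 2 * pi * f0 / 1.2))
  K2 <- K1; K2[1, j] <- 1
  spec$K <- K2
  pk2 <- pick_wavenumber(spec, f0, c(0.5, 10), refine = FALSE)
  expect_equal(pk2$kx, kx[i])
  # empty annulus errors
  expect_error(pick_wavenumber(spec, 5, c(9.99, 10)), "annulus")
})

test_that("compiled kernel, R engine and literal loop oracle agree", {
  set.seed(12)
  nz <- 5; nx <- 6; ntau <- 12
  Hw <- array(complex(real = stats::rnorm(nz * nx * ntau),
                      imaginary = stats::rnorm(nz * nx * ntau)),
              c(nz, nx, ntau))
  tp <- useweb:::tukey2(nz, nx, 0.3)
  xbar <- (0:(nx - 1)) * 1.54e-4
  u <- c(0.3, 0.8, 2.5)
  dt <- 1 / 4167
  Kc <- useweb:::steer_max_spectrum_cpp(Hw, tp, xbar, u, dt, 8, 8,
                                        1.54e-4, 1.54e-4)
  Kr <- useweb:::steer_max_spectrum_r(Hw, tp, xbar, u, dt, 8, 8,
                                      1.54e-4, 1.54e-4)
  Kd <- steer_max_direct(Hw, tp, xbar, u, dt, 8, 8, 1.54e-4, 1.54e-4)
  scale <- max(Kd)
  expect_lt(max(abs(Kc - Kr)) / scale, 1e-10)
  expect_lt(max(abs(Kc - Kd)) / scale, 1e-8)
})

test_that("an analytic packet reconstructs its phase velocity exactly", {
  w <- plane_wavefield(600, 3, "right", nz = 40, nx = 160, nt = 300,
                       t_arr = 0.006)
  pv <- useweb(w, 600, stride = 5, directions = "left_to_right",
               prefilter = FALSE,
               region = list(zlim = c(0.002, 0.004), xlim = c(0.008, 0.016)))
  v <- pv$cph[pv$mask]
  expect_gt(length(v), 5)
  expect_equal(mean(v), 3, tolerance = 0.01)
  expect_lt(stats::sd(v) / mean(v), 0.01)
})

test_that("the phase-velocity map is invariant to wavefield amplitude", {
  w <- plane_wavefield(600, 3, "right", nz = 24, nx = 96, nt = 200,
                       t_arr = 0.004)
  reg <- list(zlim = c(0.001, 0.003), xlim = c(0.005, 0.009))
  p1 <- useweb(w, 600, window = c(2.5e-3, 4.47e-3), stride = 6,
               directions = "left_to_right", prefilter = FALSE, region = reg)
  w2 <- w; w2$v <- 137.5 * w$v
  p2 <- useweb(w2, 600, window = c(2.5e-3, 4.47e-3), stride = 6,
               directions = "left_to_right", prefilter = FALSE, region = reg)
  expect_equal(p1$cph, p2$cph, tolerance = 1e-9)
})

test_that("pad refinement changes the recovered wavenumber by less than a bin", {
  w <- plane_wavefield(700, 2.5, "right", nz = 24, nx = 96, nt = 200,
                       t_arr = 0.004)
  reg <- list(zlim = c(0.0015, 0.0025), xlim = c(0.006, 0.008))
  p1 <- useweb(w, 700, window = c(2.5e-3, 4.47e-3), stride = 6,
               directions = "left_to_right", prefilter = FALSE,
               pad = c(2, 4), region = reg)
  p2 <- useweb(w, 700, window = c(2.5e-3, 4.47e-3), stride = 6,
               directions = "left_to_right", prefilter = FALSE,
               pad = c(2, 8), region = reg)
  k1 <- 2 * pi * 700 / mean(p1$cph[p1$mask])
  k2 <- 2 * pi * 700 / mean(p2$cph[p2$mask])
  nwx <- 2 * floor(4.47e-3 / (2 * 1.54e-4)) + 1
  bin <- 2 * pi / (2^ceiling(log2(4 * nwx)) * 1.54e-4)
  expect_lt(abs(k1 - k2), bin)
})

test_that("map containers and methods round-trip", {
  w <- plane_wavefield(600, 3, "right", nz = 24, nx = 96, nt = 200,
                       t_arr = 0.004)
  pv <- useweb(w, 600, window = c(2.5e-3, 4.47e-3), stride = 8,
               directions = "left_to_right", prefilter = FALSE,
               region = list(zlim = c(0.001, 0.003), xlim = c(0.005, 0.009)))
  path <- tempfile(fileext = ".rds")
  save_map(pv, path)
  back <- load_map(path)
  expect_equal(back$cph, pv$cph)
  s <- summary(pv)
  expect_s3_class(s, "summary.swe_pvmap")
  expect_true(is.finite(s$cv))
  unlink(path)
})
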