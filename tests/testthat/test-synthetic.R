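test_that("time of flight in an elastic scene matches the material speed", {
  sc <- swe_scene(background = material_elastic(25e3), duration = 0.03,
                  lateral = c(0, 0.03), depth = c(0.015, 0.025),
                  pushes = 0.003)
  w <- synthesize_wavefield(sc)$wavefield
  iz <- which.min(abs(useweb:::wf_z(w) - 0.020))
  x1 <- round(0.010 / w$dx) + 1L
  x2 <- round(0.020 / w$dx) + 1L
  a <- w$v[iz, x1, ]; b <- w$v[iz, x2, ]
  nlag <- 60
  cc <- vapply(0:nlag, function(l)
    sum(a[1:(length(a) - l)] * b[(1 + l):length(b)]), numeric(1))
  lag <- which.max(cc) - 1L
  expected <- 0.010 / sqrt(25e3 / 3000) / w$dt
  expect_lt(abs(lag - expected), 1.5)  # within one time sample (+rounding)
})

test_that("zero-amplitude pulse yields an all-zero wavefield", {
  sc <- swe_scene(background = material_elastic(25e3), duration = 0.01,
                  lateral = c(0, 0.01), depth = c(0.018, 0.022),
                  pushes = 0.005, pulse = list(amplitude = 0))
  expect_true(all(synthesize_wavefield(sc)$wavefield$v == 0))
})

test_that("synthesis is homogeneous of degree one in pulse amplitude", {
  base <- list(background = material_elastic(25e3), duration = 0.015,
               lateral = c(0, 0.015), depth = c(0.018, 0.022),
               pushes = 0.004)
  w1 <- synthesize_wavefield(do.call(swe_scene, base))$wavefield
  base$pulse <- list(amplitude = 3.7)
  w2 <- synthesize_wavefield(do.call(swe_scene, base))$wavefield
  expect_equal(w2$v, 3.7 * w1$v, tolerance = 1e-12)
})

test_that("f-k ridge of a KV scene follows the dispersion law", {
  m <- material_kv(4e3, 0.3)
  sc <- swe_scene(background = m, duration = 0.06, pushes = 0.006)
  w <- synthesize_wavefield(sc)$wavefield
  line <- extract_line(w, 0.020, xlim = c(0.009, 0.033))
  fk <- fk_spectrum(line)
  for (ff in c(300, 500, 700)) {
    j <- which.min(abs(fk$f - ff))
    row <- fk$A[, j]
    sel <- abs(fk$k) > 2 * pi * fk$f[j] / 10   # exclude the DC/low-k region
    kpk <- abs(fk$k[which(sel)[which.max(row[sel])]])
    ktrue <- 2 * pi * fk$f[j] / dispersion_law(m, fk$f[j])$c
    dk <- abs(fk$k[2] - fk$k[1])
    expect_lt(abs(kpk - ktrue), 1.5 * dk)
  }
})

test_that("scene validation rejects inconsistent descriptions", {
  expect_error(swe_scene(inclusion = list(center_z = 0.010, center_x = 0.002,
                                          radius = 0.004,
                                          model = material_elastic(80e3))),
               "inside the grid")
  expect_error(swe_scene(pulse = list(fc = 1800, bw = 1000)), "Nyquist")
  expect_error(swe_scene(pushes = 0.1), "push positions")
})

test_that("ground-truth map reflects region materials", {
  sc <- swe_scene(background = material_elastic(29e3),
                  inclusion = list(center_z = 0.020, center_x = 0.020,
                                   radius = 3.245e-3,
                                   model = material_elastic(80e3)),
                  duration = 0.01)
  sim <- synthesize_wavefield(sc)
  cm <- truth_c_map(sim, 1000)
  expect_equal(max(cm), sqrt(80e3 / 3000), tolerance = 1e-10)
  expect_equal(min(cm), sqrt(29e3 / 3000), tolerance = 1e-10)
  # inclusion area ~ pi r^2 in pixels
  npx <- sum(cm > 5)
  expect_equal(npx * sc$dz * sc$dx, pi * 3.245e-3^2, tolerance = 0.05)
})

test_that("additive noise hits the requested SNR and is reproducible", {
  v <- array(sin(2 * pi * (1:1.2e6) / 40), c(100, 100, 120))
  w <- wavefield(v, 1e-4, 1e-4, 1e-4)
  wn <- add_noise(w, 20, seed = 7)
  snr_emp <- 10 * log10(mean(w$v^2) / mean((wn$v - w$v)^2))
  expect_lt(abs(snr_emp - 20), 0.1)
  wn2 <- add_noise(w, 20, seed = 7)
  expect_identical(wn$v, wn2$v)
  expect_false(identical(add_noise(w, 20, seed = 8)$v, wn$v))
  expect_identical(add_noise(w, Inf)$v, w$v)
  w0 <- wavefield(array(0, c(4, 4, 8)), 1e-4, 1e-4, 1e-4)
  expect_error(add_noise(w0, 20), "all-zero")
})

test_that("wavefield containers round-trip through disk", {
  sc <- small_elastic_scene(duration = 0.01)
  sim <- synthesize_wavefield(sc)
  path <- tempfile(fileext = ".rds")
  save_wavefield(sim, path, attrs = list(seed = 1L))
  back <- load_wavefield(path)
  expect_s3_class(back, "swe_simulation")
  expect_equal(back$wavefield$v, sim$wavefield$v)
  expect_equal(back$attrs$seed, 1L)
  unlink(path)
  expect_error(load_wavefield(path), "no such file")
})
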