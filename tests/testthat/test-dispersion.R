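make_line <- function(f0, c0, nx = 176, nt = 256, dx = 1.54e-4,
                      dt = 1 / 4167, t_arr = 0.004, sigma_t = 2e-3) {
  x <- (0:(nx - 1)) * dx
  tt <- (0:(nt - 1)) * dt
  k0 <- 2 * pi * f0 / c0
  v <- outer(x, tt, function(xx, ti)
    cos(2 * pi * f0 * ti - k0 * xx) *
      exp(-(ti - t_arr - xx / c0)^2 / (2 * sigma_t^2)))
  attr(v, "dx") <- dx
  attr(v, "dt") <- dt
  v
}

test_that("the f-k spectrum localizes a plane wave and conserves energy", {
  v <- make_line(500, 3)
  fk <- fk_spectrum(v, pad = 2)
  pk <- which(fk$A == max(fk$A), arr.ind = TRUE)[1, ]
  expect_lt(abs(fk$f[pk[2]] - 500), 2 / (256 * attr(v, "dt") / 4167 * 4167))
  expect_lt(abs(abs(fk$k[pk[1]]) - 2 * pi * 500 / 3),
            2 * abs(fk$k[2] - fk$k[1]))
  # Parseval on the unpadded full transform
  d <- dim(v)
  A <- abs(stats::fft(v)) * attr(v, "dx") * attr(v, "dt")
  lhs <- sum(v^2) * attr(v, "dx") * attr(v, "dt")
  rhs <- sum(A^2) / (d[1] * attr(v, "dx")) / (d[2] * attr(v, "dt"))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(fk_spectrum(v[1:4, 1:4], 1e-4, 1e-4), "at least 8")
})

test_that("2D-FT dispersion of an elastic field is flat at the true speed", {
  c0 <- sqrt(45e3 / 3000)                    # 3.873 m/s
  v <- make_line(600, c0, sigma_t = 6e-3)    # broad packet, several cycles
  # multi-frequency content: superpose packets at several carriers
  for (f0 in c(400, 800)) v <- v + make_line(f0, c0, sigma_t = 6e-3)
  curve <- dispersion_2dft(v, c(400, 600, 800))
  expect_true(all(!curve$masked))
  expect_equal(curve$c, rep(c0, 3), tolerance = 0.02)
})

test_that("zero signal yields a fully masked curve", {
  z <- matrix(0, 64, 64)
  attr(z, "dx") <- 1e-4; attr(z, "dt") <- 1e-4
  expect_true(all(dispersion_2dft(z, c(300, 500))$masked))
  expect_true(all(dispersion_gst_sfk(z, c(300, 500))$masked))
})

test_that("slant-steered and 2D-FT estimates agree on elastic plane waves", {
  c0 <- 2.5
  v <- make_line(500, c0, sigma_t = 5e-3)
  c1 <- dispersion_2dft(v, 500)
  c2 <- dispersion_gst_sfk(v, 500)
  dx <- attr(v, "dx")
  kbin <- 2 * pi / (2^ceiling(log2(8 * nrow(v))) * dx)
  k1 <- 2 * pi * 500 / c1$c; k2 <- 2 * pi * 500 / c2$c
  expect_lt(abs(k1 - k2), 4 * kbin)
})

test_that("slant-steered dispersion traces a noisy viscoelastic field", {
  m <- material_kv(4e3, 0.08)
  sc <- swe_scene(background = m, duration = 0.08, snr_db = 20, seed = 21)
  w <- synthesize_wavefield(sc)$wavefield
  fg <- seq(200, 1500, by = 130)
  truth <- dispersion_law(m, fg)$c
  cs <- NULL
  for (zc in c(0.018, 0.020, 0.022))
    for (dr in c("left_to_right", "right_to_left")) {
      l <- extract_line(w, zc, xlim = c(0.008, 0.032), direction = dr)
      cv <- dispersion_gst_sfk(l, fg)
      expect_false(any(cv$masked))           # unmasked across 200-1500 Hz
      cs <- cbind(cs, cv$c)
    }
  cc <- rowMeans(cs)
  expect_lt(max(abs(cc - truth) / truth), 0.03)
})

test_that("dispersion curves export to CSV", {
  v <- make_line(500, 3)
  curve <- dispersion_2dft(v, c(400, 500))
  path <- tempfile(fileext = ".csv")
  write_dispersion_csv(curve, path)
  back <- utils::read.csv(path)
  expect_equal(back$c, curve$c, tolerance = 1e-9)
  unlink(path)
})

test_that("an exact SLS curve is recovered to within 1%", {
  truth <- material_sls(9.61e3, 15.62e3, 5.28)
  curve <- dispersion_law(truth, seq(100, 1500, by = 50))
  fit <- fit_material_model(curve, "sls")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["E1"]), 9.61e3, tolerance = 0.01)
  expect_equal(unname(coef(fit)["E2"]), 15.62e3, tolerance = 0.01)
  expect_equal(unname(coef(fit)["eta"]), 5.28, tolerance = 0.01)
})

test_that("a flat curve fit with Kelvin-Voigt drives viscosity to zero", {
  c0 <- sqrt(45e3 / 3000)
  curve <- data.frame(f = seq(100, 1200, by = 100), c = c0)
  fit <- fit_material_model(curve, "kelvin_voigt")
  expect_equal(unname(coef(fit)["mu"]), 1000 * c0^2, tolerance = 0.01)
  expect_lt(unname(coef(fit)["eta"]), 0.05)
})

test_that("noisy curves recover Kelvin-Voigt parameters within 10%", {
  truth <- material_kv(5e3, 1.5)
  f <- seq(100, 1500, by = 50)
  c_true <- dispersion_law(truth, f)$c
  mus <- etas <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    curve <- data.frame(f = f, c = c_true + stats::rnorm(length(f), sd = 0.05))
    fit <- fit_material_model(curve, "kelvin_voigt")
    mus[s] <- coef(fit)["mu"]; etas[s] <- coef(fit)["eta"]
  }
  expect_lt(abs(mean(mus) - 5e3) / 5e3, 0.1)
  expect_lt(abs(mean(etas) - 1.5) / 1.5, 0.1)
})

test_that("the fit object exposes the standard model methods", {
  truth <- material_sls(12e3, 30e3, 4)
  curve <- dispersion_law(truth, seq(100, 1400, by = 100))
  fit <- fit_material_model(curve, "sls")
  expect_equal(predict(fit, f = 600), dispersion_law(fit$model, 600)$c)
  expect_lt(max(abs(residuals(fit))), 1e-4)
  expect_output(print(fit), "sls")
  expect_error(fit_material_model(curve[1:3, ], "sls"), "at least 5")
  narrow <- dispersion_law(truth, seq(500, 700, by = 40))
  expect_error(fit_material_model(narrow, "sls"), "factor 2")
})
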