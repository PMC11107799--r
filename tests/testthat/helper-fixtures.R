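# Fixture builders shared across the suite. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# analytic plane wave cos(2 pi f t -/+ k x), optionally modulated by a
# Gaussian packet envelope moving at the group velocity cg
plane_wavefield <- function(f0, c0, direction = c("right", "left"),
                            nz = 16, nx = 96, nt = 96,
                            dz = 1.54e-4, dx = 1.54e-4, dt = 1 / 4167,
                            t_arr = NULL, sigma_t = 1.5e-3, cg = c0,
                            taper = FALSE) {
  direction <- match.arg(direction)
  k0 <- 2 * pi * f0 / c0
  sgn <- if (direction == "right") 1 else -1
  x <- (0:(nx - 1)) * dx
  tt <- (0:(nt - 1)) * dt
  v <- array(0, c(nz, nx, nt))
  for (it in seq_len(nt)) {
    carrier <- cos(2 * pi * f0 * tt[it] - sgn * k0 * x)
    if (!is.null(t_arr)) {
      env <- exp(-(tt[it] - t_arr - sgn * (x - if (sgn > 0) 0 else
        max(x)) / cg)^2 / (2 * sigma_t^2))
      carrier <- carrier * env
    }
    v[, , it] <- matrix(rep(carrier, each = nz), nz, nx)
  }
  if (taper) {
    tx <- useweb:::tukey1(nx, 0.4)
    tt2 <- useweb:::tukey1(nt, 0.4)
    for (it in seq_len(nt)) v[, , it] <- v[, , it] * tt2[it] *
      rep(tx, each = nz)
  }
  wavefield(v, dz, dx, dt)
}

# small homogeneous elastic scene, quick to render and reconstruct
small_elastic_scene <- function(E = 25e3, snr_db = Inf, seed = 1,
                                duration = 0.04) {
  swe_scene(background = material_elastic(E), duration = duration,
            snr_db = snr_db, seed = seed)
}

# literal O(N^2) direct summation of the S-transform definition
st_direct <- function(x, dt, f0, beta = 1,
                      normalization = c("unit_area", "printed")) {
  normalization <- match.arg(normalization)
  n <- length(x)
  tt <- (0:(n - 1)) * dt
  amp <- if (normalization == "unit_area") abs(f0) / sqrt(2 * pi * beta)
    else abs(f0) / (2 * pi * beta)
  vapply(seq_len(n), function(m) {
    W <- amp * exp(-f0^2 * (tt[m] - tt)^2 / (2 * beta))
    sum(x * W * exp(-2i * pi * f0 * tt)) * dt
  }, complex(1))
}

# literal loop-based spectral amplitude: direct DFT of the slant slice, no
# FFT shortcuts; mirrors the definition of the slant wavenumber spectrum
steer_max_direct <- function(Hw, taper, xbar, u, dt, pz, px, dz, dx) {
  nz <- dim(Hw)[1]; nx <- dim(Hw)[2]; ntau <- dim(Hw)[3]
  K <- matrix(0, pz, px)
  for (uu in u) {
    SF <- matrix(0i, nz, nx)
    for (ix in seq_len(nx)) {
      pos <- xbar[ix] / uu / dt
      i0 <- floor(pos)
      if (i0 < 0 || i0 >= ntau) next
      for (iz in seq_len(nz)) {
        val <- Hw[iz, ix, i0 + 1] * (1 - (pos - i0))
        if (i0 + 2 <= ntau) val <- val + Hw[iz, ix, i0 + 2] * (pos - i0)
        SF[iz, ix] <- val * taper[iz, ix]
      }
    }
    for (ikz in seq_len(pz)) {
      for (ikx in seq_len(px)) {
        s <- 0i
        for (iz in seq_len(nz)) for (ix in seq_len(nx))
          s <- s + SF[iz, ix] *
            exp(-2i * pi * ((ikz - 1) * (iz - 1) / pz +
                            (ikx - 1) * (ix - 1) / px))
        K[ikz, ikx] <- max(K[ikz, ikx], abs(s) * dz * dx)
      }
    }
  }
  K
}
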