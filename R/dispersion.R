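# 1D phase-velocity dispersion estimation at a fixed depth: the classical 2D
# Fourier (f-k) ridge tracer and the slant-steered S-transform variant that
# keeps working at frequencies where the plain f-k ridge sinks into the noise.

#' Extract the lateral-time field at the focal depth
#'
#' Convenience preprocessing chain for the 1D dispersion estimators:
#' directional filtering, depth averaging over a span centered at the focal
#' depth, restriction to a lateral segment and temporal DC removal. For
#' right-to-left waves the lateral axis is reversed so that propagation is
#' always towards increasing column index.
#'
#' @param w A [wavefield()].
#' @param center_z Focal depth in m.
#' @param span Depth-averaging span in m (default 1.69 mm).
#' @param xlim Optional lateral segment `c(x_min, x_max)` in m (e.g. 27 mm
#'   long).
#' @param direction Travel direction to isolate.
#' @param prefilter Apply the directional filter (default `TRUE`).
#' @return Matrix `v(x, t)` with attributes `dx`, `dt`.
#' @export
extract_line <- function(w, center_z, span = 1.69e-3, xlim = NULL,
                         direction = c("left_to_right", "right_to_left"),
                         prefilter = TRUE) {
  direction <- match.arg(direction)
  wd <- if (prefilter) directional_filter(w, direction) else w
  m <- depth_average(wd, center_z, span)
  if (!is.null(xlim)) {
    x <- w$x0 + (seq_len(nrow(m)) - 1) * w$dx
    keep <- x >= xlim[1] & x <= xlim[2]
    if (sum(keep) < 8L) stop("lateral segment too short", call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  if (direction == "right_to_left") m <- m[rev(seq_len(nrow(m))), ,
                                           drop = FALSE]
  m <- m - rowMeans(m)
  attr(m, "dx") <- w$dx
  attr(m, "dt") <- w$dt
  m
}

#' Frequency-wavenumber spectrum of a lateral-time field
#'
#' 2D Fourier magnitude of `v(x, t)` with physical axes: temporal frequency
#' `f` (Hz, non-negative half) and signed wavenumber `k` (rad/m). Optionally
#' normalized by the wavenumber maximum at each frequency for display.
#'
#' @param vxt Matrix `(nx, nt)`.
#' @param dx,dt Sample spacings (taken from attributes of `vxt` when `NULL`).
#' @param pad Zero-padding factor per axis (default 4).
#' @param normalize Per-frequency normalization by the ridge maximum.
#' @return List of class `swe_fk` with amplitude `A` (`nk` x `nf`), `k`
#'   (rad/m, signed, DFT order) and `f` (Hz, increasing).
#' @export
fk_spectrum <- function(vxt, dx = NULL, dt = NULL, pad = 4,
                        normalize = FALSE) {
  dx <- dx %||% attr(vxt, "dx"); dt <- dt %||% attr(vxt, "dt")
  if (is.null(dx) || is.null(dt)) stop("dx/dt required", call. = FALSE)
  d <- dim(vxt)
  if (any(d < 8L)) stop("need at least 8 samples per axis", call. = FALSE)
  pn <- 2^ceiling(log2(pad * d))
  buf <- matrix(0, pn[1], pn[2])
  buf[seq_len(d[1]), seq_len(d[2])] <- vxt
  A <- abs(stats::fft(buf)) * dx * dt
  nf <- pn[2] %/% 2 + 1
  A <- A[, seq_len(nf), drop = FALSE]
  if (normalize) {
    mx <- apply(A, 2, max)
    A <- sweep(A, 2, pmax(mx, .Machine$double.eps), "/")
  }
  structure(list(A = A, k = 2 * pi * fft_freqs(pn[1], dx),
                 f = (seq_len(nf) - 1) / (pn[2] * dt)),
            class = "swe_fk")
}

# per-frequency ridge pick over a signed-k amplitude row
ridge_pick <- function(row, kax, f, search_band, prominence) {
  kabs <- abs(kax)
  klo <- 2 * pi * f / search_band[2]
  khi <- 2 * pi * f / search_band[1]
  sel <- kabs >= klo & kabs <= khi
  if (!any(sel)) return(list(c = NA_real_, quality = NA_real_))
  vals <- row[sel]
  i <- which(sel)[which.max(vals)]
  peak <- row[i]
  med <- stats::median(row)
  qual <- if (med > 0) peak / med else Inf
  # 3-point parabolic refinement along the signed axis
  off <- 0
  if (i > 1L && i < length(row)) {
    den <- row[i - 1] - 2 * row[i] + row[i + 1]
    if (den != 0) off <- max(-0.5, min(0.5, 0.5 * (row[i - 1] - row[i + 1]) /
                                         den))
  }
  kk <- abs(kax[i] + off * sign(diff(kax[1:2])) *
              abs(kax[2] - kax[1]))
  ok <- is.finite(qual) && qual >= prominence && kk > 0
  list(c = if (ok) 2 * pi * f / kk else NA_real_,
       quality = qual)
}

new_dispersion <- function(f, c, quality, method) {
  structure(data.frame(f = f, c = c, quality = quality,
                       method = method, masked = !is.finite(c)),
            class = c("swe_dispersion", "data.frame"))
}

#' Dispersion curve from the 2D Fourier ridge
#'
#' For each requested frequency, picks the dominant wavenumber of the f-k
#' spectrum within the velocity search annulus (3-point parabolic sub-bin
#' refinement) and converts it to phase velocity `c = 2 pi f / k`.
#' Frequencies whose spectral peak is weaker than `prominence` times the
#' median of the spectrum row are masked.
#'
#' @inheritParams fk_spectrum
#' @param fgrid Frequencies in Hz at which the curve is traced (snapped to
#'   the padded FFT bins).
#' @param search_band Velocity bounds `c(c_min, c_max)` in m/s.
#' @param prominence Peak-to-row-median floor for auto-masking.
#' @return An `swe_dispersion` data frame with columns `f`, `c`, `quality`,
#'   `method`, `masked`.
#' @export
dispersion_2dft <- function(vxt, fgrid, dx = NULL, dt = NULL, pad = 4,
                            search_band = c(0.5, 10), prominence = 3) {
  fk <- fk_spectrum(vxt, dx, dt, pad)
  bins <- vapply(fgrid, function(ff) which.min(abs(fk$f - ff)), integer(1))
  res <- lapply(seq_along(fgrid), function(j) {
    ridge_pick(fk$A[, bins[j]], fk$k, fk$f[bins[j]], search_band, prominence)
  })
  new_dispersion(fk$f[bins], vapply(res, `[[`, numeric(1), "c"),
                 vapply(res, `[[`, numeric(1), "quality"), "2dft")
}

#' Dispersion curve from the slant-steered S-transform spectrum
#'
#' The 1D analogue of the USEWEB machinery: per frequency, the S-transform
#' voice of every lateral trace is slant-sliced along `tau = x / u` for a
#' series of steering group velocities, the spatial FFT amplitudes are
#' maximized over steering, and the wavenumber peak gives the phase velocity.
#' On lossy media this keeps tracing the dispersion curve at frequencies
#' where the plain f-k ridge is no longer detectable.
#'
#' @inheritParams dispersion_2dft
#' @param beta S-transform window scaling factor.
#' @param taper Tukey taper ratio applied along the lateral segment.
#' @param u_min,u_max,n_u Steering-series parameters, see
#'   [steering_series()].
#' @return An `swe_dispersion` data frame.
#' @export
dispersion_gst_sfk <- function(vxt, fgrid, dx = NULL, dt = NULL, beta = 16,
                               pad = 8, taper = 0.25,
                               search_band = c(0.5, 10), prominence = 3,
                               u_min = 0.2, u_max = 15, n_u = 48L) {
  dx <- dx %||% attr(vxt, "dx"); dt <- dt %||% attr(vxt, "dt")
  if (is.null(dx) || is.null(dt)) stop("dx/dt required", call. = FALSE)
  d <- dim(vxt)
  if (any(d < 8L)) stop("need at least 8 samples per axis", call. = FALSE)
  nx <- d[1]; nt <- d[2]
  xbar <- (0:(nx - 1)) * dx
  u <- steering_series((nx - 1) * dx, (nt - 1) * dt, dt, u_min, u_max, n_u)
  tau_len <- min(nt, ceiling((nx - 1) * dx / (u_min * dt)) + 2L)
  pnx <- 2^ceiling(log2(pad * nx))
  kax <- 2 * pi * fft_freqs(pnx, dx)
  tpr <- tukey1(nx, taper)
  cs <- qs <- rep(NA_real_, length(fgrid))
  for (j in seq_along(fgrid)) {
    f <- fgrid[j]
    H <- t(st_voice(t(vxt), dt, f, beta, "unit_area"))[, seq_len(tau_len),
                                                       drop = FALSE]
    row <- rep(0, pnx)
    idx <- xbar / dt
    for (uu in u) {
      pos <- idx / uu
      i0 <- floor(pos)
      wfrac <- pos - i0
      ok <- i0 >= 0 & i0 < tau_len
      SF <- rep(0i, nx)
      sel1 <- ok
      SF[sel1] <- H[cbind(which(sel1), i0[sel1] + 1L)] * (1 - wfrac[sel1])
      sel2 <- ok & (i0 + 2L <= tau_len)
      SF[sel2] <- SF[sel2] + H[cbind(which(sel2), i0[sel2] + 2L)] *
        wfrac[sel2]
      amp <- abs(stats::fft(c(SF * tpr, rep(0i, pnx - nx)))) * dx
      row <- pmax(row, amp)
    }
    pk <- ridge_pick(row, kax, f, search_band, prominence)
    cs[j] <- pk$c; qs[j] <- pk$quality
  }
  new_dispersion(fgrid, cs, qs, "gst_sfk")
}

#' @export
print.swe_dispersion <- function(x, ...) {
  ok <- !x$masked
  cat(sprintf("<swe_dispersion> %s: %d/%d frequencies traced\n",
              x$method[1], sum(ok), nrow(x)))
  if (any(ok))
    cat(sprintf("  f %g..%g Hz, c %.3f..%.3f m/s\n", min(x$f[ok]),
                max(x$f[ok]), min(x$c[ok]), max(x$c[ok])))
  invisible(x)
}

#' @export
plot.swe_dispersion <- function(x, ...) {
  ok <- !x$masked
  graphics::plot(x$f[ok], x$c[ok], type = "b", pch = 19,
                 xlab = "frequency [Hz]", ylab = "phase velocity [m/s]",
                 main = paste("dispersion,", x$method[1]), ...)
  invisible(x)
}

#' Write a dispersion curve to CSV
#'
#' @param curve An `swe_dispersion`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
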