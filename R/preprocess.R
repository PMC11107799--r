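# Wavefield conditioning applied ahead of reconstruction: directional
# filtering, wavenumber band-pass, DC removal, depth averaging.

# raised-cosine half-plane mask over the (kx, f) grid of a 2D DFT.
# idx_x / idx_t are signed DFT bin indices; keep the quadrants where
# sign(f) * sign(kx) == s (s = -1 keeps left-to-right travel for
# exp(i(2 pi f t - k x))), with a ramp of `width` bins across kx = 0 and a
# half/half split of the kx = 0 column and f = 0 row.
halfplane_mask <- function(idx_x, idx_t, s, width = 3, share_ridge = TRUE) {
  ramp <- if (share_ridge) {
    # raised cosine crossing 0.5 at kx = 0; the two directions sum to 1
    function(a) ifelse(a <= -width, 1,
                       ifelse(a >= width, 0,
                              0.5 * (1 - sin(pi * a / (2 * width)))))
  } else {
    # roll to 0 at kx = 0: the near-ridge band is excluded from both
    # directions (non-propagating energy carries no direction information)
    function(a) ifelse(a <= -width, 1,
                       ifelse(a >= 0, 0,
                              0.5 * (1 + cos(pi * (a + width) / width))))
  }
  m <- outer(idx_x, idx_t, function(ix, it) {
    a <- -s * sign(it) * ix                   # keep (ramp -> 1) where a < 0
    v <- ramp(a)
    v[it == 0] <- if (share_ridge) 0.5 else 0
    v
  })
  m
}

# symmetric (reflect) padding amount along one axis
pad_reflect <- function(mat, n) {
  if (n == 0) return(mat)
  top <- mat[pmin(nrow(mat), n:1), , drop = FALSE]
  bot <- mat[nrow(mat) - 0:(n - 1), , drop = FALSE]
  rbind(top, mat, bot)
}

#' Directional filtering of a shear wavefield
#'
#' Restricts, per depth row, the 2D `(x, t)` Fourier spectrum to the
#' half-plane consistent with the requested travel direction, so that waves
#' from the left push (traveling left to right) can be separated from waves
#' from the right push. The `kx = 0` column is shared half/half between the
#' two directions and a raised-cosine ramp (default 3 bins) limits ringing,
#' so the left-to-right and right-to-left outputs sum back to the input.
#'
#' @param w A [wavefield()], at least 4 samples along x and t.
#' @param direction `"left_to_right"` or `"right_to_left"`.
#' @param ramp Width in wavenumber bins of the raised-cosine transition.
#' @param pad Fraction of symmetric (reflect) padding applied to the lateral
#'   axis before the transform (default 0.25); cropped afterwards.
#' @param share_ridge If `TRUE` (default) the `kx = 0` column is split
#'   half/half between the two directions, so the two outputs sum back to
#'   the input. If `FALSE` the near-ridge band (`+/- ramp` bins) is excluded
#'   from both directions: non-propagating near-field energy carries no
#'   direction information and would otherwise leak into both outputs.
#' @param equalize Flatten the lateral RMS profile before filtering and
#'   restore it afterwards (automatic gain control). Shear-wave amplitudes
#'   fall by orders of magnitude away from the push line; without
#'   equalization the filter-mask transition rings the strong near-push
#'   region across the quiet far field. The gain cancels exactly, so a
#'   laterally uniform wave is unaffected.
#' @return A [wavefield()] of the same shape.
#' @export
directional_filter <- function(w, direction = c("left_to_right",
                                                "right_to_left"),
                               ramp = 3, pad = 0.25, share_ridge = TRUE,
                               equalize = TRUE) {
  stopifnot_wavefield(w)
  direction <- match.arg(direction)
  d <- dim(w$v)
  if (d[2] < 4L || d[3] < 4L)
    stop("need at least 4 samples along x and t", call. = FALSE)
  s <- if (direction == "left_to_right") -1 else 1
  npad <- round(pad * d[2])
  nx <- d[2] + 2L * npad
  idx_x <- signed_bins(nx)
  idx_t <- signed_bins(d[3])
  mask <- halfplane_mask(idx_x, idx_t, s, ramp, share_ridge)
  out <- w
  for (iz in seq_len(d[1])) {
    m <- w$v[iz, , ]
    g <- rep(1, d[2])
    if (equalize) {
      # lateral gain control: flatten the column RMS so the near-push
      # amplitude spike cannot ring across the row through the mask edges;
      # the gain is undone after filtering
      rms <- sqrt(rowMeans(m^2))
      floor_ <- 1e-6 * max(rms)
      if (max(rms) > 0) {
        g <- 1 / pmax(rms, floor_)
        m <- m * g
      }
    }
    m <- pad_reflect(m, npad)
    spec <- stats::fft(m) * mask
    res <- Re(stats::fft(spec, inverse = TRUE)) / length(spec)
    out$v[iz, , ] <- res[npad + seq_len(d[2]), , drop = FALSE] / g
  }
  out
}

signed_bins <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

# physical DFT frequency axis (cycles per unit) for spacing d
fft_freqs <- function(n, d) signed_bins(n) / (n * d)

# first-order Butterworth band-pass magnitude response on wavenumber
# magnitude k, band [klo, khi] (rad/m)
butterworth_bp_gain <- function(k, klo, khi) {
  k0sq <- klo * khi
  bw <- khi - klo
  num <- bw * k
  sqrt(num^2 / ((k0sq - k^2)^2 + num^2))
}

#' Wavenumber band-pass filter (k-filter)
#'
#' Applies, for each temporal-frequency frame of the 3D Fourier transform, a
#' first-order Butterworth band-pass on the spatial wavenumber magnitude
#' `sqrt(kz^2 + kx^2)`. The pass band is derived from a velocity band
#' `V0 +/- dV`: at temporal frequency `f` the retained wavenumbers are
#' `2 pi f / (V0 + dV) <= |k| <= 2 pi f / (V0 - dV)`, centered on the nominal
#' wavenumber of the shear-wave mode.
#'
#' @param w A [wavefield()].
#' @param v0 Center velocity of the band, m/s.
#' @param dv Velocity half-band, m/s (default 1); must satisfy `v0 - dv > 0`.
#' @param pad Fraction of symmetric padding per spatial axis (default 0.25).
#' @return A [wavefield()] of the same shape.
#' @export
k_bandpass <- function(w, v0, dv = 1, pad = 0.25) {
  stopifnot_wavefield(w)
  if (!is.numeric(v0) || v0 - dv <= 0)
    stop("invalid k-filter band: need v0 - dv > 0", call. = FALSE)
  d <- dim(w$v)
  npz <- round(pad * d[1]); npx <- round(pad * d[2])
  nz <- d[1] + 2L * npz; nx <- d[2] + 2L * npx
  kz <- 2 * pi * fft_freqs(nz, w$dz)
  kx <- 2 * pi * fft_freqs(nx, w$dx)
  kmag <- sqrt(outer(kz^2, kx^2, `+`))
  ft <- abs(fft_freqs(d[3], w$dt))
  # pad spatial axes (reflect), FFT over t once, then filter frame by frame
  vp <- array(0, c(nz, nx, d[3]))
  for (it in seq_len(d[3])) {
    m <- pad_reflect(w$v[, , it], npz)
    vp[, , it] <- t(pad_reflect(t(m), npx))
  }
  dim(vp) <- c(nz * nx, d[3])
  vf <- t(stats::mvfft(t(vp)))                # FFT along t
  dim(vf) <- c(nz, nx, d[3])
  for (it in seq_len(d[3])) {
    f <- ft[it]
    gain <- if (f == 0) matrix(0, nz, nx) else
      butterworth_bp_gain(kmag, 2 * pi * f / (v0 + dv), 2 * pi * f / (v0 - dv))
    vf[, , it] <- stats::fft(stats::fft(vf[, , it]) * gain,
                             inverse = TRUE) / (nz * nx)
  }
  dim(vf) <- c(nz * nx, d[3])
  vt <- Re(t(stats::mvfft(t(vf), inverse = TRUE))) / d[3]
  dim(vt) <- c(nz, nx, d[3])
  out <- w
  out$v <- vt[npz + seq_len(d[1]), npx + seq_len(d[2]), , drop = FALSE]
  out
}

#' Remove the temporal DC component of every trace
#'
#' Subtracts from each `(z, x)` trace its temporal mean, so the time average
#' of every pixel is zero.
#'
#' @param w A [wavefield()].
#' @return A [wavefield()] of the same shape.
#' @export
remove_dc <- function(w) {
  stopifnot_wavefield(w)
  d <- dim(w$v)
  m <- w$v
  dim(m) <- c(d[1] * d[2], d[3])
  m <- m - rowMeans(m)
  dim(m) <- d
  w$v <- m
  w
}

#' Average a wavefield over a depth span
#'
#' Arithmetic mean of the particle velocity over the depth rows covered by
#' `center_z +/- span/2`, e.g. 1.69 mm centered at the focal depth, yielding
#' the lateral-time field used by the 1D dispersion estimators.
#'
#' @param w A [wavefield()].
#' @param center_z Center depth in m.
#' @param span Full depth span in m; a span smaller than `dz` extracts the
#'   single nearest row.
#' @return A matrix `v(x, t)` with attributes `dx`, `dt`, `x0`.
#' @export
depth_average <- function(w, center_z, span = 1.69e-3) {
  stopifnot_wavefield(w)
  z <- wf_z(w)
  if (center_z - span / 2 < min(z) - w$dz / 2 ||
      center_z + span / 2 > max(z) + w$dz / 2)
    stop("depth span outside the grid", call. = FALSE)
  rows <- which(z >= center_z - span / 2 & z <= center_z + span / 2)
  if (length(rows) == 0L) rows <- which.min(abs(z - center_z))
  out <- apply(w$v[rows, , , drop = FALSE], c(2, 3), mean)
  attr(out, "dx") <- w$dx
  attr(out, "dt") <- w$dt
  attr(out, "x0") <- w$x0
  out
}
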