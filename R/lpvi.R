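# Local phase velocity imaging (LPVI): temporal Fourier transform, then a
# short-space 2D spatial FFT per window of the complex frequency-domain field,
# with the dominant local wavenumber giving cph = 2 pi f0 / |k|. Serves as the
# baseline the slant-steered reconstruction is compared against.

#' Temporal Fourier coefficient field at one frequency
#'
#' Transforms every `(z, x)` trace to the frequency domain (zero-padded to
#' twice the record length for finer frequency placement) and returns the
#' complex coefficient at the bin nearest `f0`.
#'
#' @param w A [wavefield()].
#' @param f0 Frequency in Hz; at most the Nyquist frequency.
#' @param pad_t Temporal zero-padding factor (default 2).
#' @return Complex matrix `(nz, nx)` with attributes `f_actual` (the bin
#'   frequency used) and `bin`.
#' @export
temporal_spectrum <- function(w, f0, pad_t = 2) {
  stopifnot_wavefield(w)
  if (length(f0) != 1L || !is.finite(f0) || f0 <= 0 || f0 > nyquist(w))
    stop(sprintf("'f0' must lie in (0, %g] Hz", nyquist(w)), call. = FALSE)
  d <- dim(w$v)
  nfft <- ceiling(pad_t) * d[3]
  fax <- (0:(nfft - 1)) / (nfft * w$dt)
  bin <- which.min(abs(fax[seq_len(nfft %/% 2 + 1)] - f0))
  m <- w$v
  dim(m) <- c(d[1] * d[2], d[3])
  m <- cbind(m, matrix(0, d[1] * d[2], nfft - d[3]))
  Vf <- stats::mvfft(t(m))[bin, ] * w$dt
  V <- matrix(Vf, d[1], d[2])
  attr(V, "f_actual") <- fax[bin]
  attr(V, "bin") <- bin
  V
}

# Butterworth k-filter applied to a single complex frequency frame
k_bandpass_frame <- function(V, dz, dx, f0, v0, dv) {
  if (v0 - dv <= 0) stop("invalid k-filter band: need v0 - dv > 0",
                         call. = FALSE)
  d <- dim(V)
  kz <- 2 * pi * fft_freqs(d[1], dz)
  kx <- 2 * pi * fft_freqs(d[2], dx)
  kmag <- sqrt(outer(kz^2, kx^2, `+`))
  gain <- butterworth_bp_gain(kmag, 2 * pi * f0 / (v0 + dv),
                              2 * pi * f0 / (v0 - dv))
  stats::fft(stats::fft(V) * gain, inverse = TRUE) / length(V)
}

#' LPVI 2D phase-velocity reconstruction
#'
#' Baseline local phase velocity imaging: the wavefield is directionally
#' filtered, transformed to the temporal-frequency domain, optionally
#' k-filtered (first-order Butterworth band-pass around the nominal
#' wavenumber derived from a velocity band `v0 +/- dv`), and a sliding
#' Tukey-tapered window with a zero-padded 2D spatial FFT yields the dominant
#' local wavenumber per window. Assembly (stride, masking, direction
#' averaging) is identical to [useweb()] for comparability.
#'
#' @inheritParams useweb
#' @param kfilter `NULL` (no k-filter) or a list with `v0` (center velocity,
#'   m/s) and `dv` (half-band, m/s, default 1).
#' @return An `swe_pvmap` (method `"lpvi"`).
#' @export
lpvi <- function(w, f0, window = 4.47e-3, taper = 0.25, stride = 1L,
                 directions = c("both", "left_to_right", "right_to_left"),
                 prefilter = TRUE, share_ridge = TRUE, kfilter = NULL,
                 pad = c(2, 8), search_band = c(0.5, 10), quality_floor = 3,
                 dyn_floor = 0.01, region = NULL, push_x = NULL,
                 push_margin = 1.5e-3) {
  stopifnot_wavefield(w)
  directions <- match.arg(directions)
  d <- dim(w$v)
  window <- rep(window, length.out = 2L)
  nwz <- 2L * floor(window[1] / (2 * w$dz)) + 1L
  nwx <- 2L * floor(window[2] / (2 * w$dx)) + 1L
  if (nwz > d[1] || nwx > d[2])
    stop("window larger than the field of view", call. = FALSE)
  pz <- 2^ceiling(log2(pad[1] * nwz))
  px <- 2^ceiling(log2(pad[2] * nwx))
  tp <- tukey2(nwz, nwx, taper)
  hz <- (nwz - 1L) %/% 2L; hx <- (nwx - 1L) %/% 2L
  czs <- center_lattice(d[1], hz, stride, w$z0, w$dz, region$zlim)
  cxs <- center_lattice(d[2], hx, stride, w$x0, w$dx, region$xlim)
  cxs <- drop_push_centers(cxs, w$x0, w$dx, hx, push_x, push_margin)
  if (length(czs) == 0L || length(cxs) == 0L)
    stop("no admissible window centers in the requested region",
         call. = FALSE)
  kz_ax <- 2 * pi * fft_freqs(pz, w$dz)
  kx_ax <- 2 * pi * fft_freqs(px, w$dx)
  dirs <- if (directions == "both")
    c("left_to_right", "right_to_left") else directions
  acc_num <- matrix(0, d[1], d[2]); acc_den <- matrix(0, d[1], d[2])
  qual <- matrix(0, d[1], d[2]); covered <- matrix(FALSE, d[1], d[2])
  for (dir in dirs) {
    wd <- if (prefilter)
      directional_filter(w, dir, share_ridge = share_ridge) else w
    V <- temporal_spectrum(wd, f0)
    if (!is.null(kfilter))
      V <- k_bandpass_frame(V, w$dz, w$dx, f0, kfilter$v0,
                            kfilter$dv %||% 1)
    dir_c <- dir_pk <- dir_q <- matrix(NA_real_, d[1], d[2])
    for (icz in czs) {
      zidx <- (icz - hz):(icz + hz)
      for (icx in cxs) {
        xidx <- (icx - hx):(icx + hx)
        patch <- V[zidx, xidx] * tp
        spec <- spectral_amplitude(patch, w$dz, w$dx, pad = c(pz, px))
        pk <- pick_wavenumber(spec, f0, search_band, refine = TRUE)
        covered[icz, icx] <- TRUE
        dir_c[icz, icx] <- pk$c
        dir_pk[icz, icx] <- pk$peak
        dir_q[icz, icx] <- pk$quality
      }
    }
    pk_ref <- suppressWarnings(max(dir_pk, na.rm = TRUE))
    ok <- is.finite(dir_q) & dir_q >= quality_floor &
      is.finite(dir_pk) & dir_pk >= dyn_floor * pk_ref
    qual <- pmax(qual, ifelse(is.finite(dir_q), dir_q, 0))
    # per pixel, keep the travel direction with the stronger spectral peak:
    # when one direction's wave is attenuation-dead or contaminated by the
    # opposite push's near field, the surviving direction decides alone
    take <- ok & dir_pk > acc_den
    acc_num[take] <- dir_pk[take] * dir_c[take]
    acc_den[take] <- dir_pk[take]
  }
  cph <- ifelse(acc_den > 0, acc_num / acc_den, NA_real_)
  structure(list(cph = cph, mask = acc_den > 0,
                 quality = ifelse(covered, qual, NA), f0 = f0, band = NULL,
                 window = window, stride = stride, dz = w$dz, dx = w$dx,
                 z0 = w$z0, x0 = w$x0, method = "lpvi",
                 search_band = search_band, call = match.call()),
            class = "swe_pvmap")
}
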