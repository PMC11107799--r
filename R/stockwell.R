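# Generalized Stockwell (S-) transform. The S-transform of a signal v(t) at
# frequency f is the convolution of v(t) exp(-i 2 pi f t) with a Gaussian
# window whose temporal standard deviation is sqrt(beta)/f, so the width of
# the analysis window scales with the period. Phase is referenced to the time
# origin: a pure tone at f yields a (tau-) constant complex value at the
# matching voice, which is what makes the slant-slice machinery downstream
# work on demodulated wavefields.

st_window_amp <- function(f, beta, normalization) {
  switch(normalization,
    unit_area = abs(f) / sqrt(2 * pi * beta),
    printed   = abs(f) / (2 * pi * beta),
    stop("unknown normalization: ", normalization))
}

# sampled Gaussian window arranged circularly on a length-m grid
st_window_circ <- function(m, dt, f, beta, normalization) {
  lag <- signed_bins(m) * dt
  st_window_amp(f, beta, normalization) * exp(-f^2 * lag^2 / (2 * beta))
}

#' Generalized S-transform of a uniformly sampled signal
#'
#' Computes the time-frequency decomposition
#' `S(tau, f) = sum_t v(t) W(tau - t, f) exp(-i 2 pi f t) dt`, where `W` is a
#' Gaussian window of temporal standard deviation `sqrt(beta)/f`. Larger
#' `beta` widens the window in time (better frequency resolution); `beta = 1`
#' recovers the classical S-transform. The evaluation is an exact linear
#' convolution performed with zero-padded FFTs, so it matches the literal
#' discrete sum to machine precision at every `tau` on the input grid.
#'
#' @param x Real or complex signal vector, uniformly sampled.
#' @param dt Sample interval in s.
#' @param f Frequency grid in Hz, strictly positive elementwise (the Gaussian
#'   window degenerates at `f = 0`).
#' @param beta Window scaling factor, > 0.
#' @param normalization `"unit_area"` (default; the window integrates to one
#'   and the time marginal of `S` recovers the Fourier coefficient at `f`) or
#'   `"printed"` (prefactor `|f| / (2 pi beta)`). The two differ by a constant
#'   factor at fixed `beta`, so spectral peak locations are identical.
#' @return Complex matrix with `length(x)` rows (tau, on the input time grid)
#'   and `length(f)` columns.
#' @examples
#' x <- sin(2 * pi * 500 * (0:255) / 4167)
#' S <- s_transform_1d(x, 1 / 4167, c(300, 500, 700))
#' which.max(abs(S[128, ]))  # 2: the 500 Hz voice dominates
#' @export
s_transform_1d <- function(x, dt, f, beta = 1,
                           normalization = c("unit_area", "printed")) {
  normalization <- match.arg(normalization)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be strictly positive (the window degenerates at f = 0)",
         call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  n <- length(x)
  out <- matrix(0i, n, length(f))
  for (j in seq_along(f))
    out[, j] <- st_voice(matrix(x, ncol = 1), dt, f[j], beta, normalization)
  out
}

# one voice (single frequency) of the S-transform for a bank of traces given
# as columns of `tr` (n x m); returns an n x m complex matrix
st_voice <- function(tr, dt, f0, beta, normalization) {
  n <- nrow(tr)
  m2 <- 2L * n
  tvec <- (0:(n - 1)) * dt
  ph <- exp(-2i * pi * f0 * tvec)
  p <- tr * ph                                 # demodulate
  ppad <- rbind(p, matrix(0i, n, ncol(tr)))
  what <- stats::fft(st_window_circ(m2, dt, f0, beta, normalization))
  conv <- stats::mvfft(stats::mvfft(ppad) * what, inverse = TRUE) / m2
  conv[seq_len(n), , drop = FALSE] * dt
}

#' S-transform decomposition of a wavefield at one frequency
#'
#' Applies [s_transform_1d()] to every `(z, x)` trace of the wavefield and
#' keeps the complex voice at the selected frequency, producing the complex
#' volume `H(z, x, tau)` that the slant-slice reconstruction consumes.
#' Evaluation is batched per depth row but is exactly the per-trace transform.
#'
#' @param w A [wavefield()].
#' @param f0 Analysis frequency in Hz; must not exceed the Nyquist frequency
#'   `1 / (2 dt)`.
#' @param beta,normalization Passed to [s_transform_1d()].
#' @param tau_len Optional number of leading time samples of the `tau` axis to
#'   retain (the slant slices only ever address
#'   `tau <= window width / u_min`); `NULL` keeps the full time axis.
#' @return An object of class `swe_spectral_volume`: list with complex array
#'   `H` `(nz, nx, ntau)`, `f0`, `beta`, and the grid metadata of `w`.
#' @export
decompose <- function(w, f0, beta = 1,
                      normalization = c("unit_area", "printed"),
                      tau_len = NULL) {
  stopifnot_wavefield(w)
  normalization <- match.arg(normalization)
  if (length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("'f0' must be a positive scalar frequency", call. = FALSE)
  if (f0 > nyquist(w))
    stop(sprintf("f0 = %g Hz exceeds the Nyquist limit %g Hz", f0,
                 nyquist(w)), call. = FALSE)
  d <- dim(w$v)
  ntau <- if (is.null(tau_len)) d[3] else min(d[3], as.integer(tau_len))
  H <- array(0i, c(d[1], d[2], ntau))
  for (iz in seq_len(d[1])) {
    tr <- t(matrix(w$v[iz, , ], nrow = d[2]))  # nt x nx
    H[iz, , ] <- t(st_voice(tr, w$dt, f0, beta, normalization)[seq_len(ntau), ,
                                                               drop = FALSE])
  }
  structure(list(H = H, f0 = f0, beta = beta, dz = w$dz, dx = w$dx,
                 dt = w$dt, z0 = w$z0, x0 = w$x0, nt = d[3]),
            class = "swe_spectral_volume")
}

#' @export
print.swe_spectral_volume <- function(x, ...) {
  d <- dim(x$H)
  cat(sprintf("<swe_spectral_volume> f0 = %g Hz, %d x %d x %d (z, x, tau)\n",
              x$f0, d[1], d[2], d[3]))
  invisible(x)
}
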