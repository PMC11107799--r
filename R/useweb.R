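# USEWEB reconstruction core: spatial windowing of the S-transform volume,
# slant-phase slicing over a series of steering group velocities, 4D spectral
# amplitude, wavenumber peak extraction, and assembly of the 2D phase-velocity
# map  cph(z, x) = 2 pi f0 / |k|.

#' @useDynLib useweb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 1D cosine-tapered (Tukey) window; ratio = 0 is rectangular, 1 is Hann
tukey1 <- function(n, ratio) {
  if (ratio < 0 || ratio > 1) stop("taper ratio must be in [0, 1]",
                                   call. = FALSE)
  if (n == 1L) return(1)
  t <- (0:(n - 1)) / (n - 1)
  w <- rep(1, n)
  if (ratio > 0) {
    e <- ratio / 2
    lo <- t < e
    hi <- t > 1 - e
    w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / e - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1) / e + 1)))
  }
  w
}

tukey2 <- function(nz, nx, ratio) outer(tukey1(nz, ratio), tukey1(nx, ratio))

#' Steering group-velocity series
#'
#' The series `u_m = xbar_max / (t_max - m * dt)`, `m = 0, 1, 2, ...`,
#' truncated before the denominator reaches zero, clamped to
#' `[u_min, u_max]` and, if necessary, decimated evenly to at most `n_max`
#' values. `xbar_max` is the maximum lateral distance within the analysis
#' window and `t_max` the maximum recorded time, so the series sweeps the
#' apparent (origin-referenced) group velocities at the native time sampling.
#'
#' @param xbar_max Window width in m.
#' @param t_max Record length in s.
#' @param dt Time sampling in s.
#' @param u_min,u_max Clamp in m/s.
#' @param n_max Maximum number of retained values.
#' @return Increasing numeric vector of steering velocities, m/s.
#' @export
steering_series <- function(xbar_max, t_max, dt, u_min = 0.2, u_max = 15,
                            n_max = 48L) {
  if (xbar_max <= 0 || t_max <= 0 || dt <= 0)
    stop("xbar_max, t_max, dt must be positive", call. = FALSE)
  m <- 0:floor((t_max - dt / 2) / dt)
  den <- t_max - m * dt
  u <- xbar_max / den[den > 0]
  u <- u[u >= u_min & u <= u_max]
  if (length(u) == 0L)
    stop("empty steering series for the given clamp", call. = FALSE)
  if (length(u) > n_max)
    u <- u[unique(round(seq(1, length(u), length.out = n_max)))]
  sort(unique(u))
}

#' Extract a tapered spatial window from a spectral volume
#'
#' Multiplies the `H(z, x, tau)` volume by a 2D Tukey taper supported on a
#' rectangular window, constant along `tau`.
#'
#' @param H An `swe_spectral_volume` from [decompose()].
#' @param center Length-2 numeric `(z, x)` window center in m.
#' @param width Window size in m; scalar or `c(height, width)`.
#' @param taper Tukey taper ratio in `[0, 1]`.
#' @param policy `"strict"` errors if the window exceeds the field of view;
#'   `"trim"` keeps the intersection.
#' @return List with the complex windowed array `Hw` `(nz, nx, ntau)`, the row
#'   and column indices used, and the taper matrix.
#' @export
extract_window <- function(H, center, width, taper = 0.25,
                           policy = c("strict", "trim")) {
  policy <- match.arg(policy)
  if (!inherits(H, "swe_spectral_volume"))
    stop("'H' must come from decompose()", call. = FALSE)
  width <- rep(width, length.out = 2L)
  d <- dim(H$H)
  hz <- floor(width[1] / (2 * H$dz)); hx <- floor(width[2] / (2 * H$dx))
  icz <- round((center[1] - H$z0) / H$dz) + 1L
  icx <- round((center[2] - H$x0) / H$dx) + 1L
  zidx <- (icz - hz):(icz + hz)
  xidx <- (icx - hx):(icx + hx)
  if (policy == "strict") {
    if (any(zidx < 1L) || any(zidx > d[1]) || any(xidx < 1L) ||
        any(xidx > d[2]))
      stop("window exceeds the field of view", call. = FALSE)
  } else {
    zidx <- zidx[zidx >= 1L & zidx <= d[1]]
    xidx <- xidx[xidx >= 1L & xidx <= d[2]]
    if (length(zidx) == 0L || length(xidx) == 0L)
      stop("window does not intersect the field of view", call. = FALSE)
  }
  tp <- tukey2(length(zidx), length(xidx), taper)
  Hw <- H$H[zidx, xidx, , drop = FALSE] *
    array(rep(tp, dim(H$H)[3]), c(length(zidx), length(xidx), dim(H$H)[3]))
  list(Hw = Hw, zidx = zidx, xidx = xidx, taper = tp)
}

#' Slant-phase slice of a windowed spectral volume
#'
#' Evaluates `SF(z, x) = Hw(z, x, tau = xbar / u)`: a constant-time slant
#' slice at steering group velocity `u`, with `xbar` measured from the
#' wave-arrival side of the window. `tau` between time samples is linearly
#' interpolated; `tau` beyond the record contributes zero.
#'
#' @param Hw Complex array `(nz, nx, ntau)` (e.g. `extract_window()$Hw`).
#' @param u Steering group velocity in m/s, > 0.
#' @param dx Lateral sample spacing in m.
#' @param dt Time sampling in s.
#' @param origin `"left"` if the wave enters the window from the left (travels
#'   left to right), `"right"` otherwise.
#' @return Complex matrix `(nz, nx)`.
#' @export
slant_slice <- function(Hw, u, dx, dt, origin = c("left", "right")) {
  origin <- match.arg(origin)
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u <= 0)
    stop("'u' must be a positive scalar", call. = FALSE)
  d <- dim(Hw)
  xbar <- (0:(d[2] - 1)) * dx
  if (origin == "right") xbar <- rev(xbar)
  SF <- matrix(0i, d[1], d[2])
  idx <- xbar / u / dt
  i0 <- floor(idx)
  wfrac <- idx - i0
  for (ix in seq_len(d[2])) {
    if (i0[ix] < 0 || i0[ix] >= d[3]) next
    col <- Hw[, ix, i0[ix] + 1L] * (1 - wfrac[ix])
    if (i0[ix] + 2L <= d[3]) col <- col + Hw[, ix, i0[ix] + 2L] * wfrac[ix]
    SF[, ix] <- col
  }
  SF
}

#' 2D spatial spectral amplitude of a slant-phase slice
#'
#' Magnitude of the zero-padded 2D spatial Fourier transform of `SF`,
#' approximating the continuous transform (amplitudes scaled by `dz * dx`).
#' Wavenumber axes are returned in rad/m, consistent with
#' `cph = 2 pi f0 / |k|`.
#'
#' @param SF Complex matrix `(nz, nx)`.
#' @param dz,dx Sample spacings in m.
#' @param pad Length-2 integer FFT sizes `(nkz, nkx)`; must be at least the
#'   window size. Defaults to 4x the window size rounded up to a power of 2.
#' @return List of class `swe_kspec` with amplitude matrix `K` (>= 0) and
#'   axes `kz`, `kx` in rad/m (DFT bin order).
#' @export
spectral_amplitude <- function(SF, dz, dx, pad = NULL) {
  d <- dim(SF)
  if (is.null(pad)) pad <- 2^ceiling(log2(4 * d))
  pad <- as.integer(rep(pad, length.out = 2L))
  if (any(pad < d)) stop("'pad' smaller than the window", call. = FALSE)
  buf <- matrix(0i, pad[1], pad[2])
  buf[seq_len(d[1]), seq_len(d[2])] <- SF
  K <- abs(stats::fft(buf)) * dz * dx
  structure(list(K = K, kz = 2 * pi * fft_freqs(pad[1], dz),
                 kx = 2 * pi * fft_freqs(pad[2], dx)),
            class = "swe_kspec")
}

#' Maximum spectral amplitude across steering velocities
#'
#' Element-wise maximum of a stack of spectral-amplitude surfaces, one per
#' steering group velocity: the wavenumber spectrum `K(kz, kx, f0)` whose
#' peak encodes the local wavenumber.
#'
#' @param specs Non-empty list of `swe_kspec` objects on the same grid.
#' @return A single `swe_kspec`.
#' @export
max_over_steering <- function(specs) {
  if (length(specs) == 0L) stop("empty steering stack", call. = FALSE)
  out <- specs[[1]]
  for (s in specs[-1]) out$K <- pmax(out$K, s$K)
  out
}

#' Local wavenumber peak of a wavenumber spectrum
#'
#' Restricts the spectrum to the annulus of wavenumber magnitudes compatible
#' with a phase-velocity search band, takes the argmax (deterministic
#' tie-break: smallest `|k|`, then smallest `kx`), and optionally refines the
#' peak by independent 3-point parabolic interpolation along `kz` and `kx`.
#'
#' @param spec An `swe_kspec` from [spectral_amplitude()] or
#'   [max_over_steering()].
#' @param f0 Analysis frequency in Hz.
#' @param search_band Velocity bounds `c(c_min, c_max)` in m/s; the annulus is
#'   `2 pi f0 / c_max <= |k| <= 2 pi f0 / c_min`.
#' @param refine Logical; parabolic sub-bin refinement.
#' @return List with `kz`, `kx`, `kmag` (rad/m), `c` (`2 pi f0 / kmag`, m/s),
#'   `peak` (amplitude) and `quality` (peak over the median amplitude inside
#'   the annulus).
#' @export
pick_wavenumber <- function(spec, f0, search_band = c(0.5, 10),
                            refine = TRUE) {
  if (!inherits(spec, "swe_kspec")) stop("need an swe_kspec", call. = FALSE)
  kmag <- sqrt(outer(spec$kz^2, spec$kx^2, `+`))
  klo <- 2 * pi * f0 / search_band[2]
  khi <- 2 * pi * f0 / search_band[1]
  sel <- kmag >= klo & kmag <= khi
  if (!any(sel))
    stop("empty search annulus: wavenumber grid too coarse for the band",
         call. = FALSE)
  vals <- spec$K[sel]
  peak <- max(vals)
  cand <- which(sel & spec$K >= peak, arr.ind = TRUE)
  if (nrow(cand) > 1L) {                      # tie-break
    km <- kmag[cand]
    cand <- cand[order(km, spec$kx[cand[, 2]]), , drop = FALSE]
  }
  iz <- cand[1, 1]; ix <- cand[1, 2]
  kzv <- spec$kz[iz]; kxv <- spec$kx[ix]
  if (refine) {
    kzv <- kzv + parab_offset(spec$K, iz, ix, 1) * bin_step(spec$kz)
    kxv <- kxv + parab_offset(spec$K, iz, ix, 2) * bin_step(spec$kx)
  }
  km <- sqrt(kzv^2 + kxv^2)
  km <- max(klo, min(khi, km))                # refinement stays in the annulus
  list(kz = kzv, kx = kxv, kmag = km, c = 2 * pi * f0 / km, peak = peak,
       quality = peak / stats::median(vals))
}

bin_step <- function(ax) if (length(ax) > 1) abs(ax[2] - ax[1]) else 0

# quadratic vertex offset (in bins) along one axis of K: least-squares
# parabola over +/- nb circular neighbors of the peak, which is much less
# noise-sensitive than a 3-point fit when the spectral lobe spans many padded
# bins; falls back to 0 when degenerate, clamped to one bin
parab_offset <- function(K, iz, ix, axis, nb = 3L) {
  n <- dim(K)[axis]
  s <- (-nb):nb
  i <- ((if (axis == 1) iz else ix) - 1L + s) %% n + 1L
  y <- if (axis == 1) K[i, ix] else K[iz, i]
  a <- stats::coef(stats::lm.fit(cbind(1, s, s^2), y))
  if (!is.finite(a[3]) || a[3] >= 0) return(0)
  off <- -a[2] / (2 * a[3])
  max(-1, min(1, off))
}

# reference R implementation of the per-window steering-max spectrum,
# built from the exported operations; numerically identical to the C++ kernel
steer_max_spectrum_r <- function(Hw, taper, xbar, u, dt, pz, px, dz, dx) {
  ntau <- dim(Hw)[3]
  Hwt <- Hw * array(rep(taper, ntau), dim(Hw))
  specs <- lapply(u, function(uu) {
    SF <- slant_slice(Hwt, uu, xbar[2] - xbar[1], dt, origin = "left")
    spectral_amplitude(SF, dz, dx, pad = c(pz, px))
  })
  max_over_steering(specs)$K
}

#' USEWEB 2D phase-velocity reconstruction
#'
#' Reconstructs the 2D shear-wave phase-velocity map of a wavefield at a
#' frequency `f0` (or band): the wavefield is directionally filtered, the
#' generalized S-transform extracts the complex field `H(z, x, tau)` at `f0`,
#' a sliding Tukey-tapered window is slant-sliced over a series of steering
#' group velocities, the 2D spatial FFT amplitudes are maximized over
#' steering, and the wavenumber peak of each window gives
#' `cph = 2 pi f0 / |k|` at the window center. Maps reconstructed from the
#' left-to-right and right-to-left traveling waves are combined per pixel by
#' keeping the direction with the stronger spectral peak.
#'
#' @param w A [wavefield()].
#' @param f0 Analysis frequency in Hz (band center when `band` is given).
#' @param band Optional vector of frequencies; their wavenumber spectra are
#'   averaged before peak picking (band policy), with `f0` used in the
#'   velocity conversion.
#' @param window Window size in m, scalar or `c(height, width)` (default
#'   4.47 mm square).
#' @param taper Tukey taper ratio of the window (default 0.25).
#' @param stride Samples between window centers (default 1).
#' @param beta,normalization S-transform parameters, see [s_transform_1d()].
#'   The imaging default `beta = 9` trades temporal resolution (ample, since
#'   records are long) for the tighter voice bandwidth needed to keep
#'   frequency-dependent attenuation from skewing the analyzed band.
#' @param directions `"both"` (default), or a single travel direction.
#' @param prefilter Apply [directional_filter()] before reconstruction
#'   (default `TRUE`; set to `FALSE` for single-direction data already
#'   filtered).
#' @param share_ridge Passed to [directional_filter()]; `FALSE` excludes the
#'   non-propagating near-ridge band from both directions.
#' @param u_min,u_max,n_u Steering-series clamp and size, see
#'   [steering_series()].
#' @param pad Zero-padding factors `(z, x)` of the window FFT (each axis is
#'   padded to the next power of two of `pad * window samples`).
#' @param search_band Velocity search band `c(c_min, c_max)` in m/s.
#' @param quality_floor Windows whose spectral peak is below
#'   `quality_floor` times the median annulus amplitude are masked.
#' @param dyn_floor Dynamic-range mask: per direction, windows whose spectral
#'   peak is below `dyn_floor` times the strongest window peak (default 0.01,
#'   i.e. -40 dB) are masked; attenuation-dead regions then come out masked
#'   instead of carrying noise-driven estimates.
#' @param region Optional list with `zlim` and/or `xlim` (m) restricting the
#'   window-center lattice (e.g. to a region of interest).
#' @param push_x Optional vector of push-line lateral positions in m. When
#'   given, windows whose footprint comes within `push_margin` of a push line
#'   are excluded: the near field there mixes both travel directions and the
#'   local-plane-wave assumption fails.
#' @param push_margin Exclusion margin around push lines, m (default 1.5 mm).
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation built from the exported operations).
#' @return An object of class `swe_pvmap`: phase-velocity matrix `cph`
#'   `(nz, nx)` (NA where masked or not reconstructed), `mask`, `quality`,
#'   `f0`, grid metadata and the reconstruction settings.
#' @examples
#' \donttest{
#' sim <- synthesize_wavefield(swe_scene(background = material_elastic(25e3),
#'                                       duration = 0.04))
#' pv <- useweb(sim$wavefield, f0 = 600, stride = 4,
#'              region = list(zlim = c(0.017, 0.023), xlim = c(0.017, 0.023)))
#' summary(pv)
#' }
#' @export
useweb <- function(w, f0, band = NULL, window = 4.47e-3, taper = 0.25,
                   stride = 1L, beta = 9,
                   normalization = c("unit_area", "printed"),
                   directions = c("both", "left_to_right", "right_to_left"),
                   prefilter = TRUE, share_ridge = TRUE,
                   u_min = 0.2, u_max = 15, n_u = 48L,
                   pad = c(2, 8), search_band = c(0.5, 10),
                   quality_floor = 3, dyn_floor = 0.01, region = NULL,
                   push_x = NULL, push_margin = 1.5e-3,
                   engine = c("cpp", "r")) {
  stopifnot_wavefield(w)
  normalization <- match.arg(normalization)
  directions <- match.arg(directions)
  engine <- match.arg(engine)
  freqs <- if (is.null(band)) f0 else band
  if (any(freqs > nyquist(w)))
    stop(sprintf("requested frequency exceeds the Nyquist limit %g Hz",
                 nyquist(w)), call. = FALSE)
  d <- dim(w$v)
  window <- rep(window, length.out = 2L)
  nwz <- 2L * floor(window[1] / (2 * w$dz)) + 1L
  nwx <- 2L * floor(window[2] / (2 * w$dx)) + 1L
  if (nwz > d[1] || nwx > d[2])
    stop("window larger than the field of view", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  pz <- 2^ceiling(log2(pad[1] * nwz))
  px <- 2^ceiling(log2(pad[2] * nwx))
  tp <- tukey2(nwz, nwx, taper)
  hz <- (nwz - 1L) %/% 2L; hx <- (nwx - 1L) %/% 2L
  xbar <- (0:(nwx - 1)) * w$dx
  u <- steering_series((nwx - 1) * w$dx, (d[3] - 1) * w$dt, w$dt,
                       u_min, u_max, n_u)
  tau_len <- min(d[3], ceiling((nwx - 1) * w$dx / (u_min * w$dt)) + 2L)

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
    flip <- dir == "right_to_left"
    if (flip) wd$v <- wd$v[, rev(seq_len(d[2])), , drop = FALSE]
    vols <- lapply(freqs, function(ff)
      decompose(wd, ff, beta, normalization, tau_len)$H)
    cxs_d <- if (flip) d[2] + 1L - rev(cxs) else cxs
    dir_c <- dir_pk <- dir_q <- matrix(NA_real_, d[1], d[2])
    for (icz in czs) {
      zidx <- (icz - hz):(icz + hz)
      for (icx in cxs_d) {
        xidx <- (icx - hx):(icx + hx)
        K <- 0
        for (H in vols) {
          Hw <- H[zidx, xidx, , drop = FALSE]
          K <- K + if (engine == "cpp")
            steer_max_spectrum_cpp(Hw, tp, xbar, u, w$dt, pz, px, w$dz, w$dx)
          else
            steer_max_spectrum_r(Hw, tp, xbar, u, w$dt, pz, px, w$dz, w$dx)
        }
        pk <- pick_wavenumber(structure(list(K = K / length(vols),
                                             kz = kz_ax, kx = kx_ax),
                                        class = "swe_kspec"),
                              f0, search_band, refine = TRUE)
        icx0 <- if (flip) d[2] + 1L - icx else icx
        covered[icz, icx0] <- TRUE
        dir_c[icz, icx0] <- pk$c
        dir_pk[icz, icx0] <- pk$peak
        dir_q[icz, icx0] <- pk$quality
      }
    }
    # dynamic-range mask: windows whose spectral peak is far below the
    # strongest window of this direction hold no usable signal
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
  mask <- acc_den > 0
  structure(list(cph = cph, mask = mask, quality = ifelse(covered, qual, NA),
                 f0 = f0, band = band, window = window, stride = stride,
                 dz = w$dz, dx = w$dx, z0 = w$z0, x0 = w$x0,
                 method = "useweb", search_band = search_band,
                 call = match.call()),
            class = "swe_pvmap")
}

# admissible window-center indices along one axis
center_lattice <- function(n, half, stride, orig, step, lim = NULL) {
  idx <- seq.int(half + 1L, n - half, by = stride)
  if (!is.null(lim)) {
    pos <- orig + (idx - 1L) * step
    idx <- idx[pos >= lim[1] & pos <= lim[2]]
  }
  idx
}

# drop window centers whose footprint comes within `margin` of a push line:
# the near field mixes both travel directions inseparably there
drop_push_centers <- function(cxs, x0, dx, hx, push_x, margin) {
  if (is.null(push_x) || length(cxs) == 0L) return(cxs)
  pos <- x0 + (cxs - 1L) * dx
  keep <- vapply(pos, function(p)
    all(push_x <= p - hx * dx - margin | push_x >= p + hx * dx + margin),
    logical(1))
  cxs[keep]
}
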