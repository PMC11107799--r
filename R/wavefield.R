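#' Spatiotemporal shear-wave particle-velocity container
#'
#' A `wavefield` holds a real 3D particle-velocity array `v` indexed
#' `(z, x, t)` (depth, lateral, time) on a regular grid, together with its
#' sample spacings and spatial origin. It is the universal input of every
#' reconstruction and preprocessing routine in the package.
#'
#' @param v Real 3D array, dimensions `(nz, nx, nt)`.
#' @param dz,dx Spatial spacings in m, strictly positive.
#' @param dt Temporal spacing in s, strictly positive.
#' @param z0,x0 Spatial origin (location of the first sample) in m.
#' @return An object of class `wavefield`.
#' @examples
#' w <- wavefield(array(0, c(4, 8, 16)), dz = 1e-4, dx = 1e-4, dt = 1e-4)
#' dim(w$v)
#' @export
wavefield <- function(v, dz, dx, dt, z0 = 0, x0 = 0) {
  if (!is.array(v) || length(dim(v)) != 3L || !is.numeric(v))
    stop("'v' must be a real 3D array (z, x, t)", call. = FALSE)
  for (nm in c("dz", "dx", "dt")) {
    s <- get(nm)
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
      stop("'", nm, "' must be a positive scalar", call. = FALSE)
  }
  structure(list(v = v, dz = dz, dx = dx, dt = dt, z0 = z0, x0 = x0),
            class = "wavefield")
}

stopifnot_wavefield <- function(w) {
  if (!inherits(w, "wavefield"))
    stop("expected a 'wavefield' object", call. = FALSE)
  invisible(w)
}

#' @export
print.wavefield <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<wavefield> %d x %d x %d (z, x, t)\n", d[1], d[2], d[3]))
  cat(sprintf("  dz = %.4g mm, dx = %.4g mm, dt = %.4g ms (fs = %.4g kHz)\n",
              1e3 * x$dz, 1e3 * x$dx, 1e3 * x$dt, 1e-3 / x$dt))
  cat(sprintf("  z: %.1f..%.1f mm, x: %.1f..%.1f mm, t: 0..%.1f ms\n",
              1e3 * x$z0, 1e3 * (x$z0 + (d[1] - 1) * x$dz),
              1e3 * x$x0, 1e3 * (x$x0 + (d[2] - 1) * x$dx),
              1e3 * (d[3] - 1) * x$dt))
  invisible(x)
}

# axis helpers ---------------------------------------------------------------

wf_z <- function(w) w$z0 + (seq_len(dim(w$v)[1]) - 1) * w$dz
wf_x <- function(w) w$x0 + (seq_len(dim(w$v)[2]) - 1) * w$dx
wf_t <- function(w) (seq_len(dim(w$v)[3]) - 1) * w$dt

#' Nyquist frequency of a wavefield's time axis
#'
#' @param w A [wavefield()].
#' @return `1 / (2 * dt)` in Hz.
#' @export
nyquist <- function(w) {
  stopifnot_wavefield(w)
  1 / (2 * w$dt)
}

#' @export
plot.wavefield <- function(x, t = NULL, ...) {
  it <- if (is.null(t)) which.max(apply(abs(x$v), 3, max)) else
    max(1L, min(dim(x$v)[3], round(t / x$dt) + 1L))
  frame <- x$v[, , it]
  graphics::image(1e3 * wf_x(x), 1e3 * wf_z(x), t(frame[rev(seq_len(nrow(frame))), ]),
                  col = grDevices::hcl.colors(64, "RdBu"),
                  xlab = "lateral x [mm]", ylab = "depth z [mm]",
                  main = sprintf("particle velocity, t = %.2f ms",
                                 1e3 * (it - 1) * x$dt), ...)
  invisible(x)
}

# container I/O ---------------------------------------------------------------

#' Read and write wavefield containers
#'
#' Wavefields (and simulator outputs carrying ground truth) are stored in the
#' package's native array container: a single-file serialized list with
#' entries `v`, `dz`, `dx`, `dt`, `z0`, `x0` plus optional `truth` and
#' `attrs` (seed, scene parameters).
#'
#' @param w A [wavefield()] or `swe_simulation` object.
#' @param path File path.
#' @param attrs Optional named list of metadata stored alongside the arrays.
#' @return `load_wavefield()` returns the stored object; `save_wavefield()`
#'   returns `path` invisibly.
#' @export
save_wavefield <- function(w, path, attrs = NULL) {
  if (inherits(w, "swe_simulation")) {
    obj <- list(v = w$wavefield$v, dz = w$wavefield$dz, dx = w$wavefield$dx,
                dt = w$wavefield$dt, z0 = w$wavefield$z0, x0 = w$wavefield$x0,
                truth = w$truth, attrs = attrs)
  } else {
    stopifnot_wavefield(w)
    obj <- list(v = w$v, dz = w$dz, dx = w$dx, dt = w$dt, z0 = w$z0,
                x0 = w$x0, truth = NULL, attrs = attrs)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_wavefield
#' @export
load_wavefield <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  w <- wavefield(obj$v, obj$dz, obj$dx, obj$dt, obj$z0 %||% 0, obj$x0 %||% 0)
  if (!is.null(obj$truth))
    return(structure(list(wavefield = w, truth = obj$truth,
                          attrs = obj$attrs), class = "swe_simulation"))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
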