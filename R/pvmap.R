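# Phase-velocity map container shared by the USEWEB and LPVI reconstructors.

#' @export
print.swe_pvmap <- function(x, ...) {
  d <- dim(x$cph)
  cat(sprintf("<swe_pvmap> %s, f0 = %g Hz, %d x %d px\n", x$method, x$f0,
              d[1], d[2]))
  nv <- sum(x$mask)
  cat(sprintf("  window %.2f x %.2f mm, stride %d; %d valid px (%.1f%%)\n",
              1e3 * x$window[1], 1e3 * x$window[2], x$stride, nv,
              100 * nv / prod(d)))
  if (nv > 1) {
    v <- x$cph[x$mask]
    cat(sprintf("  cph: mean %.3f m/s, sd %.3f m/s, CV %.2f%%\n",
                mean(v), stats::sd(v), 100 * stats::sd(v) / mean(v)))
  }
  invisible(x)
}

#' @export
summary.swe_pvmap <- function(object, ...) {
  v <- object$cph[object$mask]
  out <- list(method = object$method, f0 = object$f0,
              n_valid = length(v), mean = mean(v), sd = stats::sd(v),
              cv = 100 * stats::sd(v) / mean(v),
              range = if (length(v)) range(v) else c(NA, NA))
  class(out) <- "summary.swe_pvmap"
  out
}

#' @export
print.summary.swe_pvmap <- function(x, ...) {
  cat(sprintf("%s map at %g Hz: %d valid px\n", x$method, x$f0, x$n_valid))
  cat(sprintf("  mean %.3f m/s, sd %.3f m/s, CV %.2f%%\n", x$mean, x$sd,
              x$cv))
  invisible(x)
}

#' @export
plot.swe_pvmap <- function(x, zlim = NULL, ...) {
  zax <- x$z0 + (seq_len(nrow(x$cph)) - 1) * x$dz
  xax <- x$x0 + (seq_len(ncol(x$cph)) - 1) * x$dx
  img <- x$cph
  img[!x$mask] <- NA
  graphics::image(1e3 * xax, 1e3 * zax, t(img)[, rev(seq_len(nrow(img)))],
                  col = grDevices::hcl.colors(64, "viridis"), zlim = zlim,
                  xlab = "lateral x [mm]", ylab = "depth z [mm]",
                  main = sprintf("%s phase velocity, f0 = %g Hz [m/s]",
                                 x$method, x$f0), ...)
  invisible(x)
}

#' Read and write phase-velocity map containers
#'
#' Maps are stored as a single-file serialized list holding `cph`, `mask`,
#' `quality`, `f0` and the grid metadata (the package's native container).
#'
#' @param map An `swe_pvmap`.
#' @param path File path.
#' @return `load_map()` returns the `swe_pvmap`; `save_map()` returns `path`
#'   invisibly.
#' @export
save_map <- function(map, path) {
  if (!inherits(map, "swe_pvmap")) stop("need an swe_pvmap", call. = FALSE)
  saveRDS(unclass(map), path)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  structure(readRDS(path), class = "swe_pvmap")
}
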