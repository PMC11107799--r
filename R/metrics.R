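# Quantitative evaluation of reconstructed phase-velocity maps: ROI
# statistics (mean, SD, CV), contrast-to-noise ratio between an inclusion and
# its background, and horizontal cross-section profiles with edge estimates.

#' Regions of interest on a phase-velocity map
#'
#' @param zlim,xlim Rectangle bounds in m.
#' @param center Length-2 `(z, x)` disk center in m.
#' @param radius Disk radius in m.
#' @param label Optional label carried into reports.
#' @return An object of class `swe_roi`.
#' @export
roi_rect <- function(zlim, xlim, label = "roi") {
  structure(list(kind = "rectangle", zlim = sort(zlim), xlim = sort(xlim),
                 label = label), class = "swe_roi")
}

#' @rdname roi_rect
#' @export
roi_disk <- function(center, radius, label = "roi") {
  structure(list(kind = "disk", center = center, radius = radius,
                 label = label), class = "swe_roi")
}

roi_select <- function(map, roi) {
  z <- map$z0 + (seq_len(nrow(map$cph)) - 1) * map$dz
  x <- map$x0 + (seq_len(ncol(map$cph)) - 1) * map$dx
  inside <- switch(roi$kind,
    rectangle = outer(z >= roi$zlim[1] & z <= roi$zlim[2],
                      x >= roi$xlim[1] & x <= roi$xlim[2], `&`),
    disk = outer((z - roi$center[1])^2, (x - roi$center[2])^2, `+`) <=
      roi$radius^2,
    stop("unknown ROI kind"))
  inside & map$mask
}

#' ROI statistics of a phase-velocity map
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation `CV = SD / MEAN * 100%` over the valid (unmasked) pixels of a
#' region of interest.
#'
#' @param map An `swe_pvmap`.
#' @param roi An [roi_rect()] or [roi_disk()].
#' @param min_pixels Minimum number of valid pixels required (default 16).
#' @return List with `mean` (m/s), `sd` (m/s), `cv` (%), `n`, `label`.
#' @export
roi_stats <- function(map, roi, min_pixels = 16L) {
  sel <- roi_select(map, roi)
  v <- map$cph[sel]
  v <- v[is.finite(v)]
  if (length(v) < min_pixels)
    stop(sprintf("ROI '%s' covers only %d valid pixels (need >= %d)",
                 roi$label, length(v), min_pixels), call. = FALSE)
  m <- mean(v); s <- stats::sd(v)
  list(mean = m, sd = s, cv = 100 * s / m, n = length(v), label = roi$label)
}

#' Contrast-to-noise ratio between two regions
#'
#' `CNR = 20 * log10(|mean_inclusion - mean_background| / SD_background)` in
#' dB, computed over valid pixels of the two regions of interest.
#'
#' @param map An `swe_pvmap`.
#' @param inclusion_roi,background_roi Regions of interest.
#' @param min_pixels Minimum valid pixels per ROI.
#' @return CNR in dB (`-Inf` when the means coincide).
#' @export
cnr <- function(map, inclusion_roi, background_roi, min_pixels = 16L) {
  si <- roi_stats(map, inclusion_roi, min_pixels)
  sb <- roi_stats(map, background_roi, min_pixels)
  if (sb$sd == 0)
    stop("background SD is zero: CNR undefined", call. = FALSE)
  20 * log10(abs(si$mean - sb$mean) / sb$sd)
}

#' Horizontal cross-section profile of a map
#'
#' Lateral phase-velocity profile at the row nearest `depth`, optionally
#' averaged over `+/- smooth` neighboring rows, with estimated edge
#' positions: the lateral locations where the profile crosses the midpoint
#' between the low- and high-plateau levels (means of the lower and upper
#' quartiles of the profile).
#'
#' @param map An `swe_pvmap`.
#' @param depth Depth in m (must lie inside the grid).
#' @param smooth Number of rows averaged on each side (default 1).
#' @return List with `x` (m), `value` (m/s, NA where masked), `edges`
#'   (crossing positions in m, possibly empty) and `midpoint`.
#' @export
cross_profile <- function(map, depth, smooth = 1L) {
  z <- map$z0 + (seq_len(nrow(map$cph)) - 1) * map$dz
  if (depth < min(z) - map$dz / 2 || depth > max(z) + map$dz / 2)
    stop("depth outside the grid", call. = FALSE)
  iz <- which.min(abs(z - depth))
  rows <- max(1L, iz - smooth):min(nrow(map$cph), iz + smooth)
  img <- map$cph
  img[!map$mask] <- NA
  prof <- colMeans(img[rows, , drop = FALSE], na.rm = TRUE)
  prof[!is.finite(prof)] <- NA
  x <- map$x0 + (seq_len(ncol(map$cph)) - 1) * map$dx
  v <- prof[is.finite(prof)]
  edges <- numeric(0); mid <- NA_real_
  if (length(v) >= 8L && diff(range(v)) > 0) {
    qs <- stats::quantile(v, c(0.25, 0.75))
    lo <- mean(v[v <= qs[1]]); hi <- mean(v[v >= qs[2]])
    mid <- (lo + hi) / 2
    if (hi - lo > .Machine$double.eps^0.5 * max(abs(v))) {
      # crossings along the sequence of valid samples (maps reconstructed on
      # a stride lattice interleave masked pixels)
      sel <- is.finite(prof)
      xs <- x[sel]
      s <- prof[sel] - mid
      idx <- which(s[-length(s)] * s[-1] < 0)
      edges <- vapply(idx, function(i) {
        xs[i] + (xs[i + 1] - xs[i]) * abs(s[i]) / (abs(s[i]) + abs(s[i + 1]))
      }, numeric(1))
    }
  }
  list(x = x, value = prof, edges = edges, midpoint = mid)
}

#' Metrics report for a set of ROIs
#'
#' Convenience wrapper building a per-ROI table of mean, SD, CV and pixel
#' count, with optional CNR for an (inclusion, background) pair.
#'
#' @param map An `swe_pvmap`.
#' @param rois List of ROIs.
#' @param cnr_pair Optional length-2 indices (inclusion, background) into
#'   `rois` for which a CNR is reported.
#' @return A data frame with one row per ROI; CNR in attribute `"cnr_db"`.
#' @export
metrics_report <- function(map, rois, cnr_pair = NULL) {
  rows <- lapply(rois, function(r) {
    s <- roi_stats(map, r)
    data.frame(label = s$label, mean = s$mean, sd = s$sd, cv = s$cv,
               n = s$n, f0 = map$f0)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cnr_pair))
    attr(out, "cnr_db") <- cnr(map, rois[[cnr_pair[1]]],
                               rois[[cnr_pair[2]]])
  out
}
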