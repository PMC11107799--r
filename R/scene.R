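#' Synthetic acquisition scene
#'
#' Describes a dual-push shear-wave acquisition to be rendered by
#' [synthesize_wavefield()]: grid geometry, background material, optional
#' stiff circular inclusion, push positions, push pulse, depth focus and
#' noise level. Defaults mirror a typical research-scanner acquisition:
#' 0.154 mm pitch, 4167 Hz frame rate, ~40 mm lateral field of view, two
#' lateral pushes, 20 mm focal depth.
#'
#' @param depth,lateral Length-2 numeric, spatial extent in m (`c(min, max)`).
#' @param dz,dx Grid spacings in m.
#' @param duration Record length in s.
#' @param dt Frame interval in s.
#' @param background An `swe_material` for the background medium.
#' @param inclusion `NULL`, or a list with fields `center_z`, `center_x`,
#'   `radius` (m) and `model` (`swe_material`). Must lie fully inside the grid.
#' @param pushes Numeric vector of lateral push-line positions in m.
#' @param pulse List with `fc` (center frequency, Hz), `bw` (full width at
#'   half maximum of the Gaussian amplitude spectrum, Hz), `t0` (push onset
#'   time, s), `amplitude`, and `f_lo` (smooth high-pass corner, Hz; the
#'   band below it is excluded so the record holds no quasi-static energy).
#'   The highest synthesized component `fc + bw` must respect the Nyquist
#'   limit `1/(2 dt)`.
#' @param focal_depth Center of the Gaussian depth envelope, m.
#' @param sigma_z Standard deviation of the depth envelope, m.
#' @param sigma_push Lateral standard deviation of the push beam, m (the
#'   source is a Gaussian line distribution, not a singular line).
#' @param spreading Logical; apply cylindrical `1/sqrt(distance)` amplitude
#'   spreading away from the push line.
#' @param snr_db Additive white Gaussian noise level as a global SNR in dB;
#'   `Inf` (default) means noiseless.
#' @param seed Integer seed used for the noise realization.
#' @return An object of class `swe_scene`.
#' @examples
#' sc <- swe_scene(background = material_elastic(25e3), duration = 0.03)
#' @export
swe_scene <- function(depth = c(0.010, 0.030), lateral = c(0, 0.040),
                      dz = 1.54e-4, dx = 1.54e-4,
                      duration = 0.1, dt = 1 / 4167,
                      background = material_elastic(25e3),
                      inclusion = NULL,
                      pushes = c(0.006, 0.034),
                      pulse = list(fc = 600, bw = 1000, t0 = 0.002,
                                   amplitude = 1, f_lo = 150),
                      focal_depth = 0.020, sigma_z = 0.005,
                      sigma_push = 3e-4,
                      spreading = TRUE, snr_db = Inf, seed = 1L) {
  if (!inherits(background, "swe_material"))
    stop("'background' must be an swe_material", call. = FALSE)
  pulse <- utils::modifyList(list(fc = 600, bw = 1000, t0 = 0.002,
                                  amplitude = 1, f_lo = 150), pulse)
  if (pulse$fc + pulse$bw > 1 / (2 * dt))
    stop("scene violates Nyquist: fc + bw = ", pulse$fc + pulse$bw,
         " Hz exceeds 1/(2 dt) = ", 1 / (2 * dt), " Hz", call. = FALSE)
  if (!is.null(inclusion)) {
    need <- c("center_z", "center_x", "radius", "model")
    if (!all(need %in% names(inclusion)))
      stop("inclusion needs fields ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!inherits(inclusion$model, "swe_material"))
      stop("inclusion$model must be an swe_material", call. = FALSE)
    r <- inclusion$radius
    if (inclusion$center_z - r < depth[1] || inclusion$center_z + r > depth[2] ||
        inclusion$center_x - r < lateral[1] || inclusion$center_x + r > lateral[2])
      stop("inclusion does not lie fully inside the grid", call. = FALSE)
  }
  if (any(pushes < lateral[1]) || any(pushes > lateral[2]))
    stop("push positions must lie inside the lateral extent", call. = FALSE)
  structure(list(depth = depth, lateral = lateral, dz = dz, dx = dx,
                 duration = duration, dt = dt, background = background,
                 inclusion = inclusion, pushes = pushes, pulse = pulse,
                 focal_depth = focal_depth, sigma_z = sigma_z,
                 sigma_push = sigma_push,
                 spreading = spreading, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "swe_scene")
}

#' @export
print.swe_scene <- function(x, ...) {
  cat("<swe_scene>\n")
  cat(sprintf("  grid: z %.1f..%.1f mm, x %.1f..%.1f mm, %.0f ms @ %.0f Hz\n",
              1e3 * x$depth[1], 1e3 * x$depth[2], 1e3 * x$lateral[1],
              1e3 * x$lateral[2], 1e3 * x$duration, 1 / x$dt))
  cat("  background: ", x$background$kind, "\n")
  if (!is.null(x$inclusion))
    cat(sprintf("  inclusion: r = %.2f mm at (%.1f, %.1f) mm, %s\n",
                1e3 * x$inclusion$radius, 1e3 * x$inclusion$center_z,
                1e3 * x$inclusion$center_x, x$inclusion$model$kind))
  cat(sprintf("  pushes at x = %s mm; SNR = %s dB\n",
              paste(sprintf("%.1f", 1e3 * x$pushes), collapse = ", "),
              format(x$snr_db)))
  invisible(x)
}

# scene (YAML) configs --------------------------------------------------------

material_from_config <- function(cfg) {
  kind <- match.arg(cfg$kind, c("elastic", "kelvin_voigt", "sls"))
  rho <- cfg$rho %||% 1000
  switch(kind,
    elastic      = material_elastic(cfg$E, rho),
    kelvin_voigt = material_kv(cfg$mu, cfg$eta, rho),
    sls          = material_sls(cfg$E1, cfg$E2, cfg$eta, rho))
}

#' Build a scene from a YAML/JSON configuration file
#'
#' The configuration mirrors the arguments of [swe_scene()]; material models
#' are given as mappings with a `kind` field (`elastic`, `kelvin_voigt`,
#' `sls`) plus the corresponding parameters.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return An `swe_scene` object.
#' @export
scene_from_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  args <- cfg
  if (!is.null(args$background))
    args$background <- material_from_config(args$background)
  if (!is.null(args$inclusion))
    args$inclusion$model <- material_from_config(args$inclusion$model)
  args <- args[names(args) %in% names(formals(swe_scene))]
  do.call(swe_scene, args)
}
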