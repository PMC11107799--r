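#' Rheological material models for shear-wave propagation
#'
#' Constructors for the three material laws used by the simulator and the
#' model-fitting routines: a purely elastic solid, a Kelvin-Voigt (KV) solid
#' (spring in parallel with a dashpot) and a standard linear solid (SLS; a
#' spring in series with a Kelvin-Voigt element). All models assume an
#' incompressible medium so that Young's modulus and shear modulus are related
#' by `E = 3 * mu`; for the SLS the full complex Young's modulus is divided by
#' 3, i.e. the shear-scale parameters are `E1/3`, `E2/3` and `eta/3`.
#'
#' @param E,E1,E2 Young's moduli in Pa (strictly positive).
#' @param mu Shear modulus in Pa (strictly positive).
#' @param eta Shear viscosity in Pa s (non-negative). For [material_sls()] the
#'   viscosity is quoted on the Young scale, consistent with `E1` and `E2`.
#' @param rho Density in kg/m^3 (default 1000, appropriate for tissue-mimicking
#'   phantoms).
#'
#' @return An object of class `swe_material`: a list with fields `kind`
#'   (`"elastic"`, `"kelvin_voigt"` or `"sls"`), the model parameters, and
#'   `rho`.
#'
#' @details The elastic model is the `eta -> 0`, `E2 -> Inf` limit of the other
#'   two: its phase velocity is the frequency-independent
#'   `sqrt(E / (3 * rho))` and its attenuation is identically zero.
#'
#' @examples
#' m <- material_elastic(E = 80e3)
#' dispersion_law(m, c(100, 500, 1000))$c  # constant 5.16 m/s
#' @export
material_elastic <- function(E, rho = 1000) {
  check_positive(E = E, rho = rho)
  structure(list(kind = "elastic", E = E, mu = E / 3, eta = 0, rho = rho),
            class = "swe_material")
}

#' @rdname material_elastic
#' @export
material_kv <- function(mu, eta, rho = 1000) {
  check_positive(mu = mu, rho = rho)
  check_nonnegative(eta = eta)
  structure(list(kind = "kelvin_voigt", mu = mu, eta = eta, rho = rho),
            class = "swe_material")
}

#' @rdname material_elastic
#' @export
material_sls <- function(E1, E2, eta, rho = 1000) {
  check_positive(E1 = E1, E2 = E2, rho = rho)
  check_nonnegative(eta = eta)
  structure(list(kind = "sls", E1 = E1, E2 = E2, eta = eta, rho = rho),
            class = "swe_material")
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid material model: '", nm,
           "' must be a finite positive scalar", call. = FALSE)
  }
  invisible(TRUE)
}

check_nonnegative <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("invalid material model: '", nm,
           "' must be a finite non-negative scalar", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.swe_material <- function(x, ...) {
  cat("<swe_material>", x$kind, "\n")
  p <- switch(x$kind,
    elastic      = sprintf("  E = %g Pa", x$E),
    kelvin_voigt = sprintf("  mu = %g Pa, eta = %g Pa.s", x$mu, x$eta),
    sls          = sprintf("  E1 = %g Pa, E2 = %g Pa, eta = %g Pa.s",
                           x$E1, x$E2, x$eta))
  cat(p, sprintf(", rho = %g kg/m^3\n", x$rho), sep = "")
  invisible(x)
}

#' Complex shear modulus G*(omega) of a material model
#'
#' @param model An [material_elastic()]-family object.
#' @param omega Angular frequency in rad/s (non-negative).
#' @return Complex vector, same length as `omega`.
#' @keywords internal
#' @noRd
complex_shear_modulus <- function(model, omega) {
  switch(model$kind,
    elastic      = complex(real = rep(model$mu, length(omega)), imaginary = 0),
    kelvin_voigt = complex(real = model$mu, imaginary = omega * model$eta),
    sls          = {
      # series spring E1 with KV element (E2 || eta); whole Young modulus /3
      e1 <- model$E1; kvel <- complex(real = model$E2,
                                      imaginary = omega * model$eta)
      (e1 * kvel / (e1 + kvel)) / 3
    },
    stop("unknown material kind: ", model$kind))
}

#' Phase velocity and attenuation of a material model
#'
#' Evaluates the dispersion law of a material: the shear-wave phase velocity
#' `c(f)` and attenuation `alpha(f)` derived from the complex wavenumber
#' `k*(omega) = omega * sqrt(rho / G*(omega))`, where `G*` is the complex
#' shear modulus of the model (`mu + i omega eta` for Kelvin-Voigt; the series
#' spring/Kelvin-Voigt combination for the standard linear solid).
#'
#' @param model An `swe_material` object.
#' @param f Frequency grid in Hz, elementwise non-negative.
#' @return A data frame with columns `f` (Hz), `c` (phase velocity, m/s) and
#'   `alpha` (attenuation, Np/m). At `f = 0` the zero-frequency limit
#'   `c = sqrt(G*(0)/rho)`, `alpha = 0` is returned.
#'
#' @details For the elastic model `c` is constant and `alpha` is zero. For the
#'   Kelvin-Voigt and SLS models `c(f)` is non-decreasing; the SLS velocity
#'   plateaus at `sqrt(E1 / (3 rho))` as `f -> Inf` (the series-spring limit).
#' @examples
#' dispersion_law(material_kv(mu = 3.33e3, eta = 2), c(0, 200, 500))
#' @export
dispersion_law <- function(model, f) {
  if (!inherits(model, "swe_material"))
    stop("'model' must be an swe_material object", call. = FALSE)
  f <- as.numeric(f)
  if (length(f) == 0L || any(!is.finite(f)) || any(f < 0))
    stop("'f' must be finite and non-negative", call. = FALSE)
  omega <- 2 * pi * f
  G <- complex_shear_modulus(model, omega)
  kstar <- omega * sqrt(model$rho / G)
  cph <- ifelse(omega == 0,
                sqrt(Re(complex_shear_modulus(model, 0)) / model$rho),
                omega / Re(kstar))
  alpha <- ifelse(omega == 0, 0, -Im(kstar))
  data.frame(f = f, c = cph, alpha = alpha)
}

#' Nominal shear-wave speed from Young's modulus
#'
#' The incompressible-medium plane shear-wave speed `sqrt(E / (3 * rho))`, used
#' as the manufacturer-style nominal velocity of an elastic phantom region.
#'
#' @param E Young's modulus in Pa, strictly positive.
#' @param rho Density in kg/m^3, strictly positive.
#' @return Speed in m/s.
#' @examples
#' nominal_speed(80e3)  # 5.16 m/s
#' @export
nominal_speed <- function(E, rho = 1000) {
  check_positive(E = E, rho = rho)
  sqrt(E / (3 * rho))
}

#' Shear wavelength at a given phase velocity and frequency
#'
#' @param c Phase velocity in m/s.
#' @param f Frequency in Hz, strictly positive.
#' @return Wavelength `c / f` in m.
#' @export
wavelength <- function(c, f) {
  if (any(f <= 0)) stop("'f' must be positive", call. = FALSE)
  c / f
}
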