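# Identification of viscoelastic model parameters from a measured dispersion
# curve by bounded nonlinear least squares with a multi-start grid.

#' Fit a viscoelastic material model to a dispersion curve
#'
#' Minimizes `sum((c_model(f) - c_data(f))^2)` over the parameters of a
#' Kelvin-Voigt or standard-linear-solid model, using
#' [minpack.lm::nls.lm()] in log-parameter space from a multi-start grid of
#' log-spaced moduli (1-100 kPa) and viscosities (0.1-30 Pa s); the best
#' converged start is kept. Masked frequencies of the input curve are
#' ignored.
#'
#' @param curve An `swe_dispersion` (or any data frame with columns `f` and
#'   `c`; an optional logical `masked` column excludes points).
#' @param kind `"kelvin_voigt"` or `"sls"`.
#' @param rho Density in kg/m^3 assumed for the model.
#' @return An object of class `swe_material_fit` with the fitted
#'   `swe_material` in `$model`, the parameter vector (natural scale) in
#'   `$coefficients`, the residual norm, a convergence flag and the data
#'   used. Methods: `coef`, `print`, `summary`, `predict` (phase velocity at
#'   new frequencies), `residuals`, `fitted`, `plot`.
#' @details At least 5 unmasked points spanning a factor of 2 in frequency
#'   are required; identification degrades when the relaxation transition of
#'   the true material lies outside the fitted band.
#' @examples
#' truth <- material_sls(E1 = 9.61e3, E2 = 15.62e3, eta = 5.28)
#' curve <- dispersion_law(truth, seq(100, 1500, by = 50))
#' fit <- fit_material_model(curve, "sls")
#' coef(fit)
#' @export
fit_material_model <- function(curve, kind = c("kelvin_voigt", "sls"),
                               rho = 1000) {
  kind <- match.arg(kind)
  df <- as.data.frame(curve)
  if (!all(c("f", "c") %in% names(df)))
    stop("'curve' needs columns f and c", call. = FALSE)
  keep <- is.finite(df$f) & is.finite(df$c) & df$f > 0 & df$c > 0
  if ("masked" %in% names(df)) keep <- keep & !df$masked
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 5L)
    stop("need at least 5 unmasked dispersion points", call. = FALSE)
  if (max(df$f) / min(df$f) < 2)
    stop("dispersion points must span at least a factor 2 in frequency",
         call. = FALSE)

  make_model <- switch(kind,
    kelvin_voigt = function(p) material_kv(10^p[1], 10^p[2], rho),
    sls          = function(p) material_sls(10^p[1], 10^p[2], 10^p[3], rho))
  resid_fn <- function(p) dispersion_law(make_model(p), df$f)$c - df$c
  mod_grid <- log10(c(1e3, 5e3, 2e4, 1e5))
  eta_grid <- log10(c(0.1, 1, 6, 30))
  starts <- switch(kind,
    kelvin_voigt = expand.grid(mod_grid, eta_grid),
    sls          = expand.grid(mod_grid, mod_grid, eta_grid))
  lower <- c(rep(2, if (kind == "sls") 2 else 1), -4)
  upper <- c(rep(6.5, if (kind == "sls") 2 else 1), 2.5)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(fit$fvec^2)
    if (is.null(best) || dev < best$dev)
      best <- list(fit = fit, dev = dev)
  }
  if (is.null(best))
    stop("model fit failed to converge from every start", call. = FALSE)

  p <- best$fit$par
  model <- make_model(p)
  coefs <- switch(kind,
    kelvin_voigt = c(mu = model$mu, eta = model$eta),
    sls          = c(E1 = model$E1, E2 = model$E2, eta = model$eta))
  structure(list(model = model, kind = kind, coefficients = coefs,
                 residual_norm = sqrt(best$dev),
                 converged = best$fit$info %in% 1:3,
                 info = best$fit$info, data = df, rho = rho),
            class = "swe_material_fit")
}

#' @export
coef.swe_material_fit <- function(object, ...) object$coefficients

#' @export
print.swe_material_fit <- function(x, ...) {
  cat("<swe_material_fit>", x$kind, if (x$converged) "(converged)" else
    "(NOT converged)", "\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  residual norm %.4g m/s over %d points\n", x$residual_norm,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.swe_material_fit <- function(object, ...) {
  r <- residuals(object)
  cat("Material model fit:", object$kind, "\n")
  print(signif(object$coefficients, 4))
  cat(sprintf("  rms residual %.4g m/s, max |residual| %.4g m/s, n = %d\n",
              sqrt(mean(r^2)), max(abs(r)), length(r)))
  invisible(object)
}

#' @export
predict.swe_material_fit <- function(object, f = NULL, ...) {
  if (is.null(f)) f <- object$data$f
  dispersion_law(object$model, f)$c
}

#' @export
fitted.swe_material_fit <- function(object, ...) predict(object)

#' @export
residuals.swe_material_fit <- function(object, ...) {
  object$data$c - predict(object)
}

#' @export
plot.swe_material_fit <- function(x, ...) {
  graphics::plot(x$data$f, x$data$c, pch = 19, xlab = "frequency [Hz]",
                 ylab = "phase velocity [m/s]",
                 main = paste("dispersion fit,", x$kind), ...)
  fg <- seq(min(x$data$f), max(x$data$f), length.out = 200)
  graphics::lines(fg, dispersion_law(x$model, fg)$c, col = 2, lwd = 2)
  invisible(x)
}
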