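# useweb

Wideband 2D shear-wave phase-velocity imaging for soft tissues, in R.

Ultrasound shear-wave elastography launches shear waves with acoustic
radiation force and tracks them to map tissue stiffness. In viscoelastic
tissue the phase velocity depends on frequency, and that dispersion is the
quantity of interest — but conventional local estimators lose the wave at
high frequencies. This package implements a reconstruction that combines a
generalized Stockwell (S-) transform with short-space slant
wavenumber-frequency analysis: the wavefield `v(z, x, t)` is decomposed into
complex voices `H(z, x, tau)` at the analysis frequency `f0`, sliding
Tukey-tapered windows are sliced along `tau = x/u` over a series of steering
group velocities `u`, the 2D spatial FFT amplitudes are maximized over
steering, and the local wavenumber peak gives

```
c_ph(z, x) = 2 * pi * f0 / |k|,   |k| = sqrt(kz^2 + kx^2),
[kz, kx] = argmax K(kz, kx, f0)
```

per window. The package also provides:

* `lpvi()` — the local phase velocity imaging baseline (temporal FT +
  short-space 2D FT), with an optional first-order Butterworth wavenumber
  filter around a velocity band `V0 ± 1 m/s`;
* `dispersion_2dft()` / `dispersion_gst_sfk()` — 1D dispersion curves at the
  focal depth, and `fit_material_model()` — nonlinear least-squares
  identification of Kelvin-Voigt and standard-linear-solid parameters;
* `synthesize_wavefield()` — a dispersive wavefield simulator with exact
  per-pixel ground truth (elastic / Kelvin-Voigt / SLS media, dual lateral
  pushes, optional stiff circular inclusion, additive noise);
* `roi_stats()`, `cnr()`, `cross_profile()` — the evaluation metrics
  (coefficient of variation, contrast-to-noise ratio, edge profiles);
* a command-line wrapper (`inst/cli/swe`) with `simulate`, `reconstruct`,
  `dispersion`, `fit`, `metrics` and `profile` subcommands.

## Worked example

Simulate a homogeneous viscoelastic phantom (standard linear solid with
E1 = 9.61 kPa, E2 = 15.62 kPa, eta = 5.28 Pa s), reconstruct the 400 Hz
phase-velocity map, and compare with the ground truth:

```r
library(useweb)

phantom <- material_sls(E1 = 9.61e3, E2 = 15.62e3, eta = 5.28)
dispersion_law(phantom, c(400, 800))
#>     f        c    alpha
#> 1 400 1.526834 181.8299
#> 2 800 1.652057 348.5894

scene <- swe_scene(background = phantom, duration = 0.1,
                   snr_db = 30, seed = 5)
sim <- synthesize_wavefield(scene)

pv <- useweb(sim$wavefield, f0 = 400, stride = 4,
             region = list(zlim = c(0.017, 0.023), xlim = c(0.015, 0.025)))
summary(pv)
#> useweb map at 400 Hz: 170 valid px
#>   mean 1.484 m/s, sd 0.033 m/s, CV 2.23%

roi_stats(pv, roi_rect(c(0.017, 0.023), c(0.015, 0.025)))$cv
#> [1] 2.233863
```

The map mean (1.48 m/s) sits within a few percent of the true 400 Hz phase
velocity (1.53 m/s), and the coefficient of variation — the uniformity metric
used throughout the package — is below 3%. A dispersion curve at the focal
depth plus a model fit recovers the generating parameters:

```r
line  <- extract_line(sim$wavefield, center_z = 0.020,
                      xlim = c(0.008, 0.032))
curve <- dispersion_gst_sfk(line, seq(150, 1200, by = 75))
fit   <- fit_material_model(curve, "sls")
coef(fit)
#>         E1         E2        eta
#>  9414.0565 16469.9391     5.4400
```

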