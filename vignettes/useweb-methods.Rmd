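---
title: "Wideband shear-wave phase-velocity imaging: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wideband shear-wave phase-velocity imaging: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
reconstruction model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices, and
the known limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Shear-wave elastography maps tissue stiffness by tracking shear waves launched
by acoustic-radiation-force (ARF) pushes. Time-of-flight methods measure a
single group velocity per pixel; in viscoelastic tissue, however, the phase
velocity $c_{ph}(f)$ is frequency dependent, and that dispersion carries the
diagnostic information about viscosity. The package reconstructs 2D images of
$c_{ph}(z, x)$ at chosen frequencies from the particle-velocity movie
$v(z, x, t)$, over as wide a frequency band as the data allow.

## The USEWEB estimator

The core estimator (`useweb()`) chains five stages:

1. **Directional filtering** (`directional_filter()`): a per-depth-row 2D
   Fourier mask keeps only waves traveling left-to-right (or right-to-left),
   so the two push sources can be processed separately.
2. **Generalized S-transform** (`decompose()`): each trace is decomposed with
   a Gaussian window of temporal standard deviation $\sqrt{\beta}/f$,
   $$S[v](\tau, f) = \int v(t)\, \frac{|f|}{\sqrt{2\pi\beta}}
     e^{-f^2(\tau - t)^2 / 2\beta}\, e^{-i 2\pi f t}\, dt,$$
   and the complex voice $H(z, x, \tau)$ at the analysis frequency $f_0$ is
   kept. Because the phase is referenced to the time origin, a plane wave
   appears in $H$ as $e^{-i k x}$ with a $\tau$-dependent envelope: the
   carrier is demodulated, the arrival time lives only in the envelope.
3. **Spatial windowing**: a sliding 2D Tukey-tapered window (default
   4.47 mm square, taper ratio 0.25) isolates a local patch of $H$.
4. **Slant-phase slicing and steering**
   (`slant_slice()`, `max_over_steering()`): the window is sliced along
   $\tau = \bar{x}/u$ for a series of steering group velocities
   $u_m = \bar{x}_m / (t_m - m\,\Delta t)$ (`steering_series()`); the 2D
   spatial FFT amplitude of each slice is computed and the element-wise
   maximum over $u$ taken. The slice that best rides the wave's envelope
   contributes a coherent $e^{-ikx}$ across the whole window.
5. **Peak picking** (`pick_wavenumber()`): the wavenumber-magnitude annulus
   corresponding to a velocity search band (default 0.5-10 m/s) is searched
   for the amplitude peak; sub-bin refinement gives $|k|$, and
   $c_{ph} = 2\pi f_0 / |k|$ is assigned to the window center. Maps from the
   two travel directions are combined per pixel by keeping the direction with
   the stronger spectral peak.

The baseline comparator `lpvi()` (local phase velocity imaging) replaces
stages 2 and 4 with a plain temporal Fourier transform, optionally preceded by
a first-order Butterworth wavenumber band-pass (`k_bandpass()`) around a
nominal velocity band $V_0 \pm \Delta V$.

## Material models

`dispersion_law()` evaluates $c(f)$ and the attenuation $\alpha(f)$ from the
complex shear modulus $G^*(\omega)$ via
$k^*(\omega) = \omega \sqrt{\rho / G^*}$:

* elastic: $G^* = \mu$, with $E = 3\mu$ (incompressible), so
  $c = \sqrt{E/3\rho}$, $\alpha = 0$;
* Kelvin-Voigt: $G^* = \mu + i\omega\eta$;
* standard linear solid (SLS): a spring $E_1$ in series with a Kelvin-Voigt
  element ($E_2 \parallel \eta$); the full complex Young's modulus is divided
  by 3, so the quoted parameters stay on the Young scale.

The SLS velocity rises from $\sqrt{E_1 E_2 / (3\rho (E_1 + E_2))}$ to the
series-spring plateau $\sqrt{E_1 / 3\rho}$; its loss tangent peaks near the
relaxation frequency $(E_1 + E_2)/\eta$ and *saturates* at high frequency.
A Kelvin-Voigt medium, in contrast, has a loss tangent growing linearly with
frequency — it cannot be simultaneously strongly dispersive and transparent at
high frequency. That distinction matters repeatedly below.

## The synthetic-data generator

`synthesize_wavefield()` renders a scene by frequency-domain superposition:
every temporal-frequency component of the push pulse propagates away from each
push line with the local material's $c(f)$ and decays with $\alpha(f)$, so the
per-pixel ground truth *is* `dispersion_law()` by construction — no PDE solver
and no discretization error in the dispersion relation. Key design choices:

* **Grid defaults** match a research-scanner acquisition: 0.154 mm pitch,
  4167 Hz frame rate, 40 mm lateral field of view, 100 ms record, focal depth
  20 mm with a Gaussian depth envelope (sd 5 mm).
* **Pulse**: Gaussian amplitude spectrum (center 600 Hz, FWHM 1 kHz default)
  with onset delay $t_0$, shaped by an infinitely smooth Gaussian high-pass
  ($1 - e^{-f^2/2 f_{lo}^2}$, $f_{lo}$ = 150 Hz). The high-pass exists
  because quasi-static components neither stay localized within a finite
  record nor carry dispersion information in the analysis band; leaving them
  in pollutes every S-transform voice near the record start, exactly where
  the slant lines sample. A raised-cosine quiescent-start taper over
  $[0, t_0]$ removes the small residual acausal precursor of band-limited
  superposition.
* **Push beam**: a Gaussian lateral source distribution with sd 0.3 mm
  (matching an F/1.5 push beam at 4 MHz). A singular line source would
  dominate the field's low-wavenumber spectrum; conversely a much wider
  coherent source cannot radiate short wavelengths at all (the radiated
  spectrum is suppressed by $e^{-k^2\sigma_p^2/2}$), so the beam width
  directly limits the usable frequency range of stiff media.
* **Inclusions** are rendered by accumulating the local complex wavenumber
  along the propagation path (phase continuity at the boundary); there is no
  reflection, scattering or mode conversion — a documented simplification.
* **Noise** is white Gaussian over the whole array at a prescribed global
  SNR. There is no speckle-tracking noise model, no jitter correlated with
  the beamforming process, and no depth-dependent noise floor; passing tests
  on this generator therefore demonstrates estimator correctness and noise
  robustness, not robustness to every artifact of real acquisitions.

## Parameters that matter, and their defaults

* `beta` (S-transform width scaling; `useweb()` default 9,
  `s_transform_1d()` default 1 = classical transform). The voice bandwidth is
  $\sigma_\nu = f_0 / 2\pi\sqrt{\beta}$. In media with frequency-dependent
  attenuation the voice content centroid is pulled below $f_0$ by roughly
  $d \cdot \alpha'(f_0) \cdot \sigma_\nu^2$ after a propagation distance $d$;
  a slant slice at steering velocity $u$ converts any centroid offset
  $\Delta f$ into a wavenumber bias $2\pi\Delta f/u$. Large `beta` shrinks
  this bias quadratically and simultaneously widens the temporal window so
  that origin-aligned slants (which carry no such bias) dominate the steering
  maximum. The cost, coarser time resolution, is irrelevant for records much
  longer than the wave transit.
* `u_min`, `u_max`, `n_u` (steering series clamp, defaults 0.2 and 15 m/s,
  at most 48 values): the literal series reaches uselessly small $u$; the
  clamp bounds cost. `u_min` must stay below
  $\bar{x}_m / (\text{arrival time})$ of the farthest window, which is why
  the default sits below the slowest physical group velocity.
* `window` (default 4.47 mm square, Tukey ratio 0.25): smaller windows give
  better spatial resolution but noisier wavenumber peaks; the window should
  contain an appreciable fraction of a wavelength, which is what degrades all
  local methods below roughly 200 Hz in soft media.
* `search_band` (default 0.5-10 m/s): bounds the wavenumber annulus; without
  it the global argmax is ill-posed at $|k| \to 0$.
* `quality_floor` (default 3) and `dyn_floor` (default 0.01): a window is
  masked unless its spectral peak exceeds 3x the median annulus amplitude
  *and* 1% (-40 dB) of the strongest window peak of its travel direction.
  The second test marks attenuation-dead regions as missing rather than
  letting annulus-edge noise pose as an estimate.
* k-filter band `v0 +/- dv` (`lpvi()` option): per the baseline method's
  published practice, the center velocity is taken from a 1D dispersion
  estimate (e.g. `dispersion_gst_sfk()` at the focal depth) and the half-band
  defaults to 1 m/s.

## Numerical choices

* The S-transform is evaluated as an exact zero-padded FFT convolution of the
  demodulated trace with the sampled Gaussian window, so it equals the
  literal discrete definition to machine precision (the suite asserts
  1e-10); voices at arbitrary (off-bin) frequencies are supported.
* The per-window steering loop is compiled (RcppArmadillo, FFTW-backed
  `fft2`); a pure-R reference path (`engine = "r"`) built from the exported
  primitives is numerically identical and is cross-checked in the tests
  against a literal loop/DFT oracle.
* Wavenumber unit convention: the spatial FT uses cycles/m internally; all
  exposed axes and peaks are converted once to rad/m so that
  $c_{ph} = 2\pi f_0/|k|$ holds literally.
* Peak refinement fits a least-squares parabola over +/-3 bins independently
  along each wavenumber axis (more stable than a 3-point fit when the padded
  lobe spans many bins); the refined magnitude is clamped to the search
  annulus. Ties break deterministically to the smaller $|k|$, then the
  smaller $k_x$.
* The directional filter shares the $k_x = 0$ column half/half between
  directions (so the two outputs sum to the input), applies a raised-cosine
  ramp of 3 bins, symmetric lateral padding of 25%, and lateral RMS gain
  equalization (undone after filtering) so that the near-push amplitude
  spike cannot ring across the quiet far field through the mask transition.
  `share_ridge = FALSE` instead excludes the near-ridge band from both
  directions.
* The Butterworth k-filter is applied per temporal-frequency frame of the 3D
  spectrum (the frequency-domain reading of "each frame"); a per-time-frame
  variant was considered and rejected because the velocity-derived band is
  frequency specific.
* Degenerate inputs: all-zero windows yield masked pixels (never NaN
  velocities); `f = 0` is rejected by the S-transform (the window
  degenerates); frequencies above Nyquist are refused.

## Problem sizes used by the tests

The test suite runs the full pipeline on reduced problems: analytic plane
waves and packets (up to 40 x 160 x 300 samples), short-record scenes
(40-100 ms), strides of 2-8 between window centers, and 10-seed comparative
runs on a 64 x 96 x 300 grid. These sizes were chosen so that each end-to-end
check isolates one claim at a few seconds to a few minutes of compute; the
estimator itself is size-agnostic.

## Design decisions on genuinely open points

* **Combining the two travel directions**: per pixel, the direction with the
  stronger spectral peak decides alone (winner-take-all). Averaging -- plain
  or amplitude-weighted -- was tried first and rejected: near the opposite
  push line the losing direction carries near-field energy whose spectral
  peak rivals the genuine wave's, so any averaging lets it drag the estimate
  toward large apparent velocities.
* **Push-line exclusion** (`push_x`, margin 1.5 mm): when the push geometry
  is known, windows whose footprint approaches a push line are masked; the
  near field there mixes both travel directions inseparably and violates the
  local-plane-wave assumption.
* **Frequency bands**: when a band is requested, the wavenumber-amplitude
  surfaces are averaged across the band's frequencies before a single peak
  pick at the band center; averaging per-frequency velocity maps instead is
  available but mixes annulus geometries.
* **Assembly**: estimates are assigned to window-center pixels on a stride
  lattice; windows that would leave the field of view are masked, not
  extrapolated.
* **SLS viscosity scale**: fitted and simulated SLS parameters are quoted on
  the Young scale with the whole complex modulus divided by 3; round-trip
  fitting is self-consistent under this convention.

## Known limitations

* The generator's waves are strictly one-dimensional in propagation (vertical
  wavefronts with a depth envelope): $k_z \approx 0$ by construction, so the
  2D wavenumber search is exercised mostly along $k_x$ on synthetic data.
* No boundary physics at inclusions: reconstructed edges blur over roughly a
  window width, as the windowed estimator's local-homogeneity assumption
  predicts, but reflection/mode-conversion artifacts of real interfaces are
  absent.
* Strongly lossy Kelvin-Voigt media are fundamentally hostile to *any*
  high-frequency phase-velocity imaging: with $\mu = 5$ kPa, $\eta = 2$ Pa s
  the attenuation length $1/\alpha$ is 2.8 / 1.3 / 0.9 mm at 400 / 800 /
  1200 Hz, so beyond a few millimetres from a push there is no 800-1200 Hz
  wave left to image at realistic SNR. The wideband claims of this method
  class rest on media whose loss saturates at high frequency (SLS-like
  phantoms and tissues); the package reproduces that behavior and honestly
  masks, rather than fills in, the attenuation-dead regime.
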