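---
title: "From second-harmonic images to membrane potential, charge and curvature maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From second-harmonic images to membrane potential, charge and curvature maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shgmap)
```

## The measurement and its model

A freestanding lipid bilayer spans a circular Teflon aperture (80–120 µm)
between two aqueous compartments. Under femtosecond illumination the
membrane emits second-harmonic (SH) light only where the interface breaks
centrosymmetry. For a bilayer the two leaflets radiate with opposite phase,
so a compositionally and electrostatically symmetric membrane is dark: the
detected coherent intensity is

$$ I(2\omega, x, y) \propto I(\omega)^2 \left| \chi^{(2)}_{s,1} -
\chi^{(2)}_{s,2} + f_3 \chi^{(3)\prime}\,(\Phi_{0,1}(x,y) -
\Phi_{0,2}(x,y)) \right|^2 , $$

where $\Phi_{0,i}$ are the leaflet surface potentials, $\chi^{(3)\prime}$
couples the static field of the double layer to the SH response, and
$f_3 \to 1$ in transmission. For symmetric lipid composition the
$\chi^{(2)}$ terms cancel and the image is a map of
$|\Delta\Phi_0|^2 = |\Phi_{0,1}-\Phi_{0,2}|^2$. Divalent cations (Ca²⁺,
Ba²⁺, Mg²⁺) added to one side bind to anionic lipids and create transient,
micron-sized patches of ordered interfacial water that light up in the SH
image. This package implements the full computational chain from such image
stacks to quantitative maps, plus a synthetic-image generator that stands in
for the (undeposited) raw microscope data.

On top of the coherent signal sits hyper-Rayleigh scattering (HRS), an
incoherent SH background from the bulk solution. It is measured on a
solution-only image and subtracted frame by frame (`subtract_background()`),
clipping at zero because the downstream square-root inversion requires
non-negative intensities. Subtraction and frame averaging commute exactly,
so their order is immaterial.

## The synthetic acquisition

`simulate_stack()` emulates the experiment's statistical structure:

* domains are a spatial Poisson process inside the aperture, each a Gaussian
  potential patch of amplitude `domain_potential` (signed, volts);
* `domain_radius` (default 1.5 µm) is the FWHM of a domain's *intensity*
  footprint. Detection is quadratic in the potential, which narrows a
  Gaussian by $\sqrt{2}$, so the potential patch is built $\sqrt{2}$ wider.
  This makes the radius round-trip through the spatial autocorrelation exact
  in expectation;
* persistence is memoryless: survival per frame is
  $e^{-1/\texttt{lifetime\_frames}}$, with Poisson births keeping the
  expected count stationary. The experimental domains live for less than one
  560 ms frame, so the default lifetime is 0.3 frames;
* a fraction `registry_coupling` of domains is mirrored on the opposing
  leaflet with equal amplitude; mirrored domains cancel in
  $\Delta\Phi_0$ and are invisible — at `registry_coupling = 1` the
  coherent image is identically the background, the symmetric-membrane
  control;
* counts are Poisson (shot noise only; camera excess noise is out of scope),
  on top of a flat HRS level (default 50 counts).

Amplitude spread (`amplitude_sd`) and surface density are not constrained by
the experiment; the presets (`preset_config()`) set domain amplitudes from
the measured per-ion domain statistics (Ca −287 ± 42 mV, Ba −170 ± 40 mV,
Mg −88 ± 20 mV) and densities descending Ca > Ba > Mg, matching the
qualitative image series. Fixtures are 128 × 128 px (430 nm pixels, i.e. a
55 µm field) with a 45 µm aperture — a deliberately down-scaled field; the
package default aperture remains 100 µm.

What the simulator does *not* emulate: optical phase matching and the Gouy
phase, polarization response beyond the all-P geometry, membrane drift,
flat-field structure, and camera read/EM noise. Tests passing on synthetic
stacks therefore validate the estimators' statistical behaviour, not the
instrument model.

## Autocorrelation analysis

`sacf()` computes the mask-aware spatial autocorrelation of one frame by
FFT, zero-padded to twice the linear size so no wrap-around occurs, and
normalizes each lag by its mask-overlap count before radially averaging into
1-pixel annuli. The overlap normalization removes the edge bias a circular
aperture would otherwise imprint. The FFT route is verified against a direct
$O(N^2)$ sliding-shift oracle to $10^{-10}$.

For Gaussian-profile domains the SACF is Gaussian with
$\sigma_{\mathrm{SACF}} = \sqrt{2}\,\sigma_{\mathrm{spot}}$, so
`estimate_radius()` reports SACF-FWHM$/\sqrt{2}$ as the single-domain
radius (convention `"single_domain"`); the raw SACF FWHM is available as
convention `"sacf_fwhm"` because published characteristic radii do not
always state the deconvolution. The lag-0 bin carries the shot-noise spike
and is excluded from the Gaussian fit by default.

Two finite-size effects matter and are visible in the tests: the
mean-subtraction of a frame tilts the ACF tail by roughly the bright-area
fraction of the field (the Gaussian-spot check is run on a field much larger
than the spot), and overlapping domains broaden the SACF at high surface
density (the radius round-trip is validated on sparse fields; recovery
across radii 0.8–3.0 µm has a median error well under 10%).

`tacf()` averages per-pixel temporal autocorrelations over the aperture.
Per-pixel mean subtraction biases every lag of a length-$T$ series downward
by about $(1 + 2\sum_k \rho_k)/T$; `estimate_lifetime()` therefore fits
$A e^{-k/\tau} + c$ with a free offset. When the lag-1 correlation falls
below 0.2 the dynamics are unresolved at the frame time and only the upper
bound — one exposure, 560 ms — is reported, which is the regime the real
domains occupy. A further caveat: because detection is quadratic in the
potential, domain *pairs* contribute a $\tau/2$ component to the intensity
ACF; lifetime recovery is accurate in the sparse regime (the validation uses
about 5 domains in a 22 µm aperture) and biased low at high density.
A static stack has no temporal variance; it is returned as a unit
correlogram flagged `static` rather than as 0/0.

## Calibration and potential mapping

Sweeping an external bias $U$ across the membrane shifts the potential
difference, so the mask-averaged intensity traces the parabola
$I(U) = \mathrm{scale}\,(U - \mathrm{vertex})^2 + \mathrm{baseline}$ with
the vertex at $U = -\Delta\Phi_0$. `fit_bias_calibration()` solves the
three-parameter least-squares problem (global by default; per-pixel mode
exists but is noisier) and requires at least three distinct biases.
`intensity_to_potential()` then inverts pixelwise:
$|\Delta\Phi_0| = \sqrt{\max(I - \mathrm{baseline}, 0)/\mathrm{scale}}$.

The modulus square erases the sign of $\Delta\Phi_0$. The sign is supplied
per run from chemistry — negative for divalent cations binding the anionic
leaflet, matching the reported negative potentials — and recorded in the
map's metadata. Recovering it physically would need phase-resolved
(interferometric) SH detection, which is out of scope.

## Thermodynamic and mechanical maps

With $\Delta\Phi_0$ in hand, three desk conversions follow, all linear or
monotone and all parameterized in one place:

* surface charge density, parallel-plate capacitor across the hydrophobic
  core: $\Delta\sigma_0 = (\varepsilon_0\,\epsilon/d)\,\Delta\Phi_0$ with
  $\epsilon = 2.1$, $d = 4$ nm ($C = 4.648\times10^{-3}$ F/m², recomputed
  from the constants, never stored);
* binding free energy per divalent ion: $\Delta G = 2e|\Delta\Phi_0|/kT$,
  reported as a positive magnitude in kT at 298.15 K (the temperature is a
  parameter; the experiment does not state it);
* dissociation constant: $K_D = e^{-\Delta G}$ with $\Delta G$ in kT
  (identical to the molar $RT$ form), labelled in molar units by
  convention. Note: the tabulated constants this formula accompanies in the
  source literature are internally inconsistent with it by factors of
  2–7 (e.g. $e^{-28.6} = 3.8\times10^{-13}$, not $2.7\times10^{-12}$). The
  package evaluates the stated formula and leaves the discrepancy
  documented rather than reverse-engineered.

Domain statistics mirror the tabulated "Average" and "Domain" rows: the
average row derives every quantity from the aperture-averaged potential; the
domain rows are mean ± 1 SD over *per-domain* values. A transient domain's
characteristic potential is its patch amplitude, so `domain_values()` takes
the signed peak of each connected component on *single-frame* maps
(`domain_potentials()`); a 20-frame average would dilute a sub-frame-lifetime
domain about twenty-fold, and pixel means over a Gaussian patch understate
the amplitude by roughly 40%. Segmentation is median-smoothed thresholding
at background mean + 2 SD with a 4-pixel minimum component — a choice of
this package, exposed in the configuration.

## Flexoelectric curvature and topography

The trans-membrane field $E = \Delta\Phi_0/d$ bends the membrane:
$H = fE/(2\kappa)$, with flexocoefficient $f$ (default showcase value
$5\times10^{-19}$ C) and bending modulus $\kappa$ (default 15 kT, converted
with the same temperature as the thermodynamics). `curvature_bounds()`
evaluates the monotone closed form at the corners of an $(f, \kappa)$ box —
with the literature box $10^{-21}$–$10^{-18}$ C × 10–20 kT and
$\Delta\Phi_0 = 217$ mV it gives $3.3\times10^{-4}$–$0.66$ nm⁻¹. No single
potential reproduces both of the printed literature bounds
($3.6\times10^{-4}$ and $0.98$ nm⁻¹), so the function takes the potential
explicitly.

Topography reads "total curvature" as twice the mean curvature, giving the
small-slope Poisson problem $\nabla^2 h = 2H$ with the rim pinned
($h = 0$ where the membrane meets the aperture). Both the factor and the
boundary condition are this package's reconstruction choices and are
recorded in the output metadata. The 5-point discretization is solved by
sparse Cholesky factorization. On a grid-aligned square the solver converges
at second order (verified against a Fourier-series oracle); on a pixelated
disk the staircase rim contributes a first-order term to the maximum-depth
error, which still stays under 1% at a 200-pixel diameter.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(run_config(simulation = list(preset = "Ca")))
res$correlation$radius     # ~1.5 um domains
res$correlation$lifetime   # unresolved: < 560 ms
res$maps$summary           # Table-style averages and domain ranges
max(abs(res$topography$height))
```

The pipeline stages are: simulate (or load TIFF stacks), subtract the HRS
background, autocorrelation analysis, bias calibration on a synthetic sweep
of a uniform −200 mV membrane rendered with the same optical model,
single-frame potential mapping and domain statistics, and topography of the
representative frame (the frame with the largest aperture-mean potential
magnitude). All products are written as scaled TIFFs with YAML sidecars
(`tiff::writeTIFF` stores only [0, 1]; the sidecar records offset and
scale), plus a CSV summary and a run log with checksums.

## Problem sizes and numerical choices

The validation suite runs on deliberately small fields chosen to exercise
every code path with comfortable statistics: 64–128 px frames, 20-frame
stacks, 96 px fields for the radius round-trip, 100 simulation seeds for
lifetime recovery, and a 211 px grid for the disk topography check. Gaussian
and exponential fits use Levenberg–Marquardt with analytic-free restarts
over a small grid of width guesses; fits that fail after all restarts raise
an error with diagnostics rather than returning silently. Correlogram fits
stop at the first zero crossing so the negative tail (a finite-field
artifact) cannot drag the width. Degenerate inputs — constant fields under
the mask, empty or disconnected masks, sub-pixel domain radii, fewer than
three distinct biases — raise explicit errors or clamp with a warning, as
documented on each function.

## Known limitations

* The sign of every potential map is an input, not a measurement.
* Radius and lifetime estimators are validated in the sparse-domain regime;
  dense fields bias both (overlap broadening, quadratic-detection mixing).
* The capacitor and flexoelectric models are mean-field single-parameter
  conversions; ion-specific binding geometry, cation penetration and
  thermal undulations are outside their scope.
* Topography is reconstructed up to the stated factor-of-two and
  pinned-rim conventions; absolute heights inherit both choices. Because
  the model has bending but no surface tension, the aperture-mean curvature
  integrates into a large parabolic sag across the pinned disk; real
  membranes shed that mode through tension. The meaningful outputs are the
  spatial pattern of the deformation and comparisons across conditions
  (e.g. the Ca > Ba > Mg ordering of height fluctuations), not absolute
  depths.
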