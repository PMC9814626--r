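# shgmap

Quantitative maps of membrane potential, surface charge, ion-binding
energetics and flexoelectric curvature from wide-field second-harmonic (SH)
images of freestanding lipid bilayers.

## What it does, and for whom

A bilayer spanning a circular aperture emits coherent SH light only where
the two leaflets differ. For symmetric lipid composition the detected
intensity reduces to

    I(2ω, x, y) ∝ I(ω)² |χ⁽³⁾′ (Φ₀,₁(x,y) − Φ₀,₂(x,y))|²

so an SH image is, after background correction and calibration, a map of
the trans-membrane surface-potential difference ΔΦ₀. Divalent cations
(Ca²⁺, Ba²⁺, Mg²⁺) on one side create transient micron-sized domains of
ordered interfacial water that light up in this contrast. This package is
for experimentalists and modellers who want to go from such photon-count
image stacks (or from simulated ones) to:

- **ΔΦ₀ maps** via external-bias calibration of the quadratic SH response:
  `I(U) = scale·(U − vertex)² + baseline`, inverted pixelwise as
  `|ΔΦ₀| = sqrt((I − baseline)/scale)`;
- **surface charge density** through the parallel-plate capacitor model of
  the hydrophobic core, `Δσ₀ = (ε₀ε/d)·ΔΦ₀` (ε = 2.1, d = 4 nm);
- **binding free energy** `ΔG = 2e|ΔΦ₀|/kT` and **dissociation constant**
  `K_D = exp(−ΔG)`;
- **domain size and lifetime** from spatial/temporal image autocorrelation
  (SACF/TACF) with Gaussian fits — mask-aware, FFT-based, oracle-verified;
- **flexoelectric curvature** `H = f·ΔΦ₀/(2κd)` and membrane
  **topography** by solving `∇²h = 2H` with a pinned aperture rim;
- **synthetic SH stacks** with ground truth (Poisson-placed transient
  Gaussian domains, hyper-Rayleigh background, shot noise) for validating
  every estimator end to end.

## Worked example

```r
library(shgmap)
res <- run_pipeline(run_config(simulation = list(preset = "Ca")))
res$correlation$radius
#> Domain radius: 1.57 +/- 0.086 um (20 frames, single_domain convention)
res$correlation$lifetime
#> Domain lifetime unresolved (lag-1 TACF -0.0126): < 560 ms
res$maps$summary[1:2, ]
#>       quantity average domain_mean domain_sd domain_lo domain_hi n_domains
#> 1 potential_mV  -30.8       -305        71.4      -376      -233       335
#> 2  sigma_mC_m2   -0.143      -1.42      0.332     -1.75     -1.09      335
```

The Ca²⁺ preset plants 1.5 µm domains with sub-frame lifetimes and
amplitudes drawn from N(−287, 42) mV. The pipeline recovers the radius from
the SACF (1.57 µm), correctly reports the lifetime as unresolved at the
560 ms frame time, and the per-domain peak potentials (−305 ± 71 mV,
"Domain" row) bracket the planted distribution; the "Average" row is the
aperture-wide mean, diluted by the dark background as in the real images.
Charge, free-energy and K_D columns are desk conversions of the same
potentials; topography comes from the flexoelectric curvature of the
strongest frame. Running the Ba²⁺ and Mg²⁺ presets reproduces the
Ca²⁺ > Ba²⁺ > Mg²⁺ ordering in every derived quantity.

A thin CLI covers the same ground:

```sh
Rscript inst/cli/shgmap.R run --preset Ca --dir out/
Rscript inst/cli/shgmap.R fixtures --preset symmetric --dir fixtures/
```

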