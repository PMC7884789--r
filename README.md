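# fluorograde

Label-free discrimination of meningioma grades (WHO I/II) from non-tumoral
brain tissue using multiscale autofluorescence. The package implements the
full quantitative chain for measurements spanning deep-UV (275 nm)
micro-spectroscopy and two-photon NIR (810/890 nm) imaging:

* **Constrained Gaussian spectral unmixing** — emission spectra are fitted
  as sums of per-fluorophore Gaussians (tyrosine, tryptophan, collagen
  crosslinks, NADH, FAD, lipopigments, porphyrins, and the SHG line of
  fibrillar collagen under 890 nm excitation) with windowed peak positions
  and bandwidths; each component's *integral proportion* (Int) is its share
  of the total fitted area.
* **Molecular ratios** — Tryp/Tyr, Tryp/NADH, Tryp/Coll from deep-UV fits;
  the optical redox ratio FAD-Int/(NADH-free-Int + NADH-bound-Int +
  FAD-Int), the porphyrin/NADH (PN) and lipopigment/porphyrin (LP) ratios
  from 810 nm fits.
* **Spectral phasors** — first-harmonic Fourier coordinates (G, S) of each
  pixel spectrum, with a (peak wavelength × spectral width) reference grid
  and fluorophore fingerprint positions (NADH 495 nm, FAD 535 nm).
* **FLIM phasor analysis** — photon decays map to phasors at
  ω = 2π/(L·Ts); mono-exponentials lie on the universal circle, mixtures on
  chords. A count-weighted line fit through the pooled phasor histogram,
  intersected with the circle, yields the two component lifetimes
  (τ = S/(ωG)); projections onto the chord give long-lifetime intensity
  fraction (LLIF) histograms. Poisson-weighted bi-exponential fits
  (acceptance: reduced χ² in 0.8–1.2, weighted residuals within ±4)
  extract the protein-bound NADH lifetime from ROI-summed decays.
* **3D Gaussian-ellipsoid discrimination** — per tissue type, the
  (SHG-Int, Coll-Peak, Coll-Int) scatter is approximated by the Gaussian
  ellipsoid covering 60% of the probability mass (Mahalanobis² ≤
  χ²₃(0.60) ≈ 2.946). Gated rules classify control vs tumor (SHG-Int gate
  2.5) and grade I vs II (gate 22), scored by sensitivity Se = TP/(TP+FN)
  and specificity Sp = TN/(TN+FP); independent threshold rules cover
  Coll-Int (28), SHG-Int (2.5/22), bound-NADH lifetime (2.1/1.9 ns) and
  bound-FAD lifetime (0.7/1 ns).

A seeded synthetic generator (`tissue_preset()`, `simulate_*()`) emulates
per-grade spectra, hyperspectral cubes, TCSPC decay cubes and labelled
cohorts, so the entire pipeline runs and is tested without any instrument
data. See the methods vignette
(`vignettes/autofluorescence-grading.Rmd`) for the models, parameter
choices and limitations.

## Worked example

```r
library(fluorograde)

# a labelled cohort: 10 control, 7 grade I, 8 grade II samples
co <- simulate_cohort(10, 7, 8, seed = 1,
                      flim_shape = c(8, 8), photons_flim = 1e5)
res <- discriminate_cohort(co$features, indeterminate = "exclude")
res
#> <discrimination_result>
#>   control vs tumor:   Se = 1.000, Sp = 1.000
#>   grade I vs grade II: Se = 1.000, Sp = 1.000
#>   control-tumor overlap: 0 / 0
```

Both gated tests are perfect on this well-separated synthetic cohort and
the control and tumor ellipsoids do not overlap — the behaviour expected
when the collagen features of the classes are cleanly separated.

```r
# FLIM phasor lifetimes of the control FAD channel
img <- simulate_flim_image(tissue_preset("control"), "FAD", c(16, 16),
                           photons_per_pixel = 1e6, seed = 1,
                           llif = list(family = "uniform", min = 0.2,
                                       max = 0.8))
comp <- lifetime_components(fit_phasor_line(phasor_histogram(
  flim_phasors(img))), flim_omega(img$L, img$Ts))
comp
#> <lifetime_components> tau_short = 0.5386 ns, tau_long = 2.076 ns
```

The two universal-circle intersections recover the generating
protein-bound (0.55 ns) and free (2.1 ns) FAD lifetimes of control tissue.

```r
fit <- fit_spectrum(simulate_emission_spectrum(tissue_preset("grade2"), 890))
tidy(fit)[, c("fluorophore", "center_nm", "int_prop")]
#> 1 shg                 443      35
#> 2 nadh_free           465      16
#> 3 fad                 525      28
#> 4 lipopigments        585      17
#> 5 porphyrins_i        620       2.2
#> 6 porphyrins_ii       682       1.8
```

The grade II 890 nm spectrum unmixes to a dominant SHG contribution
(SHG-Int 35, above the grade II gate of 22), as expected for the dense
collagen network of atypical meningioma.

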