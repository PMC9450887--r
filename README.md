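# centriodyn

Quantitative analysis of centriole distal-end protein dynamics from
live-imaging experiments in syncytial fly embryos.

During the rapid nuclear cycles of early *Drosophila* embryos, centrioles
duplicate once per cycle: a daughter grows from the side of each mother while
cap proteins such as CP110 and Cep97 sit at the distal end of the centriolar
microtubules and the kinase Plk4 oscillates at the proximal end, timing the
growth of the central cartwheel. `centriodyn` implements the quantitative
machinery needed to study these dynamics:

* **Ring geometry from super-resolution images.** End-on centriolar protein
  rings are fitted with an elliptical annular Gaussian,

  `I(x, y) = B + A exp(-d(x, y)^2 / (2 w^2))`,
  `d = (sqrt((u/a)^2 + (v/b)^2) - 1) sqrt(ab)`,

  where `(u, v)` are centred, rotated coordinates, `a >= b` are the semi-axes
  (nm) and `w` is the ring cross-section width (nm). Centrioles viewed end-on
  are selected by ring eccentricity (`a/b < 1.2`, jointly with a paired
  reference marker), and radii are summarised as mean ± s.d.
* **Recruitment kinetics.** Per-centriole intensity tracks are aggregated
  into per-embryo mean ± s.d. profiles over the S-phase window (centrosome
  separation CS → nuclear envelope breakdown NEB), optionally
  background-subtracted, bleach-corrected, and scaled so the cycle maximum
  is 1. Four candidate temporal models — Lorentzian, Gaussian,
  increase–constant–decrease, increase–decrease — are fitted by least squares
  and compared with `BIC = n ln(RSS/n) + k ln(n)`. Peak intensity, absolute
  and S-phase-normalized peak centres, and time-to-peak are derived from the
  selected model.
* **Cross-embryo correlation.** Pearson correlation (with the
  `0.40 < r < 0.60` moderate / `r > 0.60` strong bands) between S-phase
  length and recruitment peak time.
* **Cartwheel growth and oscillations.** Linear-rise-then-plateau fits
  (`y = y0 + rate * min(t, period)`, size = plateau value) and oscillation
  amplitude/centre from the model repertoire.
* **Peak counting spectroscopy (PeCoS).** Background threshold calibration
  (Mean + 7 × s.d. of pooled control bins, valid when controls average
  fewer than 5 peaks per 180 s recording), supra-threshold peak counting,
  and the ROUT robust outlier screen (Q = 1%).
* **Synthetic data with ground truth.** Every estimator is driven and scored
  by a seeded generator that emulates the data structure: PSF-blurred noisy
  elliptical annuli, multi-embryo recruitment cohorts with programmable
  S-phase/peak-time coupling, growth series, and Poisson photon traces with
  concentration-dependent bursts.

## Worked example

```r
library(centriodyn)

# simulate a 20-embryo cohort: Lorentzian recruitment, frames every 30 s,
# peak time programmed as 0.5 * S-phase length
coh  <- sim_embryo_cohort(cohort_spec(), seed = 7)
prof <- preprocess_tracks(coh$tracks, coh$landmarks, scale_max1 = TRUE)
fits <- fit_embryos(prof, model = "auto")
table(fits$model)
#>
#> lorentzian
#>         20

correlate_peak_with_sphase(fits)
#> <sphase_cor> r = 0.886 (strong), p = 2.03e-07, n = 20
#>   peak_centre = -82.5 + 0.621 * sphase_length
```

The Lorentzian generator is correctly identified in all 20 embryos, and the
programmed coupling (slope 0.5) is recovered as a strong positive correlation
(`r = 0.89`, well above the 0.60 "strong" band).

Ring fitting works the same way:

```r
img <- sim_ring_image(ring_spec(a = 130, b = 100, w = 40, theta = 0.7))
fit_ring(img)
#> <ring_fit> radius = 115.0 nm (a = 130.0, b = 100.0, ecc = 1.300), w = 40.0 nm
#>   A = 1, B = 0.1, theta = 0.700 rad, rss = 4.39e-16, converged = TRUE
```

A complete simulate → fit → report run, with CSV/JSON artifacts carrying the
config hash and seed:

```r
run_pipeline(system.file("extdata", "demo-config.yaml",
                         package = "centriodyn"),
             seed = 1, out_dir = "centriodyn-out", verbose = TRUE)
```

See `vignettes/centriodyn-methods.Rmd` for the models, their assumptions,
and the numerical choices.

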