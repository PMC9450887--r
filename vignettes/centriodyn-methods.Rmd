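---
title: "Models and methods behind centriodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind centriodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centriodyn)
```

`centriodyn` analyses live-imaging measurements of centriole assembly in
syncytial fly embryos: the geometry of centriolar protein rings seen end-on
in super-resolution images, the S-phase recruitment kinetics of distal-end
cap proteins, cartwheel growth and kinase-oscillation parameters, and
photon-burst counting as a proxy for low cytoplasmic protein concentration.
This vignette describes the models, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical choices made where the procedures left freedom.

## Ring geometry: the elliptical annular Gaussian

An end-on centriolar ring in a 2-D image is modelled as

$$I(x,y) = B + A\, \exp\!\left(-\frac{d(x,y)^2}{2w^2}\right), \qquad
d = \left(\sqrt{(u/a)^2 + (v/b)^2} - 1\right)\sqrt{ab},$$

where $(u,v)$ are image coordinates centred on the ring and rotated by the
orientation $\theta$, $a \ge b$ are the semi-axes (nm), $w$ is the width of
the Gaussian ring cross-section (nm), $A$ the amplitude and $B$ the constant
background (a.u.). The distance $d$ is the *radial deviation scaled by the
geometric-mean radius* $\sqrt{ab}$, which gives $w$ proper length units and
reduces exactly to $r - r_0$ for a circle. The reported radius is the
arithmetic mean of the semi-axes, $(a+b)/2$, and the eccentricity is the
axis ratio $a/b$.

`fit_ring()` minimises the pixel-wise sum of squares over the 8 parameters
with bounded Levenberg–Marquardt (via `minpack.lm`). Numerical choices:

* **Initialization.** Centre from the intensity centroid after subtracting
  the image median; radius from the argmax of the azimuthally averaged
  radial profile; width from that profile's FWHM / 2.355; orientation and
  axis ratio from the intensity second-moment tensor. Because the
  orientation objective is multimodal, the optimiser is restarted from the
  moment-based $\theta$ and three rotated fallbacks and the best optimum is
  kept (with an early exit once an essentially exact fit is found).
* **Bounds.** Centre inside the field; $20\,\text{nm} \le a, b \le$
  field/2; $5 \le w \le 200\,\text{nm}$. These prevent the annulus-collapse
  degeneracy where the ring shrinks onto a blob.
* **Canonical form.** $a \ge b$ is enforced by swapping axes and rotating
  $\theta$ by $\pi/2$ when needed; $\theta$ is reported in $[0,\pi)$; for an
  exact circle the orientation is unidentifiable and 0 is reported by
  convention.
* **PSF.** By default the fitted model contains no PSF term, so the fitted
  $w$ absorbs the blur. This biases the radius of small rings inward: on
  noise-free rings blurred with a 60 nm PSF we measured a median radius
  bias of about $-8\%$ (up to $-28\%$ at 100 nm radius). When the
  instrument PSF is calibrated — which it routinely is on super-resolution
  systems — passing `psf_sigma` makes the forward model blur the ring
  before computing residuals, which removes the bias (median radius error
  well under 1% at 5% noise). This is the package's own design choice; both
  behaviours are exposed.

Rings viewed sufficiently end-on are selected by `select_oriented()`:
eccentricity < 1.2, applied jointly to a paired reference-marker ring when
one is available, so a centriole is kept only if both markers pass.

## Recruitment profiles and the four-model repertoire

Per-centriole intensity tracks are aggregated by `preprocess_tracks()` into
per-embryo mean ± s.d. time courses on the S-phase window, with time zero at
centrosome separation (CS) and the window ending at nuclear envelope
breakdown (NEB); mitotic frames are excluded. Options, in the order applied:
background subtraction (a supplied constant, else the embryo's 5th intensity
percentile — robust to the pulse occupying most of the window), bleach
correction (dividing by $e^{-t/\hat\tau}$ with $\hat\tau$ from a log-linear
fit to a whole-field reference series; identity when no reference is
supplied, to avoid inventing an uncited correction), aggregation to mean,
s.d. and n per time point, and optional scaling so the cycle maximum of the
mean is exactly 1.

The candidate temporal models for an S-phase recruitment pulse are

* Lorentzian: $y = B + A/(1 + ((t-t_0)/\gamma)^2)$, with $\gamma$ the
  half-width at half-maximum (the parameterization is declared here since
  width conventions differ between tools);
* Gaussian: $y = B + A e^{-(t-t_0)^2/(2\sigma^2)}$;
* increase–constant–decrease: continuous piecewise line with slopes $m_1$,
  0, $m_2$ and breakpoints $t_1 < t_2$ (5 parameters);
* increase–decrease: continuous piecewise line with breakpoint $t_b$
  (4 parameters).

Fits are unweighted least squares on the embryo mean curve (per-point s.d.
weights are available but off by default, since the object being fitted is
itself a mean profile). The smooth models use bounded Levenberg–Marquardt
with $A > 0$, widths positive, and $t_0$ confined to the window extended by
half an S-phase on both sides. The piecewise models are linear once their
breakpoints are fixed, so breakpoints are profiled over the observed time
points (keeping at least two points per segment) and then refined
continuously; the linear parameters come from exact least squares at each
candidate. Models are compared with
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln(n)$; the additive likelihood
constant cancels in comparisons. RSS is floored at $10^{-300}$ so an exact
fit on noise-free data yields a large negative but finite criterion. Ties
are broken toward fewer parameters, then the fixed repertoire order above.
A non-converged candidate is assigned infinite RSS so selection excludes it.

Peak metrics: peak intensity is the model maximum over the window
(evaluated on a fine grid); the peak centre is $t_0$ for the smooth models,
$t_b$ for increase–decrease, and the plateau midpoint $(t_1+t_2)/2$ for the
plateau model (the midpoint is a convention — the procedure this mirrors is
silent on it — and is configurable by reading `t1`/`t2` directly); the
normalized peak centre divides by the S-phase length, and a peak centre
outside the window sets an `out_of_window` flag rather than failing.

`correlate_peak_with_sphase()` computes Pearson's r between per-embryo
S-phase length and peak centre, the two-sided p-value via the t transform,
the least-squares line, and a strength label using the bands
$0.40 < r < 0.60$ moderate, $r > 0.60$ strong.

## Cartwheel growth and oscillation parameters

Cartwheel growth (tracked through incorporation of the core cartwheel
component Sas-6) is modelled as a linear rise to a plateau,
$y = y_0 + \text{rate}\cdot\min(t, \text{period})$, fitted with the same
profiled-breakpoint strategy. The derived size is
$y_0 + \text{rate}\cdot\text{period}$, enforced as an algebraic identity in
the result record. Monotone data with no plateau inside the window pin the
period at the window end and set a `boundary` flag — whether the "period"
should instead be a fitted pause with a later decrease is an open question
in the source material; the rise-plateau convention is the one implemented,
and the four-model repertoire remains available via `fit_recruitment()`.

Oscillations (e.g. centriolar Plk4 levels) are summarised by running the
four-model selection and reporting amplitude = peak intensity − baseline
(the fitted $B$ for smooth models, $y_0$ for piecewise ones — "amplitude"
is not given a formula in the source material, so the fitted-baseline
convention is declared here) and centre = peak centre.

## Peak counting spectroscopy

A PeCoS recording is a fixed-duration (180 s) photon-count trace. The
background threshold is calibrated on control recordings as
Mean + 7 × s.d., pooling all control bins (pooled statistics are
well-defined for unequal numbers of control traces; a per-trace-then-average
variant would differ only in the third decimal at these bin counts). The
calibration is valid when the controls average fewer than five counted
peaks per 180 s recording. A *peak* is one maximal contiguous run of bins
above threshold — robust to bin-to-bin noise inside one burst; counting
local maxima instead is possible by lowering `bin_width` and is left to the
caller, since the original peak topology is not specified. The acquisition
bin width is likewise unspecified; the generator default is 1 ms, a typical
photon-counting binning, and it is a free parameter throughout.

The ROUT screen removes outliers from a sample while controlling the false
discovery rate Q among removed points. The one-sample construction used:
robust centre = median; robust scale RSDR = 68.27th percentile of the
absolute residuals times $\sqrt{n/(n-1)}$; each point receives a two-sided
p-value from the t distribution (df = $n-1$) of |residual|/RSDR; outliers
are declared by a step-down sweep from the most extreme residual inward,
flagging point $i$ (in order of decreasing extremity) while
$p_{(i)} < Q\,i/n$ and stopping at the first failure. With Q = 1% and
n = 12, clean Gaussian samples lose a point in about 1% of replicates,
while a 10σ contaminant is removed in >99%.

## The synthetic generators

The generators define the study conditions under which every estimator is
validated; their defaults are fixed once and shared by the tests and the
acceptance script.

* **Rings** (`sim_ring_image()`, `sim_ring_set()`): the annular Gaussian
  rendered on a 64 × 64 grid at 40 nm/pixel (a typical reconstructed
  super-resolution pixel size), convolved with a Gaussian PSF (separable
  convolution, replicate padding — exact for a constant background), then
  corrupted with additive Gaussian or Poisson noise. Physical ordering:
  ring, then blur, then noise. Radii are drawn from 100–250 nm and axis
  ratios from 1.0–1.4, spanning centriolar ring sizes and the orientation
  filter's threshold.
* **Recruitment cohorts** (`sim_embryo_cohort()`): 20 embryos × 50
  centrioles by default (matching the reported group sizes), frames every
  30 s, S-phase lengths uniform on 420–900 s (the range of nuclear cycles
  11–13), peak time = 0.5 × S-phase + N(0, 30 s) so recruitment peaks near
  mid-S-phase, Lorentzian pulses with amplitude 1, baseline 0.1 and
  $\gamma$ = 120 s (FWHM 240 s), multiplicative lognormal per-centriole
  brightness scatter with CV 0.2 (mean exactly 1), constant background 0.1,
  additive Gaussian noise with sd 0.05 (5% of amplitude), and optional
  bleaching $e^{-t/\tau}$. All randomness derives from one top-level seed
  via per-embryo child seeds, so any embryo can be regenerated alone and
  identical spec + seed is bit-identical.
* **Matched-width repertoire.** When the four generators are compared (for
  model-selection validation) their parameters are matched so each produces
  a pulse with baseline 0.1, peak ≈ 1.1 and FWHM ≈ 240 s on a 40-point
  window: Lorentzian $\gamma$ = 120 s, Gaussian $\sigma$ = 240/2.355 ≈
  102 s, piecewise slopes $\pm 1/300$ (breakpoint 300 s) and plateau
  200–400 s. Matching the FWHM keeps the comparison about *shape*, not
  about trivially different widths.
* **Growth series** (`sim_growth_profiles()`): rise-plateau curves with
  rate 2/60 a.u./s and period 300 s (plateau size 10 a.u.) — a plateau
  near mid-S-phase as observed for cartwheel growth.
* **Photon traces** (`sim_pecos_traces()`): per-bin Poisson background
  (mean 50 counts/bin) plus burst events from a Poisson process whose rate
  is proportional to concentration; each burst adds Poisson counts around
  an exponentially decaying envelope (amplitude 200 counts, decay 5 ms,
  i.e. a millisecond-scale fluorophore transit). The true event count per
  trace is stored.

What the generators deliberately do **not** emulate: 3-D stacks and
reconstruction artifacts, spot detection and tracking (tracks are emitted
directly; the 1.1 μm tracking spot diameter is metadata only), mitotic-phase
intensities, mother/daughter assignment, and detector afterpulsing or dead
time in photon traces. Passing the validation suite therefore demonstrates
correct recovery of the stated models under realistic noise, scatter and
blur — not robustness to tracking errors or reconstruction artifacts in
real recordings.

## Validation design and problem sizes

The validation runs (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use: 50 rings per noise condition; 100 replicates
per generator for model selection (40 timepoints each); one 20-embryo
cohort for peak-time recovery and the positive correlation; 100 null-cohort
replicates for the correlation's specificity; 20 growth profiles at 5%
noise; 12 control + 5 × 50 sample PeCoS traces across a decade of transit
rates; 1000 ROUT replicates at n = 12; and two full pipeline runs compared
byte for byte. One sizing choice deserves a note: the null-correlation
check asks that |r| < 0.3 in ≥90% of replicates, but the exact null
distribution of Pearson's r at n = 20 (t transform, df = 18) places ~20% of
replicates beyond |r| = 0.3, so at that cohort size the check would fail
for purely distributional reasons no matter how good the estimator is. The
null cohorts therefore use n = 50 embryos, where the null probability of
|r| < 0.3 is ≈96% — a power calculation made before running the check, not
a tuned value. The positive-coupling cohort stays at n = 20.

## Known limitations

* The PSF-free ring fit (the default) reports a biased radius for rings
  whose radius is comparable to the PSF width; supply `psf_sigma` when the
  PSF is known.
* Bleach correction requires a reference series; no correction is attempted
  without one.
* The piecewise models assume continuity at breakpoints and at least two
  points per segment; profiles shorter than ~7 frames cannot support the
  5-parameter plateau model.
* Pearson's r and its t-based p-value assume roughly bivariate-normal
  scatter across embryos; with very few embryos the strength label is
  noisy.
* ROUT is implemented in its one-sample (constant-model) form; it is not a
  regression outlier screen here.
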