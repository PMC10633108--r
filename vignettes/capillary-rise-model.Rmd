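---
title: "Pressure-balance modelling of capillary rise in multi-bore strips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-balance modelling of capillary rise in multi-bore strips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capflow)
```

## The model and its assumptions

A wetting liquid dipped into a vertical microcapillary rises under the
Laplace pressure of its meniscus and is resisted by viscous friction and
by the growing hydrostatic head.  `capflow` models this as a quasi-steady
pressure balance: at every instant the three pressures cancel exactly and
the meniscus velocity is whatever makes them cancel,

$$u(H) \;=\; \max\!\left(0,\;
  \frac{\bigl(\Delta P_L - \rho g H\bigr)\, d_h^2}{32\,\mu\,(H + L_{dip})}
  \right),
\qquad
\Delta P_L = 2\,\sigma_{\!e\!f\!f}\left(\frac1a + \frac1b\right),$$

with $\sigma_{\!e\!f\!f} = \cos\theta\cdot\gamma$ the combined surface
drive, $a, b$ the full major and minor axes of the elliptical bore,
$d_h = 4A/P$ its hydraulic diameter ($P$ by Ramanujan's first
approximation, accurate to well below 0.01 % at these mild aspect
ratios), and $L = H + L_{dip}$ the total wetted length including the
submerged portion of the strip.

Assumptions worth keeping in view:

* **No inertia.**  The balance neglects fluid acceleration.  This is
  accurate except in the first fraction of a second after dipping, which
  is also where real image-pair velocity estimates are noisiest; the
  fitting stage down-weights that regime rather than modelling it.
* **Newtonian viscosity.**  Blood is shear-thinning, but at the wall
  shear rates of the fitted early phase ($\gamma_w = 8u/d_h \approx$
  100–800 s$^{-1}$ at 10–30 mm/s in 150–270 µm bores) a constant
  $\mu$ is a fair approximation.  Shear-rate-dependent rheology and
  diameter-dependent (Fåhræus–Lindqvist) effects are out of scope.
* **No meniscus retreat.**  Above the equilibrium height the net
  pressure would be negative; the model clamps $u$ at zero instead of
  describing backflow, which the device does not exhibit.
* **Flat front.**  The meniscus is rendered and tracked as a flat
  wet/dry transition; curvature imaging is beyond the synthetic optics.

At equilibrium the friction term vanishes and
$H_{eq} = \Delta P_L/\rho g$: equilibrium rise carries no viscosity
information at all.  `fit_from_equilibrium()` therefore returns
$\sigma_{\!e\!f\!f}$ with the viscosity explicitly marked *not
identifiable*; only transient data identify $\mu$, through the gravity
intercept of the $u$-vs-$1/H$ line.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `dip_depth` ($L_{dip}$) | m | 3e-3 | submerged strip length; regularises the $1/L$ startup singularity ($H(0)=0$ with the dipped portion filled) |
| `frame_rate` | s$^{-1}$ | 6 | recording rate of the emulated camera |
| `time_step` | s | 1e-3 | RK4 macro step; halving it moves final heights by $<0.05$ % |
| `height_noise_sd` | fraction | 0.01 | multiplicative measurement noise on recorded heights |
| `time_jitter_s` | s | 0.02 | half-width of frame-timestamp jitter, shared across capillaries within a frame |
| `aspect_ratio` | – | 1.2 | full-axis ratio $a/b$ of the bores; nothing in the device data pins it, so a mild ellipticity was fixed once |
| `diameter_cv` | – | 0.094 | lognormal bore-diameter spread, the spread-to-mean ratio of the smallest diameter class |
| `weight_u_threshold` | m/s | 0.02 | residuals above this velocity are down-weighted $\propto 1/u$ (timing noise dominates there) |

The generator's strip layout reproduces the melt-extrusion signature that
the middle eight bores run slightly wider than the outer two
(`edge_factor = 0.96`), with per-bore lognormal jitter on top.

## What the synthetic data emulate — and what they do not

`simulate_strip_array()` emulates the instrument's output: 12 strips × 10
bores sampled at 6 frames/s, per-bore elliptical geometry around the
printed mean diameters (156.3, 201.6, 261.2 µm), multiplicative height
noise, and frame-timestamp jitter (the jittered timestamps are recorded,
as a real camera records its own capture times).  `render_frames()` then
turns trajectories into grayscale frames — dark liquid columns on a light
background with a linearly anti-aliased meniscus edge and additive pixel
noise — from which `track_meniscus()` re-detects heights.

Real data differ in ways the synthetic stages deliberately do not
reproduce: wetting variability between bores beyond geometry (the
devices show more scatter in larger diameters), optical distortions,
illumination gradients, reagent-loading effects on surface properties,
and any spatial gradient of coagulation along the column.  Passing tests
therefore demonstrate that the *analysis* is correct and well
conditioned under the stated noise model, not that the instrument meets
the same error bars.

## The stimulation model

Thrombin-like stimulation is modelled as a single time-varying viscosity
multiplier
$$\mu(t)/\mu_0 = 1 + (k-1)\,\mathrm{logistic}\!\bigl((t - t_{on})/\tau\bigr),$$
with surface properties held fixed.  The dose mapping
($t_{on} = 5 + 25e^{-dose/30}$ s, $k = 1 + 5\,dose/(dose+25)$ capped at
6, $\tau = 1.5$ s) is a **synthetic stand-in**: the effective thrombin
concentration in the rising column is not experimentally accessible, so
the mapping was chosen once to place high-dose onsets within 10 s and
low-dose onsets between 10 and 30 s, with the ramp essentially complete
within about $\pm 2\tau$ of its centre.  When the multiplier reaches
`blockage_multiplier` (default 20) the column is treated as gelled and
frozen — stimulated strips eventually block rather than reach
equilibrium.  `classify_stimulated_series()` reads the story back off
velocity data by assigning each observation to the nearest member of a
fixed-multiplier curve family (ties resolve to the smaller multiplier,
the conservative call), reporting the first sustained departure from
baseline as the onset estimate.

## Numerical choices

* **Integrator.**  Explicit fixed-step RK4 on $dH/dt$ (default 1 ms
  macro step).  Each macro step is subdivided so that no substep gains
  more than `max_step_height` (0.05 mm); this startup refinement is what
  lets the same integrator handle the near-singular gravity-free limit
  ($L_{dip} \to 0$, $u \to \infty$ as $H \to 0$) used by the
  closed-form $\sqrt{t}$ verification.  No implicit solver is needed at
  these stiffness levels.
* **Optimiser.**  Box-constrained Levenberg–Marquardt
  (`minpack.lm::nls.lm`) on velocity residuals, started from a
  closed-form estimate.  The start exploits the fact that the full model
  is *linear* after the transform $u\,(H+L_{dip}) =
  (\sigma/\mu)\,x_1 + (1/\mu)\,x_2$, so ordinary least squares supplies
  consistent start values even where the $u$-vs-$1/H$ linearisation is
  biased by the dip depth; this makes the fit deterministic and immune
  to the $\sigma/\mu$ ridge that catches poorly started optimisations.
* **Clamping policy.**  Reported velocity series clamp negative finite
  differences to zero (a meniscus does not retreat) and flag them, but
  the fitter uses the raw differences: censoring the noise at zero
  would bias low-velocity points upward and inflate $\hat\mu$.
* **Sub-pixel tracking.**  The meniscus pixel is a partial-coverage
  pixel under the renderer's linear anti-aliasing, so the tracker
  inverts coverage directly (after calibrating wet/dry levels from the
  profile's own clearly-wet and clearly-dry medians, making it
  invariant to global intensity offsets).  This recovers heights to a
  few hundredths of a pixel; a plain midpoint-crossing interpolation
  was measurably worse (about 0.1 px of systematic sawtooth, enough to
  spoil 2 %-level velocity checks at low speeds).
* **Degenerate inputs.**  $L = 0$ is a singular-state error (callers
  regularise via the dip depth); axes must be ordered $a \ge b$;
  a non-negative gravity intercept marks the fit "gravity term not
  resolved" rather than returning a negative viscosity; equilibrium
  observations implying $\cos\theta > 1$ are infeasible-observation
  errors.

## Design choices that were genuinely open

* **Full axes in the Laplace form.**  The elliptical Laplace pressure is
  taken as $2\sigma(1/a+1/b)$ with $a,b$ the *full* axes, which reduces
  to the familiar $4\sigma/d$ for a circle.  A semi-axis reading would
  double the drive and is inconsistent with the circular limit.
* **Surface-property bookkeeping.**  Equilibrium-derived contact angles
  (static wetting, e.g. 61° for water with $\gamma = 72.8$ mN/m) and
  transient-fitted $\sigma_{\!e\!f\!f}$ (dynamic wetting, e.g.
  0.025 N/m for water, implying a larger dynamic angle) are kept as
  separate outputs and never reconciled into one angle — the two
  experiments measure different things.
* **Calibration fluids.**  The glycerol–water suite (0/20/40/60 % w/w at
  20 °C: $\rho$ = 998/1047/1099/1154 kg/m³, $\mu$ =
  1.005/1.76/3.72/10.8 cP, $\gamma$ = 72.8/71.0/69.5/67.5 mN/m) uses
  standard handbook values.
* **Fixed densities, bounded viscosities.**  Densities are never fitted
  (water 998, saline 1005, plasma 1025, whole blood 1055 kg/m³);
  viscosity boxes per sample class (water fixed at 1.04 cP, plasma
  < 1.7, red cells and whole blood 2–6) are applied as honest box
  constraints: when the truth lies inside the box the bound stays
  inactive, when outside the estimate sits on the bound and says so.

## Problem sizes used in the checks

The test-suite and acceptance studies run at sizes chosen to make each
statistical claim meaningful while staying desk-scale: 1000-draw
parameter sweeps for the closure and oracle identities; 12
fluid × diameter combinations integrated to $6$–$8$ characteristic times
for the equilibrium law; 45 s simulations at 6 frames/s (≈ 270 frames,
910 pooled velocity points per strip) for recovery studies; 200 seeded
replicates per diameter for the noisy-recovery success rate; and a
single-strip 45 s render→track round trip (≈ 271 frames of
750 × 91 px) for the imaging stage.

## Known limitations

Single time-varying $\mu(t)$ with no spatial gradient along the column;
no surface-property dynamics during stimulation; no shear-rate-dependent
viscosity (so the largest bores, where real data diverge from the
linear prediction, are least well served); velocity estimation assumes
monotone rise and a single meniscus per bore; the renderer's flat-front,
fixed-scale optics are far simpler than a real camera.  The dose →
$(k, t_{on})$ mapping is a labelled stand-in and should be re-estimated
from data before any quantitative dose claim.
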