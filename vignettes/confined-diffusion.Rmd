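---
title: "Measuring lipid diffusion in confined membrane geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lipid diffusion in confined membrane geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A supported lipid bilayer patterned with oxide walls confines lipids
inside micron-scale corrals that communicate with the surrounding lipid
reservoir only through narrow escape channels. Two classic fluorescence
probes then report *different* diffusion coefficients: FCS, parked at the
centre of a corral (beam waist w ≈ 0.191 μm ≪ corral radius R ≈ 12.25 μm),
sees free Brownian motion, while FRAP, which bleaches the whole corral and
watches refilling from the reservoir, sees an *effective* diffusion
coefficient throttled by the channels. confineR implements the full
quantitative machinery for this experiment: geometry description and
rasterization, a zero-flux finite-difference solver that replays the FRAP
protocol in silico, the Soumpasis and FCS fitting chains, a
Brownian-dynamics oracle, and the analytical narrow-escape models the
numerics are compared against.

# Models

## FRAP

For uniform-disk bleaching and free 2D diffusion the fractional recovery
is the Soumpasis closed form

$$I(t) = I_0 + \sum_n I_n\, K(T_n/t), \qquad
  K(x) = e^{-2x}\left[\mathrm{I}_0(2x) + \mathrm{I}_1(2x)\right],$$

with $\mathrm{I}_0, \mathrm{I}_1$ modified Bessel functions of the first
kind, $I_0$ the intensity just after the bleach, $I_n$ and $T_n$ the
amplitude and characteristic time of species $n$ (one species suffices
throughout). The characteristic time converts to a diffusion coefficient
through the bleach radius:

$$D = \frac{R^2}{4T}.$$

`fit_recovery()` performs an unweighted Levenberg–Marquardt fit with a
deterministic, derivative-free start: $I_0$ from the first post-bleach
point, the amplitude from the plateau, and $T$ from the half-recovery time
through kernel inversion ($K(x_{1/2}) = 1/2$, solved once by `uniroot`).
Unweighted least squares is the deliberate default — the simplest defensible choice when no
measurement-error model is available — and the residual RMS is always reported so
misfit is visible.

`fit_anomalous()` generalizes the kernel argument to $(T/t)^\alpha$. At
$\alpha = 1$ this reduces *exactly* to the Brownian model, which is the
property the package tests: a noiseless Brownian curve must return
$\alpha = 1.00 \pm 0.01$. Several anomalous-recovery parameterizations
circulate in the FRAP literature; the minimal exponent substitution with
an enforced Brownian reduction was chosen as the variant whose Brownian
limit is exact by construction; sub-diffusive synthetic curves ($\alpha = 0.7$) round-trip within
5%.

## FCS

The single-component 2D model is

$$G(\tau) = \frac{1}{N}\left(1 + \tau/T_D\right)^{-1}, \qquad
  D = \frac{w^2}{4 T_D},$$

with $N$ the mean molecule number in the detection area and $T_D$ the
transit time through the Gaussian detection profile
$\exp(-2r^2/w^2)$. `autocorrelate()` is a multi-tau correlator (8 points
per octave, trace re-binned by two per level) over binned intensity
traces; `fit_fcs()` uses the deterministic start $N_0 = 1/G(\tau_1)$,
$T_{D,0}$ = lag at half amplitude. Repeated acquisitions follow the
experimental protocol — 10 acquisitions of 5 s — and are combined by
`aggregate_acquisitions()`: arithmetic means of $T_D$ and $N$, with $D$
computed from the *averaged* $T_D$, not from per-acquisition D values.
`calibrate_waist()` exposes the dye calibration $w = \sqrt{4 D_{known}
T_D}$; the calibrant's reference D is user-supplied because no printed
value exists for it.

## Geometry and the unobstructed fraction

Three confinement families share one statistic, the unobstructed fraction

$$\sigma = \frac{n\,l}{2\pi R},$$

the fraction of the corral circumference open as escape channels
(`unobstructed_fraction()`). For the channel families the walls are
annular arcs of configurable radial thickness (default 1 μm) sitting just
outside the bleach circle. For the pillar family — four disks centred on
the square inscribed in the circle of radius R — the channels are not free
parameters: they are the four gap arcs between the pillar silhouettes seen
from the centre, so $\sigma = 1 - (4/\pi)\arcsin(a/R)$ for pillar radius
$a$. This closed form is inverted exactly by `sigma_sweep()` (no numerical
root-finding is needed), and $\sigma \to 0$ coincides with pillars
touching. Beyond R = 12.25 μm the in-plane dimensions of fabricated patterns vary
between experiments, so all dimensions are configuration-driven with
these defaults.

Rasterization uses a cell-centre inclusion rule on a square grid (cell is
obstacle iff its centre lies inside a shape); the mask is the single
source of geometric truth shared by the PDE solver and the
Brownian-dynamics engine. Requested spacings that cannot resolve the
narrowest channel (coarser than a quarter of it) are rejected rather than
silently smoothed.

## The obstructed-diffusion solver

`simulate_frap()` replays the experiment: concentration 1 everywhere,
multiplied by $1-\text{depth}$ inside a hard-edged bleach disk (depth 0.9
by default, a deep bleach; no Gaussian edge, no acquisition photofading),
then explicit five-point FTCS integration of the diffusion equation with
zero-flux conditions into obstacle cells and across the outer domain
edge, recording the mean concentration over the bleach disk.
`effective_diffusion()` then applies *the same fit used for experimental
data* — this "analyze the simulation like the experiment" loop is the
package's core measurement.

Numerical choices, each backed by a test:

* **Scheme**: explicit FTCS with $\Delta t = 0.2\,\Delta x^2/D$, safely
  inside the stability limit 0.25. A point source must match the 2D heat
  kernel to < 1% L2 error at the default 0.1 μm spacing.
* **Conservation**: fluxes are pairwise antisymmetric, so mass over open
  cells is conserved to machine precision (tested at < 1e-10 relative per
  simulated second through pillar obstacles).
* **Resolution**: default spacing 0.1 μm (a tenth of the narrowest default
  channel); halving spacing and time step moves the fitted effective D by
  < 2%.
* **Reservoir**: the experiment's outer bath is effectively infinite; the
  solver uses a zero-flux box instead of inventing a Dirichlet value.
  With the default half-width of 8 bleach radii the plateau bias is below
  1%. Desk-scale sweeps in the tests use half-widths of 2.5 R, where the
  depleted-reservoir bias on the recovery *plateau* is several percent;
  all sweep results are therefore reported as the ratio
  $D_{\rm eff}/D_0$ against an identically discretized unobstructed run,
  which cancels the shared bias — the same normalization the experimental
  protocol uses against outside-pattern measurements.
* **Recording windows**: absolute-recovery checks record to ≈ 5 fitted
  recovery times; σ-sweeps record to $12\,T_{\rm free}/\sigma$ so slow,
  nearly sealed corrals still show curvature to fit.

## Brownian-dynamics oracle

`brownian_evolve()` moves point tracers with Gaussian steps of per-axis
variance $2D\Delta t$, reflecting specularly off obstacle cell faces
(axis-split; corner-trapped moves are rejected in place and counted) and
off the outer box walls. The default step keeps the RMS displacement at
half a grid cell — small enough that boundary-crossing artifacts sit
below the Monte-Carlo noise of every equivalence test, while keeping
10⁴-tracer FRAP-equivalence runs to seconds. (A much smaller step was
considered and rejected: it buys no visible accuracy at these grid
resolutions and makes the equivalence tests hundreds of times slower.)
The oracle closes three loops:

* Einstein relation: free-space MSD $= 4Dt$ within 3 standard errors.
* PDE equivalence: the tracer occupancy of the bleach disk reproduces the
  solver's recovery trace within Monte-Carlo error
  (`particle_frap_occupancy()`).
* FCS generation: `fcs_trace()` emits binned intensity traces under the
  Gaussian detection profile, with optional Poisson shot noise.

`escape_times()` samples narrow-escape first-passage times on the
*analytic* disk (reflecting circle, absorbing arcs, exact segment–circle
crossing and tangent reflection) rather than on the raster. The raster is
the right shared truth for solver/tracer equivalence, but first-passage
asymptotics are sensitive to boundary roughness at exactly the small-σ
window the narrow-escape comparison needs; the analytic boundary removes
that artifact. Censored walkers (cap: 60 R²/D) are reported, never
dropped.

## Narrow-escape comparison models

Four analytical descriptions of escape-limited transport are implemented,
transcribed from the narrow-escape literature, and *every transcription
is gated on the Brownian oracle* before use:

* **NET disk** (`net_disk()`): small-window asymptotics for one absorbing
  arc, mean escape time from a uniform start
  $\tau = (R^2/D)[\ln(1/\varepsilon) + \ln 2 + 1/8]$ with
  $\varepsilon = \pi\sigma$ the absorbing half-angle. Tested within 10% of
  the first-passage oracle for σ ≤ 0.05, with the deviation growing
  beyond — the model's documented validity edge.
* **Boundary homogenization** (`boundary_homogenization()`): the patchy
  boundary (n arcs, fraction σ) replaced by a uniform trapping rate
  $\kappa = \pi D / (L \ln[1/\sin(\pi\sigma/2)])$ per boundary period
  $L = 2\pi R/n$, giving
  $\tau = (R^2/D)[\ln(1/\sin(\pi\sigma/2))/n + 1/8]$. At σ = 1 this is
  exactly the absorbing disk, $R^2/8D$; at n = 1 and small σ it matches
  the NET expression — both limits are asserted in tests.
* **Rayleigh multipole** (`rayleigh_pillars()`): effective diffusivity of
  a square array of reflecting cylinders in the pillar area fraction
  $\phi = \pi a^2/(2R^2)$ (lattice constant $R\sqrt2$), with the
  square-lattice multipole correction
  $D_{\rm eff}/D_0 = 1 - 2\phi/(1 + \phi - 0.305827\phi^4/(1 -
  1.402958\phi^8))$: the dilute limit $(1-\phi)/(1+\phi)$ at small φ,
  collapsing toward zero as pillars touch.
* **Perturbation expansion** (`perturbation_pillars()`): the second-order
  series $D_{\rm eff}/D_0 = 1 - 2\phi + 2\phi^2$, a deliberately simple
  foil for the resummed Rayleigh form, cross-validated against the Rayleigh
  form within 15% over σ ∈ [0.4, 0.95], the moderate-fraction range where
  a truncated series is meaningful. This is the loosest of the four
  model transcriptions and is flagged as such.

**Escape-time → effective-diffusion mapping.** Escape-time models do not
live natively on the $D_{\rm eff}/D_0$ axis, and more than one mapping is
defensible. The package uses one documented bijection for all of them: $D_{\rm eff}/D_0 = \tau_{\rm ref}/\tau_{\rm model}$, where
$\tau_{\rm ref} = R^2/(8D)$ is the same fully open (σ = 1, uniform start)
anchor. Because the mapping is shared and monotone, cross-model *ordering*
is independent of this choice, and the mapping lives in one place
(`tau_open_disk`) so an alternative (e.g. fitting simulated recoveries)
can be swapped in.

# The synthetic-data generator

`make_frap_dataset()` and `make_fcs_dataset()` emulate the study
conditions: FRAP recoveries at R = 12.25 μm with D = 2.92 μm²/s (the
outside-pattern coefficient) and a 0.9-depth bleach; FCS series of 10 × 5 s
acquisitions at a 191 nm waist. Detector noise is multiplicative Gaussian
on normalized FRAP intensity (1% default — a typical read-noise scale for
integrated-ROI traces) and Poisson shot noise on
FCS counts. Every dataset embeds its seed and derives per-trace sub-seeds,
so datasets are byte-identical under a fixed seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: raw image stacks and ROI extraction, photofading
during acquisition, bleach-profile softness, detector afterpulsing,
stage drift, and substrate-to-substrate variability. The generator tests
the analysis chain, not the microscope.

# Problem sizes and parameters

The package defaults are the experimental conditions (R = 12.25 μm,
D = 2.92 μm²/s, w = 0.191 μm, 0.1 μm grid, domain half-width 8 R). The
test suite exercises the same code paths at reduced sizes chosen as the
smallest problems that still discriminate the physics: bleach radii of
3–6 μm for sweep tests, half-widths of 2.5 R with ratio normalization,
500–10⁴ tracers for first-passage and equivalence oracles. The vignette's
companion acceptance checks run the full-size unobstructed round trip
(a ~10⁶-cell grid), the full 10 × 5 s FCS protocol, and the σ ≤ 0.05
narrow-escape ladder.

# Known limitations

* Strictly 2D: no interleaflet coupling, no 3D detection volume, no
  obstacle topography (the walls are only a few nm tall in reality, so the
  2D reflecting model is the natural idealization).
* The perturbation pillar model is a truncated stand-in (above).
* The correlator's mean-normalization gives the usual slight negative
  bias at lags comparable to the trace length; with 5 s acquisitions and
  ms transits this contributes ≲ a few percent to recovered D, well
  inside the stochastic tolerances used.
* Rasterized reflection is first-order accurate at obstacle faces; the
  narrow-escape oracle avoids this by using the analytic boundary.

# A worked example

```{r, eval = FALSE}
library(confineR)

# geometry: four channels, sigma = 0.125 at the fabricated radius
spec <- sigma_sweep("four_channels", 0.125, R = 12.25)[[1]]
unobstructed_fraction(spec)   # 0.125; arclength 2.4053 um each

# simulate the FRAP protocol and extract the effective D like data
mask <- frap_domain(spec, spacing = 0.15, halfwidth_factor = 2.5)
proto <- frap_protocol(bleach_radius = 12.25,
                       record_times = seq(0.5, 400, by = 2))
res <- effective_diffusion(mask, D_local = 2.92, proto)
res$D_eff

# compare against the analytical models on a sigma grid
tab <- compare_models("four_channels", c(0.1, 0.2, 0.4), R = 12.25)
tab
```
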