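---
title: "A stochastic spatial model of calcium sparks in RyR clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic spatial model of calcium sparks in RyR clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`crusparks` simulates elementary Ca²⁺ release events (sparks) from a single
cardiac calcium release unit (CRU): a cluster of ryanodine receptors (RyRs)
on the junctional sarcoplasmic reticulum (jSR) membrane, facing a narrow
dyadic cleft beneath a t-tubule. The scientific question the package is
built around is how two nanoscale properties of the CRU shape spark
dynamics: the *geometry* of the RyR cluster (compact, oblong, or dispersed
into sub-clusters, as observed in failing cardiomyocytes) and the *spatial
pattern of RyR phosphorylation* (none, uniform, concentrated in the cluster
centre, concentrated at the periphery, or a "blanket" sensitization of
every channel, the assumption most whole-cell models make).

The state of the system is a set of concentration fields on a voxelized
cube (1.008 µm side, 84³ voxels of 12 nm at the reference resolution):

* free Ca²⁺ `c` and four buffers (ATP, calmodulin, troponin C, Fluo-4) on
  the cytosolic domain,
* free Ca²⁺ `s` and calsequestrin on the SR domain (jSR slab + network-SR
  lattice, luminally connected).

Each species obeys buffered diffusion,

$$\partial_t c = D_c \nabla^2 c - \textstyle\sum_i R_i(c, b_i), \qquad
  R_i = k_{\mathrm{on},i}\, c\,(B^{\mathrm{tot}}_i - b_i) -
        k_{\mathrm{off},i}\, b_i,$$

with an analogous single-buffer system on the SR. The two domains exchange
Ca²⁺ only across membrane faces: through open RyR channels (flux
$\nu\,(s - c)$ per channel, spread over its 3×3-face footprint), and through
SERCA pump faces on the network SR, modelled as the steady-state cycling
rate of a three-state pump (two cytosolic Ca²⁺ bound per forward cycle, two
luminal Ca²⁺ per reverse cycle), which is uptake-positive at resting
conditions and vanishes on its thermodynamic equilibrium locus.

Every RyR is a two-state (closed/open) Markov channel. Both transition
rates are saturating functions of the *local* cleft Ca²⁺ concentration
(the mean over the cytosolic voxels facing the channel's footprint):

$$k^+(c) = f\!\left(\frac{c}{K^+}\right), \qquad
  f(x) = k_{\min} + (k_{\max} - k_{\min})\,\frac{x^\eta}{1 + x^\eta},$$

and the closing rate uses the same law with its own bounds (constant by
default). Phosphorylation acts solely through the half-saturation
concentration $K^+$: 55 µM for unphosphorylated channels, 25 µM for
phosphorylated channels in mixed patterns, and 45/35 µM for the blanket
pattern emulating 20 %/50 % discrete phosphorylation. Lowering $K^+$ can
only increase the opening rate at any concentration, which is the model's
definition of sensitization.

## Geometry generation

Five built-in 50-RyR layouts reproduce the compact (G1), oblong (G2) and
dispersed (G3: 2 sub-clusters, G4: 3, G5: 12) cluster archetypes, all on a
36-nm lattice with deterministic construction. The jSR is a one-voxel slab
directly beneath the RyR plane, padded laterally by one receptor width
(36 nm); a one-voxel (12 nm) cleft separates the jSR membrane from the
t-tubule exclusion slab above. The network SR is a cubic lattice frame of
one-voxel bars with a pitch of 168 nm, offset half a pitch from the cube
faces; a short luminal stalk connects each jSR island to the frame so the
whole SR is one connected lumen. The paper-level constraints this
construction is required to satisfy are *areas and volumes*, not
coordinates: with the default pitch the pump-bearing (nSR) face area lands
at 4.84 µm² for every built-in layout, inside the reference band of
4.54–4.85 µm². The connector stalks are treated as junctional plumbing and
carry no pump; this is what makes the area insensitive to how many
sub-clusters a layout has. Coordinates are voxel-centred, 0-based
internally, with the RyR plane at the mid-domain z-slice; layouts are
re-centred on the domain centre when gridded.

## Phosphorylation patterns

The inner/outer patterns implement the principal-component-ellipse
selection: channels are ranked by their normalized elliptical radius in
the eigenbasis of the 2×2 position covariance (coordinates projected on
each eigenvector, scaled by the square root of its eigenvalue). Shrinking
the PCA ellipse monotonically admits channels in increasing rank order, so
selecting the k smallest (inner) or largest (outer) ranks is the limit of
the shrink-until-k procedure without a step-size parameter. Ties are broken
by channel index; for multi-sub-cluster layouts the PCA is computed over
the whole CRU, not per sub-cluster, so "inner" means the centre of the
whole unit. A collinear layout has a zero-variance axis; its scale is
replaced by the 36-nm lattice constant (with a warning) rather than
failing. The uniform pattern samples channels without replacement with R's
RNG; `none` and `blanket` are the two trivial assignments.

## Numerics

The solver advances by first-order operator (Lie) splitting with step
`dt = 0.001 ms`:

1. **Diffusion** — explicit 7-point FTCS on each mobile species within its
   own domain, automatically substepped to satisfy the stability bound;
   internal SR/cytosol walls are no-flux (membrane exchange is its own
   operator). A Crank–Nicolson branch (`diffusion = "cn"`, cached sparse
   factorization) exists for desk-scale verification grids, where its
   second-order accuracy lets the operator be compared against a matrix
   exponential to 10⁻⁸.
2. **Buffering** — per voxel, each buffer relaxes along the *exact*
   solution of its linear binding ODE with free Ca²⁺ frozen at a midpoint
   estimate; the change is subtracted from the free pool. The update is
   second-order accurate and preserves the per-voxel total
   (free + bound) to machine precision.
3. **Membrane fluxes** — the RyR flux is stiff (a 12-nm voxel equilibrates
   with the SR in ~10 µs), so each open face's voxel pair is advanced by
   the analytic solution of the two-compartment exchange (the
   concentration difference decays as $e^{-2 g t}$), which is
   unconditionally stable and exactly conservative. SERCA uptake is
   applied per face with a positivity clamp.
4. **Gating** — on a channel clock `dt_gate` (default equal to `dt`),
   every channel draws one uniform variate in fixed index order and
   transitions with the exact constant-rate probabilities
   $1 - e^{-k\,\Delta t}$. All randomness flows through R's RNG, so a
   seeded run is bitwise reproducible.

The outer cube boundary is clamped to the resting composition by default
(an open-cytosol surrogate; the cell continues beyond the box); a sealed
mode exists and is what the conservation tests use, since only a sealed box
has an exactly conserved total. A simulation starts from the resting state
(buffers at binding equilibrium, so all reaction terms vanish) with one
uniformly chosen channel forced open, and terminates 1 ms after the last
channel closes — spark duration is by definition that termination time. A
hard cap (default 500 ms; 50 ms in the reduced preset) flags a record as
`capped` instead of raising.

The fluorescence read-out is the maximum of the bound Fluo-4 field, by
default blurred with a 3D Gaussian point-spread function of FWHM
410 × 410 × 800 nm (zero-padded; SR voxels carry no dye). ΔF/F₀ uses the
t = 0 baseline; a spark is successful when the peak reaches 0.3
(inclusive). Time to peak is measured from t = 0 (= the forced opening),
first maximum on ties. Whether to blur before thresholding is genuinely
open — both modes are provided (`psf$enabled`), the blurred one is the
default because raw voxel maxima saturate trivially at 12-nm resolution.

## Parameters

Concentrations are in µM, times in ms, lengths in µm (layouts in nm).
Buffer constants follow the values shared across dyadic-cleft models:
ATP (455 µM, fast/low-affinity), calmodulin (24 µM), troponin C (70 µM,
stationary), Fluo-4 (25 µM, K_d ≈ 1.1 µM), calsequestrin (30 mM on the SR,
K_d 630 µM); D_c = 0.22 µm²/ms, D_SR = 0.073 µm²/ms, resting Ca²⁺ 0.1 µM
(cytosol) and 1.3 mM (SR). These are plain config entries in
`default_params()` and everything is overridable.

The free gating/flux scales — `k_plus_max`, `nu_ryr`, `k_minus` — are not
printed quantities; they were fixed once with the package's own
`calibrate_ttp()` helper on the desk-scale reference setup (compact 16-RyR
cluster, 17³ grid at 36-nm voxels) so that unphosphorylated sparks land in
the physiological regime the model family targets: time to peak of a few
ms (target ≈ 7 ms), amplitudes around 0.45, durations near 10 ms, and
fidelity around 30 %. The calibrated defaults are `k_plus_max = 0.7/ms`
(η = 2.2), `k_minus = 0.5/ms` (mean open time 2 ms), and
`nu_ryr = 0.001 µm³/ms`. Calibration at the full 84³ resolution is a
cluster-scale exercise and is left to users with the hardware; the helper
works unchanged there.

## Desk-scale study conditions

The full experiment matrix of the reference design — 5 geometries × 8
phosphorylation setups × 200 runs at 84³ — is far beyond a single CPU, so
the package's tests and the acceptance script run a scaled-down version of
the same study: 16-RyR layouts (`desk_layout()`) on a 17³ grid of 36-nm
voxels, 30 runs per configuration. The `compact` layout is a single 4×4
cluster; the `dispersed` layout splits the same 16 channels into four 2×2
sub-clusters whose facing channels sit 72 nm apart — sized so that one
sub-cluster alone cannot
reach the detection threshold and spark success requires release to jump
between sub-clusters, which is exactly the regime where the spatial
phosphorylation pattern matters. Under these conditions the package
reproduces the qualitative structure of the full-scale findings: compact
clusters spark reliably without phosphorylation; dispersed clusters
essentially never do; sensitizing half the channels rescues sparking, and
centre-concentrated (inner) phosphorylation rescues it at least as well as
uniform, which does at least as well as peripheral (outer) — the ordering
is asserted only up to sampling error at 30 runs, because that is all the
effect sizes support at this scale.

What the desk scale does *not* show: absolute fidelity/amplitude/TTP values
comparable to the reference experiments (voxel volume, cluster size and
SERCA density all differ), the all-or-none bimodality of 50-RyR compact
clusters, or G5-style 12-cluster fragmentation. Those require the
reference resolution.

## Numerical choices and degenerate inputs

* Stability: the explicit diffusion substep count is
  `ceil(6 D dt / dx² / 0.9)` per species; negative concentrations abort
  with a diagnostic rather than propagating.
* The gating and PDE clocks are synchronized at multiples of `dt_gate`;
  channel order is fixed by index for reproducibility.
* Ties: rank ties in pattern selection break by channel index; ΔF/F₀ peak
  ties resolve to the earliest time.
* Degenerate statistics: a batch with zero successful sparks still reports
  its fidelity interval but flags amplitude/TTP/duration as unavailable
  (the 12-sub-cluster regime at full scale behaves this way); two
  constant equal samples compare with p = 1 by convention.
* The Agresti–Coull interval is used for fidelity (adjusted proportion
  $(x + z^2/2)/(n + z^2)$); means are reported ± standard error over
  successful sparks only, matching how the per-configuration n's in the
  reference experiments count successes. Welch's unequal-variance t-test
  is used for group contrasts (the variance differs visibly across
  configurations); percent values render at one decimal.

## Known limitations

* Operator splitting is first order; the spark statistics are
  dt-sensitive at coarse steps, which is why `dt` defaults to 1 µs and a
  halving-convergence check runs on a deterministic toy configuration.
* The SERCA cycle constants are thermodynamically consistent but not fit
  to pump data; at spark timescales uptake is a minor flux.
* The two-state RyR has no luminal-Ca²⁺ regulation, no coupled gating, and
  no multi-state inactivation.
* The optical model is an idealized Gaussian PSF without noise or
  line-scan synthesis.
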