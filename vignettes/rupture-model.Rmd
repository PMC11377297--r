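---
title: "Monte-Carlo modelling of cohesin ring rupture under DNA tether pulling"
author: "ringpull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo modelling of cohesin ring rupture under DNA tether pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringpull)
```

## The physical model

Cohesin is a ring-shaped SMC protein complex that topologically entraps
DNA. In the optical-tweezers assay this package models, a lambda-DNA is
tethered to a surface by both ends, a single cohesin ring is loaded onto
it, and a bead bound to the ring (or to a second, ring-captured DNA) is
pulled away from the DNA at constant velocity until the ring disengages
and the tension drops. The quantity of interest is the distribution of
rupture forces over many such pulls, and the two parameters that govern
it:

* `k0` (1/s) — the spontaneous rate of ring-interface disengagement at
  zero force;
* `delta` (nm) — a mechanical displacement parameter that sets how
  strongly force accelerates disengagement.

The disengagement is a Bell-model bond: `k(F) = k0 exp(delta F / kBT)`.
Larger `delta` means the interface is more force-sensitive and ruptures
at lower force; larger `k0` shifts ruptures earlier (and hence to lower
force) without changing the force sensitivity.

### Tether mechanics

The DNA is an inextensible worm-like chain. Tension at end-to-end
extension `L` follows the Marko-Siggia interpolation
(`wlc_force()`), with persistence length `P = 50` nm and contour length
`L0 = 16.32` um for lambda-DNA. The ring sits at the DNA's centre, so a
perpendicular displacement `x` of the ring from the anchor line puts the
chain in a V of total length `L = 2 sqrt((D/2)^2 + x^2)`, where `D` is
the anchor separation, and the ring feels `F = 2 F_DNA sin(alpha)` with
`tan(alpha) = 2x/D` (`tether_geometry()`).

When force is applied through a second, ring-captured DNA instead, the
bead-proximal chain (extension `L1`, tension `F1`) pulls on the middle of
the surface-tethered chain; force balance at the ring couples the chains:

* `F1 = WLC1(L1)`, `F2 = WLC2(L2)`,
* `F1 = 2 F2 sin(alpha)`,
* `(L2/2) sin(alpha) + L1 = x`, `tan(alpha) = 2 (x - L1) / D`.

Substituting the two closure relations gives
`L2 = 2 sqrt((D/2)^2 + (x - L1)^2)`: the system collapses to one strictly
increasing scalar equation in `L1`, which `solve_two_dna()` brackets and
solves with `stats::uniroot()` (the compiled simulation engine carries
its own safeguarded secant solver and is cross-checked against the R
path in the tests). Residuals of all five relations are reported through
an independent evaluator, `two_dna_residuals()`, and stay below `1e-8`.

A note on chain identities: as the closure relation is written, `L1` is
the chain pulled straight by the bead and chain 2 forms the V. Only this
reading makes the geometry consistent, so the package adopts it. The
bead-proximal chain in the experiment is the 7.2 kb circular plasmid;
its contour (7.2 kb x 0.34 nm/bp = 2448 nm) is the package's default for
chain 1 in the two-DNA scenario. With both chains at the lambda contour
the simulated mean rupture force falls to ~13 pN, well below the ~16 pN
the two-DNA experiment reports, because the overlong chain 1 slows the
force ramp too much; with the plasmid contour the simulation reproduces
the measured value. Both chains remain configurable.

### The stochastic pulling scheme

Each simulated event draws the anchor separation once from
`Normal(8.8, 0.5)` um (truncated to (0.1, 0.95) of the contour — draws
outside are unphysical), then advances `x` by `v dt` per step at
`v = 0.16` um/s. Every step evaluates the geometry, the WLC tension, the
Bell rate `k(F)`, draws a uniform `r` and forms the candidate detachment
time `t = -ln(1 - r)/k`; the ring disengages at the first step with
`t <= dt`, and the force at that step is recorded. This literal
draw-and-compare scheme is equivalent in law to a per-step Bernoulli
with `p = 1 - exp(-k dt)`, and the engine exploits the bound
`-ln(1 - r) >= r` to skip the logarithm on the (vast majority of) steps
where rupture is impossible.

The default time step is `dt = 0.01` s; 0.1 s is the coarse end of the
studied range, and the two agree within 3% in both moments (a standing
test). Pulls that reach the chain's extensibility limit (within
`1e-6 L0` of the contour) without rupturing are censored: excluded from
the force sample but counted and reported, never silently dropped or
clamped — at the strong-interface parameters the force tail approaches
high extension and silent clamping would corrupt it.

The initial displacement is `x0 = 0` (bead starts on the anchor line).
Forces are negligible until the chain is taut, so this choice shifts
rupture times only, not rupture forces.

Thermal energy defaults to `kBT = 4.114` pN nm (298 K), the
room-temperature single-molecule convention, and scales all forces
linearly at fixed lengths.

### What the simulation reproduces

```{r scenarios, eval = FALSE}
wlc <- wlc_params()
head_smp <- simulate_rupture_distribution(
  pulling_protocol(seed = 1), bond_model(0.0027, 1.23), wlc, n = 1e4
)
summary(head_smp)
```

With the head-pulled parameters (`k0 = 0.0027`/s, `delta = 1.23` nm) the
simulated distribution has mean ~20 pN and median ~24 pN; the
hinge-pulled parameters (`0.0025`/s, `1.61` nm) give median ~18 pN; the
strong-interface parameters (`2.7e-5`/s, `0.8` nm) put the peak at
~70 pN; and the two-DNA geometry with `k0 = 2e-3`/s and `delta` drawn
equiprobably from {1.23, 1.61} nm (the ring's orientation is random per
event) gives mean ~16-18 pN, strictly below the matched direct pull —
stretching two chains takes longer, the effective force ramp is slower,
and slower ramps rupture Bell bonds at lower force. All of these are
asserted by the test suite and recomputed by `scripts/acceptance.R`.

## Parameter estimation

`golden_search_fit()` estimates `(k0, delta)` from an observed
rupture-force sample by matching the simulated mean and standard
deviation, the moments through which the model's likelihood weight is
defined:

`P_i = exp{ -(mu_i - mean(F))^2 / var_mean - (sigma_i - sd(F))^2 / var_std }`

with `var_mean = s^2/n` and `var_std = s^2/(2n)` estimated from the
observed sample (the asymptotic variances of a sample mean and sd under
approximate normality; both can be overridden). The default objective is
the negative log of this weight; the raw, unweighted least-squares
distance between means and variances is available as `form = "raw"`.

### Why a nested golden search

Both moments are monotone in both parameters, which makes the
one-dimensional profiles unimodal — but the two moments trade off along
a narrow diagonal valley in `(log k0, delta)`: many parameter pairs
match the mean almost equally well, and only the sd resolves them.
Alternating single-coordinate contractions stall on the valley wall
(each coordinate looks converged while the joint optimum is far away).
The implementation therefore nests the searches: an outer golden section
on `delta` evaluates, at every trial `delta`, an inner golden section
over `log k0`; the outer objective is the profile
`min_k0 f(k0, delta)`, which is unimodal, and the stall disappears.

Every objective evaluation re-simulates with the same seed (common
random numbers), making the surface a deterministic function of the
parameters — golden-section bracketing on a noisy surface is otherwise
ill-posed. `k0` is searched in logarithm because it spans decades;
`delta` linearly.

Two practical controls trade accuracy against cost:

* `n_sim_refine` runs a second golden pass over a narrow box
  (±0.6 log-units by ±0.08 nm) around the first optimum at a larger
  simulation count, concentrating effort where Monte-Carlo noise limits
  precision. The attainable `delta` precision is roughly
  `se(sigma_sim) / |d sigma / d delta|` along the valley
  (~13 pN/nm at the strong interface), i.e. ~0.008 nm at
  `n_sim_refine = 3000`.
* `dt_sim_s` lets the objective simulate at a coarser time step than the
  protocol's. The moments carry a small discretisation bias (for the
  strong interface, sd is +0.09 pN at `dt = 0.02` vs 0.01 s), which the
  fit would absorb as a parameter shift, so for bias-free recovery the
  observed data and the objective should share one `dt`. The package's
  recovery analyses generate and fit at `dt = 0.02` s, inside the
  studied 0.01-0.1 s range, at half the cost of 0.01 s.

### Confidence intervals and stability

`likelihood_ci()` reproduces the Monte-Carlo likelihood sampling: one
parameter is scanned over a window around its optimum while the other
stays fixed; each scanned value is re-simulated, converted to the weight
`P_i`, and the central 90% of the normalised mass is reported. The scan
is a deterministic grid — uniform in `log k0` (a rate spanning decades;
positivity is automatic) and uniform in `delta` — rather than random
draws, so a run is exactly reproducible; the window widens automatically
until the endpoint weights are negligible. Because the off-parameter is
held at its optimum, these are partial (profile-style) intervals — the
mean constrains a fixed-`k0` `delta` scan steeply, which is why they are
much tighter than the joint along-valley uncertainty.

`bootstrap_stability()` refits subsamples drawn without replacement and
reports the dispersion of the recovered parameters; with the full sample
re-used (`subsample_fraction = 1`) the dispersion is exactly zero, and
it shrinks as subsamples grow. The same CRN seed is used for every
subsample fit so the dispersion reflects the data, not the simulator.

`ks_two_sample()` wraps the standard asymptotic two-sample
Kolmogorov-Smirnov test (`stats::ks.test`) for comparing rupture-force
distributions.

## The bead-attachment model

Force can only be attributed to a single ring if most beads carry one.
`sample_attachment()` implements the combinatorial capture rule: on a
DNA drawn from the occupancy distribution, each ring nucleates a bead
with probability `lambda`; remaining rings on the same DNA join that
bead with probability 1 if within 1 um of the nucleating ring, else with
probability `lambda`; captured rings are unavailable to later beads, and
rings are processed in random order (the prose rule does not specify an
order or whether far co-capture joins or nucleates — joining the
existing bead is the adopted, documented reading). Beads per DNA is
non-decreasing in `lambda`, so `calibrate_lambda()` bisects `lambda`
against an observed beads-per-DNA statistic (with common random numbers
across evaluations) and returns the implied rings-per-bead distribution.
The experimental occupancy distribution is not published, so
`generate_occupancy()` provides a synthetic stand-in: Poisson ring
counts per DNA, uniform positions.

## The synthetic-data generators

`generate_scenario()` packages the five study conditions — `head`,
`hinge`, `head_crosslinked`, `hinge_crosslinked_mixture` (a 50/50 draw
between the ~20 pN wild-type-like and ~70 pN crosslinked subpopulations,
reflecting the roughly half-and-half crosslinking yield), and `two_dna`
— with their fitted parameters and experimental sample sizes (89, 21,
24, 25, 41 events) as defaults. Each generator is a pure function of its
arguments and seed; a JSON sidecar records everything needed to
regenerate a dataset byte-for-byte. No measurement noise is added by
default (the generative model has none); optional Gaussian noise
supports robustness checks of the fitter. `generate_fd_trace()` replays
one seeded pull step by step into a full force-distance record whose
rupture force equals the event simulator's for the same seed.

What the generators do *not* emulate about real data: instrument noise
and drift, bead/trap compliance (the trap is a stiff displacement
clamp), multi-ring tethers and multi-peak force curves, the DNA
overstretching transition near 65 pN, and rebinding after
disengagement. Passing tests therefore validate the model and its
estimators under the model's own assumptions, not those aspects of the
experiment.

## Numerical choices and problem sizes

* Extensions within `1e-6 L0` of the contour are domain errors, never
  clamped; simulated pulls reaching them are censored and counted.
* Rate exponents above 500 are capped with a warning (rupture is then
  certain within any step).
* The two-DNA solver targets residuals below `1e-8` (relative); the
  engine's per-step solver converges to `|g| <= 1e-12 (1 + F1)` with a
  warm start from the previous step.
* Golden-section tolerances default to 0.01 in `log k0` and 0.004 nm in
  `delta`; a point bracket pins a parameter exactly.
* Distribution-level analyses use 10^4 events (the study's own
  simulation size); fits evaluate the objective with 800-3000 simulated
  events per candidate (first pass / refinement), which places the
  recovery noise well inside the reported confidence intervals; the
  likelihood scans default to a 1001-point grid, with coarser grids used
  in the test suite.

## Known limitations

* The moment-matching objective uses only the first two moments;
  strongly bimodal samples must be partitioned before fitting (the
  crosslinked-hinge analysis splits at 40 pN, the antimode between the
  ~20 and ~70 pN populations).
* The likelihood intervals are partial (one parameter fixed), so they
  understate the joint along-valley uncertainty; the bootstrap provides
  the complementary joint view.
* The recorded rupture force is the scalar ring tension; no transverse
  force components or bead geometry corrections are modelled.
* Censored pulls are reported but not used in the fit; at parameter
  sets where censoring is non-negligible the moment match would be
  biased low.
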