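# ringpull

Monte-Carlo simulation and fitting of protein-ring rupture forces under
DNA tether pulling.

Cohesin is a ring-shaped SMC complex that topologically entraps DNA and
holds sister chromatids together against spindle forces. In
single-molecule optical-tweezers assays, a bead attached to a DNA-bound
cohesin ring (or to a second DNA captured by the ring) is pulled at
constant velocity until the ring disengages; the distribution of rupture
forces over many pulls encodes the mechanical stability of the ring's
interfaces. `ringpull` is for biophysicists analysing or modelling such
experiments: it simulates the full pulling geometry and rupture
kinetics, and it estimates the ring's disengagement parameters from
measured rupture forces.

## The model

* **Tether mechanics** — the DNA is a worm-like chain (Marko–Siggia
  interpolation; default P = 50 nm, L0 = 16.32 µm for λ-DNA). Pulling
  the ring a distance *x* perpendicular to the anchor line (anchor
  separation *D*) puts the chain in a V:
  L = 2√((D/2)² + x²), F_ring = 2 F_DNA sin α, tan α = 2x/D.
  When force arrives through a second ring-captured DNA, the two chains
  couple through the force balance F1 = 2 F2 sin α and the associated
  closure relations, solved as a nonlinear system at every time step.
* **Rupture kinetics** — a Bell bond: k(F) = k0·exp(δF/k_BT), with k0
  the spontaneous interface-opening rate and δ the mechanical
  displacement parameter. Each time step draws a uniform r and ruptures
  when t_detach = −ln(1−r)/k(F) ≤ dt.
* **Estimation** — (k0, δ) are fitted by matching the simulated mean and
  standard deviation of the rupture-force distribution to the observed
  ones with a two-dimensional (nested/profiled) golden-section search
  under common random numbers; 90% confidence intervals come from
  Monte-Carlo sampling of the likelihood weight
  P_i = exp{−(µ_i−mean F)²/var_mean − (σ_i−sd F)²/var_std},
  and bootstrap refits check stability.
* **Bead attachment** — a combinatorial model of bead–ring capture with
  a single efficiency parameter λ, calibrated against the observed
  beads-per-DNA statistic to infer how many rings each bead reports on.

## Worked example

```r
library(ringpull)

wlc <- wlc_params()                       # lambda-DNA tether
proto <- pulling_protocol(seed = 1)       # 0.16 um/s, dt 0.01 s, D ~ N(8.8, 0.5) um

## rupture-force distribution for head-pulled cohesin
smp <- simulate_rupture_distribution(proto, bond_model(0.0027, 1.23), wlc, n = 1e4)
smp
#> <rupture_sample> n = 10000 events (0 censored)
#>   mean = 19.9 pN, sd = 8.85 pN, median = 22.7 pN

## refit the generated sample: recovers the generating parameters
proto2 <- pulling_protocol(dt_s = 0.02, seed = 2)
obs <- simulate_rupture_distribution(proto2, bond_model(0.0027, 1.23), wlc, n = 1e4)
fit <- golden_search_fit(obs, pulling_protocol(dt_s = 0.02), wlc,
                         n_sim = 800, seed = 3, n_sim_refine = 3000)
fit
#> <ringpull_fit> k0 = 0.002687 /s (not computed), delta = 1.231 nm (not computed)
#>   objective = 0.1857 (weighted), 368 evaluations x 800 simulated events, seed 3
```

The mean rupture force of ~20 pN with a median of ~23 pN reproduces the
head-pulled experiment; the refit lands inside the reported 90%
confidence intervals (k0 ∈ (0.0023, 0.0036) s⁻¹, δ ∈ (1.17, 1.29) nm).
Scenario generators (`generate_scenario()`) cover the hinge-pulled,
interface-crosslinked, bimodal-mixture and two-DNA experiments the same
way.

## Analysis workflow

The `analysis/` scripts run the package end to end and write their
tables under `results/`:

1. `01_simulate_scenarios.R` — rupture-force distributions per scenario,
   plus a force–distance trace.
2. `02_two_dna.R` — two-DNA pulling vs the matched direct pull.
3. `03_parameter_recovery.R` — refits of simulated datasets with
   confidence intervals and bootstrap.
4. `04_bead_attachment.R` — λ calibration and rings-per-bead
   distribution.

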