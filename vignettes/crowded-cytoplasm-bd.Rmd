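---
title: "Brownian dynamics of a crowded cytoplasm model: methods and design"
author: "crowdbd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian dynamics of a crowded cytoplasm model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`crowdbd` simulates concentrated protein solutions — the bacterial cytoplasm
being the motivating case — as flexible coarse-grained particles undergoing
overdamped Brownian dynamics in a periodic cubic box.

## Coarse-grained proteins

Each protein is a cluster of 1–5 spheres. The sphere count is a
piecewise-constant function of molecular weight (1 below 5 kDa, then one
more sphere per band 5–14, 14–23, 23–32, and 5 above 32 kDa). The bands are
treated as half-open `[lo, hi)`, so a protein sitting exactly on a boundary
(e.g. 14 or 32 kDa) belongs to the larger band; the boundaries are an
argument of `clusterCountForMW()` for users who prefer another convention.

Sphere positions come from k-means clustering of the C-alpha trace
(`kmeansCalpha()`: k-means++ seeding, 50 restarts of Lloyd's algorithm,
lowest within-cluster sum of squares wins, deterministic per seed — the
clustering itself does not prescribe an initialization, so we chose a
standard, reproducible one). Sphere radii are proportional to
n_residues^(1/3), so sphere *volume* is proportional to residue count; a
single global scale factor is then solved (by `uniroot` on the union volume,
to 1e-6 relative tolerance) so that the union of the spheres — overlaps
counted once — matches the all-atom reference volume. A literal
radius-proportional-to-n option (`proportionality = "linear"`) is provided
because the phrase "proportional to the number of residues" admits both
readings; the volume-proportional reading preserves mass density across
cluster sizes and is the default. When only the molecular weight is known,
the reference volume is MW × 1.21 Å³/Da, a standard protein partial
specific volume.

Union volumes are exact for one and two spheres (spherical-lens formula).
For three or more spheres the default is pairwise inclusion–exclusion with
triple overlaps ignored; for the chain-like geometries k-means produces,
triple overlaps are rare, and a Monte-Carlo estimator with a caller-chosen
sample count (`method = "mc"`) is available both as a cross-check and for
pathological geometries.

## Force field

Three harmonic terms, all in the convention **E = k·x² (no ½ prefactor)** —
the force constants are meaningless without this statement:

* stretching, over **every** intra-protein sphere pair,
  E_s = Σ k_s (l − l⁰)², k_s = 0.06 kcal/mol/Å²;
* bending, over every vertex-distinct triple,
  E_b = Σ g (θ − θ⁰)², g = 0.006 kcal/mol/rad²;
* inter-protein repulsion for overlapping spheres of *different* molecules,
  E_r = Σ k_r (σ − r)² for r < σ (σ = sum of radii), k_r = 0.1 kcal/mol/Å²
  by default (sweepable to 1.0).

Equilibrium lengths and angles are those of the reference (k-means) frame,
so a freshly built protein is at its energy minimum. Intra-protein pairs
never repel, regardless of distance. There are no electrostatics and no
attractive terms. Near-collinear angles are handled by clamping sin θ at
1e-8 in the gradient — a measure-zero configuration that would otherwise
produce NaNs. Forces are analytic and are tested against central finite
differences of the energies.

## Mean-field hydrodynamics

Rather than a mobility tensor, each sphere's diffusion coefficient is
rescaled by its local crowding:

* the **local volume fraction** φᵢ is the fraction of a cutoff ball of
  radius R_cut = 4aᵢ occupied by sphere volume: the sphere's own volume
  plus exact sphere–ball intersection volumes of all neighbors
  (minimum-image distances). Partial overlaps use the closed-form lens
  volume, not center counting.
* the **Tokuyama short-time function**
  H(φ) = 2b²/(1−b) − c/(1+2c) − bc(2+c)/[(1+c)(1−b+c)],
  b = √(9φ/8), c = 11φ/16, gives D = D⁰/(1+H(φ)).

Design choices worth stating:

* The sphere's own volume is **included** in φᵢ (the printed definition of
  the local fraction starts with the central sphere's volume). An isolated
  sphere therefore has φ = 1/64 and diffuses ≈2.6% below its
  Stokes–Einstein value. `includeSelf = FALSE` restores the strict dilute
  limit for users who prefer it.
* φ is clamped at 0.63 (random close packing vicinity). H(φ) diverges as
  φ → 8/9; transient deep overlaps during equilibration would otherwise
  stall or destabilize a run. The clamp is logged via the trajectory's
  `maxPhiSeen` metadata.
* A neighbor can contribute through at most one periodic image; the engine
  refuses to run with HI if 2·R_cut exceeds the box length.

## Propagation

The overdamped Ermak–McCammon update
rⁿ⁺¹ = rⁿ + (Dⁿ·Δt/k_BT)·Fⁿ + Rⁿ, with Rⁿ Gaussian, zero-mean, variance
2DⁿΔt per component, is applied with per-sphere, per-step effective D.
φ and forces are evaluated once per step at the current positions (explicit
scheme). The ∇·D correction for position-dependent diffusion is omitted —
deliberately, to match the scheme as defined; D varies weakly and smoothly
on the step scale. Mass never enters (the inertial Langevin form is
documented context only), D is a scalar per sphere, and rotational coupling
is not modeled.

Temperature and viscosity are not part of the model definition we inherited,
so the defaults are T = 298.15 K and η = 0.891 mPa·s (water at 25 °C), and
per-sphere dilute-limit coefficients come from Stokes–Einstein,
D⁰ = k_BT/(6πηa); all three are configurable and echoed into trajectory
metadata. In these units 1 Å²/ns = 10 µm²/s.

**RNG policy.** All noise comes from R's RNG (seeded by `config@seed`);
three normal draws are consumed per sphere per step, in sphere order,
whether or not the sphere is frozen and regardless of the HI/repulsion
toggles (φ evaluation consumes no randomness). A seed therefore yields the
*same* noise stream under every control setting, which makes paired control
experiments (HI on/off, frozen/mobile) seed-matched by construction, and
`hydrodynamics = FALSE` reproduces free-draining dynamics bit-for-bit.

**Numerics.** Pair interactions use a Verlet pair list rebuilt by a direct
O(N²) scan whenever any sphere has moved more than half the skin (default
10 Å) since the last build; at the system sizes this package targets
(N ≲ 10³) a flat pair list beats cell lists because the φ interaction reach
(4aᵢ + aⱼ ≈ 150 Å) is a large fraction of the box. Positions are integrated
unwrapped (so molecules are never split across the boundary and MSDs need
no reconstruction); wrapped coordinates and image counters are derived
views. A step larger than a stability bound (many standard deviations of
the free step) aborts the run with the offending sphere and step number —
the symptom of a too-large time step or an unrelaxed initial packing.

## Box assembly

`assembleBox()` inserts each molecule at a uniform random position and
orientation (quaternion-uniform rotations), accepting a placement when no
inter-protein overlap exceeds `overlapTol` (default 0.5 Å) under minimum
image. For dense packings, failed insertions fall back (relax = "auto") to
the least-overlapping candidate followed by steepest descent on the
repulsive energy with rigid whole-molecule moves, which preserves internal
geometry exactly and removes overlaps deeper than the tolerance. Everything
is deterministic per seed.

# Analysis suite

* `msdMultiOrigin()` — MSD(τ) = ⟨|r(T+τ)−r(T)|²⟩ over all overlapping time
  origins. Overlapping origins maximize statistics but are correlated, so
  spreads are *never* derived from origin scatter — only across blocks or
  trajectories.
* `fitAlpha()` — OLS of log₁₀MSD on log₁₀τ; slope = α (MSD ∝ τ^α).
* `estimateDBlocks()` — the block protocol: discard an initial transient,
  split into blocks, per-block log-log fit with the slope constrained to 1
  (D read off the intercept, 10^intercept/6); the free-slope α is reported
  alongside and the estimate is *flagged* when |α−1| exceeds a tolerance
  (default 0.25) rather than silently accepted.
* `timeDependentD()` — D(τ) = MSD(τ)/(6τ); decreasing during subdiffusion,
  flat in the normal regime.
* `displacementAutocorrelation()` — Cδ(t) = ⟨δr(T;δ)·δr(T+t;δ)⟩ over
  origins, raw and normalized by Cδ(0). Because the raw scale is
  arbitrary-looking in most published plots, both are returned; the
  fractional-Brownian-motion inversion always uses the normalized curve.
* `alphaFromMinCorrelation()` — inverts min C = 2^(α−1) − 1, the FBM
  increment-correlation relation; min C = −0.067 ↔ α ≈ 0.90.
* `gaussianityCheck()` — per-component excess kurtosis and KS distance
  against a matched Gaussian; a descriptive report, no hard threshold.
* `fgnSim()`/`fbmPath()` — exact fractional Gaussian noise by circulant
  embedding (Davies–Harte); the estimator-validation oracle with known α =
  2H and known increment correlation 2^(2H−1) − 1.

COM series weight spheres by volume (the residue-count proxy used to size
them); equal weights are one argument away. The minimum of the normalized
Cδ is located on the discrete grid t ∈ {δ, 2δ, ...} — with finite data the
minimum is at t = δ in every regime we simulate, matching the analytic FBM
location.

# What the synthetic generator emulates — and what it does not

`makeSyntheticProtein()` produces connected chains of 1–5 spheres with radii
in 10–30 Å, the size range of coarse-grained abundant bacterial proteins,
and valid all-pair topology; `assembleBox()` packs them to cytoplasm-like
occupied fractions (20–40%). This reproduces the *geometric and dynamic*
features that drive the model's claims: polydispersity, flexibility,
excluded volume, and crowding-dependent mobility. It does **not** reproduce
a real proteome's shape distribution (k-means clusters of real folds are
more anisotropic), its abundance spectrum, or any specific protein. Tests
passing on synthetic boxes therefore validate the simulator and estimators,
not biological numbers; reproducing measured diffusion coefficients
requires building the box from real structures and compositions, which the
builders support (`readCompositionTable()`, `buildCGProtein()`).

# Problem sizes used by the shipped checks

The packaged test-suite and the reproduction script are sized for a single
CPU:

* force/φ oracles: boxes of 34–100+ spheres, against O(N²) brute force;
* free-diffusion and HI-limit checks: 10⁴–2×10⁵ steps of a single sphere;
* control experiments (no repulsion; frozen vs mobile crowders): boxes of
  ~130–160 spheres at 30% occupancy, 2–5 µs per run;
* the paired HI-on/HI-off experiment: a 416-sphere box at 30% occupancy,
  10 µs per arm at dt = 0.01 ns, 16 tracer copies, block-MSD D estimates in
  the 50–500 ns window after a 1 µs discard. Ten microseconds per arm is
  the package's default protocol for this experiment: the without/with-HI
  ratio stabilizes well before that (the D estimators' block SDs are < 1%
  of D), and longer arms change the ratio only within its quoted spread.

# Known limitations

* The mean-field HI is scalar and local: no far-field coupling, no
  lubrication, no rotational hydrodynamics. It is the approximation whose
  consequences the control experiments probe, not a numerical shortcut.
* The repulsion is soft (harmonic); transient overlaps occur and deepen at
  higher temperature or larger dt.
* Pairwise-truncated union volumes slightly underestimate unions with
  triple overlaps; use the Monte-Carlo method where that matters.
* The anomalous-diffusion diagnosis tests FBM signatures only; it cannot
  exclude other subdiffusion mechanisms that mimic the increment
  correlation.
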