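---
title: "Quantifying vesicle deformation and rupture under shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle deformation and rupture under shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vesishear` analyses bead-resolution configurations of block-copolymer
nanovesicles — polymersomes self-assembled from PB5–PEO10–PB5 triblock
chains — under uniform shear. This vignette explains each method, its
assumptions and tunable parameters, the synthetic-data generator that
stands in for MD trajectories, and the numerical choices made where the
methods left freedom.

```{r setup, message = FALSE}
library(vesishear)
```

## The data model

A snapshot is a `bead_frame`: a tibble of beads with coordinates in nm,
a species per bead (`B` hydrophobic butadiene, `A` hydrophilic ethylene
oxide, `W`/`WF` solvent) and an orthorhombic box. Chains are 20 beads in
the B5–A10–B5 pattern, listed in a `chain_topology`. Readers exist for
GRO (nm), LAMMPS text dumps and XYZ (both Angstrom by default); no
periodic wrapping is applied on read — each analysis decides (clustering
supports minimum-image; shape, chain and contour analyses require whole,
unwrapped molecules and say so in their contracts).

## Aggregates and rupture

Two copolymer beads belong to one aggregate when their
centre-to-centre distance is strictly below the cutoff, 0.5 nm by
default — the non-bonded interaction range of the underlying
coarse-grained model. Aggregates are connected components of this
contact graph; the neighbour search uses cell lists (cells no smaller
than the cutoff) so cost grows linearly with bead count, and the
partition is tested against a brute-force all-pairs oracle. A pair at
exactly 0.5 nm is *not* bonded: the rule is a strict inequality, and
this boundary choice is observable in tests.

Chains are assigned to the cluster holding the majority of their beads,
ties going to the larger cluster. The rupture order parameter is the
fraction of chains in the largest cluster. Because no formal rupture
rule accompanies the reported rupture events, the detector here is a
declared convention: rupture is the first frame whose largest-cluster
fraction drops below 0.9 *and stays below it for 3 consecutive frames*.
The persistence filter prevents a transient neck-thinning frame from
being labelled a rupture; both threshold and persistence are arguments.

## Radial structure

`pair_correlation()` profiles the density of `B`, `A` or `W` beads
against distance from the unweighted centre of mass of a cluster:
shells of width `dr` (default 0.1 nm) are half-open — a bead on the
inner boundary is counted, one on the outer boundary belongs to the
next shell — and normalised by the mean density
`rho = 3 N_m / (4 pi r_max^3)`, `r_max` being the distance of the
farthest counted bead. Two conventions are worth stating: the centre of
mass weights all beads equally (bead masses are not part of the data
model), and the farthest bead, which the half-open rule would exclude,
is counted in the final shell so that shell counts always sum to `N_m`.

## Shape, orientation, volume

The gyration tensor is the mean outer product of centred positions; its
eigenvalues give the ellipticity `E = (lambda1 - lambda3) / (lambda1 +
lambda3)` (0 for a sphere) and its leading eigenvector the orientation
angles: `theta_V` between the x–y projection and the flow (x) axis,
`phi_V` between the x–z projection and the gradient-normal (z) axis.
Eigenvectors carry no sign, so both angles are folded to [0°, 90°].

Enclosed volume and surface area are computed by voxelisation (default
voxel 0.5 nm): beads are dilated by `bead_radius` (default 0.264 nm,
half a regular coarse-grained bead diameter), sub-probe pores are
sealed by morphological closing with a 2-voxel ball, the exterior is
identified by flood fill from the box boundary, and `V` is the volume
of everything not exterior — membrane plus enclosed solvent core, the
outer-surface convention. `A` is the area of the exterior-facing
surface, evaluated as the gradient-magnitude integral of a
Gaussian-smoothed (sigma 1.2 voxels) solid indicator; by the co-area
formula this measures the isosurface area without the ~1.5x staircase
bias of voxel-face counting, and it reproduces spheres to well under a
percent at the default voxel. If the flood fill reaches the structure's
centroid the shape is open: a warning is raised and `V` falls back to
the occupied voxels alone. The reduced volume is `nu = 3 V / (4 pi
R^3)` with `R = sqrt(A / (4 pi))` — the radius of the area-equivalent
sphere, the convention that is arithmetically consistent with reported
values of `V`, `A` and `nu` for tank-treading vesicles (`nu = 1` for a
sphere).

```{r}
reduced_volume(9506, 3447)
```

## Chain statistics and entropy

`Q` is the distance between a chain's first and last bead; a bond
longer than 1.5 nm is treated as evidence of an unwrapped-molecule
violation and errors. `p(Q)` is a histogram on a fixed-origin grid
(origin 0, bin 0.25 nm) and the configurational entropy is the Shannon
form `H = -sum p ln p` in nats. The literal printed form `sum p ln p`
is nonpositive and cannot "increase on broadening" as the accompanying
description requires, so the standard sign is used here. Entropy of a
binned pdf depends on the grid: comparisons are only meaningful between
identical grids, which is why the bin origin and width are fixed
arguments rather than data-driven.

Chain orientation `theta_c` is the angle between the x–y projection of
the end-to-end vector and the flow axis, folded to [0°, 90°] (chain end
labelling is arbitrary). Chains whose end-to-end vector has no x–y
projection are skipped and counted. Under isotropy the folded projected
angle is uniform — a chi-square test in the suite checks this.

## Contour profiles

The contour coordinate `s` runs around the vesicle outline from the
midplane of the upper bilayer, counterclockwise. Concretely: beads are
expressed in the principal frame of the gyration tensor; angular bins
about the centre of mass start centred on the `+lambda2` direction (the
"top") with `+lambda1` as the major axis, and `s` is the cumulative arc
length along the mid-radius polyline. Per bin, the bilayer thickness is
the spread between the 2.5th and 97.5th percentiles of radial bead
distance (percentile envelopes resist outlier beads; min/max would
not), the bead density is beads per nm of contour, and `Qbar(s)` is the
mean extension of chains assigned by their centre of mass.

Two measurement choices deserve emphasis. First, the thickness envelope
is evaluated in a ±2 nm slab about the principal plane — an equatorial
cross-section — because projecting all beads of a three-dimensional
shell onto the plane would mix polar beads into every wedge and destroy
the radial band; the density, by contrast, counts every bead in the
wedge so that density x arc length sums exactly to the bead count.
Second, for strongly waisted shapes a wedge along the major axis also
sweeps the near-axis membrane of the neck, so the envelope keeps only
the outermost contiguous radial band. Empty bins (a ruptured outline)
are flagged and carry `NA`.

## SASA

Shrake–Rupley construction: each bead carries a deterministic
golden-spiral point set (default 960 points) on its expanded sphere of
radius `bead_radius + probe_radius`; a point survives if it lies outside
every neighbour's expanded sphere, and the exposed fractions sum to the
area swept by the probe centre. Both radii default to 0.264 nm (the
solvent-bead scale); because the probe radius is a convention, SASA
values are only compared at a fixed probe, and the package reports the
radii alongside the area. The estimator converges monotonically in the
point count and matches the two-sphere spherical-cap closed form to
better than 1% at 4000 points.

## Flow dynamics

The Weissenberg number `Wi = shear_rate x tau` uses the relaxation time
`tau` of equilibrium shape fluctuations: the ellipticity
autocorrelation is fitted by a single exponential with `ACF(0)` fixed
at 1, over lags down to an ACF floor of 0.1 (the resolvable regime).
The fit is iteratively reweighted by the Bartlett variance of an AR(1)
sample ACF, which keeps long noisy lags from dominating. One point of
statistical honesty: a single 50,000-step series sampled at 0.05 ns
with `tau = 6` ns carries an information floor of roughly 7% relative
standard deviation for `tau` — no estimator beats it — so recovery
checks are phrased on the ensemble mean across seeds, and `tau_se`
accompanies every estimate.

The critical strain `gamma_c = shear_rate x t_rupture` decreases with
`Wi` above the rupture threshold, and is fitted by
`gamma_c = gamma_inf + (gamma* - gamma_inf) exp(-alpha (Wi - Wi*))`
with `(Wi*, gamma*)` anchored at the smallest-`Wi` rupturing point, so
the curve passes through the threshold exactly and only `alpha` and
`gamma_inf` are estimated (Levenberg–Marquardt, multiple starts). A fit
with `alpha <= 0` — critical strain not decreasing in `Wi` — is flagged
as misspecified.

```{r}
wi <- c(10.2, 12, 15, 18, 24, 30)
gc <- 8.52 + (62 - 8.52) * exp(-0.548 * (wi - 10.2))
fit <- fit_critical_strain(data.frame(Wi = wi, gamma_c = gc))
tidy(fit)
```

## The synthetic generator

`make_vesicle()` builds bead-resolution morphologies with the
statistical structure the analyses assume, so that every stage can be
validated against known ground truth without MD.

**Geometry.** Sphere (default: outer radius 16 nm, 3871 chains — the
full-size equilibrium system), ellipsoid, dumbbell (two spherical ends
bridged by a catenoid-like neck, profile Gaussian-smoothed so surface
normals vary continuously across the shoulder), and fragments
(separated mini-vesicles with prescribed chain counts). The membrane
thickness defaults to 5 nm, matching the measured equilibrium wall
thickness (4.8 ± 0.4 nm); the larger ~10 nm figure sometimes quoted
for the whole bilayer includes diffuse hydrophilic coronas that a
20-bead chain model compressed into two leaflets cannot span while
keeping the membrane connected. Thickness may be a function of the
polar angle for contour-varying membranes (dumbbells thick at the ends,
thin at the neck).

**Chain packing.** Anchors run along an equal-area spiral over the
outer surface at 0.42 nm steps, leaflets alternating slot by slot.
Each hairpin stands normal to the surface: two arms side by side
0.47 nm apart at 0.47 nm bead spacing, hydrophilic loop at the
interface, hydrophobic ends reaching to just short of mid-membrane,
with a 0.87 nm longitudinal stagger that sets the end-to-end distance
near 1 nm. The spiral layout is deliberate: consecutive outer/inner
deep arm ends meet at mid-membrane within the 0.5 nm cutoff, so the
intact membrane is a *single* aggregate by construction — isolated
radial hairpins at realistic chain counts could never percolate
laterally, and without connectivity the rupture order parameter would
be meaningless. The arm gap is 0.47 nm rather than 0.5 nm because a
pair at exactly the cutoff is not bonded under the strict rule. A
`stretched_fraction` of chains is laid tangentially as quasilinear
20-bead chains (~8.9 nm), optionally confined to the neck band —
reproducing the bimodal `p(Q)` of a deformed dumbbell. Solvent fills
the core (and optionally the exterior) on a cubic lattice at
8.4 beads/nm^3.

**Time series.** `make_ellipticity_series()` draws a stationary AR(1)
process — the discretised Ornstein–Uhlenbeck process — whose population
ACF is exactly `exp(-lag/correlation_time)`; `make_rupture_trajectory()`
scripts sphere → ellipsoid → dumbbell interpolation with neck thinning
and splits the structure into two aggregates at the first frame whose
strain strictly exceeds the prescribed rupture strain, with constant
bead count throughout. Every generator is bit-reproducible under a
fixed seed and leaves the caller's RNG stream untouched.

**What the generator does and does not emulate.** It reproduces the
geometric and statistical observables the analyses consume — interface
ordering in `g(r)`, shape anisotropy, thickness and density profiles,
hairpin/stretched extension statistics, connectivity and fragmentation.
It does not model forces, thermal disorder (beads sit exactly on their
constructed positions), solvent dynamics, or membrane fluctuation
spectra; passing tests demonstrate the correctness of the analysis
chain, not the physics of any particular force field. The hairpin
geometry is geometric, not fitted: no equilibrium end-to-end value is
available to calibrate against, so ~1 nm is a construction convention.
Where the membrane is thicker than the end-cap radius of curvature the
inner offset surface self-intersects and the cap fills in — recovered
"thickness" there reads the filled cap, which is why feasibility checks
reject thickness above the local diameter and the tests use feasible
shapes.

## Problem sizes and determinism

The full-scale system behind these methods (a 32 nm vesicle in a
200 x 80 x 40 nm box, 4.4 million beads, 50 ns of shear) is far beyond
what a test suite should build. The suite therefore exercises the
stages on vesicles of 150–3871 chains (3,000–77,420 beads), rupture
trajectories of ~10 frames at 500–1200 chains, AR(1) series of 5 x 10^4
steps, and Monte-Carlo oracles of 10^5–10^6 points — sizes at which
every tolerance stated in the tests is comfortably resolvable in a few
minutes on one core. All stochastic tests fix seeds; `run_pipeline()`
writes byte-identical CSVs for identical configs.

## Known limitations

- Orthorhombic boxes only; triclinic (sheared-box) input is rejected at
  parse time. Analyses of NEMD data therefore assume pre-unwrapped,
  rectangular-box configurations.
- The dimensionless shear rate relating membrane viscosity and bending
  modulus is out of scope, as are stress/viscosity computations and
  tumbling-regime classification.
- SASA is numerical (Shrake–Rupley), not analytic; absolute values
  depend on the probe convention and should be compared only within a
  fixed convention.
- The contour profiler requires the outline to be star-shaped about the
  centre of mass in the principal plane; heavily overhanging shapes
  (late-stage necks) violate this and are only qualitatively profiled.
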