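---
title: "Methods: lipid order, configurational dynamics, and water validation at a dual-membrane junction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid order, configurational dynamics, and water validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctlipid)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical choices behind them, and what
the synthetic generator does and does not emulate.

## The system and its coordinate conventions

The target geometry is a dodecameric channel spanning two parallel lipid
bilayers whose extracellular (EC) leaflets face each other across a
~3.5 nm gap — the architecture of a cell-to-cell junction.  Throughout
the package:

* coordinates are in Ångström; the junction axis is **z** and the
  junction midplane is z = 0;
* a density map's `origin` is the world position of the **center** of
  voxel (0, 0, 0); voxel indices are 0-based;
* subunit and rod labels are 1-based;
* the EC leaflet of each membrane is the one nearer z = 0, the IC leaflet
  the outward-facing one.

The D6 point group is realized as six rotations about z plus six 2-fold
rotations about in-plane axes at 30° spacing, so the two hemichannels are
related by the 2-folds in the junction midplane.  The operation set is
verified closed to 1e-9 at construction.

## Acyl-chain order parameters

For each acyl C–H bond, `S_CD = −⟨(3cos²θ − 1)/2⟩` with θ measured
against the bilayer normal.  The normal is fixed to z rather than
estimated per lipid: the junction geometry is planar, local-normal
estimation adds noise without changing planar-fixture results, and the
fixed normal matches common practice for flat bilayers.  Consequences:
+0.5 when bonds are locked perpendicular to z, −1 when parallel, 0 for
isotropic orientations; every reported value is range-checked against
[−1, 0.5] and violations abort.

Carbon numbering starts at the carbonyl (ester) carbon — position 1 —
so "carbons 4–11" means the mid-chain window where order parameters
plateau.  This is worth stating because force-field atom names are often
offset by one from chemical numbering.

Distance-resolved profiles average S_CD in contiguous 5 Å concentric
shells starting at distance 0 from the protein surface.  A lipid's
distance is the minimum heavy-atom-to-heavy-atom distance to the protein,
re-evaluated every frame; the choice of min-atom distance (vs center of
mass or phosphorus) is configurable in the code path and logged, since
reasonable conventions differ.  Shells are reported with `n = 0` rather
than dropped, so profiles align across runs.  Lipids from both membranes
pool together; EC and IC leaflets are averaged separately (they are
physically distinct populations).

The per-lipid scalar (`per_lipid_scd()`) is the unweighted mean of the
per-carbon time-averaged values over both chains restricted to carbons
4–11, suitable for coloring lipids by local ordering.

## Density maps

`compute_density_map()` replaces each selected atom with a normalized 3D
Gaussian whose standard deviation equals the atom's radius, sums over
atoms, and averages over frames, so the map integral (sum × voxel³)
equals the mean selected-atom count.  Numerical choices:

* **Truncation at 4 sd** per atom: < 0.01% mass loss at bounded cost.
* **Radii**: van der Waals defaults (H 1.2, C 1.7, N 1.55, O 1.52,
  P 1.8 Å), configurable — visualization tools differ in the radii they
  inherit, so the table is explicit rather than assumed.
* **Interpolation is trilinear everywhere** (resampling, symmetrization,
  σ lookups).  Trilinear error scales as (voxel/feature-width)²; the test
  fixtures choose voxel sizes accordingly.
* **σ statistics over the full grid**, not a mask, matching common
  map-contour conventions; `sigma_at()` returns −∞ for points outside the
  lattice so out-of-grid positions fail any contour test instead of
  erroring mid-pipeline.
* Out-of-extent atoms are truncated, never wrapped: fixtures are
  pre-wrapped and the analysis does not model periodic boundaries.

Run averaging requires identical lattices (within 1e-6);
D6-symmetrization averages the 12 rotated trilinear resamples and
zero-fills (with a count in a warning) samples that leave the lattice.

## Rod catalogue and configurational states

The EC-leaflet acyl density resolves into rod-shaped features.  The
catalogue thresholds the map at σ_min = 8 inside the leaflet z-slab,
labels 26-connected voxel components, and discards components under 20
voxels as noise.  Components are assigned to subunits by the angular
sector of their centroid (12 sectors of 30°), and numbered within each
subunit by increasing centroid radius with azimuth breaking ties.  Radii
are quantized (2 Å bins) before ordering: rods of a common lattice ring
differ in measured centroid radius only by sub-voxel noise, and without
binning that noise — not azimuth — would decide their order.  The
resulting numbering is deterministic and symmetry-consistent across
subunits.

Chain occupancy couples region and threshold: a carbon counts only when
its nearest voxel belongs to the rod's voxel set **and** the interpolated
σ at its position is ≥ σ_min, because interpolated σ can dip below
threshold near component edges.  A chain occupies a rod at ≥ 5 qualifying
carbons; when several rods qualify the highest carbon count wins, ties to
the lowest rod id.  States are ordered SN1-first ("i–j"); an unordered
rendering is available behind a flag.  Both chains in one rod is tracked
as "degenerate" rather than folded into "none", so its prevalence stays
visible.

The 15 Å protein-proximity criterion is evaluated **per frame** by
default (membership can toggle); a fixed-membership mode exists because
the alternative reading is defensible.  Dwell records are maximal runs of
identical labels over in-range frames; a lipid is "stable" when the
sequence of pair-states it visits (ignoring interleaved none/degenerate
frames) never changes, "transitioning" otherwise, and "unclassified" if
it never occupies a pair-state.

## Water validation

Three criteria per modeled water (oxygen position only — modeled waters
typically lack hydrogens):

1. ≥ 2 hydrogen-bond donor/acceptor partners: N/O atoms strictly closer
   than 4.0 Å.  This is distance-only; interactive tools supplement such
   screens with visual inspection and angle checks, which cannot be
   reproduced deterministically, so the strict distance rule is the
   reproducible core and an angle hook is left as an extension point.
2. σ ≥ 2.5 in **both** independent half-maps (AND semantics).
3. Supporting only: experimental map σ ≥ 5.3 and MD water-map σ ≥ 5.0 at
   the position.  The verdict requires criteria 1–2; criterion 3 is
   reported as an additional measure for weak experimental densities, not
   required.

Map lookups are point lookups at the oxygen position; a small
peak-search radius is a documented alternative but not the default.

## Model comparison statistics

Superposition uses the SVD (Kabsch) solution with det = +1 enforced;
"backbone" means N, CA, C, O, with a Cα-only mode for Cα r.m.s.d.
figures.  Atom pairing matches (chain, residue id, atom name) restricted
to residues present in both models; when no chain ids are shared, chains
pair in order and residues by global sequence alignment (gap opening 10,
extension 0.5), with the policy recorded on the pairing object.

RMSF replicates are each subunit of each run — a 12-subunit channel
simulated in two runs gives n = 24 replicate values per residue position;
the grouping is configurable since other replicate definitions are
defensible.  Each replicate is internally superposed to its time-average
before fluctuations are measured.  Confidence intervals are two-tailed
Student-t: mean ± t(0.975, n−1)·sd/√n, symmetric, zero-width when
replicates agree exactly.

## What the synthetic generator emulates — and what it does not

`generate_system()` builds a 12-wedge pseudo-protein spanning both
membranes (midplanes ±39.5 Å, head-group planes ±22 and ±57 Å, i.e. a
~3.5 nm EC–EC gap, matching the printed junction dimensions), four
leaflets of two-chain 14-carbon lipids with explicit hydrogens, and gap
waters with planted partner atoms.  Lipids are **posed geometrically,
not simulated**: the artifact tests analysis code, not force fields.

* **Order model**: per lipid-frame, a chain director tilted by
  |N(0, tilt_sd)| at uniform azimuth; all-trans chains except for
  per-bond 60° kinks with probability `gauche_prob`; C–H unit vectors
  perpendicular to the local chain direction at uniform azimuths.  For
  all-trans chains this gives the closed form
  E[S_CD] = 0.5 − 0.75·E[sin²α], which the generator records from its own
  tilt draws as the planted target.  Defaults: EC tilt sd 5°, no kinks
  (S_CD ≈ 0.49, deep in the gel regime — the planted contrast is
  deliberately strong); IC tilt sd 20° with 10% kinks (S_CD ≈ 0.17,
  a realistic fluid leaflet).
* **Rod lattice**: 19 sites per sector on rings at radii 26–56 Å with
  uniform angular spacing per ring (minimum site separation > 5 Å), chain
  start just above the EC head plane.  Planted rod maps use thin
  (σ 0.8 → 0.65 Å) Gaussian rods on a padded slab so rod voxels sit well
  above the 8σ contour while the rings stay separable.  Site numbering
  follows the same (radius, azimuth) convention as the catalogue, so
  planted and recovered labels coincide.
* **Kinetics**: rod-hopping lipids follow a stationary Markov chain over
  three candidate pair-states (stay probability 1 − dt/mean_dwell, other
  states uniform), giving a planted mean dwell of `mean_dwell_ns`
  (default 2 ns at 0.1 ns/frame).
* **Water scenes**: waters spaced so they cannot hydrogen-bond each
  other, partners planted at 2.8/3.0 Å pointing out of the water plane;
  half-maps add two independent Gaussian noise fields (default sd half
  the noiseless map's grid sd, which keeps decoy positions near 0σ and
  planted peaks tens of σ); an "MD" map contains a chosen fraction of the
  waters.

Not emulated: realistic energetics, head-group chemistry beyond a single
phosphorus, solvent dynamics, ions, membrane curvature, periodic
boundaries, and experimental map artifacts (local resolution variation,
masking, sharpening).  Passing tests therefore demonstrate that the
analysis correctly recovers planted geometric/kinetic/density truths at
realistic scales — not that it has been validated against experimental
heterogeneity.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive runs: the
ordered-EC reference fixture uses 200 EC lipids × 100 frames (seed 7 by
default); rod-catalogue fixtures use the full 228-rod lattice on ~0.55 Å
voxels; kinetic recovery uses 50 lipids × 2000 frames at the label level
and 8 lipids × 30 frames through the full geometric pipeline; CI coverage
uses 1000 simulated replicate sets of n = 24.  Every stochastic stage is
driven by an explicit integer seed, and the pipeline runner records
package version, parameters, seeds, and input checksums in a provenance
YAML next to each output.

## Known limitations

* No united-atom hydrogen reconstruction: S_CD requires explicit
  hydrogens and aborts otherwise, naming the carbon.
* The σ statistics assume the full grid is a fair background; heavily
  masked maps would need a masked variant.
* Only isotropic voxels and mode-2 MRC are supported.
* The rod catalogue keeps all components that survive the size filter;
  if more than 19 per subunit survive, they are reported rather than
  merged — how to merge supernumerary rods is left to the caller.
* Sequence-alignment pairing assumes standard amino-acid residue names.
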