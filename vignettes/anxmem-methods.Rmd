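---
title: "Methods: orientation scanning, interaction energetics and membrane response in anxmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation scanning, interaction energetics and membrane response in anxmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxmem)
```

# Scope and scientific setting

Annexin A2 (AnxA2) is a Ca²⁺-regulated peripheral membrane protein: a
compact disc of four ~70-residue repeats whose convex face carries
annexin-type Ca²⁺ sites. Its association with negatively charged
membranes (phosphatidylserine, PI(4,5)P₂) is mediated by Ca²⁺ bridges
and by direct lysine-lipid contacts, and the binding is believed to be
orientation-selective: only the convex-face-down pose aligns the Ca²⁺
sites with the membrane surface.

`anxmem` implements the *analysis* layer for studying this problem: it
builds protein-bilayer-Ca²⁺ systems in systematically varied
orientations, scores them with a simplified nonbonded interaction
model, profiles residue-level contacts against crystallographic Ca²⁺
sites, and quantifies the membrane's response (curvature and acyl-chain
order) to protein and ion binding. It does **not** run molecular
dynamics: trajectories are either supplied by the user (multi-model
PDB, or any reader producing the `md_trajectory` contract) or produced
by the package's own statistical pseudo-trajectory generator, which
exists so that every analysis stage can be validated against known
ground truth.

# System building

## Composition arithmetic

`composition_counts()` converts mole fractions into integer lipid
counts with **largest-remainder rounding**, so counts always sum
exactly to the requested total; per-leaflet splits halve each count,
with odd counts giving the extra lipid to the upper (protein-facing)
leaflet. The reference mixture POPC:DOPC:POPS:CHOL =
0.38:0.19:0.24:0.19 on 400 lipids yields 152/76/96/76; the
PI(4,5)P₂-containing variants (21%/3%, 12%/12% and 19%/5% POPS/PIP₂)
yield 84/12, 48/48 and 76/20. Headgroup charges are typed: 0 for PC,
PE and cholesterol, −1e for POPS, −4e for PI(4,5)P₂.

`neutralize_and_salt()` adds monovalent counter-ions so the net system
charge is exactly zero and `min(n_Na, n_Cl) = round(c · N_A · V)` pairs
provide the bulk salt (default 150 mM). Because the exact water count
of a solvated system is not recoverable from composition tables alone,
the free volume `V` defaults to the box volume minus a membrane and
interface exclusion slab of thickness `2·leaflet_z + 20` Å; this is an
explicit stand-in, not a solvation model.

## Orientation generation

The build pipeline mirrors standard practice for peripheral-protein
placement:

1. `principal_axis_align()` rotates the protein so its first and second
   principal axes lie along X and Y (flat over the membrane). The
   axis-sign ambiguity is resolved by requiring a non-negative first-atom
   coordinate along axes 1 and 2; axis 3 is their cross product, which
   forces a proper rotation. The sign rule matters because orientation
   labels are defined relative to this pose. Exactly isotropic or
   collinear atom clouds have no unique axes and raise an error
   (relative eigenvalue-gap tolerance 1e-8).
2. `rotate_about_com()` applies `R = Ry(θy)·Rx(θx)` about the centroid,
   right-handed, X first. The handedness convention is internal; the
   physically meaningful relations (e.g. two orientations differing by
   a 180° X-rotation) hold under any consistent choice, and that is
   what the tests pin down.
3. `generate_orientation_grid()` enumerates the Cartesian product of
   angle lists row-major (X outer), labelled `O1…On`. The default grid
   X ∈ {0, 60, …, 300} × Y ∈ {−60, 0, 60} gives the standard 18
   orientations with `O5 = (60°, 0°)` — the convex-face-down pose — and
   `O14 = (240°, 0°)`, its X-inverted counterpart.
4. `place_at_min_distance()` translates the protein along Z only until
   the minimum over *all* protein-membrane atom pairs equals the target
   (6 Å for the standard build; 2 Å for PI(4,5)P₂ systems, whose bulky
   headgroups would otherwise keep the protein out of contact range).
   All atoms, not only heavy atoms, enter the minimum — the stricter
   reading. The root is found to 1e-10 Å on the upper branch of the
   distance-vs-shift curve, so the protein always ends above the
   membrane; placement is idempotent and X/Y are untouched.
5. `seed_ions()` drops Ca²⁺ into the interfacial slab (between the
   highest upper-leaflet phosphate and the lowest protein atom,
   laterally within the protein's bounding box), uniformly with a
   2.5 Å minimum separation enforced by rejection; the RNG is seeded,
   so builds are reproducible. The standard build uses 12 ions.

## Interaction model

All energies use a deliberately simple nonbonded model
(`energy_params()`): Coulomb `k·q₁q₂/(ε·r)` with
`k = 332.0636 kcal·Å/(mol·e²)` and vacuum dielectric, plus
Lennard-Jones `4ε[(σ/r)¹² − (σ/r)⁶]` with Lorentz-Berthelot combining,
truncated sharply at 12 Å, over minimum-image distances in an
orthorhombic box. There is no switching function, no long-range
electrostatics and no solvent screening. Consequently **absolute
energies are not comparable to force-field enthalpies**; what the model
supports is everything relational: decompositions, thresholds,
rankings, profiles and correlations. `group_energy()` is exact (it is
tested against a naive all-pairs double loop at 1e-10 kcal/mol on
~2000-atom systems), symmetric and additive over disjoint partitions.

## Bound-ion criterion and enthalpy decomposition

A Ca²⁺ ion counts as *bound* when, with respect to **both** the protein
and the membrane, its interaction is attractive with magnitude at least
1 kcal/mol (`E ≤ −1`) **and** its minimal distance is below 10 Å
(`bound_ion_criteria()`). The energy threshold is read as a magnitude:
the selected ions are the ones interacting at least that strongly; the
opposite signed reading would keep only non-interacting ions, which
would contradict the quantity the criterion feeds. Classification is
monotone — tightening either threshold never adds ions — and is applied
per frame; time series then average the per-frame counts, which is why
the reported `n_bound_ca` may be fractional.

The binding enthalpy (`binding_enthalpy()`) is the sum of the
protein-membrane and protein-bound-Ca²⁺ terms. The membrane-Ca²⁺
energy is *excluded by definition*: it mostly reflects where the
charged lipids happen to sit, not the protein's binding.

# Residue profiles and orientation comparison

`min_distance_profile()` reports, per residue, the minimal distance to
a partner group and its inverse; time-averaged variants average the
*inverse* distance over the window, because that is the plotted,
contact-weighted quantity (a residue far away in half the frames and
bound in the other half should still stand out). Contact residues are
those with average minimal distance at or below 3 Å by default
(`identify_contact_residues()`); the threshold is configurable since
visual site assignment has no canonical cutoff.
`crystal_site_overlap()` then compares the observed residue set against
a reference list (e.g. crystallographic Ca²⁺ coordination sites read
from JSON) by exact set operations.

`rotational_rmsd()` compares orientations while *preserving their
membrane-relative pose*: the mobile backbone (N/CA/C/O) is translated
onto the reference centroid and rotated **about Z only**, by the
closed-form optimal angle `θ* = atan2(Σ(y_r x_m − x_r y_m),
Σ(x_r x_m + y_r y_m))` on centered coordinates. A full 3D Kabsch fit is
deliberately out of scope — it would rotate away exactly the
orientational difference being measured. The degenerate case (both
atan2 arguments zero) returns 0°. Per-frame RMSDs are computed first
and then window-averaged; averaging coordinates before the RMSD would
conflate fluctuation with displacement.

# Membrane response

## Curvature as phosphate z-shift

`z_shift_map()` uses the simplest leaflet-resolved bending descriptor:
each lipid's P-atom z minus the leaflet mean, so every map has exactly
zero mean by construction (cholesterol, which has no phosphate, is
excluded). `curvature_energy_correlation()` computes the Pearson
correlation between z-shift and per-lipid interaction energy over *all*
leaflet lipids — excluding zero-energy lipids would bias the
correlation — per frame, then averages over the window. Undefined
correlations (zero variance, fewer than 3 lipids) are reported as `NA`
with a reason rather than silently dropped; a leaflet whose lipids are
all beyond the interaction cutoff from the partner produces exactly
this, which is the expected signature of the non-interacting leaflet.

## Acyl-chain order

`scd_per_lipid()` computes the deuterium order parameter
`S_CD = ⟨(3cos²θ − 1)/2⟩` over all chain C-H bond vectors against the
bilayer normal. An all-trans chain along Z gives −0.5 exactly; the
magic angle (cos²θ = 1/3) gives 0; the reported value is the magnitude
|S_CD|, the convention of NMR-style ordering plots, with the signed
value retained. All chain carbons of a lipid are averaged (per-carbon
output would be a trivial extension; no canonical carbon subset
exists). `scd_vs_energy()` window-averages |S_CD| and the per-lipid
protein and Ca²⁺ energies, flagging *dual interactors* — lipids
interacting with both partners at ≥ 1 kcal/mol magnitude (no canonical
threshold exists; 1 kcal/mol matches the bound-ion energy scale).

# The synthetic-system generator

`synth_bilayer()`, `synth_protein()`, `synth_system()` and
`synth_trajectory()` produce systems and pseudo-trajectories whose
statistical structure is imposed, not emergent. The generator has no
physics; its single contract is that every quantity the analysis
modules estimate has a generator-side ground truth
(`oracle_statistics()`) computed from the internals.

* **Bilayer**: lipids on a square lattice at 65 Å² per lipid (a typical
  fluid-phase area), P planes at ±18 Å (a typical phosphate-phosphate
  half-distance), types shuffled by the seeded RNG. Each
  non-cholesterol lipid carries a P bead (holding the headgroup
  charge), 8 chain carbons at 1.5 Å spacing and two hydrogens per
  carbon at 1.09 Å. Cholesterol is a single neutral bead, so it is
  structurally excluded from curvature and order analyses, matching the
  analysis conventions.
* **Protein**: residues on the lower half of a flattened ellipsoid
  (convex face down), four-atom pseudo-backbones, charges on CA.
  Charged residues (LYS +1e, GLU/ASP −1e) are placed bottom-up on the
  membrane-facing face, so e.g. six lysines are the six
  membrane-closest residues in an upright placement. The distinct
  ellipsoid axes make the principal axes well defined.
* **Frames**: per frame, protein/ion/headgroup beads receive i.i.d.
  Gaussian jitter (default σ = 0.3 Å, a small-amplitude positional
  fluctuation); if curvature coupling is on, each lipid is displaced in
  z by `−A·Σ_ions exp(−d_xy²/(2λ²))` (defaults A = 2 Å, λ = 10 Å; the
  protein-facing leaflet at full and the opposite leaflet at half
  amplitude, so the distal leaflet follows the proximal one); chains
  are rebuilt each frame with per-carbon segment tilts
  `α ~ N(0, σ_tilt)`.
* **Order coupling**: the per-lipid tilt SD starts at `tilt_sigma0`
  (default 25°, giving |S_CD| ≈ 0.38) and is modulated by
  `1 − 0.5·exp(−d²/(2·15²)) + 0.5·F/F_max` — tighter chains (more
  order) under the protein footprint, looser chains (less order) where
  the ion field F is strong. These two opposite trends are exactly what
  the order-vs-energy analysis must be able to tell apart.
* **Phases**: the chain azimuth and C-H azimuths are drawn once at
  build time and reused across frames. Because the order parameter
  depends only on the tilt α and the C-H azimuth ψ (`H·ẑ = sinψ·sinα`),
  this gives an exact closed-form oracle
  `E[S_CD|ψ] = (3 sin²ψ (1 − e^{−2σ²})/2 − 1)/2` per lipid while
  keeping a zero-noise configuration bit-identical across frames.

`oracle_statistics()` reports (i) the imposed leaflet-centered
curvature field, (ii) its correlation with a generator-side interaction
proxy — the headgroup point charge at the P site against the partner
point charges, Coulomb within the generator's 12 Å locality scale — and
(iii) the expected per-lipid |S_CD| from the closed form above. The
proxy is an independent code path from the energetics module; its
locality truncation matters, because an untruncated 1/d sum is
dominated by long-range tails and no longer measures the *local* ion
proximity that drives the imposed field.

## What the generator does and does not emulate

It emulates: typed-lipid composition on two leaflets, charge structure,
an interfacial ion layer, frame-to-frame positional noise, an ion-tied
bending field and proximity-tied chain ordering. It does **not**
emulate lipid diffusion, conformational sampling, water, electrostatic
screening or any relaxation dynamics. Passing the recovery tests
therefore shows that the analysis estimators are *correct and
calibrated* on data of known structure — not that the synthetic data
resemble any particular experimental membrane.

## Parameter recovery

The validation configuration uses 200 lipids per leaflet, 50 frames,
the protein charged-face-down at 6 Å, and ions *scattered* uniformly
over the box above the upper leaflet rather than seeded under the
protein. The scatter placement is essential: it decouples the ion
field from the protein footprint, so the curvature-ion correlation is
strong (imposed, ~0.4) while the curvature-protein correlation stays
near zero — the contrast the analysis is meant to resolve. Under these
conditions the analysis recovers the oracle ion correlation within
±0.1, the (near-zero) protein correlation within ±0.1 of its oracle,
the population-mean |S_CD| within ±0.02, and the signs of both order
couplings. The per-lipid |S_CD| sampling error at 8 segments × 2
hydrogens × 50 frames is ~0.01, so the ±0.02 recovery statement is made
at the population level (mean absolute error over lipids), not per
lipid. The lower leaflet sits beyond the 12 Å cutoff from both
partners, so its correlations are reported `NA` ("zero variance") — the
expected non-interacting-leaflet signature, not a failure.

# Numerical choices and degenerate inputs

* Coordinates are Å internally; GRO nanometers are converted on I/O.
* Minimum-image distances require an orthorhombic box; `box = NULL`
  disables periodicity (used during building, where the protein starts
  far above the membrane and wrapping would be wrong).
* Atom pairs closer than 1e-6 Å raise a singularity error rather than
  returning astronomical energies.
* `place_at_min_distance()` brackets the upper root of the
  minimal-distance curve; a protein laterally outside the membrane
  footprint (no Z shift can reach the target) is an error.
* Equidistant targets in distance profiles are unproblematic (the
  minimum is well defined); ties in largest-remainder rounding are
  broken by position in the composition vector; the degenerate
  rotational-RMSD case returns 0°.
* Structure files carry no charges or LJ parameters; these come from a
  YAML/JSON table keyed by (residue, atom) with wildcard fallback, and
  an atom with no applicable record is an error, never silently zero.

# Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
systems: module tests on 80-lipid bilayers with a 20-60-residue
protein (~2000 atoms), property suites on randomized systems of the
same scale, and the recovery study on the 400-lipid, 50-frame
configuration (~8400 atoms, ~10⁶ pair interactions per frame). These
sizes were chosen so the full suite completes in a few minutes on one
CPU while keeping every estimator in its intended statistical regime.

# Known limitations

* The energy model is unscreened vacuum electrostatics with a hard
  cutoff; only relational statements (rankings, thresholds,
  correlations, decompositions) are meaningful.
* Salt counts are bookkeeping from an approximate free volume, not
  placed ions.
* The pseudo-trajectory is stationary white noise around a fixed
  configuration; nothing relaxes, drifts or diffuses.
* Binary trajectory formats (XTC/DCD) are not read; any reader
  producing `md_trajectory`'s frame-list contract can be plugged in.
* `as_membrane()` infers roles from atom-name conventions (`P`,
  `C<k>`, `H<k>…`); exotic naming schemes need an alias table or
  pre-processing.
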