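---
title: "Conservation-based capsid hot spots and their free-energy validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-based capsid hot spots and their free-energy validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidhot)
```

## The model

An icosahedral capsid is generated from its asymmetric unit — 1/60th of the
shell, holding T quasi-equivalent copies of the capsid protein — by the 60
proper rotations of the icosahedral group *I*. `capsidhot` treats two
questions:

* **Prediction.** Which interface residues are plausible self-assembly hot
  spots? The working hypothesis is evolutionary: a residue that has been
  conserved across a virus family both *in sequence* and *in its
  quaternary-structure position* at a subunit interface is likely to carry
  the interaction. The prediction is the three-way intersection of the
  interface set, the strict-MSA-conservation set, and the angular
  co-location set. No energies are computed.
* **Validation.** Given umbrella-sampling series along the subunit
  center-of-mass separation ξ, reconstruct the potential of mean force,
  read the binding free energy off its global minimum (zeroed at large
  separation), and difference point mutants against the wild type.

### Symmetry

The group is built by closure from two generators — a 5-fold rotation about
an icosahedron vertex axis and the 2-fold about z — in the standard setting
with three mutually perpendicular 2-fold axes on the coordinate axes. This
is self-verifying: the construction is accepted only if it yields exactly 60
operators, closed under composition, with conjugacy classes of size
1/15/20/24 (identity/2-/3-/5-fold). Fold classes follow from the trace
(`tr = 1 + 2 cos θ`), axes from the unit eigenvector of eigenvalue +1.
Operator membership and orthogonality use a Frobenius tolerance of 1e-8 —
far above double-precision accumulation, far below any geometric
distinction. Subunit labels combine the chain's class letter with the
1-based operator index; published databases use their own copy-index
conventions, so labels here are presentation, geometry is the contract.

### Interfaces

A residue is an interface residue of a subunit pair when any of its heavy
atoms lies within the contact cutoff of a heavy atom of the partner.
The cutoff defaults to 4.5 Å, the conventional close-contact radius between
heavy atoms, and is configurable because database contact tables computed
with other criteria may need matching. `NumInt` counts distinct partner
residues in contact. The cell-list accelerated search is exact — it is
property-tested against the all-pairs computation on random configurations.
Interfaces inherit the symmetry fold of the operator relating their two
subunits; for cross-class pairs the fold is assigned only when that
operator's axis actually passes through the contact region (within 20° of
the contact centroid direction), otherwise the contact is tagged `quasi`
(hexamer-style quasi-equivalent contacts, and contacts between chains of
one asymmetric-unit copy, which are related by the identity).

Solvent-accessible surface areas use the sphere-point method with a 1.4 Å
probe and 960 points per atom on a deterministic golden-spiral lattice, with
Bondi-type van der Waals radii; buried area is isolated-minus-complexed
SASA, clamped at zero (values below −0.5 Ų abort, as they indicate an
inconsistency rather than discretization error).

### Angular maps and conservation

Each interface residue is represented by the geometric center of its
side-chain heavy atoms (Cα for glycine or when no side chain exists — the
paper-style choice of a single representative point per residue is open;
side-chain centroids best reflect interface chemistry and a Cα mode is
provided for sensitivity checks). The point is projected to
ψ = arccos(z/r) ∈ [0°, 180°] and φ = atan2(y, x) ∈ [−180°, 180°); the radius
is discarded. Maps are comparable only between structures in the same
standard icosahedral orientation, which is asserted via an orientation tag;
inputs are assumed already oriented (capsid center at the origin), as curated
icosahedral structures are.

Residue correspondence across family members is keyed through alignment
columns, not nearest map neighbours: the residue compared in another member
is the *aligned* one, which is what makes intersecting spatial conservation
with sequence conservation meaningful. A reference residue is
space-conserved when every other member's corresponding residue (same
quasi-equivalent chain class) lies within the overlap threshold in *both*
angles, 3.0° by default, with φ differences taken on the circle so maps do
not split at ±180°. The threshold is inclusive (a 2.9° displacement is
conserved, 3.1° is not) and monotone (the 3° set is contained in the 4°
set). A quorum mode (`require_all_members = FALSE`) is available because
"conserved in all members" versus "conserved in most" is a genuine modelling
choice; all-members is the default and the stricter claim.

## The synthetic family generator

`make_toy_family()` manufactures the statistical situation the pipeline is
meant to resolve, with the truth planted and returned alongside the data:

* Chains are Cα-only bead chains. Planted interface residues sit 1.9 Å from
  the z 2-fold axis at radius ≈ 46 Å, so after assembly each lies 3.8 Å from
  its own symmetry image — inside the 4.5 Å cutoff — while every other bead
  is verified (by direct distance computation against all 59 images, inside
  the generator) to stay at least 0.5 Å clear of it.
* Non-interface beads cluster around the direction (ψ = 36°, φ = 8°), found
  numerically to maximize the self-separation of an icosahedral orbit
  (≈ 26.6°); the three quasi-equivalent chains occupy distinct radial shells
  (44, 60, 76 Å), which makes cross-chain image contacts impossible
  regardless of direction, since rotations preserve radius. The shells are a
  deliberate abstraction — real quasi-equivalent chains share one shell —
  but they let the generator *guarantee* its plant instead of merely making
  it likely.
* Sequence columns are identical across members exactly at the planted
  conserved positions; at every other column member 2 is forced to differ
  from member 1, so strict conservation is exactly the planted set.
* Space-conserved interface residues keep their azimuth across members to
  within the angular noise (default 1°, safely inside the 3° threshold);
  other interface residues are displaced by 7–8.5° with alternating sign —
  more than twice the threshold — so they cannot pass.

Passing the planted-recovery test therefore shows the pipeline's set
algebra, symmetry handling, projection and threshold semantics are correct.
It does **not** show robustness to what real data adds: alignment errors and
gaps, numbering offsets between structure and sequence, structures solved in
slightly different orientations, missing residues, or conservation that is
partial rather than planted. Those failure modes must be assessed on real
structures.

## WHAM and the binding free energy

Window series (centers ξᵢ, spring constants k in kJ·mol⁻¹·nm⁻²; energies are
converted once, at 1 kcal = 4.184 kJ, and bookkept in kcal/mol) are
histogrammed on a common grid — bins left-closed right-open, default width
0.05 nm — and the standard coupled WHAM equations are iterated in log space
(log-sum-exp throughout) with the gauge F₁ = 0 until the largest window
offset change falls below 1e-8 kcal/mol (cap 100,000 iterations; the
converged flag is honest and the PMF constructor refuses unconverged
solutions unless forced). Temperature defaults to 300 K with
k_B = 0.0019872 kcal·mol⁻¹·K⁻¹. Adjacent windows with no shared occupied
bins abort with a disconnected-support error, since the offsets would be
undetermined across the gap.

The PMF is zeroed on the mean over the last occupied 5% of the sampled ξ
range — the large-separation plateau — excluding starved bins (fewer counts
than 20% of the median bin) whose noise would otherwise leak into the
reference. ΔG is the global minimum, ties broken toward smaller separation;
a minimum inside the reference region (or a non-negative one) is reported as
ΔG = 0 with a no-binding flag. ΔΔG is plain differencing with errors in
quadrature. Errors come from a seeded block bootstrap (default block length
1, appropriate for the uncorrelated synthetic samples; raise it for
autocorrelated MD series — no automatic equilibration or correlation-time
detection is attempted, keeping the estimator transparent).

Two numerical properties matter when interpreting recovery tests:

* WHAM evaluates the bias at bin centers. With stiff springs and steep
  potential walls this approximation, not statistics, dominates the residual
  at the default bin width; the double-well recovery test uses 0.01 nm bins
  for that reason, and compares against the Boltzmann *bin average* of the
  potential — the exact expectation of a histogram estimator.
* The recovered ΔG sits above the point minimum by up to the in-bin
  variation of the potential around the minimum (the minimum bin reports a
  softmin over its width), which sets the "within bin resolution" tolerance
  used in the recovery checks (≈ 0.14 kcal/mol for the default synthetic
  well and 0.05 nm bins).

The umbrella sampler used as the oracle draws *exactly* from the biased
Boltzmann density by inverse CDF on a 10⁴-point grid (piecewise-linear
within cells), so recovery tests carry no Markov-chain error and their only
noise is sampling noise. Window placement for the headline recovery check —
42 windows at 2000 kJ·mol⁻¹·nm⁻² over 0.8–3.54 nm — spaces centers at
≈ 1.3 bias standard deviations, chosen so adjacent histograms overlap well;
with sparser spacing the window-offset estimates perform a visible random
walk along the profile.

### Problem sizes

The test suite and the acceptance script run entirely on synthetic inputs
sized for a desk machine: 4-member T=3 toy families (180 subunits of 30
beads each per capsid), 100-configuration contact-search property checks,
and umbrella recovery at 42 windows × 50,000 samples (≈ 2×10⁶ draws, WHAM to
1e-8 in a few thousand iterations). The full suite runs in about a minute
and a half; the acceptance script in well under a minute.

## Known limitations

* Inputs must share the standard icosahedral orientation; no automatic
  superposition between differently oriented capsids is attempted.
* Strict identity is the only sequence-conservation mode (no similarity
  classes or conservation scores).
* The bootstrap ± on ΔG estimates sampling noise only; it says nothing
  about force-field or sampling-time systematics in the upstream MD that
  produced real window series.
* mmCIF, binary trajectory formats, and alignment computation are out of
  scope; alignments are consumed, not produced.
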