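---
title: "Methods: membrane geometry, tether reach and motif censuses for BBSome cargo recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane geometry, tether reach and motif censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbscargo)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter and why they default as they do, what
the synthetic generators emulate (and do not), and the numerical choices and
limitations a user should know before trusting a verdict.

## The question

The BBSome removes GPCRs from cilia, yet the residues by which it recognizes
its best-characterized cargo — the tryptophan/arginine pair in Smoothened's
helix 8 — normally lie buried in the inner leaflet of the ciliary membrane.
Whether the BBSome can reach those residues at all, and in which
conformational state of helix 8, is a geometry problem. It decomposes into
independent, individually testable calculations: where the membrane plane is
(given how the ARL6 GTPase anchors), how close the cargo-binding surface can
ever come to that plane, how far a peptide tether of known length can reach,
and how widespread the binding motif is across ciliary GPCRs. This package
implements each step as a small, deterministic operation with explicit
parameters.

## Membrane placement from an amphipathic anchor

ARF-family GTPases bind bilayers through an N-terminal amphipathic helix
lying membrane-parallel within the lipid-headgroup layer; the start of the
folded GTPase domain (Ser15 in ARL6) therefore pins the complex's membrane
register. `place_membrane()` turns this into three constraints on a
headgroup plane:

1. *Parallelism* — the plane normal is perpendicular to the anchor-helix
   axis. The axis is fitted by self-superposition of the CA trace shifted by
   one residue: the residual screw rotation's axis is the helix axis, exact
   for an ideal helix and least-squares for a distorted one. This avoids the
   small but systematic bias a principal-component fit shows on helices with
   partial turns.
2. *Depth* — the helix CA centroid sits `headgroup_depth` (default 3 Å)
   below the plane. The reference surface is the phosphate/headgroup level;
   3 Å approximates the half-thickness of a headgroup layer and is
   configurable because no single value is canonical.
3. *Non-penetration* — no heavy atom of the complex rises above the plane by
   more than `penetration_tolerance` (default 2 Å, allowing headgroup-layer
   excursions but not core penetration).

Constraints 1–2 leave one angular degree of freedom (the normal's direction
around the helix axis). The physically meaningful resolution is the helix's
own amphipathy: the hydrophobic face buries into the membrane. The
implementation computes a hydrophobicity-weighted sum of unit radial CA
vectors (Eisenberg consensus scale), projects it perpendicular to the axis,
and takes the feasible direction on a 2° grid closest to that face vector.
For a helix with no amphipathic contrast (a homopolymer) the face is
undefined and an arbitrary perpendicular is used — parallelism and depth
still hold, direction is reported as unresolved by physics. If no direction
satisfies non-penetration, an infeasibility report is returned rather than a
least-bad plane passed off as a placement.

## Anchored orientation search

`min_patch_distance()` asks the adversarial question: over *every*
orientation the anchor permits, how close can a given surface patch get to
the membrane? Orientations are parameterized as rotations of the plane
normal about the helix axis (full circle, default 2° grid) crossed with
tilts of the normal toward the axis within the anchor's
`parallelism_tolerance` (default ±5°, 1° grid) — a deterministic grid chosen
over stochastic search for exact reproducibility. For each candidate plane
the non-penetration constraint is checked against all heavy atoms, and the
minimum patch-atom depth is recorded; the reported value is the minimum over
feasible planes. Nested grids guarantee the estimate is monotone
non-increasing as the step shrinks; tests check a 2° grid against a 0.5°
oracle and require agreement within 0.5 Å. On the deposited complex the
patch would be the cargo-binding cleft of the BBS7 β-propeller; the region
is configurable because no residue list is canonical.

## Tether reach and the conformational verdict

A peptide tether of *n* inter-residue steps spans at most *n*·3.5 Å when
fully extended and *n*·1.5 Å when α-helical. The steps are counted as
`contact − anchor` on author numbering (Lys543→Trp549 is 6 steps), not
inclusive residues; the rise constants are exactly those that make a 6-step
tether reach 21 Å and 9 Å, and the same constants parameterize the synthetic
generators, so `make_extended_chain()`/`make_ideal_helix()` extents equal
`max_reach()` identically. `conformational_verdict()` then partitions
states: a state is compatible when the measured minimum site distance does
not exceed its reach, and "must be unfolded" is returned exactly when the
extended state alone is compatible. These are hard geometric bounds, not
polymer statistics — a worm-like-chain model would only tighten the verdict,
never loosen it, since real chains reach less far than the rigid maximum.

## Hydrophobic moments, helix-8 windows and sequence properties

The per-residue mean hydrophobic moment is
μH = |Σₙ Hₙ·e^{inδ}|/N with δ = 100° per residue and H from the Eisenberg
consensus scale by default; values are scale-relative, so every report names
the scale. Helix-8 windows are placed directly after a supplied TM7 end
(window length defaulting to 17 residues, the SMO H8 span 543–559) or, when
TM7 is unknown, heuristically as the maximal-μH window confined to the first
25 residues of the C-tail, where helix 8 lies. "Recovery" of a planted
window is scored as the heuristic start landing within ±2 residues of the
planted start: windows shifted by one or two positions share ~90% of their
residues and any in-window motif call is unaffected at that offset.

Theoretical pI is solved by bisection on the Henderson–Hasselbalch net
charge under a Bjellqvist-style pKa set (N-term 7.5, C-term 3.55; K 10.0,
R 12.0, H 5.98, D 4.05, E 4.45, C 9.0, Y 10.0); the returned pI satisfies
net charge = 0 within 10⁻⁶ by construction and reports name the pKa set,
since published "theoretical pI" values are set-dependent and exact
reproduction of any particular calculator is not claimed.

## Motif scanning and censuses

Motifs are ordered residue classes with bounded gaps. The BBSome-binding
patterns are kept strictly separate — `[W/F/Y]R` (strict), `[W/F/Y][K/R]`
(relaxed) and `[W/F/Y]x[K/R]` (one-gap) — because the strict and relaxed
censuses answer different questions and merging them silently would blur
which pattern produced which count. The PH-domain PIP motif is
`Kxₙ[K/R]xR` with n defaulting to 3–8. The scanner enumerates matches
depth-first from every start position; overlapping matches are all reported,
identical spans reached through different internal gap decompositions once;
X matches no class (conservative for unmodelled residues). Tests hold the
scanner equal to an independent brute-force oracle (concrete regex expansion
with lookahead) on 10³ random sequences. Census counts are
sequences-with-≥1-in-window-match, so strict ≤ relaxed is a containment
invariant, not an empirical observation.

## Domain rotations

`domain_rotation()` uses a two-step protocol: superpose the second
conformation onto the first on a stable reference selection (for the
BBSome, the lower-lobe subunits), then superpose the moving domain's CA
atoms and report the rotation angle of that residual transform. Reported
domain rotations of this kind (a ~20° propeller rotation upon GTPase
binding) rarely come with a stated measurement protocol; the two-step
procedure here is the package's own choice, fixed and documented so the
number is reproducible. Superposition is least-squares with a
reflection guard (det +1, chirality preserved); the rotation angle is
extracted with the atan2 axis/trace form, which keeps near-zero angles
accurate where acos((tr−1)/2) loses six digits.

## Lipid-site occlusion

Template PH-domain/PIP co-structures are superposed onto the query PH
domain (CA correspondence by residue number, or an explicit pairing;
≥20 pairs required) and their ligands transferred by the fitted transform.
Clashes are environment heavy atoms within 3.0 Å of any ligand heavy atom —
a deliberately conservative contact-distance cutoff — with the PH domain
itself excluded. The verdict is `blocked` when the median-over-templates
clash count exceeds the threshold (default 0: *any* clash blocks, matching
qualitative structural practice), `distant` when clash-free but the placed
ligand centroid lies more than 10 Å (1 nm) from the membrane plane, else
`open`. The centroid is the documented reference point for the membrane
distance; a phosphate-atom reference would differ by a few Å and can be
emulated by passing the phosphate alone as the ligand. The median over
templates makes the call robust to any single aberrant template.

## What the synthetic generators emulate — and what they do not

All fixtures are CA-level and deterministic given a seed, with planted
ground truth emitted alongside (machine-readable sidecars where files are
written) so tests never re-derive truth from the code under test.

* **Membrane fixture**: an 18-residue anchor helix (five exact turns, so its
  hydrophobic face is symmetric about the planted normal), a body modelled
  as a spherical envelope (radius 30 Å, closest approach 5 Å below the
  plane — it is the protein *surface* that limits how far the plane can
  swing) and a cargo patch recessed 24 Å. This plants the regime of a large
  coat complex whose cargo-binding surface stays beyond helical tether
  reach in every anchored orientation; the recovered minimum distance
  (~18–21 Å across seeds) is then a computation, not an input.
* **GPCR cohort**: 26 C-tail-like sequences whose H8 windows carry planted
  motifs at the study composition (20 strict, 3 relaxed-only, 3 none).
  Windows are amphipathic by construction with the aromatic planted on the
  hydrophobic face and the basic residue off it, as in membrane-embedded
  helix 8; aromatics occur only in planted motifs and the polar face
  excludes Gly (hydrophobicity +0.48 on the Eisenberg scale — not polar),
  so in-window counts are exact by construction. Flanks are uniform
  background.
* **Clash fixture**: planted clashing atoms at distances spread over
  1.9–2.9 Å so cutoff monotonicity is informative, decoys ≥13 Å away.
* **Rotation fixture**: noiseless planted rotation plus an unrelated global
  motion.

What passing these tests shows: the geometry, search, scanning and verdict
machinery is correct against known truth. What it does not show: anything
about real deposited coordinates — side-chain packing, missing residues,
alternate conformers, or whether a particular receptor's H8 annotation is
biologically right. Runs on deposited models are supported through
`read_structure()` with a user-supplied subunit→chain map (deposited entries
do not standardize which chain is which subunit) but require those files
locally; nothing is fetched.

## Numerical choices and degenerate inputs

* Superposition requires ≥3 non-collinear points and errors otherwise;
  reflection is never permitted.
* Planes normalize their normal at construction and reject zero vectors;
  distances are Å everywhere, nm converted at interfaces (the 1 nm rule is
  stored as 10 Å; the 250 nm cilium as radius 1250 Å, reading the quoted
  figure as a diameter — both interpretations are one constructor argument
  apart).
* Residue ranges are inclusive, 1-based, author-numbered; insertion codes
  sort after their base number; selections that resolve to nothing raise
  rather than return empty models.
* Non-standard residues are retained in geometry and become X in sequences —
  including modified residues with a known parent (MSE), because a scan
  should not claim a methionine the model does not literally contain.
* The helix-axis fit needs ≥4 CA atoms; anchors shorter than that are
  rejected.
* Grid searches are deterministic; there is no RNG anywhere outside the
  synthetic generators, and each generator takes an explicit seed.

## Problem sizes

The shipped workflow and tests run at deliberately desk-scale sizes — a
432-atom membrane fixture, 26-sequence cohorts, 10³ random sequences for the
scanner oracle, 0.5° oracle grids on ~120-atom toys — chosen so the complete
analysis reruns in minutes while still exercising every code path at the
tolerances stated above. All sizes are function arguments and scale up
unchanged.

## Known limitations

* The membrane is a plane (or a tangent cylinder for the curvature check);
  there is no bilayer deformation, insertion energetics, or electrostatics —
  charge compatibility is a residue-level census, deliberately cruder than a
  Poisson–Boltzmann map.
* The orientation search treats the complex as rigid; a flexible anchor
  linker would enlarge the feasible set and can only *decrease* the minimum
  distance, so bounds of the form "≥ x Å" should be read as rigid-body
  bounds.
* Motif patterns are hard residue classes, not position-weight matrices; a
  borderline aromatic-basic pair either matches or does not.
* The heuristic H8 annotator assumes helix 8 begins within the first 25
  residues of the supplied C-tail; receptors with unusual TM7–H8 linkers
  need an explicit `tm7_end`.
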