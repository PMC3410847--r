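---
title: "Backrub motions at helix N-caps and sheet aromatics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backrub motions at helix N-caps and sheet aromatics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the geometric model, the filters and thresholds of the
motif scanners, the ensemble-averaging protocol, the design search and
its energy function, and the synthetic-data generators that stand in
for a curated crystal-structure database. It also records the design
choices made where the construction was genuinely open.

## The backrub model

A backrub at residue *i* is a rotation of the dipeptide — C,O of
*i*−1; all atoms of *i* including the sidechain, which rides the move
like a hinge; N,H of *i*+1 — by an angle θ~1,3~ about the axis from
Cα(*i*−1) to Cα(*i*+1), followed by counter-rotations θ~1,2~ and
θ~2,3~ of the two individual peptide groups about their own Cα–Cα
axes. The two flanking Cαs are pivots and never move; all strain is
redirected into the three N-Cα-C bond angles (τ) of the window. Angles
follow the right-hand rule about the N-to-C axis direction, so a
single sign convention covers application, fitting, and reporting.
Because the counter-rotation axes involve the central Cα, which itself
rides the primary rotation, the package takes those axes in the
*rotated* conformation; this makes the move set exactly invertible
(`test-backrub.R` asserts the round trip to 10⁻⁶ Å).

`restoringCounterRotations()` defines the counter-rotation angle as
the 1-D optimum (tolerance 10⁻⁴°) that returns each peptide's carbonyl
O to its pre-backrub position, scaled by a factor ε ∈ [0, 1] with
default 0.7. The carbonyl-restoring objective was chosen because the
counter-rotations exist to preserve the peptides' H-bonding; an
alternative that minimises |τ − 111°| at the peptide's outer residue
is available behind the `objective` argument but is not the default.

`fitBackrub()` inverts the model: given two conformations in a common
frame it searches θ~1,3~ on a 0.5° grid over ±30°, refines by
golden-section to 0.01°, seeds the secondary angles from the
carbonyl-restoring rule, and polishes all three angles with a simplex.
The fitted atom set is the window backbone (C,O of *i*−1; N,H, CA, CB,
C,O of *i*; N,H of *i*+1), dropping atoms absent from either
conformation (e.g. Cβ at Gly). A backrub angle is a property of a
*pair* of conformations, never of one structure.

## Hydrogen bonds and hydrogen building

Mainchain H-bonds use the DSSP pseudo-energy
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with the
standard −0.5 kcal/mol cutoff. Sidechain-mainchain bonds (Ser OG, Thr
OG1, Asn OD1, Asp OD1/OD2, Tyr OH as acceptors) reuse the same
functional form with the sidechain O and its covalently bonded carbon
substituted, and the same cutoff, for uniformity.

Hydrogens are built from ideal internal coordinates: the amide H in
the peptide plane at N–H 1.00 Å opposite the preceding carbonyl, HA by
tetrahedral completion, and sidechain hydrogens from the same
construction templates used by the chain builder. N-terminal residues
and Pro get no amide H. Building is idempotent — placement depends only
on heavy atoms — so stripping and rebuilding is a no-op to 10⁻⁶ Å.
Amide-flip optimisation for Asn/Gln/His is deliberately not
implemented; it belongs to database curation, which is out of scope.

## Motif definitions

**Helix annotation.** Helices are unions of α-like (*i* → *i*+4
mainchain bond, acceptor notation) and 3₁₀-like (*i* → *i*+3) turns,
requiring at least five residues including both caps. The N-terminus
is extended residue-by-residue while the candidate cap's Cα lies
within 5.9 Å of the *i*+3 Cα — the cap must sit inside the helix Cα
cylinder even where the first mainchain bond is weak. The cap class
comes from the cap's own bonds: *i*+4 only → `alpha`, *i*+3 only →
`three10`, both → `bifurcated` (always excluded from the analysis).
C-caps are intentionally not annotated.

**N-cap scanning** keeps alpha-class caps; the category is ND
(Asn/Asp), ST (Ser/Thr) or `other`. ND/ST additionally require the
*i*+3 sidechain-mainchain bond present and the *i*+2 one absent (both
judged by the DSSP energy criterion — the package resolves this
otherwise-open point in favour of the energy form used everywhere
else). Cap φ,ψ must fall in the primary window (−100°, 155°) to
(−60°, 180°); a secondary window of the same dimensions centred at
(−150°, 170°) labels the second population, which is analysed
separately and never averaged with the first. The cap's maximum
non-hydrogen B-factor must be below 40 Å².

**Mid-helix controls** are central residues with strictly helical φ,ψ
((−65°, −45°) to (−55°, −35°)), at least four H-labelled residues on
each side, at least 13 in the helix, and B ≤ 20 Å².

**β aromatics.** Phe/Tyr with a plus χ₁ rotamer ((0°, 120°]) in
antiparallel sheet; the opposite residue is the narrow-pair partner
whose N and O both H-bond the aromatic's O and N (a Pro opposite can
never supply both bonds and drops out by construction). Both residues
need one additional β-annotated neighbour in each direction and
maximum non-hydrogen B-factor below 40 Å² (applied to all non-hydrogen
atoms of both residues). The **fray** statistic guards against strand
ends:

* t~N~ = torsion(Cα~a~(i−1), Cα~a~(i), Cα~o~(j), Cα~o~(j+1)),
* t~C~ = torsion(Cα~a~(i+1), Cα~a~(i), Cα~o~(j), Cα~o~(j−1)),
* p~a~, p~o~ = the Cα(i−1), i, i+1 planar angles on each strand,
* f = |t~N~ − t~C~| − |p~a~ − p~o~|,

with hits required to have f < 10°. The absolute-difference form with
the pleat difference subtracted as a correction is the default; a
signed variant is available via `motifConfig()$fraySigned`. The
correction term is remarkably effective: rigid hinge-like motions of a
half-strand change twist and pleat by exactly compensating amounts, so
f responds only to genuine pulling-apart of the pair (this drove the
design of the generator's fray perturbation, below).

## Ensemble superposition and averaging

Members are superposed on a named Cα frame by least-squares rigid
superposition (SVD-based, with determinant correction). The motif
residue's own Cα is never part of the frame, to avoid biasing its
average position: N-caps use *i*−1 and *i*+1..*i*+3 (four Cαs),
mid-helix controls *i*+1..*i*+3, and β aromatics the aromatic
*i*±1, *i*±2 plus the opposite Cα as an anchor (five Cαs). Members
with frame RMSD above 1 Å are pruned. When a reference must be picked
from the data, `selectReference()` tries the candidates (ten, in the
survey protocol) and keeps the one pruning fewest members, ties broken
by lower mean RMSD and then input order — every tie-break in the
package resolves by input order so reruns are bit-identical.

Averages are arithmetic means of the named backbone atoms (including
hydrogens) and Cβ; a member missing an atom is dropped from that
atom's mean and the count is recorded. Mean hydrogen positions can be
slightly non-ideal; they are kept raw for reporting. A sidechain
beyond Cβ is rebuilt from the member-median χ angles anchored on the
mean N/CA/Cβ, so the attached rotamer preserves the averaged Cβ.
Displacement reports superpose average B onto average A via the frame,
list per-atom displacements, fit the backrub between the averages, and
take Δτ from *ensemble-mean* τ values when supplied — τ measured on
averaged coordinates is less reliable because pre-window atoms vary
across members.

## The design search

`buildIdealNcapTemplate()` constructs the idealized N-cap: the cap and
its preceding residue in polyproline-II conformation (φ,ψ = −80°,
170°), eight ideal-helix residues (−60°, −40°) after it, all other
residues Ala, all τ at 111°, ideal bonds and angles throughout, full
hydrogens. The template is deliberately minimal — nothing precedes the
*i*−1 residue, matching the stated construction; extra leading
residues would add spurious packing on the backward side of the
backrub coordinate.

`enumerateGmec()` scans the full discrete space: primary backrub
−15°…+15° in 0.5° steps with ε = 0.7 counter-rotations at the design
position (and optionally a second backrub position, used for the
β-sheet case at the opposite residue), the modal rotamers of the
design residue, and optionally a single-peptide rotation −5°…+15° in
1° steps (for N-caps, the peptide entering *i*+3, which steers that
amide's H-bonding direction). Conformations failing the τ filter
(|τ − 111°| ≤ 8° at every moved residue; 8° ≈ 3 standard deviations of
observed τ variation) are counted and skipped. Every surviving point
is scored, so the minimum is the global minimum energy conformation of
the input model by construction — no pruning argument is needed, and
the test suite asserts the returned minimum equals the minimum over
the stored ranking and that grid refinement never raises it. The
single-position spaces here are ~4 × 10³–10⁴ points and enumerate in
seconds.

**Energy function.** Pairwise over all atom pairs touching a moved
atom: Coulomb electrostatics with a distance-dependent dielectric
ε(r) = 6r (constant dielectric available), Amber-style ff94-era
partial charges and 12-6 Lennard-Jones parameters, and the
Lazaridis–Karplus EEF1 Gaussian-exclusion pairwise desolvation term
with published per-atom parameters (heavy atoms only). 1-2 and 1-3
pairs are excluded; 1-4 pairs are scaled by 1/1.2 (electrostatics) and
1/2 (van der Waals); bonded topology is detected from distances on the
starting conformation. Following the design-code lineage this model
descends from, the solvation term is scaled by 0.5 and Lennard-Jones
radii by 0.95; both factors are `energyModel()` arguments. Without the
solvation scaling, apolar-burial rewards overwhelm the capping H-bond
and non-capping rotamers win the N-cap searches, which contradicts the
motif's observed chemistry.

**No nonbonded cutoff by default.** On templates this small a hard
unswitched cutoff is a liability: as the backrub grid sweeps atoms
across the cutoff sphere, pairs enter and leave the sum in ~0.3
kcal/mol jumps — the same order as the energy differences separating
neighbouring grid points — and the discontinuities, not the physics,
can decide the minimum. The default is therefore exact summation over
all pairs (affordable at ~10² atoms); a finite cutoff remains
available for larger systems.

**Rotamer library.** A plain-text table of modal χ values for the
common rotamers of the buildable residue types, bundled under
`inst/extdata/rotamers.tsv`; any library in the same four-column
format can be substituted. Hydroxyl and amide hydrogens beyond the
listed χ angles are placed at ideal staggered/planar positions.

## Synthetic data: what it emulates and what it does not

The generators replace a curated, quality-filtered crystal-structure
survey, which cannot be reconstructed here. They share one
internal-coordinate builder with the design templates, so every
parameter written into a structure can be re-measured exactly by the
geometry module.

* `generateIdealHelix()` — ideal α (−60°, −40°) or 3₁₀ (−71°, −18°)
  helices.
* `generateIdealSheet()` — two antiparallel strands whose (φ,ψ) are
  solved numerically from a requested Cα-level twist and pleat; the
  second strand is the two-fold image of the first, placed by
  optimising the narrow-pair H-bond geometry (N···O 2.95 Å, H···O
  1.95 Å at the central and ±2 pairs). The `frayPerturb` argument
  pulls the C-ward half of the second strand away from the pair with
  a compensating twist, solved by nested root finding so the measured
  fray matches the target; because fraying physically separates the
  strand ends, large targets cost the flanking H-bonds, exactly as in
  real frayed pairs.
* `generateBackrubPairEnsembles()` — population A is n noisy copies of
  a motif window, population B is n noisy copies of the window after a
  known backrub (ε-restored); noise is i.i.d. isotropic Gaussian per
  coordinate and B-factors are uniform in a range. The manifest
  records the seed and ground truth. Defaults (θ = 11°, σ = 0.1 Å,
  n = 400 per population, B ∈ [5, 15] Å²) mirror the scale of the
  crystal-survey populations: a few hundred examples per category with
  coordinate uncertainty of roughly a tenth of an ångström.

The noise model is deliberately the simplest defensible one. It does
not emulate crystal packing, correlated (TLS-like) displacements,
resolution-dependent error, sidechain rotamer spread beyond modal
values, or sequence context. Passing recovery tests therefore shows
that the estimator chain (superpose → prune → average → fit) is
unbiased and converges under honest isotropic noise — not that every
real crystallographic complication averages out.

## Numerical choices and problem sizes

* Superposition needs ≥ 3 frame atoms; degenerate (collinear) frames
  are not special-cased — the SVD handles them with the determinant
  correction.
* All optimisations are deterministic (golden-section, Nelder-Mead
  with fixed starts); all stochastic generation takes an explicit
  seed; ties resolve by input order.
* Torsions follow the standard signed convention (verified against an
  independent implementation on a real structure in the test suite);
  the Cβ branch uses the L-amino-acid improper torsion −122.6°.
* The test suite exercises parameter recovery at n = 100 and n = 400
  members per population and convergence over n = 10/40/160 with three
  seeds; the design comparisons enumerate the full 0.5°-step grids.
  These sizes were chosen to estimate each quantity comfortably inside
  its stated tolerance.

## Known limitations

* Sidechain construction templates cover Gly, Ala, Ser, Thr, Asn, Asp,
  Phe, Tyr — the types the analyses need. Energy parameters cover the
  same set; scanning arbitrary PDB files works for all residue types,
  but design and energy evaluation require the covered set.
* The energy function is a screening model: distance-dependent
  dielectric, no polarisation, implicit solvent. Quantities that hinge
  on sub-0.1-Å placement of a single H-bond are sensitive to its
  details; the package reports what its stated model computes.
* Shear and peptide-flip backbone moves, multi-position combinatorial
  design, continuous sidechain minimisation, and mmCIF/multi-model
  input are out of scope.
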