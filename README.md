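# backrubr

Single-amino-acid changes at certain protein motifs are not absorbed by
sidechain rotamers alone: the backbone answers with a **backrub**, a
local motion in which the dipeptide around residue *i* rotates by a
small angle θ<sub>1,3</sub> about the Cα(i−1)–Cα(i+1) axis, with small
counter-rotations θ<sub>1,2</sub> and θ<sub>2,3</sub> of the two
individual peptides about their own Cα–Cα axes to restore amide and
carbonyl H-bonding. Strain concentrates in the flanking N-Cα-C bond
angles (τ). `backrubr` is an R package for studying this motion in two
motifs where a single-residue difference leaves a clear backbone
signature:

* **α-helix N-caps** — the half-in/half-out residue at a helix
  N-terminus, whose sidechain O can H-bond the *i*+3 backbone amide.
  Ser/Thr caps (short sidechain) and Asn/Asp caps (one bond longer)
  place the cap Cα on opposite sides of the neutral helix geometry.
* **plus-χ₁ aromatics in antiparallel β-sheet** — Phe/Tyr with χ₁ in
  (0°, 120°] packing their ring across the narrow pair of inter-strand
  H-bonds against the opposite residue (Gly vs. anything else).

The package provides, as plain R functions over an S4 `Structure`
class:

* PDB reading/writing (via `bio3d`), torsions, τ, Cβ deviation, rotamer
  bins, DSSP-style H-bond pseudo-energies, ideal hydrogen building;
* the backrub engine: `applyBackrub()`, carbonyl-restoring
  counter-rotations with an ε scale factor, single-peptide rotations,
  `fitBackrub()` between conformation pairs, and τ-strain accounting;
* motif mining: helix annotation with N-cap extension and α/3₁₀/
  bifurcated cap classes, `findNcapMotifs()`, mid-helix controls,
  antiparallel bridge detection, the strand-pair **fray** statistic, and
  `findBetaAromaticMotifs()`;
* ensemble analysis: frame superposition (Kabsch), RMSD pruning,
  reference selection, coordinate averaging with median-χ rotamer
  attachment, and displacement reports;
* an exhaustive **GMEC** design search (`enumerateGmec()`): backrub
  grid × rotamers × single-peptide rotation, scored with
  molecular-mechanics electrostatics + 12-6 van der Waals + EEF1
  implicit solvation under a τ filter — enumeration makes the returned
  minimum provably global over the discrete space;
* synthetic-data generators (ideal helices, ideal antiparallel sheets
  with controlled fray, two-population ensembles related by a known
  backrub plus Gaussian noise) with recorded ground truth.

## Worked example

Build the idealized Ser N-cap template (cap and its preceding residue
in polyproline-II conformation, followed by an ideal helix), scan it
for N-cap motifs, then apply and re-fit a backrub:

```r
library(backrubr)

tmpl <- buildIdealNcapTemplate("SER")
tmpl
#> Structure: 100 atoms, 10 residues, 1 chain(s)
#>   chain A: residues 1..10

findNcapMotifs(tmpl)
#>   chain resno  aa category cluster phi psi hbEnergy hbLength maxB
#> 1     A     2 SER       ST primary -80 170    -1.02     2.69   10
```

The scanner reports one Ser/Thr-category cap in the primary φ,ψ
cluster, with its *i*+3 sidechain-mainchain H-bond (pseudo-energy
−1.02 kcal/mol, O···H 2.69 Å) and the cap's maximum B-factor.

```r
cr <- restoringCounterRotations(tmpl, "A", 2, theta13 = 11, epsilon = 0.7)
round(cr, 3)
#> theta12 theta23
#>  -5.342  -3.036

moved <- applyBackrub(tmpl, "A", 2, BackrubMove(11, cr[1], cr[2]))
fitBackrub(tmpl, moved, "A", 2)
#> BackrubFit: theta13 = +11.00 deg (theta12 -5.34, theta23 -3.04), residual 0.0000 A

round(tauStrain(tmpl, moved, "A", 2), 2)
#> dtau.im1   dtau.i dtau.ip1
#>     4.44     1.56    -6.41
```

An 11° primary rotation with ε-scaled counter-rotations is recovered
exactly by the fit, and the τ strain lands at the flanking residues, as
the backrub model predicts.

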