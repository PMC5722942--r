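---
title: "Classifying insulin conformational states from coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying insulin conformational states from coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulinconf)
```

## The problem

Insulin is a two-chain hormone (A chain, 21 residues; B chain, 30 residues)
held together by three bridges: the intra-chain A6–A11 cystine and the
inter-chain A7–B7 and A20–B19 cystines. Receptor-free T-state monomers are
not structurally uniform at the A-chain N-terminus. Two conformations
recur in crystal structures:

* **Class 1** — residues A1–A9 form a regular α-helix; the backbone amide
  of Thr^A8 makes the canonical (*i*, *i*+4) hydrogen bond to the carbonyl
  of Glu^A4.
* **Class 2** — A1–A5 form a single α-turn while A3–A9 widen towards an
  (*i*, *i*+5) π-like helix; the Thr^A8 amide instead bonds to the
  carbonyl of Val^A3. This wider, rotated geometry matches the
  receptor-bound conformation, and it requires a *contracted* A6–A11
  Cα–Cα span.

Because the switch between the two classes is gated by the geometry of the
A6–A11 bridge, replacing the disulfide by a rigid dicarba (C=C) linkage
locks the molecule: a *cis* double bond still permits the short A6–A11
span of Class 2; the longer *trans* geometry does not. Quantifying all of
this from coordinates requires a small set of well-defined measurements,
which this package implements end to end:

1. backbone hydrogen-bond detection (Kabsch–Sander energies) and
   DSSP-style helix typing;
2. the two classifiers — T/R state from B1–B7 helicity, Class 1/2/3₁₀
   from the Thr^A8 best acceptor;
3. bridge geometry — Cα–Cα and Sγ–Sγ distances, the five disulfide χ
   torsions, dicarba *cis*/*trans* from the Cβ–Cγ=Cγ′–Cβ′ torsion;
4. helix-axis fitting and per-residue azimuths for the A1–A5 rotation;
5. ensemble (multi-model) statistics: per-frame RMSD to a Class 2
   reference, Thr^A8 partner occupancies, class occupancy, helicity;
6. a synthetic-structure generator that builds two-chain insulin-like
   monomers of either class, with disulfide or *cis*/*trans* dicarba
   bridges, so that every estimator can be validated against known truth.

## Hydrogen bonds and helix typing

X-ray coordinate sets rarely include hydrogens, so amide hydrogens are
reconstructed at 1.01 Å from N in the C(prev)–N–Cα plane, opposing the
bisector of the two heavy-atom bonds (the trigonal sp² position);
experimentally present hydrogens are reused. Donor–acceptor pairs are
scored with the Kabsch–Sander electrostatic model used by DSSP,

$$E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
      - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \ \mathrm{kcal/mol},$$

with a bond recorded when $E < -0.5$ kcal/mol. One criterion serves
everything — helix typing, the class rule, the occupancy statistics —
which keeps the classifiers mutually consistent. Helix types follow the
DSSP priority: two consecutive (*i*, *i*+4) turns make H, then
(*i*, *i*+3) G, then (*i*, *i*+5) I; isolated turns are T, the rest C.

Design choices worth knowing:

* The class label uses the **single lowest-energy acceptor** of the
  Thr^A8 amide; bifurcated bonds resolve by energy, ties by smaller
  sequence separation and then lower residue number.
* The T/R rule calls a monomer R when ≥ 3 residues of B1–B7 are H or G.
  The threshold is a convention (the R-state helical extension is many
  residues long, so the call is insensitive to it between 2 and 5); it is
  exposed as `tr_min_helical` and echoed in every output.
* An incomplete B1–B7 backbone yields `UNDETERMINED`, which surveys
  exclude rather than guess.

## Bridge geometry

Bridge typing is connectivity-based, never name-based, because dicarba
half-residues appear under varying residue codes in deposited files:
a bridge is a disulfide when both Sγ atoms exist within 2.5 Å, and
dicarba when each residue carries a γ-carbon bonded to Cβ (within
1.75 Å) and the two γ-carbons are themselves within bonding distance.
The *cis*/*trans* call uses the Cβ–Cγ=Cγ′–Cβ′ torsion with the |τ| < 90°
convention. χ angles are reported from the lower-numbered residue, with
the reversed walk stored as well so conformer labels do not depend on
orientation. The disulfide conformer label — signs of (χ1, χ3, χ1′) plus
a 60° bin of χ3 — is a deliberately coarse, deterministic stand-in for
finer cystine taxonomies; 0° boundaries are assigned to "+".

## Helix axes and azimuths

The A1–A8 helix axis is fitted by the bisector (Kahn-style) construction:
at each interior residue the bisector of the Cα virtual-bond angle points
at the local helix centre; successive bisector pairs give centres, and a
principal-component line through the centres gives the axis. This is
robust for helices as short as the 8-residue A-chain N-terminal helix,
where cylinder regression is poorly conditioned. Rise and twist are the
mean axial and angular steps of the Cα projections (for the canonical
α-torsion construction used by the generator these measure ≈ 1.5 Å and
≈ 99–100°/residue; the π-widened construction gives ≈ 1.0–1.15 Å and
≈ 84–87°).

Azimuths are measured in the plane normal to the axis. The zero direction
is the perpendicular component of the Cys^A6 Cα direction. When two
structures are compared, the mobile monomer is first superposed on the
reference via the conserved B8–B20 Cα atoms and *both* profiles are
measured from the reference structure's A6 direction, so a rigid rotation
of the A-chain helix shows up directly as a uniform azimuth shift of
A1–A5. The exact reference convention is a package decision — it is fixed
and documented so cross-structure differences are well-defined, but
absolute azimuth values are not comparable to conventions defined
elsewhere.

## Curation rules for structure surveys

Surveys of deposited structures apply three filters before
classification: resolution strictly better than 2.8 Å ("better than" is
a strict inequality — a 2.80 Å structure fails); A6–A11 Sγ–Sγ bond
length within [1.95, 2.05] Å for disulfides (lengths outside that window
indicate a poorly modelled cystine; dicarba bridges are exempt but
flagged); and an explicit exclusion list for insulin-degrading-enzyme
complexes, supplied by id because complex detection from content is out
of scope. Excluded monomers are itemised in the survey summary, never
silently dropped. Alternate locations resolve to the highest-occupancy
conformer (ties to altloc "A"). Canonical insulin numbering is assigned
by gap-free alignment to the human A/B sequences with substitutions
tolerated, so author numbering in the file is never used for logic.
Surveys report per-monomer rows (an asymmetric unit with two insulins
contributes two rows); per-entry aggregation is left to the caller, since
class membership routinely differs *within* one asymmetric unit.

## Ensemble statistics

Multi-model files are treated as conformational ensembles (e.g. MD
frames). The headline series is the RMSD of all heavy atoms of residues
A1–A4 against a representative Class 2 structure, computed after
superposition on the Cα atoms of the conserved B9–B19 helix — the fit
selection is a package default (the measurement segment must not
influence its own fit) and is configurable. A frame counts as Class 2
when this RMSD falls below 1.5 Å (configurable). Thr^A8 partner
occupancies are fractions of frames whose best acceptor is A3, A4, A5,
another residue, or none; they sum to one by construction. Frames are
treated as given — no statistical-inefficiency correction is applied to
frame correlation, so standard errors derived from these fractions assume
independent frames. Heavy atoms only, unweighted, by default.

## The synthetic generator: what it does and does not emulate

`build_class_toy()` constructs noiseless two-chain monomers from backbone
torsions by the natural-extension reference frame (NeRF) method with
canonical bond geometry (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å,
ω = 180°). Backbone amide hydrogens, which the construction knows
exactly, are emitted as atoms; the classifiers reuse file hydrogens in
preference to reconstruction, so synthetic structures are classified
from their exact hydrogens while hydrogen-free X-ray inputs go through
the reconstruction path (which the test suite exercises separately).

The A chain follows the class torsion programme (α through A1–A9 for
Class 1; an α-turn then π-widened (−57°, −70°) torsions for A4–A9 in
Class 2 — chosen so that the defining observable, the Thr^A8 best
acceptor, is Val^A3, not to match any particular deposited geometry).
The A8–A12 linker torsions, bridge χ1 angles and the rigid placement of
the B chain are **frozen closure solutions**: least-squares fits,
computed once, to the construction targets — A6–A11 Cα–Cα of 4.78 Å
(Class 1) vs 4.55 Å (Class 2), A7–B7 Cα–Cα of 4.62 vs 4.76 Å, Sγ–Sγ
bonds at 2.04 Å, dicarba C=C at 1.33 Å with the core torsion at 0°/180°,
and no steric clashes. ψ8 and φ9 are allowed small deviations from the
ideal helix in these fits: an exactly ideal A1–A9 α-helix caps the
reachable A6–A11 span at ≈ 4.9 Å, above the Class 1 target — real
Class 1 helices are likewise not ideal. The Class 1 *trans*-dicarba toy
closes at an A6–A11 span of 5.17 Å, emulating the elongated *trans*
bridge; the Class 2 *cis*-dicarba toy closes at ≈ 4.3 Å (the *cis*
closure compromises between the 4.50 Å target and the planar C=C
torsion). For Class 2 with a *trans* bridge no acceptable closure
exists — every candidate carried an order of magnitude more bond strain
and steric clash than the other variants — so the generator raises an
infeasible-closure error for that combination, consistent with the
elongated *trans* geometry being unable to reach the contracted Class 2
arrangement. These targets are the study conditions of the generator;
they are constants, not tuning knobs.

Noise emulates the coordinate uncertainty of a restrained refinement:
after i.i.d. Gaussian displacement of every atom, the bridge bond
lengths (Sγ–Sγ or Cγ=Cγ′) are re-imposed by rescaling each bond about
its midpoint, exactly as refinement restraints keep bonded distances at
target values while absolute positions carry the error. Without this,
per-atom noise of σ = 0.1 Å would scatter the Sγ–Sγ length far outside
the [1.95, 2.05] Å curation window that deposited structures satisfy.

Ensembles draw frames i.i.d. from a class mixture and add isotropic
Gaussian coordinate noise; the true labels are emitted alongside. That
makes them exact oracles for the estimators (mixture fractions, partner
occupancies, RMSD spread) but deliberately unphysical: no force field, no
temporal correlation, no side chains beyond Cβ and the bridge atoms, no
solvent. Passing the parameter-recovery suites therefore demonstrates
that the *estimators* are correct on data whose truth is known — it does
not certify accuracy on real MD trajectories, where H-bond criteria and
frame correlation matter. Default noise (σ = 0.1 Å per coordinate) is of
the order of coordinate uncertainty in good X-ray structures; the
classifier-recovery suite runs at σ = 0.15 Å, where the class label is
still recovered in ≥ 99% of draws.

## Numerical choices

* Superposition is the SVD-based Kabsch solution with the determinant
  sign correction (reflections forbidden); weights default to uniform.
  It is cross-checked in the test suite against an independent
  quaternion (QCP) eigenvalue oracle to 10⁻⁹ Å.
* Torsions are IUPAC-signed, reported in (−180°, 180°]; the NeRF
  construction inverts to its input torsions to < 10⁻⁶ degrees.
* Helix-axis fits refuse inputs of fewer than 5 Cα atoms and flag
  near-straight inputs (mean angular step < 5°) as low-confidence.
* Degenerate χ paths (collinear atoms, possible in synthetic edge cases)
  produce NA angles rather than errors; bridge typing is unaffected.
* Problem sizes in the shipped tests — 500-seed classifier recovery,
  1000-frame mixture recovery, 200-frame summary checks — were chosen to
  give stable binomial statistics from the generator.

## Known limitations

* The H-bond criterion behind the historical Class 1/2 counts of curated
  surveys is not fully specified in the literature; borderline structures
  can classify differently under energy-based vs geometric criteria. The
  package fixes one criterion (Kabsch–Sander, −0.5 kcal/mol) and exposes
  it, so discrepancies are diagnosable per structure.
* mmCIF support covers the `_atom_site` loop and the refinement
  resolution record — sufficient for coordinate analysis, not a general
  mmCIF data model.
* No crystallographic symmetry expansion: the asymmetric unit is analysed
  as deposited.
* Azimuth values are convention-consistent within the package only.

## A worked example

```{r example}
toy1 <- build_class_toy("CLASS1")
toy2 <- build_class_toy("CLASS2")
classify_a1_helix(toy1)
classify_a1_helix(toy2)
extract_bridge_geometry(toy1, "A6A11")
extract_bridge_geometry(toy2, "A6A11")

ens <- build_ensemble(c(CLASS1 = 0.7, CLASS2 = 0.3), n_frames = 100,
                      noise_sigma = 0.1, seed = 1)
summarize_ensemble(as_ensemble(ens$frames))
```
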