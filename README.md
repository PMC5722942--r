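# insulinconf

Conformational classification and bridge geometry of insulin structures.

Receptor-free T-state insulin monomers occur in two conformations of the
A-chain N-terminal helix. In **Class 1** residues A1–A9 form a regular
α-helix and the backbone amide of Thr^A8 makes the canonical (*i*, *i*+4)
hydrogen bond to the Glu^A4 carbonyl. In **Class 2** — the conformation
that matches receptor-bound insulin — A1–A5 form a single α-turn, A3–A9
widen towards an (*i*, *i*+5) π-like helix, and the Thr^A8 amide bonds to
the Val^A3 carbonyl instead. The switch is gated by the geometry of the
intra-chain A6–A11 bridge: Class 2 requires a contracted Cα^A6–Cα^A11
span, which a flexible disulfide (or a *cis* C=C dicarba replacement)
permits and an elongated *trans* dicarba bridge does not.

`insulinconf` implements the complete coordinate-level analysis behind
these statements, for structural biologists working with insulin crystal
structures or conformational ensembles:

* **Structure I/O** — PDB (single- and multi-model) and mmCIF parsing,
  identification of insulin monomers by sequence, canonical A1..A21 /
  B1..B30 numbering, A/B pairing by A7–B7 bridge proximity, and the
  survey curation filters (resolution better than 2.8 Å; A6–A11 Sγ–Sγ in
  [1.95, 2.05] Å; exclusion lists).
* **Hydrogen bonds & classifiers** — Kabsch–Sander energies
  (`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond if
  `E < −0.5`), DSSP-style helix typing (H/G/I/T/C), the T/R-state rule,
  and the Class 1 / Class 2 / 3₁₀ rule from the Thr^A8 best acceptor.
* **Bridge geometry** — Cα–Cα and Sγ–Sγ distances, the five disulfide χ
  torsions with sign-bin conformer labels, dicarba *cis*/*trans* from the
  Cβ–Cγ=Cγ′–Cβ′ torsion.
* **Helix axes & azimuths** — bisector-construction axis fits (rise,
  twist) and per-residue azimuths quantifying the A1–A5 rotation between
  classes.
* **Ensemble statistics** — per-frame RMSD of A1–A4 heavy atoms against a
  Class 2 reference (after fitting on the conserved B9–B19 helix), Thr^A8
  hydrogen-bond partner occupancies, class occupancy and helicity.
* **Synthetic generator** — NeRF torsion-to-Cartesian construction of
  two-chain insulin-like toys in either class, with disulfide or
  *cis*/*trans* dicarba bridges and seeded Gaussian noise, plus mixture
  ensembles with known labels for estimator validation.

## A worked example

```r
library(insulinconf)

toy1 <- build_class_toy("CLASS1")
toy2 <- build_class_toy("CLASS2")

classify_a1_helix(toy1)
#> A1-helix conformation CLASS1 (Thr-A8 amide -> A4)
classify_a1_helix(toy2)
#> A1-helix conformation CLASS2 (Thr-A8 amide -> A3)

extract_bridge_geometry(toy1, "A6A11")
#> Bridge A6A11 (disulfide): Ca-Ca 4.79 A, Sg-Sg 2.04 A
extract_bridge_geometry(toy2, "A6A11")
#> Bridge A6A11 (disulfide): Ca-Ca 4.55 A, Sg-Sg 2.04 A
```

The two class labels come from the Thr^A8 best acceptor (Glu^A4 vs
Val^A3), and the A6–A11 Cα–Cα distances show the contraction that
defines the active-capable Class 2 conformation. The same functions run
unchanged on parsed crystal structures
(`identify_insulin_monomers(parse_structure("file.pdb"))`).

Ensemble analysis with a known 30% Class 2 mixture:

```r
ens <- build_ensemble(c(CLASS1 = 0.7, CLASS2 = 0.3), n_frames = 100,
                      noise_sigma = 0.1, seed = 1)
summarize_ensemble(as_ensemble(ens$frames))
#> Ensemble of 100 frames: RMSD 4.47 +/- 2.91 A vs Class 2 reference
#>   Class 2 occupancy (RMSD < 1.5 A): 0.320
#>   Thr-A8 partner occupancy: A3 0.320, A4 0.680, A5 0.000, other 0.000, none 0.000
```

The recovered Class 2 occupancy and the A3 partner fraction match the
mixture that generated the frames.

A command-line wrapper is installed with the package
(`system.file("scripts/insulinconf", package = "insulinconf")`) with
`classify`, `survey`, `ensemble` and `synth` commands.

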