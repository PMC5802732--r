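---
title: "Distinguishing the tRNA deacylases DTD and ATD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing the tRNA deacylases DTD and ATD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atdkit)
```

## The scientific problem

D-aminoacyl-tRNA deacylase (DTD) is a homodimeric *trans*-editing enzyme
that removes D-amino acids (and achiral glycine) mischarged on tRNAs. Its
enantioselectivity rests on a cross-subunit Gly-Pro dipeptide: the motif of
one protomer sits in the active-site pocket of the other, with a *cis*
peptide bond that points both carbonyl oxygens into the pocket and
sterically rejects all L-amino acids. ATD (Animalia-specific tRNA
deacylase) is a paralog in which the same motif adopts a *trans* bond. The
flip rotates the Gly/Pro ψ torsions by roughly 180°, turns the carbonyl
oxygens away from the pocket, and thereby relaxes the L-chiral rejection —
which is what lets ATD clear L-alanine mischarged by eukaryotic AlaRS onto
tRNA-Thr genes that carry a G4•U69 wobble pair in the acceptor stem.

The package implements the four quantitative legs of that argument —
active-site geometry, sequence signatures, acceptor-stem genomics, and
deacylation kinetics — together with a synthetic-data module that
generates inputs with known ground truth for each of them.

## Geometric analyses

**Torsions.** `dihedralAngle()` uses the standard IUPAC sign convention
(the sign of the scalar triple product; values in (−180°, 180°]).
`backboneTorsions()` assigns ω(i) to the peptide bond *preceding* residue
i, so a "Gly-cisPro" call is the ω of the proline. A C(i−1)–N(i) distance
above 2.5 Å is treated as a chain break: φ and ω across the break, and ψ
before it, are undefined rather than silently wrong. Missing backbone
atoms likewise give `NA` angles, not errors.

**cis/trans boundary.** The literature rarely states a numeric boundary;
we use the symmetric, total rule ω ∈ (−90°, +90°] → cis, otherwise trans.
Every ω has exactly one label and the boundary sits midway between the
ideal geometries (0° and 180°). The boundary's inclusivity at +90° is
arbitrary but fixed and tested.

**Motif location and the acceptor pocket.** `findGlyProMotifs()` reports
every Gly immediately followed by Pro. The pocket of a chain is the
Cα centroid of its signature motif-1 match (`PQATL`/`SQFTL`, one mismatch
allowed); the acceptor chain of a site is the chain whose pocket centroid
is nearest the Gly-Pro Cα centroid, which flags the cross-subunit
arrangement in a homodimer. Chains without a motif match fall back to the
chain Cα centroid — a deliberate degradation that keeps the operation
total on arbitrary structures.

**Carbonyl orientation.** The orientation report measures (a) the angle
between the Gly and Pro C=O unit vectors and (b) their mean projection on
the pocket axis (carbonyl-C midpoint → acceptor pocket centroid). Labels:
angle > 45° is "non-parallel", otherwise the projection sign separates
"outward-parallel" (into the pocket, the DTD selectivity filter) from
"inward-parallel" (toward the core, the ATD geometry). The 45° threshold
cleanly separates the two near-parallel regimes the structures display;
the label flip under reflection of the oxygens through the pocket-normal
plane is covered by a constructed test.

**Superposition.** `kabschSuperpose()` is a plain SVD Kabsch fit with the
determinant sign correction (reflections excluded).  `alignSuperpose()`
pairs Cα atoms through global sequence alignment (BLOSUM62, gap open 10 /
extend 0.5, chains matched greedily by alignment score), then alternates
fitting with pruning of pairs deviating by more than 3.5 Å until stable.
rmsd and pair count are non-increasing over iterations; if pruning would
leave fewer than three pairs the last viable set is kept. Published
rmsd/Cα-count pairs for these proteins came from unnamed programs, so any
comparison to printed values must be tolerance-based, never exact.

**Rigidity and contacts.** Motif rigidity is the z-score of the motif's
mean backbone B-factor against the donor chain's backbone distribution;
negative z means the motif is more rigid. A uniform non-zero B-field has
no signal and returns z = 0; an all-zero B-field is an error. Contacts
report side-chain heavy atoms of a probe residue within 3.5 Å of motif
backbone atoms, with a same-chain flag that distinguishes the DTD
arrangement (same-monomer arginine locks the motif) from ATD's
(partner-subunit arginine).

## Sequence-family classification

The classifier scores a sequence by (best ATD-pattern hits at ≤ 1
mismatch) − (best DTD-pattern hits at ≤ 1 mismatch); positive is ATD,
negative DTD, zero "unknown". One mismatch absorbs within-family
variation; the wildcard in `N.GPVT` reflects the variable position in the
DTD motif. Pairwise identity uses global alignment and divides identical
columns by aligned columns excluding terminal overhangs — an explicit
choice, since "percent identity" is otherwise underdefined.

Anchor residues (Arg7 in DTD; Gln16/Arg151 in ATD) are read off a global
alignment to per-family reference sequences. The bundled references are
**synthetic** — hand-constructed strings that carry the motifs and anchors
at the canonical positions (`referenceSequence()`); real curated
references can be passed in their place. Anchors aligned into gaps are
flagged unresolved rather than guessed.

## tRNA acceptor-stem analysis

Gene sequences are numbered on the canonical 1–72 scheme: a terminal CCA
(the mature-tRNA tail, normally absent from genomic sequences) is
stripped, the last remaining base is the discriminator, and 5′ position i
pairs with position L − i, so pair 4 corresponds to 4•69 of a 76-nt
mature tRNA. G4•U69 requires G on the 5′ strand; the reversed U4•G69 is
counted separately because only the G-on-5′ geometry is the AlaRS
misrecognition element. The score filter is strictly greater-than (score
> 50), matching database practice, and each gene copy counts once
(isodecoder duplicates are not collapsed — the alternative convention
would change percentages, and which one the published counts used is not
stated).

Co-occurrence: an organism is "enriched" when its tRNA-Thr G4•U69
fraction is ≥ 10% — a deliberate operational cutoff below the 20–40%
band seen in enriched genomes and well above background. The 2×2
enriched × ATD-present table yields a concordance (diagonal fraction) and
a two-sided Fisher exact p-value via `stats::fisher.test()`; the test
suite cross-checks it against an exhaustive hypergeometric enumeration for
every table with margins ≤ 12.

## Deacylation kinetics

`fitDecay()` fits S(t) = S₀·e^(−kt) — no plateau term, matching the
first-order model used for these assays — by Levenberg-Marquardt least
squares with a log-linear start and the box constraints k ≥ 0,
S₀ ∈ (0, 1.2]. Hitting the iteration cap returns the best estimate with
`converged = FALSE` instead of failing. "The enzyme acts at X nM" is
operationalised as: the smallest tested concentration achieving ≥ 50%
depletion at the final timepoint (`minEffectiveConc()`); the
discrimination factor is the ratio of these concentrations between
cognate and non-cognate substrates, and the EF-Tu protection factor the
same ratio with/without EF-Tu. The threshold and timepoint convention are
parameters, not constants, because the underlying phrase is qualitative.

## The synthetic-data module: what it emulates, and what it does not

The generators define the study conditions for all tests:

* `buildPeptide()` constructs chains by NeRF internal-coordinate extension
  from a fixed ideal-geometry table (N–CA 1.458, CA–C 1.525, C–N 1.329,
  C–O 1.231 Å; N-CA-C 111.2°, CA-C-N 116.2°, C-N-CA 121.7°). Torsions
  round-trip to < 1e-6°. Dimers are placed by a two-fold rotation that
  drops each chain's Gly-Pro next to the partner's pocket, 5 Å along the
  dyad axis.
* `syntheticDeacylaseDimer()` builds family mimics from the synthetic
  reference sequences: cis (ω = 0°) vs trans (ω = 180°) Gly-Pro, ψ
  torsions flipped by 180° between families, motif B-factors set below a
  varied chain baseline. These mimics exercise every structure-stage
  operation offline. They are **not** folded proteins: their chains are
  extended ribbons, so cross-family superposition rmsd is large and not
  comparable to values measured between the real, homologous folds, and
  the simplified backbone does not reproduce the parallel-carbonyl
  arrangement of the genuine active sites — orientation labels are
  therefore validated on constructed fixtures with controlled geometry,
  not asserted on the mimics. Passing tests demonstrate correctness of
  the operations, not realism of the mimics.
* `genTRNASet()` builds 73-nt genes (72 positions + discriminator, no CCA)
  with Watson-Crick stems and the pair-4 G•U inserted at a stated
  probability; arms are random filler, with no cloverleaf realism beyond
  the acceptor stem. Stems whose 3′ end would accidentally spell CCA are
  resampled, since the numbering convention would strip them.
* `genDecaySeries()`/`genDoseSeries()` produce exponential decays with
  Gaussian noise clipped to [0, 1.2]; dose ladders use k(c) = κ·c, with
  EF-Tu protection modelled as a fold-reduction of k (occupancy scaling).
  The default ladder (1, 5, 50, 500, 5000 nM) and the effective
  concentrations built into the defaults (non-cognate 1 nM, cognate 50 nM;
  50× / 100× protection under activated EF-Tu) mirror the reported assay
  behaviour of these substrates.
* `genPresenceTable()` assigns enriched/ATD states agreeing with a stated
  concordance; enriched organisms draw Thr fractions in the 20–40% band,
  others 0–5%.
* Every generator runs in an isolated RNG stream restored afterwards, so
  draws in one generator never shift another's output, and identical
  seeds give byte-identical tables.

A bundled file, `extdata/human_trna_synthetic_snapshot.tsv`, is a
**synthetic** pinned snapshot constructed to carry the documented human
per-isotype rates (tRNA-Thr 4/20 = 20%, tRNA-Cys 2/59 ≈ 3.4%); it stands
in for a live database snapshot, whose numbers are version-dependent and
deliberately not asserted against any particular release.

## Problem sizes and numerical checks

The test suite and the acceptance script use deliberately modest sizes
chosen to estimate each quantity stably: 100 random quadruples against a
rotation-scan dihedral oracle (1e-6°), 100 random dihedral specifications
through the builder round-trip (1e-6°), Euler-grid superposition oracles
on 6-point sets (1e-4 Å), exhaustive Fisher enumeration for all margins
≤ 12 (1e-9), 200-gene binomial checks of enrichment, 500 replicate decay
fits at σ = 0.02 (median k bias < 2%), and 20-organism co-occurrence
tables. The pipeline demo runs all five stages on the same synthetic
conditions.

## Known limitations

* PDB parsing is delegated to bio3d; the mmCIF reader is a minimal
  `_atom_site` loop parser (coordinates, occupancy, B, altloc) — it does
  not handle multi-model files or semicolon-delimited text blocks.
* Highest-occupancy altloc selection (ties by letter) is applied globally;
  correlated altloc groups are not kept consistent beyond that rule.
* The superposition protocol (sequence-guided pairing, 3.5 Å iterative
  pruning) is one reasonable choice among several used by structure
  viewers; printed rmsd values from other tools will differ slightly.
* The family classifier is a motif scorer, not a profile HMM; highly
  diverged family members with degraded motifs classify as "unknown".
* Enrichment counts gene copies, not distinct isodecoders.
* No cavity-volume computation is attempted; carbonyl-orientation labels
  stand in for the pocket-space argument.
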