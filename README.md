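# atdkit

Comparative analysis of the two paralogous tRNA-editing deacylases: DTD
(D-aminoacyl-tRNA deacylase) and ATD (Animalia-specific tRNA deacylase).
The package is aimed at structural bioinformaticians and RNA biologists who
want to reproduce, on their own structures, sequences and assay data, the
chain of evidence that distinguishes the two families:

1. **Active-site geometry.** Both enzymes are homodimers carrying a
   cross-subunit Gly-Pro dipeptide in the partner subunit's pocket. The
   discriminating feature is the conformation of the Gly-Pro peptide bond,
   read from the backbone ω torsion: ω ∈ (−90°, +90°] is *cis* (DTD),
   otherwise *trans* (ATD). The cis→trans switch flips the Gly/Pro ψ
   torsions by ~180° and reverses the orientation of the two carbonyl
   oxygens relative to the pocket axis ("outward parallel" vs "inward
   parallel"), which is what relaxes the L-chiral rejection filter.
2. **Sequence signatures.** DTD carries the motifs `SQFTL` / `NxGPVT`,
   ATD `PQATL` / `TNGPYTH`; a mismatch-tolerant motif score classifies
   sequences, and conserved anchors (Arg7 in DTD; Gln16 and Arg151 in ATD)
   are located by alignment to reference sequences.
3. **tRNA acceptor stems.** ATD's physiological substrate arises from
   tRNAs carrying a G4•U69 wobble pair (5′ G at position 4 paired with U
   at 69), which eukaryotic AlaRS misreads. The package reconstructs
   acceptor-stem pairing from gene sequences, computes per-isotype G4•U69
   enrichment per organism, and tests co-occurrence of enrichment with ATD
   presence (2×2 table, concordance, two-sided Fisher exact test).
4. **Deacylation kinetics.** Time courses follow first-order decay
   S(t) = S₀·e^(−k·t); k_obs is fit by nonlinear least squares. Substrate
   discrimination is expressed as the ratio of minimal effective enzyme
   concentrations (≥ 50% substrate depletion at the final timepoint), and
   EF-Tu protection as the same ratio with and without EF-Tu.

A first-class synthetic-data module generates every input type — peptide
chains and dimers with prescribed backbone dihedrals (internal-coordinate
NeRF construction), family sequences with embedded motifs, tRNA gene sets
with controlled wobble frequency, noisy decay curves, and presence/absence
tables with controlled concordance — so the entire pipeline runs and is
tested without any downloads.

## Worked example

```r
library(atdkit)

## a synthetic ATD-like homodimer (stand-in built by the package itself)
atd <- syntheticDeacylaseDimer("ATD")
atd
#> MacroStructure 'synthetic_ATD_dimer'
#>   2 polymer chain(s): A B
#>   1598 polymer atoms, 0 heteroatoms (incl. waters)
#>   320 polymer residues

site <- findGlyProMotifs(atd)[[1]]
site
#> MotifSite: Gly73-transPro74  donor A -> acceptor B [cross-subunit]  (omega 180.0 deg)
motifRigidity(atd, site)$motif_z
#> [1] -2.73

## kinetic discrimination from a dose ladder (1-5000 nM enzyme)
concs <- c(1, 5, 50, 500, 5000)
non <- genDoseSeries("L-Ala-tRNA-Thr-G4U69", concs, k_per_nM = 0.05,
                     noise_sd = 0.02, seed = 2)
cog <- genDoseSeries("L-Thr-tRNA-Thr-G4U69", concs, k_per_nM = 0.001,
                     noise_sd = 0.02, seed = 3)
discriminationFactor(non, cog)
#> $conc_noncognate  1      # nM: non-cognate attacked at 1 nM
#> $conc_cognate     50     # nM: cognate needs 50 nM
#> $factor           50     # >= 50-fold discrimination

## G4:U69 enrichment from a tRNA gene table
snap <- readTRNATable(system.file("extdata",
        "human_trna_synthetic_snapshot.tsv", package = "atdkit"))
wobbleEnrichment(filterByScore(snap, 50), "Thr")
#>                            organism isotype n_total n_wobble fraction
#> 1 Homo sapiens (synthetic snapshot)     Thr      20        4       20
```

The motif site shows the hallmark ATD call: a cross-subunit Gly-Pro whose
peptide bond is *trans* (ω = 180°) and more rigid than its chain baseline
(negative B-factor z-score). The discrimination factor of 50 means the
enzyme depletes the non-cognate substrate at a 50-fold lower enzyme
concentration than the cognate one, and the enrichment row reports that
20% of this gene set's tRNA-Thr genes carry G4•U69.

The whole pipeline can also be driven from a YAML config
(`inst/extdata/demo-config.yaml`):

```r
cfg <- validateConfig(system.file("extdata", "demo-config.yaml",
                                  package = "atdkit"))
runPipeline(cfg)   # writes TSV/JSON outputs plus report.json
```

or from the shell via `Rscript inst/scripts/atdqc.R run --config FILE`.

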