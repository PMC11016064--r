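# plpscreen

Reverse-docking ("one substrate, many enzymes") screening of
PLP-dependent enzymes and aldehyde dehydrogenases, ranked by evidence of
catalytically favorable conformations.

## The problem and who this is for

When a metabolic reaction has no known gene — a "pathway hole" — and the
reaction is known to depend on a recognizable cofactor family, the search
space is the family's proteome-wide enzyme set.  Binding affinity alone
cannot identify the enzyme: an active site may bind a substrate well
without being able to react with it.  This package is for computational
biologists running such screens: it docks a single covalent
cofactor–substrate adduct into every enzyme of the set (through an
external docking engine) and ranks the enzymes by geometric evidence that
the docked poses are *catalytically competent*, not just bound.

## The core criterion

PLP-dependent enzymes bind amino-acid substrates as the covalent
*external aldimine* and cleave the Cα bond oriented parallel to the
cofactor ring's π system (the Dunathan stereoelectronic hypothesis).
For each docked pose the package fits the pyridine-ring plane
`Ax + By + Cz = D` and computes, for each Cα bond with direction
`(a, b, c)`,

    |sin(χ)| = |Aa + Bb + Cc| / (sqrt(a² + b² + c²) · sqrt(A² + B² + C²))

with χ₁ for Cα–COOH, χ₂ for Cα–Cβ, χ₃ for Cα–Hα.  A pose is a
**catalytically favorable conformation (CFC)** for a reaction when the
inspected bond's |sin(χ)| is strictly the largest of the three and the
imine carbon lies within 5 Å of the catalytic lysine's NZ (for aldehyde
dehydrogenases: a ≤ 3.5 Å near-attack distance to the catalytic cysteine
SG, no angular condition).

Pose ensembles are clustered on ligand RMSD at 3 Å; enzymes are ranked
by seven metrics over the best (lowest-energy), largest, and catalytic
(most-CFC) clusters — LCC, BCC, LCE, BCE, LCaaE, BCaaE, CC-CFC — with
CC-CFC, the number of CFC poses in the catalytic cluster, as the
headline method.  Rankings are validated by ROC/AUROC and Spearman
correlation, and the package includes the kinetics-side math
(Michaelis–Menten fits with propagated kcat/Km errors, competitive-
inhibition Ki) used when candidates are tested at the bench.

## Worked example

A full synthetic screen — no engine or downloads needed; the fixture
generators emulate docked ensembles with controlled geometry:

```r
library(plpscreen)

scr <- make_screen_fixture(12, 4, effect = "extreme", seed = 101,
                           n_poses = 200)
ranking <- rank_enzymes(scr$scores, "CC_CFC")
head(ranking[, c("rank", "enzyme_id", "LCC", "BCE", "CC_CFC",
                 "mean_abs_sin_chi_inspected", "mean_d")], 6)
#>   rank enzyme_id LCC   BCE CC_CFC mean_abs_sin_chi_inspected mean_d
#> 1    1      E012 100 -9.48     94                      0.906   4.18
#> 2    2      E001 100 -9.54     94                      0.905   4.18
#> 3    3      E007 100 -9.71     90                      0.875   4.30
#> 4    4      E009 100 -9.34     85                      0.837   4.45
#> 5    5      E010 100 -9.85      0                      0.202   7.00
#> 6    6      E005 100 -9.72      0                      0.201   7.00

auroc(ranking, scr$labels)
#> [1] 1
```

The four label-positive enzymes (CFC-enriched by construction) occupy
the top four ranks: their catalytic clusters hold 85–94 CFC poses with
the inspected bond nearly perpendicular to the ring plane (mean |sin χ₂|
≈ 0.9) and catalytic distances ≈ 4.2 Å, while negatives have zero CFC
and sit at the 7 Å decoy distance.  Note the energy and size columns do
not separate positives from negatives — that is the point of the
geometric metric.

Kinetics on simulated assay data:

```r
d <- make_mm_data(2, 0.5, c(0.1, 0.25, 0.5, 1, 2, 5), noise_sd = 0.02,
                  seed = 7, replicates = 4)
fit_michaelis_menten(d)
#> kcat = 2.005 +/- 0.014 1/s;  Km = 0.49 +/- 0.011 mM
#> kcat/Km = 4091 +/- 97 1/s/M
```

A thin command-line wrapper ships in `inst/scripts/plpscreen`
(`prepare-enzymes`, `prepare-substrate`, `rank`, `fixture-screen`,
`fit-mm`, `fit-ki`).

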