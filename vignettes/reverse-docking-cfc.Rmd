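---
title: "Reverse-docking enzyme screening by catalytically favorable conformations"
author: "plpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-docking enzyme screening by catalytically favorable conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plpscreen)
```

## The screening problem

Classical docking screens many ligands against one receptor.  This package
supports the converse, *one substrate against many enzymes*: given a
candidate metabolic reaction whose enzyme is unknown, the substrate is
docked into the active site of every member of an enzyme family and the
enzymes are ranked by how strongly their docked pose ensembles suggest
catalysis, not merely binding.

For enzymes that depend on pyridoxal 5'-phosphate (PLP), binding and
catalysis can be separated geometrically.  The substrate's primary amine
condenses with the cofactor into a covalent Schiff base, the *external
aldimine*, and which of the three bonds around the substrate's C&alpha;
is cleaved depends on its orientation relative to the cofactor's pyridine
ring: by the Dunathan stereoelectronic hypothesis, the bond most parallel
to the ring's &pi; system — equivalently, most perpendicular to the ring
plane — is the labile one.  Decarboxylases break C&alpha;–COOH,
aldolases C&alpha;–C&beta;, and racemases/aminotransferases/other lyases
C&alpha;–H&alpha;.  A docked conformation therefore carries evidence
about the *reaction*, not just the complex.

## The geometric score

For each docked pose the package fits the pyridine-ring plane
$Ax + By + Cz = D$ by SVD of the six centered ring-atom coordinates (the
normal is the direction of least variance), forms the three bond
directions $(a, b, c)$ from C&alpha;, and evaluates

$$|\sin\chi| = \frac{|Aa + Bb + Cc|}{\sqrt{a^2+b^2+c^2}\,\sqrt{A^2+B^2+C^2}}$$

so that 1 means the bond is orthogonal to the ring plane and 0 means it
lies in it.  The three values are $\chi_1$ (C&alpha;–COOH), $\chi_2$
(C&alpha;–C&beta;), $\chi_3$ (C&alpha;–H&alpha;).  A pose is a
*catalytically favorable conformation* (CFC) for a reaction when

* the inspected bond's $|\sin\chi|$ is **strictly** the largest of the
  three (ties are conservatively rejected), and
* the catalytic distance $d$ — from the flexible catalytic lysine's NZ to
  the aldimine's imine carbon — passes the distance gate.

Two distance gates are provided because both appear in practice: the
per-pose gate ($d \le 5$ Å for the pose itself, the default) and the
cluster-mean gate (the catalytic cluster's mean distance $< 5$ Å).  They
agree on well-behaved ensembles but differ on stragglers inside a good
cluster; both are implemented and tested, and `cfc_rule()` selects
between them.

For aldehyde dehydrogenases the analogous criterion is purely a
*near-attack* distance: the substrate's aldehyde carbon within 3.5 Å of
the catalytic cysteine's thiolate, with no angular condition
(`cfc_rule("ALDH")`).

## Clusters and the seven ranking metrics

The docking engine returns an ensemble (200 poses by default, one per
independent run).  Poses are clustered on ligand-RMSD at 3 Å with
energy-ordered greedy leader clustering: poses are visited by ascending
energy and join the first cluster whose lowest-energy member (leader) is
within the cutoff.  The engine's own clustering algorithm is not
published, so this package pins a deterministic, standard alternative and
re-clusters from raw coordinates rather than trusting engine bookkeeping.

Three clusters matter: the *best cluster* BC (lowest best energy,
energetically favored), the *largest cluster* LC (most members,
statistically favored), and the *catalytic cluster* CC (most CFC poses —
ties go to the lower best energy, so an ensemble with no CFC anywhere
falls back to BC).  From these come seven ranking metrics: LCC and BCC
(cluster sizes), LCE and BCE (best energies), LCaaE and BCaaE (best
energies recomputed over only the amino-acid atoms of the aldimine,
discounting the constant PLP moiety), and CC-CFC (the CFC count of the
catalytic cluster).  Counts rank descending, energies ascending; ties
break by higher catalytic-cluster mean $|\sin\chi|$, then lower mean
energy, then enzyme id, and the tie-break is recorded in the output.

The amino-acid-only energies deserve a note: the original decomposition
came from the docking engine's own utility.  Here a self-contained
pairwise scorer is used instead — a 12-6 Lennard-Jones term with
per-element parameters (arithmetic-mean radii, geometric-mean well
depths) plus a Coulomb term with distance-dependent dielectric
$\varepsilon(r) = 4r$, over pairs within 8 Å.  The parameter table is an
argument, so engine-parity values can be dropped in; the defaults are
AutoDock4-flavored.  Absolute values differ from the engine's, rankings
on synthetic fixtures do not depend on that.

When an enzyme has several chains (fold-type I PLP enzymes are obligate
dimers with shared active sites, so every chain is docked separately),
the enzyme is represented in a ranking by its best chain under the
active metric.  The aggregation rule is this package's choice; published
screens show one row per enzyme without stating the rule.

## Enzyme-set preparation

Monomeric structure models are assembled into oligomers by superposing
the monomer onto each chain of a template: CA atoms of sequence-aligned
residue pairs, Kabsch superposition (SVD with determinant correction).
Template selection follows a fixed priority — heteromers excluded,
experimental structures before repository models, more chains before
fewer, better resolution/model quality last.  The original pipeline used
a sequence-independent structural aligner for the superposition step;
CA-after-sequence-alignment is deterministic and adequate in the regime
that matters here (a model superposed onto templates of essentially the
same sequence), and is documented as a fidelity deviation.  Alignment
acceptance requires 30% identity over at least 50 aligned residues per
template chain.

The catalytic residue is located by mapping the annotated position from
the reference sequence onto each chain through global pairwise alignment
(match 1, mismatch −1, gap open 5, extend 1 — chosen for robustness on
near-identical sequences, the intended regime).  Mapping is by ordinal
position along the chain, so author numbering quirks do not matter.  A
chain whose mapped residue is not the expected type yields no site; an
enzyme with zero sites is flagged for discard, mirroring how set members
without a conserved catalytic lysine are removed from real screens.  The
docking grid is centered on the anchor atom (lysine NZ, or cysteine SG
in aldehyde-dehydrogenase mode) and is a cube of edge
$S = \max(\text{maxDist}, 14)$ Å, where maxDist is the substrate's
maximum interatomic distance; the published rule states the dependence
and the 14 Å floor, and linear pass-through above the floor is the
simplest consistent reading (it is exposed as an argument).  Fixed
per-family boxes (e.g. 11 × 18 × 11 Å) are supported for the
aldehyde-dehydrogenase mode.

## Substrate preparation

`build_external_aldimine()` condenses the chosen primary amine of the
substrate with the 4-position carbon of PLP into the imine at the graph
level, then delegates the chemistry to Open Babel: 3D generation, pH 7.4
protonation (carboxylates deprotonated, phosphate dianionic, free
primary amines protonated, quaternary ammonium untouched), MMFF94s
minimization, Gasteiger partial charges.  If the supplied PLP bears the
4-aldehyde, the aldehyde oxygen leaves on condensation, so heavy atoms
obey substrate + PLP − 1.  These steps are contracts, not coordinate
reproductions of any particular toolkit: tests pin this package's own
outputs and graph-level invariants, never externally produced
coordinates.  The imine is modeled neutral by default; the protonated
iminium of the catalytic state can be produced by supplying a
protonated SMILES, but no claim is made about which the original screens
used.

Atom roles are recovered from the molecular graph alone (pyridine ring
as the 6-cycle through the ring nitrogen, ring positions oriented by the
3-hydroxyl, C&alpha; as the imine nitrogen's other carbon), which makes
the annotation invariant to atom input order.  Glycine-like substrates
have two &alpha;-hydrogens: both are recorded and $\chi_3$ takes the
larger $|\sin|$; no screened substrate makes this choice consequential.
If a pose file lacks hydrogens, H&alpha; is rebuilt at the ideal
tetrahedral position from C&alpha;'s three heavy neighbors and the
result is flagged.

## Validation statistics and kinetics

Rankings over a labeled set are summarized by ROC curves and the AUROC,
computed by the Mann–Whitney formulation (probability that a random
positive outranks a random negative, ties counting one half; tied metric
values receive average ranks — the original reports do not state tie
handling, so the standard convention is used).  Agreement between two
screens is Spearman rank correlation over shared enzymes.

The kinetics utilities cover the validation side of such a study:
nonlinear least squares of $v = k_\mathrm{cat} S / (K_m + S)$ (starting
values: maximum observed velocity, substrate level nearest half-max;
parameter SDs from the fit covariance), catalytic efficiency
$k_\mathrm{cat}/K_m$ with mM→M conversion and ratio error propagation
$\sigma_{\mathrm{eff}} = \mathrm{eff}\sqrt{(\sigma_{k}/k)^2 +
(\sigma_{K}/K)^2}$, and competitive-inhibition $K_i$ from the secondary
plot ($K_m^{app} = K_m^0 (1 + [I]/K_i)$, so $K_i = K_m^0/\mathrm{slope}$)
— the secondary-plot route is used because that is the stated published
procedure, although a global fit would agree on ideal data.  Velocities
are taken pre-normalized by enzyme concentration; a raw-velocity mode
with an enzyme-concentration argument is provided.

## What the synthetic fixtures emulate — and what they do not

Real screens need proteome-scale structure models and many CPU-days of
docking, so the package ships generators that emulate the *outputs* of
that pipeline with controlled ground truth: pose ensembles whose ring
plane and C&alpha; bonds achieve requested $|\sin\chi|$ values exactly
by construction, with chosen catalytic distances, cluster layouts
(members, separations, energy distributions) and per-pose CFC
probabilities; toy receptors with a known catalytic lysine or cysteine;
labeled screens in which positives are CFC-enriched by a stated effect
size; and noisy Michaelis–Menten data.  Members of a cluster are
jittered by a rigid translation under 0.9 Å plus 0.02 Å atomic noise —
deliberately inside the 3 Å clustering cutoff, so the requested cluster
structure survives by construction.  All generators consume an explicit
seed, save and restore the global RNG state, and are byte-reproducible.

Fixtures exercise geometry and statistics only.  They do not mimic real
active-site chemistry, receptor strain, pose-energy correlation, or
docking-engine failure modes; a perfect AUROC on an extreme-effect
fixture validates the ranking arithmetic, not the docking.  Published
headline AUROC values from proteome-scale screens are correspondingly
out of reach at desk scale and are not asserted anywhere in the tests.

## Numerical choices and problem sizes

* Plane fitting: SVD least squares over all six ring atoms; the normal's
  sign is canonicalized (first nonzero component positive) and
  $|\sin\chi|$ is insensitive to it.  The published plane–line angle
  formula only uses the bond *direction*, so the "line equation" is
  interpreted as the direction vector.
* Strict inequality for the Dunathan maximum; exact ties are not CFC.
* Greedy leader clustering is deterministic given energies; equal
  energies are visited in pose order.
* Michaelis–Menten fitting tightens `nls` convergence (`tol = 1e-10`)
  so noiseless data are recovered to numerical precision, with a
  Levenberg–Marquardt fallback for hard starts.
* Degenerate inputs error early with typed conditions: collinear point
  sets, empty ensembles, missing role atoms, non-positive grid edges,
  all-zero velocities, non-competitive inhibition series.

Test and validation runs use deliberately modest sizes — ensembles of
200 poses (the engine default), screens of 20–40 enzymes for the
pipeline checks and 500 enzymes at 40 poses each for the AUROC
convergence check, 1000 random poses for the brute-force classification
cross-check — which keep the full suite in the low minutes on one CPU
while still exercising every code path at realistic ensemble sizes.

## Known limitations

* The docking engine is wrapped, not reimplemented; without an engine
  only fixture ensembles or previously produced pose files can be
  analyzed.
* The amino-acid-only energy is not byte-comparable to any engine's
  decomposition; only its ordering behavior is relied on.
* Oligomer assembly requires alignable template chains; heteromeric
  assemblies must be specified explicitly via `assemble_heteromer()`.
* Sequence mapping assumes globally alignable sequences; distant
  homologs with large rearrangements are out of scope.

## A worked miniature screen

```{r screen, eval = FALSE}
scr <- make_screen_fixture(20, 6, effect = "extreme", seed = 101,
                           n_poses = 200, aa_energies = TRUE)
ranking <- rank_enzymes(scr$scores, "CC_CFC")
head(ranking[, c("rank", "enzyme_id", "CC_CFC", "BCE",
                 "mean_abs_sin_chi_inspected", "mean_d")])
auroc(ranking, scr$labels)   # 1.0 on the extreme-effect fixture
```
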