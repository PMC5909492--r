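---
title: "Mutual polymorphism in a heterodimer contact zone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual polymorphism in a heterodimer contact zone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidecyl)
```

## The problem

Plant LysM receptor-like kinases such as NFR5 and K1 are thought to perceive
rhizobial Nod factors as a heterodimer, with the ligand caught in the cavity
between the two receptor ectodomains.  If two proteins (or a protein and a
decorated ligand) interact across a contact surface, population-level
variation on one side is expected to be mirrored on the other: patches where
both subunits are variable ("mutual polymorphism") or both invariant
("mutual conservatism") are candidate functional epitopes, while one-sided
variation is more likely neutral.  `slidecyl` turns that idea into a
concrete computational pipeline operating on (i) atomic coordinates of a
docked two-subunit complex and (ii) pooled population alignments of the two
genes with per-haplotype copy counts.

## The contact surface

After a rigid re-orientation that puts the centroid--centroid axis on Z and
the origin at the midpoint between centroids, the contact zone is
discretised on a square XY grid (step 1 Å by default).  For each grid
column the surface height is the midpoint between the highest atom of the
lower subunit and the lowest atom of the upper subunit; a node is dropped
when either side is absent, when the subunits interpenetrate there, or when
the vertical gap exceeds `gap_threshold`.

Numerical choices worth stating:

* **Capture radius.**  A zero-width vertical ray almost never meets an atom
  center, so each column's bounds are taken over atoms within
  `step * sqrt(2) / 2` lateral distance — the smallest radius for which
  every atom is seen by at least one column.
* **Gap threshold.**  Default 8 Å: wide enough to keep a ligand-width
  cavity inside the contact zone, narrow enough to exclude open solvent.
  It is a parameter, not a constant of the method.
* **XY orientation.**  The in-plane orientation is fixed by rotating the
  first principal axis of the pooled atoms onto +X, with the eigenvector
  sign chosen by the third moment of the projections.  This makes the whole
  pipeline deterministic and invariant (to ~1e-9) under rigid pre-motions
  of the input complex; the sign rule is only ambiguous for exactly
  mirror-symmetric complexes, which do not occur with real coordinates.

## Sliding-cylinder diversity maps

At every defined node `C`, residues of one subunit are collected inside a
vertical cylinder of radius `r` (default 4 Å, unbounded in Z — the method
bounds membership laterally, and the subunit itself bounds it vertically).
Each residue `i` receives

* `f_i` — the fraction of its atoms inside the cylinder,
* `d_i` — the mean 3D distance of its atoms to the node, and
* the Gauss-decay weight `w_i = f_i * exp(-(d_i - min_j d_j)^2 / h)`,

with bandwidth `h = s^2 / 2` by default, where `s` is the mean
atom-to-centroid distance of the subunit (its "mean size", in Å, so `h` is
in Å²).  The node's diversity is then the residue-weighted population
statistic over the alignment columns mapped to those residues:

* **pi** — the average pairwise mismatch fraction over all pairs of
  population copies, `2 / (N (N-1) L) * sum_{j>k} sum_i (1 - I(A_ji, A_ki)) w_i`.
  Copy counts are honoured combinatorially (per-column state counts), never
  by materialising 100 rows.
* **dN/dS** — per-codon synonymous/non-synonymous site counts are the
  classic expected counts from the nine single-nucleotide neighbours
  (averaged over haplotypes, count-weighted); substitution counts enumerate
  the distinct single-nucleotide differences of each observed codon from
  the major codon, each classified against the major-codon background.
  The region ratio is `(sum k_n_sub w / sum k_n_site w) / (sum k_s_sub w /
  sum k_s_site w)`.

Two genuinely open choices were resolved as follows.  Substitutions are
counted against the **major codon** rather than over all codon pairs: in a
pooled population the dominant haplotype is the natural reference, and the
rule is deterministic (the alternative is discussed but not implemented as
the default).  Variant stop codons count as non-synonymous.  When the
synonymous substitution total is zero the ratio is reported as the sentinel
`undefined-high` (saturating the RG channel at 1) and when there is no
variation at all as `no-variation` (intensity 0); sentinels propagate
explicitly rather than as `Inf`/`NaN`.

The residue-to-column mapping slides the structure's chain sequence along
the count-weighted alignment consensus and takes the offset of maximal
identity, refusing matches under 0.9 identity.  This is packaging
convention, not science: structure numbering and alignment numbering come
from different programs and must be reconciled somehow.

## RG classification

The two subunits' maps become red and green channels, each normalised by
its own maximum over defined nodes (an all-zero channel stays zero; hence
classification is invariant to positive rescaling of either map).  The
four-way filter is applied with black first:

1. **black** — both intensities below `black_frac` (default 0.2): mutual
   conservatism;
2. **green** — G more than `ratio` (default 2) times R;
3. **red** — symmetric;
4. **yellow** — the remainder: comparable, non-negligible polymorphism on
   both sides.

Black-first precedence plus yellow-as-remainder guarantees a partition.
Under intensities uniform on the unit square the measure split is black
4%, red and green 24% each, yellow 48% — mutual and one-sided zones are
close to, but not exactly, equiprobable; the package documents its measured
split (a property test checks these areas by Monte Carlo) instead of
forcing equality.

## Ternary pose assembly and filtering

Two binary docking poses sharing subunit A are merged by superposing the
A copies (Kabsch on atoms matched by residue index and atom name; the
A--ligand pose is the anchor) and carrying B along.  Ligand--B contact is
then summarised by the mean nearest-atom distance `d`, the minimum distance
`dm`, and the overlapped-atom count `N_o` at threshold `t_o = 1` Å
(strict inequality).  A pose survives iff `N_o <= 10` and `d <= 5` Å —
both bounds inclusive, read literally from "not higher than".  Surviving
poses are clustered by heterodimer orientation: single-linkage on pairwise
B-subunit RMSD in A-anchored frames, cut at 5 Å, with the lowest-energy
member representing each cluster.  The RMSD is computed on B only: poses
merged from one shared A--ligand pose have identical ligand coordinates,
which carry no orientation information and would only dilute the distance.

Active-site co-occurrence uses the frequency-weighted indicator formula
`M_ij = sum_m f_m sum_s I_ms(i) I_ms(j)` and is biclustered by the
normalised-cut spectral embedding (leading eigenvectors of the
symmetrically normalised affinity, rows renormalised, k-means with a fixed
20-restart seed), which recovers planted block structure exactly and is
deterministic.

## Population tree congruence

Haplotypes of each gene (with copy counts) are collapsed to `k = 15`
pseudo-haplotypes by average-linkage clustering on Hamming distances —
linkage and distance are unstated upstream, so the standard deterministic
pair was chosen.  Pseudo-haplotypes are embedded in 3D by classical metric
scaling (deterministic sign convention; degenerate axes zero-padded) and
each population becomes a Gaussian mixture: component means from the
embedding, weights equal to pseudo-haplotype frequencies, and a shared
isotropic variance `sigma2 = (0.1 * mean inter-component distance)^2` — a
scale-free default, configurable, chosen so components are well separated
but not point masses.

Congruence between two mixtures is the squared L2 distance between their
densities, evaluated in closed form through pairwise Gaussian product
integrals.  The L2 form was chosen because it is symmetric, analytic,
zero exactly at identity and monotone in separation; a grid-integration
oracle in the test suite confirms the closed form to 1e-4.  The
superimposition minimises this discrepancy over rotations, translations
and mirror reflections — Kabsch on the frequency-weighted component means
for both the proper and improper branch, keeping the smaller discrepancy;
no scaling, since the method's motions are listed as rotation, translation
and reflection only.

Significance is assessed by shuffling pseudo-haplotype frequencies 1,000
times and recomputing the superimposed discrepancy; the p-value is
`(1 + #{null <= observed}) / (n_perm + 1)`.  Both mixtures' frequencies are
shuffled (the stronger null; shuffling one side only is available).  One
caveat is worth knowing: pseudo-haplotypes are indexed in decreasing
frequency order and the superimposition pairs components by index, so two
populations with similarly skewed frequency profiles are already partially
matched under the observed statistic.  The null therefore tests the joint
congruence of geometry and frequency profile, not geometry alone —
decoupled controls with independently shuffled frequencies are
non-significant in well over 90% of runs, which the acceptance suite
checks.

Tanglegrams connect leaves of the two neighbour-joining trees (ape's NJ)
that are mutual 5-nearest neighbours in the common post-superimposition
frame, ties broken by index.

## What the synthetic generator does and does not emulate

`synth_spec()` fixes the study conditions: pooled populations of 100 gene
copies collapsing to tens of haplotypes (defaults 40 nt / 25 aa;
study-scale runs use 77/50 and 36/30) with Zipf-skewed copy counts
(exponent 1, mimicking a dominant-haplotype population), codon-consistent
nucleotide/amino-acid pairs, and polymorphism confined to planted patches
with a 25% synonymous share.  Dimer fixtures are residue slabs on a 2.5 Å
lattice with 0.15 Å coordinate jitter and a planar interface at z = 0, 4 Å
of separation; ligands are short linear chains laid across the interface.
Synonymous-only haplotypes are derived one synonymous nucleotide step from
the major haplotype so that the major-codon substitution decomposition
stays synonymous by construction.

These fixtures are deliberately simple.  They have planar interfaces,
uniform residue sizes and no indel structure beyond gap handling, no
recombination, no selection, and geometry uncorrelated with sequence
except where planted.  Passing tests therefore demonstrates that the
machinery recovers planted truth under controlled conditions — correct
formulas, correct geometry, correct invariances — not that real receptor
interfaces behave like slabs, and not that a significant congruence test
on real data implies physical interaction.

## Problem sizes and tolerances

The test suite runs at small, fixed sizes chosen to exercise every code
path while staying quick: random-alignment oracles at n <= 20 sequences and
L <= 50 columns (50 replicates, agreement to 1e-12); all 61 sense codons
against a per-position enumeration oracle (exact); 8 x 8-residue slabs for
patch recovery; 20 random rigid motions for invariance (surface and maps to
1e-9, pose metrics to 1e-6); 1,000 permutations for the congruent pair and
50 seeded decoupled controls at 199 permutations each.  Grid integration of
the mixture L2 distance uses a 61-point-per-axis lattice spanning six
standard deviations beyond the component means.

## Known limitations

* The contact surface is single-valued in z per column, so deeply
  interdigitated interfaces with overhangs are flattened to their midpoint
  band.
* dN/dS within a cylinder is a descriptive ratio of weighted counts — no
  multiple-hit correction, no codon-model likelihood — and is undefined
  (sentinel) where synonymous variation is absent.
* The congruence test inherits the rank-pairing caveat above; it is a test
  of joint frequency-and-geometry congruence.
* Pose energies are accepted as given (lower is better); the package never
  computes physical energies.
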