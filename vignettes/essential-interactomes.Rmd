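---
title: "Assembling and scoring bacterial essential interactomes"
author: "essint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and scoring bacterial essential interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essint)
```

## The problem

Genes whose deletion abolishes viability concentrate in a small set of
conserved cellular machines, and most of those machines work as protein
complexes. A practical route to a bacterial "essential interactome" is to
(i) pool essential-gene calls from several species, (ii) pull candidate
pairwise interactions between those proteins from an evidence database,
(iii) predict a three-dimensional model for every surviving pair with a
multimer structure predictor, and (iv) keep the pairs whose models look
like real interfaces. `essint` implements that pipeline downstream of the
structure predictor: candidate-edge construction and filtering, confidence
scoring and triage of predicted binary complexes, interface geometry and
conservation statistics, validation against experimentally solved
references, and assembly of the resulting graph. A seeded synthetic-data
generator stands in for the GPU-scale prediction step so that every stage
can be exercised, with known ground truth, on a laptop.

## Candidate-edge construction

Essentiality calls are per-species tables of protein accessions. Species
are made comparable through an ortholog-group map (accession to group id),
and a group counts as essential only when it is flagged in at least
`min_essential_species` distinct species (default 2) — a single-species
call is treated as too weak to anchor an "essential" interaction.

Candidate edges come from STRING-format tables with a `combined` and an
`experimental` sub-score. An edge survives when

* `combined > 0.7` **or** `experimental > 0.15` (both thresholds strict;
  an edge at exactly the threshold is dropped),
* both endpoints are in the essential set,
* neither endpoint belongs to an excluded family (ribosomal proteins and
  tRNA ligases by default — they form huge assemblies that a binary
  predictor cannot treat meaningfully), and
* after per-species filtering, the pair is observed in at least
  `min_species_support` species (default 2 of 4).

The thresholds are applied per species *before* the consensus step; the
alternative (consensus first, thresholds on some aggregate score) would
let two sub-threshold observations vote an edge in, which is not what an
evidence cutoff is meant to do. Synthetic-lethal pairs are appended after
filtering, bypass the both-essential rule (their defining property is that
each member is dispensable alone), and are exempt from the multi-species
rule because such screens exist in a single reference organism. Edges are
canonicalized to lexicographic endpoint order, so all outputs are
invariant to row order and to the orientation of the input pairs.
Random negative pairs for calibration are rejection-sampled without
replacement from a seeded generator and verified against the positive set.

## Confidence scoring of predicted complexes

Each prediction job yields five ranked models; the representative is the
ipTM argmax (ties to the lexicographically smallest model id). Triage uses
the conventional bands: *unlikely* below 0.4, *plausible* from 0.4 to 0.6
inclusive on both ends, *high confidence* above 0.6. The inclusive
plausible band is deliberate: the outer categories are defined by strict
inequalities, so boundary scores must land in the middle class for the
three categories to partition [0, 1].

Two structure-aware estimators complement ipTM, with all constants shipped
in `inst/extdata/score_constants.yaml` (each group cites its source
publication; nothing is transcribed into code):

* **pDockQ** = $L/(1+e^{-k(x-x_0)}) + b$ with
  $x = \langle\mathrm{pLDDT}\rangle_\mathrm{iface}\cdot\ln N_\mathrm{contacts}$,
  contacts being C$\beta$ pairs (C$\alpha$ for glycine) within 8 Å.
* **pDockQ2** replaces the contact count with a PAE term: per chain,
  $X = \langle\mathrm{pLDDT}\rangle_\mathrm{iface}\cdot\langle 1/(1+(\mathrm{PAE}_{ij}/d_0)^2)\rangle$
  over interchain contact pairs with $d_0 = 10$ Å, pushed through its own
  published sigmoid and averaged over the two chains.

Both scores return 0 for a contact-free model, are invariant under
rigid-body motion, and pDockQ is monotone in interface pLDDT at fixed
contact count — all property-tested. Raw ipTM is the default ranking
quantity; the weighted $0.8\,\mathrm{ipTM}+0.2\,\mathrm{pTM}$ ranking
confidence can be read instead (`read_ranking(use =
"ranking_confidence")`) because predictor JSON files often carry only the
weighted value and the two are close but not identical.

## Interface analysis

The analysis cutoffs are 4.5 Å for *contact* residue pairs (any heavy-atom
distance) and 10 Å for *interface* residues, so contacts always nest
inside the interface. *Surface* atoms are those with at least 6.5 Å² of
solvent-accessible area on the isolated chain; the cutoff is an area even
though it is often quoted with a length unit, because the function it
mirrors thresholds exposed area. Solvent-accessible surface area is
computed with a Shrake–Rupley quadrature: each atom's van der Waals sphere
(Bondi radii, configurable, unknown elements fall back to a default with a
warning) is inflated by a 1.4 Å probe and covered with a golden-spiral
lattice of 960 test points; a point is buried if it falls inside any
neighbouring inflated sphere. Buried interface area is
$\mathrm{SASA}(A)+\mathrm{SASA}(B)-\mathrm{SASA}(AB)$; the per-chain
$\Delta$SASA split is reported alongside, since either convention appears
in the literature ("interface area" is sometimes the sum, sometimes half
of it).

Conservation tracks are integer scores from 1 (most variable) to 9 (most
conserved), supplied per residue. The interface-versus-surface contrast is
a Wilcoxon rank-sum test with tie correction (ties are guaranteed on a
9-level scale, so the normal approximation with correction is used
throughout rather than an exact route that ties would invalidate);
interface residues are removed from the surface contrast set to keep the
two samples disjoint. Residue-type contact networks count, per model, each
interchain residue pair whose side chains (heavy atoms minus backbone N,
CA, C, O; glycine contributes its CA) touch at 4.5 Å, accumulating
undirected weights over a model set.

## Validation against reference structures

Superposition is a Kabsch SVD fit with reflection correction; degenerate
(collinear) point sets are rejected. Residue correspondence between a
model and its reference is fixed by a chain map plus author sequence
numbering — the pipeline's models share sequences with their references,
so no alignment search is performed.

* **i-RMSD**: backbone RMSD over reference-defined interface residues
  (10 Å criterion) after superposing on those residues. Backbone
  (N, CA, C, O) is the default; a heavy-atom mode exists because the
  convention is not universal.
* **Fnat**: fraction of reference interchain residue contacts (heavy-atom
  5 Å) preserved in the model.
* **L-RMSD**: ligand backbone RMSD after superposing on the receptor (the
  longer reference chain; ties go to the first chain).
* **DockQ** $= (F_\mathrm{nat} + 1/(1+(\mathrm{iRMS}/1.5)^2) +
  1/(1+(\mathrm{LRMS}/8.5)^2))/3$.
* **TM-score** over the concatenated chains with
  $d_0 = 1.24(L-15)^{1/3}-1.8$ (floored at 0.5, $L$ = reference residue
  count), maximized by the standard iterative scheme: superpositions
  seeded from contiguous fragments (full length, halves, quarters), each
  refined by re-fitting on residues inside a distance shell until the
  score stops improving.

Crosslink restraints default to 20 Å C$\alpha$–C$\alpha$ between lysines —
the upper end of the 15–20 Å window spanned by lysine-reactive
crosslinkers — and are configurable per restraint; restraints whose
residues are absent or not lysine are skipped and reported rather than
counted as violations. The benchmark metadata filter keeps heterodimers
released after 2021-09-30, solved by X-ray or cryo-EM at ≤ 2 Å, marked as
their structural cluster's representative, with training-set identity
strictly below 30%; the clustering itself is an input flag since it is
produced by external tools.

## Distribution statistics and the graph

Selected-versus-random score sets are compared with ECDFs and a two-sample
Kolmogorov–Smirnov test whose p-value is exact when $nm \le 10^4$ (with an
exhaustive permutation enumeration when ties block the classical exact
distribution, feasible for pooled sizes up to ~14), and asymptotic
otherwise. The histogram contrast uses 10 equal-width bins on [0, 1]
(configurable; a per-bin 2×2 chi-square without continuity correction plus
an overall homogeneity statistic, with expected-count-below-5 flags).
Category summaries report percentages to 2 decimals with half-up rounding
so they can be compared digit-for-digit with tabulated values. The
interactome graph is a simple undirected `igraph` with ipTM, pDockQ,
pDockQ2 and category edge attributes; duplicate pairs keep the
maximum-ipTM record (mirroring best-model selection), self-loops are
rejected, and exports are GraphML plus a Cytoscape-style
source/target TSV.

## The synthetic-data generator

`synth_interactome()` emulates the database-derived inputs: four species
per Gram group, a 60-group protein universe, each group essential in a
species with probability 0.6, 40 planted high-evidence edges (combined
scores around 0.78–0.99, experimental 0.2–0.9, observed in a random subset
of species), an equal number of sub-threshold decoys, small
ribosomal/tRNA-ligase families, and two synthetic-lethal pairs. Scores get
Gaussian noise (sd 0.05) and are quantized to the 0–1000 integer export
scale; the ground truth (which edges survive all filters) is computed from
the quantized values actually written, so recovery tests are exact rather
than probabilistic. These sizes keep a 25-seed recovery sweep in the test
suite under a few seconds while still exercising every filter clause.

`synth_dimer()` builds two ideal polyalanine α-helices (φ = −57°,
ψ = −47°, standard bond geometry, constructed by natural-extension
internal-to-Cartesian placement) with the second chain rotated 180° about
the helix axis and offset by `interface_separation` (default 9 Å, which
yields a genuine contact interface); `axial_offset` slides chain B along
the axis so that only the overlapping segment is interfacial, which is how
fixtures obtain surface residues outside the 10 Å band. The perturbed copy
adds seeded coordinate noise and/or a rigid offset to chain B, giving
monotone families for RMSD/TM-score tests.

`synth_confidence()` and `synth_conservation()` are statistical
surrogates: pLDDT ~ N(90, 3) and interchain PAE ~ N(3, 1) for
high-quality bundles versus N(50, 10) and N(25, 4) for low quality, and
uniform 1–9 conservation with a clipped `+shift` on interface residues.
They reproduce none of a real predictor's error structure — no correlation
between pLDDT and local geometry, no PAE asymmetry patterns, no
domain-level error modes — so passing tests demonstrate the correctness of
the downstream arithmetic and orderings, not predictive performance on
real complexes.

## Numerical choices and degenerate inputs

Distance cutoffs are inclusive (a pair at exactly the cutoff counts).
SASA quadrature error scales with the point count; doubling 960 points
moves per-atom values by well under 0.5% of the atom's sphere area, and
the buried area of fully separated chains is zero only up to that
tolerance. Score-free models (all B-factors zero) raise an error rather
than silently scoring with pLDDT 0. Kabsch rejects collinear sets;
TM-score requires at least 3 matched residues; Fnat refuses references
with no interchain contacts; the conservation contrast refuses samples
smaller than 2. Waters are dropped on reading; alternate locations
collapse to the highest-occupancy copy; multi-model files keep the first
model; insertion codes trigger sequential renumbering with a logged map.

## Problem sizes in the shipped tests

The suite builds everything it needs at run time: dimers of 10–24 residues
per chain, interactomes of 60 groups × 4 species, 25-seed recovery sweeps,
a 1000-replicate null calibration and a 100-replicate power check for the
conservation contrast, and Monte-Carlo SASA oracles of 10^5–10^6 points on
2–3-atom fixtures. The full suite and the acceptance script each complete
in well under the times a routine CI run allows.

## Known limitations

* Binary complexes only; stoichiometries beyond two chains are out of
  scope (operations that need two chains say so).
* Orthology, conservation scoring and structural clustering are inputs,
  not computations; the package trusts their ids and flags.
* The KS exact-with-ties route is exhaustive and therefore limited to
  small pooled samples; larger tied samples get the asymptotic p-value.
* pDockQ/pDockQ2 constants are taken from their publications as-is; no
  refitting is attempted, so scores on exotic complexes inherit whatever
  calibration bias the originals carry.
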