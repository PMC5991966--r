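---
title: "Methods: conformational-ensemble analysis and allosteric site characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-ensemble analysis and allosteric site characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostruct)
```

## The problem

Small GTPases such as Rab11 cycle between GDP- and GTP-bound states and are
crystallized in many conformations — alone, with nucleotide analogs, and in
complex with effectors. A single static structure hides transient surface
pockets; an ensemble of deposited chains, analyzed jointly, can reveal them.
This package implements that ensemble workflow end to end: build a common
C-alpha frame across the chains, superpose them on their most rigid core,
quantify flexibility and correlated motions, select a small set of
representative structures by clustering in low-dimensional embeddings, probe
allosteric communication with residue interaction networks, re-score docking
hits against the candidate pockets, and compare pocket conservation across
related GTPases (Rab1, H-Ras).

## Ensemble construction and superposition

Each chain is parsed into an ordered residue list; only residues with a
resolved C-alpha are kept, alternate locations resolve to the
highest-occupancy copy (ties to altloc "A"), waters are discarded,
insertion-coded residues are excluded from the shared frame, and
selenomethionine is read as methionine. Author residue numbering is used
verbatim, because the literature's residue labels (S20, E108, ...) are author
numbers. The **residue frame** is the sorted intersection of residue numbers
resolved in every member; all matrices are indexed by it.

Superposition uses the Kabsch algorithm (SVD of the cross-covariance with a
determinant correction, so reflections are never returned). The reference is
deliberately deterministic: fit everything to the first member, then one
refinement pass onto the member mean. The **invariant core** is found by
iterative trimming: superpose on the current core, compute each core
residue's positional scatter as the volume of its scatter ellipsoid (the
product of the principal axes of the 3x3 positional covariance, in cubic
angstrom), drop the most variable residue, repeat. The stop rule —
maximum scatter volume at most `v_stop = 1.0` cubic angstrom, with a core
floor of `max(30, 0.4 m)` residues — is a package choice: iterative
core-finding of this family is standard, but published descriptions rarely
state their thresholds, so both knobs are exposed as arguments.

## Flexibility, deviation, and correlated motions

RMSF is the root-mean-square displacement of each residue about its
ensemble-mean position after core superposition. Pairwise RMSD matrices are
computed in the *shared* superposed frame (no per-pair refit), optionally
restricted to a sequence region (switch 1: residues 39-46, interswitch:
47-67, switch 2: 68-79, P-loop: 18-25, and the RabF/RabSF motifs are
predefined). The dynamical cross-correlation matrix is
\(C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
\sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}\)
with displacements taken about the ensemble mean after core superposition —
for a crystal-structure ensemble (not a trajectory) this reference must be
made explicit, and the ensemble mean is the only reference that makes the
matrix independent of member order. Residues with zero fluctuation would
make \(C_{ij}\) undefined; they are reported as 0 and flagged rather than
raising an error, so fully rigid synthetic residues do not abort runs.

## Embeddings and representative selection

Three complementary embeddings of the n x 3m coordinate matrix feed
hierarchical clustering:

* **PCA** on the column-centered matrix (via SVD). Reported variance
  fractions are eigenvalues over total variance; component signs are fixed
  so each component's largest-magnitude loading is positive, which makes
  score files reproducible run to run.
* **FastICA**, hand-implemented: PCA whitening to d dimensions followed by
  deflationary fixed-point iterations with the log-cosh contrast
  (an approximation to negentropy), tolerance 1e-6, at most 200 iterations
  per component, mandatory seed. Non-convergence is flagged on the result
  (with partial components kept) instead of thrown, since nearly Gaussian
  inputs are legitimate.
* **LLE**: per-sample reconstruction weights over the k nearest neighbors,
  solved by constrained least squares with the neighbor Gram matrix
  regularized by `1e-3 * trace` (needed whenever k exceeds the local
  intrinsic rank); the embedding is the bottom non-trivial eigenvectors of
  \((I - W)^\top (I - W)\). A disconnected neighbor graph has no meaningful
  global embedding, so it is an error that names the components.

The LLE neighborhood size k is chosen by re-embedding for each candidate and
keeping the k that maximizes the Pearson correlation between high-dimensional
and embedded pairwise distance matrices. The literature this follows cites an
unpublished selection procedure without reproducing it; the
distance-correlation criterion is this package's documented stand-in, chosen
because it is deterministic, cheap at these ensemble sizes, and directly
measures what LLE should preserve. Candidates whose neighbor graph is
disconnected score `NA` and are skipped.

Clustering is agglomerative (`hclust`) on Euclidean distances in the
embedding, average linkage by default; the linkage and the number of
clusters k are per-analysis settings because dendrogram cut choices are not
derivable from first principles. Each cluster is represented by its
**clustroid** — the member minimizing summed within-cluster distance, with
ties broken by member order — a definition that is exhaustively checkable
and is asserted in the tests.

## Residue interaction networks

For each representative, residues become nodes and an edge joins two
residues iff their C-alpha separation is at most 7.0 angstrom, weighted by
that distance (to three decimals). Betweenness centrality is
weighted-shortest-path betweenness normalized by \((N-1)(N-2)/2\). Shortest
paths between site residues and nucleotide-site residues are
minimum-total-weight paths; among ties the path with fewer nodes and then
the lexicographically smallest residue sequence wins — the tie rule is a
package decision made purely for determinism, since regression tests need
byte-identical outputs. Nucleotide contacts are residues with any heavy atom
within 4.0 angstrom of a bound GDP/GTP(-analog) heavy atom.
Center-of-mass distances are measured from each residue's C-alpha to the
mass-weighted center of all polypeptide atoms (ligands excluded); whether
published helper tools use all atoms or C-alpha only is unknown, which is
why comparisons against printed center-of-mass distances should treat them
as bounds rather than point values.

## Screening re-score and rule of five

Docking tables (ligand, target, site, Vina free energy, interaction count)
are validated and duplicate records collapse to the lowest energy. The
weighted score normalizes the negated energy and the interaction count to
[0, 1] by min-max *within the compared list* — the published weighting (80%
energy, 20% interactions) specifies no scale, and min-max is the only choice
that makes the two terms commensurate without external calibration; a
constant column normalizes to 1.0 so degenerate lists still rank. Ranking
descends by score with ties broken by lower energy, then ligand id.

Interaction counts can be recomputed from coordinates by the geometric
profiler: hydrogen bond = protein N/O to ligand N/O within 3.5 angstrom;
hydrophobic contact = apolar carbon pairs within 4.0; salt bridge = opposite
charge-group centers (Lys NZ, Arg CZ, Asp/Glu carboxylate midpoints; ligand
nitrogens and carboxylate-like groups) within 5.5; pi-cation = cation to
aromatic ring centroid within 6.0. Crystal structures carry no hydrogens,
so angle criteria are deliberately omitted; these are the widely used
distance-only defaults. Apolar carbons and ligand rings are inferred from a
1.8 angstrom covalent-distance bond graph, since ligand records carry no
connectivity.

Rule-of-five evaluation counts violations of donors <= 5, acceptors <= 10,
mass < 500, logP <= 5, and passes a compound with at most one violation.
The published descriptor table this was calibrated against marks a
six-donor compound as compliant (supporting the one-violation convention)
but leaves several single-violation compounds unmarked, so only the
unambiguous rows (marked compounds, and compounds with two or more
violations) are asserted in the tests.

## Sequence and binding-site conservation

Global pairwise alignment is Needleman-Wunsch with BLOSUM62, gap open 10 and
gap extension 0.5 (a length-L gap costs open + L*extend), standing in for
the web aligner used in the literature. Percent identity divides identical
columns by mutually non-gap columns; site identity restricts the columns to
those whose residue number in the first sequence belongs to the site residue
set (site 1: 11 residues around D19/S20 and the 101-112 helix face;
site 2: 16 residues on the distal helix face and the 145-149 loop). An `X`
marks an unknown residue and never counts as an identity. Published
identities from other aligners can differ by a few percentage points purely
from gap placement and denominator conventions; with an 11-residue site the
identity is quantized in steps of 9 points, so small printed percentages may
not be exactly representable under any column-restricted definition.

The package ships transcribed reference sequences for the Rab11a GTPase
domain (with a few unverifiable positions masked as X), Rab1a and H-Ras, and
a `fetch_uniprot()` helper for retrieving canonical records where a network
is available; computed identities on the bundled copies are reported as
such.

## The synthetic-data generators

All tests run without downloads because the generators produce every input
with recorded ground truth:

* `make_chain()`: self-avoiding C-alpha walks (3.8 angstrom virtual bonds,
  3.0 angstrom clash floor by rejection) with minimal backbone/CB dummy
  atoms so the profiler and center-of-mass code have atoms to work on.
* `make_ensemble()`: members = base chain + planted family mean + planted
  collective modes + isotropic noise, then a random rigid transform per
  member — applied by default precisely so no test can accidentally bypass
  the superposition step. Defaults emulate the crystal-ensemble setting
  analyzed here: 27 members, 160 residues, three families, 3.0 angstrom
  between-family displacement against 0.3 angstrom coordinate noise (a 10:1
  ratio), and two soft modes (1.0 and 0.6 angstrom).
* `make_correlated_ensemble()`: displacement amplitudes drawn from a
  multivariate normal carrying the requested pairwise correlations along a
  shared direction, so the population DCCM entry equals the planted rho
  exactly; the symmetric matrix square root tolerates rho = +/-1.
* `make_complex_fixture()`: minimal complexes containing exactly one planted
  interaction per type at an exact distance, everything else spaced beyond
  every cutoff — including just-over-cutoff boundary fixtures.
* `make_screen_table()`: score tables with the ground-truth ranking recorded
  by direct arithmetic.

What the generators deliberately do not emulate: real side-chain packing,
secondary structure, crystallographic disorder correlated with B-factors,
and chemically realistic ligands. Green tests on synthetic data therefore
demonstrate that the *computations* are correct under known ground truth,
not that any biological conclusion transfers; conclusions about real
ensembles require the deposited coordinates, which the accession-driven
checks consume from a local cache when available.

## Problem sizes and numerical choices

The shipped analyses and tests use 27-member x 160-residue ensembles
(matching the crystal-ensemble scale), n = 1000 members for correlation
recovery, 500 samples for source separation, 200 random networks of at most
8 nodes for exhaustive path enumeration, and 100 random 10-point pairs for
the rotation-space cross-check — sizes at which every brute-force oracle is
exact and fast. Degenerate inputs are first-class: collinear superposition
subsets and empty region selections are errors; zero-fluctuation residues,
constant score columns and unreachable node pairs are flagged results, not
errors, because they occur naturally in clean synthetic data.

## Known limitations

* Representative selection below the dendrogram cut (linkage, k) is
  configuration, not inference; the package reports but never asserts
  cluster counts.
* The interaction profiler is distance-only; without hydrogens or formal
  charges it over-counts relative to profilers that model protonation and
  geometry, which is acceptable for its role here (an interaction *count*
  entering a 20% score term).
* Identity values depend on aligner conventions at the few-percent level;
  the bundled Rab11a sequence is the GTPase domain only, which slightly
  inflates full-sequence identities relative to full-length comparisons.
* Docking engines are out of scope: score tables are inputs, and only the
  re-scoring on top of them is implemented.
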