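---
title: "Hierarchical combinatorial assembly of protein complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical combinatorial assembly of protein complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierasm)
```

## The problem

Deep-learning structure predictors produce excellent models of protein
*pairs*, but large multi-subunit complexes exceed GPU memory and degrade
prediction quality.  `hierasm` takes the opposite route: predict only
small subsets (pairs, occasionally triples to quintuples), then assemble
the full complex *combinatorially* from the pairwise geometry, guided by
the predictor's own confidence estimates.  The inputs per predicted model
are the coordinates, a per-residue plDDT confidence (0–100) and the
predicted aligned error matrix (PAE, in Ångström, 0–30): the expected
positional error of residue *i* when the model is aligned on residue *j*.
Low inter-chain PAE is the signal that an interface is trustworthy.

The pipeline has three stages:

1. **Job planning** (`plan_subset_jobs()`): which subunit subsets to
   predict.  Pairs are always predicted; up to three larger subsets of
   three to five subunits per subunit are planned greedily from the best
   pairwise scores, subject to a 1,800-residue total sequence budget so
   each job fits common GPU memory.
2. **Unified representation** (`select_representatives()`,
   `build_transform_library()`): one rigid *representative* structure per
   subunit (the copy with maximal mean plDDT across all models, ties
   broken by model id and copy index), plus a library of scored rigid
   transformations between representatives, one per interacting pair per
   model.
3. **Combinatorial assembly** (`assemble()`): N iterations of expansion,
   filtering and clustering over subcomplexes, with a beam of the K best
   candidates per subunit composition.

## Extracting and scoring transformations

Two placements interact when some Cα–Cα distance is strictly below 8 Å.
For an interacting pair (A, B) the representatives A′ and B′ are
superposed onto their placements by minimal-RMSD (Kabsch) fits T₁ and T₂;
the library records the relative transform that places B′ in A′'s
reference frame (apply T₂, then the inverse of T₁ — equivalently the
transform-chain composition usually written T₂∘T₁⁻¹).  Because predicted
models disagree most in disordered regions, the superposition uses only
residues with plDDT above 80; when fewer than half the residues qualify,
the ⌈L/2⌉ residues of highest plDDT are used instead (the rounding is a
package choice; the rule is only stated as "at least half").

Each transformation is scored from the mean inter-subunit PAE `P` as

    S = max(1, 100 − P²/4)

so scores live in [1, 100].  The quadratic keeps differences between
confident interfaces (P of 1–5) meaningful while flattening everything
the predictor already distrusts.  `P` averages over *all* residue pairs
of both inter-subunit PAE blocks, not only interface residues: the score
is meant to rate the whole relative placement, and the all-pairs mean is
isolated in `compute_mean_pae()` should a different definition be wanted.
Near-duplicate transforms of the same pair (transformed-representative
RMSD below 1 Å, the clustering tolerance) are merged keeping the best
score; for homomeric pairs both orientations are kept since neither copy
is privileged.

## The assembly loop

With N total subunit copies, iteration *i* (2…N) merges disjoint
subcomplexes of sizes *k* and *i−k* through every library transformation
between an anchor subunit on each side; the rigid motion induced through
the anchors moves the whole second side.  A candidate's raw score is the
sum of the (possibly symmetry-rewarded) transformation scores over its
binary assembly tree.  Per subunit composition the K best cluster
leaders are kept (default K = 100).  If no full-size assembly survives,
the largest partial assemblies are returned.

Three filters act on every candidate:

* **Steric clashes.** Backbone atoms (N, CA, C, O) with plDDT above 80
  participate; a static disordered tail would otherwise veto every
  arrangement.  An atom clashes when its centre penetrates another
  subunit's van-der-Waals surface by more than 1 Å, read as sphere
  overlap depth `r_i + r_j − d > 1`, with standard element radii
  (N 1.55, C 1.70, O 1.52 Å).  A candidate is discarded when, for some
  tested subunit pair, more than 5% of one subunit's confident backbone
  atoms clash.  The implementation prunes by bounding spheres and a
  Cα-level residue prescreen (backbone atoms sit within ~1.5 Å of their
  Cα, so atoms can only clash if their Cαs are within 6.5 Å); an
  unpruned all-pairs check backs it in the test-suite oracle.
* **Chain connectivity.** Subunits that are segments of one chain (they
  share chain identifiers; order and linker length follow from
  `start_res` and sequence length) must keep their junction Cαs within
  `(n_linker + 1) × 3 Å`.  The `+1` covers the peptide bond itself when
  the segments abut (`n_linker = 0`), where a literal reading ("number
  of linker residues times 3 Å") would demand a 0 Å bound.  With
  multiple copies the placed copies are matched greedily by distance.
* **Restraint violation** (below).

**Symmetry reward.** Pairwise assembly systematically underrates large
symmetric oligomers, so when a merged subcomplex consists of more than
five copies of one subunit forming a single orbit under one repeated
library transformation (tracked on the assembly tree), the merging
score is boosted to `S + S(100−S)/100`.  The boost has a fixed point at
100 and roughly halves the distance to it.

**Clustering.** Candidates of identical composition are clustered
greedily in descending score order with a 1 Å Cα RMSD threshold.  With
*p* identical copies there are *p*! equivalent labelings; the
correspondence is resolved on the subunit centroids: when the number of
per-type permutations is small (at most 24 combinations, e.g. up to four
copies of one subunit) they are enumerated outright, otherwise the
correspondence starts from copy order and hill-climbs over pairwise
swaps until the centroid RMSD stops improving — pure swap climbing can
stall in local minima that need a 3-cycle, which the small-case
enumeration removes at negligible cost.  The final correspondence is
scored by full Cα RMSD.  The test suite validates the resolution against
the factorial enumeration of the full-Cα optimum: exact for up to three
copies, and within 0.5 Å for four copies over 100 seeded trials, with
gaps logged rather than hidden.

**Bounded expansion.** Exhaustive expansion over beams × anchors ×
transforms is quadratic in K and explodes on decoy-rich homomers.  Two
bounded-search devices keep it tractable without touching the top of the
ranking: (i) candidates are deduplicated by a frame-invariant fingerprint
(sorted subunit-pair centroid distances at 0.1 Å resolution, plus the raw
score) before any geometry is built — residual collisions are exactly
what the 1 Å clustering would merge anyway; (ii) per composition only
`pool_factor × K` best-scoring candidates are retained pre-clustering,
and beam pairs are visited in descending raw-score order with the
admissible bound `raw₁ + raw₂ + 2·max(S)` so provably non-competitive
merges are skipped.  The best-scoring candidate can never be pruned by
either device, which is what the exhaustive-enumeration equivalence test
checks.

**Determinism.** There is no randomness anywhere in assembly; ties are
broken by (score, geometry fingerprint) everywhere, so identical inputs
give identical ranked outputs.

## Distance restraints and assembly groups

Crosslinking mass-spectrometry data enter as Cα–Cα upper bounds with an
experimental weight w₁ in (0, 1].  Each restraint also gets a structure
weight w₂ = mean plDDT of its two endpoint residues / 100, so links
anchored in disordered regions count less.  With multiple copies a
restraint is ambiguous: it is satisfied if *any* candidate endpoint pair
is below the bound (strict `<`, matching the interaction threshold
convention).  The satisfaction ratio of a subcomplex is

    ratio = Σ_satisfied w₁·w₂ / Σ_applicable w₁·w₂

where a restraint is applicable when both endpoint subunits are present;
with nothing applicable the ratio is 1.  Scores are multiplied by the
ratio at every iteration, and candidates violating more than 10% of the
applicable restraint *weight* are discarded.  Reading the "percentage of
restraints" in the same weighted currency as the ratio keeps one
consistent bookkeeping; a count-based reading would treat a low-plDDT
link and a high-confidence one as equals.  The final ranking likewise
multiplies the predicted confidence by the ratio when restraints are
present — without this, a high-scoring geometry violating restraints
would keep rank 1 and restraints could never change the answer; without
restraints the ranking is unchanged.

Known subcomplexes can be enforced as assembly groups: any candidate
containing part of a group may contain only members of that group, so
groups are completed before cross-group merges are attempted.

## Predicted confidence

The confidence of an assembled structure is the weighted mean of the
transformation scores used to build it, with each transformation
weighted by the amino-acid count of the smaller of the two subcomplexes
it merged: transformations that positioned more of the structure matter
more.  Confidence lies in [1, 100] and is invariant to the tree
serialization order.

## Stoichiometry scanning

The expensive inputs — representatives and the transformation library —
are computed once; `scan_stoichiometries()` then re-runs only the (fast)
assembly per candidate copy number of one subunit.  Two signals locate
the true stoichiometry: the confidence curve (the symmetry reward makes
closed, fully symmetric arrangements the most confident, and an
arrangement past its geometric capacity cannot be built at all) and the
assemblability flag itself, which drops to `FALSE` once the clash filter
rejects every candidate.

## Evaluation utilities

`pairwise_connectivity()` diagnoses whether assembly is possible at all:
a graph over the placed subunit copies of a reference structure (copies,
not unique subunits, so a missing homomer interface is visible) with an
edge wherever some library transform reproduces the true relative
placement at acceptable interface quality, default threshold 0.23 on a
DockQ-style composite (`edge_quality()`: native-contact fraction with
Cα contacts at 8 Å, interface RMSD scaled by 1.5 Å, ligand RMSD scaled
by 8.5 Å; the function is pluggable so a reference implementation can be
substituted).  The returned ratio is the amino-acid fraction of the
largest connected component.  `tm_score()` implements the standard
length-normalized TM-score with `d0 = 1.24(L−15)^{1/3} − 1.8` (floored
at 0.5 Å), optimized by iterative superposition refinement from several
starts and sharing the copy-correspondence machinery.

## The synthetic data generator

`toy_complex_spec()` fabricates everything a predictor would provide:
idealized subunits, ground-truth complexes (ring / chain / tree
topologies, contacting neighbours placed at a 6 Å minimal Cα distance,
non-neighbours kept beyond the 8 Å interaction threshold), pair models
in PDB + score-JSON form with controllable Gaussian coordinate noise
(`coord_noise_sd`, per coordinate), plDDT profiles (default 90, optional
low-confidence tails to exercise the alignment and clash masks),
block-structured PAE (defaults: intra 1 Å, true interfaces 2 Å, decoys
30 Å), and decoy pair models in uniformly random relative orientations
placed in surface contact — geometrically plausible, distinguishable
from true interactions only through PAE, which is exactly the signal
the method relies on.

Design notes, chosen once:

* Toy subunits of more than 25 residues are antiparallel helix bundles
  rather than single long helices.  A lone ideal helix has ~2.3 Å radial
  spread and is nearly degenerate to rotation about its own axis, so
  coordinate noise produces wildly unstable superpositions — a pathology
  no globular domain has, and fixtures exist to emulate real inputs.
* Simulated crosslinks are sampled under a Cα–Cα cutoff *stratified
  across contacting subunit pairs* (even quotas, uniform within a pair).
  Plain uniform sampling over residue pairs lets the largest interface
  monopolize every link, leaving other subunits unconstrained — real
  crosslink datasets report links across all interfaces.  The defaults
  used in the rescue experiments (12 links, 10 Å bound) are scaled to
  the toy complexes, whose diameters are ~30–50 Å.
* The generator does not enforce `pae_true < pae_decoy`: the
  restraint-guidance experiments deliberately invert the two to create
  fixtures where decoys outscore true interfaces.
* What the fixtures do **not** emulate: side chains, secondary-structure
  packing, sequence-dependent geometry, missing residues, PAE
  heterogeneity within a block, or predictor failure modes beyond rigid
  decoys.  Passing tests demonstrate the algorithmics — scoring,
  search, filtering, restraint integration — not predictive accuracy on
  real proteins, which is bounded by the upstream predictor.

All generator outputs are byte-identical functions of the spec seed.

## Numerical choices and problem sizes

Kabsch superposition uses the SVD determinant correction (no
reflections) and refuses fewer than three points.  Rotation matrices are
validated to 10⁻⁶ orthonormality.  Clustering comparisons use the
Kabsch energy form of the fitted RMSD (no rotation is built).  PDB
coordinates carry three decimals, so file round-trips are exact to
5×10⁻⁴ Å; precision-critical tests use in-memory models.

The test suite and the acceptance script run on deliberately small
instances chosen to finish within minutes on one CPU while still
exercising every code path: rings of 10 × 20-residue subunits (with 5
decoys), hetero trees of 6 × 15–60-residue subunits, stoichiometry scans
over 2–15 copies, and exhaustive-enumeration cross-checks on instances
of at most 4 copies and 6 transforms, where enumeration is feasible.

## Known limitations

* Gap-free inputs: predicted models with missing residues are rejected,
  not repaired (fixtures never produce them; real-world gap tolerance is
  an extension point at the I/O boundary).
* Chains are matched to subunits by exact sequence, ties broken by
  config order; two subunits sharing one sequence are therefore
  interchangeable at input time.
* The correspondence heuristic is not guaranteed optimal beyond three
  identical copies; the tests record its gap against factorial
  enumeration rather than asserting perfection.
* No force-field relaxation: interfaces inherit representative-subunit
  side effects (the method trades interface finesse for global
  assembly), and clashes below the filter thresholds survive.
* The stoichiometry scan varies one subunit's copy number; grid scans
  over several subunits are out of scope.
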