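# hierasm

Hierarchical combinatorial assembly of large protein complexes from
predicted pairwise subunit models.

## The problem

Deep-learning structure predictors are excellent at protein *pairs* but
struggle with large multi-subunit assemblies: GPU memory bounds the total
sequence length, sampling degrades as the number of inter-chain contacts
grows, and each run converges to a single answer.  `hierasm` targets the
structural biologist who has (or can compute) predicted models of subunit
pairs and small subsets — e.g. AlphaFold-Multimer runs driven through
ColabFold, with per-residue plDDT and the predicted aligned error (PAE)
matrix — and wants the full complex, optionally guided by crosslinking
mass-spectrometry distance restraints, with stoichiometry scanning when
copy numbers are uncertain.

## The method

1. **Unified representation.**  For every subunit the copy with maximal
   mean plDDT over all predicted models becomes its rigid
   *representative*.  Every interacting pair in every model (Cα–Cα
   distance < 8 Å) yields a rigid transformation between representatives,
   obtained from the minimal-RMSD (Kabsch) superpositions T₁, T₂ of the
   representatives onto their placements, composed as T₂∘T₁⁻¹ and
   restricted to confident residues (plDDT > 80, or the top half).
   Each transformation is scored from the mean inter-subunit PAE `P`:

       S = max(1, 100 − P²/4),   S ∈ [1, 100]

2. **Combinatorial assembly.**  With N subunit copies, iteration *i*
   (2…N) merges disjoint subcomplexes of sizes *k* and *i−k* through
   every applicable library transformation, discards candidates with
   steric clashes (> 5% of a subunit's confident backbone atoms
   penetrating > 1 Å into another subunit's van-der-Waals surface),
   broken chain connectivity (same-chain segments further apart than
   `(n_linker + 1) × 3 Å`) or restraint violations (> 10% of the
   applicable restraint weight), clusters the survivors at 1 Å RMSD with
   copy-correspondence resolution, and keeps the K = 100 best per
   subunit composition.  Subcomplexes with more than five identical
   copies related by one repeated transformation earn a symmetry reward
   `S + S(100−S)/100`.

3. **Confidence.**  An assembly's predicted confidence is the
   amino-acid-weighted mean of the transformation scores used to build
   it (weight = size of the smaller merged side).  Crosslink restraints
   multiply scores by the weighted satisfaction ratio
   `Σ_satisfied w₁w₂ / Σ_all w₁w₂`.

A synthetic-fixture generator fabricates complete inputs (toy complexes
with ring/chain/tree geometry, controllable coordinate noise, plDDT/PAE
profiles and decoy interactions) so the entire pipeline runs and is
tested without a structure predictor.  See the methods vignette
(`vignettes/assembly-methods.Rmd`) for the full model description and
design rationale.

## Worked example

Assemble a 10-copy ring whose inputs also contain five decoy pair
models (wrong orientations, high PAE):

```r
library(hierasm)

spec <- toy_complex_spec("ring",
                         list(list(name = "R", length = 20, copies = 10)),
                         seed = 1, n_decoys = 5)
fab    <- fabricate_predictions(spec)                 # predictor stand-ins
models <- unname(fab$pred)
reps   <- select_representatives(models)
lib    <- build_transform_library(models, reps)
res    <- assemble(reps, lib, fab$gt$config)

res$full
#> [1] TRUE
predicted_confidence(res$subcomplexes[[1]])
#> [1] 99.55
assembly_rmsd(res$subcomplexes[[1]], fab$gt, reps)
#> [1] 0
```

The true interfaces carry PAE 2 (score 99); the five decoys carry PAE 30
(score 1).  The beam reassembles the ring onto the ground truth exactly
(noise-free fixture; with 0.5 Å coordinate noise the recovery stays
under 1 Å), and the confidence 99.55 reflects the symmetry reward that boosts
merges once more than five identical copies share one transformation.
Stoichiometry scanning reuses one transformation library across copy
numbers (here the decoy-free library of the same ring, which keeps the
14 assembly runs fast):

```r
spec0 <- toy_complex_spec("ring",
                          list(list(name = "R", length = 20, copies = 10)),
                          seed = 1)
fab0  <- fabricate_predictions(spec0)
reps0 <- select_representatives(unname(fab0$pred))
lib0  <- build_transform_library(unname(fab0$pred), reps0)
tab   <- scan_stoichiometries("R", 2:15, fab0$gt$config, reps0, lib0)
tab$copies[which.max(tab$confidence)]
#> [1] 10
range(tab$copies[tab$assembled])
#> [1]  2 10
```

Confidence rises from 6 copies (where the symmetry reward starts) to a
maximum at the true count of 10; 11 or more copies cannot be placed
without major steric clashes, so the scan reports them as unassembled —
both signals point at the right stoichiometry.

A command-line interface wraps the same pipeline
(`hierasm simulate | unify | plan-jobs | assemble | evaluate |
connectivity | scan-stoichiometry`); it is installed as `exec/hierasm`
inside the package installation directory.

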