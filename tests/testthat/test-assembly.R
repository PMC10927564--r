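test_that("merging applies the transformation to the whole second side", {
  fab <- fx("chain3", function() fx_chain(3))
  cfg <- fab$gt$config
  sA <- hierasm:::new_singleton("A", cfg)
  sB <- hierasm:::new_singleton("B", cfg)
  eAB <- Filter(function(e) e$a == "A" && e$b == "B", fab$lib)[[1]]
  dimer <- merge_subcomplexes(sA, sB, eAB, 1, 1, cfg)
  expect_equal(dimer$size, 2)
  expect_lt(assembly_rmsd(
    dimer, local({ g <- fab$gt; g$placements <- g$placements[1:2]
                   g$contacts <- g$contacts[1, , drop = FALSE]; g }),
    fab$reps), 1e-5)
  ## cardinality: a 3+2 merge yields 5 placements
  fabr <- fx("ring10", function() fx_ring(10))
  e <- fabr$lib[[1]]
  arc2 <- merge_subcomplexes(hierasm:::new_singleton("R", fabr$gt$config),
                             hierasm:::new_singleton("R", fabr$gt$config),
                             e, 1, 1, fabr$gt$config)
  arc3 <- merge_subcomplexes(arc2,
                             hierasm:::new_singleton("R", fabr$gt$config),
                             e, 2, 1, fabr$gt$config)
  arc5 <- merge_subcomplexes(arc3, arc2, e, 3, 1, fabr$gt$config)
  expect_equal(arc5$size, 5)
  expect_equal(vapply(arc5$placements, `[[`, 0L, "copy"), 0:4)
})

test_that("merging is associative in geometry: (A+B)+C equals A+(B+C)", {
  fab <- fx("chain3", function() fx_chain(3))
  cfg <- fab$gt$config
  sA <- hierasm:::new_singleton("A", cfg)
  sB <- hierasm:::new_singleton("B", cfg)
  sC <- hierasm:::new_singleton("C", cfg)
  eAB <- Filter(function(e) e$a == "A" && e$b == "B", fab$lib)[[1]]
  eBC <- Filter(function(e) e$a == "B" && e$b == "C", fab$lib)[[1]]
  left <- merge_subcomplexes(merge_subcomplexes(sA, sB, eAB, 1, 1, cfg),
                             sC, eBC, 2, 1, cfg)
  right <- merge_subcomplexes(sA, merge_subcomplexes(sB, sC, eBC, 1, 1, cfg),
                              eAB, 1, 1, cfg)
  expect_lt(as.numeric(correspondence_rmsd(left, right, fab$reps)), 1e-6)
})

test_that("merging two subcomplexes sharing a scarce copy is rejected", {
  fab <- fx("chain3", function() fx_chain(3))  # one copy per subunit
  cfg <- fab$gt$config
  sA <- hierasm:::new_singleton("A", cfg)
  eAA <- list(rt = translate_rt(10), score = 50, tid = "x")
  expect_error(merge_subcomplexes(sA, sA, eAA, 1, 1, cfg),
               class = "hierasm_precondition_error")
})

test_that("the symmetry reward follows S + S(100-S)/100 for true orbits", {
  ring6 <- list(homo = "R", tids = "R|R|001", size = 6L)
  ring5 <- list(homo = "R", tids = "R|R|001", size = 5L)
  mixed <- list(homo = NULL, tids = c("a", "b"), size = 8L)
  expect_equal(symmetry_reward(100, ring6), 100)   # fixed point
  expect_equal(symmetry_reward(50, ring6), 75)
  expect_equal(symmetry_reward(50, ring5), 50)     # five copies: no reward
  expect_equal(symmetry_reward(50, mixed), 50)
  S <- c(1, 5, 10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 85, 90, 92, 95,
         96, 98, 99, 99.5, 100)
  expected <- c(1.99, 9.75, 19, 36, 43.75, 51, 64, 75, 84, 91, 93.75,
                96, 97.75, 99, 99.36, 99.75, 99.84, 99.96, 99.99,
                99.9975, 100)
  got <- vapply(S, symmetry_reward, 0, sub = ring6)
  expect_equal(got, expected, tolerance = 1e-13)
})

test_that("well-separated subunits pass the clash filter, superposed fail", {
  su <- make_toy_subunit("A", 20, 1)
  reps <- list(A = rep_from_toy(su))
  cfg <- list(A = subunit_def("A", su$sequence, c("A", "B")))
  far <- manual_subcomplex(c("A", "A"), list(rt_identity(), translate_rt(50)))
  expect_true(clash_filter(far, reps)$keep)
  expect_equal(nrow(clash_filter(far, reps)$report), 0)
  dup <- manual_subcomplex(c("A", "A"), list(rt_identity(), rt_identity()))
  res <- clash_filter(dup, reps)
  expect_false(res$keep)
  expect_true(brute_clash_discard(dup, reps))
})

test_that("penetration fractions sit on the right side of the 5% rule", {
  ## slide one copy toward the other until the clashing fraction crosses
  ## the 4% / 6% bands, then check the filter against the brute-force
  ## all-pairs oracle at both operating points
  su <- make_toy_subunit("F", 25, 3)
  reps <- list(F = rep_from_toy(su))
  acfg <- assembly_config()
  keep_theta <- find_tilt_in_band(reps, acfg, 0.005, 0.05)
  disc_theta <- find_tilt_in_band(reps, acfg, 0.05, 0.12)
  expect_false(is.na(keep_theta))
  expect_false(is.na(disc_theta))
  keep_sub <- tilted_pair(keep_theta)
  disc_sub <- tilted_pair(disc_theta)
  expect_true(clash_filter(keep_sub, reps, acfg)$keep)
  expect_false(clash_filter(disc_sub, reps, acfg)$keep)
  expect_false(brute_clash_discard(keep_sub, reps, acfg))
  expect_true(brute_clash_discard(disc_sub, reps, acfg))
})

test_that("only confident atoms participate in clash detection", {
  su <- make_toy_subunit("A", 20, 1)
  ## all atoms below the plDDT cutoff: nothing can clash
  reps_lo <- list(A = rep_from_toy(su, plddt = 50))
  dup <- manual_subcomplex(c("A", "A"), list(rt_identity(), rt_identity()))
  expect_true(clash_filter(dup, reps_lo)$keep)
})

test_that("chain connectivity bounds consecutive same-chain segments", {
  su1 <- make_toy_subunit("D1", 20, 1)
  su2 <- make_toy_subunit("D2", 20, 1)
  ## both domains live on chain "A"; 2 linker residues between them
  cfg <- list(D1 = subunit_def("D1", su1$sequence, "A", start_res = 1),
              D2 = subunit_def("D2", su2$sequence, "A", start_res = 23))
  reps <- list(D1 = rep_from_toy(su1), D2 = rep_from_toy(su2))
  segs <- hierasm:::chain_segments(cfg)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$n_linker, 2L)
  ## bound is (2+1)*3 = 9 A between the junction Calphas
  apart <- manual_subcomplex(c("D1", "D2"),
                             list(rt_identity(), translate_rt(100)))
  expect_false(connectivity_filter(apart, cfg, reps))
  ## place D2 so its first residue sits 5 A from D1's last residue
  target <- rt_apply(rt_identity(), reps$D1$ca[20, ]) + c(5, 0, 0)
  off <- target - reps$D2$ca[1, ]
  near <- manual_subcomplex(c("D1", "D2"),
                            list(rt_identity(),
                                 translate_rt(off[1], off[2], off[3])))
  expect_true(connectivity_filter(near, cfg, reps))
  ## subunits on different chains are never tested
  cfg2 <- list(D1 = subunit_def("D1", su1$sequence, "A"),
               D2 = subunit_def("D2", su2$sequence, "B"))
  expect_true(connectivity_filter(apart, cfg2, reps))
})

test_that("correspondence RMSD is invariant to relabeling identical copies", {
  fab <- fx("ring10", function() fx_ring(10))
  truth <- gt_as_subcomplex(fab$gt, fab$reps)
  swapped <- truth
  swapped$placements <- swapped$placements[c(2, 1, 3:10)]
  expect_lt(as.numeric(correspondence_rmsd(truth, swapped, fab$reps)), 1e-6)
})

test_that("the centroid-swap heuristic matches factorial enumeration for p = 3", {
  su <- make_toy_subunit("A", 15, 2)
  reps <- list(A = rep_from_toy(su))
  for (s in 1:10) {
    rts <- lapply(1:3, function(k) random_rt(s * 10 + k))
    a <- manual_subcomplex(rep("A", 3), rts)
    perm <- hierasm:::with_seed(s, sample(3))
    g <- random_rt(s + 500)
    b <- manual_subcomplex(rep("A", 3),
                           lapply(rts[perm], function(rt) rt_compose(g, rt)))
    heur <- as.numeric(correspondence_rmsd(a, b, reps))
    brute <- brute_correspondence_rmsd(a, b, reps)
    expect_equal(heur, brute, tolerance = 1e-6)
  }
})

test_that("for p = 4 the heuristic stays within 0.5 A of the optimum", {
  su <- make_toy_subunit("A", 15, 2)
  reps <- list(A = rep_from_toy(su))
  gaps <- numeric(0)
  for (s in 1:25) {
    rts <- lapply(1:4, function(k) random_rt(s * 20 + k))
    a <- manual_subcomplex(rep("A", 4), rts)
    perm <- hierasm:::with_seed(s + 1000, sample(4))
    g <- random_rt(s + 2000)
    b <- manual_subcomplex(rep("A", 4),
                           lapply(rts[perm], function(rt) rt_compose(g, rt)))
    gaps <- c(gaps,
              as.numeric(correspondence_rmsd(a, b, reps)) -
                brute_correspondence_rmsd(a, b, reps))
  }
  expect_true(all(gaps >= -1e-9))
  expect_lt(max(gaps), 0.5)
})

test_that("clustering keeps the best-scoring member as leader", {
  fab <- fx("ring10", function() fx_ring(10))
  truth <- gt_as_subcomplex(fab$gt, fab$reps)
  mk <- function(score, jitter_seed = NULL, shift = 0) {
    s <- truth
    if (!is.null(jitter_seed)) {
      s$placements <- lapply(s$placements, function(p) {
        p$rt <- rt_compose(hierasm:::with_seed(jitter_seed + p$copy, {
          rigid_transform(diag(3), stats::rnorm(3, sd = 0.05))
        }), p$rt)
        p
      })
    }
    if (shift != 0) {
      s$placements[[1]]$rt <- rt_compose(translate_rt(shift),
                                         s$placements[[1]]$rt)
    }
    s$score <- score
    s$score_raw <- score
    s
  }
  ## identical geometry, scores 90 and 80: one cluster led by 90
  out <- cluster_subcomplexes(list(mk(80), mk(90)), fab$reps)
  expect_length(out, 1)
  expect_equal(out[[1]]$score, 90)
  ## one copy moved 10 A: two clusters
  out2 <- cluster_subcomplexes(list(mk(90), mk(80, shift = 10)), fab$reps)
  expect_length(out2, 2)
  ## 100 small-noise replicas collapse into one cluster
  noisy <- lapply(1:100, function(k) mk(50 + k / 100, jitter_seed = k))
  expect_length(cluster_subcomplexes(noisy, fab$reps), 1)
})

test_that("an exact-transform ring reassembles to the ground truth", {
  fab <- fx("ring10", function() fx_ring(10))
  res <- assemble(fab$reps, fab$lib, fab$gt$config)
  expect_true(res$full)
  expect_lt(assembly_rmsd(res$subcomplexes[[1]], fab$gt, fab$reps), 1)
})

test_that("missing transforms yield the largest achievable partial complex", {
  fab <- fx("chain3", function() fx_chain(3))
  lib_ab <- Filter(function(e) e$a == "A" && e$b == "B", fab$lib)
  res <- assemble(fab$reps, lib_ab, fab$gt$config)
  expect_false(res$full)
  expect_equal(res$size, 2)
  expect_setequal(vapply(res$subcomplexes[[1]]$placements, `[[`, "",
                         "subunit"), c("A", "B"))
})

test_that("assembly output is deterministic", {
  fab <- fx("tree6_decoy3", function() fx_tree(6, n_decoys = 3))
  r1 <- assemble(fab$reps, fab$lib, fab$gt$config)
  r2 <- assemble(fab$reps, fab$lib, fab$gt$config)
  expect_equal(length(r1$subcomplexes), length(r2$subcomplexes))
  for (k in seq_along(r1$subcomplexes)) {
    expect_identical(r1$subcomplexes[[k]]$key, r2$subcomplexes[[k]]$key)
    expect_equal(r1$subcomplexes[[k]]$score, r2$subcomplexes[[k]]$score)
  }
})

test_that("widening the beam never lowers the top-1 score", {
  fab <- fx("tree6_decoy3", function() fx_tree(6, n_decoys = 3))
  tops <- vapply(c(2L, 10L, 50L), function(K) {
    res <- assemble(fab$reps, fab$lib, fab$gt$config,
                    assembly_config(K = K))
    res$subcomplexes[[1]]$score_raw
  }, 0)
  expect_true(all(diff(tops) >= -1e-9))
})

test_that("assembly groups are completed before cross-group merges", {
  fab <- fx("chain3", function() fx_chain(3))
  ## feasible group: B and C interact, so {B,C} forms first and the full
  ## complex is still reached
  res <- assemble(fab$reps, fab$lib, fab$gt$config,
                  groups = list(c("B", "C")))
  expect_true(res$full)
  expect_lt(assembly_rmsd(res$subcomplexes[[1]], fab$gt, fab$reps), 1)
  ## infeasible group: A and C never interact, the group cannot complete
  ## and blocks everything beyond singletons except B alone
  res2 <- assemble(fab$reps, fab$lib, fab$gt$config,
                   groups = list(c("A", "C")))
  expect_false(res2$full)
  expect_equal(res2$size, 1)
  ## overlapping groups are rejected
  expect_error(assemble(fab$reps, fab$lib, fab$gt$config,
                        groups = list(c("A", "B"), c("B", "C"))),
               class = "hierasm_config_error")
})

test_that("an empty transformation library is an assembly error", {
  fab <- fx("chain3", function() fx_chain(3))
  expect_error(assemble(fab$reps, list(), fab$gt$config),
               class = "hierasm_assembly_error")
})
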