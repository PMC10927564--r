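test_that("the representative is the placement with maximal mean plDDT", {
  su <- make_toy_subunit("A", 10, 1)
  pae <- matrix(1, 10, 10)
  m85 <- toy_model("m1", "A", list(su$ca), list(rep(85, 10)), pae)
  m91 <- toy_model("m2", "A", list(rt_apply(random_rt(1), su$ca)),
                   list(rep(91, 10)), pae)
  reps <- select_representatives(list(m85, m91))
  expect_equal(reps$A$model_id, "m2")
  expect_equal(reps$A$mean_plddt, 91)
  ## single model: that placement
  expect_equal(select_representatives(list(m85))$A$model_id, "m1")
  ## ties broken by model id order, deterministically
  m_tie <- toy_model("m0", "A", list(rt_apply(random_rt(2), su$ca)),
                     list(rep(85, 10)), pae)
  expect_equal(select_representatives(list(m85, m_tie))$A$model_id, "m0")
})

test_that("a plDDT-boosted model is selected as representative", {
  spec_hi <- toy_complex_spec("chain",
                              list(list(name = "A", length = 15, copies = 1),
                                   list(name = "B", length = 15, copies = 1)),
                              seed = 9, plddt_core = 96)
  spec_lo <- toy_complex_spec("chain",
                              list(list(name = "A", length = 15, copies = 1),
                                   list(name = "B", length = 15, copies = 1)),
                              seed = 9, plddt_core = 88)
  hi <- fabricate_predictions(spec_hi)$pred[[1]]
  hi$model_id <- "boosted"
  lo <- fabricate_predictions(spec_lo)$pred[[1]]
  reps <- select_representatives(list(lo, hi))
  expect_equal(reps$A$model_id, "boosted")
  expect_equal(reps$A$mean_plddt, 96)
})

test_that("interaction uses a strict 8 A Calpha threshold", {
  one <- matrix(c(0, 0, 0), 1, 3)
  pae <- matrix(1, 2, 2)
  at <- function(d) matrix(c(d, 0, 0), 1, 3)
  m79 <- toy_model("m", c("A", "B"), list(one, at(7.9)), list(90, 90), pae)
  m80 <- toy_model("m", c("A", "B"), list(one, at(8.0)), list(90, 90), pae)
  expect_length(find_interacting_pairs(m79), 1)
  expect_length(find_interacting_pairs(m80), 0)
  ## three placements in a line: only consecutive pairs interact
  m3 <- toy_model("m", c("A", "B", "C"),
                  list(one, at(6), at(12)), list(90, 90, 90),
                  matrix(1, 3, 3))
  expect_equal(find_interacting_pairs(m3), list(c(1, 2), c(2, 3)))
})

test_that("extracted transforms reproduce known relative placements", {
  fab <- fx("chain3", function() fx_chain(3))
  m <- fab$pred[[1]]
  pr <- find_interacting_pairs(m)[[1]]
  ## identity case: representative extracted from this same model
  rt <- extract_transform(m, pr, fab$reps)
  a <- m$placements[[pr[1]]]$subunit
  b <- m$placements[[pr[2]]]$subunit
  T1 <- kabsch(fab$reps[[a]]$ca, m$placements[[pr[1]]]$ca)
  dimer_model <- rt_apply(rt_compose(T1, rt), fab$reps[[b]]$ca)
  expect_lt(coord_rmsd(dimer_model, m$placements[[pr[2]]]$ca), 1e-6)
})

test_that("a known rigid motion applied to a placement is recovered", {
  su <- make_toy_subunit("A", 20, 1)
  sv <- make_toy_subunit("B", 20, 1)
  mv <- random_rt(3)
  ## B placed next to A by a known motion
  shifted <- rt_apply(mv, sweep(sv$ca, 2, c(10, 0, 0), "+"))
  m <- toy_model("m", c("A", "B"), list(su$ca, shifted),
                 list(rep(90, 20), rep(90, 20)), matrix(1, 40, 40))
  reps <- select_representatives(list(m))
  rt <- extract_transform(m, c(1, 2), reps)
  expect_lt(coord_rmsd(rt_apply(rt, reps$B$ca), shifted), 1e-6)
})

test_that("low-plDDT tails are excluded from the alignment", {
  su <- make_toy_subunit("A", 30, 1)
  sv <- make_toy_subunit("B", 20, 1)
  plddt_a <- c(rep(90, 20), rep(40, 10))  # 10-residue disordered tail
  base_b <- sweep(sv$ca, 2, c(12, 0, 0), "+")
  m_ref <- toy_model("ref", c("A", "B"), list(su$ca, base_b),
                     list(plddt_a, rep(90, 20)), matrix(1, 50, 50))
  ## same model but with the tail swung 20 A away
  ca_disp <- su$ca
  ca_disp[21:30, ] <- ca_disp[21:30, ] + 20
  m_disp <- toy_model("ref", c("A", "B"), list(ca_disp, base_b),
                      list(plddt_a, rep(90, 20)), matrix(1, 50, 50))
  reps <- select_representatives(list(m_ref))
  rt_ref <- extract_transform(m_ref, c(1, 2), reps)
  rt_disp <- extract_transform(m_disp, c(1, 2), reps)
  expect_lt(max(abs(rt_ref$R - rt_disp$R)), 1e-3)
  expect_lt(max(abs(rt_ref$t - rt_disp$t)), 1e-3)
})

test_that("alignment falls back to the top half by plDDT", {
  idx <- hierasm:::alignment_residues(c(85, 90, 95, 70, 60, 50))
  expect_equal(idx, c(1, 2, 3))  # three residues above 80 = ceil(6/2)
  idx2 <- hierasm:::alignment_residues(rep(70, 6))
  expect_length(idx2, 3)         # none above 80: ceil(6/2) highest
  idx3 <- hierasm:::alignment_residues(c(90, 90, 90, 90, 70, 50))
  expect_equal(idx3, 1:4)        # all confident residues kept
})

test_that("the PAE score formula matches hand-computed values exactly", {
  P <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17,
         18, 19, 19.8, 20, 25, 30)
  expected <- c(100, 99.75, 99, 97.75, 96, 93.75, 91, 87.75, 84, 79.75,
                75, 69.75, 64, 57.75, 51, 43.75, 36, 27.75, 19, 9.75,
                1.99, 1, 1, 1)
  expect_equal(score_transformation(P), expected, tolerance = 1e-13)
  ## monotone non-increasing; clamped to 1 beyond sqrt(396)
  grid <- seq(0, 31, by = 0.25)
  expect_true(all(diff(score_transformation(grid)) <= 0))
  expect_true(all(score_transformation(grid[grid >= sqrt(396)]) == 1))
  expect_error(score_transformation(-0.1),
               class = "hierasm_parameter_error")
  expect_error(score_transformation(31.5),
               class = "hierasm_parameter_error")
})

test_that("mean PAE averages both inter-subunit blocks", {
  su <- make_toy_subunit("A", 10, 1)
  sv <- make_toy_subunit("B", 10, 1)
  pae <- matrix(0, 20, 20)
  pae[1:10, 11:20] <- 4
  pae[11:20, 1:10] <- 6
  m <- toy_model("m", c("A", "B"),
                 list(su$ca, sweep(sv$ca, 2, c(7, 0, 0), "+")),
                 list(rep(90, 10), rep(90, 10)), pae)
  expect_equal(compute_mean_pae(m, c(1, 2)), 5.0)
  ## uniform block: the mean is that constant, asymmetric sizes included
  su2 <- make_toy_subunit("C", 20, 1)
  pae2 <- matrix(0, 30, 30)
  pae2[1:10, 11:30] <- 3; pae2[11:30, 1:10] <- 3
  m2 <- toy_model("m2", c("A", "C"),
                  list(su$ca, sweep(su2$ca, 2, c(7, 0, 0), "+")),
                  list(rep(90, 10), rep(90, 20)), pae2)
  expect_equal(compute_mean_pae(m2, c(1, 2)), 3.0)
})

test_that("the transform library has one deduplicated entry per pair", {
  fab <- fx("tree6", function() fx_tree(6))
  expect_length(fab$lib, 5)   # spanning tree over 6 unique subunits
  fabd <- fx("tree6_decoy3", function() fx_tree(6, n_decoys = 3))
  expect_length(fabd$lib, 8)
  expect_equal(sum(vapply(fabd$lib, `[[`, 0, "score") == 1), 3)
  ## duplicating every model changes nothing (identical geometry merges)
  models <- unname(fab$pred)
  doubled <- c(models, lapply(models, function(m) {
    m$model_id <- paste0(m$model_id, "_copy"); m
  }))
  lib2 <- build_transform_library(doubled, fab$reps)
  expect_length(lib2, 5)
})

test_that("extracted transforms are invariant to a global rigid motion", {
  fab <- fx("chain3", function() fx_chain(3))
  m <- fab$pred[[1]]
  g <- random_rt(42)
  m2 <- m
  for (k in seq_along(m2$placements)) {
    m2$placements[[k]]$ca <- rt_apply(g, m2$placements[[k]]$ca)
    m2$placements[[k]]$bb <- rt_apply(g, m2$placements[[k]]$bb)
  }
  pr <- find_interacting_pairs(m)[[1]]
  t1 <- extract_transform(m, pr, fab$reps)
  t2 <- extract_transform(m2, pr, fab$reps)
  expect_lt(max(abs(t1$R - t2$R)), 1e-6)
  expect_lt(max(abs(t1$t - t2$t)), 1e-6)
})

test_that("subset jobs are planned greedily within the length budget", {
  cfg <- list(A = subunit_def("A", strrep("A", 100), "A"),
              B = subunit_def("B", strrep("C", 100), "B"),
              C = subunit_def("C", strrep("D", 100), "C"),
              D = subunit_def("D", strrep("E", 100), "D"))
  lib <- list(scored_transformation("A", "B", rt_identity(), 2),
              scored_transformation("A", "C", rt_identity(), 6),
              scored_transformation("B", "C", rt_identity(), 4),
              scored_transformation("C", "D", rt_identity(), 10))
  jobs <- plan_subset_jobs(lib, cfg)
  expect_true(all(vapply(jobs, length, 0L) %in% 3:4))
  expect_true(all(vapply(jobs, function(j) {
    sum(vapply(j, function(s) nchar(cfg[[s]]$sequence), 0L))
  }, 0L) <= 1800))
  ## highest-scoring partner first: A's best partner is B (score 99)
  expect_equal(jobs[[1]][1:2], c("A", "B"))
  ## an oversized subunit is flagged and gets no job
  cfg2 <- c(cfg, list(X = subunit_def("X", strrep("G", 1900), "X")))
  jobs2 <- plan_subset_jobs(lib, cfg2)
  expect_equal(attr(jobs2, "flagged"), "X")
  ## determinism
  expect_identical(jobs, plan_subset_jobs(lib, cfg))
})
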