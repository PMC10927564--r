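## Shared fixtures, built once per test run and memoised.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- builder()
  .fx_env[[name]]
}

## n unique toy subunits as a tree, in-memory models only
fx_tree <- function(n = 6, length = 15, seed = 3, n_decoys = 0, ...) {
  spec <- toy_complex_spec(
    "tree",
    lapply(seq_len(n), function(i) list(name = LETTERS[i], length = length,
                                        copies = 1)),
    seed = seed, n_decoys = n_decoys, ...)
  fab <- fabricate_predictions(spec)
  fab$reps <- select_representatives(unname(fab$pred))
  fab$lib <- build_transform_library(unname(fab$pred), fab$reps)
  fab
}

fx_ring <- function(copies = 10, length = 20, seed = 1, n_decoys = 0, ...) {
  spec <- toy_complex_spec(
    "ring", list(list(name = "R", length = length, copies = copies)),
    seed = seed, n_decoys = n_decoys, ...)
  fab <- fabricate_predictions(spec)
  fab$reps <- select_representatives(unname(fab$pred))
  fab$lib <- build_transform_library(unname(fab$pred), fab$reps)
  fab
}

fx_chain <- function(n = 3, length = 20, seed = 2, n_decoys = 0, ...) {
  spec <- toy_complex_spec(
    "chain",
    lapply(seq_len(n), function(i) list(name = LETTERS[i], length = length,
                                        copies = 1)),
    seed = seed, n_decoys = n_decoys, ...)
  fab <- fabricate_predictions(spec)
  fab$reps <- select_representatives(unname(fab$pred))
  fab$lib <- build_transform_library(unname(fab$pred), fab$reps)
  fab
}

## Worst-case transformed-representative RMSD between the best library
## transform and the ground-truth relative placement, over all contacts.
recovery_rmsd <- function(fab) {
  reps <- fab$reps
  truth <- gt_as_subcomplex(fab$gt, reps)
  worst <- 0
  for (k in seq_len(nrow(fab$gt$contacts))) {
    i <- fab$gt$contacts$i[k]; j <- fab$gt$contacts$j[k]
    a <- fab$gt$placements[[i]]$subunit
    b <- fab$gt$placements[[j]]$subunit
    true_rt <- rt_compose(rt_inverse(truth$placements[[i]]$rt),
                          truth$placements[[j]]$rt)
    best <- Inf
    for (e in fab$lib) {
      rt <- if (e$a == a && e$b == b) e$rt
            else if (e$a == b && e$b == a) rt_inverse(e$rt)
            else next
      best <- min(best, coord_rmsd(rt_apply(rt, reps[[b]]$ca),
                                   rt_apply(true_rt, reps[[b]]$ca)))
    }
    worst <- max(worst, best)
  }
  worst
}

## Build a minimal in-memory predicted model from explicit Calpha blocks.
## Backbone = Calpha atoms only (enough for alignment-level tests).
toy_model <- function(model_id, subunits, cas, plddts, pae) {
  placements <- lapply(seq_along(subunits), function(k) {
    ca <- cas[[k]]
    list(subunit = subunits[k], copy = 0L, chain = LETTERS[k],
         ca = ca, bb = ca, bb_elety = rep("CA", nrow(ca)),
         bb_res = seq_len(nrow(ca)) - 1L)
  })
  predicted_model(model_id, placements, unlist(plddts), pae)
}

## A subcomplex assembled directly from explicit placements.
manual_subcomplex <- function(subunits, rts, copies = NULL) {
  if (is.null(copies)) {
    copies <- stats::ave(seq_along(subunits), subunits,
                         FUN = seq_along) - 1L
  }
  placements <- lapply(seq_along(subunits), function(k) {
    list(subunit = subunits[k], copy = copies[k], rt = rts[[k]])
  })
  structure(list(placements = placements, size = length(placements),
                 score_raw = 0, ratio = 1, score = 0, nodes = list(),
                 tree = NULL, tids = character(), homo = NULL, key = NULL),
            class = "subcomplex")
}

random_rt <- function(seed) {
  hierasm:::with_seed(seed, rigid_transform(hierasm:::random_rotation(),
                                            stats::rnorm(3, sd = 10)))
}

## Representative-shaped object directly from a toy subunit.
rep_from_toy <- function(su, plddt = 90) {
  L <- nrow(su$ca)
  list(subunit = su$name, ca = su$ca, bb = su$bb, bb_elety = su$bb_elety,
       bb_res = su$bb_res, plddt = rep(plddt, L), model_id = "toy",
       copy = 0L, mean_plddt = plddt)
}

translate_rt <- function(x, y = 0, z = 0) rigid_transform(diag(3), c(x, y, z))

## Two copies of a subunit: one upright at the origin, one offset along x
## and tilted about y so its end dips gradually into the first copy as
## the tilt grows -- produces clash fractions that cross the 5% rule one
## residue at a time.
tilted_pair <- function(theta, x0 = 8) {
  Ry <- matrix(c(cos(theta), 0, sin(theta),
                 0, 1, 0,
                 -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  manual_subcomplex(c("F", "F"),
                    list(rt_identity(), rigid_transform(Ry, c(x0, 0, 0))))
}

## Find tilt angles whose maximal clash fraction falls in the given band.
find_tilt_in_band <- function(reps, acfg, lo, hi) {
  for (theta in seq(0, 1.4, by = 0.0025)) {
    s <- tilted_pair(theta)
    rp <- clash_filter(s, reps, acfg)$report
    fr <- if (nrow(rp)) max(rp$frac_i, rp$frac_j) else 0
    if (fr > lo && fr <= hi) return(theta)
    if (fr > hi) return(NA_real_)
  }
  NA_real_
}
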