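#' Predicted confidence of an assembled subcomplex
#'
#' The confidence of an assembly is the weighted mean of the transformation
#' scores used to build it, where each transformation's weight is the
#' number of amino acids in the smaller of the two subcomplexes it merged:
#' transformations that moved more of the structure matter more.  The
#' result lies between the smallest and largest transformation score, in
#' `[1, 100]`.
#'
#' @param sub a `subcomplex` with at least one merge in its tree.
#' @return Confidence in `[1, 100]`.
#' @export
predicted_confidence <- function(sub) {
  if (!length(sub$nodes)) {
    hier_stop("confidence is undefined for a single-subunit assembly",
              "undefined_confidence")
  }
  W <- vapply(sub$nodes, `[[`, 0, "W")
  S <- vapply(sub$nodes, `[[`, 0, "S")
  sum(W * S) / sum(W)
}

## Express a toy ground truth as a subcomplex over given representatives:
## each placement's transform is the superposition of the representative
## onto the ground-truth coordinates, so downstream comparisons are
## independent of the arbitrary frames representatives were extracted in.
#' @rdname assembly_rmsd
#' @export
gt_as_subcomplex <- function(gt, reps) {
  placements <- lapply(seq_along(gt$placements), function(k) {
    p <- gt$placements[[k]]
    list(subunit = p$subunit, copy = p$copy,
         rt = kabsch(reps[[p$subunit]]$ca, gt_ca(gt, k)))
  })
  structure(list(placements = placements, size = length(placements),
                 score_raw = 0, ratio = 1, score = 0, nodes = list(),
                 tree = NULL, tids = character(), homo = NULL, key = NULL),
            class = "subcomplex")
}

#' Calpha RMSD of an assembly against the toy ground truth
#'
#' Resolves the copy correspondence (centroid-swap heuristic) and returns
#' the superposed Calpha RMSD between an assembled subcomplex and the
#' ground-truth placement of a toy complex.
#'
#' @param sub an assembled `subcomplex`.
#' @param gt a [build_ground_truth()] result.
#' @param reps representatives used for the assembly.
#' @return RMSD in Angstrom.
#' @export
assembly_rmsd <- function(sub, gt, reps) {
  as.numeric(correspondence_rmsd(gt_as_subcomplex(gt, reps), sub, reps))
}

## Contact pairs (strict < threshold on Calpha distances) between the
## placements of a subcomplex.
subcomplex_contacts <- function(sub, reps, threshold = 8) {
  n <- length(sub$placements)
  cas <- lapply(sub$placements, function(p) rt_apply(p$rt, reps[[p$subunit]]$ca))
  ci <- integer(); cj <- integer()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (min_cross_dist(cas[[i]], cas[[j]]) < threshold) {
          ci <- c(ci, i); cj <- c(cj, j)
        }
      }
    }
  }
  data.frame(i = ci, j = cj)
}

#' Interface quality of a transformation against the true dimer
#'
#' A DockQ-style composite of three interface measures between the dimer
#' induced by a candidate transformation and the true relative placement of
#' the same two subunits: the fraction of native contacts reproduced
#' (contacts: Calpha pairs under 8 Angstrom), the interface RMSD after
#' superposing the native interface residues (scaled by 1.5 Angstrom), and
#' the ligand RMSD with the first subunit taken as receptor (scaled by 8.5
#' Angstrom).  Values near 1 indicate a near-native interface; the
#' conventional acceptability threshold is 0.23.
#'
#' @param rt candidate `rigid_transform` mapping subunit `b`'s
#'   representative into `a`'s frame.
#' @param a,b subunit names.
#' @param true_rt the true relative transform in the same frames.
#' @param reps representatives.
#' @return Quality in `[0, 1]`.
#' @export
edge_quality <- function(rt, a, b, true_rt, reps) {
  A <- reps[[a]]$ca
  Bm <- rt_apply(rt, reps[[b]]$ca)
  Bn <- rt_apply(true_rt, reps[[b]]$ca)
  thr <- 8
  dist2 <- function(x, y) {
    outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  }
  native <- dist2(A, Bn) < thr^2
  model <- dist2(A, Bm) < thr^2
  n_native <- sum(native)
  if (n_native == 0L) return(0)
  fnat <- sum(native & model) / n_native
  ## interface residues of the native dimer (10 A heavy cutoff on Calpha)
  iface <- dist2(A, Bn) < 100
  ia <- which(rowSums(iface) > 0)
  ib <- which(colSums(iface) > 0)
  nat_if <- rbind(A[ia, , drop = FALSE], Bn[ib, , drop = FALSE])
  mod_if <- rbind(A[ia, , drop = FALSE], Bm[ib, , drop = FALSE])
  irms <- if (nrow(nat_if) >= 3L) coord_rmsd(mod_if, nat_if, fit = TRUE)
          else Inf
  ## ligand RMSD: receptor frames already coincide (A identical)
  lrms <- coord_rmsd(Bm, Bn)
  (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
}

#' Pairwise connectivity of a transformation library against a reference
#'
#' Diagnoses whether the library can assemble the complex at all: a graph
#' is built with one node per placed subunit copy of the reference and an
#' edge between contacting copies whenever some library transformation
#' reproduces their true relative placement at acceptable quality
#' (default: [edge_quality()] above 0.23).  The returned ratio is the
#' number of amino acids in the largest connected component over the total;
#' 1 means a spanning set of usable transformations exists.
#'
#' @param library list of `scored_transformation`s.
#' @param truth reference structure as a `subcomplex` (e.g.
#'   [gt_as_subcomplex()]).
#' @param config named list of [subunit_def()] (for amino-acid counts).
#' @param reps representatives.
#' @param threshold edge acceptance threshold (default 0.23).
#' @param quality_fn pluggable quality function with the signature of
#'   [edge_quality()].
#' @return Ratio in `(0, 1]`, with the component membership in attribute
#'   `"components"`.
#' @export
pairwise_connectivity <- function(library, truth, config, reps,
                                  threshold = 0.23,
                                  quality_fn = edge_quality) {
  config <- validate_config(config)
  n <- length(truth$placements)
  weights <- vapply(truth$placements,
                    function(p) seq_length(config[[p$subunit]]), 0L)
  contacts <- subcomplex_contacts(truth, reps)
  edges <- integer(0)
  for (k in seq_len(nrow(contacts))) {
    i <- contacts$i[k]; j <- contacts$j[k]
    a <- truth$placements[[i]]$subunit
    b <- truth$placements[[j]]$subunit
    true_rt <- rt_compose(rt_inverse(truth$placements[[i]]$rt),
                          truth$placements[[j]]$rt)
    ok <- FALSE
    for (e in library) {
      if (e$a == a && e$b == b) {
        q <- quality_fn(e$rt, a, b, true_rt, reps)
      } else if (e$a == b && e$b == a) {
        q <- quality_fn(rt_inverse(e$rt), a, b, true_rt, reps)
      } else next
      if (q > threshold) { ok <- TRUE; break }
    }
    if (ok) edges <- c(edges, i, j)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  comp_aa <- vapply(seq_len(comp$no), function(cc) {
    sum(weights[comp$membership == cc])
  }, 0)
  out <- max(comp_aa) / sum(weights)
  attr(out, "components") <- comp$membership
  out
}

#' TM-score between two equal-composition structures
#'
#' Length-normalized template-modeling score with the standard distance
#' scale `d0 = 1.24 (L - 15)^(1/3) - 1.8` (floored at 0.5 Angstrom), `L`
#' the reference length.  The copy correspondence for identical subunits is
#' resolved with the centroid-swap machinery of [correspondence_rmsd()];
#' the superposition is optimized by iterative refinement (refit on
#' residues within the inclusion distance) from several starts: all
#' residues and each subunit individually.
#'
#' @param model,reference `subcomplex`es of identical composition.
#' @param reps representatives.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(model, reference, reps) {
  r <- correspondence_rmsd(reference, model, reps)
  corr <- attr(r, "correspondence")
  ref_xyz <- do.call(rbind, lapply(reference$placements, function(p)
    rt_apply(p$rt, reps[[p$subunit]]$ca)))
  mod_xyz <- do.call(rbind, lapply(model$placements[corr], function(p)
    rt_apply(p$rt, reps[[p$subunit]]$ca)))
  L <- nrow(ref_xyz)
  if (nrow(mod_xyz) != L) hier_stop("residue counts differ", "precondition")
  d0 <- max(0.5, 1.24 * max(L - 15, 1)^(1 / 3) - 1.8)
  lens <- vapply(reference$placements, function(p) nrow(reps[[p$subunit]]$ca), 0L)
  stops <- cumsum(lens)
  starts_idx <- c(list(seq_len(L)),
                  lapply(seq_along(lens), function(k) {
                    (stops[k] - lens[k] + 1L):stops[k]
                  }))
  best <- 0
  incl <- max(d0, 3.5)
  for (idx in starts_idx) {
    if (length(idx) < 3L) next
    for (it in 1:20) {
      Tt <- kabsch(mod_xyz[idx, , drop = FALSE], ref_xyz[idx, , drop = FALSE])
      moved <- rt_apply(Tt, mod_xyz)
      d <- sqrt(rowSums((moved - ref_xyz)^2))
      sc <- mean(1 / (1 + (d / d0)^2))
      if (sc > best) best <- sc
      new_idx <- which(d < incl)
      if (length(new_idx) < 3L || identical(new_idx, idx)) break
      idx <- new_idx
    }
  }
  best
}
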