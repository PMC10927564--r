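#' Select a representative structure per subunit
#'
#' Every subunit typically appears in many predicted models; the copy with
#' the maximal mean plDDT is selected as the single rigid representative
#' used during assembly.  Ties are broken lexicographically by
#' (model_id, copy index), which makes selection deterministic.
#'
#' @param models list of [predicted_model()] objects.
#' @return Named list of representatives, each with the subunit's backbone
#'   coordinates (in the source model's frame), per-residue plDDT,
#'   provenance (`model_id`, `copy`) and `mean_plddt`.
#' @export
select_representatives <- function(models) {
  best <- list()
  ## deterministic scan order: models sorted by id, placements in order
  ord <- order(vapply(models, `[[`, "", "model_id"))
  for (m in models[ord]) {
    for (p in m$placements) {
      mp <- mean(p$plddt)
      cur <- best[[p$subunit]]
      better <- is.null(cur) || mp > cur$mean_plddt + 1e-12
      if (better) {
        best[[p$subunit]] <- list(
          subunit = p$subunit, ca = p$ca, bb = p$bb,
          bb_elety = p$bb_elety, bb_res = p$bb_res, plddt = p$plddt,
          model_id = m$model_id, copy = p$copy, mean_plddt = mp)
      }
    }
  }
  best
}

## Coverage check used by pipeline entry points
check_rep_coverage <- function(reps, config) {
  missing <- setdiff(names(config), names(reps))
  if (length(missing)) {
    hier_stop(paste("no predicted model covers subunit(s):",
                    paste(missing, collapse = ", ")), "coverage")
  }
  invisible(reps)
}

#' Find interacting placement pairs within a model
#'
#' Two placements interact when some Calpha-Calpha distance between them is
#' strictly below 8 Angstrom.
#'
#' @param model a [predicted_model()].
#' @param threshold interaction distance (Angstrom, default 8, strict `<`).
#' @return list of integer pairs (placement indices).
#' @export
find_interacting_pairs <- function(model, threshold = 8) {
  n <- length(model$placements)
  out <- list()
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- min_cross_dist(model$placements[[i]]$ca, model$placements[[j]]$ca)
      if (d < threshold) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

## Residues used for superposition: plDDT > 80, or if fewer than half the
## residues qualify, the ceil(L/2) residues of highest plDDT.
alignment_residues <- function(plddt, cutoff = 80) {
  L <- length(plddt)
  idx <- which(plddt > cutoff)
  half <- ceiling(L / 2)
  if (length(idx) < half) {
    idx <- order(-plddt, seq_len(L))[seq_len(half)]
    idx <- sort(idx)
  }
  idx
}

#' Extract the relative transformation for an interacting pair
#'
#' Superposes each representative onto its placement in the model (Kabsch,
#' restricted to confident residues: plDDT > 80 in the representative, or
#' the top half by plDDT when fewer qualify), giving T1 for the first
#' placement and T2 for the second, and returns the relative transform that
#' maps the second representative into the first representative's reference
#' frame.  Disordered low-plDDT regions, which fold differently in every
#' model, are thereby excluded from the alignment.
#'
#' @param model a [predicted_model()].
#' @param pair integer pair of placement indices.
#' @param reps representatives from [select_representatives()].
#' @return A `rigid_transform` mapping representative-B coordinates into
#'   representative-A's frame.
#' @export
extract_transform <- function(model, pair, reps) {
  pa <- model$placements[[pair[1]]]
  pb <- model$placements[[pair[2]]]
  ra <- reps[[pa$subunit]]
  rb <- reps[[pb$subunit]]
  if (is.null(ra) || is.null(rb)) {
    hier_stop("missing representative for one of the paired subunits",
              "coverage")
  }
  ia <- alignment_residues(ra$plddt)
  ib <- alignment_residues(rb$plddt)
  if (length(ia) < 3L || length(ib) < 3L) {
    hier_stop("fewer than 3 usable alignment residues", "degenerate_alignment")
  }
  T1 <- kabsch(ra$ca[ia, , drop = FALSE], pa$ca[ia, , drop = FALSE])
  T2 <- kabsch(rb$ca[ib, , drop = FALSE], pb$ca[ib, , drop = FALSE])
  rt_compose(rt_inverse(T1), T2)
}

#' Mean inter-subunit PAE for a placement pair
#'
#' Averages the predicted aligned error over all residue pairs of both
#' inter-subunit blocks of the PAE matrix (A-aligned-on-B and
#' B-aligned-on-A).
#'
#' @param model a [predicted_model()].
#' @param pair integer pair of placement indices.
#' @return Mean PAE in Angstrom.
#' @export
compute_mean_pae <- function(model, pair) {
  pa <- model$placements[[pair[1]]]
  pb <- model$placements[[pair[2]]]
  ia <- pa$start + seq_len(pa$len) - 1L
  ib <- pb$start + seq_len(pb$len) - 1L
  mean(c(model$pae[ia, ib], model$pae[ib, ia]))
}

#' PAE-derived transformation score
#'
#' Maps the mean inter-subunit PAE `P` (Angstrom) to a score in `[1, 100]`
#' by `max(1, 100 - P^2/4)`.  The quadratic makes small differences between
#' confident interfaces (low PAE) meaningful while flattening the
#' distinction between interfaces that are predicted inaccurate anyway.
#'
#' @param mean_pae mean PAE `P`, `0 <= P <= 31`.
#' @return Score in `[1, 100]`.
#' @export
score_transformation <- function(mean_pae) {
  if (any(!is.finite(mean_pae)) || any(mean_pae < 0) || any(mean_pae > 31)) {
    hier_stop("mean PAE must lie in [0, 31]", "parameter")
  }
  pmax(1, 100 - mean_pae^2 / 4)
}

#' Construct a scored transformation
#'
#' @param a,b subunit names; the transform maps b's representative into a's
#'   frame.
#' @param rt a `rigid_transform`.
#' @param mean_pae mean inter-subunit PAE of the source interface.
#' @param model_id provenance.
#' @return A `scored_transformation`.
#' @export
scored_transformation <- function(a, b, rt, mean_pae, model_id = NA_character_) {
  structure(list(a = a, b = b, rt = rt, mean_pae = mean_pae,
                 score = score_transformation(mean_pae),
                 model_id = model_id, tid = NA_character_),
            class = "scored_transformation")
}

#' Build the deduplicated library of scored transformations
#'
#' Walks every interacting pair of every model, extracts the relative
#' transformation between representatives and its PAE score, and collects
#' them into a library keyed by subunit pair.  The pair is stored in
#' canonical order (names sorted; for homomeric pairs both orientations are
#' kept since neither copy is privileged).  Near-duplicate transformations
#' for the same pair (RMSD of the transformed representative below
#' `dedup_rmsd`) are merged keeping the best score.
#'
#' @param models list of [predicted_model()].
#' @param reps representatives from [select_representatives()].
#' @param dedup_rmsd merge threshold in Angstrom (default 1, matching the
#'   assembly clustering tolerance).
#' @return list of `scored_transformation`s with assigned `tid`s.
#' @export
build_transform_library <- function(models, reps, dedup_rmsd = 1) {
  entries <- list()
  ord <- order(vapply(models, `[[`, "", "model_id"))
  add_entry <- function(a, b, rt, pae, mid) {
    key <- paste(a, b, sep = "|")
    cur <- entries[[key]]
    moved <- rt_apply(rt, reps[[b]]$ca)
    for (k in seq_along(cur)) {
      if (coord_rmsd(moved, cur[[k]]$moved) < dedup_rmsd) {
        if (score_transformation(pae) > cur[[k]]$e$score) {
          cur[[k]]$e <- scored_transformation(a, b, rt, pae, mid)
          cur[[k]]$moved <- moved
          entries[[key]] <<- cur
        }
        return(invisible())
      }
    }
    cur[[length(cur) + 1L]] <- list(e = scored_transformation(a, b, rt, pae, mid),
                                    moved = moved)
    entries[[key]] <<- cur
    invisible()
  }
  for (m in models[ord]) {
    for (pr in find_interacting_pairs(m)) {
      a <- m$placements[[pr[1]]]$subunit
      b <- m$placements[[pr[2]]]$subunit
      rt <- extract_transform(m, pr, reps)
      pae <- compute_mean_pae(m, pr)
      if (a <= b) {
        add_entry(a, b, rt, pae, m$model_id)
        if (a == b) add_entry(a, b, rt_inverse(rt), pae, m$model_id)
      } else {
        add_entry(b, a, rt_inverse(rt), pae, m$model_id)
      }
    }
  }
  lib <- list()
  for (key in sort(names(entries))) {
    for (k in seq_along(entries[[key]])) {
      e <- entries[[key]][[k]]$e
      e$tid <- sprintf("%s|%03d", key, k)
      lib[[length(lib) + 1L]] <- e
    }
  }
  lib
}

#' Plan larger-subset prediction jobs
#'
#' Some groups of subunits form intertwined structures that a pairwise
#' prediction cannot capture, so for each subunit up to three additional
#' prediction jobs of three to five subunits are planned: the subunit plus
#' its highest-scoring pairwise partners, greedily, subject to a total
#' sequence-length budget that fits common GPU memory.
#'
#' @param library a transformation library (best pair scores are taken from
#'   it), or `NULL` together with `pair_scores`.
#' @param config named list of [subunit_def()].
#' @param budget total sequence-length budget per job (default 1800).
#' @param max_jobs_per_subunit cap on planned jobs per subunit (default 3).
#' @return list of character vectors (subunit subsets); subunits whose own
#'   sequence exceeds the budget are reported in attribute `"flagged"`.
#' @export
plan_subset_jobs <- function(library, config, budget = 1800,
                             max_jobs_per_subunit = 3L) {
  config <- validate_config(config)
  ## best score per unordered partner pair
  best <- list()
  for (e in library) {
    key <- paste(sort(c(e$a, e$b)), collapse = "|")
    best[[key]] <- max(best[[key]] %||% -Inf, e$score)
  }
  partner_tab <- function(s) {
    part <- character(); sc <- numeric()
    for (o in setdiff(names(config), s)) {
      key <- paste(sort(c(s, o)), collapse = "|")
      if (!is.null(best[[key]])) { part <- c(part, o); sc <- c(sc, best[[key]]) }
    }
    part[order(-sc, part)]
  }
  seen <- character()
  jobs <- list()
  flagged <- character()
  for (s in names(config)) {
    if (seq_length(config[[s]]) > budget) {
      flagged <- c(flagged, s)
      next
    }
    partners <- partner_tab(s)
    emitted <- 0L
    for (size in 3:5) {
      if (emitted >= max_jobs_per_subunit) break
      if (length(partners) < size - 1L) break
      members <- c(s, partners[seq_len(size - 1L)])
      total <- sum(vapply(members, function(m) seq_length(config[[m]]), 0L))
      if (total > budget) break
      key <- paste(sort(members), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      jobs[[length(jobs) + 1L]] <- members
      emitted <- emitted + 1L
    }
  }
  attr(jobs, "flagged") <- flagged
  jobs
}
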