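#' Specification of a synthetic toy complex
#'
#' Describes a parametric toy complex used to fabricate the inputs the
#' assembly pipeline expects from a structure predictor: pair-model
#' coordinates with controllable Gaussian noise, per-residue plDDT profiles,
#' block-structured PAE matrices and decoy (wrongly docked) pair models.
#' Subunits are short idealized helical backbones; the complex geometry is
#' one of three topologies:
#'
#' * `ring` - `copies` rotational copies of one subunit about a common axis,
#' * `chain` - subunits placed consecutively along a line, neighbours in
#'   contact,
#' * `tree`  - each subunit attached in contact to a randomly chosen earlier
#'   subunit.
#'
#' All outputs are deterministic functions of `seed`.
#'
#' @param topology one of `"ring"`, `"chain"`, `"tree"`.
#' @param subunit_specs list of `list(name=, length=, copies=)`; `ring`
#'   requires a single entry.
#' @param seed integer seed controlling sequences, geometry and noise.
#' @param coord_noise_sd per-coordinate Gaussian noise (Angstrom) added to
#'   fabricated model coordinates.
#' @param plddt_core baseline plDDT for core residues (default 90).
#' @param plddt_tail,plddt_tail_len optional low-confidence C-terminal tail:
#'   the last `plddt_tail_len` residues get plDDT `plddt_tail`.
#' @param pae_true inter-subunit PAE (Angstrom) written for correctly
#'   modelled pairs.
#' @param pae_decoy inter-subunit PAE written for decoy pairs.
#' @param pae_intra intra-subunit PAE block value.
#' @param n_decoys number of decoy pair models to fabricate.
#' @param contact_dist target minimal Calpha-Calpha distance (Angstrom)
#'   between subunits placed in contact.
#' @return A `toy_complex_spec`.
#' @export
toy_complex_spec <- function(topology = c("ring", "chain", "tree"),
                             subunit_specs,
                             seed = 1L,
                             coord_noise_sd = 0,
                             plddt_core = 90,
                             plddt_tail = 40,
                             plddt_tail_len = 0L,
                             pae_true = 2,
                             pae_decoy = 30,
                             pae_intra = 1,
                             n_decoys = 0L,
                             contact_dist = 6) {
  topology <- match.arg(topology)
  stopifnot(length(subunit_specs) >= 1L)
  for (s in subunit_specs) {
    if (is.null(s$name) || is.null(s$length)) {
      hier_stop("each subunit spec needs 'name' and 'length'", "parameter")
    }
    if (s$length < 5L) {
      hier_stop("toy subunits need length >= 5", "parameter")
    }
  }
  if (topology == "ring" && length(subunit_specs) != 1L) {
    hier_stop("ring topology takes exactly one subunit spec", "parameter")
  }
  if (any(c(pae_true, pae_decoy, pae_intra) < 0) ||
      any(c(pae_true, pae_decoy, pae_intra) > 31)) {
    hier_stop("PAE values must lie in [0,31]", "parameter")
  }
  structure(list(topology = topology, subunit_specs = subunit_specs,
                 seed = as.integer(seed), coord_noise_sd = coord_noise_sd,
                 plddt_core = plddt_core, plddt_tail = plddt_tail,
                 plddt_tail_len = as.integer(plddt_tail_len),
                 pae_true = pae_true, pae_decoy = pae_decoy,
                 pae_intra = pae_intra, n_decoys = as.integer(n_decoys),
                 contact_dist = contact_dist),
            class = "toy_complex_spec")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ideal helix constants: rise per residue and twist chosen so consecutive
## Calpha atoms sit 3.8 A apart.
HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
HELIX_RADIUS <- sqrt(3.8^2 - HELIX_RISE^2) / (2 * sin(HELIX_TWIST / 2))

#' Build an idealized toy subunit backbone
#'
#' Returns an idealized Calpha trace with N, CA, C, O backbone atoms, a
#' deterministic random sequence, and a tiny seeded jitter so different
#' seeds give distinguishable structures.  Subunits of up to 25 residues
#' are a single ideal helix (consecutive Calpha spacing 3.8 Angstrom);
#' longer subunits are folded into an antiparallel bundle of helical
#' segments so they stay roughly globular - a single long helix is almost
#' rotationally degenerate about its own axis, which no real protein
#' domain is.  The subunit is centred at its Calpha centroid.
#'
#' @param name subunit name (enters the seed, so different subunits differ).
#' @param length number of residues (>= 5).
#' @param seed integer seed.
#' @return A list with `name`, `sequence`, `ca`, `bb`, `bb_elety`, `bb_res`.
#' @export
make_toy_subunit <- function(name, length, seed = 1L) {
  if (length < 5L) hier_stop("toy subunit length must be >= 5", "parameter")
  with_seed(str_seed(name, seed), {
    sequence <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    seg_len <- 25L
    n_seg <- ceiling(length / seg_len)
    bundle_r <- if (n_seg > 1L) 5 else 0
    ca <- matrix(0, length, 3L)
    pos <- 0L
    for (s in seq_len(n_seg)) {
      take <- min(seg_len, length - pos)
      i <- seq_len(take) - 1L
      z <- i * HELIX_RISE
      if (s %% 2L == 0L) z <- max(z) - z   # antiparallel
      phi <- 2 * pi * (s - 1L) / max(n_seg, 2L)
      ca[pos + seq_len(take), ] <- cbind(
        bundle_r * cos(phi) + HELIX_RADIUS * cos(i * HELIX_TWIST),
        bundle_r * sin(phi) + HELIX_RADIUS * sin(i * HELIX_TWIST),
        z)
      pos <- pos + take
    }
    ## local frames for pendant backbone atoms
    nxt <- rbind(ca[-1, , drop = FALSE], ca[length, , drop = FALSE])
    prv <- rbind(ca[1, , drop = FALSE], ca[-length, , drop = FALSE])
    e1 <- nxt - prv
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(ca[, 1], ca[, 2], 0)
    e2 <- e2 / sqrt(rowSums(e2^2))
    bb <- matrix(0, 4L * length, 3L)
    bb_elety <- rep(c("N", "CA", "C", "O"), length)
    bb_res <- rep(seq_len(length) - 1L, each = 4L)
    for (k in seq_len(length)) {
      rows <- (k - 1L) * 4L + 1:4
      bb[rows[1], ] <- ca[k, ] - 1.2 * e1[k, ] + 0.4 * e2[k, ]
      bb[rows[2], ] <- ca[k, ]
      bb[rows[3], ] <- ca[k, ] + 1.2 * e1[k, ] + 0.4 * e2[k, ]
      bb[rows[4], ] <- ca[k, ] + 1.4 * e1[k, ] + 1.4 * e2[k, ]
    }
    bb <- bb + matrix(stats::rnorm(3L * nrow(bb), sd = 0.0015), ncol = 3L)
    bb <- sweep(bb, 2L, colMeans(bb[bb_elety == "CA", , drop = FALSE]))
    list(name = name, sequence = sequence,
         ca = bb[bb_elety == "CA", , drop = FALSE],
         bb = bb, bb_elety = bb_elety, bb_res = bb_res)
  })
}

min_cross_dist <- function(a, b) {
  ## minimal distance between two point sets
  sqrt(min(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)))
}

CHAIN_ID_POOL <- c(LETTERS, letters, as.character(0:9))

## Bisect a monotone placement parameter so the minimal Calpha distance
## between `fixed` and `mover(s)` equals `target`.
bisect_contact <- function(fixed_ca, mover, target, lo = 0.1, hi = 500) {
  f <- function(s) min_cross_dist(fixed_ca, mover(s)) - target
  if (f(hi) < 0) hier_stop("cannot separate subunits: geometry too tight",
                           "geometry")
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Place all subunit copies of a toy complex (ground truth)
#'
#' Builds the ideal subunit structures, the subunit config, and rigid
#' placements for every copy according to the spec's topology, guaranteeing
#' that subunits placed in contact have minimal Calpha-Calpha distance near
#' `contact_dist` (inside the 8 Angstrom interaction threshold) while
#' non-contacting pairs stay beyond it.  Also returns the exact relative
#' transformations between all contacting pairs.
#'
#' @param spec a [toy_complex_spec()].
#' @return A `toy_ground_truth` list: `spec`, `config` (subunit
#'   definitions), `subunits` (ideal structures), `placements` (subunit,
#'   copy, `rt`), `contacts` (data.frame of contacting placement pairs) and
#'   `true_transforms` (relative `rt` per contact).
#' @export
build_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  subunits <- list()
  defs <- list()
  chain_cursor <- 0L
  expanded <- list()   # one entry per copy: list(subunit, copy)
  for (s in spec$subunit_specs) {
    copies <- s$copies %||% 1L
    su <- make_toy_subunit(s$name, s$length, spec$seed)
    subunits[[s$name]] <- su
    ids <- CHAIN_ID_POOL[chain_cursor + seq_len(copies)]
    chain_cursor <- chain_cursor + copies
    defs[[length(defs) + 1L]] <- subunit_def(s$name, su$sequence, ids,
                                             s$start_res %||% 1L)
    for (cp in seq_len(copies) - 1L) {
      expanded[[length(expanded) + 1L]] <- list(subunit = s$name, copy = cp)
    }
  }
  defs <- validate_config(defs)
  n <- length(expanded)
  placements <- vector("list", n)

  place_ring <- function() {
    su <- subunits[[expanded[[1]]$subunit]]
    delta <- 2 * pi / n
    mover <- function(Rr) {
      a0 <- sweep(su$ca, 2L, c(Rr, 0, 0), "+")
      rt_apply(rigid_transform(rot_z(delta)), a0)
    }
    fixed <- function(Rr) sweep(su$ca, 2L, c(Rr, 0, 0), "+")
    f <- function(Rr) min_cross_dist(fixed(Rr), mover(Rr)) - spec$contact_dist
    lo <- 1; hi <- 2000
    if (f(hi) < 0) hier_stop("ring too tight for this subunit", "geometry")
    if (f(lo) > 0) lo <- 0.01
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    Rr <- (lo + hi) / 2
    lapply(seq_len(n) - 1L, function(j) {
      Rj <- rot_z(j * delta)
      rigid_transform(Rj, as.numeric(Rj %*% c(Rr, 0, 0)))
    })
  }

  place_linear_or_tree <- function(tree) {
    pl <- vector("list", n)
    pl[[1]] <- rigid_transform(with_seed(spec$seed + 11L, random_rotation()))
    centers <- matrix(0, n, 3)
    with_seed(spec$seed + 13L, {
      for (k in 2:n) {
        parent <- if (tree) sample.int(k - 1L, 1L) else k - 1L
        su_k <- subunits[[expanded[[k]]$subunit]]
        par_ca <- rt_apply(pl[[parent]], subunits[[expanded[[parent]]$subunit]]$ca)
        ok <- FALSE
        for (try in 1:100) {
          Rk <- random_rotation()
          dir <- if (tree) {
            v <- stats::rnorm(3); v / sqrt(sum(v^2))
          } else c(1, 0, 0)
          mover <- function(s) {
            sweep(su_k$ca %*% t(Rk), 2L, centers[parent, ] + s * dir, "+")
          }
          s_hat <- tryCatch(
            bisect_contact(par_ca, mover, spec$contact_dist),
            error = function(e) NA_real_)
          if (is.na(s_hat)) next
          cand_rt <- rigid_transform(Rk, centers[parent, ] + s_hat * dir)
          cand_ca <- rt_apply(cand_rt, su_k$ca)
          clear <- TRUE
          for (m in seq_len(k - 1L)) {
            if (m == parent) next
            other <- rt_apply(pl[[m]], subunits[[expanded[[m]]$subunit]]$ca)
            if (min_cross_dist(cand_ca, other) <= 8.5) { clear <- FALSE; break }
          }
          if (clear) {
            pl[[k]] <- cand_rt
            centers[k, ] <- cand_rt$t
            ok <- TRUE
            break
          }
        }
        if (!ok) hier_stop("could not place subunit without overlap", "geometry")
      }
    })
    pl
  }

  rts <- switch(spec$topology,
                ring = place_ring(),
                chain = place_linear_or_tree(FALSE),
                tree = place_linear_or_tree(TRUE))
  for (k in seq_len(n)) {
    placements[[k]] <- list(subunit = expanded[[k]]$subunit,
                            copy = expanded[[k]]$copy, rt = rts[[k]])
  }

  ## contacting pairs (strict < 8 A) and their exact relative transforms
  cas <- lapply(placements, function(p) rt_apply(p$rt, subunits[[p$subunit]]$ca))
  ci <- integer(); cj <- integer()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (min_cross_dist(cas[[i]], cas[[j]]) < 8) {
        ci <- c(ci, i); cj <- c(cj, j)
      }
    }
  }
  true_transforms <- lapply(seq_along(ci), function(k) {
    rt_compose(rt_inverse(placements[[ci[k]]]$rt), placements[[cj[k]]]$rt)
  })
  structure(list(spec = spec, config = defs, subunits = subunits,
                 placements = placements,
                 contacts = data.frame(i = ci, j = cj),
                 true_transforms = true_transforms),
            class = "toy_ground_truth")
}

## Ground-truth coordinates of placement k
gt_ca <- function(gt, k) {
  p <- gt$placements[[k]]
  rt_apply(p$rt, gt$subunits[[p$subunit]]$ca)
}

plddt_profile <- function(spec, len) {
  p <- rep(spec$plddt_core, len)
  if (spec$plddt_tail_len > 0L) {
    tail_idx <- seq.int(max(1L, len - spec$plddt_tail_len + 1L), len)
    p[tail_idx] <- spec$plddt_tail
  }
  p
}

write_pair_model <- function(dir, model_id, gt, members_bb, members_def,
                             plddts, pae) {
  xyz <- NULL; chain <- character(); resno <- integer()
  resid <- character(); elety <- character(); b <- numeric()
  for (m in seq_along(members_bb)) {
    su <- members_bb[[m]]
    d <- members_def[[m]]
    res3 <- seq_to_resid(d$sequence)
    xyz <- rbind(xyz, su$bb)
    chain <- c(chain, rep(CHAIN_ID_POOL[m], nrow(su$bb)))
    resno <- c(resno, su$bb_res + d$start_res)
    resid <- c(resid, res3[su$bb_res + 1L])
    elety <- c(elety, su$bb_elety)
    b <- c(b, plddts[[m]][su$bb_res + 1L])
  }
  spath <- file.path(dir, paste0(model_id, ".pdb"))
  write_pdb_atoms(spath, xyz, chain, resno, resid, elety, b)
  jpath <- file.path(dir, paste0(model_id, "_scores.json"))
  jsonlite::write_json(list(plddt = unlist(plddts),
                            pae = apply(pae, 1L, as.list)),
                       jpath, auto_unbox = TRUE, digits = NA)
  data.frame(model_id = model_id, structure = spath, scores = jpath,
             stringsAsFactors = FALSE)
}

## In-memory predicted_model for the same members that go into the files
## (exact coordinates, no PDB rounding).
make_pair_pred <- function(model_id, members_bb, members_def, plddts, pae) {
  counter <- integer(0)
  placements <- lapply(seq_along(members_bb), function(m) {
    su <- members_bb[[m]]
    nm <- members_def[[m]]$name
    cp <- counter[nm] %|na|% 0L
    counter[nm] <<- cp + 1L
    list(subunit = nm, copy = cp, chain = CHAIN_ID_POOL[m],
         ca = su$bb[su$bb_elety == "CA", , drop = FALSE],
         bb = su$bb, bb_elety = su$bb_elety, bb_res = su$bb_res)
  })
  predicted_model(model_id, placements, unlist(plddts), pae)
}

block_pae <- function(la, lb, intra, inter) {
  m <- matrix(inter, la + lb, la + lb)
  m[seq_len(la), seq_len(la)] <- intra
  m[la + seq_len(lb), la + seq_len(lb)] <- intra
  m
}

#' Fabricate predicted pair models for a toy complex
#'
#' Emits one structure/score file pair per contacting subunit pair of the
#' ground truth (coordinates are the ground-truth placement plus Gaussian
#' noise; the inter-subunit PAE block is `pae_true`) and `n_decoys` decoy
#' models (random relative orientation in surface contact; inter-subunit PAE
#' `pae_decoy`).  Intra-subunit PAE blocks are `pae_intra` and plDDT follows
#' the spec's profile, so PAE is the only signal separating decoys from true
#' interactions.
#'
#' @param spec a [toy_complex_spec()].
#' @param dir output directory (created if needed), or `NULL` to fabricate
#'   in-memory models only.
#' @param gt optionally, a prebuilt [build_ground_truth()] result.
#' @return A list: `gt`, `models` (data.frame of `model_id`, `structure`,
#'   `scores`, provenance columns `pi`/`pj` with the ground-truth placement
#'   indices, NA for decoys).
#' @export
fabricate_predictions <- function(spec, dir = NULL, gt = NULL) {
  if (is.null(gt)) gt <- build_ground_truth(spec)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  preds <- list()
  with_seed(spec$seed + 101L, {
    for (k in seq_len(nrow(gt$contacts))) {
      i <- gt$contacts$i[k]; j <- gt$contacts$j[k]
      pi_ <- gt$placements[[i]]; pj_ <- gt$placements[[j]]
      sui <- gt$subunits[[pi_$subunit]]; suj <- gt$subunits[[pj_$subunit]]
      bi <- sui; bj <- suj
      bi$bb <- rt_apply(pi_$rt, sui$bb) +
        matrix(stats::rnorm(3L * nrow(sui$bb), sd = spec$coord_noise_sd), ncol = 3L)
      bj$bb <- rt_apply(pj_$rt, suj$bb) +
        matrix(stats::rnorm(3L * nrow(suj$bb), sd = spec$coord_noise_sd), ncol = 3L)
      la <- nchar(sui$sequence); lb <- nchar(suj$sequence)
      mid <- sprintf("pair_%s%d_%s%d", pi_$subunit, pi_$copy,
                     pj_$subunit, pj_$copy)
      defs <- list(gt$config[[pi_$subunit]], gt$config[[pj_$subunit]])
      plddts <- list(plddt_profile(spec, la), plddt_profile(spec, lb))
      pae <- block_pae(la, lb, spec$pae_intra, spec$pae_true)
      rec <- if (!is.null(dir)) {
        write_pair_model(dir, mid, gt, list(bi, bj), defs, plddts, pae)
      } else {
        data.frame(model_id = mid, structure = NA_character_,
                   scores = NA_character_, stringsAsFactors = FALSE)
      }
      preds[[mid]] <- make_pair_pred(mid, list(bi, bj), defs, plddts, pae)
      rec$pi <- i; rec$pj <- j; rec$decoy <- FALSE
      manifest <- rbind(manifest, rec)
    }
    types <- names(gt$subunits)
    for (d in seq_len(spec$n_decoys)) {
      ab <- if (length(types) == 1L) c(types, types)
            else sample(types, 2L)
      sua <- gt$subunits[[ab[1]]]; sub_ <- gt$subunits[[ab[2]]]
      Rd <- random_rotation()
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      mover <- function(s) sweep(sub_$ca %*% t(Rd), 2L, s * v, "+")
      s_hat <- bisect_contact(sua$ca, mover, spec$contact_dist)
      bd <- sub_
      bd$bb <- rt_apply(rigid_transform(Rd, s_hat * v), sub_$bb) +
        matrix(stats::rnorm(3L * nrow(sub_$bb), sd = spec$coord_noise_sd), ncol = 3L)
      ba <- sua
      ba$bb <- sua$bb +
        matrix(stats::rnorm(3L * nrow(sua$bb), sd = spec$coord_noise_sd), ncol = 3L)
      la <- nchar(sua$sequence); lb <- nchar(sub_$sequence)
      mid <- sprintf("decoy_%02d", d)
      defs <- list(gt$config[[ab[1]]], gt$config[[ab[2]]])
      plddts <- list(plddt_profile(spec, la), plddt_profile(spec, lb))
      pae <- block_pae(la, lb, spec$pae_intra, spec$pae_decoy)
      rec <- if (!is.null(dir)) {
        write_pair_model(dir, mid, gt, list(ba, bd), defs, plddts, pae)
      } else {
        data.frame(model_id = mid, structure = NA_character_,
                   scores = NA_character_, stringsAsFactors = FALSE)
      }
      preds[[mid]] <- make_pair_pred(mid, list(ba, bd), defs, plddts, pae)
      rec$pi <- NA_integer_; rec$pj <- NA_integer_; rec$decoy <- TRUE
      manifest <- rbind(manifest, rec)
    }
  })
  list(gt = gt, models = manifest, pred = preds)
}

#' Write a complete fixture bundle
#'
#' Writes the subunit config, all fabricated model/score files, and the
#' ground-truth reference structure to a directory, in exactly the formats
#' the I/O layer reads.
#'
#' @param spec a [toy_complex_spec()].
#' @param dir output directory.
#' @return As [fabricate_predictions()], plus `config_path`.
#' @export
fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fab <- fabricate_predictions(spec, file.path(dir, "models"))
  cfg_path <- file.path(dir, "subunits.json")
  write_subunit_config(fab$gt$config, cfg_path)
  fab$config_path <- cfg_path
  fab
}

#' Simulate crosslink restraints from a ground-truth complex
#'
#' Samples `n` residue pairs from distinct placed subunit copies whose
#' ground-truth Calpha-Calpha distance is below `max_dist`.  Sampling is
#' stratified over the contacting subunit-copy pairs (quota as even as
#' possible, remainder in deterministic pair order; residue pairs uniform
#' within each stratum under `seed`), mirroring how crosslinking
#' experiments report links across every interface rather than
#' concentrating on the largest one.  Each sampled pair becomes a restraint
#' record with the `max_dist` bound and full experimental weight (w1 = 1).
#' If fewer than `n` pairs are eligible, all eligible pairs are returned
#' with a warning.
#'
#' @param gt a [build_ground_truth()] result.
#' @param n number of crosslinks to sample.
#' @param max_dist Calpha-Calpha upper bound in Angstrom.
#' @param seed integer seed.
#' @return data.frame of restraint records (see [read_restraints()]).
#' @export
simulate_crosslinks <- function(gt, n, max_dist = 20, seed = 1L) {
  stopifnot(n >= 1L)
  cas <- lapply(seq_along(gt$placements), function(k) gt_ca(gt, k))
  np <- length(gt$placements)
  strata <- list()
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      d2 <- outer(rowSums(cas[[i]]^2), rowSums(cas[[j]]^2), "+") -
        2 * tcrossprod(cas[[i]], cas[[j]])
      hits <- which(d2 < max_dist^2, arr.ind = TRUE)
      if (nrow(hits)) {
        strata[[length(strata) + 1L]] <- data.frame(
          subunit_a = gt$placements[[i]]$subunit, res_a = hits[, 1],
          subunit_b = gt$placements[[j]]$subunit, res_b = hits[, 2],
          stringsAsFactors = FALSE)
      }
    }
  }
  total <- sum(vapply(strata, nrow, 0L))
  if (total == 0L) {
    warning("no eligible residue pairs under the distance bound; 0 restraints")
    return(data.frame(subunit_a = character(), res_a = integer(),
                      subunit_b = character(), res_b = integer(),
                      max_dist = numeric(), w1 = numeric()))
  }
  if (total < n) {
    warning(sprintf("only %d of %d requested crosslinks are achievable",
                    total, n))
    n <- total
  }
  out <- with_seed(seed, {
    quota <- integer(length(strata))
    left <- n
    while (left > 0L) {
      for (s in seq_along(strata)) {
        if (left == 0L) break
        if (quota[s] < nrow(strata[[s]])) {
          quota[s] <- quota[s] + 1L
          left <- left - 1L
        }
      }
    }
    picked <- lapply(seq_along(strata), function(s) {
      strata[[s]][sort(sample.int(nrow(strata[[s]]), quota[s])), ,
                  drop = FALSE]
    })
    do.call(rbind, picked)
  })
  out$max_dist <- max_dist
  out$w1 <- 1.0
  rownames(out) <- NULL
  out
}
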