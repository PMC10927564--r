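#' Assembly configuration
#'
#' Tunable parameters of the combinatorial assembly stage.  Defaults follow
#' the method's standard operating point: beam width `K = 100` subcomplexes
#' kept per subunit composition, steric clashes counted for backbone atoms
#' with plDDT above 80 that penetrate another subunit's van-der-Waals
#' surface by more than 1 Angstrom (a subcomplex is discarded when over 5%
#' of a subunit's confident backbone atoms clash), sequence connectivity
#' allowing 3 Angstrom per linker residue, clustering at 1 Angstrom RMSD,
#' restraint violation tolerance of 10% of the applicable restraint weight,
#' and a symmetry reward once more than five identical copies are related
#' by one repeated transformation.
#'
#' @param K beam width per subunit composition.
#' @param clash_penetration penetration depth threshold (Angstrom).
#' @param clash_fraction maximal tolerated clashing-atom fraction.
#' @param clash_plddt_min plDDT cutoff for atoms considered in clash checks.
#' @param linker_rate Angstrom allowed per linker residue (plus one bond).
#' @param cluster_rmsd clustering RMSD threshold (Angstrom).
#' @param restraint_violation_max maximal violated weight fraction.
#' @param symmetry_min_copies minimal copy count for the symmetry reward
#'   (default 6, i.e. "more than five").
#' @param interaction_dist Calpha interaction threshold (Angstrom).
#' @param pool_factor pre-clustering candidate pool per composition, as a
#'   multiple of `K`.
#' @return An `assembly_config`.
#' @export
assembly_config <- function(K = 100L,
                            clash_penetration = 1.0,
                            clash_fraction = 0.05,
                            clash_plddt_min = 80,
                            linker_rate = 3.0,
                            cluster_rmsd = 1.0,
                            restraint_violation_max = 0.10,
                            symmetry_min_copies = 6L,
                            interaction_dist = 8,
                            pool_factor = 2L) {
  stopifnot(K >= 1L, clash_penetration > 0, clash_fraction > 0,
            clash_plddt_min > 0, linker_rate > 0, cluster_rmsd > 0,
            restraint_violation_max > 0, symmetry_min_copies >= 1L,
            pool_factor >= 1L)
  structure(list(K = as.integer(K), clash_penetration = clash_penetration,
                 clash_fraction = clash_fraction,
                 clash_plddt_min = clash_plddt_min,
                 linker_rate = linker_rate, cluster_rmsd = cluster_rmsd,
                 restraint_violation_max = restraint_violation_max,
                 symmetry_min_copies = as.integer(symmetry_min_copies),
                 interaction_dist = interaction_dist,
                 pool_factor = as.integer(pool_factor)),
            class = "assembly_config")
}

## ---- subcomplex bookkeeping -------------------------------------------

new_singleton <- function(subunit, config, gcache = NULL) {
  geom <- if (!is.null(gcache)) {
    gc <- gcache[[subunit]]
    list(ca = list(gc$ca), at = list(gc$xyz),
         actr = matrix(gc$ctr, 1L, 3L), abound = gc$bound,
         cctr = matrix(gc$cactr, 1L, 3L))
  }
  structure(list(
    placements = list(list(subunit = subunit, copy = 0L, rt = rt_identity())),
    size = 1L, score_raw = 0, ratio = 1, score = 0,
    nodes = list(), tree = list(leaf = list(subunit = subunit, copy = 0L)),
    tids = character(), homo = subunit, key = NULL, geom = geom,
    counts = stats::setNames(1L, subunit), sus = subunit,
    aa = seq_length(config[[subunit]])),
    class = "subcomplex")
}

placement_counts <- function(sub) {
  if (!is.null(sub$counts)) return(sub$counts)
  tab <- table(vapply(sub$placements, `[[`, "", "subunit"))
  stats::setNames(as.integer(tab), names(tab))
}

composition_key <- function(counts) {
  counts <- counts[order(names(counts))]
  paste(sprintf("%s:%d", names(counts), counts), collapse = ",")
}

subunit_aa <- function(sub, config) {
  sum(vapply(sub$placements,
             function(p) seq_length(config[[p$subunit]]), 0L))
}

## Canonical geometry key: relative transforms of all placements expressed
## in the frame of an anchor placement (anchor = each copy of the
## lexicographically smallest subunit present; the minimal serialization
## wins).  Rounded so that candidates generated along different assembly
## routes, which agree only to floating-point noise, collide.
canonical_key <- function(sub) {
  n <- length(sub$placements)
  sus <- vapply(sub$placements, `[[`, "", "subunit")
  Rs <- lapply(sub$placements, function(p) p$rt$R)
  ts <- lapply(sub$placements, function(p) p$rt$t)
  anchors <- which(sus == min(sus))
  best <- NULL
  for (a in anchors) {
    Ra <- t(Rs[[a]]); ta <- ts[[a]]
    parts <- character(n)
    for (p in seq_len(n)) {
      v <- round(c(Ra %*% Rs[[p]], Ra %*% (ts[[p]] - ta)), 2)
      v[v == 0] <- 0
      parts[p] <- paste0(sus[p], "@", paste(sprintf("%.2f", v), collapse = ","))
    }
    key <- paste(sort(parts), collapse = ";")
    if (is.null(best) || key < best) best <- key
  }
  best
}

placement_centroids <- function(sub, reps) {
  if (!is.null(sub$geom)) return(sub$geom$cctr)
  t(vapply(sub$placements, function(p) {
    rt_apply(p$rt, colMeans(reps[[p$subunit]]$ca))
  }, numeric(3)))
}

## Cheap frame-invariant geometry fingerprint: subunit-pair labels with
## rounded centroid distances, sorted.  Used together with the raw score to
## deduplicate candidates generated along different assembly routes; two
## genuinely different geometries colliding in both fingerprint and score
## are treated as one (a coarse form of the 1 Angstrom clustering that
## follows anyway).
geo_hash_raw <- function(sus, cc) {
  n <- length(sus)
  if (n == 1L) return(sus)
  d2 <- outer(rowSums(cc^2), rowSums(cc^2), "+") - 2 * tcrossprod(cc)
  parts <- character(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      lab <- if (sus[i] <= sus[j]) paste0(sus[i], "~", sus[j])
             else paste0(sus[j], "~", sus[i])
      parts[k] <- sprintf("%s:%.1f", lab, sqrt(max(d2[i, j], 0)))
    }
  }
  paste(sort(parts), collapse = ";")
}

geo_hash <- function(sub) {
  sus <- vapply(sub$placements, `[[`, "", "subunit")
  geo_hash_raw(sus, sub$geom$cctr)
}

#' Symmetry reward for a transformation score
#'
#' Assemblies built from pairwise interactions underestimate the predictor's
#' confidence in large symmetric oligomers, so when a merged subcomplex
#' consists of more than five copies of one subunit all related by the same
#' repeated pairwise transformation, the score `S` of the merging
#' transformation is boosted to `S + S*(100 - S)/100` (a fixed point at
#' 100).
#'
#' @param s transformation score in `[1, 100]`.
#' @param sub the merged `subcomplex` (context for the symmetry test).
#' @param config an [assembly_config()].
#' @return The (possibly boosted) score.
#' @export
symmetry_reward <- function(s, sub, config = assembly_config()) {
  stopifnot(s >= 1, s <= 100)
  qualifies <- !is.null(sub$homo) && !is.na(sub$homo) &&
    length(sub$tids) == 1L && sub$size >= config$symmetry_min_copies
  if (qualifies) s + s * (100 - s) / 100 else s
}

#' Merge two subcomplexes through a scored transformation
#'
#' The transformation `entry` relates the representative of the anchor
#' subunit in `sub2` to the anchor subunit in `sub1`; the induced rigid
#' motion is applied to every placement of `sub2`, bringing it into
#' `sub1`'s frame.  Copies of each subunit are relabelled so the merged
#' subcomplex numbers them 0..(count-1).  The merged score adds the (possibly
#' symmetry-rewarded) transformation score, and the assembly tree gains one
#' internal node recording the amino-acid sizes of both sides.
#'
#' @param sub1,sub2 `subcomplex`es with jointly feasible copy counts.
#' @param entry list with fields `rt` (maps anchor-2 representative into
#'   anchor-1 frame), `score`, `tid`.
#' @param anchor1,anchor2 placement indices of the anchor subunits.
#' @param config named list of [subunit_def()].
#' @param acfg an [assembly_config()].
#' @return The merged `subcomplex` (unfiltered).
#' @export
merge_subcomplexes <- function(sub1, sub2, entry, anchor1, anchor2,
                               config, acfg = assembly_config()) {
  p1 <- sub1$placements[[anchor1]]
  p2 <- sub2$placements[[anchor2]]
  counts1 <- placement_counts(sub1)
  counts2 <- placement_counts(sub2)
  for (su in names(counts2)) {
    declared <- n_copies(config[[su]])
    if ((counts1[su] %|na|% 0L) + counts2[[su]] > declared) {
      hier_stop(sprintf(
        "merge would exceed the %d declared copies of subunit '%s'",
        declared, su), "precondition")
    }
  }
  M <- rt_compose(p1$rt, rt_compose(entry$rt, rt_inverse(p2$rt)))
  placements <- sub1$placements
  for (p in sub2$placements) {
    p$rt <- rt_compose(M, p$rt)
    p$copy <- p$copy + (counts1[p$subunit] %|na|% 0L)
    placements[[length(placements) + 1L]] <- p
  }
  size <- sub1$size + sub2$size
  combined <- counts1
  for (su in names(counts2)) {
    combined[su] <- (combined[su] %|na|% 0L) + counts2[[su]]
  }
  geom <- NULL
  if (!is.null(sub1$geom) && !is.null(sub2$geom)) {
    Rt <- t(M$R)
    mv <- function(x) sweep(x %*% Rt, 2L, M$t, "+")
    geom <- list(
      ca = c(sub1$geom$ca, lapply(sub2$geom$ca, mv)),
      at = c(sub1$geom$at, lapply(sub2$geom$at, mv)),
      actr = rbind(sub1$geom$actr, mv(sub2$geom$actr)),
      abound = c(sub1$geom$abound, sub2$geom$abound),
      cctr = rbind(sub1$geom$cctr, mv(sub2$geom$cctr)))
  }
  homo <- if (!is.null(sub1$homo) && !is.null(sub2$homo) &&
              identical(sub1$homo, sub2$homo)) sub1$homo else NULL
  tids <- unique(c(sub1$tids, sub2$tids, entry$tid))
  aa1 <- sub1$aa %||% subunit_aa(sub1, config)
  aa2 <- sub2$aa %||% subunit_aa(sub2, config)
  sus1 <- sub1$sus %||% vapply(sub1$placements, `[[`, "", "subunit")
  sus2 <- sub2$sus %||% vapply(sub2$placements, `[[`, "", "subunit")
  merged <- structure(list(
    placements = placements, size = size,
    score_raw = NA_real_, ratio = 1, score = NA_real_,
    nodes = NULL, tree = NULL, tids = tids, homo = homo,
    key = NULL, geom = geom, counts = combined, sus = c(sus1, sus2),
    aa = aa1 + aa2), class = "subcomplex")
  S <- symmetry_reward(entry$score, merged, acfg)
  W <- min(aa1, aa2)
  merged$nodes <- c(sub1$nodes, sub2$nodes, list(list(S = S, W = W,
                                                      tid = entry$tid)))
  merged$tree <- list(tid = entry$tid, S = S, W = W,
                      left = sub1$tree, right = sub2$tree)
  merged$score_raw <- sub1$score_raw + sub2$score_raw + S
  merged$score <- merged$score_raw
  merged
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

## ---- filters -----------------------------------------------------------

## Per-representative clash atom set: confident backbone atoms, radii,
## residue bookkeeping for two-level pruning, and a bounding sphere.
clash_atoms <- function(rep, acfg) {
  keep <- rep$plddt[rep$bb_res + 1L] > acfg$clash_plddt_min
  xyz <- rep$bb[keep, , drop = FALSE]
  radii <- unname(VDW_RADII[rep$bb_elety[keep]])
  res <- rep$bb_res[keep] + 1L          # 1-based residue of each kept atom
  L <- nrow(rep$ca)
  res_atoms <- split(seq_len(nrow(xyz)), factor(res, levels = seq_len(L)))
  ctr <- if (nrow(xyz)) colMeans(xyz) else c(0, 0, 0)
  list(xyz = xyz, radii = radii, res = res, res_atoms = res_atoms,
       ca = rep$ca, cactr = colMeans(rep$ca), ctr = ctr,
       bound = if (nrow(xyz)) max(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) else 0,
       n = nrow(xyz))
}

clash_cache <- function(reps, acfg) lapply(reps, clash_atoms, acfg = acfg)

## Clash fractions between two placed subunits using cached transformed
## coordinates.  Two-level pruning: Calpha residue pairs within 6.5 A
## (backbone atoms sit within ~1.5 A of their Calpha and the largest
## clashing center distance is 2*1.7 - pen < 3.4 A), then exact atom-level
## spheres on the surviving residues.
pair_clash_fracs_xyz <- function(ca1, at1, cc1, ca2, at2, cc2, pen) {
  d2ca <- outer(rowSums(ca1^2), rowSums(ca2^2), "+") -
    2 * tcrossprod(ca1, ca2)
  close <- which(d2ca < 6.5^2, arr.ind = TRUE)
  if (!nrow(close)) return(c(0, 0))
  r1 <- unique(close[, 1]); r2 <- unique(close[, 2])
  ia <- unlist(cc1$res_atoms[r1], use.names = FALSE)
  ib <- unlist(cc2$res_atoms[r2], use.names = FALSE)
  if (!length(ia) || !length(ib)) return(c(0, 0))
  x1 <- at1[ia, , drop = FALSE]; x2 <- at2[ib, , drop = FALSE]
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  thr <- outer(cc1$radii[ia], cc2$radii[ib], "+") - pen
  hit <- d2 < thr * thr & thr > 0
  c(sum(rowSums(hit) > 0) / cc1$n, sum(colSums(hit) > 0) / cc2$n)
}

#' Steric-clash filter
#'
#' Counts, for every tested pair of placed subunits, the confident
#' (plDDT > `clash_plddt_min`) backbone atoms of one subunit whose centers
#' penetrate the other subunit's van-der-Waals surface by more than
#' `clash_penetration` (sphere-overlap depth `r_i + r_j - d`).  The
#' subcomplex is discarded when for some subunit in some pair the clashing
#' fraction of its confident backbone atoms exceeds `clash_fraction`.
#'
#' @param sub a `subcomplex`.
#' @param reps representatives (or a prebuilt cache via `cache`).
#' @param acfg an [assembly_config()].
#' @param sides optional list of two integer vectors of placement indices;
#'   when given only cross-side pairs are tested (as during a merge), else
#'   all pairs.
#' @param cache optional precomputed `clash_cache(reps, acfg)`.
#' @return list with `keep` and a `report` data.frame of per-pair fractions.
#' @export
clash_filter <- function(sub, reps, acfg = assembly_config(), sides = NULL,
                         cache = NULL) {
  if (is.null(cache)) cache <- clash_cache(reps, acfg)
  n <- length(sub$placements)
  geom <- sub$geom
  if (is.null(geom)) {
    geom <- list(ca = vector("list", n), at = vector("list", n),
                 actr = matrix(0, n, 3), abound = numeric(n))
    for (k in seq_len(n)) {
      p <- sub$placements[[k]]
      gc <- cache[[p$subunit]]
      geom$ca[[k]] <- rt_apply(p$rt, gc$ca)
      geom$at[[k]] <- rt_apply(p$rt, gc$xyz)
      geom$actr[k, ] <- rt_apply(p$rt, gc$ctr)
      geom$abound[k] <- gc$bound
    }
  }
  if (is.null(sides)) {
    prs <- utils::combn(n, 2L)
    pairs_i <- prs[1, ]; pairs_j <- prs[2, ]
  } else {
    grid <- expand.grid(i = sides[[1]], j = sides[[2]])
    pairs_i <- grid$i; pairs_j <- grid$j
  }
  keep <- TRUE
  rep_i <- integer(); rep_j <- integer(); fi <- numeric(); fj <- numeric()
  for (k in seq_along(pairs_i)) {
    i <- pairs_i[k]; j <- pairs_j[k]
    cci <- cache[[sub$placements[[i]]$subunit]]
    ccj <- cache[[sub$placements[[j]]$subunit]]
    if (cci$n == 0L || ccj$n == 0L) next  # no confident atoms to clash
    lim <- geom$abound[i] + geom$abound[j] + 3.4
    if (sum((geom$actr[i, ] - geom$actr[j, ])^2) > lim^2) next
    fr <- pair_clash_fracs_xyz(geom$ca[[i]], geom$at[[i]], cci,
                               geom$ca[[j]], geom$at[[j]], ccj,
                               acfg$clash_penetration)
    if (fr[1] > 0 || fr[2] > 0) {
      rep_i <- c(rep_i, i); rep_j <- c(rep_j, j)
      fi <- c(fi, fr[1]); fj <- c(fj, fr[2])
    }
    if (fr[1] > acfg$clash_fraction || fr[2] > acfg$clash_fraction) {
      keep <- FALSE
      break
    }
  }
  list(keep = keep,
       report = data.frame(i = rep_i, j = rep_j, frac_i = fi, frac_j = fj))
}

## Consecutive same-chain segments derived from the config: subunits that
## share chain identifiers are segments of one chain, ordered by start_res.
chain_segments <- function(config) {
  segs <- list()
  seen <- character()
  for (d in config) {
    key <- paste(sort(d$chain_names), collapse = ",")
    seen <- c(seen, key)
  }
  for (key in unique(seen)) {
    members <- config[seen == key]
    if (length(members) < 2L) next
    ord <- order(vapply(members, `[[`, 0L, "start_res"))
    members <- members[ord]
    for (k in seq_len(length(members) - 1L)) {
      d1 <- members[[k]]; d2 <- members[[k + 1L]]
      segs[[length(segs) + 1L]] <- list(
        first = d1$name, second = d2$name,
        n_linker = max(0L, d2$start_res - (d1$start_res + seq_length(d1))))
    }
  }
  segs
}

#' Chain-connectivity filter
#'
#' When a chain is split into several subunits, consecutive segments must
#' stay close enough for the intervening linker: the Calpha of the first
#' segment's C-terminal residue and the Calpha of the next segment's
#' N-terminal residue may be at most `(n_linker + 1) * linker_rate`
#' Angstrom apart (`n_linker` residues absent from both segments; the +1
#' covers the peptide bond when segments abut).  With multiple copies the
#' placed copies of both segments are matched greedily by distance and
#' every matched pair must satisfy the bound.  Subunits from different
#' chains are never tested.
#'
#' @param sub a `subcomplex`.
#' @param config named list of [subunit_def()].
#' @param reps representatives.
#' @param acfg an [assembly_config()].
#' @param segments optional precomputed [chain_segments()] list.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
connectivity_filter <- function(sub, config, reps, acfg = assembly_config(),
                                segments = NULL) {
  if (is.null(segments)) segments <- chain_segments(config)
  if (!length(segments)) return(TRUE)
  sus <- vapply(sub$placements, `[[`, "", "subunit")
  for (sg in segments) {
    ia <- which(sus == sg$first)
    ib <- which(sus == sg$second)
    if (!length(ia) || !length(ib)) next
    bound <- (sg$n_linker + 1) * acfg$linker_rate
    La <- seq_length(config[[sg$first]])
    ptsA <- t(vapply(ia, function(i)
      placement_res_ca(sub$placements[[i]], La, reps), numeric(3)))
    ptsB <- t(vapply(ib, function(j)
      placement_res_ca(sub$placements[[j]], 1L, reps), numeric(3)))
    D <- sqrt(outer(rowSums(ptsA^2), rowSums(ptsB^2), "+") -
                2 * tcrossprod(ptsA, ptsB))
    ## greedy min-distance matching over min(n_a, n_b) copy pairs
    m <- min(length(ia), length(ib))
    for (k in seq_len(m)) {
      idx <- arrayInd(which.min(D), dim(D))
      if (D[idx] > bound) return(FALSE)
      D[idx[1], ] <- Inf
      D[, idx[2]] <- Inf
    }
  }
  TRUE
}

## ---- clustering --------------------------------------------------------

#' Copy-correspondence-resolved Calpha RMSD between subcomplexes
#'
#' With `p` identical copies of a subunit there are `p!` equivalent
#' labelings; comparing two subcomplexes requires the correspondence that
#' minimizes RMSD.  The heuristic superposes only the subunit centroids
#' under the initial (copy-order) correspondence, then repeatedly swaps the
#' correspondence of identical-subunit pairs whenever a swap (followed by
#' re-superposition) lowers the centroid RMSD; the final correspondence is
#' scored by full Calpha RMSD after superposition.
#'
#' @param a,b `subcomplex`es with identical subunit composition.
#' @param reps representatives.
#' @return RMSD in Angstrom, with the correspondence (indices into `b`'s
#'   placements, aligned to `a`'s) in attribute `"correspondence"`.
#' @export
#' @name correspondence_rmsd
NULL

## Precomputed comparison cache for one subcomplex: subunit labels,
## per-placement centroids, transformed Calpha blocks and a
## permutation-invariant signature (sorted pairwise centroid distances).
cluster_cache <- function(sub, reps) {
  sus <- vapply(sub$placements, `[[`, "", "subunit")
  if (!is.null(sub$geom)) {
    cen <- sub$geom$cctr
    blocks <- sub$geom$ca
  } else {
    cen <- placement_centroids(sub, reps)
    blocks <- lapply(sub$placements, function(p)
      rt_apply(p$rt, reps[[p$subunit]]$ca))
  }
  sig <- if (nrow(cen) >= 2L) sort(stats::dist(cen)) else numeric(0)
  list(sus = sus, cen = cen, blocks = blocks, sig = sig)
}

## Superposed RMSD without building the rotation: Kabsch energy form,
## rmsd^2 = (|Pc|^2 + |Qc|^2 - 2 * sum(corrected singular values)) / n.
fit_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- P - rep(colMeans(P), each = n)
  Qc <- Q - rep(colMeans(Q), each = n)
  sv <- svd(crossprod(Pc, Qc))
  s <- sv$d
  if (det(sv$u) * det(sv$v) < 0) s[3] <- -s[3]
  sqrt(max(0, (sum(Pc * Pc) + sum(Qc * Qc) - 2 * sum(s)) / n))
}

corr_rmsd_cached <- function(ca, cb) {
  n <- length(ca$sus)
  corr <- integer(n)
  for (su in unique(ca$sus)) {
    corr[which(ca$sus == su)] <- which(cb$sus == su)
  }
  full_rmsd <- function(corr) {
    fit_rmsd(do.call(rbind, cb$blocks[corr]),
             do.call(rbind, ca$blocks))
  }
  cen_rmsd <- function(corr) {
    if (n >= 3L) fit_rmsd(cb$cen[corr, , drop = FALSE], ca$cen)
    else full_rmsd(corr)  # too few centroids to superpose; use Calpha
  }
  ## small permutation spaces are enumerated outright on the centroids
  ## (the swap heuristic can stall in a local minimum needing a 3-cycle);
  ## larger ones use pairwise-swap hill climbing
  dup_types <- unique(ca$sus[duplicated(ca$sus)])
  n_combo <- prod(factorial(vapply(dup_types, function(su)
    sum(ca$sus == su), 0)))
  if (length(dup_types) && n_combo <= 24) {
    best <- cen_rmsd(corr)
    best_corr <- corr
    enum <- function(types_left, cur_corr) {
      if (!length(types_left)) {
        r <- cen_rmsd(cur_corr)
        if (r < best) { best <<- r; best_corr <<- cur_corr }
        return(invisible())
      }
      su <- types_left[1]
      idx <- which(ca$sus == su)
      slots <- which(cb$sus == su)
      for (p in all_perms(length(idx))) {
        cand <- cur_corr
        cand[idx] <- slots[p]
        enum(types_left[-1], cand)
      }
    }
    enum(dup_types, corr)
    corr <- best_corr
  } else if (length(dup_types)) {
    cur <- cen_rmsd(corr)
    repeat {
      improved <- FALSE
      for (su in dup_types) {
        idx <- which(ca$sus == su)
        for (u in seq_len(length(idx) - 1L)) {
          for (v in (u + 1L):length(idx)) {
            cand <- corr
            cand[idx[c(u, v)]] <- cand[idx[c(v, u)]]
            r2 <- cen_rmsd(cand)
            if (r2 < cur - 1e-9) {
              corr <- cand; cur <- r2; improved <- TRUE
            }
          }
        }
      }
      if (!improved) break
    }
  }
  out <- full_rmsd(corr)
  attr(out, "correspondence") <- corr
  out
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

correspondence_rmsd <- function(a, b, reps) {
  sus_a <- sort(vapply(a$placements, `[[`, "", "subunit"))
  sus_b <- sort(vapply(b$placements, `[[`, "", "subunit"))
  if (!identical(sus_a, sus_b)) {
    hier_stop("subunit compositions differ", "precondition")
  }
  corr_rmsd_cached(cluster_cache(a, reps), cluster_cache(b, reps))
}

#' Greedy leader clustering of equal-composition subcomplexes
#'
#' Candidates are visited in descending score order; each joins the first
#' existing cluster whose leader is within `cluster_rmsd`
#' correspondence-resolved Calpha RMSD, otherwise it founds a new cluster.
#' Leaders (the best-scoring member of each cluster) are returned in score
#' order; collection stops once `max_leaders` clusters exist.
#'
#' @param cands list of `subcomplex`es sharing one composition.
#' @param reps representatives.
#' @param acfg an [assembly_config()].
#' @param max_leaders stop after this many clusters (default `acfg$K`).
#' @return list of cluster-leader `subcomplex`es.
#' @export
cluster_subcomplexes <- function(cands, reps, acfg = assembly_config(),
                                 max_leaders = acfg$K) {
  if (length(cands) <= 1L) return(cands)
  keys <- vapply(cands, function(s) s$key %||% canonical_key(s), "")
  ord <- order(-vapply(cands, `[[`, 0, "score"), keys)
  cands <- cands[ord]
  keys <- keys[ord]
  leaders <- list()
  lcache <- list()
  lkeys <- character()
  slack <- 4 * acfg$cluster_rmsd + 1
  for (ci in seq_along(cands)) {
    s <- cands[[ci]]
    if (keys[ci] %in% lkeys) next  # exact duplicate of a leader
    cc <- cluster_cache(s, reps)
    joined <- FALSE
    for (k in seq_along(leaders)) {
      ## conservative prescreen on the sorted centroid-distance signature
      if (length(cc$sig) && max(abs(cc$sig - lcache[[k]]$sig)) > slack) next
      if (corr_rmsd_cached(lcache[[k]], cc) < acfg$cluster_rmsd) {
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      leaders[[length(leaders) + 1L]] <- s
      lcache[[length(lcache) + 1L]] <- cc
      lkeys <- c(lkeys, keys[ci])
      if (length(leaders) >= max_leaders) break
    }
  }
  leaders
}

## ---- the assembly loop -------------------------------------------------

## Oriented transform lookup: entries for ordered pair (x, y) are library
## records (a=x, b=y) as-is plus inverted records of (y, x).
build_lib_index <- function(library) {
  idx <- new.env(parent = emptyenv())
  push <- function(key, val) {
    assign(key, c(get0(key, envir = idx, ifnotfound = list()), list(val)),
           envir = idx)
  }
  for (e in library) {
    push(paste(e$a, e$b, sep = "|"),
         list(rt = e$rt, score = e$score, tid = e$tid))
    if (e$a != e$b) {
      push(paste(e$b, e$a, sep = "|"),
           list(rt = rt_inverse(e$rt), score = e$score, tid = e$tid))
    }
  }
  idx
}

parse_composition <- function(key) {
  parts <- strsplit(key, ",", fixed = TRUE)[[1]]
  su <- sub(":.*$", "", parts)
  stats::setNames(as.integer(sub("^.*:", "", parts)), su)
}

## groups feasibility: a composition containing part of a group must contain
## only members of that group (groups are finished before cross merges).
groups_allow <- function(counts, groups, config) {
  if (!length(groups)) return(TRUE)
  total <- sum(counts)
  for (g in groups) {
    present <- sum(counts[names(counts) %in% g])
    full <- sum(vapply(g, function(s) n_copies(config[[s]]), 0L))
    if (present > 0L && present < full && total > present) return(FALSE)
  }
  TRUE
}

#' Hierarchically assemble a complex from a transformation library
#'
#' Runs the combinatorial beam assembly: iteration `i` (2..N, with N the
#' total declared subunit copies) creates candidate subcomplexes of size
#' `i` by merging disjoint, previously kept subcomplexes of sizes `k` and
#' `i - k` through every applicable library transformation; candidates with
#' steric clashes, chain-connectivity violations or excessive restraint
#' violations are discarded, the survivors are deduplicated and clustered,
#' and the `K` best-scoring cluster leaders per subunit composition are
#' kept.  If no full-size assembly survives, the largest partial assemblies
#' are returned instead.  The output is sorted by predicted confidence.
#'
#' @param reps representatives from [select_representatives()].
#' @param library list of `scored_transformation`s.
#' @param config named list of [subunit_def()].
#' @param acfg an [assembly_config()].
#' @param restraints optional: restraint records (data.frame) or a list from
#'   [bind_restraints()].
#' @param groups optional list of subunit-name groups assembled first.
#' @return An `assembly_result`: list with `subcomplexes` (ranked), `full`
#'   (logical: complete assembly reached), `size`, `target_size`, and a
#'   per-iteration `log` data.frame.
#' @export
assemble <- function(reps, library, config, acfg = assembly_config(),
                     restraints = NULL, groups = NULL) {
  config <- validate_config(config)
  check_rep_coverage(reps, config)
  if (!length(library)) hier_stop("empty transformation library", "assembly")
  groups <- validate_groups(groups, config)
  if (is.data.frame(restraints)) {
    restraints <- bind_restraints(restraints, reps, config)
  }
  declared <- vapply(config, n_copies, 0L)
  N <- sum(declared)
  idx <- build_lib_index(library)
  ccache <- clash_cache(reps, acfg)
  segments <- chain_segments(config)
  pool_max <- acfg$pool_factor * acfg$K

  beams <- new.env(parent = emptyenv())   # composition key -> list of subcomplexes
  comp_by_size <- vector("list", N)
  for (su in names(config)) {
    s <- new_singleton(su, config, ccache)
    s$key <- su
    ck <- composition_key(stats::setNames(1L, su))
    assign(ck, list(s), envir = beams)
    comp_by_size[[1]] <- c(comp_by_size[[1]], ck)
  }
  log_rows <- NULL
  max_size <- 1L

  emax2 <- 2 * max(vapply(library, `[[`, 0, "score"))

  for (i in 2:N) {
    pools <- new.env(parent = emptyenv())  # composition -> candidate pool
    seen <- new.env(parent = emptyenv())   # geometry+score fingerprints
    n_gen <- 0L; n_kept <- 0L
    for (k in seq_len(i %/% 2L)) {
      ik <- i - k
      c1s <- comp_by_size[[k]]
      c2s <- comp_by_size[[ik]]
      if (is.null(c1s) || is.null(c2s)) next
      for (c1 in c1s) {
        cnt1 <- parse_composition(c1)
        for (c2 in c2s) {
          if (k == ik && c2 < c1) next
          cnt2 <- parse_composition(c2)
          combined <- cnt1
          for (su in names(cnt2)) {
            combined[su] <- (combined[su] %|na|% 0L) + cnt2[[su]]
          }
          if (any(combined > declared[names(combined)])) next
          if (!groups_allow(combined, groups, config)) next
          ckey <- composition_key(combined)
          b1 <- get(c1, envir = beams)
          b2 <- get(c2, envir = beams)
          same_beam <- (c1 == c2)
          pool <- get0(ckey, envir = pools, ifnotfound = new_pool())
          for (u in seq_along(b1)) {
            s1 <- b1[[u]]
            vstart <- if (same_beam) u else 1L
            ## beams are raw-score sorted: once even the best remaining
            ## partner cannot beat the pool threshold, stop
            if (length(pool$scores) >= pool_max &&
                s1$score_raw + b2[[vstart]]$score_raw + emax2 <= pool$thresh)
              break
            for (v in vstart:length(b2)) {
              s2 <- b2[[v]]
              if (length(pool$scores) >= pool_max &&
                  s1$score_raw + s2$score_raw + emax2 <= pool$thresh) break
              pool <- expand_pair(pool, s1, s2, idx, config, acfg, reps,
                                  ccache, segments, restraints, pool_max,
                                  seen)
            }
          }
          n_gen <- n_gen + pool$gen; pool$gen <- 0L
          n_kept <- n_kept + pool$kept; pool$kept <- 0L
          assign(ckey, pool, envir = pools)
        }
      }
    }
    ## cluster and truncate each new composition; beams stay sorted by raw
    ## score for the expansion bound above
    comps <- sort(ls(pools))
    for (ckey in comps) {
      pool <- get(ckey, envir = pools)
      if (!length(pool$cands)) next
      leaders <- cluster_subcomplexes(pool$cands, reps, acfg)
      if (length(leaders)) {
        ord <- order(-vapply(leaders, `[[`, 0, "score_raw"),
                     vapply(leaders, `[[`, "", "key"))
        assign(ckey, leaders[ord], envir = beams)
        comp_by_size[[i]] <- c(comp_by_size[[i]], ckey)
        max_size <- max(max_size, i)
      }
    }
    log_rows <- rbind(log_rows, data.frame(
      iteration = i, generated = n_gen, kept = n_kept,
      compositions = length(comp_by_size[[i]] %||% character())))
  }

  full_key <- composition_key(declared)
  out <- get0(full_key, envir = beams, ifnotfound = NULL)
  full <- !is.null(out) && length(out) > 0L
  if (!full) {
    out <- list()
    sz <- max_size
    for (ckey in comp_by_size[[sz]]) {
      out <- c(out, get(ckey, envir = beams))
    }
  }
  ## rank by predicted confidence; with restraints present the confidence
  ## is modulated by the satisfaction ratio, consistent with the score
  ## modulation during assembly
  conf <- vapply(out, function(s) {
    if (length(s$nodes)) predicted_confidence(s) * (s$ratio %||% 1) else -Inf
  }, 0)
  keys <- vapply(out, function(s) s$key %||% "", "")
  out <- out[order(-conf, keys)]
  structure(list(subcomplexes = out, full = full,
                 size = if (full) N else max_size, target_size = N,
                 log = log_rows),
            class = "assembly_result")
}

new_pool <- function() {
  list(cands = list(), scores = numeric(), keys = character(),
       thresh = -Inf, gen = 0L, kept = 0L)
}

## Candidate construction on the fast path: the induced motion M and the
## moved centroids are already computed for deduplication, so the full
## merge just moves the cached geometry and extends the bookkeeping.
fast_merge <- function(s1, s2, e, S, M, Rt, cctr2, config) {
  counts1 <- s1$counts
  placements <- s1$placements
  for (p in s2$placements) {
    p$rt <- rt_compose(M, p$rt)
    p$copy <- p$copy + (counts1[p$subunit] %|na|% 0L)
    placements[[length(placements) + 1L]] <- p
  }
  combined <- counts1
  for (su in names(s2$counts)) {
    combined[su] <- (combined[su] %|na|% 0L) + s2$counts[[su]]
  }
  mv <- function(x) sweep(x %*% Rt, 2L, M$t, "+")
  geom <- list(ca = c(s1$geom$ca, lapply(s2$geom$ca, mv)),
               at = c(s1$geom$at, lapply(s2$geom$at, mv)),
               actr = rbind(s1$geom$actr, mv(s2$geom$actr)),
               abound = c(s1$geom$abound, s2$geom$abound),
               cctr = rbind(s1$geom$cctr, cctr2))
  W <- min(s1$aa, s2$aa)
  structure(list(
    placements = placements, size = s1$size + s2$size,
    score_raw = s1$score_raw + s2$score_raw + S, ratio = 1,
    score = s1$score_raw + s2$score_raw + S,
    nodes = c(s1$nodes, s2$nodes, list(list(S = S, W = W, tid = e$tid))),
    tree = list(tid = e$tid, S = S, W = W, left = s1$tree, right = s2$tree),
    tids = unique(c(s1$tids, s2$tids, e$tid)),
    homo = if (!is.null(s1$homo) && identical(s1$homo, s2$homo)) s1$homo,
    key = NULL, geom = geom, counts = combined,
    sus = c(s1$sus, s2$sus), aa = s1$aa + s2$aa),
    class = "subcomplex")
}

## Expansion of one subcomplex pair: enumerates anchor subunit pairs and
## library transforms; scores and deduplicates cheaply (centroid fingerprint)
## before building candidate geometry and running the filters.
expand_pair <- function(pool, s1, s2, idx, config, acfg, reps, ccache,
                        segments, restraints, pool_max, seen) {
  sus1 <- s1$sus
  sus2 <- s2$sus
  sym_base <- !is.null(s1$homo) && identical(s1$homo, s2$homo) &&
    (s1$size + s2$size) >= acfg$symmetry_min_copies
  tids12 <- unique(c(s1$tids, s2$tids))
  side1 <- seq_along(sus1)
  side2 <- length(sus1) + seq_along(sus2)
  for (a1 in seq_along(sus1)) {
    for (a2 in seq_along(sus2)) {
      entries <- get0(paste(sus1[a1], sus2[a2], sep = "|"), envir = idx,
                      ifnotfound = NULL)
      if (is.null(entries)) next
      p1rt <- s1$placements[[a1]]$rt
      p2inv <- rt_inverse(s2$placements[[a2]]$rt)
      for (e in entries) {
        pool$gen <- pool$gen + 1L
        S <- e$score
        if (sym_base && all(tids12 == e$tid)) S <- S + S * (100 - S) / 100
        sc_raw <- s1$score_raw + s2$score_raw + S
        if (length(pool$scores) >= pool_max && sc_raw <= pool$thresh) next
        M <- rt_compose(p1rt, rt_compose(e$rt, p2inv))
        Rt <- t(M$R)
        cctr2 <- sweep(s2$geom$cctr %*% Rt, 2L, M$t, "+")
        key <- paste0(
          geo_hash_raw(c(sus1, sus2), rbind(s1$geom$cctr, cctr2)), "#",
          formatC(sc_raw, digits = 9, format = "g"))
        if (!is.null(get0(key, envir = seen, ifnotfound = NULL))) next
        assign(key, TRUE, envir = seen)
        cand <- fast_merge(s1, s2, e, S, M, Rt, cctr2, config)
        cand$key <- key
        if (!is.null(restraints)) {
          ar <- apply_restraints(cand$score_raw, cand, restraints, reps, acfg)
          if (!ar$keep) next
          cand$ratio <- ar$ratio
          cand$score <- ar$score
        }
        if (!clash_filter(cand, reps, acfg, sides = list(side1, side2),
                          cache = ccache)$keep) next
        if (!connectivity_filter(cand, config, reps, acfg, segments)) next
        pool$cands[[length(pool$cands) + 1L]] <- cand
        pool$scores <- c(pool$scores, cand$score)
        pool$keys <- c(pool$keys, key)
        pool$kept <- pool$kept + 1L
        np <- length(pool$cands)
        if (np > 2L * pool_max) {
          keep <- order(-pool$scores, pool$keys)[seq_len(pool_max)]
          pool$cands <- pool$cands[keep]
          pool$scores <- pool$scores[keep]
          pool$keys <- pool$keys[keep]
          pool$thresh <- min(pool$scores)
        } else if (np >= pool_max && (np == pool_max || np %% 64L == 0L)) {
          pool$thresh <- sort(pool$scores, decreasing = TRUE)[pool_max]
        }
      }
    }
  }
  pool
}
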