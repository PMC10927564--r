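## Independent brute-force oracles used to validate the heuristics.

## All-pairs, plain-loop steric clash check (no pruning, no caching):
## fraction of confident backbone atoms of each subunit penetrating any
## other subunit's van-der-Waals spheres by more than `pen`.
brute_clash_discard <- function(sub, reps, acfg = assembly_config()) {
  vdw <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52)
  n <- length(sub$placements)
  atoms <- lapply(sub$placements, function(p) {
    rep <- reps[[p$subunit]]
    keep <- rep$plddt[rep$bb_res + 1L] > acfg$clash_plddt_min
    list(xyz = rt_apply(p$rt, rep$bb[keep, , drop = FALSE]),
         r = unname(vdw[rep$bb_elety[keep]]))
  })
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ai <- atoms[[i]]; aj <- atoms[[j]]
      ci <- rep(FALSE, nrow(ai$xyz)); cj <- rep(FALSE, nrow(aj$xyz))
      for (u in seq_len(nrow(ai$xyz))) {
        d <- sqrt(colSums((t(aj$xyz) - ai$xyz[u, ])^2))
        hit <- (ai$r[u] + aj$r - d) > acfg$clash_penetration
        if (any(hit)) { ci[u] <- TRUE; cj[hit] <- TRUE }
      }
      if (mean(ci) > acfg$clash_fraction || mean(cj) > acfg$clash_fraction) {
        return(TRUE)
      }
    }
  }
  FALSE
}

## Exhaustive assembly enumeration: all binary assembly trees over all
## subsets of the declared copies, times all transform choices and anchor
## pairs, with the same clash/connectivity filters.  Returns every
## surviving full-size subcomplex (deduplicated on the exact canonical
## transform serialization).
enumerate_assemblies <- function(reps, library, config,
                                 acfg = assembly_config()) {
  declared <- vapply(config, function(d) length(d$chain_names), 0L)
  N <- sum(declared)
  idx <- list()
  for (e in library) {
    k <- paste(e$a, e$b, sep = "|")
    idx[[k]] <- c(idx[[k]], list(list(rt = e$rt, score = e$score,
                                      tid = e$tid)))
    if (e$a != e$b) {
      k2 <- paste(e$b, e$a, sep = "|")
      idx[[k2]] <- c(idx[[k2]], list(list(rt = rt_inverse(e$rt),
                                          score = e$score, tid = e$tid)))
    }
  }
  by_size <- vector("list", N)
  by_size[[1]] <- lapply(names(config), function(su) {
    s <- hierasm:::new_singleton(su, config)
    s
  })
  for (i in 2:N) {
    found <- list()
    keys <- character()
    for (k in seq_len(i %/% 2L)) {
      for (s1 in by_size[[k]]) {
        for (s2 in by_size[[i - k]]) {
          for (a1 in seq_along(s1$placements)) {
            for (a2 in seq_along(s2$placements)) {
              pkey <- paste(s1$placements[[a1]]$subunit,
                            s2$placements[[a2]]$subunit, sep = "|")
              for (e in idx[[pkey]] %||% list()) {
                cand <- tryCatch(
                  merge_subcomplexes(s1, s2, e, a1, a2, config, acfg),
                  error = function(err) NULL)
                if (is.null(cand)) next
                if (!clash_filter(cand, reps, acfg)$keep) next
                if (!connectivity_filter(cand, config, reps, acfg)) next
                key <- paste0(hierasm:::canonical_key(cand), "#",
                              format(cand$score_raw, digits = 12))
                if (key %in% keys) next
                keys <- c(keys, key)
                found[[length(found) + 1L]] <- cand
              }
            }
          }
        }
      }
    }
    by_size[[i]] <- found
    if (!length(found)) break
  }
  out <- by_size[[N]] %||% list()
  out[order(-vapply(out, `[[`, 0, "score_raw"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Factorial-enumeration correspondence RMSD: minimum fitted Calpha RMSD
## over all per-subunit-type copy permutations.
brute_correspondence_rmsd <- function(a, b, reps) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  sus_a <- vapply(a$placements, function(p) p$subunit, "")
  sus_b <- vapply(b$placements, function(p) p$subunit, "")
  xa <- do.call(rbind, lapply(a$placements, function(p)
    rt_apply(p$rt, reps[[p$subunit]]$ca)))
  types <- unique(sus_a)
  slots <- lapply(types, function(su) which(sus_b == su))
  perm_sets <- lapply(slots, perms)
  grid <- perm_sets[[1]]
  if (length(types) > 1L) {
    for (t2 in 2:length(types)) {
      grid <- unlist(lapply(grid, function(g) {
        lapply(perm_sets[[t2]], function(p) c(g, p))
      }), recursive = FALSE)
    }
  }
  best <- Inf
  a_slots <- unlist(lapply(types, function(su) which(sus_a == su)))
  for (g in grid) {
    corr <- integer(length(sus_a))
    corr[a_slots] <- g
    xb <- do.call(rbind, lapply(b$placements[corr], function(p)
      rt_apply(p$rt, reps[[p$subunit]]$ca)))
    best <- min(best, coord_rmsd(xb, xa, fit = TRUE))
  }
  best
}

## Direct recomputation of the weighted satisfaction ratio by explicit
## loops over restraints, copies and endpoint pairs.
brute_satisfaction <- function(sub, restraints, reps) {
  num <- 0; den <- 0
  sus <- vapply(sub$placements, function(p) p$subunit, "")
  for (r in restraints) {
    ia <- which(sus == r$a); ib <- which(sus == r$b)
    if (!length(ia) || !length(ib)) next
    if (r$a == r$b && length(ia) < 2L) next
    sat <- FALSE
    for (i in ia) for (j in ib) {
      if (r$a == r$b && i == j) next
      xa <- rt_apply(sub$placements[[i]]$rt, reps[[r$a]]$ca[r$res_a, ])
      xb <- rt_apply(sub$placements[[j]]$rt, reps[[r$b]]$ca[r$res_b, ])
      if (sqrt(sum((xa - xb)^2)) < r$max_dist) sat <- TRUE
    }
    den <- den + r$w
    if (sat) num <- num + r$w
  }
  if (den == 0) 1 else num / den
}
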