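#' Bind crosslink records to weighted restraints
#'
#' Each restraint record names two subunits and residues; because identical
#' copies of a subunit are indistinguishable in the data, a restraint is
#' ambiguous over all copies of each endpoint subunit.  Each record gets two
#' weights: the experimental confidence `w1` taken from the record, and a
#' structure weight `w2` equal to the mean representative plDDT of the two
#' endpoint residues scaled to (0,1], so crosslinks anchored in disordered
#' regions count less.
#'
#' @param records data.frame as from [read_restraints()].
#' @param reps representatives from [select_representatives()].
#' @param config named list of [subunit_def()].
#' @return list of `weighted_restraint`s.
#' @export
bind_restraints <- function(records, reps, config) {
  config <- validate_config(config)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    for (side in c("a", "b")) {
      su <- r[[paste0("subunit_", side)]]
      if (is.null(config[[su]])) {
        hier_stop(sprintf("restraint %d references unknown subunit '%s'", i, su),
                  "reference")
      }
      res <- r[[paste0("res_", side)]]
      if (res < 1L || res > seq_length(config[[su]])) {
        hier_stop(sprintf("restraint %d: residue %d outside subunit '%s'",
                          i, res, su), "reference")
      }
      if (is.null(reps[[su]])) {
        hier_stop(sprintf("restraint %d: no representative for subunit '%s'",
                          i, su), "coverage")
      }
    }
    w2 <- mean(c(reps[[r$subunit_a]]$plddt[r$res_a],
                 reps[[r$subunit_b]]$plddt[r$res_b])) / 100
    w2 <- max(w2, 1e-6)
    out[[i]] <- structure(list(
      a = r$subunit_a, res_a = as.integer(r$res_a),
      b = r$subunit_b, res_b = as.integer(r$res_b),
      max_dist = r$max_dist, w1 = r$w1 %||% 1.0, w2 = w2,
      w = (r$w1 %||% 1.0) * w2), class = "weighted_restraint")
  }
  out
}

## Calpha coordinate of a given residue (1-based) for one placement
placement_res_ca <- function(p, res, reps) {
  rt_apply(p$rt, reps[[p$subunit]]$ca[res, ])
}

restraint_satisfied <- function(sub, r, reps) {
  ia <- which(vapply(sub$placements, `[[`, "", "subunit") == r$a)
  ib <- which(vapply(sub$placements, `[[`, "", "subunit") == r$b)
  if (!length(ia) || !length(ib)) return(NA)  # not applicable
  for (i in ia) {
    xa <- placement_res_ca(sub$placements[[i]], r$res_a, reps)
    for (j in ib) {
      if (r$a == r$b && i == j) next
      xb <- placement_res_ca(sub$placements[[j]], r$res_b, reps)
      if (sqrt(sum((xa - xb)^2)) < r$max_dist) return(TRUE)
    }
  }
  if (r$a == r$b && length(ia) < 2L) return(NA)  # needs two copies
  FALSE
}

#' Weighted restraint satisfaction ratio of a subcomplex
#'
#' The ratio is the sum of weights (`w1 * w2`) of satisfied restraints over
#' the sum of weights of all restraints applicable to the subcomplex.  A
#' restraint is applicable when both endpoint subunits are present, and
#' satisfied when any candidate endpoint pair (over all copies) has a
#' Calpha-Calpha distance strictly below its bound.  With no applicable
#' restraint the ratio is 1.
#'
#' @param sub a `subcomplex`.
#' @param restraints list from [bind_restraints()].
#' @param reps representatives.
#' @return Ratio in `[0, 1]`.
#' @export
satisfaction_ratio <- function(sub, restraints, reps) {
  num <- 0; den <- 0
  for (r in restraints) {
    sat <- restraint_satisfied(sub, r, reps)
    if (is.na(sat)) next
    den <- den + r$w
    if (sat) num <- num + r$w
  }
  if (den == 0) 1 else num / den
}

#' Modulate a subcomplex score by restraint satisfaction
#'
#' Multiplies the raw score by the satisfaction ratio, and flags the
#' subcomplex for discarding when the violated weight fraction
#' (1 - ratio) exceeds `config$restraint_violation_max`.
#'
#' @param score raw (unmodulated) subcomplex score.
#' @param sub a `subcomplex`.
#' @param restraints list from [bind_restraints()].
#' @param reps representatives.
#' @param config an [assembly_config()].
#' @return list with `score` (modulated), `ratio`, and `keep`.
#' @export
apply_restraints <- function(score, sub, restraints, reps,
                             config = assembly_config()) {
  ratio <- satisfaction_ratio(sub, restraints, reps)
  list(score = score * ratio, ratio = ratio,
       keep = (1 - ratio) <= config$restraint_violation_max)
}
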