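#' Scan candidate stoichiometries of one subunit
#'
#' The expensive inputs (representatives and the transformation library)
#' are computed once from the predicted models and reused across copy
#' numbers, so enumerating stoichiometries costs only repeated assembly
#' runs.  For each copy count of the varied subunit the scan records
#' whether a complete assembly survived filtering and, if so, the predicted
#' confidence of the best one.  Two signals locate the true stoichiometry:
#' the confidence curve and the geometric capacity (copy counts that cannot
#' be placed without major steric clashes report `assembled = FALSE`).
#'
#' @param vary name of the subunit whose copy number is scanned.
#' @param copies integer vector of copy counts to try (min 1).
#' @param config named list of [subunit_def()]; all other subunits keep
#'   their declared copies.
#' @param reps representatives.
#' @param library transformation library.
#' @param acfg an [assembly_config()].
#' @param restraints,groups passed through to [assemble()].
#' @return data.frame with columns `copies`, `assembled`, `confidence`,
#'   `size`, `score`; the best subcomplex per copy count is in attribute
#'   `"best"`.
#' @export
scan_stoichiometries <- function(vary, copies, config, reps, library,
                                 acfg = assembly_config(),
                                 restraints = NULL, groups = NULL) {
  config <- validate_config(config)
  if (is.null(config[[vary]])) {
    hier_stop(paste("unknown subunit:", vary), "reference")
  }
  copies <- sort(unique(as.integer(copies)))
  if (!length(copies) || min(copies) < 1L) {
    hier_stop("copy range must be non-empty with minimum 1", "parameter")
  }
  used <- unlist(lapply(config, `[[`, "chain_names"))
  spare <- setdiff(CHAIN_ID_POOL, used)
  rows <- NULL
  best_list <- list()
  for (cc in copies) {
    cfg_c <- config
    d <- cfg_c[[vary]]
    ids <- d$chain_names
    if (cc <= length(ids)) {
      ids <- ids[seq_len(cc)]
    } else {
      extra <- cc - length(ids)
      if (extra > length(spare)) {
        hier_stop("not enough chain identifiers for the requested copies",
                  "capacity")
      }
      ids <- c(ids, spare[seq_len(extra)])
    }
    d$chain_names <- ids
    cfg_c[[vary]] <- d
    total <- sum(vapply(cfg_c, n_copies, 0L))
    if (total < 2L) {
      rows <- rbind(rows, data.frame(copies = cc, assembled = FALSE,
                                     confidence = NA_real_, size = 1L,
                                     score = NA_real_))
      best_list[[as.character(cc)]] <- NULL
      next
    }
    res <- assemble(reps, library, cfg_c, acfg, restraints = restraints,
                    groups = groups)
    top <- if (length(res$subcomplexes)) res$subcomplexes[[1]] else NULL
    conf <- if (res$full && !is.null(top) && length(top$nodes)) {
      predicted_confidence(top)
    } else NA_real_
    rows <- rbind(rows, data.frame(
      copies = cc, assembled = res$full, confidence = conf,
      size = res$size,
      score = if (!is.null(top)) top$score else NA_real_))
    best_list[[as.character(cc)]] <- top
  }
  rownames(rows) <- NULL
  attr(rows, "best") <- best_list
  rows
}
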