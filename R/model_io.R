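## Classed error helper: every user-facing validation failure carries a
## condition class so callers (and tests) can distinguish failure modes.
hier_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("hierasm_", class, "_error"),
                                     "hierasm_error")))
}

MAX_TOTAL_COPIES <- 128L

#' Define an assembly subunit
#'
#' A subunit is the atomic unit of assembly: a full chain or a contiguous
#' domain of a chain, with its own amino-acid sequence and copy count.  The
#' copy count is implied by the number of chain identifiers: one identifier
#' per copy in the target complex.  Domains that are segments of one chain
#' share the same chain identifiers and are distinguished by `start_res`.
#'
#' @param name unique identifier string.
#' @param sequence one-letter amino-acid sequence.
#' @param chain_names character vector of chain identifiers, one per copy.
#' @param start_res first residue number (1-based author numbering).
#' @return A `subunit_def` object.
#' @export
subunit_def <- function(name, sequence, chain_names, start_res = 1L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    hier_stop("subunit name must be a non-empty string", "format")
  }
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) {
    hier_stop(sprintf("subunit '%s': sequence must be non-empty", name), "format")
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)) {
    hier_stop(sprintf("subunit '%s': sequence contains non-standard letters", name),
              "format")
  }
  chain_names <- as.character(chain_names)
  if (length(chain_names) < 1L) {
    hier_stop(sprintf("subunit '%s': chain_names must be non-empty", name), "format")
  }
  structure(list(name = name, sequence = sequence,
                 chain_names = chain_names,
                 start_res = as.integer(start_res)),
            class = "subunit_def")
}

n_copies <- function(def) length(def$chain_names)
seq_length <- function(def) nchar(def$sequence)

## Validate a list of subunit_def as a config; returns the list named by
## subunit for convenient lookup.
validate_config <- function(defs) {
  if (length(defs) == 0L) hier_stop("empty subunit config", "format")
  nms <- vapply(defs, function(d) d$name, "")
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    hier_stop(sprintf("duplicate subunit name(s): %s",
                      paste(unique(dup), collapse = ", ")), "format")
  }
  total <- sum(vapply(defs, n_copies, 0L))
  if (total > MAX_TOTAL_COPIES) {
    hier_stop(sprintf("config declares %d subunit copies; at most %d supported",
                      total, MAX_TOTAL_COPIES), "capacity")
  }
  names(defs) <- nms
  defs
}

#' Read a subunit configuration file
#'
#' The config is a JSON object with a `subunits` array (a bare array is also
#' accepted); each element carries `name`, `sequence`, `chain_names` and
#' optionally `start_res` (default 1).
#'
#' @param path path to a JSON config file.
#' @return Named list of [subunit_def()] objects.
#' @export
read_subunit_config <- function(path) {
  if (!file.exists(path)) hier_stop(paste("no such config file:", path), "format")
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) hier_stop(
                    paste("config parse failure:", conditionMessage(e)), "format"))
  if (!is.null(raw$subunits)) raw <- raw$subunits
  if (!length(raw)) hier_stop("config lists no subunits", "format")
  defs <- lapply(seq_along(raw), function(i) {
    rec <- raw[[i]]
    for (f in c("name", "sequence", "chain_names")) {
      if (is.null(rec[[f]])) {
        hier_stop(sprintf("config record %d ('%s') is missing field '%s'",
                          i, rec$name %||% "?", f), "format")
      }
    }
    subunit_def(rec$name, rec$sequence, unlist(rec$chain_names),
                rec$start_res %||% 1L)
  })
  validate_config(defs)
}

#' Write a subunit configuration file
#' @param defs named list of [subunit_def()].
#' @param path output JSON path.
#' @export
write_subunit_config <- function(defs, path) {
  defs <- validate_config(defs)
  out <- list(subunits = lapply(unname(defs), function(d) {
    list(name = d$name, sequence = d$sequence,
         chain_names = as.list(d$chain_names), start_res = d$start_res)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an in-memory predicted model
#'
#' A predicted model holds the coordinates of one or more placed subunit
#' copies together with the predictor's per-residue plDDT and the all-vs-all
#' predicted aligned error (PAE) matrix, both ordered consistently with the
#' concatenated placements.
#'
#' @param model_id identifier string (provenance).
#' @param placements list of placements, each with fields `subunit`, `copy`
#'   (0-based), `ca` (L x 3), `bb` (4L x 3 backbone N/CA/C/O), `bb_elety`,
#'   `bb_res` (0-based residue offset per backbone atom).
#' @param plddt per-residue confidence, 0-100, over all placements.
#' @param pae square PAE matrix (Angstrom, 0-31) over the same ordering.
#' @return A `predicted_model`.
#' @export
predicted_model <- function(model_id, placements, plddt, pae) {
  lens <- vapply(placements, function(p) nrow(p$ca), 0L)
  total <- sum(lens)
  plddt <- as.numeric(plddt)
  pae <- as.matrix(pae)
  if (length(plddt) != total) {
    hier_stop(sprintf("model '%s': %d plDDT values for %d residues",
                      model_id, length(plddt), total), "score_dialect")
  }
  if (nrow(pae) != total || ncol(pae) != total) {
    hier_stop(sprintf("model '%s': PAE matrix is %dx%d for %d residues",
                      model_id, nrow(pae), ncol(pae), total), "score_dialect")
  }
  if (any(plddt < 0 | plddt > 100)) {
    hier_stop(sprintf("model '%s': plDDT outside [0,100]", model_id),
              "score_dialect")
  }
  if (any(pae < 0 | pae > 31)) {
    hier_stop(sprintf("model '%s': PAE outside [0,31]", model_id),
              "score_dialect")
  }
  ## annotate residue spans and per-placement plDDT
  offset <- 0L
  for (i in seq_along(placements)) {
    L <- lens[i]
    placements[[i]]$start <- offset + 1L
    placements[[i]]$len <- L
    placements[[i]]$plddt <- plddt[(offset + 1L):(offset + L)]
    offset <- offset + L
  }
  structure(list(model_id = model_id, placements = placements,
                 plddt = plddt, pae = pae),
            class = "predicted_model")
}

## One-letter <-> three-letter residue names via bio3d tables.
seq_to_resid <- function(sequence) {
  bio3d::aa123(strsplit(sequence, "")[[1]])
}

read_scores_json <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) hier_stop(
                    paste("scores parse failure:", conditionMessage(e)),
                    "score_dialect"))
  plddt <- raw$plddt
  pae <- raw$pae %||% raw$predicted_aligned_error
  if (is.null(plddt) || is.null(pae)) {
    hier_stop(paste("scores file", path,
                    "must carry 'plddt' and 'pae' (or 'predicted_aligned_error')"),
              "score_dialect")
  }
  if (is.list(pae) && !is.matrix(pae)) pae <- do.call(rbind, pae)
  list(plddt = as.numeric(plddt), pae = as.matrix(pae))
}

#' Read a predicted model (structure + confidence scores)
#'
#' Reads a PDB structure of a subunit pair/subset together with its
#' ColabFold-style score file (JSON with per-residue `plddt` and the `pae`
#' matrix), and maps every chain onto a configured subunit by exact sequence
#' match (ties broken by config order).  Residue numbering in the structure
#' must run from the subunit's `start_res` with no gaps; models with missing
#' residues are rejected rather than silently truncated.
#'
#' @param structure_path PDB (or mmCIF readable by bio3d) file.
#' @param scores_path JSON score file.
#' @param config named list of [subunit_def()].
#' @param model_id identifier; defaults to the structure file base name.
#' @return A [predicted_model()].
#' @export
read_predicted_model <- function(structure_path, scores_path, config,
                                 model_id = NULL) {
  config <- validate_config(config)
  model_id <- model_id %||% sub("\\.(pdb|cif|ent)$", "",
                                basename(structure_path))
  pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  copy_counter <- stats::setNames(integer(length(config)), names(config))
  placements <- list()
  for (ch in chains) {
    ca <- at[at$chain == ch & at$elety == "CA", , drop = FALSE]
    bb <- at[at$chain == ch & at$elety %in% c("N", "CA", "C", "O"), ,
             drop = FALSE]
    if (nrow(ca) == 0L) next
    seq1 <- paste(bio3d::aa321(ca$resid), collapse = "")
    hit <- NULL
    for (d in config) {
      if (d$sequence == seq1) { hit <- d; break }
    }
    if (is.null(hit)) {
      hier_stop(sprintf("model '%s': chain %s sequence matches no subunit",
                        model_id, ch), "identity")
    }
    expected <- hit$start_res + seq_len(seq_length(hit)) - 1L
    if (!identical(as.integer(ca$resno), as.integer(expected))) {
      hier_stop(sprintf(
        "model '%s': chain %s residue numbering does not run %d..%d (missing or renumbered residues)",
        model_id, ch, min(expected), max(expected)), "identity")
    }
    cp <- copy_counter[[hit$name]]
    copy_counter[[hit$name]] <- cp + 1L
    placements[[length(placements) + 1L]] <- list(
      subunit = hit$name, copy = cp, chain = ch,
      ca = as.matrix(ca[, c("x", "y", "z")]),
      bb = as.matrix(bb[, c("x", "y", "z")]),
      bb_elety = bb$elety,
      bb_res = as.integer(bb$resno) - hit$start_res)
  }
  if (!length(placements)) {
    hier_stop(sprintf("model '%s': no protein chains found", model_id),
              "identity")
  }
  sc <- read_scores_json(scores_path)
  predicted_model(model_id, placements, sc$plddt, sc$pae)
}

## Van der Waals radii for backbone atoms (Angstrom, standard element radii).
VDW_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52)

## Write a multi-chain PDB given explicit per-atom vectors.
write_pdb_atoms <- function(file, xyz, chain, resno, resid, elety, b) {
  bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)), chain = chain,
                   resno = resno, resid = resid, elety = elety, b = b,
                   chainter = TRUE)
}

#' Write an assembled complex to PDB with a metadata sidecar
#'
#' Chain identifiers are taken from each subunit's `chain_names` (copy `i`
#' maps to the `i`-th identifier) and author residue numbering restarts at
#' each subunit's `start_res`.  The plDDT of the representative is stored in
#' the B-factor column.  A JSON sidecar (same path with extension `.json`)
#' records the score, predicted confidence, restraint satisfaction and the
#' assembly tree.
#'
#' @param sub a `subcomplex` (see [assemble()]).
#' @param path output PDB path.
#' @param reps representatives, as from [select_representatives()].
#' @param config named list of [subunit_def()].
#' @param metadata write the JSON sidecar? (default `TRUE`)
#' @return Invisibly, the PDB path.
#' @export
write_assembly <- function(sub, path, reps, config, metadata = TRUE) {
  config <- validate_config(config)
  ord <- order(match(vapply(sub$placements, `[[`, "", "subunit"),
                     names(config)),
               vapply(sub$placements, `[[`, 0L, "copy"))
  xyz <- NULL; chain <- character(); resno <- integer()
  resid <- character(); elety <- character(); bvals <- numeric()
  for (p in sub$placements[ord]) {
    d <- config[[p$subunit]]
    if (is.null(d)) hier_stop(paste("unknown subunit in assembly:", p$subunit),
                              "config")
    if (p$copy + 1L > n_copies(d)) {
      hier_stop(sprintf(
        "subunit '%s': copy %d exceeds the %d declared chain name(s)",
        p$subunit, p$copy + 1L, n_copies(d)), "config")
    }
    rep <- reps[[p$subunit]]
    if (is.null(rep)) hier_stop(paste("no representative for", p$subunit),
                                "config")
    co <- rt_apply(p$rt, rep$bb)
    if (any(!is.finite(co))) {
      hier_stop(paste("non-finite coordinates for subunit", p$subunit),
                "format")
    }
    res3 <- seq_to_resid(d$sequence)
    xyz <- rbind(xyz, co)
    chain <- c(chain, rep(d$chain_names[p$copy + 1L], nrow(co)))
    resno <- c(resno, rep$bb_res + d$start_res)
    resid <- c(resid, res3[rep$bb_res + 1L])
    elety <- c(elety, rep$bb_elety)
    bvals <- c(bvals, rep$plddt[rep$bb_res + 1L])
  }
  write_pdb_atoms(path, xyz, chain, resno, resid, elety, bvals)
  if (metadata) {
    meta <- list(
      score = sub$score,
      raw_score = sub$score_raw,
      predicted_confidence = if (length(sub$nodes)) predicted_confidence(sub)
                             else NULL,
      restraint_satisfaction = sub$ratio %||% 1,
      n_placements = length(sub$placements),
      assembly_tree = serialize_tree(sub$tree))
    jsonlite::write_json(meta, sub("\\.pdb$", ".json", path),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

serialize_tree <- function(tree) {
  if (is.null(tree)) return(NULL)
  if (!is.null(tree$leaf)) {
    return(list(leaf = paste0(tree$leaf$subunit, ".", tree$leaf$copy)))
  }
  list(transform_id = tree$tid, score = tree$S, weight = tree$W,
       left = serialize_tree(tree$left), right = serialize_tree(tree$right))
}

#' Read a crosslink restraint table
#'
#' Tab- or comma-separated text with a header and columns `subunit_a`,
#' `res_a`, `subunit_b`, `res_b`, `max_dist` and optionally `w1`
#' (experimental confidence weight, default 1.0).  Residue indices are
#' 1-based within the subunit sequence.
#'
#' @param path restraint table path.
#' @param config optional named list of [subunit_def()]; when given, subunit
#'   names and residue ranges are validated against it.
#' @return data.frame of restraint records.
#' @export
read_restraints <- function(path, config = NULL) {
  if (!file.exists(path)) hier_stop(paste("no such restraint file:", path),
                                    "format")
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("subunit_a", "res_a", "subunit_b", "res_b", "max_dist")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    hier_stop(paste("restraint table missing column(s):",
                    paste(miss, collapse = ", ")), "format")
  }
  if (is.null(tab$w1)) tab$w1 <- 1.0
  if (any(tab$max_dist <= 0)) {
    hier_stop("restraint max_dist must be positive", "format")
  }
  if (any(tab$w1 <= 0 | tab$w1 > 1)) {
    hier_stop("restraint w1 must lie in (0,1]", "format")
  }
  if (!is.null(config)) {
    config <- validate_config(config)
    for (i in seq_len(nrow(tab))) {
      for (side in c("a", "b")) {
        su <- tab[[paste0("subunit_", side)]][i]
        d <- config[[su]]
        if (is.null(d)) {
          hier_stop(sprintf("restraint row %d references unknown subunit '%s'",
                            i, su), "reference")
        }
        res <- tab[[paste0("res_", side)]][i]
        if (res < 1L || res > seq_length(d)) {
          hier_stop(sprintf(
            "restraint row %d: residue %d outside subunit '%s' (length %d)",
            i, res, su, seq_length(d)), "reference")
        }
      }
    }
  }
  tab
}

#' Write a restraint table
#' @param tab data.frame as returned by [read_restraints()].
#' @param path output TSV path.
#' @export
write_restraints <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a scored transformation library
#'
#' The library is serialized as JSON: one record per transformation with the
#' subunit pair, the 3x3 rotation (row-major), the translation, the mean
#' inter-subunit PAE, the derived score and the provenance model id.
#'
#' @param lib list of scored transformations (see [build_transform_library()]).
#' @param path JSON path.
#' @return `write_transform_library` the path; `read_transform_library` the
#'   library.
#' @export
write_transform_library <- function(lib, path) {
  recs <- lapply(lib, function(e) list(
    subunit_a = e$a, subunit_b = e$b,
    rotation = as.numeric(t(e$rt$R)), translation = as.numeric(e$rt$t),
    mean_pae = e$mean_pae, score = e$score, model_id = e$model_id))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform_library
#' @export
read_transform_library <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    scored_transformation(
      r$subunit_a, r$subunit_b,
      rigid_transform(matrix(unlist(r$rotation), 3, 3, byrow = TRUE),
                      unlist(r$translation)),
      r$mean_pae, r$model_id)
  })
  lib
}

#' Read an assembly-group specification
#'
#' JSON of the form `{"groups": [["A","B"], ...]}`: each group is assembled
#' to completion before any merge across group boundaries is attempted.
#'
#' @param path JSON path.
#' @param config optional config for name validation.
#' @return list of character vectors.
#' @export
read_groups <- function(path, config = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- raw$groups %||% raw
  groups <- lapply(groups, as.character)
  validate_groups(groups, config)
}

validate_groups <- function(groups, config = NULL) {
  if (!length(groups)) return(list())
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) {
    hier_stop("assembly groups must be disjoint", "config")
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    hier_stop("each assembly group needs at least 2 subunits", "config")
  }
  if (!is.null(config)) {
    config <- validate_config(config)
    unknown <- setdiff(all_members, names(config))
    if (length(unknown)) {
      hier_stop(paste("assembly group references unknown subunit(s):",
                      paste(unknown, collapse = ", ")), "config")
    }
  }
  groups
}
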