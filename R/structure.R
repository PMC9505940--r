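#' Parse a PDB chain into a C-alpha coarse-grained structure
#'
#' Extracts the alpha-carbon trace of one chain. Alternate locations keep the
#' highest-occupancy copy (ties go to altloc 'A'); modified residues with a
#' standard parent (e.g. MSE) are mapped to their one-letter parent code,
#' other non-standard residues are skipped with a logged note. PDB parsing is
#' done by \pkg{bio3d}.
#'
#' @param pdb Path to a PDB file, or PDB text (a string with newlines or a
#'   character vector of lines).
#' @param chain_id Single chain identifier.
#' @param structure_id Optional label; defaults to the file basename.
#' @return A `cg_structure`: list with `structure_id`, `chain_id`, `resno`
#'   (author residue numbers), `insert` (insertion codes, `""` if none),
#'   `resid` (one-letter codes), `xyz` (N x 3 coordinate matrix, Angstrom)
#'   and `bfactors` (numeric vector or `NULL`).
#' @examples
#' s <- make_toy_chain(n_residues = 20, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(s, f)
#' s2 <- parse_calpha(f, "A")
#' @export
parse_calpha <- function(pdb, chain_id, structure_id = NULL) {
  stopifnot(is.character(chain_id), length(chain_id) == 1)
  if (length(pdb) > 1 || grepl("\n", pdb) || !file.exists(pdb)) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tf)
    if (is.null(structure_id)) structure_id <- "pdb_text"
    pdb_file <- tf
  } else {
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(pdb), ignore.case = TRUE)
    pdb_file <- pdb
  }
  p <- bio3d::read.pdb(pdb_file, verbose = FALSE, rm.alt = FALSE)
  at <- p$atom
  if (!chain_id %in% at$chain)
    stop("chain '", chain_id, "' not found in ", structure_id)
  at <- at[at$chain == chain_id & at$elety == "CA", , drop = FALSE]

  res3 <- at$resid
  res1 <- rep(NA_character_, nrow(at))
  std3 <- bio3d::aa123(.STD_AA)
  res1[res3 %in% std3] <- bio3d::aa321(res3[res3 %in% std3])
  mod <- res3 %in% names(.MODRES_MAP)
  res1[mod] <- .MODRES_MAP[res3[mod]]
  if (anyNA(res1)) {
    skipped <- unique(res3[is.na(res1)])
    psp_log("WARN", "skipping non-standard residue(s) without a parent: ",
            paste(skipped, collapse = ", "))
    at <- at[!is.na(res1), , drop = FALSE]
    res1 <- res1[!is.na(res1)]
  }
  if (nrow(at) == 0)
    stop("no CA atoms of standard residues in chain '", chain_id, "' of ", structure_id)

  ins <- ifelse(is.na(at$insert) | at$insert == " ", "", at$insert)
  key <- paste0(at$resno, ins)
  if (anyDuplicated(key)) {
    # alternate locations: keep highest occupancy, ties -> altloc 'A' (then order)
    alt <- ifelse(is.na(at$alt) | at$alt == " ", "", at$alt)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      if (all(alt[idx] == "")) next  # genuine duplicate numbering -> error below
      best <- idx[order(-occ[idx], alt[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
    res1 <- res1[keep]
    ins <- ins[keep]
    key <- key[keep]
  }
  if (anyDuplicated(key))
    stop("duplicate author numbering in chain '", chain_id, "' after filtering: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  xyz <- cbind(at$x, at$y, at$z)
  b <- at$b
  bfactors <- if (all(is.na(b))) NULL else as.numeric(b)

  s <- structure(list(structure_id = structure_id, chain_id = chain_id,
                      resno = as.integer(at$resno), insert = ins,
                      resid = unname(res1), xyz = unname(xyz),
                      bfactors = bfactors),
                 class = "cg_structure")
  gaps <- which(sqrt(rowSums((s$xyz[-1, , drop = FALSE] -
                              s$xyz[-nrow(s$xyz), , drop = FALSE])^2)) > 4.5)
  if (length(gaps))
    psp_log("WARN", "CA-CA distance > 4.5 A after residue position(s) ",
            paste(s$resno[gaps], collapse = ", "),
            "; consecutive residues are still treated as bonded")
  s
}

#' Specify a point mutation
#'
#' @param chain_id Chain identifier.
#' @param wt_res,mut_res One-letter codes of the wildtype and mutant residue
#'   (must differ).
#' @param position Author residue number.
#' @param insert Optional insertion code (default `""`).
#' @return A `mutation_spec` object.
#' @export
mutation_spec <- function(chain_id, wt_res, position, mut_res, insert = "") {
  wt_res <- toupper(wt_res); mut_res <- toupper(mut_res)
  if (!wt_res %in% .STD_AA || !mut_res %in% .STD_AA)
    stop("wt_res and mut_res must be standard one-letter residue codes")
  if (wt_res == mut_res)
    stop("wt_res and mut_res must differ")
  structure(list(chain_id = chain_id, position = as.integer(position),
                 insert = insert, wt_res = wt_res, mut_res = mut_res),
            class = "mutation_spec")
}

#' Parse a mutation token like "D89E"
#'
#' The first character is the wildtype residue, the last the mutant residue,
#' and the middle is the author position with an optional trailing insertion
#' code letter (e.g. `"D89AE"` is position 89, insertion code A).
#'
#' @param token Mutation string.
#' @param chain_id Chain the mutation applies to.
#' @return A `mutation_spec`.
#' @export
parse_mutation <- function(token, chain_id) {
  m <- regexec("^([A-Za-z])([0-9]+)([A-Za-z]?)([A-Za-z])$", trimws(token))[[1]]
  parts <- regmatches(trimws(token), list(m))[[1]]
  if (length(parts) != 5)
    stop("cannot parse mutation token '", token, "'")
  mutation_spec(chain_id, parts[2], as.integer(parts[3]), parts[5],
                insert = toupper(parts[4]))
}

# index of an author position within a cg_structure (0 if absent)
position_index <- function(structure, position, insert = "") {
  match(paste0(position, insert),
        paste0(structure$resno, structure$insert), nomatch = 0L)
}

#' Apply a point mutation to a coarse-grained structure
#'
#' Replaces the residue type at the mutation position; coordinates, ordering
#' and B-factors are untouched (the model is C-alpha only, so a mutation
#' changes spring stiffnesses, never geometry). Records whose wildtype
#' residue does not match the structure are rejected, mirroring the exclusion
#' of such mutations from the benchmark sets.
#'
#' @param structure A `cg_structure`.
#' @param spec A `mutation_spec` (or a token string, if `chain_id` can be
#'   taken from the structure).
#' @return The mutated `cg_structure`.
#' @export
apply_mutation <- function(structure, spec) {
  stopifnot(inherits(structure, "cg_structure"))
  if (is.character(spec)) spec <- parse_mutation(spec, structure$chain_id)
  stopifnot(inherits(spec, "mutation_spec"))
  idx <- position_index(structure, spec$position, spec$insert)
  if (idx == 0L)
    stop("position ", spec$position, spec$insert, " not found in ",
         structure$structure_id)
  if (structure$resid[idx] != spec$wt_res)
    stop(structure$structure_id, " has ", structure$resid[idx], " at position ",
         spec$position, spec$insert, ", not the stated wildtype ", spec$wt_res,
         " (wildtype-mismatch)", call. = FALSE)
  out <- structure
  out$resid[idx] <- spec$mut_res
  out
}

# invert a mutation spec (forward X->Y becomes reverse Y->X)
invert_mutation <- function(spec) {
  mutation_spec(spec$chain_id, spec$mut_res, spec$position, spec$wt_res,
                insert = spec$insert)
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("C-alpha structure", x$structure_id, "chain", x$chain_id, "-",
      length(x$resid), "residues\n")
  invisible(x)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("Mutation %s%d%s%s (chain %s)\n", x$wt_res, x$position,
              x$insert, x$mut_res, x$chain_id))
  invisible(x)
}
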