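# Orchestration: single predictions, batch runs and provenance headers.
# These back the thin command-line wrapper in exec/psp-gnm.

ddg_row <- function(structure_id, chain, mutation_token, res) {
  data.frame(structure_id = structure_id, chain = chain,
             mutation = mutation_token, direction = res$direction,
             raw_ddg = res$raw_ddg, scaled_ddg = res$scaled_ddg,
             n_matched = res$n_matched, status = res$status,
             stringsAsFactors = FALSE)
}

provenance_header <- function(params, inputs = character(0)) {
  ver <- as.character(utils::packageVersion("pspgnm"))
  cfg <- paste(names(params), vapply(params, function(p)
    paste(format(p), collapse = ","), ""), sep = "=", collapse = " ")
  h <- c(paste0("# pspgnm ", ver), paste0("# config: ", cfg))
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs)) {
    md5 <- tools::md5sum(inputs)
    h <- c(h, paste0("# input: ", basename(names(md5)), " md5=", unname(md5)))
  }
  h
}

write_predictions <- function(df, file, params, inputs = character(0)) {
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  writeLines(provenance_header(params, inputs), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Predict ddG for one mutation from a PDB file
#'
#' Parses the wildtype chain, applies the mutation and computes the forward
#' ddG; with `reverse_pdb` (an independently solved mutant structure) the
#' reverse prediction is computed by structure swap and both rows are
#' returned.
#'
#' @param wt_pdb Path to the wildtype PDB file.
#' @param chain Chain identifier.
#' @param mutation Mutation token, e.g. `"D89E"`.
#' @param potential A `contact_potential` (default [mj_potential()]).
#' @param reverse_pdb Optional path to a mutant-structure PDB for the reverse
#'   direction.
#' @param rc,n_modes,break_fraction,convention,scale Model parameters, see
#'   [compute_ddg()].
#' @param out Optional TSV output path (provenance header + one row per
#'   direction).
#' @return data.frame with columns `structure_id`, `chain`, `mutation`,
#'   `direction`, `raw_ddg`, `scaled_ddg`, `n_matched`, `status`; the full
#'   `ddg_result` objects are attached as `attr(x, "results")`.
#' @export
run_single <- function(wt_pdb, chain, mutation, potential = mj_potential(),
                       reverse_pdb = NULL, rc = 9, n_modes = 10,
                       break_fraction = 0.5, convention = "boltzmann_negated",
                       scale = c(1, 0), out = NULL) {
  wt <- parse_calpha(wt_pdb, chain)
  spec <- parse_mutation(mutation, chain)
  fwd <- compute_ddg(wt, spec, potential, rc = rc, n_modes = n_modes,
                     break_fraction = break_fraction, convention = convention,
                     scale = scale)
  rows <- ddg_row(wt$structure_id, chain, mutation, fwd)
  results <- list(forward = fwd)
  if (!is.null(reverse_pdb)) {
    mut_st <- parse_calpha(reverse_pdb, chain)
    rev <- compute_reverse_ddg(wt, spec, potential, mut_structure = mut_st,
                               rc = rc, n_modes = n_modes,
                               break_fraction = break_fraction,
                               convention = convention, scale = scale)
    rows <- rbind(rows, ddg_row(mut_st$structure_id, chain, mutation, rev))
    results$reverse <- rev
  }
  params <- list(rc = rc, n_modes = n_modes, break_fraction = break_fraction,
                 convention = convention, scale = scale)
  if (!is.null(out))
    write_predictions(rows, out, params, c(wt_pdb, reverse_pdb))
  attr(rows, "results") <- results
  rows
}

#' Predict ddG for every record of a mutation table
#'
#' One output row per record, in input order. A record that fails (missing
#' PDB, wildtype mismatch, unstable model, ...) yields a row with
#' `status = "error"` and the message; the batch never aborts. Re-running
#' with identical inputs produces a byte-identical TSV.
#'
#' @param table_csv Path to a mutation table, see [read_mutation_table()].
#' @param pdb_dir Directory containing `<pdb_id>.pdb` files.
#' @param potential,rc,n_modes,break_fraction,convention,scale See
#'   [compute_ddg()].
#' @param out Optional TSV output path.
#' @return data.frame of prediction rows (invisibly when `out` is given).
#' @export
run_batch <- function(table_csv, pdb_dir, potential = mj_potential(),
                      rc = 9, n_modes = 10, break_fraction = 0.5,
                      convention = "boltzmann_negated", scale = c(1, 0),
                      out = NULL) {
  if (!dir.exists(pdb_dir)) stop("pdb_dir does not exist: ", pdb_dir)
  records <- read_mutation_table(table_csv)
  structures <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(records)), function(r) {
    rec <- records[r, ]
    res <- tryCatch({
      pdb_file <- file.path(pdb_dir, paste0(rec$pdb_id, ".pdb"))
      if (!file.exists(pdb_file)) stop("missing PDB file: ", basename(pdb_file))
      key <- paste(rec$pdb_id, rec$chain)
      st <- if (!is.null(structures[[key]])) structures[[key]]
            else structures[[key]] <- parse_calpha(pdb_file, rec$chain)
      spec <- mutation_spec(rec$chain, rec$wt_res, rec$position, rec$mut_res,
                            insert = rec$insert)
      dd <- if (identical(rec$direction, "reverse"))
        compute_reverse_ddg(st, spec, potential, rc = rc, n_modes = n_modes,
                            break_fraction = break_fraction,
                            convention = convention, scale = scale)
      else
        compute_ddg(st, spec, potential, rc = rc, n_modes = n_modes,
                    break_fraction = break_fraction, convention = convention,
                    scale = scale)
      ddg_row(rec$pdb_id, rec$chain, rec$mutation, dd)
    }, error = function(e) {
      data.frame(structure_id = rec$pdb_id, chain = rec$chain,
                 mutation = rec$mutation, direction = rec$direction,
                 raw_ddg = NA_real_, scaled_ddg = NA_real_, n_matched = NA_integer_,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  df <- do.call(rbind, rows)
  params <- list(rc = rc, n_modes = n_modes, break_fraction = break_fraction,
                 convention = convention, scale = scale)
  if (!is.null(out)) {
    write_predictions(df, out, params, table_csv)
    return(invisible(df))
  }
  df
}
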