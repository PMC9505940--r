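#' Read a benchmark mutation table
#'
#' Delimited text with a header naming at least `pdb_id`, `chain`, `mutation`,
#' `temperature` (degrees C), `ph` and `exp_ddg` (kcal/mol); an optional
#' `direction` column defaults to `"forward"`. Malformed rows (unparsable
#' mutation token) are collected into a rejects report attached as
#' `attr(x, "rejects")`, never silently dropped.
#'
#' @param path Path to the table.
#' @param sep Field separator (default `","`).
#' @return data.frame of records in file order, with parsed `wt_res`,
#'   `position`, `insert`, `mut_res` columns.
#' @export
read_mutation_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cannot read mutation table: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("pdb_id", "chain", "mutation", "temperature", "ph", "exp_ddg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$direction)) df$direction <- "forward"
  df$temperature <- suppressWarnings(as.numeric(df$temperature))
  df$ph <- suppressWarnings(as.numeric(df$ph))
  df$exp_ddg <- suppressWarnings(as.numeric(df$exp_ddg))

  ok <- grepl("^[A-Za-z][0-9]+[A-Za-z]?[A-Za-z]$", trimws(df$mutation))
  rejects <- df[!ok, , drop = FALSE]
  if (nrow(rejects)) {
    rejects$reason <- "unparsable mutation token"
    psp_log("WARN", nrow(rejects), " row(s) rejected: unparsable mutation token")
  }
  df <- df[ok, , drop = FALSE]
  parsed <- lapply(seq_len(nrow(df)),
                   function(i) parse_mutation(df$mutation[i], df$chain[i]))
  df$wt_res <- vapply(parsed, `[[`, "", "wt_res")
  df$position <- vapply(parsed, `[[`, 1L, "position")
  df$insert <- vapply(parsed, `[[`, "", "insert")
  df$mut_res <- vapply(parsed, `[[`, "", "mut_res")
  rownames(df) <- NULL
  attr(df, "rejects") <- rejects
  df
}

#' Filter records by experimental temperature and pH
#'
#' Keeps records whose temperature and pH are both present and inside the
#' closed intervals. The defaults are the near-physiological window in which
#' structure-based predictions agree best with experiment.
#'
#' @param records data.frame with `temperature` and `ph` columns.
#' @param t_range Closed temperature interval, degrees C (default `c(24, 26)`).
#' @param ph_range Closed pH interval (default `c(6.8, 7.2)`).
#' @return The filtered data.frame.
#' @export
filter_conditions <- function(records, t_range = c(24, 26),
                              ph_range = c(6.8, 7.2)) {
  keep <- !is.na(records$temperature) & !is.na(records$ph) &
    records$temperature >= t_range[1] & records$temperature <= t_range[2] &
    records$ph >= ph_range[1] & records$ph <= ph_range[2]
  records[keep, , drop = FALSE]
}

#' Pearson correlation coefficient
#'
#' @param x,y Equal-length numeric vectors (length >= 2, finite, non-zero
#'   variance).
#' @return Correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need two equal-length vectors with at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  stats::cor(x, y)
}

#' Root mean squared error
#'
#' `sqrt(sum((x - y)^2) / N)` with divisor N.
#'
#' @param x,y Equal-length numeric vectors.
#' @return RMSE (kcal/mol when inputs are ddG values).
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1)
    stop("need two equal-length non-empty vectors")
  sqrt(sum((x - y)^2) / length(x))
}

#' Antisymmetry between forward and reverse predictions
#'
#' Pearson correlation between paired forward and reverse ddG values;
#' thermodynamic consistency requires -1.
#'
#' @param fwd,rev Paired prediction vectors.
#' @return Correlation in [-1, 1].
#' @export
antisymmetry <- function(fwd, rev) pearson(fwd, rev)

#' Bias score between forward and reverse predictions
#'
#' `delta = sum(fwd_i + rev_i) / (2N)`; 0 indicates no systematic preference
#' for predicting either mutation class as destabilizing.
#'
#' @param fwd,rev Paired prediction vectors.
#' @return Bias, kcal/mol.
#' @export
bias <- function(fwd, rev) {
  if (length(fwd) != length(rev) || length(fwd) < 1)
    stop("need paired non-empty vectors")
  sum(fwd + rev) / (2 * length(fwd))
}

#' Summary metrics for a prediction set
#'
#' @param calc,exp Paired calculated and experimental ddG vectors.
#' @param fwd,rev Optional paired forward/reverse predictions for
#'   antisymmetry and bias.
#' @return List with `n`, `pcc`, `rmse` and (when forward/reverse pairs are
#'   given) `antisymmetry` and `bias`.
#' @export
evaluation_summary <- function(calc, exp, fwd = NULL, rev = NULL) {
  out <- list(n = length(calc), pcc = pearson(calc, exp),
              rmse = rmse(calc, exp))
  if (!is.null(fwd) && !is.null(rev)) {
    out$antisymmetry <- antisymmetry(fwd, rev)
    out$bias <- bias(fwd, rev)
  }
  out
}

#' Scan cutoff distance and mode count over a mutation set
#'
#' Runs the full pipeline for every (rc, n_modes) grid point over a set of
#' mutation records with resolvable structures, reporting agreement with the
#' experimental values and the percentage of mutations that obtained a
#' computed (non-defaulted) prediction. Per-record failures are counted and
#' the scan continues.
#'
#' @param records data.frame from [read_mutation_table()] (or equivalent).
#' @param structures Named list of `cg_structure` objects keyed by `pdb_id`.
#' @param potential A `contact_potential`.
#' @param rc_grid Cutoff distances to scan (default `7:12` Angstrom).
#' @param mode_grid Mode counts to scan (default `c(5, 10, 20, 30, 40, 50)`).
#' @param break_fraction,convention Passed to [compute_ddg()].
#' @param zeros `"include"` (defaulted-zero predictions enter the metrics as
#'   0, the default) or `"exclude"`.
#' @return data.frame with columns `rc`, `n_modes`, `pcc`, `rmse`,
#'   `pct_predictions`, `n_failed`, sorted by `pcc` descending.
#' @export
parameter_scan <- function(records, structures, potential, rc_grid = 7:12,
                           mode_grid = c(5, 10, 20, 30, 40, 50),
                           break_fraction = 0.5,
                           convention = "boltzmann_negated",
                           zeros = c("include", "exclude")) {
  zeros <- match.arg(zeros)
  grid <- expand.grid(rc = rc_grid, n_modes = mode_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    rc <- grid$rc[g]; nm <- grid$n_modes[g]
    pred <- rep(NA_real_, nrow(records))
    status <- rep("failed", nrow(records))
    for (r in seq_len(nrow(records))) {
      st <- structures[[records$pdb_id[r]]]
      res <- tryCatch({
        if (is.null(st)) stop("no structure for ", records$pdb_id[r])
        spec <- mutation_spec(records$chain[r], records$wt_res[r],
                              records$position[r], records$mut_res[r],
                              insert = records$insert[r])
        compute_ddg(st, spec, potential, rc = rc, n_modes = nm,
                    break_fraction = break_fraction, convention = convention)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        psp_log("WARN", "scan rc=", rc, " modes=", nm, " record ", r,
                " failed: ", conditionMessage(res))
        next
      }
      pred[r] <- res$raw_ddg
      status[r] <- res$status
    }
    use <- if (zeros == "include") status %in% c("computed", "defaulted_zero")
           else status == "computed"
    pcc_val <- if (sum(use) >= 2 && stats::sd(pred[use]) > 0 &&
                   stats::sd(records$exp_ddg[use]) > 0)
      pearson(pred[use], records$exp_ddg[use]) else NA_real_
    rmse_val <- if (sum(use) >= 1) rmse(pred[use], records$exp_ddg[use]) else NA_real_
    data.frame(rc = rc, n_modes = nm, pcc = pcc_val, rmse = rmse_val,
               pct_predictions = 100 * sum(status == "computed") / nrow(records),
               n_failed = sum(status == "failed"))
  })
  out <- do.call(rbind, rows)
  out[order(-out$pcc), , drop = FALSE]
}
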