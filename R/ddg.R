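#' Pair broken contacts by rank
#'
#' Pairs the k-th contact broken at the mutation site in the wildtype trace
#' with the k-th in the mutant trace, for k up to the shorter list; the
#' partners need not be the same residue.
#'
#' @param wt_list,mut_list data.frames from [broken_contacts_at()].
#' @return data.frame with columns `rank`, `wt_partner_index`,
#'   `wt_partner_restype`, `wt_msf`, `mut_partner_index`,
#'   `mut_partner_restype`, `mut_msf` (zero rows if either list is empty).
#' @export
match_ranks <- function(wt_list, mut_list) {
  n <- min(nrow(wt_list), nrow(mut_list))
  idx <- seq_len(n)
  data.frame(rank = idx,
             wt_partner_index = wt_list$partner_index[idx],
             wt_partner_restype = wt_list$partner_restype[idx],
             wt_msf = wt_list$msf_at_break[idx],
             mut_partner_index = mut_list$partner_index[idx],
             mut_partner_restype = mut_list$partner_restype[idx],
             mut_msf = mut_list$msf_at_break[idx],
             stringsAsFactors = FALSE)
}

# total contact energy between the residue type at the mutation site and the
# rank-matched partners' types
site_energy_sum <- function(potential, site_res, partner_types) {
  if (length(partner_types) == 0) return(0)
  sum(potential$energies[cbind(rep(site_res, length(partner_types)),
                               partner_types)])
}

#' Compute the stability change (ddG) of a point mutation
#'
#' Builds the mutant model (identical coordinates, mutated residue type),
#' partially unfolds both wildtype and mutant networks, extracts the contacts
#' broken at the mutation site, rank-matches them, and evaluates
#'
#'   `raw = -((sum MJ_mut - sum MJ_wt) - (sum MSF_mut - sum MSF_wt))`
#'
#' where the MJ sums use the contact energy between the residue type at the
#' mutation site (wildtype type on the wildtype side, mutant type on the
#' mutant side) and each rank-matched partner's type, and the MSF sums use
#' the distance fluctuation recorded at the iteration each contact broke. If
#' no contact involving the mutation site breaks on either side, the
#' theoretical value 0 is returned with `status = "defaulted_zero"`.
#'
#' @param wt_structure Wildtype `cg_structure`.
#' @param mutation A `mutation_spec` (or token string).
#' @param potential A `contact_potential`.
#' @param rc,n_modes,break_fraction,convention,zero_tolerance Model
#'   parameters passed to [unfold()].
#' @param scale Length-2 numeric `c(slope, intercept)` applied to the raw
#'   value (default `c(1, 0)`, i.e. raw output). For reverse-direction
#'   results the intercept is subtracted rather than added, so that
#'   rescaling preserves exact antisymmetry. Defaulted-zero results are
#'   reported as 0 on both scales.
#' @param mut_structure Optional mutant `cg_structure` (e.g. an independently
#'   solved mutant); by default built with [apply_mutation()].
#' @param entropy_from Where the entropy-term MSF values come from:
#'   `"at_break"` (default) uses the fluctuation recorded at the iteration
#'   each contact broke; `"native"` re-evaluates the same residue pairs on
#'   the intact native-state network.
#' @param direction `"forward"` or `"reverse"` (label only; see
#'   [compute_reverse_ddg()]).
#' @return A `ddg_result`: list with `raw_ddg`, `scaled_ddg`, `n_matched`,
#'   `status` (`"computed"`/`"defaulted_zero"`), `direction`, `components`
#'   (named: sum_mj_mut, sum_mj_wt, sum_msf_mut, sum_msf_wt), `mutation`,
#'   `matches`, `terminations` and `params`.
#' @examples
#' pair <- make_mutant_pair(n_residues = 20, seed = 3)
#' res <- compute_ddg(pair$wt, pair$spec, mj_potential())
#' res$raw_ddg
#' @export
compute_ddg <- function(wt_structure, mutation, potential, rc = 9,
                        n_modes = 10, break_fraction = 0.5,
                        convention = c("boltzmann_negated", "literal_eq2"),
                        zero_tolerance = 1e-8, scale = c(1, 0),
                        mut_structure = NULL,
                        entropy_from = c("at_break", "native"),
                        direction = "forward") {
  convention <- match.arg(convention)
  entropy_from <- match.arg(entropy_from)
  if (is.character(mutation))
    mutation <- parse_mutation(mutation, wt_structure$chain_id)
  idx_wt <- position_index(wt_structure, mutation$position, mutation$insert)
  if (idx_wt == 0L)
    stop("position ", mutation$position, mutation$insert, " not found in ",
         wt_structure$structure_id)
  if (is.null(mut_structure)) {
    mut_structure <- apply_mutation(wt_structure, mutation)  # validates wt_res
    idx_mut <- idx_wt
  } else {
    if (wt_structure$resid[idx_wt] != mutation$wt_res)
      stop(wt_structure$structure_id, " has ", wt_structure$resid[idx_wt],
           " at position ", mutation$position, mutation$insert,
           ", not the stated wildtype ", mutation$wt_res,
           " (wildtype-mismatch)", call. = FALSE)
    idx_mut <- position_index(mut_structure, mutation$position, mutation$insert)
    if (idx_mut == 0L)
      stop("position ", mutation$position, mutation$insert, " not found in ",
           mut_structure$structure_id)
    if (mut_structure$resid[idx_mut] != mutation$mut_res)
      stop(mut_structure$structure_id, " has ", mut_structure$resid[idx_mut],
           " at position ", mutation$position, mutation$insert,
           ", not the stated mutant ", mutation$mut_res, call. = FALSE)
  }

  tr_wt <- unfold(wt_structure, potential, rc = rc, n_modes = n_modes,
                  break_fraction = break_fraction, convention = convention,
                  zero_tolerance = zero_tolerance)
  tr_mut <- unfold(mut_structure, potential, rc = rc, n_modes = n_modes,
                   break_fraction = break_fraction, convention = convention,
                   zero_tolerance = zero_tolerance)
  bw <- broken_contacts_at(tr_wt, idx_wt)
  bm <- broken_contacts_at(tr_mut, idx_mut)

  params <- list(rc = rc, n_modes = n_modes, break_fraction = break_fraction,
                 convention = convention, zero_tolerance = zero_tolerance,
                 scale = scale, entropy_from = entropy_from)
  terminations <- c(wt = tr_wt$termination, mut = tr_mut$termination)

  if (nrow(bw) == 0 || nrow(bm) == 0) {
    return(structure(list(raw_ddg = 0, scaled_ddg = 0, n_matched = 0L,
                          status = "defaulted_zero", direction = direction,
                          components = c(sum_mj_mut = 0, sum_mj_wt = 0,
                                         sum_msf_mut = 0, sum_msf_wt = 0),
                          mutation = mutation, matches = match_ranks(bw, bm),
                          terminations = terminations, params = params),
                     class = "ddg_result"))
  }

  m <- match_ranks(bw, bm)
  sum_mj_wt <- site_energy_sum(potential, mutation$wt_res, m$wt_partner_restype)
  sum_mj_mut <- site_energy_sum(potential, mutation$mut_res, m$mut_partner_restype)
  if (entropy_from == "native") {
    native_msf <- function(st, idx, partners) {
      modes <- decompose(build_kirchhoff(st, potential, rc = rc,
                                         convention = convention),
                         zero_tolerance = zero_tolerance)
      pinv <- pseudo_inverse(modes, min(n_modes, modes$n - modes$zero_mode_count))
      distance_msf(pinv, rep(idx, length(partners)), partners)
    }
    sum_msf_wt <- sum(native_msf(wt_structure, idx_wt, m$wt_partner_index))
    sum_msf_mut <- sum(native_msf(mut_structure, idx_mut, m$mut_partner_index))
  } else {
    sum_msf_wt <- sum(m$wt_msf)
    sum_msf_mut <- sum(m$mut_msf)
  }
  raw <- -((sum_mj_mut - sum_mj_wt) - (sum_msf_mut - sum_msf_wt))
  scaled <- if (direction == "reverse") scale[1] * raw - scale[2]
            else scale[1] * raw + scale[2]
  structure(list(raw_ddg = raw, scaled_ddg = scaled, n_matched = nrow(m),
                 status = "computed", direction = direction,
                 components = c(sum_mj_mut = sum_mj_mut, sum_mj_wt = sum_mj_wt,
                                sum_msf_mut = sum_msf_mut,
                                sum_msf_wt = sum_msf_wt),
                 mutation = mutation, matches = m,
                 terminations = terminations, params = params),
            class = "ddg_result")
}

#' Compute ddG for the reverse mutation by swapping structures
#'
#' The wildtype and mutant structures switch roles and the mutation is
#' inverted (Y at the position reverting to X). When the mutant model came
#' from [apply_mutation()] (identical coordinates), the reverse raw ddG is
#' the exact negation of the forward one; with an independently solved mutant
#' structure the two traces genuinely differ.
#'
#' @inheritParams compute_ddg
#' @param mut_structure Mutant `cg_structure`; by default built from
#'   `wt_structure` with [apply_mutation()].
#' @return A `ddg_result` with `direction = "reverse"`.
#' @export
compute_reverse_ddg <- function(wt_structure, mutation, potential,
                                mut_structure = NULL, rc = 9, n_modes = 10,
                                break_fraction = 0.5,
                                convention = c("boltzmann_negated", "literal_eq2"),
                                zero_tolerance = 1e-8, scale = c(1, 0),
                                entropy_from = c("at_break", "native")) {
  convention <- match.arg(convention)
  entropy_from <- match.arg(entropy_from)
  if (is.character(mutation))
    mutation <- parse_mutation(mutation, wt_structure$chain_id)
  if (is.null(mut_structure))
    mut_structure <- apply_mutation(wt_structure, mutation)
  compute_ddg(wt_structure = mut_structure, mutation = invert_mutation(mutation),
              potential = potential, rc = rc, n_modes = n_modes,
              break_fraction = break_fraction, convention = convention,
              zero_tolerance = zero_tolerance, scale = scale,
              mut_structure = wt_structure, entropy_from = entropy_from,
              direction = "reverse")
}

#' Fit the linear rescaling of raw ddG to experimental values
#'
#' Ordinary least squares of experimental ddG on raw predictions; the fitted
#' `(slope, intercept)` can be passed as `scale` to [compute_ddg()].
#'
#' @param raw_values Raw predictions.
#' @param experimental_values Experimental ddG, kcal/mol (same length, >= 3
#'   points, non-degenerate variance).
#' @return Named numeric `c(slope, intercept)`.
#' @export
fit_scaling <- function(raw_values, experimental_values) {
  if (length(raw_values) != length(experimental_values))
    stop("raw and experimental vectors must have equal length")
  if (length(raw_values) < 3)
    stop("need at least 3 points to fit a scaling line")
  if (stats::sd(raw_values) == 0)
    stop("raw predictions have zero variance; scaling line is undefined")
  fit <- stats::lm(experimental_values ~ raw_values)
  c(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

#' @export
print.ddg_result <- function(x, ...) {
  mut <- x$mutation
  cat(sprintf("ddG %s%d%s%s [%s]: raw = %.4f, scaled = %.4f (%s, N = %d)\n",
              mut$wt_res, mut$position, mut$insert, mut$mut_res, x$direction,
              x$raw_ddg, x$scaled_ddg, x$status, x$n_matched))
  invisible(x)
}
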