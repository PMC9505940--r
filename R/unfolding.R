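#' Enumerate breakable (non-bonded) contacts
#'
#' All residue pairs with sequence separation > 1 whose CA-CA distance is
#' within `rc`. Backbone-bonded pairs are never breakable and are excluded.
#'
#' @param structure A `cg_structure`.
#' @param rc Distance cutoff in Angstrom (default 9).
#' @return m x 2 integer matrix of pairs (i < j), ordered by (i, j).
#' @export
enumerate_contacts <- function(structure, rc = 9) {
  stopifnot(inherits(structure, "cg_structure"))
  d <- as.matrix(stats::dist(structure$xyz))
  nb <- abs(row(d) - col(d)) > 1 & d <= rc & upper.tri(d)
  up <- which(nb, arr.ind = TRUE)
  out <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Simulate partial unfolding by iterative contact breaking
#'
#' Per iteration: decompose the current Kirchhoff matrix; if the network has
#' fragmented (more than one zero mode) stop with `termination = "unstable"`;
#' otherwise reconstruct the truncated pseudo-inverse from the `n_modes`
#' slowest non-zero modes, evaluate the distance MSF over the currently
#' connected non-bonded contacts, and break the single contact with the
#' largest MSF (ties: smallest i, then smallest j). Iteration stops once
#' `break_fraction` of the initial contacts are broken.
#'
#' @param structure A `cg_structure`.
#' @param potential A `contact_potential`.
#' @param rc Cutoff distance, Angstrom (default 9).
#' @param n_modes Slow non-zero modes used for the pseudo-inverse (default 10;
#'   capped at N - 1).
#' @param break_fraction Fraction of initial contacts to break (default 0.5).
#' @param convention Spring convention, see [spring_constant()].
#' @param zero_tolerance Zero-mode tolerance, see [decompose()].
#' @param break_per_iter Contacts removed per iteration (default 1, the
#'   documented behaviour; larger values are experimental).
#' @return An `unfolding_trace`: list with `initial_contact_count`, `events`
#'   (data.frame: iteration, i, j, msf), `termination` (`"reached_fraction"`
#'   or `"unstable"`), `break_fraction`, `resid`, `structure_id`, `chain_id`
#'   and `params`.
#' @export
unfold <- function(structure, potential, rc = 9, n_modes = 10,
                   break_fraction = 0.5,
                   convention = c("boltzmann_negated", "literal_eq2"),
                   zero_tolerance = 1e-8, break_per_iter = 1L) {
  convention <- match.arg(convention)
  stopifnot(break_fraction > 0, break_fraction <= 1, break_per_iter >= 1)
  k <- build_kirchhoff(structure, potential, rc = rc, convention = convention)
  m0 <- nrow(k$contacts)
  target <- ceiling(break_fraction * m0)

  ev_iter <- integer(0); ev_i <- integer(0); ev_j <- integer(0); ev_msf <- numeric(0)
  termination <- "reached_fraction"
  iter <- 0L
  while (length(ev_i) < target && nrow(k$contacts) > 0) {
    modes <- decompose(k, zero_tolerance = zero_tolerance)
    if (modes$zero_mode_count > 1) {
      termination <- "unstable"
      psp_log("INFO", structure$structure_id, ": model unstable at iteration ",
              iter + 1L, " (", modes$zero_mode_count, " zero modes)")
      break
    }
    nm <- min(n_modes, modes$n - modes$zero_mode_count)
    pinv <- pseudo_inverse(modes, nm)
    cc <- k$contacts
    msf <- distance_msf(pinv, cc[, 1], cc[, 2])
    n_take <- min(break_per_iter, target - length(ev_i), nrow(cc))
    for (t in seq_len(n_take)) {
      mx <- max(msf)
      cand <- which(msf == mx)
      pick <- cand[order(cc[cand, 1], cc[cand, 2])][1]
      iter <- iter + 1L
      ev_iter <- c(ev_iter, iter)
      ev_i <- c(ev_i, cc[pick, 1]); ev_j <- c(ev_j, cc[pick, 2])
      ev_msf <- c(ev_msf, msf[pick])
      k <- remove_contact(k, cc[pick, 1], cc[pick, 2])
      keep <- seq_len(nrow(cc)) != pick
      cc <- cc[keep, , drop = FALSE]
      msf <- msf[keep]
    }
  }
  structure(list(initial_contact_count = m0,
                 events = data.frame(iteration = ev_iter, i = ev_i, j = ev_j,
                                     msf = ev_msf),
                 termination = termination, break_fraction = break_fraction,
                 resid = structure$resid,
                 structure_id = structure$structure_id,
                 chain_id = structure$chain_id,
                 params = list(rc = rc, n_modes = n_modes,
                               convention = convention,
                               zero_tolerance = zero_tolerance)),
            class = "unfolding_trace")
}

#' Contacts broken at a given residue during unfolding
#'
#' Filters the trace to events involving `position_index` and re-ranks them
#' 1..n in break order. These ranks are what forward/reverse ddG computation
#' matches between the wildtype and mutant traces.
#'
#' @param trace An `unfolding_trace`.
#' @param position_index Internal (1-based) residue index.
#' @return data.frame with columns `rank`, `partner_index`, `partner_restype`,
#'   `msf_at_break` (zero rows if the position was never involved).
#' @export
broken_contacts_at <- function(trace, position_index) {
  stopifnot(inherits(trace, "unfolding_trace"),
            position_index >= 1, position_index <= length(trace$resid))
  ev <- trace$events
  hit <- ev$i == position_index | ev$j == position_index
  ev <- ev[hit, , drop = FALSE]
  partner <- ifelse(ev$i == position_index, ev$j, ev$i)
  data.frame(rank = seq_len(nrow(ev)),
             partner_index = as.integer(partner),
             partner_restype = trace$resid[partner],
             msf_at_break = ev$msf,
             stringsAsFactors = FALSE)
}

#' Export an unfolding trace as TSV
#'
#' @param trace An `unfolding_trace`.
#' @param file Output path, or `NULL` to return the data.frame only.
#' @return The events data.frame, invisibly.
#' @export
write_trace <- function(trace, file = NULL) {
  ev <- trace$events
  out <- data.frame(iteration = ev$iteration, res_i = ev$i, res_j = ev$j,
                    msf = ev$msf)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @export
print.unfolding_trace <- function(x, ...) {
  cat("Unfolding trace for", x$structure_id, "chain", x$chain_id, "\n")
  cat(" ", nrow(x$events), "of", x$initial_contact_count,
      "contacts broken; termination:", x$termination, "\n")
  invisible(x)
}
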