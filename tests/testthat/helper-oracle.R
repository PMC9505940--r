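# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (double loops, modal sums, reduced-Laplacian
# solves) and share no code path with the package implementation.

# naive O(N^2) Kirchhoff construction by explicit double loop
oracle_kirchhoff <- function(structure, potential, rc = 9,
                             convention = "boltzmann_negated",
                             broken = NULL) {
  n <- length(structure$resid)
  g <- matrix(0, n, n)
  is_broken <- function(i, j) {
    if (is.null(broken) || nrow(broken) == 0) return(FALSE)
    any(broken[, 1] == min(i, j) & broken[, 2] == max(i, j))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (abs(i - j) == 1) {
      g[i, j] <- -exp(-(potential$min_energy - 1))
    } else {
      d <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2))
      if (d <= rc && !is_broken(i, j)) {
        e <- potential$energies[structure$resid[i], structure$resid[j]]
        g[i, j] <- if (convention == "boltzmann_negated") -exp(-e) else -exp(e)
      }
    }
  }
  for (i in seq_len(n)) g[i, i] <- -sum(g[i, -i])
  g
}

# distance MSF of pair (i, j) as an explicit modal sum over the n_modes
# smallest eigenvalues above tolerance
oracle_pair_msf <- function(g, i, j, n_modes, zero_tolerance = 1e-8) {
  e <- eigen(g, symmetric = TRUE)
  lam <- rev(e$values)
  V <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  nz <- which(lam >= zero_tolerance * max(max(lam), 1))
  use <- nz[seq_len(min(n_modes, length(nz)))]
  sum(vapply(use, function(k) (V[i, k] - V[j, k])^2 / lam[k], 0))
}

# step-by-step unfolding, rebuilding the Kirchhoff matrix from scratch at
# every iteration; returns events + termination like the package trace
oracle_unfold <- function(structure, potential, rc = 9, n_modes = 10,
                          break_fraction = 0.5, convention = "boltzmann_negated",
                          zero_tolerance = 1e-8) {
  n <- length(structure$resid)
  cc <- list()
  for (i in seq_len(n - 2)) for (j in seq((i + 2), n)) {
    d <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2))
    if (d <= rc) cc[[length(cc) + 1]] <- c(i, j)
  }
  contacts <- do.call(rbind, cc)
  if (is.null(contacts)) contacts <- matrix(integer(0), 0, 2)
  m0 <- nrow(contacts)
  target <- ceiling(break_fraction * m0)
  broken <- matrix(integer(0), 0, 2)
  events <- data.frame(iteration = integer(0), i = integer(0), j = integer(0),
                       msf = numeric(0))
  termination <- "reached_fraction"
  iter <- 0L
  while (nrow(events) < target) {
    g <- oracle_kirchhoff(structure, potential, rc, convention, broken)
    lam <- rev(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
    if (sum(lam < zero_tolerance * max(max(lam), 1)) > 1) {
      termination <- "unstable"
      break
    }
    remaining <- contacts[!apply(contacts, 1, function(p)
      any(broken[, 1] == p[1] & broken[, 2] == p[2])), , drop = FALSE]
    msf <- apply(remaining, 1, function(p)
      oracle_pair_msf(g, p[1], p[2], n_modes, zero_tolerance))
    best <- which(msf == max(msf))
    best <- best[order(remaining[best, 1], remaining[best, 2])][1]
    iter <- iter + 1L
    events <- rbind(events, data.frame(iteration = iter,
                                       i = remaining[best, 1],
                                       j = remaining[best, 2],
                                       msf = msf[best]))
    broken <- rbind(broken, remaining[best, , drop = FALSE])
  }
  list(initial_contact_count = m0, events = events, termination = termination)
}

# ddG assembled by hand from two oracle traces and direct table lookups
oracle_ddg <- function(wt, mut, spec, potential, rc = 9, n_modes = 10,
                       break_fraction = 0.5) {
  idx <- which(wt$resno == spec$position & wt$insert == spec$insert)
  tw <- oracle_unfold(wt, potential, rc, n_modes, break_fraction)
  tm <- oracle_unfold(mut, potential, rc, n_modes, break_fraction)
  at_pos <- function(tr, st) {
    ev <- tr$events[tr$events$i == idx | tr$events$j == idx, , drop = FALSE]
    partner <- ifelse(ev$i == idx, ev$j, ev$i)
    list(types = st$resid[partner], msf = ev$msf)
  }
  bw <- at_pos(tw, wt)
  bm <- at_pos(tm, mut)
  nn <- min(length(bw$types), length(bm$types))
  if (nn == 0) return(list(raw = 0, status = "defaulted_zero"))
  s_mj_wt <- 0; s_mj_mut <- 0
  for (k in seq_len(nn)) {
    s_mj_wt <- s_mj_wt + potential$energies[spec$wt_res, bw$types[k]]
    s_mj_mut <- s_mj_mut + potential$energies[spec$mut_res, bm$types[k]]
  }
  raw <- -((s_mj_mut - s_mj_wt) - (sum(bm$msf[seq_len(nn)]) - sum(bw$msf[seq_len(nn)])))
  list(raw = raw, status = "computed", trace_wt = tw, trace_mut = tm)
}

# textbook metric formulas
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}
oracle_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))
oracle_bias <- function(f, r) {
  s <- 0
  for (i in seq_along(f)) s <- s + f[i] + r[i]
  s / (2 * length(f))
}

# effective resistance by grounding node 1 and solving the reduced Laplacian
oracle_effective_resistance <- function(L, i, j) {
  n <- nrow(L)
  e <- rep(0, n); e[i] <- 1; e[j] <- -1
  v <- rep(0, n)
  v[-1] <- solve(L[-1, -1], e[-1])
  v[i] - v[j]
}
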