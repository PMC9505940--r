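#' Build the weighted Kirchhoff (connectivity) matrix
#'
#' Backbone neighbours (|i-j| = 1) are always connected with the stiff bonded
#' spring; non-bonded pairs are connected iff their CA-CA distance is within
#' `rc`. Off-diagonal entries are minus the spring constant of the pair
#' (see [spring_constant()]); diagonal entries make every row sum to zero.
#'
#' @param structure A `cg_structure` with at least 2 residues.
#' @param potential A `contact_potential`.
#' @param rc Distance cutoff in Angstrom (default 9).
#' @param convention Spring-sign convention, see [spring_constant()].
#' @return A `kirchhoff` object: list with `gamma` (N x N matrix), `n`, `rc`,
#'   `convention` and `contacts` (m x 2 matrix of currently connected
#'   non-bonded pairs, i < j).
#' @export
build_kirchhoff <- function(structure, potential, rc = 9,
                            convention = c("boltzmann_negated", "literal_eq2")) {
  stopifnot(inherits(structure, "cg_structure"))
  convention <- match.arg(convention)
  n <- length(structure$resid)
  if (n < 2) stop("need at least 2 residues")
  d <- as.matrix(stats::dist(structure$xyz))
  seqsep <- abs(row(d) - col(d))
  bonded <- seqsep == 1
  nb <- seqsep > 1 & d <= rc

  E <- potential$energies[structure$resid, structure$resid]
  K <- if (convention == "boltzmann_negated") exp(-E) else exp(E)
  g <- matrix(0, n, n)
  g[nb] <- -K[nb]
  g[bonded] <- -exp(-(potential$min_energy - 1))
  diag(g) <- -rowSums(g)

  up <- which(nb & upper.tri(nb), arr.ind = TRUE)
  contacts <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  dimnames(contacts) <- list(NULL, c("i", "j"))
  structure(list(gamma = g, n = n, rc = rc, convention = convention,
                 contacts = contacts),
            class = "kirchhoff")
}

#' Construct a Kirchhoff object directly from a spring-constant matrix
#'
#' Low-level constructor used for closed-form checks (e.g. uniform-spring
#' path graphs, where distance fluctuations reduce to graph effective
#' resistance). `k` is a symmetric non-negative matrix of spring constants
#' with zero diagonal; every positive entry is treated as a breakable contact.
#'
#' @param k Symmetric spring-constant matrix.
#' @return A `kirchhoff` object.
#' @export
kirchhoff_from_springs <- function(k) {
  stopifnot(is.matrix(k), nrow(k) == ncol(k), isSymmetric(k))
  n <- nrow(k)
  g <- -k
  diag(g) <- 0
  diag(g) <- -rowSums(g)
  up <- which(k > 0 & upper.tri(k), arr.ind = TRUE)
  contacts <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  dimnames(contacts) <- list(NULL, c("i", "j"))
  structure(list(gamma = g, n = n, rc = NA_real_, convention = "custom",
                 contacts = contacts),
            class = "kirchhoff")
}

# remove one non-bonded contact, keeping row sums exactly zero
remove_contact <- function(k, i, j) {
  g <- k$gamma
  g[i, i] <- g[i, i] + g[i, j]
  g[j, j] <- g[j, j] + g[j, i]
  g[i, j] <- 0
  g[j, i] <- 0
  k$gamma <- g
  keep <- !(k$contacts[, 1] == i & k$contacts[, 2] == j)
  k$contacts <- k$contacts[keep, , drop = FALSE]
  k
}

#' Eigen-decompose a Kirchhoff matrix
#'
#' @param kirchhoff A `kirchhoff` object or a symmetric matrix.
#' @param zero_tolerance Relative tolerance: eigenvalues below
#'   `zero_tolerance * max(lambda_max, 1)` count as zero modes. A connected
#'   network has exactly one zero mode; more than one signals a fragmented
#'   (unstable) model.
#' @return A `mode_set`: list with `values` (ascending), `vectors`
#'   (column-matched, orthonormal), `zero_mode_count` and `n`.
#' @export
decompose <- function(kirchhoff, zero_tolerance = 1e-8) {
  g <- if (inherits(kirchhoff, "kirchhoff")) kirchhoff$gamma else kirchhoff
  stopifnot(is.matrix(g), isSymmetric(unname(g)))
  e <- eigen(g, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  lam_max <- max(values)
  zmc <- sum(values < zero_tolerance * max(lam_max, 1))
  structure(list(values = values, vectors = vectors,
                 zero_mode_count = as.integer(zmc), n = length(values)),
            class = "mode_set")
}

#' Truncated pseudo-inverse of the Kirchhoff matrix
#'
#' Reconstructs `sum_k lambda_k^-1 V_k V_k'` over the `n_modes` smallest
#' non-zero eigenvalues (the slow modes). The physical prefactor 3K_B T/gamma
#' is fixed to 1: it cancels in every ranking and correlation the method uses.
#'
#' @param modes A `mode_set` from [decompose()].
#' @param n_modes Number of slow non-zero modes (1 to N - zero modes). Using
#'   all N-1 non-zero modes of a connected network reproduces the
#'   Moore-Penrose pseudo-inverse.
#' @return Symmetric N x N matrix.
#' @export
pseudo_inverse <- function(modes, n_modes) {
  stopifnot(inherits(modes, "mode_set"))
  if (modes$zero_mode_count > 1)
    stop("unstable model: ", modes$zero_mode_count,
         " zero modes (fragmented network)", call. = FALSE)
  nz <- modes$n - modes$zero_mode_count
  if (n_modes < 1 || n_modes > nz)
    stop("n_modes must be between 1 and ", nz)
  idx <- modes$zero_mode_count + seq_len(n_modes)
  V <- modes$vectors[, idx, drop = FALSE]
  p <- V %*% (t(V) / modes$values[idx])
  (p + t(p)) / 2
}

#' Mean-squared fluctuation in the distance between two residues
#'
#' The internal distance change `pinv[i,i] + pinv[j,j] - 2 pinv[i,j]`
#' (arbitrary units, prefactor 1). With uniform springs and all modes this is
#' the graph effective resistance between i and j. Vectorized over `i`, `j`.
#'
#' @param pinv Pseudo-inverse matrix from [pseudo_inverse()].
#' @param i,j Residue indices (i != j).
#' @return Non-negative value(s).
#' @export
distance_msf <- function(pinv, i, j) {
  if (any(i == j)) stop("i and j must differ")
  pinv[cbind(i, i)] + pinv[cbind(j, j)] - 2 * pinv[cbind(i, j)]
}

#' Per-residue mean-squared fluctuations
#'
#' @param pinv Pseudo-inverse matrix.
#' @return The diagonal of `pinv` (length N, non-negative).
#' @export
residue_msf <- function(pinv) diag(pinv)

#' Residue-residue cross-correlation map
#'
#' `C_ij = pinv_ij / sqrt(pinv_ii * pinv_jj)`, with unit diagonal; bounded in
#' [-1, 1] when all modes are used.
#'
#' @param pinv Pseudo-inverse matrix with strictly positive diagonal.
#' @return N x N correlation matrix.
#' @export
cross_correlation <- function(pinv) {
  d <- diag(pinv)
  if (any(d <= 0)) stop("pseudo-inverse diagonal must be strictly positive")
  C <- pinv / sqrt(outer(d, d))
  diag(C) <- 1
  C
}

#' Agreement between computed fluctuations and experimental B-factors
#'
#' @param structure A `cg_structure` carrying B-factors.
#' @param msf_vector Per-residue MSF from [residue_msf()].
#' @return Pearson correlation coefficient.
#' @export
bfactor_agreement <- function(structure, msf_vector) {
  if (is.null(structure$bfactors))
    stop("structure ", structure$structure_id, " carries no B-factors")
  if (length(structure$bfactors) != length(msf_vector))
    stop("MSF vector length does not match residue count")
  if (stats::sd(structure$bfactors) == 0 || stats::sd(msf_vector) == 0)
    stop("zero variance in B-factors or MSF")
  stats::cor(structure$bfactors, msf_vector)
}

#' @export
print.kirchhoff <- function(x, ...) {
  cat("Kirchhoff matrix:", x$n, "residues,", nrow(x$contacts),
      "non-bonded contacts (rc =", x$rc, "A,", x$convention, ")\n")
  invisible(x)
}
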