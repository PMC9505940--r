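test_that("a two-residue chain gives the bonded 2x2 Kirchhoff matrix", {
  p <- synthetic_potential(fill = -1, min_energy = -7)
  s <- cg(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  k <- build_kirchhoff(s, p)
  expect_equal(k$gamma, matrix(exp(8) * c(1, -1, -1, 1), 2, 2), tolerance = 0)
  expect_identical(nrow(k$contacts), 0L)
})

test_that("cutoff geometry decides which pairs connect", {
  s <- cg(cbind(3.8 * 0:4, 0, 0))           # straight chain, 3.8 A spacing
  k <- build_kirchhoff(s, MJ, rc = 9)
  for (i in 1:3) expect_lt(k$gamma[i, i + 2], 0)   # 7.6 A <= 9
  for (i in 1:2) expect_identical(k$gamma[i, i + 3], 0)  # 11.4 A > 9
})

test_that("the Kirchhoff matrix equals a naive double-loop construction", {
  s <- make_toy_chain(30, seed = 11, geometry = "random_compact")
  for (conv in c("boltzmann_negated", "literal_eq2")) {
    k <- build_kirchhoff(s, MJ, rc = 9, convention = conv)
    expect_equal(k$gamma, oracle_kirchhoff(s, MJ, 9, conv), tolerance = 1e-12)
    expect_true(isSymmetric(k$gamma))
    expect_lt(max(abs(rowSums(k$gamma))), 1e-10)
  }
})

test_that("zero modes count connected components", {
  s <- make_toy_chain(15, seed = 2)
  expect_identical(decompose(build_kirchhoff(s, MJ))$zero_mode_count, 1L)
  block <- matrix(0, 6, 6)
  block[1:3, 1:3] <- block[4:6, 4:6] <- 1
  diag(block) <- 0
  expect_identical(decompose(kirchhoff_from_springs(block))$zero_mode_count, 2L)
})

test_that("the eigensystem satisfies the eigen equation", {
  k <- build_kirchhoff(make_toy_chain(30, seed = 3), MJ)
  m <- decompose(k)
  for (i in seq_len(m$n))
    expect_lt(max(abs(k$gamma %*% m$vectors[, i] - m$values[i] * m$vectors[, i])),
              1e-8 * max(1, m$values[i]))
  expect_equal(crossprod(m$vectors), diag(m$n), tolerance = 1e-8)
})

test_that("the truncated pseudo-inverse has the spectral limits", {
  k <- build_kirchhoff(make_toy_chain(20, seed = 4), MJ)
  m <- decompose(k)
  full <- pseudo_inverse(m, m$n - 1)
  expect_equal(full, MASS::ginv(k$gamma), tolerance = 1e-8)
  r1 <- pseudo_inverse(m, 1)
  v <- m$vectors[, 2]
  expect_equal(r1, tcrossprod(v) / m$values[2], tolerance = 1e-10)
  # truncation equals an independent full-decomposition-and-sum construction
  e <- eigen(k$gamma, symmetric = TRUE)
  lam <- rev(e$values); V <- e$vectors[, rev(seq_len(m$n))]
  p10 <- matrix(0, m$n, m$n)
  for (kk in 2:11) p10 <- p10 + tcrossprod(V[, kk]) / lam[kk]
  expect_equal(pseudo_inverse(m, 10), p10, tolerance = 1e-8)
})

test_that("truncated pseudo-inverse converges monotonically to the full one", {
  k <- build_kirchhoff(make_toy_chain(20, seed = 5), MJ)
  m <- decompose(k)
  full <- pseudo_inverse(m, m$n - 1)
  err <- vapply(1:(m$n - 1), function(nm)
    norm(pseudo_inverse(m, nm) - full, "F"), 0)
  expect_true(all(diff(err) <= 1e-10))
})

test_that("uniform-spring path distance MSF is the effective resistance |i-j|", {
  n <- 8
  springs <- matrix(0, n, n)
  springs[abs(row(springs) - col(springs)) == 1] <- 1
  m <- decompose(kirchhoff_from_springs(springs))
  pinv <- pseudo_inverse(m, m$n - 1)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    expect_equal(distance_msf(pinv, i, j), abs(i - j), tolerance = 1e-8)
    expect_identical(distance_msf(pinv, i, j), distance_msf(pinv, j, i))
  }
  # termini fluctuate most; the MSF profile of a symmetric chain is palindromic
  msf <- residue_msf(pinv)
  expect_identical(which.max(msf) %in% c(1L, n), TRUE)
  expect_equal(msf, rev(msf), tolerance = 1e-10)
})

test_that("distance MSF equals effective resistance on random weighted graphs", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    springs <- matrix(0, n, n)
    springs[abs(row(springs) - col(springs)) == 1] <- runif(1, 0.5, 2)
    extra <- which(upper.tri(springs) & springs == 0, arr.ind = TRUE)
    pick <- extra[sample(nrow(extra), min(4, nrow(extra))), , drop = FALSE]
    w <- runif(nrow(pick), 0.5, 3)
    springs[pick] <- w; springs[pick[, c(2, 1)]] <- w
    K <- kirchhoff_from_springs(springs)
    m <- decompose(K)
    pinv <- pseudo_inverse(m, m$n - 1)
    for (q in 1:4) {
      ij <- sample(n, 2)
      expect_equal(distance_msf(pinv, ij[1], ij[2]),
                   oracle_effective_resistance(K$gamma, ij[1], ij[2]),
                   tolerance = 1e-8)
    }
  }
})

test_that("stiffening one spring never increases any distance MSF", {
  set.seed(7)
  n <- 7
  springs <- matrix(0, n, n)
  springs[abs(row(springs) - col(springs)) == 1] <- 1
  springs[2, 5] <- springs[5, 2] <- 1
  springs[3, 7] <- springs[7, 3] <- 1
  m1 <- decompose(kirchhoff_from_springs(springs))
  p1 <- pseudo_inverse(m1, n - 1)
  stiffer <- springs
  stiffer[2, 5] <- stiffer[5, 2] <- 4
  m2 <- decompose(kirchhoff_from_springs(stiffer))
  p2 <- pseudo_inverse(m2, n - 1)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_lte(distance_msf(p2, i, j), distance_msf(p1, i, j) + 1e-12)
})

test_that("distance MSF matches the explicit modal sum", {
  k <- build_kirchhoff(make_toy_chain(20, seed = 6), MJ)
  m <- decompose(k)
  pinv <- pseudo_inverse(m, 10)
  cc <- k$contacts
  for (r in seq_len(min(10, nrow(cc))))
    expect_equal(distance_msf(pinv, cc[r, 1], cc[r, 2]),
                 oracle_pair_msf(k$gamma, cc[r, 1], cc[r, 2], 10),
                 tolerance = 1e-10)
  # residue MSF is the i == j self-limit of the same modal sum
  e <- eigen(k$gamma, symmetric = TRUE)
  lam <- rev(e$values); V <- e$vectors[, rev(seq_len(m$n))]
  self <- vapply(seq_len(m$n), function(i)
    sum(V[i, 2:11]^2 / lam[2:11]), 0)
  expect_equal(residue_msf(pinv), self, tolerance = 1e-10)
})

test_that("cross-correlations are unit-diagonal, bounded and brute-force equal", {
  k <- build_kirchhoff(make_toy_chain(20, seed = 8), MJ)
  m <- decompose(k)
  pinv <- pseudo_inverse(m, m$n - 1)
  C <- cross_correlation(pinv)
  expect_equal(diag(C), rep(1, m$n), tolerance = 0)
  expect_true(all(C >= -1 - 1e-10 & C <= 1 + 1e-10))
  n <- m$n
  brute <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    brute[i, j] <- pinv[i, j] / sqrt(pinv[i, i] * pinv[j, j])
  diag(brute) <- 1
  expect_equal(C, brute, tolerance = 1e-12)
})

test_that("B-factor agreement is a Pearson correlation with guards", {
  s <- make_toy_chain(25, seed = 9)
  k <- build_kirchhoff(s, MJ)
  m <- decompose(k)
  msf <- residue_msf(pseudo_inverse(m, 10))
  s_self <- s; s_self$bfactors <- msf
  expect_equal(bfactor_agreement(s_self, msf), 1, tolerance = 1e-12)
  s_neg <- s; s_neg$bfactors <- -msf
  expect_equal(bfactor_agreement(s_neg, msf), -1, tolerance = 1e-12)
  set.seed(10)
  s_noisy <- s; s_noisy$bfactors <- 2 * msf + rnorm(25, sd = 0.1 * sd(msf))
  expect_equal(bfactor_agreement(s_noisy, msf),
               oracle_pearson(s_noisy$bfactors, msf), tolerance = 1e-12)
  s_none <- s; s_none$bfactors <- NULL
  expect_error(bfactor_agreement(s_none, msf), "no B-factors")
  expect_error(bfactor_agreement(s_self, msf[-1]), "length")
})

test_that("the unstable branch rejects pseudo-inversion", {
  tr <- decompose(dumbbell_structure() |>
                    build_kirchhoff(synthetic_potential(fill = 30),
                                    convention = "literal_eq2"))
  expect_gt(tr$zero_mode_count, 1L)
  expect_error(pseudo_inverse(tr, 5), "unstable")
})
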