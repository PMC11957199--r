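test_that("single-orbital closed shell gives E0 + 2 h11 + (11|11)", {
  H <- random_hamiltonian(1, 1, 1, seed = 2)
  d <- list(alpha = 1L, beta = 1L)
  expect_equal(slater_condon(H, d, d),
               H$E0 + 2 * H$h[1, 1] + H$eri[1, 1, 1, 1], tolerance = 1e-12)
  r <- casci(H)
  expect_equal(r$energy, H$E0 + 2 * H$h[1, 1] + H$eri[1, 1, 1, 1],
               tolerance = 1e-12)
})

test_that("Slater-Condon matrix equals the brute-force second-quantized matrix", {
  for (cfg in list(c(2, 1, 1, 21), c(3, 2, 1, 22), c(4, 2, 2, 23))) {
    H <- random_hamiltonian(cfg[1], cfg[2], cfg[3], seed = cfg[4])
    S <- full_cas_space(H$M, H$n_alpha, H$n_beta)
    A_fast <- sqdbinder:::ham_block(H, S)
    A_oracle <- bf_hamiltonian_matrix(H)
    expect_lt(max(abs(A_fast - A_oracle)), 1e-12)
    expect_lt(max(abs(A_fast - t(A_fast))), 1e-12) # hermiticity
  }
})

test_that("elements vanish beyond double excitations and across sectors", {
  H <- random_hamiltonian(4, 2, 2, seed = 5)
  # alpha strings 0011 vs 1100 and beta 0011 vs 0101: 3 excitations total
  d1 <- list(alpha = 3L, beta = 3L)
  d2 <- list(alpha = 12L, beta = 10L)
  expect_identical(slater_condon(H, d1, d2), 0)
  expect_error(slater_condon(H, d1, list(alpha = 7L, beta = 3L)),
               class = "sqdbinder_argument_error")
})

test_that("projected Hamiltonian action is consistent with the dense matrix", {
  H <- random_hamiltonian(4, 2, 2, seed = 31)
  S <- det_subspace(occ_strings(4, 2)[1:4], occ_strings(4, 2)[c(1, 3, 5)], 4)
  A <- sqdbinder:::ham_block(H, S)
  es <- eigen(A, symmetric = TRUE)
  v <- ci_vector(S, es$vectors[, S$dim])
  hv <- apply_hamiltonian(H, v, mode = "projected")
  expect_lt(max(abs(hv$coefficients - es$values[S$dim] * v$coefficients)), 1e-10)

  z <- apply_hamiltonian(H, ci_vector(S, numeric(S$dim)))
  expect_true(all(z$coefficients == 0))

  # full-mode result re-projected onto S equals the projected result
  hv_full <- apply_hamiltonian(H, v, mode = "full")
  idx <- sqdbinder:::match_subspace(S, hv_full$subspace)
  expect_lt(max(abs(hv_full$coefficients[idx] - hv$coefficients)), 1e-10)
})

test_that("Davidson reproduces dense ground states and respects variational order", {
  H <- random_hamiltonian(5, 3, 2, seed = 41)
  S <- full_cas_space(5, 3, 2) # d = 100, Davidson path
  r <- davidson_lowest(H, S)
  dense <- eigen(sqdbinder:::ham_block(H, S), symmetric = TRUE)$values
  expect_equal(r$energy, min(dense), tolerance = 1e-10)
  expect_lte(r$residual, 1e-8)

  # single determinant: energy equals its diagonal element
  d1 <- list(alpha = occ_strings(5, 3)[4], beta = occ_strings(5, 2)[2])
  S1 <- det_subspace(d1$alpha, d1$beta, 5)
  r1 <- davidson_lowest(H, S1)
  expect_equal(r1$energy, slater_condon(H, d1, d1), tolerance = 1e-12)

  # nested subspaces: variational monotonicity
  a <- occ_strings(5, 3); b <- occ_strings(5, 2)
  Ssmall <- det_subspace(a[1:4], b[1:4], 5)
  Sbig <- det_subspace(a[1:7], b[1:6], 5)
  e_small <- davidson_lowest(H, Ssmall, compute_variance = FALSE)$energy
  e_big <- davidson_lowest(H, Sbig, compute_variance = FALSE)$energy
  e_full <- r$energy
  expect_lte(e_big, e_small + 1e-10)
  expect_lte(e_full, e_big + 1e-10)
  expect_lte(e_full, r1$energy + 1e-10)
})

test_that("occupations match the brute-force density-matrix diagonal", {
  # RHF determinant: step-function occupations
  S <- full_cas_space(4, 2, 2)
  rhf <- rhf_masks(2, 2)
  v <- numeric(S$dim)
  v[det_index(S, rhf$alpha, rhf$beta)] <- 1
  expect_equal(occupations(ci_vector(S, v)),
               c(1, 1, 0, 0, 1, 1, 0, 0), tolerance = 1e-12)

  # equal superposition of two determinants averages their occupations
  v2 <- numeric(S$dim)
  v2[det_index(S, 3L, 3L)] <- 1 / sqrt(2)
  v2[det_index(S, 12L, 5L)] <- 1 / sqrt(2)
  expect_equal(occupations(ci_vector(S, v2)),
               c(.5, .5, .5, .5, 1, .5, .5, 0), tolerance = 1e-12)

  # random state: compare against <psi| a^dag_p a_p |psi> via the oracle
  set.seed(9)
  v3 <- rnorm(S$dim)
  v3 <- v3 / sqrt(sum(v3^2))
  psi <- ci_vector(S, v3)
  n <- occupations(psi)
  dets <- sqdbinder:::subspace_dets(S)
  for (p in 1:4) for (sp in 0:1) {
    bit <- bitwShiftL(1L, p - 1L)
    occ <- if (sp == 0) bitwAnd(dets$alpha, bit) else bitwAnd(dets$beta, bit)
    expect_equal(n[sp * 4 + p], sum(v3^2 * (occ != 0)), tolerance = 1e-12)
  }
  expect_equal(sum(n[1:4]), 2, tolerance = 1e-10)
  expect_equal(sum(n[5:8]), 2, tolerance = 1e-10)
  expect_error(occupations(ci_vector(S, v3 * 2)),
               class = "sqdbinder_argument_error")
})

test_that("variance vanishes at eigenstates and matches the brute-force sum", {
  H <- random_hamiltonian(4, 2, 2, seed = 51)
  ref <- casci(H)
  expect_lt(ref$variance, 1e-10)

  # single determinant: variance = sum over connected dets of |<x|H|det>|^2
  S <- full_cas_space(4, 2, 2)
  d1 <- list(alpha = 5L, beta = 6L)
  S1 <- det_subspace(d1$alpha, d1$beta, 4)
  psi1 <- ci_vector(S1, 1)
  A <- bf_hamiltonian_matrix(H)
  j <- det_index(S, d1$alpha, d1$beta)
  expect_equal(variance(H, psi1), sum(A[-j, j]^2), tolerance = 1e-10)

  # any other state has strictly positive variance
  set.seed(3)
  v <- rnorm(S$dim)
  psi <- ci_vector(S, v / sqrt(sum(v^2)))
  expect_gt(variance(H, psi), 1e-6)
})

test_that("casci matches dense diagonalization and reports capacity errors", {
  H <- random_hamiltonian(4, 2, 2, seed = 61)
  r <- casci(H)
  dense <- eigen(bf_hamiltonian_matrix(H), symmetric = TRUE)$values
  expect_equal(r$energy, min(dense), tolerance = 1e-10)
  expect_error(casci(H, max_dim = 10), class = "sqdbinder_capacity_error")
})
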