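test_that("occupation initialization averages correct-number configurations", {
  # all shots on the closed-shell reference
  rhf <- rhf_masks(2, 2)
  s <- sample_set(rhf$alpha, rhf$beta, 500L, 4L)
  expect_equal(init_occupations(s, 2, 2), c(1, 1, 0, 0, 1, 1, 0, 0))

  # two equal-count configurations: bitwise average
  s2 <- sample_set(c(3L, 5L), c(3L, 6L), c(10L, 10L), 4L)
  expect_equal(init_occupations(s2, 2, 2),
               c(1, .5, .5, 0, .5, 1, .5, 0))

  # nothing with the right particle number: informative failure
  s3 <- sample_set(7L, 3L, 5L, 4L)
  expect_error(init_occupations(s3, 2, 2),
               class = "sqdbinder_initialization_error")
})

test_that("initial occupations match the conditional expectation under noise", {
  # exhaustive enumeration oracle at M = 3: E[bit p | correct numbers]
  # for a corrupted single configuration
  M <- 3L
  eps <- 0.15
  a0 <- 3L; b0 <- 4L
  masks <- 0:(2^M - 1)
  popc <- vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:2), 1L)),
                 numeric(1))
  flip_prob <- function(from, to)
    eps^popc[bitwXor(from, to) + 1] * (1 - eps)^(M - popc[bitwXor(from, to) + 1])
  pa <- vapply(masks, flip_prob, numeric(1), from = a0)
  pb <- vapply(masks, flip_prob, numeric(1), from = b0)
  ka <- popc == 2 # correct alpha count
  kb <- popc == 1
  exp_bit <- function(p, keep, bit) {
    sum(p[keep] * (bitwAnd(bitwShiftR(masks[keep], bit - 1L), 1L))) /
      sum(p[keep])
  }
  expected <- c(vapply(1:3, exp_bit, numeric(1), p = pa, keep = ka),
                vapply(1:3, exp_bit, numeric(1), p = pb, keep = kb))

  shots <- 60000L
  noisy <- corrupt(sample_set(a0, b0, shots, M), noise_model(eps, seed = 13))
  n_est <- init_occupations(noisy, 2, 1)
  kept <- sample_shots(filter_correct_number(noisy, 2, 1))
  sigma <- sqrt(expected * (1 - expected) / kept)
  expect_true(all(abs(n_est - expected) < 3 * pmax(sigma, 1e-6)))
})

test_that("configuration recovery restores counts and respects the weights", {
  # correct configurations are untouched for any estimate
  set.seed(1)
  out <- recover_configuration(5L, 3L, runif(8), 2, 2, 4)
  expect_equal(out, list(alpha = 5L, beta = 3L))

  # degenerate weights force a unique completion
  set.seed(1)
  out2 <- recover_configuration(0L, 3L, c(1, 0, 1, 1), 1, 2, 2)
  expect_equal(out2$alpha, 1L)

  # deficit-one completion frequencies follow the occupation weights
  M <- 3L
  w <- c(0.6, 0.3, 0.1)
  trials <- 40000L
  set.seed(99)
  picks <- vapply(seq_len(trials), function(i)
    recover_configuration(0L, 7L, c(w, 1, 1, 1), 1, 3, M)$alpha, integer(1))
  freq <- as.vector(table(factor(picks, levels = c(1L, 2L, 4L)))) / trials
  sigma <- sqrt(w * (1 - w) / trials)
  expect_true(all(abs(freq - w) < 3 * sigma))

  # surplus removal: all outputs have the target counts
  set.seed(7)
  outs <- replicate(200, recover_configuration(7L, 1L, runif(6), 2, 1, 3),
                    simplify = FALSE)
  expect_true(all(vapply(outs, function(o)
    popcounts(o$alpha) == 2 && popcounts(o$beta) == 1, logical(1))))
})

test_that("recovery is the identity on noiseless sample sets", {
  H <- random_hamiltonian(4, 2, 2, seed = 23)
  psi <- casci(H, compute_variance = FALSE)$state
  s <- sample_state(psi, 3000, seed = 4)
  n <- init_occupations(s, 2, 2)
  rec <- sqdbinder:::recover_all(s, n, 2, 2)
  expect_equal(rec$alpha, s$alpha)
  expect_equal(rec$count, s$count)
})

test_that("batches are seeded draws from the pool with the configured shape", {
  pool <- sample_set(c(3L, 5L), c(3L, 5L), c(70L, 30L), 4L)
  cfg <- recovery_config(K = 4, batch_size = 500, seed = 31)
  b1 <- make_batches(pool, cfg)
  b2 <- make_batches(pool, cfg)
  expect_length(b1, 4)
  expect_identical(b1, b2)
  expect_true(all(vapply(b1, sample_shots, numeric(1)) == 500))

  # a single-configuration pool reproduces itself
  pool1 <- sample_set(3L, 3L, 100L, 4L)
  b <- make_batches(pool1, recovery_config(K = 1, batch_size = 100, seed = 1))
  expect_equal(b[[1]]$alpha, 3L)
  expect_equal(b[[1]]$count, 100L)
})

test_that("recovery_config defaults mirror the production run settings", {
  cfg <- recovery_config()
  expect_equal(cfg$K, 10L)
  expect_equal(cfg$batch_size, 10000L)
  expect_equal(cfg$iterations, 10L)
  expect_error(recovery_config(K = 0), class = "sqdbinder_argument_error")
})

test_that("batch subspaces are Cartesian products of the sampled strings", {
  b <- sample_set(c(3L, 12L), c(5L, 6L), c(1L, 1L), 4L)
  S <- build_subspace(b)
  expect_equal(S$dim, 4L)
  expect_equal(S$alpha, c(3L, 12L))
  expect_equal(S$beta, c(5L, 6L))

  b1 <- sample_set(3L, 5L, 10L, 4L)
  expect_equal(build_subspace(b1)$dim, 1L)

  bad <- sample_set(c(3L, 7L), c(5L, 5L), c(1L, 1L), 4L)
  expect_error(build_subspace(bad), class = "sqdbinder_contract_violation")
})

test_that("the recovery loop matches the exact reference when coverage is complete", {
  H <- random_hamiltonian(4, 2, 2, seed = 29)
  ref <- casci(H, compute_variance = FALSE)
  raw <- sample_state(ref$state, 20000, seed = 6) # epsilon = 0
  cfg <- recovery_config(K = 3, batch_size = 20000, iterations = 1, seed = 7)
  hist <- recovery_loop(H, raw, cfg, compute_variance = FALSE)
  expect_equal(hist$iterations[[1]]$energy_min, ref$energy, tolerance = 1e-8)
  expect_length(hist$iterations[[1]]$energies, 3)
  expect_equal(hist$energy, min(hist$iterations[[1]]$energies))
})

test_that("every iteration stays variational and recovered pools are pure", {
  H <- random_hamiltonian(4, 2, 2, seed = 37)
  ref <- casci(H, compute_variance = FALSE)
  psi <- apply_lucj(lucj_from_ccsd(random_t2(2, 2, seed = 8, scale = 0.3)),
                    4, 2, 2)
  raw <- corrupt(sample_state(psi, 8000, seed = 9),
                 noise_model(0.05, seed = 10))
  cfg <- recovery_config(K = 3, batch_size = 2000, iterations = 5,
                         energy_tol = 0, seed = 11)
  hist <- recovery_loop(H, raw, cfg, compute_variance = FALSE)
  for (it in hist$iterations)
    expect_gte(it$energy_min, ref$energy - 1e-10)
  # occupation estimates stay in [0, 1] and sum to the electron counts
  n <- hist$occupations
  expect_true(all(n >= -1e-12 & n <= 1 + 1e-12))
  expect_equal(sum(n[1:4]), 2, tolerance = 1e-8)
  expect_equal(sum(n[5:8]), 2, tolerance = 1e-8)
})

test_that("larger batches do not worsen the converged energy", {
  H <- random_hamiltonian(4, 2, 2, seed = 43)
  psi <- apply_lucj(lucj_from_ccsd(random_t2(2, 2, seed = 12, scale = 0.3)),
                    4, 2, 2)
  med_err <- vapply(c(400, 4000), function(bs) {
    errs <- vapply(1:5, function(sd) {
      raw <- corrupt(sample_state(psi, 8000, seed = 100 + sd),
                     noise_model(0.03, seed = 200 + sd))
      cfg <- recovery_config(K = 2, batch_size = bs, iterations = 3,
                             energy_tol = 0, seed = 300 + sd)
      recovery_loop(H, raw, cfg, compute_variance = FALSE)$energy
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_lte(med_err[2], med_err[1] + 1e-8)
})
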