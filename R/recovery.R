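## Self-consistent configuration recovery: repair particle-number-broken
## samples with occupation-number estimates, diagonalize batch subspaces,
## and iterate the occupations to convergence.

#' Recovery-loop configuration
#'
#' @param K number of batches drawn per iteration.
#' @param batch_size shots per batch.
#' @param iterations maximum recovery iterations.
#' @param energy_tol early-stop threshold on the change of the minimum
#'   batch energy (Hartree).
#' @param seed integer seed governing every stochastic step of the loop.
#' @return an object of class `"recovery_config"`.
#' @export
recovery_config <- function(K = 10, batch_size = 10000, iterations = 10,
                            energy_tol = 1e-6, seed = NULL) {
  if (K < 1 || batch_size < 1 || iterations < 1)
    sqd_error("K, batch_size and iterations must all be >= 1", "argument_error")
  structure(list(K = as.integer(K), batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 energy_tol = energy_tol, seed = seed),
            class = "recovery_config")
}

#' Initialize occupation estimates from correct-number samples
#'
#' The count-weighted mean of each spin-orbital occupation bit over the
#' configurations that already have the correct particle numbers: the
#' starting estimate \eqn{n_{p\sigma}} of the recovery loop.
#'
#' @param samples a `"sample_set"` (typically noisy).
#' @param n_alpha,n_beta target electron counts.
#' @return numeric vector of length `2M` in `[0, 1]` (alpha block then
#'   beta block).
#' @export
init_occupations <- function(samples, n_alpha, n_beta) {
  ok <- filter_correct_number(samples, n_alpha, n_beta)
  if (sample_shots(ok) == 0)
    sqd_error(paste0(
      "no sampled configuration has the correct particle number; ",
      "increase the shot count or lower the noise level"),
      "initialization_error")
  M <- attr(ok, "M")
  w <- ok$count / sum(ok$count)
  n_a <- as.vector(crossprod(mask_bits(ok$alpha, M), w))
  n_b <- as.vector(crossprod(mask_bits(ok$beta, M), w))
  pmin(pmax(c(n_a, n_b), 0), 1)
}

## repair one spin-sector mask to exactly N electrons using the occupation
## estimate for that sector; draws from the current RNG stream
recover_sector <- function(mask, n_sector, N, M) {
  cnt <- popcounts(mask)
  if (cnt == N) return(mask)
  if (cnt < N) {
    cand <- which(bitwAnd(bitwShiftR(mask, seq_len(M) - 1L), 1L) == 0L)
    w <- n_sector[cand]
    need <- N - cnt
    if (sum(w) <= 0) w <- rep(1, length(cand)) # degenerate: uniform fallback
    pick <- if (length(cand) == 1) cand else sample(cand, need, prob = w)
    bitwOr(mask, bits_to_mask(replace(rep(0, M), pick, 1)))
  } else {
    occ <- which(bitwAnd(bitwShiftR(mask, seq_len(M) - 1L), 1L) == 1L)
    w <- 1 - n_sector[occ]
    drop <- cnt - N
    if (sum(w) <= 0) w <- rep(1, length(occ))
    pick <- if (length(occ) == 1) occ else sample(occ, drop, prob = w)
    bitwAnd(mask, bitwNot(bits_to_mask(replace(rep(0, M), pick, 1))))
  }
}

#' Recover a single configuration to the correct particle numbers
#'
#' Treats the two spin sectors independently: a sector with the correct
#' electron count is returned unchanged; otherwise electrons are added on
#' empty orbitals with probability proportional to the occupation estimate
#' \eqn{n_{p\sigma}} (or removed from occupied orbitals with probability
#' proportional to \eqn{1 - n_{p\sigma}}), one at a time without
#' replacement, until the count is correct.  If every candidate
#' probability vanishes the choice falls back to uniform.  Draws use the
#' current RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param alpha,beta integer occupation masks of the configuration.
#' @param n occupation estimate of length `2M` (alpha block then beta).
#' @param n_alpha,n_beta target electron counts.
#' @param M orbital count.
#' @return `list(alpha =, beta =)` with exactly the target counts.
#' @export
recover_configuration <- function(alpha, beta, n, n_alpha, n_beta, M) {
  list(alpha = recover_sector(alpha, n[seq_len(M)], n_alpha, M),
       beta = recover_sector(beta, n[M + seq_len(M)], n_beta, M))
}

## recover every shot of a sample set (current RNG stream)
recover_all <- function(samples, n, n_alpha, n_beta) {
  M <- attr(samples, "M")
  ok <- popcounts(samples$alpha) == n_alpha & popcounts(samples$beta) == n_beta
  good <- samples[ok, , drop = FALSE]
  bad <- samples[!ok, , drop = FALSE]
  if (nrow(bad) == 0)
    return(sample_set(good$alpha, good$beta, good$count, M))
  sh <- expand_shots(sample_set(bad$alpha, bad$beta, bad$count, M))
  na <- length(sh$alpha)
  ra <- integer(na); rb <- integer(na)
  for (i in seq_len(na)) {
    rec <- recover_configuration(sh$alpha[i], sh$beta[i], n, n_alpha, n_beta, M)
    ra[i] <- rec$alpha; rb[i] <- rec$beta
  }
  sample_set(c(good$alpha, ra), c(good$beta, rb),
             c(good$count, rep(1L, na)), M)
}

## draw K batches of batch_size shots with replacement from the pool's
## count distribution (current RNG stream)
draw_batches <- function(pool, K, batch_size) {
  M <- attr(pool, "M")
  lapply(seq_len(K), function(b) {
    idx <- sample.int(nrow(pool), batch_size, replace = TRUE, prob = pool$count)
    tab <- tabulate(idx, nbins = nrow(pool))
    sample_set(pool$alpha, pool$beta, tab, M)
  })
}

#' Draw batch subsamples from a recovered pool
#'
#' `config$K` independent draws of `config$batch_size` shots, uniformly
#' with replacement from the pool's count distribution (batches may
#' overlap).  Seeded by `config$seed`.
#'
#' @param samples a `"sample_set"` (the recovered pool).
#' @param config a `"recovery_config"`.
#' @return list of `K` `"sample_set"` batches.
#' @export
make_batches <- function(samples, config) {
  stopifnot(inherits(samples, "sample_set"), inherits(config, "recovery_config"))
  if (nrow(samples) == 0)
    sqd_error("cannot draw batches from an empty pool", "argument_error")
  with_seed(config$seed, draw_batches(samples, config$K, config$batch_size))
}

#' Determinant subspace spanned by a batch
#'
#' The subspace is the Cartesian product of the unique alpha half-strings
#' and unique beta half-strings occurring in the batch,
#' \eqn{S(b) = A \times B} with dimension \eqn{d = |A||B|}; this product
#' closure is what lets a batch of \eqn{10^4} samples span a subspace of
#' \eqn{\sim 2.5\cdot 10^5} determinants in a (16e,12o) space.
#'
#' @param batch a `"sample_set"` whose configurations all have the correct
#'   particle numbers.
#' @return a `"det_subspace"`.
#' @export
build_subspace <- function(batch) {
  stopifnot(inherits(batch, "sample_set"))
  M <- attr(batch, "M")
  pa <- unique(popcounts(batch$alpha))
  pb <- unique(popcounts(batch$beta))
  if (length(pa) != 1 || length(pb) != 1)
    sqd_error("batch contains configurations with inconsistent particle numbers",
              "contract_violation")
  det_subspace(batch$alpha, batch$beta, M)
}

#' Self-consistent configuration recovery loop
#'
#' Each iteration recovers every raw shot with the current occupation
#' estimate, draws `K` batches, diagonalizes each batch subspace
#' Hamiltonian, records the minimum batch energy \eqn{\min_b E(b)}, and
#' updates the occupation estimate as the uniform average of the batch
#' ground states' occupation numbers.  Iterations stop after
#' `config$iterations` steps or when the minimum energy changes by less
#' than `config$energy_tol`.
#'
#' @param H an `"as_hamiltonian"`.
#' @param raw a `"sample_set"` of raw (noisy) measurement shots.
#' @param config a `"recovery_config"`.
#' @param tol Davidson residual tolerance.
#' @param compute_variance record per-batch Hamiltonian variances.
#' @return an object of class `"recovery_history"`: per-iteration records
#'   (`energy_min`, per-batch `energies`, `dims`, `variances`,
#'   `occupations`), the final energy and occupation estimate, and the
#'   iteration at which the energy stopped changing.
#' @export
recovery_loop <- function(H, raw, config, tol = 1e-8,
                          compute_variance = TRUE) {
  stopifnot(inherits(H, "as_hamiltonian"), inherits(raw, "sample_set"),
            inherits(config, "recovery_config"))
  n <- init_occupations(raw, H$n_alpha, H$n_beta)
  iters <- list()
  e_prev <- NA_real_
  best <- NULL
  final_result <- NULL
  with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      pool <- recover_all(raw, n, H$n_alpha, H$n_beta)
      batches <- draw_batches(pool, config$K, config$batch_size)
      results <- lapply(seq_along(batches), function(b) {
        S <- build_subspace(batches[[b]])
        tryCatch(
          davidson_lowest(H, S, tol = tol, compute_variance = compute_variance),
          sqdbinder_error = function(e) {
            sqd_error(paste0("batch ", b, ": ", conditionMessage(e)),
                      "batch_error")
          })
      })
      energies <- vapply(results, `[[`, numeric(1), "energy")
      bmin <- which.min(energies)
      occ_mat <- vapply(results, `[[`, numeric(2L * H$M), "occupations")
      n <- rowMeans(occ_mat) # uniform average across batches
      iters[[it]] <- list(
        iteration = it,
        energy_min = energies[bmin],
        energies = energies,
        dims = vapply(results, function(r) r$state$subspace$dim, numeric(1)),
        variances = vapply(results, `[[`, numeric(1), "variance"),
        occupations = n)
      final_result <- results[[bmin]]
      if (is.null(best) || energies[bmin] < best$energy)
        best <- list(energy = energies[bmin], result = results[[bmin]],
                     iteration = it)
      if (!is.na(e_prev) && abs(energies[bmin] - e_prev) < config$energy_tol) {
        e_prev <- energies[bmin]
        break
      }
      e_prev <- energies[bmin]
    }
  })
  structure(list(iterations = iters,
                 energy = iters[[length(iters)]]$energy_min,
                 final = final_result,
                 best = best,
                 occupations = n,
                 n_iterations = length(iters),
                 config = config),
            class = "recovery_history")
}

#' @export
print.recovery_history <- function(x, ...) {
  cat(sprintf(
    "Configuration recovery: %d iteration(s), final min-batch energy %.10f Ha\n",
    x$n_iterations, x$energy))
  e <- vapply(x$iterations, `[[`, numeric(1), "energy_min")
  cat("  E_min per iteration:", paste(sprintf("%.8f", e), collapse = ", "), "\n")
  invisible(x)
}
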