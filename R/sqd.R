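## End-to-end sample-based quantum diagonalization: the model-fitting
## surface of the package.

#' Sample-based quantum diagonalization of an active-space Hamiltonian
#'
#' Runs the full SQD pipeline: evaluate the LUCJ ansatz state, draw
#' measurement shots from it, corrupt them with the bit-flip noise model,
#' and run self-consistent configuration recovery with batch-subspace
#' diagonalization.  The fitted ground-state energy is the converged
#' minimum batch energy \eqn{\min_b E(b)}.
#'
#' All randomness (sampling, noise, recovery) is governed by the seeds in
#' `sampler_seed`, `noise$seed` and `config$seed`, so a run is exactly
#' reproducible.
#'
#' @param H an `"as_hamiltonian"`.
#' @param ansatz an `"lucj_parameters"` object (see [lucj_from_ccsd()]), or
#'   a precomputed `"ci_vector"` to sample from directly.
#' @param shots number of measurement shots.
#' @param noise a `"noise_model"`; use `noise_model(0)` for an ideal
#'   device.
#' @param config a `"recovery_config"`.
#' @param sampler_seed seed for the measurement draws.
#' @param tol Davidson residual tolerance.
#' @param compute_variance record per-batch Hamiltonian variances.
#' @return an object of class `"sqd"` with components `energy` (Hartree),
#'   `history` (`"recovery_history"`), `occupations`, `variance` (variance
#'   of the best batch state), `state` (best batch ground state), counts of
#'   raw/correct-number shots, and the call.
#' @seealso [casci()] for the exact reference, [extrapolate_energy()] for
#'   zero-variance extrapolation, [binding_energy()] for the supramolecular
#'   difference.
#' @examples
#' H <- random_hamiltonian(4, 2, 2, seed = 7, scale = 0.5)
#' psi <- apply_lucj(lucj_from_ccsd(random_t2(2, 2, seed = 1, scale = 0.1)),
#'                   4, 2, 2)
#' fit <- sqd(H, psi, shots = 2000, noise = noise_model(0.02, seed = 2),
#'            config = recovery_config(K = 3, batch_size = 1000,
#'                                     iterations = 4, seed = 3),
#'            sampler_seed = 4)
#' print(fit)
#' coef(fit)
#' @export
sqd <- function(H, ansatz, shots, noise = noise_model(0.01),
                config = recovery_config(), sampler_seed = NULL,
                tol = 1e-8, compute_variance = TRUE) {
  stopifnot(inherits(H, "as_hamiltonian"))
  psi <- if (inherits(ansatz, "ci_vector")) {
    ansatz
  } else if (inherits(ansatz, "lucj_parameters")) {
    apply_lucj(ansatz, H$M, H$n_alpha, H$n_beta)
  } else {
    sqd_error("ansatz must be lucj_parameters or a ci_vector", "argument_error")
  }
  raw <- sample_state(psi, shots, seed = sampler_seed)
  noisy <- corrupt(raw, noise)
  n_correct <- sample_shots(filter_correct_number(noisy, H$n_alpha, H$n_beta))
  history <- recovery_loop(H, noisy, config, tol = tol,
                           compute_variance = compute_variance)
  final <- history$final
  structure(list(energy = history$energy,
                 variance = final$variance,
                 state = final$state,
                 occupations = history$occupations,
                 history = history,
                 shots = shots,
                 shots_correct_number = n_correct,
                 noise = noise, config = config, H = H,
                 call = match.call()),
            class = "sqd")
}

#' @rdname sqd
#' @export
run_sqd <- sqd

#' @export
print.sqd <- function(x, ...) {
  cat("Sample-based quantum diagonalization\n")
  cat(sprintf("  (%de,%do) active space, %d shots (%.1f%% with correct particle number)\n",
              x$H$n_alpha + x$H$n_beta, x$H$M, x$shots,
              100 * x$shots_correct_number / max(1, x$shots)))
  cat(sprintf("  E_min = %.10f Ha after %d recovery iteration(s)\n",
              x$energy, x$history$n_iterations))
  invisible(x)
}

#' @export
coef.sqd <- function(object, ...) {
  c(energy = object$energy)
}

#' @export
summary.sqd <- function(object, ...) {
  it <- object$history$iterations
  tab <- data.frame(
    iteration = vapply(it, `[[`, numeric(1), "iteration"),
    energy_min = vapply(it, `[[`, numeric(1), "energy_min"),
    d_max = vapply(it, function(z) max(z$dims), numeric(1)),
    variance_min = vapply(it, function(z) {
      v <- z$variances[which.min(z$energies)]
      if (is.na(v)) NA_real_ else v
    }, numeric(1)))
  structure(list(fit = object, iterations = tab), class = "summary.sqd")
}

#' @export
print.summary.sqd <- function(x, ...) {
  print(x$fit)
  cat("\nPer-iteration record:\n")
  print(x$iterations, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sqd <- function(x, ...) {
  it <- x$history$iterations
  e <- vapply(it, `[[`, numeric(1), "energy_min")
  plot(seq_along(e), e, type = "b", pch = 19,
       xlab = "recovery iteration", ylab = "min-batch energy (Hartree)",
       main = "SQD configuration-recovery convergence", ...)
  invisible(x)
}

#' Random closed-shell doubles amplitudes
#'
#' Seeded Gaussian doubles amplitudes with the closed-shell pair symmetry
#' \eqn{t_{ij}^{ab} = t_{ji}^{ba}}; used to drive synthetic LUCJ states in
#' tests and demonstrations when no coupled-cluster engine is involved.
#'
#' @param nocc,nvirt occupied and virtual orbital counts.
#' @param seed integer seed.
#' @param scale standard deviation of the entries.
#' @return array of dimensions `(nocc, nocc, nvirt, nvirt)`.
#' @export
random_t2 <- function(nocc, nvirt, seed, scale = 0.1) {
  with_seed(seed, {
    t2 <- array(rnorm(nocc^2 * nvirt^2, sd = scale),
                c(nocc, nocc, nvirt, nvirt))
    (t2 + aperm(t2, c(2, 1, 4, 3))) / 2
  })
}
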