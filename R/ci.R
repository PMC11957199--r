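## Determinant-basis CI engine: Slater-Condon matrix elements, subspace
## Hamiltonian action, Davidson ground states, occupation numbers and
## Hamiltonian variance.

#' Slater-Condon matrix element between two determinants
#'
#' Computes \eqn{\langle d_1|\hat H|d_2\rangle}, including the scalar
#' offset `E0` on the diagonal.  Antisymmetry phases follow the package
#' convention: spin-orbitals ordered alpha block (ascending orbital) then
#' beta block, creation operators applied in descending position order.
#'
#' @param H an `"as_hamiltonian"`.
#' @param d1,d2 determinants as `list(alpha =, beta =)` integer masks with
#'   equal per-sector particle numbers.
#' @return matrix element in Hartree.
#' @export
slater_condon <- function(H, d1, d2) {
  stopifnot(inherits(H, "as_hamiltonian"))
  if (popcounts(d1$alpha) != popcounts(d2$alpha) ||
      popcounts(d1$beta) != popcounts(d2$beta))
    sqd_error("determinants must be in the same particle-number sector",
              "argument_error")
  cpp_sc_element(d1$alpha, d1$beta, d2$alpha, d2$beta, H$h,
                 as.numeric(H$eri), H$E0)
}

## dense Hamiltonian block between two subspaces (bra rows, ket columns)
ham_block <- function(H, S_bra, S_ket = S_bra,
                      max_entries = getOption("sqdbinder.max_dense", 4e7)) {
  db <- subspace_dets(S_bra)
  dk <- subspace_dets(S_ket)
  if (as.double(S_bra$dim) * S_ket$dim > max_entries)
    sqd_error(sprintf(
      "dense Hamiltonian block of %d x %d determinants exceeds the memory budget",
      S_bra$dim, S_ket$dim), "capacity_error")
  cpp_sc_matrix(db$alpha, db$beta, dk$alpha, dk$beta, H$h,
                as.numeric(H$eri), H$E0)
}

## all determinants of the full sector; used as the support of the
## unprojected Hamiltonian action (entries beyond double excitations of S
## are exactly zero by the Slater-Condon rules)
full_sector_space <- function(H, max_dim = getOption("sqdbinder.max_cas", 2e4)) {
  d <- cas_dimension(H$M, H$n_alpha, H$n_beta)
  if (d > max_dim)
    sqd_error(sprintf(
      "full determinant sector has dimension %.0f, over the budget of %.0f",
      d, max_dim), "capacity_error")
  full_cas_space(H$M, H$n_alpha, H$n_beta)
}

#' Apply the Hamiltonian to a CI vector
#'
#' In `"projected"` mode returns \eqn{\hat P_S \hat H \hat P_S v} with
#' support on the vector's own subspace `S`; in `"full"` mode returns
#' \eqn{\hat H v} supported on the complete particle-number sector (the
#' entries outside single/double excitations of `S` vanish identically).
#' The full mode is what the Hamiltonian-variance computation needs.
#'
#' @param H an `"as_hamiltonian"`.
#' @param v a `"ci_vector"` (need not be normalized; the action is linear).
#' @param mode `"projected"` or `"full"`.
#' @return a `"ci_vector"` on `v$subspace` (projected) or on the full
#'   sector (full).
#' @export
apply_hamiltonian <- function(H, v, mode = c("projected", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "ci_vector"))
  if (mode == "projected") {
    A <- ham_block(H, v$subspace)
    ci_vector(v$subspace, as.vector(A %*% v$coefficients))
  } else {
    Sfull <- full_sector_space(H)
    A <- ham_block(H, Sfull, v$subspace)
    ci_vector(Sfull, as.vector(A %*% v$coefficients))
  }
}

#' Orbital occupation numbers of a CI state
#'
#' \eqn{n_{p\sigma} = \sum_x |c_x|^2 x_{p\sigma}}: the diagonal of the
#' one-particle density matrix in the computational orbitals.  Entries lie
#' in `[0, 1]` and the per-spin sums equal the sector electron counts.
#'
#' @param psi a normalized `"ci_vector"`.
#' @return numeric vector of length `2M` (alpha block then beta block).
#' @export
occupations <- function(psi) {
  check_normalized(psi)
  S <- psi$subspace
  P <- Mod(ci_matrix(psi))^2
  wa <- rowSums(P) # weight per alpha string
  wb <- colSums(P)
  n_alpha <- as.vector(crossprod(mask_bits(S$alpha, S$M), wa))
  n_beta <- as.vector(crossprod(mask_bits(S$beta, S$M), wb))
  pmin(pmax(c(n_alpha, n_beta), 0), 1)
}

#' Hamiltonian variance of a CI state
#'
#' \eqn{\Delta H = \langle\psi|\hat H^2|\psi\rangle -
#' \langle\psi|\hat H|\psi\rangle^2}, evaluated with the full (unprojected)
#' Hamiltonian action over the complete particle-number sector, so it is
#' exactly zero at a full-CAS eigenstate and strictly positive otherwise.
#' Values within `-1e-10` of zero are clipped to zero.
#'
#' @param H an `"as_hamiltonian"`.
#' @param psi a normalized `"ci_vector"`.
#' @return variance in Hartree squared.
#' @export
variance <- function(H, psi) {
  check_normalized(psi)
  hv <- apply_hamiltonian(H, psi, mode = "full")
  h2 <- sum(Mod(hv$coefficients)^2)
  # <psi|H|psi> from the entries of Hv on the support of psi
  Sfull <- hv$subspace
  idx <- match_subspace(psi$subspace, Sfull)
  e <- Re(sum(Conj(psi$coefficients) * hv$coefficients[idx]))
  out <- h2 - e^2
  if (out < -1e-10)
    sqd_error(sprintf("variance came out %.3e < 0; numerical failure", out),
              "numeric_error")
  max(out, 0)
}

## linear indices of the determinants of S inside the (super)space Sbig
match_subspace <- function(S, Sbig) {
  ia <- match(S$alpha, Sbig$alpha)
  ib <- match(S$beta, Sbig$beta)
  if (anyNA(ia) || anyNA(ib))
    sqd_error("subspace is not contained in the enclosing space",
              "argument_error")
  nb <- length(Sbig$beta)
  as.vector(t(outer((ia - 1L) * nb, ib, `+`)))
}

#' Lowest eigenpair of the subspace Hamiltonian by the Davidson method
#'
#' Diagonalizes \eqn{\hat H_{S} = \hat P_S \hat H \hat P_S} for the lowest
#' eigenpair with a diagonally preconditioned Davidson iteration (restarted
#' at `max_subspace` trial vectors, start vector on the lowest-diagonal
#' determinant).  Tiny problems fall back to direct dense diagonalization.
#' The returned state also carries its occupation numbers and, when
#' `compute_variance = TRUE` and the full sector fits the memory budget,
#' its Hamiltonian variance.
#'
#' @param H an `"as_hamiltonian"`.
#' @param S a `"det_subspace"` compatible with `H` (same particle numbers).
#' @param tol residual 2-norm threshold in Hartree.
#' @param max_iter maximum Davidson iterations.
#' @param max_subspace trial-space size at which the iteration restarts.
#' @param compute_variance populate the `variance` field (requires
#'   enumerating the full sector; set `FALSE` to skip).
#' @return an object of class `"subspace_result"`: fields `energy`
#'   (Hartree), `state` (`"ci_vector"`), `occupations` (length `2M`),
#'   `variance` (Hartree^2 or `NA`), `residual`, `iterations`.
#' @export
davidson_lowest <- function(H, S, tol = 1e-8, max_iter = 200,
                            max_subspace = 25, compute_variance = TRUE) {
  stopifnot(inherits(H, "as_hamiltonian"), inherits(S, "det_subspace"))
  if (S$n_alpha != H$n_alpha || S$n_beta != H$n_beta)
    sqd_error("subspace particle numbers do not match the Hamiltonian",
              "argument_error")
  A <- ham_block(H, S)
  d <- S$dim
  if (d <= 32) {
    e <- eigen(A, symmetric = TRUE)
    vec <- e$vectors[, d]
    ene <- e$values[d]
    res <- 0
    iters <- 0L
  } else {
    dav <- davidson_core(A, tol = tol, max_iter = max_iter,
                         max_subspace = max_subspace)
    vec <- dav$vector
    ene <- dav$value
    res <- dav$residual
    iters <- dav$iterations
    if (!dav$converged)
      sqd_error(sprintf(
        "Davidson did not converge in %d iterations (best residual %.3e)",
        max_iter, res), "convergence_error", residual = res, energy = ene)
  }
  # fix sign: largest-magnitude coefficient positive
  vec <- vec / sqrt(sum(vec^2))
  k <- which.max(abs(vec))
  if (vec[k] < 0) vec <- -vec
  psi <- ci_vector(S, vec)
  var <- NA_real_
  if (compute_variance) {
    var <- tryCatch(variance(H, psi), sqdbinder_capacity_error = function(e) NA_real_)
  }
  structure(list(energy = ene, state = psi, occupations = occupations(psi),
                 variance = var, residual = res, iterations = iters),
            class = "subspace_result")
}

#' @export
print.subspace_result <- function(x, ...) {
  cat(sprintf("Subspace eigenpair: E = %.10f Ha on d = %d determinants\n",
              x$energy, x$state$subspace$dim))
  if (!is.na(x$variance))
    cat(sprintf("  Hamiltonian variance: %.3e Ha^2\n", x$variance))
  cat(sprintf("  Davidson: %d iterations, residual %.2e\n",
              x$iterations, x$residual))
  invisible(x)
}

## Davidson iteration for the lowest eigenpair of a dense symmetric matrix.
davidson_core <- function(A, tol = 1e-8, max_iter = 200, max_subspace = 25) {
  d <- nrow(A)
  diagA <- diag(A)
  v0 <- numeric(d)
  v0[which.min(diagA)] <- 1
  V <- matrix(v0, d, 1)
  W <- A %*% V
  best <- list(value = Inf, vector = v0, residual = Inf)
  for (it in seq_len(max_iter)) {
    Tm <- crossprod(V, W)
    Tm <- (Tm + t(Tm)) / 2
    es <- eigen(Tm, symmetric = TRUE)
    k <- ncol(Tm)
    theta <- es$values[k]
    y <- es$vectors[, k]
    x <- as.vector(V %*% y)
    r <- as.vector(W %*% y) - theta * x
    rn <- sqrt(sum(r^2))
    if (rn < best$residual)
      best <- list(value = theta, vector = x, residual = rn)
    if (rn <= tol)
      return(list(value = theta, vector = x, residual = rn,
                  iterations = it, converged = TRUE))
    denom <- theta - diagA
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-300) * 1e-8
    t_new <- r / denom
    if (ncol(V) >= min(max_subspace, d)) {
      V <- matrix(x, d, 1) # restart from the current Ritz vector
      W <- A %*% V
    }
    # orthogonalize against V (twice, for stability)
    for (pass in 1:2) t_new <- t_new - V %*% crossprod(V, t_new)
    tn <- sqrt(sum(t_new^2))
    if (tn < 1e-12) {
      # stagnation: perturb with the residual direction
      t_new <- r - V %*% crossprod(V, r)
      tn <- sqrt(sum(t_new^2))
      if (tn < 1e-14)
        return(list(value = theta, vector = x, residual = rn,
                    iterations = it, converged = rn <= tol * 10))
    }
    V <- cbind(V, t_new / tn)
    W <- cbind(W, A %*% V[, ncol(V)])
  }
  list(value = best$value, vector = best$vector, residual = best$residual,
       iterations = max_iter, converged = FALSE)
}

#' Complete active space CI ground state
#'
#' Diagonalizes the Hamiltonian over the complete determinant space of the
#' active space: the exact reference that sample-based subspace
#' diagonalization converges to.  The state's Hamiltonian variance is zero
#' to solver tolerance.
#'
#' @inheritParams davidson_lowest
#' @param max_dim capacity guard on the full-space dimension.
#' @return a `"subspace_result"`.
#' @export
casci <- function(H, tol = 1e-8, max_dim = getOption("sqdbinder.max_cas", 2e4),
                  compute_variance = TRUE) {
  d <- cas_dimension(H$M, H$n_alpha, H$n_beta)
  if (d > max_dim)
    sqd_error(sprintf(
      "full CAS dimension d = %.0f exceeds the budget of %.0f", d, max_dim),
      "capacity_error")
  S <- full_cas_space(H$M, H$n_alpha, H$n_beta)
  davidson_lowest(H, S, tol = tol, compute_variance = compute_variance)
}
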