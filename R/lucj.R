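## Truncated local unitary cluster Jastrow (LUCJ) ansatz.
##
## The ansatz applied to the restricted closed-shell Hartree-Fock
## determinant is the four-factor product
##
##     |Psi> = e^{-K2} e^{K1} e^{iJ1} e^{-K1} |x_RHF>,
##
## where K1, K2 generate one-body orbital rotations (anti-Hermitian M x M,
## spin-summed) and J1 is a symmetric density-density coupling over
## spin-orbital pairs, e^{iJ1} acting as a diagonal phase per determinant.
## Parameters are initialized from closed-shell CCSD doubles amplitudes via
## the cluster-Jastrow decomposition implemented in lucj_from_ccsd(); a
## hardware-locality mask restricts which spin-orbital pairs may couple in
## J1.

#' LUCJ locality mask
#'
#' Boolean `2M x 2M` pattern over spin-orbital pairs (alpha block then beta
#' block) restricting the density-density coupling `J1`.  `"dense"` allows
#' all pairs; `"line_heavyhex"` models a heavy-hex qubit layout where
#' same-spin couplings are nearest-neighbour (`|p - r| <= 1`) and
#' opposite-spin couplings exist only on the same orbital (`p == r`).
#'
#' @param M spatial orbital count.
#' @param pattern `"dense"` or `"line_heavyhex"`.
#' @return logical `2M x 2M` matrix, symmetric under pair transposition.
#' @export
lucj_mask <- function(M, pattern = c("dense", "line_heavyhex")) {
  pattern <- match.arg(pattern)
  if (pattern == "dense") return(matrix(TRUE, 2 * M, 2 * M))
  p <- rep(seq_len(M), 2)
  spin <- rep(c(1L, 2L), each = M)
  same_spin <- outer(spin, spin, `==`)
  dist <- abs(outer(p, p, `-`))
  (same_spin & dist <= 1) | (!same_spin & dist == 0)
}

#' LUCJ parameter set
#'
#' @param K1,K2 anti-Hermitian `M x M` orbital-rotation generators
#'   (`e^K` unitary).
#' @param J1 real symmetric `2M x 2M` density-density coupling over
#'   spin-orbital pairs.
#' @param mask logical `2M x 2M` locality pattern; `J1` must vanish outside
#'   it.
#' @return an object of class `"lucj_parameters"`.
#' @export
lucj_parameters <- function(K1, K2, J1, mask) {
  M <- nrow(K1)
  chk_antiherm <- function(K, nm) {
    if (max(abs(K + Conj(t(K)))) > 1e-12)
      sqd_error(paste0(nm, " must be anti-Hermitian"), "argument_error")
  }
  chk_antiherm(K1, "K1")
  chk_antiherm(K2, "K2")
  if (max(abs(J1 - t(J1))) > 1e-12)
    sqd_error("J1 must be symmetric", "argument_error")
  if (any(abs(J1[!mask]) > 0))
    sqd_error("J1 must vanish outside the locality mask", "argument_error")
  structure(list(K1 = K1, K2 = K2, J1 = J1, mask = mask, M = M),
            class = "lucj_parameters")
}

#' @export
print.lucj_parameters <- function(x, ...) {
  cat(sprintf("LUCJ parameters: M = %d orbitals, %d active J couplings\n",
              x$M, sum(x$J1 != 0)))
  cat(sprintf("  |K1| = %.4f, |K2| = %.4f (Frobenius)\n",
              sqrt(sum(Mod(x$K1)^2)), sqrt(sum(Mod(x$K2)^2))))
  invisible(x)
}

## principal matrix logarithm of a unitary matrix (normal, so its
## eigendecomposition is well conditioned)
logm_unitary <- function(U) {
  e <- eigen(U)
  K <- e$vectors %*% diag(log(e$values), nrow(U)) %*% solve(e$vectors)
  (K - Conj(t(K))) / 2 # enforce exact anti-Hermiticity
}

## Cluster-Jastrow factorization of a closed-shell doubles operator.
##
## With E_mu = sum_{ia} X^mu_{ia} E_{ai} (spin-summed singlet excitations)
## and lambda_mu, X^mu the eigenpairs of the (ia) x (jb) matrix of t2, the
## anti-Hermitian doubles generator satisfies exactly
##
##   T2 - T2^dag = i sum_mu lambda_mu (A_mu B_mu + B_mu A_mu)
##               = sum_mu [ i (lambda_mu/2) Q1_mu^2 - i (lambda_mu/2) Q2_mu^2 ],
##
## where A = (E + E^dag)/2, B = (E - E^dag)/(2i) are Hermitian one-body
## operators and Q1 = A + B, Q2 = A - B.  Each factor e^{i theta Q^2} is a
## rotated Jastrow: diagonalizing Q = U D U^dag gives
## e^{i theta Q^2} = e^{K} e^{iJ} e^{-K} with K = log U and
## J_{p sigma, r tau} = theta d_p d_r.
ucj_factors_from_t2 <- function(t2, n_pairs = NULL) {
  dm <- dim(t2)
  if (length(dm) != 4 || dm[1] != dm[2] || dm[3] != dm[4])
    sqd_error("t2 must be an (occ, occ, virt, virt) array", "argument_error")
  nocc <- dm[1]; nvirt <- dm[3]; M <- nocc + nvirt
  # (ia) x (jb) matrix; symmetric because t_{ij}^{ab} = t_{ji}^{ba}
  Tm <- matrix(aperm(t2, c(3, 1, 4, 2)), nocc * nvirt, nocc * nvirt)
  Tm <- (Tm + t(Tm)) / 2
  es <- eigen(Tm, symmetric = TRUE)
  ord <- order(-abs(es$values))
  if (is.null(n_pairs)) n_pairs <- sum(abs(es$values) > 1e-14)
  n_pairs <- min(n_pairs, length(ord))
  factors <- list()
  for (mu in seq_len(n_pairs)) {
    lam <- es$values[ord[mu]]
    X <- matrix(es$vectors[, ord[mu]], nvirt, nocc) # X[a, i]
    x <- matrix(0, M, M)
    x[nocc + seq_len(nvirt), seq_len(nocc)] <- X # coefficient of a^dag_a a_i
    A <- (x + t(x)) / 2
    B <- 1i * (t(x) - x) / 2
    for (sgn in c(1, -1)) {
      Q <- if (sgn > 0) A + B else A - B
      eq <- eigen(Q, symmetric = TRUE)
      U <- eq$vectors
      dd <- c(eq$values, eq$values) # both spins share the spatial rotation
      factors[[length(factors) + 1L]] <-
        list(K = logm_unitary(U), J = sgn * (lam / 2) * outer(dd, dd))
    }
  }
  factors
}

#' Truncated LUCJ parameters from CCSD doubles amplitudes
#'
#' Maps closed-shell CCSD doubles amplitudes to the truncated
#' \eqn{e^{-K_2} e^{K_1} e^{iJ_1} e^{-K_1}} form: the amplitude tensor is
#' reshaped to its \eqn{(ia)\times(jb)} matrix, whose dominant eigenpair
#' yields (via the exact cluster-Jastrow factorization of a squared
#' one-body operator) an orbital rotation `K1` plus diagonal coupling `J1`,
#' and a second rotation `K2` from the conjugate factor whose Jastrow is
#' dropped by the truncation.  Entries of `J1` outside the locality mask
#' are zeroed after construction.  Singles amplitudes are not used.
#'
#' @param t2 doubles amplitudes, an array with dimensions
#'   `(nocc, nocc, nvirt, nvirt)` (`t2[i, j, a, b]`).
#' @param mask logical `2M x 2M` locality pattern from [lucj_mask()].
#' @return an `"lucj_parameters"` object.
#' @export
lucj_from_ccsd <- function(t2, mask = lucj_mask(dim(t2)[1] + dim(t2)[3])) {
  dm <- dim(t2)
  if (length(dm) != 4 || dm[1] != dm[2] || dm[3] != dm[4])
    sqd_error("t2 must be an (occ, occ, virt, virt) array", "argument_error")
  M <- dm[1] + dm[3]
  if (!all(dim(mask) == c(2 * M, 2 * M)))
    sqd_error("mask must be 2M x 2M", "argument_error")
  zero <- matrix(0, M, M)
  if (max(abs(t2)) == 0)
    return(lucj_parameters(zero, zero, matrix(0, 2 * M, 2 * M), mask))
  fac <- ucj_factors_from_t2(t2, n_pairs = 1)
  J1 <- fac[[1]]$J
  J1[!mask] <- 0
  J1 <- (J1 + t(J1)) / 2
  lucj_parameters(K1 = fac[[1]]$K, K2 = fac[[2]]$K, J1 = J1, mask = mask)
}

## complex matrix exponential by scaling and squaring with a Taylor series
expm_complex <- function(A) {
  n <- nrow(A)
  nrm <- max(colSums(Mod(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  B <- A / 2^s
  E <- diag(1 + 0i, n)
  term <- diag(1 + 0i, n)
  for (k in 1:30) {
    term <- term %*% B / k
    E <- E + term
    if (max(Mod(term)) < 1e-16) break
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

## one-body operator matrix in a single-spin string basis for a complex
## coefficient matrix k (anti-Hermitian for rotations)
onebody_string_matrix <- function(strings, k) {
  re <- cpp_onebody_string_matrix(as.integer(strings), Re(k))
  if (is.complex(k) && max(abs(Im(k))) > 0)
    re <- re + 1i * cpp_onebody_string_matrix(as.integer(strings), Im(k))
  re
}

## apply e^{scale * Khat} (spin-summed one-body generator) to a coefficient
## matrix over S = A x B: C <- exp(Oa) C exp(Ob)^T
apply_orbital_rotation <- function(C, S, K, scale = 1) {
  Oa <- onebody_string_matrix(S$alpha, K) * scale
  Ob <- onebody_string_matrix(S$beta, K) * scale
  expm_complex(Oa) %*% C %*% t(expm_complex(Ob))
}

## diagonal Jastrow phase per determinant: theta(x) = x^T J x over
## spin-orbital occupations (full double sum, diagonal once via n^2 = n)
jastrow_phases <- function(S, J) {
  Xa <- mask_bits(S$alpha, S$M)
  Xb <- mask_bits(S$beta, S$M)
  Jaa <- J[seq_len(S$M), seq_len(S$M)]
  Jbb <- J[S$M + seq_len(S$M), S$M + seq_len(S$M)]
  Jab <- J[seq_len(S$M), S$M + seq_len(S$M)]
  ta <- rowSums((Xa %*% Jaa) * Xa) # |A| vector
  tb <- rowSums((Xb %*% Jbb) * Xb)
  cross <- Xa %*% Jab %*% t(Xb) # |A| x |B|
  outer(ta, tb, `+`) + 2 * cross
}

#' Evaluate the truncated LUCJ state over the full determinant space
#'
#' Applies \eqn{e^{-K_1}}, the diagonal Jastrow phase \eqn{e^{iJ_1}},
#' \eqn{e^{K_1}} and \eqn{e^{-K_2}} in sequence to the restricted
#' Hartree-Fock determinant (lowest `n_alpha`/`n_beta` orbitals occupied),
#' exactly, as a complex CI vector over the complete particle-number
#' sector.  Orbital rotations act through the series exponential of the
#' one-body generator per spin-string sector, so particle number is
#' conserved exactly; every factor is unitary, so the state stays
#' normalized.  This is the classical stand-in for executing the ansatz
#' circuit.
#'
#' @param params an `"lucj_parameters"`.
#' @param M orbital count (must match `params$M`).
#' @param n_alpha,n_beta electron counts.
#' @param max_dim capacity guard on the full-sector dimension.
#' @return a complex `"ci_vector"` over the full sector.
#' @export
apply_lucj <- function(params, M, n_alpha, n_beta,
                       max_dim = getOption("sqdbinder.max_cas", 2e4)) {
  stopifnot(inherits(params, "lucj_parameters"))
  if (params$M != M) sqd_error("params built for a different M", "argument_error")
  d <- cas_dimension(M, n_alpha, n_beta)
  if (d > max_dim)
    sqd_error(sprintf("full sector dimension %.0f over budget %.0f", d, max_dim),
              "capacity_error")
  S <- full_cas_space(M, n_alpha, n_beta)
  rhf_a <- bits_to_mask(rep(1, n_alpha))
  rhf_b <- bits_to_mask(rep(1, n_beta))
  C <- matrix(0 + 0i, length(S$alpha), length(S$beta))
  C[match(rhf_a, S$alpha), match(rhf_b, S$beta)] <- 1
  C <- apply_orbital_rotation(C, S, params$K1, scale = -1)
  C <- C * exp(1i * jastrow_phases(S, params$J1))
  C <- apply_orbital_rotation(C, S, params$K1, scale = 1)
  C <- apply_orbital_rotation(C, S, params$K2, scale = -1)
  nrm <- sqrt(sum(Mod(C)^2))
  ci_from_matrix(S, C / nrm)
}
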