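## Brute-force second-quantization oracle, independent of the package's
## Slater-Condon path: builds operator matrices by applying creation and
## annihilation operators to explicit occupation masks, with phases counted
## over the global spin-orbital ordering (alpha block then beta block).

bf_apply_ops <- function(alpha, beta, M, ops) {
  # ops: list of c(create, is_beta, orb), applied right-to-left
  sign <- 1
  for (k in rev(seq_along(ops))) {
    o <- ops[[k]]
    orb <- o[3]
    bit <- bitwShiftL(1L, orb - 1L)
    if (o[2] == 0) {
      occ_before <- if (orb > 1)
        sum(bitwAnd(bitwShiftR(alpha, seq_len(orb - 1) - 1L), 1L)) else 0
      if (o[1] == 1) {
        if (bitwAnd(alpha, bit) != 0) return(NULL)
        if (occ_before %% 2 == 1) sign <- -sign
        alpha <- bitwOr(alpha, bit)
      } else {
        if (bitwAnd(alpha, bit) == 0) return(NULL)
        if (occ_before %% 2 == 1) sign <- -sign
        alpha <- bitwAnd(alpha, bitwNot(bit))
      }
    } else {
      na <- sum(bitwAnd(bitwShiftR(alpha, seq_len(M) - 1L), 1L))
      occ_before <- na + (if (orb > 1)
        sum(bitwAnd(bitwShiftR(beta, seq_len(orb - 1) - 1L), 1L)) else 0)
      if (o[1] == 1) {
        if (bitwAnd(beta, bit) != 0) return(NULL)
        if (occ_before %% 2 == 1) sign <- -sign
        beta <- bitwOr(beta, bit)
      } else {
        if (bitwAnd(beta, bit) == 0) return(NULL)
        if (occ_before %% 2 == 1) sign <- -sign
        beta <- bitwAnd(beta, bitwNot(bit))
      }
    }
  }
  list(alpha = alpha, beta = beta, sign = sign)
}

## dense Hamiltonian matrix over the full particle-number sector, built by
## operator application term by term
bf_hamiltonian_matrix <- function(H) {
  S <- full_cas_space(H$M, H$n_alpha, H$n_beta)
  dets <- sqdbinder:::subspace_dets(S)
  d <- S$dim
  M <- H$M
  key <- paste(dets$alpha, dets$beta)
  A <- matrix(0, d, d)
  diag(A) <- H$E0
  for (j in seq_len(d)) {
    for (p in 1:M) for (r in 1:M) for (sp in 0:1) {
      if (H$h[p, r] == 0) next
      out <- bf_apply_ops(dets$alpha[j], dets$beta[j], M,
                          list(c(1, sp, p), c(0, sp, r)))
      if (is.null(out)) next
      i <- match(paste(out$alpha, out$beta), key)
      A[i, j] <- A[i, j] + out$sign * H$h[p, r]
    }
    for (p in 1:M) for (r in 1:M) for (q in 1:M) for (s in 1:M)
      for (sp in 0:1) for (tau in 0:1) {
        v <- H$eri[p, r, q, s]
        if (v == 0) next
        out <- bf_apply_ops(dets$alpha[j], dets$beta[j], M,
                            list(c(1, sp, p), c(1, tau, q),
                                 c(0, tau, s), c(0, sp, r)))
        if (is.null(out)) next
        i <- match(paste(out$alpha, out$beta), key)
        A[i, j] <- A[i, j] + 0.5 * out$sign * v
      }
  }
  A
}

## dense matrix of a spin-summed one-body operator (complex coefficients
## amat[p, r] of a^dag_p a_r) over a determinant subspace, via the oracle
bf_onebody_matrix <- function(amat, S) {
  dets <- sqdbinder:::subspace_dets(S)
  d <- S$dim
  M <- S$M
  key <- paste(dets$alpha, dets$beta)
  A <- matrix(0 + 0i, d, d)
  for (j in seq_len(d)) {
    for (p in seq_len(M)) for (r in seq_len(M)) for (sp in 0:1) {
      if (amat[p, r] == 0) next
      out <- bf_apply_ops(dets$alpha[j], dets$beta[j], M,
                          list(c(1, sp, p), c(0, sp, r)))
      if (is.null(out)) next
      i <- match(paste(out$alpha, out$beta), key)
      A[i, j] <- A[i, j] + out$sign * amat[p, r]
    }
  }
  A
}

## linear index of a determinant inside a subspace (alpha-major)
det_index <- function(S, alpha, beta) {
  (match(alpha, S$alpha) - 1L) * length(S$beta) + match(beta, S$beta)
}

rhf_masks <- function(n_alpha, n_beta) {
  list(alpha = as.integer(bitwShiftL(1L, n_alpha) - 1L),
       beta = as.integer(bitwShiftL(1L, n_beta) - 1L))
}
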