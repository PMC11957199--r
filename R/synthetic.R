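## Synthetic dimer model: a minimal two-monomer Hamiltonian family with a
## one-dimensional separation coordinate, used to exercise the
## bound/unbound binding protocol end to end where a full-CI reference is
## cheap.  It is a synthetic stand-in for engine-derived integrals, not a
## model of any real molecule.

#' Synthetic two-monomer dissociation Hamiltonian
#'
#' A (4e,4o) model dimer: each monomer contributes two orbitals (one low,
#' one high on-site energy) and two electrons, with fixed intra-monomer
#' hopping and on-site repulsion.  Each monomer is net neutral: the
#' inter-monomer electron-electron repulsion (`1/distance` per orbital
#' pair), the electron-core attraction on the opposite monomer's orbitals
#' and the core-core term in `E0` cancel exactly at the monopole level, so
#' the long-range tail of the curve is flat.  Inter-monomer one-electron
#' hopping decays exponentially with the separation and produces a bound
#' minimum at intermediate separation, so binding curves computed from
#' this family behave qualitatively like a dimer dissociation scan.
#'
#' @param distance separation coordinate (arbitrary length units, > 0).
#' @param hop_scale prefactor of the inter-monomer hopping.
#' @param hop_range decay length of the inter-monomer hopping.
#' @return an `"as_hamiltonian"` with `M = 4`, two electrons per spin.
#' @export
toy_dimer_hamiltonian <- function(distance, hop_scale = 0.35,
                                  hop_range = 0.7) {
  if (distance <= 0) sqd_error("distance must be > 0", "argument_error")
  M <- 4
  # monomer A owns orbitals {1, 3} (low, high), monomer B owns {2, 4};
  # the ordering puts both low orbitals first so the closed-shell
  # reference determinant (orbitals 1, 2) is the mean-field-like ground
  # configuration.  Core charge 2 per monomer.
  A_orbs <- c(1L, 3L); B_orbs <- c(2L, 4L)
  onsite <- c(-1.1, -1.1, -0.4, -0.4)
  h <- diag(onsite - 2 / distance) # attraction to the other monomer's core
  t_intra <- -0.25
  h[1, 3] <- h[3, 1] <- t_intra
  h[2, 4] <- h[4, 2] <- t_intra
  t_inter <- -hop_scale * exp(-(distance - 1) / hop_range)
  for (p in A_orbs) for (q in B_orbs) h[p, q] <- h[q, p] <- t_inter
  eri <- array(0, c(M, M, M, M))
  for (p in 1:M) eri[p, p, p, p] <- 0.55
  intra <- 0.35
  eri[1, 1, 3, 3] <- eri[3, 3, 1, 1] <- intra
  eri[2, 2, 4, 4] <- eri[4, 4, 2, 2] <- intra
  vinter <- 1 / distance
  for (p in A_orbs) for (q in B_orbs) {
    eri[p, p, q, q] <- vinter
    eri[q, q, p, p] <- vinter
  }
  # core-core repulsion of two charge-2 monomers plus a steep
  # overlap-repulsion wall at short range
  E0 <- 4 / distance + 90 * exp(-distance / 0.25)
  active_space_hamiltonian(M, 2, 2, E0, h, eri)
}

#' First-order (MP2-like) doubles amplitudes for a closed-shell Hamiltonian
#'
#' Perturbative doubles amplitudes
#' \deqn{t_{ij}^{ab} = \frac{(ia|jb)}{f_{ii} + f_{jj} - f_{aa} - f_{bb}}}
#' built from the diagonal of the closed-shell Fock operator in the
#' Hamiltonian's own orbital basis (no canonicalization).  These carry the
#' physical sign structure of coupled-cluster doubles and are the package's
#' stand-in parameterization of the ansatz when no external coupled-cluster
#' engine is involved; amplitudes from such an engine can be supplied via
#' [read_t2()] instead.
#'
#' @param H an `"as_hamiltonian"` with `n_alpha == n_beta`.
#' @return array `(nocc, nocc, nvirt, nvirt)` of doubles amplitudes.
#' @export
mp2_like_t2 <- function(H) {
  if (H$n_alpha != H$n_beta)
    sqd_error("closed-shell amplitudes need n_alpha == n_beta", "argument_error")
  M <- H$M
  no <- H$n_alpha
  nv <- M - no
  if (nv < 1) sqd_error("no virtual orbitals", "argument_error")
  occ <- seq_len(no)
  f <- H$h
  for (j in occ)
    f <- f + 2 * H$eri[, , j, j] - H$eri[, j, j, ]
  eps <- diag(f)
  t2 <- array(0, c(no, no, nv, nv))
  for (i in occ) for (j in occ) for (a in seq_len(nv)) for (b in seq_len(nv)) {
    den <- eps[i] + eps[j] - eps[no + a] - eps[no + b]
    t2[i, j, a, b] <- H$eri[i, no + a, j, no + b] / den
  }
  t2
}
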