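## Active-space Hamiltonians: container, validation, random fixtures and
## FCIDUMP input/output.

#' Active-space molecular Hamiltonian
#'
#' Container for a second-quantized Hamiltonian restricted to an active
#' space of `M` spatial orbitals:
#' \deqn{\hat H = E_0 + \sum_{pr\sigma} h_{pr} a^\dagger_{p\sigma} a_{r\sigma}
#'  + \tfrac12 \sum_{prqs\sigma\tau} (pr|qs)\,
#'    a^\dagger_{p\sigma} a^\dagger_{q\tau} a_{s\tau} a_{r\sigma},}
#' with `E0` a scalar collecting nuclear repulsion and inactive-orbital
#' contributions, `h` the symmetric one-electron integral matrix and `eri`
#' the two-electron integrals in chemist notation \eqn{(pr|qs)} with the
#' full 8-fold permutational symmetry.  All energies are in Hartree.
#'
#' @param M number of spatial orbitals.
#' @param n_alpha,n_beta electron counts per spin sector.
#' @param E0 scalar energy offset (Hartree).
#' @param h symmetric `M x M` one-electron integral matrix.
#' @param eri `M x M x M x M` array of chemist-notation two-electron
#'   integrals; all 8 symmetry-equivalent entries must be populated.
#' @param tol tolerance for the symmetry checks.
#' @return an object of class `"as_hamiltonian"`.
#' @seealso [read_fcidump()], [random_hamiltonian()], [casci()]
#' @export
active_space_hamiltonian <- function(M, n_alpha, n_beta, E0, h, eri,
                                     tol = 1e-10) {
  M <- as.integer(M)
  n_alpha <- as.integer(n_alpha)
  n_beta <- as.integer(n_beta)
  if (M < 1) sqd_error("M must be >= 1", "argument_error")
  if (n_alpha < 0 || n_alpha > M || n_beta < 0 || n_beta > M)
    sqd_error("electron counts must satisfy 0 <= N_sigma <= M", "argument_error")
  h <- as.matrix(h)
  if (!all(dim(h) == c(M, M)))
    sqd_error("h must be M x M", "argument_error")
  if (max(abs(h - t(h))) > tol)
    sqd_error("h must be symmetric", "argument_error")
  if (!is.array(eri) || !all(dim(eri) == c(M, M, M, M)))
    sqd_error("eri must be an M^4 array", "argument_error")
  dev <- max(abs(eri - aperm(eri, c(2, 1, 3, 4))),
             abs(eri - aperm(eri, c(1, 2, 4, 3))),
             abs(eri - aperm(eri, c(3, 4, 1, 2))))
  if (dev > tol)
    sqd_error("eri must have the 8-fold (pr|qs) permutational symmetry",
              "argument_error")
  structure(list(M = M, n_alpha = n_alpha, n_beta = n_beta,
                 E0 = as.numeric(E0), h = h, eri = eri),
            class = "as_hamiltonian")
}

#' @export
print.as_hamiltonian <- function(x, ...) {
  cat(sprintf("Active-space Hamiltonian: (%de,%do), E0 = %.8f Ha\n",
              x$n_alpha + x$n_beta, x$M, x$E0))
  cat(sprintf("  N_alpha = %d, N_beta = %d; CAS dimension %s\n",
              x$n_alpha, x$n_beta,
              format(cas_dimension(x$M, x$n_alpha, x$n_beta), big.mark = ",")))
  invisible(x)
}

#' Random active-space Hamiltonian fixture
#'
#' Draws a reproducible random Hamiltonian: `h` from a symmetrized standard
#' Gaussian and `eri` from a Gaussian 4-tensor symmetrized over the 8
#' chemist-notation permutations.  Intended for tests and synthetic
#' end-to-end runs; the instances are not positive definite or physical,
#' which is irrelevant for the solver contracts they exercise.
#'
#' @inheritParams active_space_hamiltonian
#' @param seed integer seed; the same seed reproduces the Hamiltonian
#'   bit-for-bit.
#' @param scale standard deviation of the Gaussian entries.
#' @return an `"as_hamiltonian"` object.
#' @export
random_hamiltonian <- function(M, n_alpha, n_beta, seed, scale = 1) {
  if (M < 1 || n_alpha > M || n_beta > M)
    sqd_error("invalid counts: need M >= 1 and N_sigma <= M", "argument_error")
  with_seed(seed, {
    h <- matrix(rnorm(M * M, sd = scale), M, M)
    h <- (h + t(h)) / 2
    g <- array(rnorm(M^4, sd = scale), c(M, M, M, M))
    g <- (g + aperm(g, c(2, 1, 3, 4))) / 2
    g <- (g + aperm(g, c(1, 2, 4, 3))) / 2
    g <- (g + aperm(g, c(3, 4, 1, 2))) / 2
    E0 <- rnorm(1, sd = scale)
    active_space_hamiltonian(M, n_alpha, n_beta, E0, h, g)
  })
}

## canonical representative test: emit (pr|qs) only once per symmetry class
.canon_pairs <- function(M) {
  idx <- which(lower.tri(diag(M), diag = TRUE), arr.ind = TRUE)
  # rows: p >= r pairs, compound index for ordering
  data.frame(p = idx[, 1], r = idx[, 2],
             pr = (idx[, 1] - 1) * idx[, 1] / 2 + idx[, 2])
}

#' Write an active-space Hamiltonian in FCIDUMP format
#'
#' Emits the standard text FCIDUMP dialect: an `&FCI` namelist header with
#' `NORB`, `NELEC`, `MS2`, `ORBSYM` (all 1; point-group symmetry is not
#' used) and `ISYM=1`, followed by `value p r q s` records with 1-based
#' indices and chemist-notation two-electron integrals.  Only one canonical
#' representative per 8-fold symmetry class is written, and values below
#' `1e-12` are omitted (except `E0`, always written as the terminating
#' `0 0 0 0` record).
#'
#' @param H an `"as_hamiltonian"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(H, path) {
  stopifnot(inherits(H, "as_hamiltonian"))
  M <- H$M
  con <- tryCatch(file(path, "w"),
                  error = function(e) sqd_error(
                    paste0("cannot open '", path, "' for writing"), "io_error"))
  on.exit(close(con))
  nelec <- H$n_alpha + H$n_beta
  ms2 <- H$n_alpha - H$n_beta
  writeLines(c(
    sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", M, nelec, ms2),
    paste0("  ORBSYM=", paste(rep("1", M), collapse = ","), ","),
    "  ISYM=1,",
    "&END"), con)
  fmt <- function(v, p, r, q, s) sprintf("%23.16E %4d %4d %4d %4d", v, p, r, q, s)
  pairs <- .canon_pairs(M)
  lines <- character(0)
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(i)) { # (pr) >= (qs) by compound pair index
      p <- pairs$p[i]; r <- pairs$r[i]; q <- pairs$p[j]; s <- pairs$r[j]
      v <- H$eri[p, r, q, s]
      if (abs(v) > 1e-12) lines <- c(lines, fmt(v, p, r, q, s))
    }
  }
  for (i in seq_len(nrow(pairs))) {
    v <- H$h[pairs$p[i], pairs$r[i]]
    if (abs(v) > 1e-12) lines <- c(lines, fmt(v, pairs$p[i], pairs$r[i], 0, 0))
  }
  lines <- c(lines, fmt(H$E0, 0, 0, 0, 0))
  writeLines(lines, con)
  invisible(path)
}

#' Read an FCIDUMP file
#'
#' Parses the standard FCIDUMP text format (1-based indices, chemist
#' notation).  All 8 permutations of each stored \eqn{(pr|qs)} value are
#' populated; the scalar offset is taken from the `0 0 0 0` record, and the
#' per-spin electron counts are derived from `NELEC` and `MS2`.
#'
#' @param path path to an FCIDUMP file.
#' @return an `"as_hamiltonian"`.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path))
    sqd_error(paste0("file not found: ", path), "io_error")
  txt <- readLines(path, warn = FALSE)
  hdr_end <- grep("(&END|/)\\s*$", txt, ignore.case = TRUE)[1]
  if (is.na(hdr_end))
    sqd_error("malformed FCIDUMP: no end of &FCI namelist found", "format_error")
  hdr <- paste(txt[seq_len(hdr_end)], collapse = " ")
  getkey <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr,
                                 ignore.case = TRUE))
    if (length(m) == 0)
      sqd_error(paste0("malformed FCIDUMP header: missing ", key), "format_error")
    as.integer(sub(paste0("(?i)", key, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  M <- getkey("NORB")
  nelec <- getkey("NELEC")
  ms2 <- getkey("MS2")
  if (M < 1 || (nelec + ms2) %% 2 != 0)
    sqd_error("malformed FCIDUMP header: inconsistent NORB/NELEC/MS2",
              "format_error")
  n_alpha <- (nelec + ms2) %/% 2
  n_beta <- (nelec - ms2) %/% 2
  h <- matrix(0, M, M)
  eri <- array(0, c(M, M, M, M))
  E0 <- 0
  body <- txt[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 5)
      sqd_error(paste0("malformed FCIDUMP record: '", ln, "'"), "format_error")
    v <- suppressWarnings(as.numeric(sub("[dD]", "E", f[1])))
    ix <- suppressWarnings(as.integer(f[2:5]))
    if (is.na(v) || anyNA(ix))
      sqd_error(paste0("malformed FCIDUMP record: '", ln, "'"), "format_error")
    if (any(ix < 0 | ix > M))
      sqd_error(paste0("FCIDUMP index out of range [1, ", M, "]: '", ln, "'"),
                "format_error")
    p <- ix[1]; r <- ix[2]; q <- ix[3]; s <- ix[4]
    if (all(ix == 0)) {
      E0 <- v
    } else if (q == 0 && s == 0) {
      if (p == 0 || r == 0)
        sqd_error(paste0("FCIDUMP one-electron record with zero index: '",
                         ln, "'"), "format_error")
      h[p, r] <- v; h[r, p] <- v
    } else {
      if (any(ix == 0))
        sqd_error(paste0("FCIDUMP two-electron record with zero index: '",
                         ln, "'"), "format_error")
      for (pr in list(c(p, r), c(r, p)))
        for (qs in list(c(q, s), c(s, q))) {
          eri[pr[1], pr[2], qs[1], qs[2]] <- v
          eri[qs[1], qs[2], pr[1], pr[2]] <- v
        }
    }
  }
  active_space_hamiltonian(M, n_alpha, n_beta, E0, h, eri)
}

#' Rotate an active-space Hamiltonian to a new orbital basis
#'
#' Applies an orthogonal orbital rotation `U` (columns are the new
#' orbitals in the old basis) to the one- and two-electron integrals.
#' Spectra, and therefore all energies, are invariant under the rotation.
#'
#' @param H an `"as_hamiltonian"`.
#' @param U orthogonal `M x M` matrix.
#' @return the rotated `"as_hamiltonian"`.
#' @export
rotate_orbitals <- function(H, U) {
  stopifnot(inherits(H, "as_hamiltonian"))
  U <- as.matrix(U)
  if (!all(dim(U) == c(H$M, H$M)) ||
      max(abs(crossprod(U) - diag(H$M))) > 1e-10)
    sqd_error("U must be an orthogonal M x M matrix", "argument_error")
  h2 <- crossprod(U, H$h %*% U)
  g <- H$eri
  for (k in 1:4) { # transform one index per cycle, then rotate it to the back
    dim(g) <- c(H$M, H$M^3)
    g <- crossprod(U, g)
    dim(g) <- rep(H$M, 4)
    g <- aperm(g, c(2, 3, 4, 1))
  }
  active_space_hamiltonian(H$M, H$n_alpha, H$n_beta, H$E0, h2, g)
}

#' Closed-shell mean-field orbitals within the active space
#'
#' Plain restricted closed-shell self-consistent field over the active
#' orbitals: iterates the Fock operator
#' \eqn{F = h + 2J(P) - K(P)} to self-consistency and returns the
#' canonical orbital coefficients and energies.  Used to canonicalize
#' synthetic Hamiltonians before building perturbative amplitudes, the
#' same role the mean-field step plays ahead of coupled cluster in a
#' production workflow.
#'
#' @param H an `"as_hamiltonian"` with `n_alpha == n_beta`.
#' @param max_iter,tol iteration controls on the density change.
#' @return list with `U` (orbital coefficients, columns ordered by
#'   energy), `energies`, and `converged`.
#' @export
canonical_orbitals <- function(H, max_iter = 100, tol = 1e-10) {
  if (H$n_alpha != H$n_beta)
    sqd_error("closed-shell mean field needs n_alpha == n_beta",
              "argument_error")
  M <- H$M
  occ <- seq_len(H$n_alpha)
  G <- matrix(H$eri, M^2, M^2) # (pr) x (qs)
  Gx <- matrix(aperm(H$eri, c(1, 4, 3, 2)), M^2, M^2) # (ps) x (qr)
  C <- eigen(H$h, symmetric = TRUE)$vectors
  P_old <- matrix(Inf, M, M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- 2 * tcrossprod(C[, occ, drop = FALSE])
    if (max(abs(P - P_old)) < tol) {
      converged <- TRUE
      break
    }
    P_old <- P
    J <- matrix(G %*% as.vector(P), M, M)
    K <- matrix(Gx %*% as.vector(P), M, M)
    F_mat <- H$h + J - 0.5 * K
    C <- eigen((F_mat + t(F_mat)) / 2, symmetric = TRUE)$vectors
  }
  e <- eigen((F_mat + t(F_mat)) / 2, symmetric = TRUE)
  list(U = e$vectors[, order(e$values)], energies = sort(e$values),
       converged = converged)
}
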