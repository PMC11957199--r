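## Determinant subspaces and CI vectors.
##
## A determinant is a pair of occupation bit masks (alpha, beta); bit p-1
## set means spatial orbital p occupied in that spin sector.  A subspace is
## the Cartesian product of a sorted unique list of alpha strings A and
## beta strings B; its basis is indexed alpha-major: the determinant
## (A[i], B[j]) has linear index (i-1)*|B| + j.

#' Number of determinants in a complete active space
#'
#' The complete (Ne, Mo) determinant space factorizes over spin sectors,
#' \eqn{d = \binom{M}{N_\alpha}\binom{M}{N_\beta}}; e.g. a (16e,12o) space
#' has \eqn{\binom{12}{8}^2 = 245{,}025} determinants.
#'
#' @param M spatial orbital count.
#' @param n_alpha,n_beta electrons per spin sector.
#' @return the dimension as a double (counts can exceed integer range).
#' @export
cas_dimension <- function(M, n_alpha, n_beta) {
  choose(M, n_alpha) * choose(M, n_beta)
}

#' Determinant subspace from alpha and beta occupation strings
#'
#' @param alpha_strings,beta_strings integer occupation masks; duplicates
#'   are removed and the lists sorted.  All alpha strings must share one
#'   particle number, and likewise the beta strings.
#' @param M spatial orbital count.
#' @return an object of class `"det_subspace"` with fields `alpha`, `beta`,
#'   `M`, `n_alpha`, `n_beta` and `dim`.
#' @export
det_subspace <- function(alpha_strings, beta_strings, M) {
  alpha <- sort(unique(as.integer(alpha_strings)))
  beta <- sort(unique(as.integer(beta_strings)))
  if (length(alpha) == 0 || length(beta) == 0)
    sqd_error("subspace must contain at least one determinant", "argument_error")
  if (any(alpha >= bitwShiftL(1L, M)) || any(beta >= bitwShiftL(1L, M)))
    sqd_error("occupation strings exceed M orbitals", "argument_error")
  pa <- unique(popcounts(alpha))
  pb <- unique(popcounts(beta))
  if (length(pa) != 1 || length(pb) != 1)
    sqd_error("all strings of a spin sector must share one particle number",
              "argument_error")
  structure(list(alpha = alpha, beta = beta, M = as.integer(M),
                 n_alpha = pa, n_beta = pb,
                 dim = length(alpha) * length(beta)),
            class = "det_subspace")
}

#' @export
print.det_subspace <- function(x, ...) {
  cat(sprintf(
    "Determinant subspace: |A| = %d alpha x |B| = %d beta strings, d = %d\n",
    length(x$alpha), length(x$beta), x$dim))
  cat(sprintf("  M = %d orbitals, (N_alpha, N_beta) = (%d, %d)\n",
              x$M, x$n_alpha, x$n_beta))
  invisible(x)
}

#' Complete determinant space of an active space
#'
#' @inheritParams cas_dimension
#' @return a `"det_subspace"` spanning the full (Ne, Mo) sector.
#' @export
full_cas_space <- function(M, n_alpha, n_beta) {
  det_subspace(occ_strings(M, n_alpha), occ_strings(M, n_beta), M)
}

## parallel vectors of (alpha, beta) masks for every determinant, in the
## alpha-major linear order
subspace_dets <- function(S) {
  na <- length(S$alpha); nb <- length(S$beta)
  list(alpha = rep(S$alpha, each = nb), beta = rep(S$beta, times = na))
}

#' CI vector over a determinant subspace
#'
#' @param subspace a `"det_subspace"`.
#' @param coefficients numeric or complex vector of length `subspace$dim`
#'   in the alpha-major order.
#' @return an object of class `"ci_vector"`.
#' @export
ci_vector <- function(subspace, coefficients) {
  stopifnot(inherits(subspace, "det_subspace"))
  if (length(coefficients) != subspace$dim)
    sqd_error("coefficient length must equal the subspace dimension",
              "argument_error")
  if (any(!is.finite(Mod(coefficients))))
    sqd_error("coefficients must be finite", "argument_error")
  structure(list(subspace = subspace, coefficients = coefficients),
            class = "ci_vector")
}

#' @export
print.ci_vector <- function(x, ...) {
  cat(sprintf("CI vector on d = %d determinants (norm %.6f)\n",
              x$subspace$dim, sqrt(sum(Mod(x$coefficients)^2))))
  invisible(x)
}

ci_norm <- function(psi) sqrt(sum(Mod(psi$coefficients)^2))

check_normalized <- function(psi, tol = 1e-8) {
  if (abs(ci_norm(psi) - 1) > tol)
    sqd_error("CI vector must be normalized", "argument_error")
  invisible(psi)
}

## coefficients as an |A| x |B| matrix (alpha rows, beta columns)
ci_matrix <- function(psi) {
  matrix(psi$coefficients, nrow = length(psi$subspace$alpha),
         ncol = length(psi$subspace$beta), byrow = TRUE)
}

ci_from_matrix <- function(S, C) {
  ci_vector(S, as.vector(t(C)))
}
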