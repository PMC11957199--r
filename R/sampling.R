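## Synthetic measurement device: computational-basis sampling of a CI
## state and particle-number-breaking bit-flip noise.

#' Multiset of sampled electronic configurations
#'
#' @param alpha,beta integer occupation masks per distinct configuration.
#' @param count multiplicities (shots per configuration).
#' @param M orbital count (bitstrings have length `2M`).
#' @return an object of class `"sample_set"`: a data frame with columns
#'   `alpha`, `beta`, `count` and attributes `M` and `shots`.
#' @export
sample_set <- function(alpha, beta, count, M) {
  df <- data.frame(alpha = as.integer(alpha), beta = as.integer(beta),
                   count = as.integer(count))
  if (any(df$count < 0)) sqd_error("counts must be >= 0", "argument_error")
  df <- df[df$count > 0, , drop = FALSE]
  if (nrow(df) > 0) {
    key <- paste(df$alpha, df$beta)
    agg <- rowsum(df$count, key, reorder = FALSE)
    first <- !duplicated(key)
    df <- data.frame(alpha = df$alpha[first], beta = df$beta[first],
                     count = as.integer(agg[match(unique(key), rownames(agg))]))
    df <- df[order(df$alpha, df$beta), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, M = as.integer(M), shots = sum(df$count),
            class = c("sample_set", "data.frame"))
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d shots over %d distinct configurations (M = %d)\n",
              attr(x, "shots"), nrow(x), attr(x, "M")))
  invisible(x)
}

sample_shots <- function(x) attr(x, "shots")

#' Sample configurations from a CI state
#'
#' Draws `shots` i.i.d. computational-basis measurements of a normalized
#' state, with configuration probabilities \eqn{|\langle x|\Psi\rangle|^2}.
#' Deterministic for a fixed seed.
#'
#' @param psi a normalized `"ci_vector"` (real or complex).
#' @param shots number of measurement shots.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a `"sample_set"`.
#' @export
sample_state <- function(psi, shots, seed = NULL) {
  check_normalized(psi)
  if (shots < 0) sqd_error("shots must be >= 0", "argument_error")
  M <- psi$subspace$M
  if (shots == 0)
    return(sample_set(integer(0), integer(0), integer(0), M))
  p <- Mod(psi$coefficients)^2
  p <- p / sum(p)
  counts <- with_seed(seed, as.integer(rmultinom(1, shots, p)))
  dets <- subspace_dets(psi$subspace)
  keep <- counts > 0
  sample_set(dets$alpha[keep], dets$beta[keep], counts[keep], M)
}

#' Bit-flip noise model
#'
#' Uniform independent per-bit flips with probability `epsilon`: the
#' minimal synthetic stand-in for device noise, whose defining signature is
#' that it breaks particle-number conservation.  Correlated or coherent
#' hardware errors are deliberately not modeled.
#'
#' @param epsilon per-bit flip probability in `[0, 1]`.
#' @param seed integer seed for the flip draws.
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(epsilon = 0.01, seed = NULL) {
  if (epsilon < 0 || epsilon > 1)
    sqd_error("epsilon must lie in [0, 1]", "argument_error")
  structure(list(epsilon = epsilon, seed = seed), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Bit-flip noise model: epsilon = %g\n", x$epsilon))
  invisible(x)
}

## expand a sample set to one row per shot
expand_shots <- function(samples) {
  idx <- rep(seq_len(nrow(samples)), samples$count)
  list(alpha = samples$alpha[idx], beta = samples$beta[idx])
}

flip_masks <- function(n, M, epsilon) {
  if (n == 0) return(integer(0))
  flips <- matrix(runif(n * M) < epsilon, n, M)
  as.integer(flips %*% bitwShiftL(1L, seq_len(M) - 1L))
}

#' Corrupt samples with independent bit flips
#'
#' Flips every bit of every shot independently with probability
#' `noise$epsilon`, emulating the noisy device distribution
#' \eqn{\tilde p(x) \neq |\langle x|\Psi\rangle|^2}; the total shot count
#' is preserved while particle number generally is not.
#'
#' @param samples a `"sample_set"`.
#' @param noise a `"noise_model"`.
#' @return a `"sample_set"` of corrupted configurations.
#' @export
corrupt <- function(samples, noise) {
  stopifnot(inherits(samples, "sample_set"), inherits(noise, "noise_model"))
  M <- attr(samples, "M")
  if (noise$epsilon == 0 || sample_shots(samples) == 0) return(samples)
  sh <- expand_shots(samples)
  n <- length(sh$alpha)
  with_seed(noise$seed, {
    if (noise$epsilon == 1) {
      full <- as.integer(bitwShiftL(1L, M) - 1L)
      a <- bitwXor(sh$alpha, full)
      b <- bitwXor(sh$beta, full)
    } else {
      a <- bitwXor(sh$alpha, flip_masks(n, M, noise$epsilon))
      b <- bitwXor(sh$beta, flip_masks(n, M, noise$epsilon))
    }
    sample_set(a, b, rep(1L, n), M)
  })
}

#' Retain only configurations with the correct particle numbers
#'
#' @param samples a `"sample_set"`.
#' @param n_alpha,n_beta required per-sector electron counts.
#' @return a `"sample_set"` (possibly empty).
#' @export
filter_correct_number <- function(samples, n_alpha, n_beta) {
  stopifnot(inherits(samples, "sample_set"))
  keep <- popcounts(samples$alpha) == n_alpha & popcounts(samples$beta) == n_beta
  sample_set(samples$alpha[keep], samples$beta[keep], samples$count[keep],
             attr(samples, "M"))
}

#' Write a sample set as plain text
#'
#' Writes one `bitstring count` line per distinct configuration (alpha
#' block then beta block, orbital 1 leftmost) plus a JSON metadata sidecar
#' `<path>.json` holding `M`, `shots` and any extra fields, mirroring
#' measurement-outcome dumps so hardware data could be ingested later.
#'
#' @param samples a `"sample_set"`.
#' @param path output path for the two-column text file.
#' @param meta named list of extra metadata (e.g. `seed`, `epsilon`).
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(samples, path, meta = list()) {
  stopifnot(inherits(samples, "sample_set"))
  M <- attr(samples, "M")
  lines <- if (nrow(samples) > 0)
    paste(det_bitstring(samples$alpha, samples$beta, M), samples$count)
  else character(0)
  writeLines(lines, path)
  meta <- c(list(M = M, shots = sample_shots(samples)), meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a sample set written by [write_sample_set()]
#'
#' @param path path to the two-column text file (with `<path>.json`
#'   metadata sidecar).
#' @return a `"sample_set"`.
#' @export
read_sample_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  M <- as.integer(meta$M)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0)
    return(sample_set(integer(0), integer(0), integer(0), M))
  f <- strsplit(trimws(txt), "\\s+")
  bs <- vapply(f, `[`, "", 1)
  cnt <- as.integer(vapply(f, `[`, "", 2))
  masks <- parse_bitstring(bs, M)
  sample_set(masks$alpha, masks$beta, cnt, M)
}
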