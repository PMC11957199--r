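## Zero-variance energy extrapolation.  Near the exact ground state the
## subspace energy is linear in the Hamiltonian variance; regressing the
## energy on variance/energy^2 and reading off the intercept estimates the
## zero-variance (exact) energy from a ladder of inexpensive subspace
## solutions.

#' Extrapolate subspace energies to zero Hamiltonian variance
#'
#' Ordinary least squares of the energies against
#' \eqn{x = \Delta H / E^2} (the Hamiltonian variance divided by the
#' square of the variational energy).  The intercept is the zero-variance
#' energy estimate; its standard error is the reported error estimate.
#' Three or four points from increasing batch sizes are the typical
#' protocol.
#'
#' @param variance Hamiltonian variances \eqn{\Delta H} (Hartree^2), or a
#'   two-column object `cbind(variance, energy)`.
#' @param energy subspace energies (Hartree), omitted if `variance` has
#'   two columns.
#' @return an object of class `"sqd_extrapolation"` with components
#'   `intercept`, `slope`, `stderr_intercept`, and `points` (a data frame
#'   with `variance`, `energy`, `x`).
#' @examples
#' ex <- extrapolate_energy(c(0.001, 0.002, 0.003) * c(1.05, 1.1, 1.15)^2,
#'                          c(-1.050, -1.100, -1.150))
#' coef(ex)
#' @export
extrapolate_energy <- function(variance, energy = NULL) {
  if (is.null(energy)) {
    variance <- as.matrix(variance)
    stopifnot(ncol(variance) == 2)
    energy <- variance[, 2]
    variance <- variance[, 1]
  }
  if (length(variance) != length(energy) || length(energy) < 2)
    sqd_error("need >= 2 (variance, energy) points", "argument_error")
  x <- variance / energy^2
  if (diff(range(x)) < 1e-300)
    sqd_error("all abscissae variance/energy^2 coincide; extrapolation is degenerate",
              "degenerate_design_error")
  n <- length(x)
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (energy - mean(energy))) / sxx
  intercept <- mean(energy) - slope * xb
  resid <- energy - (intercept + slope * x)
  s2 <- if (n > 2) sum(resid^2) / (n - 2) else 0
  se_int <- sqrt(s2 * (1 / n + xb^2 / sxx))
  structure(list(intercept = intercept, slope = slope,
                 stderr_intercept = se_int,
                 points = data.frame(variance = variance, energy = energy,
                                     x = x),
                 residuals = resid),
            class = "sqd_extrapolation")
}

#' @export
print.sqd_extrapolation <- function(x, ...) {
  cat(sprintf(
    "Zero-variance extrapolation over %d points:\n", nrow(x$points)))
  cat(sprintf("  E(0) = %.8f +/- %.8f Ha (slope %.4f)\n",
              x$intercept, x$stderr_intercept, x$slope))
  invisible(x)
}

#' @export
coef.sqd_extrapolation <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.sqd_extrapolation <- function(object, x = 0, ...) {
  object$intercept + object$slope * x
}

#' @export
plot.sqd_extrapolation <- function(x, ...) {
  pts <- x$points
  plot(pts$x, pts$energy, pch = 19,
       xlab = expression(Delta * H / E^2), ylab = "energy (Hartree)",
       xlim = c(0, max(pts$x) * 1.05),
       main = "Zero-variance energy extrapolation", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::points(0, x$intercept, pch = 4, cex = 1.4)
  invisible(x)
}

#' Energy/variance ladder over increasing batch sizes
#'
#' Convenience wrapper running [sqd()] at several batch sizes on the same
#' sample set configuration and collecting the (variance, energy) pair of
#' the best batch at each size, ready for [extrapolate_energy()].
#'
#' @param H an `"as_hamiltonian"`.
#' @param ansatz as in [sqd()].
#' @param shots total shots.
#' @param batch_sizes increasing batch sizes, e.g. `c(9000, 11000, 14000)`.
#' @param noise a `"noise_model"`.
#' @param config a `"recovery_config"` template; its `batch_size` is
#'   overridden per ladder point.
#' @param sampler_seed measurement seed.
#' @return data frame with columns `batch_size`, `variance`, `energy`.
#' @export
energy_variance_ladder <- function(H, ansatz, shots, batch_sizes,
                                   noise = noise_model(0),
                                   config = recovery_config(),
                                   sampler_seed = NULL) {
  rows <- lapply(batch_sizes, function(bs) {
    cfg <- config
    cfg$batch_size <- as.integer(bs)
    fit <- sqd(H, ansatz, shots, noise = noise, config = cfg,
               sampler_seed = sampler_seed, compute_variance = TRUE)
    data.frame(batch_size = bs, variance = fit$variance, energy = fit$energy)
  })
  do.call(rbind, rows)
}
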