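## Supramolecular binding energies and one-dimensional binding curves.
##
## With a consistent active space, the binding energy is the difference
## between the bound dimer and a far-separated (unbound) dimer reference,
##     E_binding = E_AB(bound) - E_AB(unbound),
## computed once per system with the unbound monomers at 48.000 Angstrom
## and reported in kcal/mol.

#' Supramolecular binding energy
#'
#' @param E_bound energy of the bound dimer (Hartree).
#' @param E_unbound energy of the far-separated dimer reference (Hartree).
#' @return an object of class `"binding_result"` with `E_bound`,
#'   `E_unbound` (Hartree) and `E_binding` (kcal/mol).
#' @examples
#' binding_energy(-152.108, -152.100) # -5.02 kcal/mol
#' @export
binding_energy <- function(E_bound, E_unbound) {
  if (!is.finite(E_bound) || !is.finite(E_unbound))
    sqd_error("energies must be finite", "argument_error")
  structure(list(E_bound = E_bound, E_unbound = E_unbound,
                 E_binding = hartree_to_kcal(E_bound - E_unbound)),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("Binding energy: %.4f kcal/mol\n", x$E_binding))
  cat(sprintf("  E_bound = %.10f Ha, E_unbound = %.10f Ha\n",
              x$E_bound, x$E_unbound))
  invisible(x)
}

## resolve a Hamiltonian entry of a manifest: path to an FCIDUMP file or
## an in-memory object
resolve_hamiltonian <- function(x) {
  if (inherits(x, "as_hamiltonian")) return(x)
  if (is.character(x) && length(x) == 1) return(read_fcidump(x))
  sqd_error("expected an as_hamiltonian or an FCIDUMP path", "argument_error")
}

#' Binding-energy curve along a dissociation coordinate
#'
#' Computes one energy per grid distance plus a single shared unbound
#' reference, and assembles the per-distance binding energies.  Every
#' point must use the same active-space definition; that consistency is
#' what makes the bound/unbound difference meaningful.  The reported
#' minimum is the grid arg-min (no interpolation).
#'
#' @param manifest a list (or path to a YAML file) with entries:
#'   `points`, a list of `list(distance =, fcidump =)` (an
#'   `"as_hamiltonian"` may stand in for `fcidump`); `unbound`, the
#'   reference in the same form; `method`, `"casci"` (default) or
#'   `"sqd"`; and for `"sqd"` the entries `shots`, `epsilon`, `K`,
#'   `batch_size`, `steps`, `energy_tol`, `seed`, plus either per-point
#'   `t2` amplitude files (see [read_t2()]) or `amplitudes: "mp2"` (the
#'   default) to build perturbative amplitudes from each point's own
#'   integrals.
#' @param label method label stored on the curve.
#' @return an object of class `"binding_curve"`: a data frame with columns
#'   `distance`, `E_bound`, `E_unbound`, `E_binding` (kcal/mol), with the
#'   grid arg-min distance in `attr(, "min_distance")`.
#' @export
pes_scan <- function(manifest, label = NULL) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  if (is.null(manifest$points) || length(manifest$points) == 0)
    sqd_error("manifest has no grid points", "argument_error")
  if (is.null(manifest$unbound))
    sqd_error("manifest has no unbound reference", "argument_error")
  method <- if (is.null(manifest$method)) "casci" else manifest$method
  dists <- vapply(manifest$points, function(p) as.numeric(p$distance),
                  numeric(1))
  if (any(diff(dists) <= 0))
    sqd_error("grid distances must be strictly increasing", "argument_error")
  solve_point <- function(p, what) {
    H <- resolve_hamiltonian(if (!is.null(p$fcidump)) p$fcidump else p$H)
    if (method == "casci") {
      casci(H, compute_variance = FALSE)$energy
    } else if (method == "sqd") {
      t2 <- if (!is.null(p$t2)) {
        if (is.character(p$t2)) read_t2(p$t2) else p$t2
      } else if (identical(manifest$amplitudes %||% "mp2", "mp2")) {
        mp2_like_t2(H)
      } else {
        sqd_error(paste0("sqd point '", what, "' needs t2 amplitudes"),
                  "argument_error")
      }
      ans <- lucj_from_ccsd(t2, lucj_mask(H$M, manifest$mask %||% "dense"))
      cfg <- recovery_config(
        K = manifest$K %||% 10, batch_size = manifest$batch_size %||% 10000,
        iterations = manifest$steps %||% 10,
        energy_tol = manifest$energy_tol %||% 1e-6,
        seed = manifest$seed %||% 1)
      fit <- sqd(H, ans, shots = manifest$shots %||% 200000,
                 noise = noise_model(manifest$epsilon %||% 0.01,
                                     seed = (manifest$seed %||% 1) + 1),
                 config = cfg, sampler_seed = (manifest$seed %||% 1) + 2,
                 compute_variance = FALSE)
      fit$energy
    } else {
      sqd_error(paste0("unknown method '", method, "'"), "argument_error")
    }
  }
  E_unbound <- solve_point(manifest$unbound, "unbound")
  E_bound <- vapply(seq_along(manifest$points), function(i) {
    tryCatch(solve_point(manifest$points[[i]], sprintf("%.3f", dists[i])),
             sqdbinder_io_error = function(e) sqd_error(
               paste0("grid point ", sprintf("%.3f", dists[i]), ": ",
                      conditionMessage(e)), "missing_point_error"))
  }, numeric(1))
  out <- data.frame(distance = dists, E_bound = E_bound,
                    E_unbound = E_unbound,
                    E_binding = hartree_to_kcal(E_bound - E_unbound))
  structure(out, method = if (is.null(label)) method else label,
            min_distance = dists[which.min(E_bound)],
            class = c("binding_curve", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binding_curve <- function(x, ...) {
  cat(sprintf("Binding curve (%s), %d grid points:\n",
              attr(x, "method"), nrow(x)))
  print(data.frame(distance = x$distance,
                   E_binding_kcal = round(x$E_binding, 4)), row.names = FALSE)
  cat(sprintf("  minimum at %.3f Angstrom (grid arg-min)\n",
              attr(x, "min_distance")))
  invisible(x)
}

#' @export
plot.binding_curve <- function(x, ...) {
  plot(x$distance, x$E_binding, type = "b", pch = 19,
       xlab = "separation (Angstrom)", ylab = "binding energy (kcal/mol)",
       main = sprintf("Binding curve (%s)", attr(x, "method")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Write / read closed-shell doubles amplitudes as plain text
#'
#' Text exchange format for CCSD doubles amplitudes produced by an
#' external coupled-cluster engine: a header line `nocc nvirt` followed by
#' one `i j a b value` record per non-negligible amplitude (1-based
#' occupied/virtual indices).
#'
#' @param t2 array `(nocc, nocc, nvirt, nvirt)`.
#' @param path file path.
#' @return `write_t2`: `path` invisibly; `read_t2`: the amplitude array.
#' @export
write_t2 <- function(t2, path) {
  dm <- dim(t2)
  idx <- which(abs(t2) > 1e-14, arr.ind = TRUE)
  lines <- c(paste(dm[1], dm[3]),
             sprintf("%d %d %d %d %.16e", idx[, 1], idx[, 2], idx[, 3],
                     idx[, 4], t2[idx]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_t2
#' @export
read_t2 <- function(path) {
  if (!file.exists(path)) sqd_error(paste0("file not found: ", path), "io_error")
  txt <- readLines(path, warn = FALSE)
  hd <- as.integer(strsplit(trimws(txt[1]), "\\s+")[[1]])
  t2 <- array(0, c(hd[1], hd[1], hd[2], hd[2]))
  for (ln in txt[-1]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    t2[as.integer(f[1]), as.integer(f[2]), as.integer(f[3]),
       as.integer(f[4])] <- as.numeric(f[5])
  }
  t2
}
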