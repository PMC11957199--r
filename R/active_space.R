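## Integration boundary to an external electronic-structure engine for
## mean-field + atomic valence active space (AVAS) construction.  The
## engine is delegated; everything downstream of the returned Hamiltonian
## (or of an FCIDUMP file) is self-contained.

#' Active-space specification
#'
#' Describes a target active space by the atomic-orbital labels whose span
#' selects the active orbitals (AVAS-style), together with the intended
#' electron and orbital counts, e.g. `O[2s,2p], H[1s]` giving (16e,12o) for
#' the water dimer or `C[2s,2p,3s,3p], H[1s,2s]` giving (16e,24o) for the
#' methane dimer.
#'
#' @param ao_labels character vector of atomic-orbital labels, e.g.
#'   `c("O 2s", "O 2p", "H 1s")`.
#' @param n_electrons,n_orbitals target active-space size.
#' @return an object of class `"active_space_spec"`.
#' @export
active_space_spec <- function(ao_labels, n_electrons, n_orbitals) {
  n_orbitals <- as.integer(n_orbitals)
  n_electrons <- as.integer(n_electrons)
  if (n_orbitals < 1)
    sqd_error("n_orbitals must be >= 1", "argument_error")
  if (n_electrons > 2L * n_orbitals)
    sqd_error("n_electrons must be <= 2 * n_orbitals", "argument_error")
  structure(list(ao_labels = as.character(ao_labels),
                 n_electrons = n_electrons, n_orbitals = n_orbitals),
            class = "active_space_spec")
}

#' Build an active-space Hamiltonian through an external engine
#'
#' Delegates mean-field, AVAS orbital selection and integral transformation
#' to an external electronic-structure engine and reads the FCIDUMP file it
#' produces.  The engine is any executable accepting
#' `--xyz <file> --basis <name> --ao-labels <comma-list> --nelec <n>
#' --norb <n> --out <fcidump>`; its location is taken from `engine` or the
#' `SQDBINDER_ENGINE` environment variable.  When no engine is available
#' the function signals an error of class
#' `"sqdbinder_environment_error"`; the rest of the package is usable from
#' FCIDUMP files alone.
#'
#' @param geom an `"xyz_geometry"`.
#' @param spec an `"active_space_spec"`.
#' @param basis basis-set name (e.g. `"aug-cc-pVQZ"`).
#' @param engine path to the engine executable, or `""` to use
#'   `SQDBINDER_ENGINE`.
#' @return an `"as_hamiltonian"` with `spec$n_orbitals` orbitals and
#'   `spec$n_electrons` electrons; `E0` includes nuclear repulsion and
#'   inactive-orbital contributions.
#' @export
prepare_active_space <- function(geom, spec, basis,
                                 engine = Sys.getenv("SQDBINDER_ENGINE", "")) {
  stopifnot(inherits(geom, "xyz_geometry"), inherits(spec, "active_space_spec"))
  if (!nzchar(engine) || (Sys.which(engine) == "" && !file.exists(engine)))
    sqd_error(paste0(
      "no electronic-structure engine available (set SQDBINDER_ENGINE or ",
      "pass `engine`); use read_fcidump() on precomputed integrals instead"),
      "environment_error")
  xyz <- tempfile(fileext = ".xyz")
  out <- tempfile(fileext = ".fcidump")
  on.exit(unlink(c(xyz, out)), add = TRUE)
  write_xyz(geom, xyz)
  status <- system2(engine,
                    c("--xyz", shQuote(xyz), "--basis", shQuote(basis),
                      "--ao-labels", shQuote(paste(spec$ao_labels, collapse = ";")),
                      "--nelec", spec$n_electrons, "--norb", spec$n_orbitals,
                      "--out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out))
    sqd_error(paste0("engine '", engine, "' failed with status ", status),
              "environment_error")
  H <- read_fcidump(out)
  if (H$M != spec$n_orbitals || H$n_alpha + H$n_beta != spec$n_electrons)
    sqd_error(sprintf(
      "engine returned a (%de,%do) space; requested (%de,%do)",
      H$n_alpha + H$n_beta, H$M, spec$n_electrons, spec$n_orbitals),
      "environment_error")
  H
}
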