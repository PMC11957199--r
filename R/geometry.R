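## Molecular geometries (XYZ) and rigid dimer-separation scans.

#' Molecular geometry
#'
#' @param element character vector of element symbols.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param comment free-text comment (second line of an XYZ file).
#' @return an object of class `"xyz_geometry"` wrapping a data frame with
#'   columns `element`, `x`, `y`, `z`.
#' @export
geometry <- function(element, x, y, z, comment = "") {
  element <- as.character(element)
  if (any(!nzchar(element)))
    sqd_error("element symbols must be non-empty", "geometry_error")
  coords <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (any(!is.finite(coords)))
    sqd_error("coordinates must be finite", "geometry_error")
  structure(list(atoms = data.frame(element = element, x = coords[, 1],
                                    y = coords[, 2], z = coords[, 3],
                                    stringsAsFactors = FALSE),
                 comment = as.character(comment)[1]),
            class = "xyz_geometry")
}

#' @export
print.xyz_geometry <- function(x, ...) {
  cat(sprintf("Geometry: %d atoms (%s)\n", nrow(x$atoms),
              paste(x$atoms$element, collapse = " ")))
  if (nzchar(x$comment)) cat("  comment:", x$comment, "\n")
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' @param path path to an XYZ file (atom count, comment line, then one
#'   `element x y z` line per atom, coordinates in Angstrom).
#' @return an `"xyz_geometry"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) sqd_error(paste0("file not found: ", path), "io_error")
  txt <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(txt[1])))
  if (is.na(n) || length(txt) < n + 2)
    sqd_error("malformed XYZ file", "format_error")
  rows <- strsplit(trimws(txt[2 + seq_len(n)]), "\\s+")
  geometry(vapply(rows, `[`, "", 1),
           as.numeric(vapply(rows, `[`, "", 2)),
           as.numeric(vapply(rows, `[`, "", 3)),
           as.numeric(vapply(rows, `[`, "", 4)),
           comment = txt[2])
}

#' Write an XYZ geometry file
#'
#' @param geom an `"xyz_geometry"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path) {
  stopifnot(inherits(geom, "xyz_geometry"))
  a <- geom$atoms
  writeLines(c(nrow(a), geom$comment,
               sprintf("%-3s %18.10f %18.10f %18.10f", a$element, a$x, a$y, a$z)),
             path)
  invisible(path)
}

#' Distance between two atoms of a geometry
#' @param geom an `"xyz_geometry"`.
#' @param i,j 1-based atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(geom, i, j) {
  a <- geom$atoms
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

#' Rigidly translate one monomer along the anchor axis
#'
#' Translates monomer B as a rigid body along the axis from `anchor_a` (an
#' atom of monomer A) to `anchor_b` (an atom of monomer B) so that the
#' anchor-anchor distance equals `target_distance`.  The internal geometry
#' of each monomer is unchanged; this generates one-dimensional
#' dissociation scans and the far-separated (e.g. 48.000 Angstrom) unbound
#' reference of the supramolecular binding protocol.
#'
#' @param geom an `"xyz_geometry"` containing both monomers.
#' @param monomer_b_atoms integer indices of the atoms of monomer B.
#' @param anchor_a,anchor_b anchor atom indices (e.g. the two oxygens of a
#'   water dimer); `anchor_b` must belong to monomer B and `anchor_a` must
#'   not.
#' @param target_distance desired anchor separation in Angstrom.
#' @return a new `"xyz_geometry"`.
#' @export
translate_monomer <- function(geom, monomer_b_atoms, anchor_a, anchor_b,
                              target_distance) {
  stopifnot(inherits(geom, "xyz_geometry"))
  monomer_b_atoms <- as.integer(monomer_b_atoms)
  if (!(anchor_b %in% monomer_b_atoms))
    sqd_error("anchor_b must belong to monomer B", "geometry_error")
  if (anchor_a %in% monomer_b_atoms)
    sqd_error("anchor_a must not belong to monomer B", "geometry_error")
  a <- geom$atoms
  ra <- c(a$x[anchor_a], a$y[anchor_a], a$z[anchor_a])
  rb <- c(a$x[anchor_b], a$y[anchor_b], a$z[anchor_b])
  d0 <- sqrt(sum((rb - ra)^2))
  if (d0 <= 0)
    sqd_error("anchor atoms are coincident; translation axis undefined",
              "geometry_error")
  shift <- (target_distance - d0) * (rb - ra) / d0
  a$x[monomer_b_atoms] <- a$x[monomer_b_atoms] + shift[1]
  a$y[monomer_b_atoms] <- a$y[monomer_b_atoms] + shift[2]
  a$z[monomer_b_atoms] <- a$z[monomer_b_atoms] + shift[3]
  out <- geom
  out$atoms <- a
  out
}

#' Generate a rigid one-dimensional dissociation scan
#'
#' Applies [translate_monomer()] over a grid of anchor distances, returning
#' one geometry per grid point (plus, typically, a far-separated unbound
#' reference appended by the caller).
#'
#' @inheritParams translate_monomer
#' @param distances numeric vector of target anchor distances in Angstrom.
#' @return named list of `"xyz_geometry"` objects, one per distance.
#' @export
pes_geometries <- function(geom, monomer_b_atoms, anchor_a, anchor_b,
                           distances) {
  out <- lapply(distances, function(d)
    translate_monomer(geom, monomer_b_atoms, anchor_a, anchor_b, d))
  names(out) <- sprintf("%.3f", distances)
  out
}
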