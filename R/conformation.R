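# Conformation and ensemble containers. A conformation binds an atom table
# (identity, chemistry flags, module assignment, vdW radius) to Cartesian
# coordinates in Angstrom; an ensemble holds many frames of the same atom
# table as a bio3d-style xyz matrix (one row per frame).

new_conformation <- function(atoms, topology = NULL, frame = 1L) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "resno", "entity", "entity_label",
                  "module", "radius", "apolar", "donor", "acceptor",
                  "x", "y", "z") %in% names(atoms)))
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
      any(!is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$radius <= 0)) stop("non-positive van der Waals radius")
  structure(list(atoms = atoms, topology = topology, frame = frame),
            class = "conformation")
}

#' Extract the coordinate matrix of a conformation
#' @param conformation a `conformation`
#' @return n x 3 numeric matrix (Angstrom)
#' @export
coords <- function(conformation) {
  UseMethod("coords")
}

#' @export
coords.conformation <- function(conformation) {
  as.matrix(conformation$atoms[, c("x", "y", "z")])
}

#' @export
coords.default <- function(conformation) as.matrix(conformation)

set_coords <- function(conformation, xyz) {
  conformation$atoms[, c("x", "y", "z")] <- xyz
  conformation
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x$atoms), " atoms",
      if (!is.null(x$topology)) paste0(" (", x$topology$name, ")"),
      "\n", sep = "")
  invisible(x)
}

new_ensemble <- function(atoms, xyz, topology = NULL, frame_spacing = 1) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("an ensemble needs at least one frame")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz width does not match the atom count")
  structure(list(atoms = atoms, xyz = xyz, topology = topology,
                 n_frames = nrow(xyz), frame_spacing = frame_spacing),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("<conformation_ensemble> ", x$n_frames, " frames x ",
      nrow(x$atoms), " atoms",
      if (!is.null(x$topology)) paste0(" (", x$topology$name, ")"),
      "\n", sep = "")
  invisible(x)
}

frame_coords <- function(ensemble, frame) {
  if (frame < 1L || frame > ensemble$n_frames)
    stop("frame index out of range: ", frame)
  matrix(ensemble$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Extract one frame of an ensemble as a conformation
#' @param ensemble a `conformation_ensemble`
#' @param frame 1-based frame index
#' @return a `conformation`
#' @export
conformation_at <- function(ensemble, frame) {
  at <- ensemble$atoms
  at[, c("x", "y", "z")] <- frame_coords(ensemble, frame)
  new_conformation(at, ensemble$topology, frame = frame)
}

#' Wrap a single conformation as a one-frame ensemble
#' @param conformation a `conformation`
#' @return a `conformation_ensemble`
#' @export
as_ensemble <- function(conformation) {
  stopifnot(inherits(conformation, "conformation"))
  new_ensemble(conformation$atoms,
               matrix(t(coords(conformation)), nrow = 1L),
               conformation$topology)
}
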