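# Core geometric computations: vector helpers, internal-coordinate placement,
# Kabsch superposition, radius of gyration, dihedrals and the
# Ramachandran-rule secondary-structure assignment.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

# Place atom D bonded to C with |CD| = bond, angle(B,C,D) = angle and
# dihedral(A,B,C,D) = torsion (degrees). Standard natural-extension
# (NeRF-style) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Signed dihedral angle (degrees) for four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two matched coordinate sets; reflections are excluded by construction.
#'
#' @param mobile,reference numeric matrices (n x 3) of matched coordinates
#' @param selection optional integer/logical row selection applied to both
#' @return an object of class `superposition`: list with `rotation`
#'   (3 x 3 proper orthonormal matrix), `translation` (length-3 vector;
#'   the transform is `x %*% rotation + translation`), and `rmsd`
#'   (Angstrom, over the selection).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(x, x)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.null(selection)) {
    mobile <- mobile[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (!identical(dim(mobile), dim(reference)))
    stop("coordinate sets must have matching dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  s <- svd(crossprod(X, Y))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2L)
    stop("degenerate (collinear or duplicate) selection")
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = cr - cm %*% R, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 4), "Angstrom\n")
  invisible(x)
}

#' Per-frame RMSD series of an ensemble against a reference conformation
#'
#' Each frame is superposed on the reference by [kabsch_superpose()] over
#' the selection (default: backbone CA atoms) before the RMSD is taken.
#'
#' @param ensemble a `conformation_ensemble`
#' @param reference a `conformation` or a frame index into `ensemble`
#'   (default: first frame)
#' @param selection atom selection: `"CA"` (default), `"backbone"`,
#'   `"all"`, or an integer/logical index into the atom table
#' @return list with `rmsd` (per-frame vector, Angstrom) and `mean`
#' @export
rmsd_series <- function(ensemble, reference = 1L, selection = "CA") {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  sel <- resolve_selection(ensemble$atoms, selection)
  if (is.numeric(reference) && length(reference) == 1L) {
    ref_xyz <- frame_coords(ensemble, reference)
  } else {
    stopifnot(inherits(reference, "conformation"))
    ref_xyz <- coords(reference)
  }
  r <- vapply(seq_len(ensemble$n_frames), function(f)
    kabsch_superpose(frame_coords(ensemble, f), ref_xyz, sel)$rmsd, 0)
  list(rmsd = r, mean = mean(r))
}

#' Radius of gyration
#'
#' Mass-unweighted root-mean-square distance of the selected atoms from
#' their centroid.
#'
#' @param conformation a `conformation` or an n x 3 coordinate matrix
#' @param selection atom selection (see [rmsd_series()]); ignored for bare
#'   matrices
#' @return radius of gyration in Angstrom
#' @export
radius_of_gyration <- function(conformation, selection = "all") {
  if (inherits(conformation, "conformation")) {
    sel <- resolve_selection(conformation$atoms, selection)
    x <- coords(conformation)[sel, , drop = FALSE]
  } else x <- as.matrix(conformation)
  if (nrow(x) < 1L) stop("empty selection")
  sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
}

# Ramachandran rectangles used by the secondary-structure rule, degrees.
.SS_REGIONS <- list(
  H = list(phi = c(-100, -30), psi = c(-80, -5)),
  E = list(phi = c(-180, -45), psi = c(90, 180)))

#' Backbone secondary-structure assignment by Ramachandran-region rule
#'
#' Assigns `H` (helix), `E` (extended/strand) or `C` (coil) per residue from
#' backbone (phi, psi) torsions using fixed rectangular regions (helix:
#' phi in \[-100, -30\], psi in \[-80, -5\]; strand: phi in \[-180, -45\],
#' psi in \[90, 180\]). This hydrogen-free rule replaces a full DSSP
#' assignment. Chain termini, where phi or psi is undefined, are labelled
#' `C`.
#'
#' @param conformation a `conformation` with backbone N, CA, C atoms
#' @return character vector of per-residue labels
#' @export
assign_secondary_structure <- function(conformation) {
  stopifnot(inherits(conformation, "conformation"))
  at <- conformation$atoms
  res_idx <- sort(unique(at$resno[at$entity == "res"]))
  xyz <- coords(conformation)
  bb <- function(i, name) {
    j <- which(at$entity == "res" & at$resno == i & at$name == name)
    if (length(j) != 1L) stop("missing backbone atom ", name,
                              " in residue ", i)
    xyz[j, ]
  }
  n <- length(res_idx)
  lab <- rep("C", n)
  if (n >= 3L) for (k in 2:(n - 1L)) {
    i <- res_idx[k]
    phi <- dihedral_angle(bb(res_idx[k - 1L], "C"), bb(i, "N"),
                          bb(i, "CA"), bb(i, "C"))
    psi <- dihedral_angle(bb(i, "N"), bb(i, "CA"), bb(i, "C"),
                          bb(res_idx[k + 1L], "N"))
    for (s in names(.SS_REGIONS)) {
      r <- .SS_REGIONS[[s]]
      if (phi >= r$phi[1] && phi <= r$phi[2] &&
          psi >= r$psi[1] && psi <= r$psi[2]) { lab[k] <- s; break }
    }
  }
  names(lab) <- res_idx
  lab
}

# Resolve an atom selection against an atom table.
resolve_selection <- function(atoms, selection) {
  if (is.numeric(selection) || is.logical(selection)) return(selection)
  switch(selection,
    CA = which(atoms$name == "CA" & atoms$entity == "res"),
    backbone = which(atoms$name %in% c("N", "CA", "C", "O") &
                       atoms$entity == "res"),
    all = seq_len(nrow(atoms)),
    stop("unknown selection: ", selection))
}
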