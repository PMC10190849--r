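# Shrake-Rupley solvent-accessible surface area with a deterministic
# generalized-spiral sample lattice (no RNG), so repeated runs are
# bit-identical for a fixed point count.

#' Options for SASA computation
#'
#' @param probe probe (solvent) radius in Angstrom; 1.4 approximates water
#' @param n_points number of sample points per atom sphere (>= 2); more
#'   points reduce the lattice discretisation error roughly as 1/n
#' @param radii identifier of the bundled van der Waals radii table
#' @return a list of class `sasa_options`
#' @export
sasa_options <- function(probe = 1.4, n_points = 960L, radii = "bondi") {
  stopifnot(probe >= 0, n_points >= 2L)
  structure(list(probe = probe, n_points = as.integer(n_points),
                 radii = radii), class = "sasa_options")
}

# Deterministic generalized spiral on the unit sphere
# (Rakhmanov-Saff-Zhou construction).
spiral_lattice <- function(n) {
  key <- paste0("spiral", n)
  cached <- .pepconj_cache[[key]]
  if (!is.null(cached)) return(cached)
  k <- seq_len(n)
  h <- -1 + 2 * (k - 1) / (n - 1)
  theta <- acos(pmin(1, pmax(-1, h)))
  phi <- numeric(n)
  if (n > 2L) for (i in 2:(n - 1L))
    phi[i] <- (phi[i - 1L] + 3.6 / sqrt(n * (1 - h[i]^2))) %% (2 * pi)
  pts <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  .pepconj_cache[[key]] <- pts
  pts
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals spheres of all atoms: for
#' each atom, sample points on the expanded sphere of radius
#' `r + probe` are tested against every neighbouring expanded sphere, and
#' the accessible fraction scales the expanded-sphere area. The sample
#' lattice is a deterministic generalized spiral, so results carry no
#' Monte-Carlo noise. Coincident atoms of equal radius mutually occlude
#' (each point lies exactly on the other's expanded sphere, and boundary
#' points count as buried).
#'
#' @param conformation a `conformation`, or an n x 3 coordinate matrix (in
#'   which case `radii` must be supplied)
#' @param options a [sasa_options()] list
#' @param radii per-atom van der Waals radii (Angstrom), required for bare
#'   coordinate matrices
#' @return numeric vector of per-atom areas in Angstrom^2
#' @examples
#' # isolated carbon: 4*pi*(1.7 + 1.4)^2 ~ 120.76 A^2
#' sasa(matrix(0, 1, 3), radii = 1.7)
#' @export
sasa <- function(conformation, options = sasa_options(), radii = NULL) {
  if (inherits(conformation, "conformation")) {
    xyz <- coords(conformation)
    radii <- conformation$atoms$radius
  } else {
    xyz <- as.matrix(conformation)
    if (is.null(radii)) stop("radii must be supplied for bare coordinates")
    radii <- rep_len(radii, nrow(xyz))
  }
  n <- nrow(xyz)
  if (n == 0L) return(numeric(0))
  R <- radii + options$probe
  pts <- spiral_lattice(options$n_points)
  m <- nrow(pts)

  # neighbour lists from the full distance matrix (systems here are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (R[i] + R)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, m)
    for (j in nb) {
      if (!any(accessible)) break
      dx <- p[accessible, 1L] - xyz[j, 1L]
      dy <- p[accessible, 2L] - xyz[j, 2L]
      dz <- p[accessible, 3L] - xyz[j, 3L]
      # boundary points count as buried (coincident equal atoms occlude
      # each other completely); tolerance absorbs round-off on the sphere
      accessible[accessible] <- (dx * dx + dy * dy + dz * dz) >
        R[j]^2 + 1e-9
    }
    out[i] <- 4 * pi * R[i]^2 * sum(accessible) / m
  }
  out
}
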