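# Synthetic conformation generator: ideal-geometry backbones in helix /
# hairpin / extended motifs, default-rotamer side chains, grafted ligand
# templates, planted contacts and Gaussian-perturbed ensembles. These
# generators stand in for molecular-dynamics trajectories, which this
# package treats as opaque external inputs.

# Idealized backbone parameters (Angstrom / degrees).
.BB <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_C_OXT = 1.25, b_CA_CB = 1.53,
  a_N_CA_C = 111.2, a_CA_C_N = 116.6, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_CA_C_OXT = 117.0, a_N_CA_CB = 110.5,
  t_CB = -122.0, omega = 180)

# Motif (phi, psi) defaults.
.MOTIFS <- list(
  helix = c(-60, -45),
  extended = c(-135, 135),
  strand = c(-139, 135))

motif_phi_psi <- function(motif, n) {
  motif <- match.arg(motif, c("helix", "hairpin", "extended"))
  if (motif == "hairpin") {
    # antiparallel strands joined by a two-residue type-I' turn
    phi <- rep(.MOTIFS$strand[1], n)
    psi <- rep(.MOTIFS$strand[2], n)
    if (n >= 4L) {
      t1 <- ceiling(n / 2)
      phi[t1] <- 60; psi[t1] <- 30
      if (t1 + 1L <= n) { phi[t1 + 1L] <- 90; psi[t1 + 1L] <- 0 }
    }
  } else {
    pp <- .MOTIFS[[motif]]
    phi <- rep(pp[1], n); psi <- rep(pp[2], n)
  }
  list(phi = phi, psi = psi)
}

#' Build an ideal-geometry conformation for a conjugate topology
#'
#' Constructs backbone heavy atoms (N, CA, C, O, plus OXT at the
#' C-terminus) by natural extension with idealized bond lengths and angles,
#' places side chains at default rotamers from the bundled internal
#' coordinate table, grafts ligand templates at their anchors, and assigns
#' van der Waals radii, apolar flags, hydrogen-bond donor/acceptor flags
#' and formal charge groups (Lys/Arg side chains and the free N-terminus
#' cationic; Asp/Glu side chains, the free C-terminus and ligand sulfonate/
#' carboxylate groups anionic). Hydrogens are omitted; all detectors in
#' this package operate on heavy atoms.
#'
#' The construction is fully deterministic: the same recipe always yields
#' identical coordinates.
#'
#' @param topology a `conjugate_topology`
#' @param motif backbone motif: `"helix"`, `"hairpin"` or `"extended"`
#'   (default: the topology's registry motif, else `"extended"`)
#' @param phi,psi optional per-residue torsion overrides (degrees,
#'   recycled); `NA` entries fall back to the motif value
#' @return a `conformation`
#' @examples
#' conf <- build_conformation(get_design("Pbeta"), motif = "hairpin")
#' table(assign_secondary_structure(conf))
#' @export
build_conformation <- function(topology, motif = NULL, phi = NULL,
                               psi = NULL) {
  stopifnot(inherits(topology, "conjugate_topology"))
  res <- topology$residues
  n <- nrow(res)
  if (is.null(motif)) motif <- if (is.null(topology$motif)) "extended"
                               else topology$motif
  tors <- motif_phi_psi(motif, n)
  if (!is.null(phi)) {
    phi <- rep_len(phi, n); tors$phi[!is.na(phi)] <- phi[!is.na(phi)]
  }
  if (!is.null(psi)) {
    psi <- rep_len(psi, n); tors$psi[!is.na(psi)] <- psi[!is.na(psi)]
  }

  zmat <- sidechain_zmat()
  atoms <- list()   # rows collected per atom
  bonds <- list()   # character keys "resno|name" pairs
  pos <- list()     # "resno|name" -> coordinates
  key <- function(i, nm) paste0(i, "|", nm)
  add_bond <- function(i1, n1, i2, n2)
    bonds[[length(bonds) + 1L]] <<- c(key(i1, n1), key(i2, n2))
  add_atom <- function(i, nm, el, p) {
    pos[[key(i, nm)]] <<- p
    atoms[[length(atoms) + 1L]] <<- list(resno = i, name = nm, element = el,
                                         x = p[1], y = p[2], z = p[3])
  }

  for (i in seq_len(n)) {
    if (i == 1L) {
      Npos <- c(0, 0, 0)
      CApos <- c(.BB$b_N_CA, 0, 0)
      th <- .BB$a_N_CA_C * pi / 180
      Cpos <- CApos + .BB$b_CA_C * c(-cos(th), sin(th), 0)
    } else {
      Npos <- place_atom(pos[[key(i - 1L, "N")]], pos[[key(i - 1L, "CA")]],
                         pos[[key(i - 1L, "C")]], .BB$b_C_N, .BB$a_CA_C_N,
                         tors$psi[i - 1L])
      CApos <- place_atom(pos[[key(i - 1L, "CA")]], pos[[key(i - 1L, "C")]],
                          Npos, .BB$b_N_CA, .BB$a_C_N_CA, .BB$omega)
      Cpos <- place_atom(pos[[key(i - 1L, "C")]], Npos, CApos,
                         .BB$b_CA_C, .BB$a_N_CA_C, tors$phi[i])
      add_bond(i - 1L, "C", i, "N")
    }
    add_atom(i, "N", "N", Npos)
    add_atom(i, "CA", "C", CApos)
    add_atom(i, "C", "C", Cpos)
    add_bond(i, "N", i, "CA"); add_bond(i, "CA", i, "C")
    Opos <- place_atom(Npos, CApos, Cpos, .BB$b_C_O, .BB$a_CA_C_O,
                       tors$psi[i] + 180)
    add_atom(i, "O", "O", Opos)
    add_bond(i, "C", i, "O")
    if (res$is_C_terminal[i]) {
      add_atom(i, "OXT", "O",
               place_atom(Npos, CApos, Cpos, .BB$b_C_OXT, .BB$a_CA_C_OXT,
                          tors$psi[i]))
      add_bond(i, "C", i, "OXT")
    }
    code3 <- res$code3[i]
    if (code3 != "GLY") {
      CBpos <- place_atom(Cpos, Npos, CApos, .BB$b_CA_CB, .BB$a_N_CA_CB,
                          .BB$t_CB)
      add_atom(i, "CB", "C", CBpos)
      add_bond(i, "CA", i, "CB")
      rows <- zmat[zmat$resid == code3, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        z <- rows[r, ]
        p <- place_atom(pos[[key(i, z$ggp)]], pos[[key(i, z$gp)]],
                        pos[[key(i, z$parent)]], z$bond, z$angle, z$torsion)
        add_atom(i, z$atom, substr(z$atom, 1L, 1L), p)
        add_bond(i, z$parent, i, z$atom)
      }
    }
  }

  at <- do.call(rbind, lapply(atoms, as.data.frame))
  at$entity <- "res"
  at$resid3 <- res$code3[at$resno]
  at$entity_label <- paste0(at$resid3, at$resno)
  at$module <- res$module[at$resno]

  # chemistry flags for residue atoms
  at$donor <- at$acceptor <- FALSE
  at$charge_group <- NA_character_
  at$charge_sign <- 0L
  for (i in seq_len(n)) {
    code3 <- res$code3[i]
    sel <- at$resno == i
    lbl <- at$entity_label[sel][1]
    nm <- at$name
    at$donor[sel & nm == "N" & code3 != "PRO"] <- TRUE
    at$acceptor[sel & nm %in% c("O", "OXT")] <- TRUE
    d <- .SC_DONORS[[code3]]
    if (!is.null(d)) at$donor[sel & nm %in% d] <- TRUE
    a <- .SC_ACCEPTORS[[code3]]
    if (!is.null(a)) at$acceptor[sel & nm %in% a] <- TRUE
    cg <- .SC_CHARGE[[code3]]
    if (!is.null(cg)) {
      at$charge_group[sel & nm %in% cg$atoms] <- paste0(lbl, ":SC")
      at$charge_sign[sel & nm %in% cg$atoms] <- cg$sign
    }
    if (res$is_N_terminal[i]) {
      at$charge_group[sel & nm == "N"] <- paste0(lbl, ":NT")
      at$charge_sign[sel & nm == "N"] <- 1L
      at$donor[sel & nm == "N"] <- TRUE
    }
    if (res$is_C_terminal[i]) {
      at$charge_group[sel & nm %in% c("O", "OXT")] <- paste0(lbl, ":CT")
      at$charge_sign[sel & nm %in% c("O", "OXT")] <- -1L
    }
  }

  # graft ligands
  templates <- ligand_registry()
  lig_no <- n
  for (l in topology$ligands) {
    lig_no <- lig_no + 1L
    tmpl <- templates[[l$template]]
    anchor <- anchor_atom_name(res$code3[l$anchor_residue], l$site, zmat)
    akey <- key(l$anchor_residue, anchor$atom)
    if (is.null(pos[[akey]]))
      stop("ligand anchor atom ", anchor$atom, " missing in residue ",
           l$anchor_residue)
    apos <- pos[[akey]]
    ppos <- pos[[key(l$anchor_residue, anchor$parent)]]
    u <- unitv(apos - ppos)
    lxyz <- as.matrix(tmpl$atoms[, c("x", "y", "z")])
    link_i <- match(tmpl$link_atom, tmpl$atoms$name)
    ctr <- colMeans(lxyz)
    tdir <- ctr - lxyz[link_i, ]
    if (vnorm(tdir) < 1e-8) tdir <- c(1, 0, 0)
    R <- rotation_between(unitv(tdir), u)
    lxyz <- sweep(lxyz, 2, lxyz[link_i, ]) %*% t(R)
    lxyz <- sweep(lxyz, 2, apos + tmpl$link_bond * u, "+")

    # conjugation consumes the anchor's amine/thiol/carboxylate chemistry
    ak <- at$resno == l$anchor_residue & at$name == anchor$atom
    at$donor[ak] <- FALSE
    at$charge_group[ak] <- NA_character_; at$charge_sign[ak] <- 0L
    if (anchor$atom == "C") {  # C-terminal conjugation: no free carboxylate
      ck <- at$resno == l$anchor_residue & at$name %in% c("O", "OXT")
      at$charge_group[ck] <- NA_character_; at$charge_sign[ck] <- 0L
    }

    lat <- tmpl$atoms
    lat$x <- lxyz[, 1]; lat$y <- lxyz[, 2]; lat$z <- lxyz[, 3]
    lat <- data.frame(resno = lig_no, name = lat$name, element = lat$element,
                      x = lat$x, y = lat$y, z = lat$z,
                      entity = "lig", resid3 = l$template,
                      entity_label = l$label, module = l$module,
                      donor = lat$donor, acceptor = lat$acceptor,
                      charge_group = ifelse(is.na(lat$group), NA_character_,
                                            paste0(l$label, ":", lat$group)),
                      charge_sign = lat$sign,
                      stringsAsFactors = FALSE)
    lat$apolar_tmpl <- tmpl$atoms$apolar
    for (r in seq_len(nrow(lat)))
      pos[[key(lig_no, lat$name[r])]] <- lxyz[r, ]
    for (b in tmpl$bonds %||% list())
      add_bond(lig_no, b[[1]], lig_no, b[[2]])
    bonds[[length(bonds) + 1L]] <- c(akey, key(lig_no, tmpl$link_atom))
    at <- rbind_atom_tables(at, lat)
  }

  # apolar flag: carbon/sulfur not bonded to nitrogen or oxygen; ligand
  # atoms keep their template assignment
  akeys <- key(at$resno, at$name)
  el <- setNames(at$element, akeys)
  polar_nb <- setNames(rep(FALSE, nrow(at)), akeys)
  for (b in bonds) {
    if (el[b[1]] %in% c("N", "O")) polar_nb[b[2]] <- TRUE
    if (el[b[2]] %in% c("N", "O")) polar_nb[b[1]] <- TRUE
  }
  at$apolar <- at$element %in% c("C", "S") & !polar_nb[akeys]
  if ("apolar_tmpl" %in% names(at)) {
    tl <- !is.na(at$apolar_tmpl)
    at$apolar[tl] <- at$apolar_tmpl[tl]
    at$apolar_tmpl <- NULL
  }

  at$radius <- vdw_radius(at$element)
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  new_conformation(at[, c("serial", "name", "element", "resno", "resid3",
                          "entity", "entity_label", "module", "radius",
                          "apolar", "donor", "acceptor", "charge_group",
                          "charge_sign", "x", "y", "z")], topology)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbind_atom_tables <- function(a, b) {
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  rbind(a, b[names(a)])
}

# Anchor atom for a ligand site on a given residue type: side_chain uses the
# terminal side-chain heavy atom (SG for Cys, NZ for Lys, ...).
anchor_atom_name <- function(code3, site, zmat) {
  if (site == "N_term") return(list(atom = "N", parent = "CA"))
  if (site == "C_term") return(list(atom = "C", parent = "CA"))
  rows <- zmat[zmat$resid == code3, , drop = FALSE]
  if (!nrow(rows)) {
    if (code3 == "GLY") stop("glycine has no side-chain anchor")
    return(list(atom = "CB", parent = "CA"))
  }
  last <- rows[nrow(rows), ]
  list(atom = last$atom, parent = last$parent)
}

# Proper rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- vcross(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(vcross(a, p))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

#' Plant non-covalent contacts into a conformation
#'
#' Moves designated atoms so that each requested contact satisfies its
#' detector criterion by a margin, then re-detects and verifies that (a)
#' every planted contact is found and (b) no unplanted contact of the same
#' kind exists between the entities named in the plant list. Atom
#' placement explores a deterministic set of candidate directions around
#' the stationary partner and keeps the position farthest from all other
#' atoms, so planting one contact does not silently create another.
#'
#' @param conformation a `conformation`
#' @param plants a list of plant records, each a list with elements
#'   `kind` (`"hbond"`, `"saltbridge"` or `"hydrophobic"`), `a`, `b`
#'   (entity labels such as `"PHE16"` or `"Cy"`), optional `atom_a`,
#'   `atom_b` (atom names; defaults pick the first suitable donor/
#'   acceptor/charged/apolar atom), optional `distance` (Angstrom;
#'   defaults: 2.9 hbond, 3.8 salt bridge, 4.0 hydrophobic) and optional
#'   `move` (`"a"` or `"b"`, which partner's atom is relocated;
#'   default `"a"`)
#' @param criteria detector criteria, see [interaction_criteria()]
#' @return the modified `conformation`
#' @export
plant_contacts <- function(conformation, plants,
                           criteria = interaction_criteria()) {
  stopifnot(inherits(conformation, "conformation"))
  if (!length(plants)) return(conformation)
  at <- conformation$atoms
  xyz <- coords(conformation)

  find_atom <- function(label, atom, kind, role) {
    sel <- which(at$entity_label == label)
    if (!length(sel)) stop("no residue or ligand labelled ", label)
    if (!is.null(atom)) {
      j <- sel[at$name[sel] == atom]
      if (length(j) != 1L) stop("atom ", atom, " not found in ", label)
      return(j)
    }
    pick <- switch(kind,
      hbond = if (role == "a") sel[at$donor[sel]] else sel[at$acceptor[sel]],
      saltbridge = if (role == "a") sel[at$charge_sign[sel] > 0]
                   else sel[at$charge_sign[sel] < 0],
      hydrophobic = sel[at$apolar[sel]])
    if (!length(pick)) stop("no suitable ", kind, " atom in ", label)
    pick[1]
  }

  default_d <- c(hbond = 2.9, saltbridge = 3.8, hydrophobic = 4.0)
  planted <- list()
  for (p in plants) {
    kind <- match.arg(p$kind, c("hbond", "saltbridge", "hydrophobic"))
    ia <- find_atom(p$a, p$atom_a, kind, "a")
    ib <- find_atom(p$b, p$atom_b, kind, "b")
    d <- p$distance %||% default_d[[kind]]
    move <- match.arg(p$move %||% "a", c("a", "b"))
    mover <- if (move == "a") ia else ib
    anchor <- if (move == "a") ib else ia
    cur <- vnorm(xyz[mover, ] - xyz[anchor, ])
    if (abs(cur - d) > 1e-9) {
      dirs <- spiral_lattice(64L)
      cand <- sweep(dirs * d, 2, xyz[anchor, ], "+")
      others <- setdiff(seq_len(nrow(xyz)), c(mover, anchor))
      sep <- apply(cand, 1L, function(q)
        min(sqrt(colSums((t(xyz[others, , drop = FALSE]) - q)^2))))
      xyz[mover, ] <- cand[which.max(sep), ]
    }
    planted[[length(planted) + 1L]] <-
      list(kind = kind, a = p$a, b = p$b, ia = ia, ib = ib, distance = d)
  }
  conformation$atoms[, c("x", "y", "z")] <- xyz

  # verification by re-detection, restricted to the planted entities
  mentioned <- unique(unlist(lapply(planted, function(p) c(p$a, p$b))))
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  want <- unique(vapply(planted, function(p)
    paste(p$kind, pair_key(p$a, p$b)), ""))
  got <- character(0)
  kinds <- unique(vapply(planted, `[[`, "", "kind"))
  for (kind in kinds) {
    rec <- switch(kind,
      hbond = detect_hbonds(conformation, criteria),
      saltbridge = detect_salt_bridges(conformation, criteria),
      hydrophobic = hydrophobic_contact_atoms(conformation,
        criteria = criteria)$records)
    if (nrow(rec)) {
      keep <- rec$a %in% mentioned & rec$b %in% mentioned
      got <- c(got, paste(kind, pair_key(rec$a[keep], rec$b[keep])))
    }
  }
  got <- unique(got)
  missing <- setdiff(want, got)
  extra <- setdiff(got, want)
  if (length(missing) || length(extra))
    stop("infeasible plant: ",
         if (length(missing)) paste0("not realised: ",
                                     paste(missing, collapse = "; "), ". "),
         if (length(extra)) paste0("unplanned contacts created: ",
                                   paste(extra, collapse = "; ")))
  conformation
}

#' Gaussian-perturbed conformational ensemble
#'
#' Emulates thermal fluctuation around a relaxed structure: frame 1 is the
#' input conformation, and every later frame adds i.i.d. Gaussian
#' displacements (standard deviation `amplitude` per Cartesian component)
#' to every atom. For large ensembles the mean all-atom RMSD of perturbed
#' frames against the input approaches `amplitude * sqrt(3)`.
#'
#' @param conformation a `conformation`
#' @param amplitude per-component displacement standard deviation, Angstrom
#' @param n_frames total number of frames (including the unperturbed first)
#' @param seed integer seed; identical seeds give identical ensembles
#' @return a `conformation_ensemble`
#' @export
perturb_ensemble <- function(conformation, amplitude = 0.3, n_frames = 20L,
                             seed = NULL) {
  stopifnot(inherits(conformation, "conformation"),
            amplitude >= 0, n_frames >= 1L)
  base <- as.numeric(t(coords(conformation)))
  if (!is.null(seed)) set.seed(seed)
  xyz <- matrix(rep(base, each = n_frames), nrow = n_frames)
  if (n_frames > 1L && amplitude > 0) {
    for (f in 2:n_frames)
      xyz[f, ] <- base + rnorm(length(base), 0, amplitude)
  }
  new_ensemble(conformation$atoms, xyz, conformation$topology)
}

#' Worked-example fixtures with the published contact networks planted
#'
#' Builds an extended-motif conformation of `Pbeta` or `Pbeta_R4C` and
#' plants the interaction network reported for that design in the source
#' interaction analysis: for Pbeta, four hydrogen bonds
#' (PHE16:PRO3, VAL14:ALA5, LYS7:LYS12, ALA5:VAL14) and two salt bridges
#' (LYS12:ASP11, LYS7:GLU9); for Pbeta_R4C, six inter-module hydrogen
#' bonds (Cy:ASP11, LYS12:Cy, ALA17:VAL2, ALA1:Cy, GLN6:VAL14,
#' ILE4:PHE15), three inter-module salt bridges (LYS12:Cy, LYS12:ASP11,
#' ALA1:Cy), one intra-module salt bridge (LYS7:GLU9) and a hydrophobic
#' R1-on-assembly-module burial. Salt-bridge-only pairs are planted at
#' 3.8 Angstrom (inside the salt-bridge cutoff, outside the hydrogen-bond
#' cutoff); pairs the analysis lists under both interaction kinds
#' (LYS12:Cy, ALA1:Cy) are planted at 2.9 Angstrom.
#'
#' @param design `"Pbeta"` or `"Pbeta_R4C"`
#' @param criteria an [interaction_criteria()] list
#' @return list with `conformation`, `hbond_pairs`, `saltbridge_pairs`
#'   (expected unordered entity pairs as two-column data frames) and
#'   `saltbridge_scope` (`"inter"`/`"intra"` per pair)
#' @export
worked_example_fixture <- function(design = c("Pbeta", "Pbeta_R4C"),
                                   criteria = interaction_criteria()) {
  design <- match.arg(design)
  conf <- build_conformation(get_design(design), motif = "extended")
  hb <- function(a, b, atom_a = NULL, atom_b = NULL, move = "a")
    list(kind = "hbond", a = a, b = b, atom_a = atom_a, atom_b = atom_b,
         distance = 2.9, move = move)
  sb <- function(a, b, atom_a = NULL, atom_b = NULL, move = "a",
                 distance = 3.8)
    list(kind = "saltbridge", a = a, b = b, atom_a = atom_a,
         atom_b = atom_b, distance = distance, move = move)
  if (design == "Pbeta") {
    plants <- list(
      hb("PHE16", "PRO3", "N", "O"),
      hb("VAL14", "ALA5", "N", "O"),
      hb("LYS7", "LYS12", "NZ", "O"),
      hb("ALA5", "VAL14", "N", "O"),
      sb("LYS12", "ASP11", "NZ", "OD1"),
      sb("LYS7", "GLU9", "NZ", "OE1", move = "b"))
    conf <- plant_contacts(conf, plants, criteria)
    hbp <- rbind(c("PHE16", "PRO3"), c("VAL14", "ALA5"),
                 c("LYS7", "LYS12"), c("ALA5", "VAL14"))
    sbp <- rbind(c("LYS12", "ASP11"), c("LYS7", "GLU9"))
    scope <- c("inter", "intra")   # ASM:R1 boundary pair vs within-R1
  } else {
    plants <- list(
      hb("ASP11", "Cy", "N", "O1"),
      hb("LYS12", "Cy", "NZ", "O4"),
      hb("ALA1", "Cy", "N", "O2"),
      hb("ALA17", "VAL2", "N", "O"),
      hb("GLN6", "VAL14", "NE2", "O"),
      hb("ILE4", "PHE15", "N", "O"),
      sb("LYS12", "Cy", "NZ", "O4", distance = 2.9),
      sb("ALA1", "Cy", "N", "O2", distance = 2.9),
      sb("LYS12", "ASP11", "NZ", "OD1", move = "b"),
      sb("LYS7", "GLU9", "NZ", "OE1"))
    conf <- plant_contacts(conf, plants, criteria)
    # hydrophobic R1-on-ASM burial, planted separately
    conf <- plant_contacts(conf, list(
      list(kind = "hydrophobic", a = "ILE4", b = "GLU18",
           atom_a = "CD1", atom_b = "CG", distance = 4.0, move = "a"),
      list(kind = "hydrophobic", a = "ALA5", b = "LYS12",
           atom_a = "CB", atom_b = "CD", distance = 4.0, move = "a")),
      criteria)
    hbp <- rbind(c("ASP11", "Cy"), c("LYS12", "Cy"), c("ALA1", "Cy"),
                 c("ALA17", "VAL2"), c("GLN6", "VAL14"),
                 c("ILE4", "PHE15"))
    sbp <- rbind(c("LYS12", "Cy"), c("ALA1", "Cy"), c("LYS12", "ASP11"),
                 c("LYS7", "GLU9"))
    scope <- c("inter", "inter", "inter", "intra")
  }
  list(conformation = conf,
       hbond_pairs = data.frame(a = hbp[, 1], b = hbp[, 2],
                                stringsAsFactors = FALSE),
       saltbridge_pairs = data.frame(a = sbp[, 1], b = sbp[, 2],
                                     stringsAsFactors = FALSE),
       saltbridge_scope = scope)
}
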