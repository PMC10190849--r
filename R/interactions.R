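# Non-covalent interaction detectors (hydrogen bonds, salt bridges,
# hydrophobic contacts) and their aggregation into module-pair landscapes
# and contact-lifetime series.

#' Geometric criteria for contact detection
#'
#' The source literature on assembly-motif conjugates does not fix
#' geometric definitions, so these defaults are common conventions,
#' recorded in every report rather than inferred values: donor-acceptor
#' heavy-atom distance <= 3.5 Angstrom for hydrogen bonds (angle screening
#' would apply only when hydrogens are modelled; all generators here are
#' heavy-atom only, so detection is distance-based and flagged as such),
#' minimum distance between opposite formal charge groups <= 4.0 Angstrom
#' for salt bridges, apolar-atom pair distance <= 5.0 Angstrom for
#' hydrophobic contacts, and a minimum residue separation of 2 for
#' hydrogen-bond and hydrophobic pairs (salt bridges are restricted to
#' formal charge groups and may involve adjacent residues).
#'
#' @param hbond_dmax donor-acceptor heavy-atom cutoff, Angstrom
#' @param hbond_angle_min donor-H-acceptor angle floor, degrees (recorded;
#'   applied only to structures that model hydrogens)
#' @param saltbridge_dmax charge-group minimum-distance cutoff, Angstrom
#' @param hydrophobic_dmax apolar pair cutoff, Angstrom
#' @param min_seq_sep minimum |i - j| between residues for hydrogen-bond
#'   and hydrophobic pairs
#' @return a list of class `interaction_criteria`
#' @export
interaction_criteria <- function(hbond_dmax = 3.5, hbond_angle_min = 130,
                                 saltbridge_dmax = 4.0,
                                 hydrophobic_dmax = 5.0,
                                 min_seq_sep = 2L) {
  structure(list(hbond_dmax = hbond_dmax, hbond_angle_min = hbond_angle_min,
                 saltbridge_dmax = saltbridge_dmax,
                 hydrophobic_dmax = hydrophobic_dmax,
                 min_seq_sep = as.integer(min_seq_sep),
                 hydrogens = "absent (distance-only detection)"),
            class = "interaction_criteria")
}

empty_records <- function() {
  data.frame(kind = character(0), a = character(0), b = character(0),
             module_a = character(0), module_b = character(0),
             atom_a = character(0), atom_b = character(0),
             distance = numeric(0), frame = integer(0),
             stringsAsFactors = FALSE)
}

# allowed entity pair given the residue-separation rule
pair_allowed <- function(at, i, j, min_seq_sep) {
  if (at$entity_label[i] == at$entity_label[j]) return(FALSE)
  if (at$entity[i] == "res" && at$entity[j] == "res")
    return(abs(at$resno[i] - at$resno[j]) >= min_seq_sep)
  TRUE
}

#' Detect hydrogen bonds in a conformation
#'
#' One record per (donor atom, acceptor atom) pair whose heavy-atom
#' distance is within the cutoff; donor and acceptor must belong to
#' different residues/ligands, with residue pairs at least
#' `min_seq_sep` apart in sequence.
#'
#' @param conformation a `conformation` (donor/acceptor flags assigned)
#' @param criteria an [interaction_criteria()] list
#' @param frame frame index stamped on the records
#' @return a data frame of contact records (columns `kind`, `a` = donor
#'   entity, `b` = acceptor entity, modules, atom names, `distance`,
#'   `frame`)
#' @export
detect_hbonds <- function(conformation, criteria = interaction_criteria(),
                          frame = 1L) {
  at <- conformation$atoms
  xyz <- coords(conformation)
  don <- which(at$donor)
  acc <- which(at$acceptor)
  if (!length(don) || !length(acc)) return(empty_records())
  out <- list()
  for (i in don) {
    d2 <- colSums((t(xyz[acc, , drop = FALSE]) - xyz[i, ])^2)
    hit <- acc[d2 <= criteria$hbond_dmax^2]
    for (j in hit) {
      if (!pair_allowed(at, i, j, criteria$min_seq_sep)) next
      out[[length(out) + 1L]] <- data.frame(
        kind = "hbond", a = at$entity_label[i], b = at$entity_label[j],
        module_a = at$module[i], module_b = at$module[j],
        atom_a = at$name[i], atom_b = at$name[j],
        distance = sqrt(sum((xyz[i, ] - xyz[j, ])^2)), frame = frame,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_records())
  do.call(rbind, out)
}

#' Detect salt bridges in a conformation
#'
#' A salt bridge is recorded per (cationic group, anionic group) pair
#' whose minimum inter-atomic distance is within the cutoff. Formal charge
#' groups are Lys/Arg side chains and free N-termini (cationic); Asp/Glu
#' side chains, free C-termini and ligand sulfonate/carboxylate groups
#' (anionic). The reported atoms realise the minimum distance.
#'
#' @inheritParams detect_hbonds
#' @return a data frame of contact records (one row per charge-group pair)
#' @export
detect_salt_bridges <- function(conformation,
                                criteria = interaction_criteria(),
                                frame = 1L) {
  at <- conformation$atoms
  xyz <- coords(conformation)
  grp <- unique(at$charge_group[!is.na(at$charge_group)])
  if (length(grp) < 2L) return(empty_records())
  ginfo <- lapply(grp, function(g) {
    idx <- which(at$charge_group %in% g)
    list(idx = idx, sign = at$charge_sign[idx[1]],
         label = at$entity_label[idx[1]], module = at$module[idx[1]])
  })
  pos <- ginfo[vapply(ginfo, `[[`, 0L, "sign") > 0]
  neg <- ginfo[vapply(ginfo, `[[`, 0L, "sign") < 0]
  out <- list()
  for (gp in pos) for (gn in neg) {
    if (gp$label == gn$label) next   # same residue/ligand
    best <- Inf; bi <- bj <- NA_integer_
    for (i in gp$idx) {
      d2 <- colSums((t(xyz[gn$idx, , drop = FALSE]) - xyz[i, ])^2)
      k <- which.min(d2)
      if (d2[k] < best) { best <- d2[k]; bi <- i; bj <- gn$idx[k] }
    }
    if (sqrt(best) <= criteria$saltbridge_dmax) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "saltbridge", a = gp$label, b = gn$label,
        module_a = gp$module, module_b = gn$module,
        atom_a = at$name[bi], atom_b = at$name[bj],
        distance = sqrt(best), frame = frame, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_records())
  do.call(rbind, out)
}

#' Hydrophobic contact atoms between two module partitions
#'
#' Counts the distinct apolar atoms (carbon/sulfur not bonded to N/O, plus
#' apolar ligand atoms) participating in at least one cross-partition pair
#' within the cutoff. With both partitions `NULL`, every pair of distinct
#' modules is considered (the "inter-module" hydrophobic atom count).
#'
#' @param conformation a `conformation`
#' @param partition_a,partition_b character vectors of module ids, or
#'   `NULL` for the all-inter-module count
#' @param criteria an [interaction_criteria()] list
#' @param frame frame index stamped on the records
#' @return list with `count` (distinct participating apolar atoms),
#'   `atoms` (their serials) and `records` (atom-pair records)
#' @export
hydrophobic_contact_atoms <- function(conformation, partition_a = NULL,
                                      partition_b = NULL,
                                      criteria = interaction_criteria(),
                                      frame = 1L) {
  at <- conformation$atoms
  xyz <- coords(conformation)
  ap <- which(at$apolar)
  sel_a <- if (is.null(partition_a)) ap else ap[at$module[ap] %in% partition_a]
  sel_b <- if (is.null(partition_b)) ap else ap[at$module[ap] %in% partition_b]
  cross_only <- is.null(partition_a) && is.null(partition_b)
  out <- list()
  involved <- integer(0)
  if (length(sel_a) && length(sel_b)) {
    for (i in sel_a) {
      d2 <- colSums((t(xyz[sel_b, , drop = FALSE]) - xyz[i, ])^2)
      hit <- sel_b[d2 <= criteria$hydrophobic_dmax^2]
      for (j in hit) {
        if (i >= j && j %in% sel_a && i %in% sel_b) next  # count pair once
        if (cross_only && at$module[i] == at$module[j]) next
        if (!cross_only && at$module[i] == at$module[j] &&
            identical(sort(partition_a), sort(partition_b))) next
        if (!pair_allowed(at, i, j, criteria$min_seq_sep)) next
        involved <- c(involved, i, j)
        out[[length(out) + 1L]] <- data.frame(
          kind = "hydrophobic", a = at$entity_label[i],
          b = at$entity_label[j],
          module_a = at$module[i], module_b = at$module[j],
          atom_a = at$name[i], atom_b = at$name[j],
          distance = sqrt(sum((xyz[i, ] - xyz[j, ])^2)), frame = frame,
          stringsAsFactors = FALSE)
      }
    }
  }
  involved <- sort(unique(involved))
  list(count = length(involved), atoms = at$serial[involved],
       records = if (length(out)) do.call(rbind, out) else empty_records())
}

#' Module-pair interaction landscape of an ensemble
#'
#' Runs the three contact detectors on every frame and aggregates them per
#' module pair (self-pairs included): mean hydrogen-bond and salt-bridge
#' counts per frame, mean number of distinct apolar atoms in cross-pair
#' hydrophobic contact, plus inter-/intra-module totals and per-contact
#' occupancy (fraction of frames in which a contact is present).
#'
#' @param ensemble a `conformation_ensemble`
#' @param criteria an [interaction_criteria()] list
#' @return an object of class `interaction_landscape`: list with
#'   `pair_means` (one row per module pair), `totals` (inter/intra means
#'   per kind), `occupancy` (one row per distinct contact), `records`
#'   (every per-frame record), `n_frames` and `criteria`
#' @export
interaction_landscape <- function(ensemble,
                                  criteria = interaction_criteria()) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  nf <- ensemble$n_frames
  mods <- unique(ensemble$atoms$module)
  recs <- vector("list", nf)
  hyatoms <- vector("list", nf)
  for (f in seq_len(nf)) {
    conf <- conformation_at(ensemble, f)
    hy <- hydrophobic_contact_atoms(conf, criteria = criteria, frame = f)
    recs[[f]] <- rbind(detect_hbonds(conf, criteria, f),
                       detect_salt_bridges(conf, criteria, f),
                       hy$records)
    hyatoms[[f]] <- hy
  }
  all_rec <- do.call(rbind, recs)

  mkey <- function(m1, m2) paste(pmin(m1, m2), pmax(m1, m2), sep = ":")
  pairs <- expand.grid(a = mods, b = mods, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  pair_means <- data.frame(
    module_a = pairs$a, module_b = pairs$b,
    hbond_mean = 0, saltbridge_mean = 0, hydrophobic_atoms_mean = 0,
    stringsAsFactors = FALSE)
  if (nrow(all_rec)) {
    key <- mkey(all_rec$module_a, all_rec$module_b)
    for (r in seq_len(nrow(pair_means))) {
      pk <- mkey(pair_means$module_a[r], pair_means$module_b[r])
      sub <- all_rec[key == pk, , drop = FALSE]
      pair_means$hbond_mean[r] <- sum(sub$kind == "hbond") / nf
      pair_means$saltbridge_mean[r] <- sum(sub$kind == "saltbridge") / nf
      # distinct atoms per frame for this module pair, averaged
      hsub <- sub[sub$kind == "hydrophobic", , drop = FALSE]
      if (nrow(hsub)) {
        per_frame <- vapply(seq_len(nf), function(f) {
          ff <- hsub[hsub$frame == f, , drop = FALSE]
          length(unique(c(paste(ff$a, ff$atom_a), paste(ff$b, ff$atom_b))))
        }, 0L)
        pair_means$hydrophobic_atoms_mean[r] <- mean(per_frame)
      }
    }
  }

  intra <- all_rec$module_a == all_rec$module_b
  totals <- data.frame(
    kind = rep(c("hbond", "saltbridge"), each = 2L),
    scope = rep(c("inter", "intra"), 2L),
    mean_per_frame = c(
      sum(all_rec$kind == "hbond" & !intra) / nf,
      sum(all_rec$kind == "hbond" & intra) / nf,
      sum(all_rec$kind == "saltbridge" & !intra) / nf,
      sum(all_rec$kind == "saltbridge" & intra) / nf),
    stringsAsFactors = FALSE)
  totals <- rbind(totals, data.frame(
    kind = "hydrophobic_atoms", scope = "inter",
    mean_per_frame = mean(vapply(hyatoms, `[[`, 0L, "count")),
    stringsAsFactors = FALSE))

  occ <- data.frame(kind = character(0), a = character(0), b = character(0),
                    occupancy = numeric(0), stringsAsFactors = FALSE)
  if (nrow(all_rec)) {
    ck <- paste(all_rec$kind, pmin(all_rec$a, all_rec$b),
                pmax(all_rec$a, all_rec$b))
    uk <- !duplicated(ck)
    occ <- data.frame(
      kind = all_rec$kind[uk],
      a = all_rec$a[uk], b = all_rec$b[uk],
      occupancy = vapply(ck[uk], function(k)
        length(unique(all_rec$frame[ck == k])) / nf, 0),
      stringsAsFactors = FALSE)
    rownames(occ) <- NULL
  }

  structure(list(pair_means = pair_means, totals = totals, occupancy = occ,
                 records = all_rec, n_frames = nf, criteria = criteria),
            class = "interaction_landscape")
}

#' @export
print.interaction_landscape <- function(x, ...) {
  cat("<interaction_landscape> ", x$n_frames, " frames\n", sep = "")
  nz <- x$pair_means[x$pair_means$hbond_mean > 0 |
                       x$pair_means$saltbridge_mean > 0 |
                       x$pair_means$hydrophobic_atoms_mean > 0, ,
                     drop = FALSE]
  if (nrow(nz)) print(nz, row.names = FALSE) else cat("  no contacts\n")
  invisible(x)
}

#' Lifetime (presence) series of one contact across an ensemble
#'
#' @param ensemble a `conformation_ensemble`
#' @param kind `"hbond"`, `"saltbridge"` or `"hydrophobic"`
#' @param a,b entity labels of the two partners (order-insensitive)
#' @param criteria an [interaction_criteria()] list
#' @return list with `present` (logical per frame) and `occupancy`
#' @export
lifetime_series <- function(ensemble, kind, a, b,
                            criteria = interaction_criteria()) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  kind <- match.arg(kind, c("hbond", "saltbridge", "hydrophobic"))
  present <- vapply(seq_len(ensemble$n_frames), function(f) {
    conf <- conformation_at(ensemble, f)
    rec <- switch(kind,
      hbond = detect_hbonds(conf, criteria, f),
      saltbridge = detect_salt_bridges(conf, criteria, f),
      hydrophobic = hydrophobic_contact_atoms(conf, criteria = criteria,
                                              frame = f)$records)
    any((rec$a == a & rec$b == b) | (rec$a == b & rec$b == a))
  }, TRUE)
  list(present = present, occupancy = mean(present))
}
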