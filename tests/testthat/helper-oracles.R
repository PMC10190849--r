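# Independent oracles and fixture generators used across the suite.

# Closed-form accessible area of sphere 1 (radius r1) occluded by sphere 2
# (radius r2) at centre distance d, probe p: spherical-cap geometry on the
# expanded spheres.
two_sphere_area <- function(r1, r2, d, p = 1.4) {
  R1 <- r1 + p; R2 <- r2 + p
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d <= abs(R1 - R2)) return(if (R1 <= R2) 0 else 4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Random atom table (<= 200 atoms) with residue/ligand entities and random
# chemistry flags, for detector equivalence checks.
random_conformation <- function(n_res = 40, box = 16, seed = 1) {
  set.seed(seed)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    is_lig <- runif(1) < 0.1
    k <- sample(2:5, 1)
    lbl <- if (is_lig) paste0("Lig", i) else paste0("RES", i)
    grp_sign <- if (runif(1) < 0.35) sample(c(-1L, 1L), 1) else 0L
    grp_atoms <- if (grp_sign != 0L) sample(k, sample(1:2, 1)) else integer(0)
    for (j in seq_len(k)) {
      serial <- serial + 1L
      el <- sample(c("C", "N", "O", "S"), 1,
                   prob = c(0.5, 0.2, 0.25, 0.05))
      rows[[serial]] <- data.frame(
        serial = serial, name = paste0(el, j),
        element = el, resno = i, resid3 = "UNK",
        entity = if (is_lig) "lig" else "res",
        entity_label = lbl,
        module = sample(c("R1", "ASM", "R4"), 1),
        radius = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)[[el]],
        apolar = el %in% c("C", "S") && runif(1) < 0.8,
        donor = el == "N" && runif(1) < 0.7,
        acceptor = el == "O" && runif(1) < 0.8,
        charge_group = if (j %in% grp_atoms) paste0(lbl, ":G")
                       else NA_character_,
        charge_sign = if (j %in% grp_atoms) grp_sign else 0L,
        x = runif(1, 0, box), y = runif(1, 0, box), z = runif(1, 0, box),
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  pepconj:::new_conformation(at)
}

# Brute-force all-pairs hydrogen-bond detector (pair keys, undeduplicated
# logic written independently of the package implementation).
bf_hbond_keys <- function(conf, crit = interaction_criteria()) {
  at <- conf$atoms
  xyz <- coords(conf)
  keys <- character(0)
  for (i in seq_len(nrow(at))) {
    if (!at$donor[i]) next
    for (j in seq_len(nrow(at))) {
      if (!at$acceptor[j]) next
      if (at$entity_label[i] == at$entity_label[j]) next
      if (at$entity[i] == "res" && at$entity[j] == "res" &&
          abs(at$resno[i] - at$resno[j]) < crit$min_seq_sep) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= crit$hbond_dmax)
        keys <- c(keys, paste(at$entity_label[i], at$name[i],
                              at$entity_label[j], at$name[j]))
    }
  }
  sort(keys)
}

# Brute-force salt-bridge detector at charge-group pair level.
bf_saltbridge_keys <- function(conf, crit = interaction_criteria()) {
  at <- conf$atoms
  xyz <- coords(conf)
  grp <- unique(at$charge_group[!is.na(at$charge_group)])
  keys <- character(0)
  for (g1 in grp) for (g2 in grp) {
    i1 <- which(at$charge_group %in% g1)
    i2 <- which(at$charge_group %in% g2)
    if (at$charge_sign[i1[1]] <= 0 || at$charge_sign[i2[1]] >= 0) next
    if (at$entity_label[i1[1]] == at$entity_label[i2[1]]) next
    dmin <- Inf
    for (i in i1) for (j in i2)
      dmin <- min(dmin, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    if (dmin <= crit$saltbridge_dmax) keys <- c(keys, paste(g1, g2))
  }
  sort(keys)
}

# Brute-force hydrophobic contact atoms across different modules.
bf_hydrophobic_atoms <- function(conf, crit = interaction_criteria()) {
  at <- conf$atoms
  xyz <- coords(conf)
  ap <- which(at$apolar)
  involved <- integer(0)
  for (i in ap) for (j in ap) {
    if (i >= j) next
    if (at$module[i] == at$module[j]) next
    if (at$entity_label[i] == at$entity_label[j]) next
    if (at$entity[i] == "res" && at$entity[j] == "res" &&
        abs(at$resno[i] - at$resno[j]) < crit$min_seq_sep) next
    if (sum((xyz[i, ] - xyz[j, ])^2) <= crit$hydrophobic_dmax^2)
      involved <- c(involved, i, j)
  }
  sort(unique(involved))
}

# unordered entity-pair keys of a record table
pair_keys <- function(rec) {
  if (!nrow(rec)) return(character(0))
  sort(unique(paste(pmin(rec$a, rec$b), pmax(rec$a, rec$b))))
}
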