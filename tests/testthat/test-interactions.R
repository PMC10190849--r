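# Contact detectors and landscape aggregation.

# minimal hand-built atom tables for cutoff checks
make_pair_conf <- function(d, donor_el = "N", acceptor_el = "O",
                           signs = c(0L, 0L)) {
  at <- data.frame(
    serial = 1:2, name = c("D1", "A1"), element = c(donor_el, acceptor_el),
    resno = c(1L, 5L), resid3 = "UNK", entity = "res",
    entity_label = c("RES1", "RES5"), module = c("R1", "ASM"),
    radius = 1.6, apolar = FALSE, donor = c(TRUE, FALSE),
    acceptor = c(FALSE, TRUE),
    charge_group = ifelse(signs != 0L, c("RES1:G", "RES5:G"), NA),
    charge_sign = signs,
    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE)
  pepconj:::new_conformation(at)
}

test_that("hydrogen-bond detection applies the distance cutoff", {
  hit <- detect_hbonds(make_pair_conf(2.9))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$a, "RES1"); expect_equal(hit$b, "RES5")
  expect_equal(hit$distance, 2.9)
  expect_equal(nrow(detect_hbonds(make_pair_conf(3.8))), 0L)
  # adjacent residues are excluded
  conf <- make_pair_conf(2.9)
  conf$atoms$resno <- c(1L, 2L)
  expect_equal(nrow(detect_hbonds(conf)), 0L)
})

test_that("salt-bridge detection uses charge-group minimum distance", {
  hit <- detect_salt_bridges(make_pair_conf(3.5, signs = c(1L, -1L)))
  expect_equal(nrow(hit), 1L)
  expect_equal(nrow(detect_salt_bridges(
    make_pair_conf(4.5, signs = c(1L, -1L)))), 0L)
  # like charges never bridge
  expect_equal(nrow(detect_salt_bridges(
    make_pair_conf(3.0, signs = c(1L, 1L)))), 0L)
})

test_that("hydrophobic counts are distinct participating atoms", {
  # two fully interdigitated apolar clusters across modules
  n <- 4L
  at <- data.frame(
    serial = 1:(2 * n), name = paste0("C", 1:(2 * n)), element = "C",
    resno = rep(c(1L, 5L), each = n), resid3 = "UNK", entity = "res",
    entity_label = rep(c("LEU1", "LEU5"), each = n),
    module = rep(c("R1", "ASM"), each = n),
    radius = 1.7, apolar = TRUE, donor = FALSE, acceptor = FALSE,
    charge_group = NA_character_, charge_sign = 0L,
    x = c(seq(0, 3, length.out = n), seq(0.5, 3.5, length.out = n)),
    y = rep(c(0, 1.5), each = n), z = 0, stringsAsFactors = FALSE)
  conf <- pepconj:::new_conformation(at)
  hy <- hydrophobic_contact_atoms(conf, "R1", "ASM")
  expect_equal(hy$count, 2L * n)   # every atom participates
  # polar-only interface gives zero
  at$apolar <- FALSE
  expect_equal(hydrophobic_contact_atoms(
    pepconj:::new_conformation(at), "R1", "ASM")$count, 0L)
  # partitions beyond the cutoff give zero
  at$apolar <- TRUE
  at$x[at$module == "ASM"] <- at$x[at$module == "ASM"] + 50
  expect_equal(hydrophobic_contact_atoms(
    pepconj:::new_conformation(at), "R1", "ASM")$count, 0L)
})

test_that("detectors agree with brute-force all-pairs oracles", {
  for (seed in 1:8) {
    conf <- random_conformation(n_res = 30, seed = seed)
    hb <- detect_hbonds(conf)
    got_hb <- if (nrow(hb)) sort(paste(hb$a, hb$atom_a, hb$b, hb$atom_b))
              else character(0)
    expect_identical(got_hb, bf_hbond_keys(conf), info = seed)
    sb <- detect_salt_bridges(conf)
    at <- conf$atoms
    got_sb <- if (nrow(sb))
      sort(paste(at$charge_group[match(paste(sb$a, sb$atom_a),
                                       paste(at$entity_label, at$name))],
                 at$charge_group[match(paste(sb$b, sb$atom_b),
                                       paste(at$entity_label, at$name))]))
      else character(0)
    expect_identical(got_sb, bf_saltbridge_keys(conf), info = seed)
    hy <- hydrophobic_contact_atoms(conf)
    expect_identical(sort(hy$atoms),
                     conf$atoms$serial[bf_hydrophobic_atoms(conf)],
                     info = seed)
  }
})

test_that("landscape means are frame-wise means of detector counts", {
  fx <- worked_example_fixture("Pbeta")
  conf <- fx$conformation
  # frame 2: break two of the four planted hydrogen bonds
  xyz2 <- coords(conf)
  br <- conf$atoms$entity_label == "PHE16" & conf$atoms$name == "N"
  xyz2[br, ] <- xyz2[br, ] + c(0, 0, 60)
  br2 <- conf$atoms$entity_label == "VAL14" & conf$atoms$name == "N"
  xyz2[br2, ] <- xyz2[br2, ] + c(0, 0, 60)
  ens <- pepconj:::new_ensemble(conf$atoms,
                                rbind(as.vector(t(coords(conf))),
                                      as.vector(t(xyz2))),
                                conf$topology)
  land <- interaction_landscape(ens)
  hb_total <- sum(land$pair_means$hbond_mean)
  expect_equal(hb_total, (4 + 2) / 2)   # 4 then 2 hydrogen bonds
  # consistency: means equal frame-wise mean of per-frame counts
  per_frame <- vapply(1:2, function(f)
    nrow(detect_hbonds(conformation_at(ens, f))), 0L)
  expect_equal(hb_total, mean(per_frame))
  # inter+intra decomposition sums to the total for every kind
  tot <- land$totals
  expect_equal(sum(tot$mean_per_frame[tot$kind == "hbond"]), hb_total)
  sb_total <- sum(land$pair_means$saltbridge_mean)
  expect_equal(sum(tot$mean_per_frame[tot$kind == "saltbridge"]), sb_total)
  # occupancy: the broken contact is present in 1 of 2 frames
  occ <- land$occupancy
  k <- occ$kind == "hbond" &
    pmin(occ$a, occ$b) == "PHE16" & pmax(occ$a, occ$b) == "PRO3"
  expect_equal(occ$occupancy[k], 0.5)
  k2 <- occ$kind == "saltbridge" &
    pmin(occ$a, occ$b) == "GLU9" & pmax(occ$a, occ$b) == "LYS7"
  expect_equal(occ$occupancy[k2], 1)
})

test_that("a single frame reproduces that frame's counts", {
  fx <- worked_example_fixture("Pbeta")
  land <- interaction_landscape(as_ensemble(fx$conformation))
  expect_equal(sum(land$pair_means$hbond_mean), 4)
  expect_equal(sum(land$pair_means$saltbridge_mean), 2)
})

test_that("lifetime series track planted contact presence", {
  fx <- worked_example_fixture("Pbeta")
  conf <- fx$conformation
  xyz_on <- as.vector(t(coords(conf)))
  xyz2 <- coords(conf)
  br <- conf$atoms$entity_label == "PHE16" & conf$atoms$name == "N"
  xyz2[br, ] <- xyz2[br, ] + c(0, 0, 60)
  xyz_off <- as.vector(t(xyz2))
  # alternating frames
  ens <- pepconj:::new_ensemble(conf$atoms,
                                rbind(xyz_on, xyz_off, xyz_on, xyz_off),
                                conf$topology)
  lt <- lifetime_series(ens, "hbond", "PHE16", "PRO3")
  expect_equal(lt$present, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lt$occupancy, 0.5)
  # always present / never formed
  expect_equal(lifetime_series(ens, "saltbridge", "LYS12",
                               "ASP11")$occupancy, 1)
  expect_equal(lifetime_series(ens, "hbond", "ALA1", "GLU18")$occupancy, 0)
})
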