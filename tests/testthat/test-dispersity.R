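# The %SASA statistic, the 75% classifier and the cleavage exposure delta.

opts_fast <- sasa_options(n_points = 240)

test_that("a molecule that is all assembly module scores exactly 100%", {
  top <- parse_conjugate_spec(list(
    name = "asm_only", modules = list(list(id = "ASM",
                                           sequence = "KLVFFAE"))))
  e <- percent_sasa(build_conformation(top, motif = "extended"),
                    options = opts_fast)
  expect_equal(e$percent_sasa, 100)
  expect_equal(e$percent_of_means, 100)
})

test_that("an occluding shell buries the module almost completely", {
  # one module carbon enclosed by a shell of context atoms
  shell <- pepconj:::spiral_lattice(80L) * 3.0
  at <- data.frame(
    serial = 1:81, name = "C", element = "C",
    resno = c(1L, rep(2L, 80)), resid3 = "UNK", entity = "res",
    entity_label = c("ASM1", rep("SH2", 80)),
    module = c("ASM", rep("R1", 80)),
    radius = 1.7, apolar = TRUE, donor = FALSE, acceptor = FALSE,
    charge_group = NA_character_, charge_sign = 0L,
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    stringsAsFactors = FALSE)
  conf <- pepconj:::new_conformation(at)
  e <- percent_sasa(as_ensemble(conf), options = opts_fast)
  expect_lt(e$percent_sasa, 5)
  # deleting the shell restores 100% by definition
  e2 <- percent_sasa(as_ensemble(conf), options = opts_fast,
                     atom_subset = at$module == "ASM")
  expect_equal(e2$percent_sasa, 100)
})

test_that("the 75% threshold reproduces the published dispersibility calls", {
  expect_equal(classify_dispersity(88.6), "assembly_prone")
  expect_equal(classify_dispersity(45.3), "dispersed")
  expect_equal(classify_dispersity(75), "dispersed")  # strict inequality
  expect_error(classify_dispersity(50, threshold = 0))
})

test_that("%SASA is invariant to rigid motion of the whole conformation", {
  # the sample lattice is fixed in space, so rotating the molecule changes
  # the discretisation slightly; the tolerance scales as ~1/n_points
  conf <- build_conformation(get_design("Pbeta"), motif = "hairpin")
  opts <- sasa_options(n_points = 480)
  e0 <- percent_sasa(conf, options = opts)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  conf2 <- pepconj:::set_coords(conf, sweep(coords(conf) %*% R, 2,
                                            c(10, 5, -4), "+"))
  e1 <- percent_sasa(conf2, options = opts)
  expect_equal(e1$percent_sasa, e0$percent_sasa, tolerance = 0.005)
})

test_that("adding occluders near the module never raises %SASA", {
  conf <- build_conformation(get_design("Pbeta"), motif = "extended")
  at <- conf$atoms
  base <- percent_sasa(conf, options = opts_fast)$percent_sasa
  set.seed(3)
  asm <- which(at$module == "ASM")
  prev <- base
  for (k in 1:4) {
    target <- sample(asm, 1)
    extra <- at[1, ]
    extra$serial <- nrow(at) + k
    extra$module <- "R1"; extra$resno <- 99L + k
    extra$entity_label <- paste0("X", k)
    extra[, c("x", "y", "z")] <-
      at[target, c("x", "y", "z")] + runif(3, -2, 2)
    at <- rbind(at, extra)
    cur <- percent_sasa(pepconj:::new_conformation(at),
                        options = opts_fast)$percent_sasa
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("cleavage exposure delta is zero exactly when nothing occludes", {
  conf <- build_conformation(get_design("Pbeta"), motif = "extended")
  # push the whole released segment far away: no occlusion remains
  far <- conf
  mv <- far$atoms$resno <= 11
  far$atoms$x[mv] <- far$atoms$x[mv] + 1000
  hd <- hydrolysis_exposure_delta(far, options = opts_fast)
  expect_identical(hd$delta, 0)
  expect_identical(hd$product$percent_sasa, hd$precursor$percent_sasa)
  # in contact, the delta is strictly positive
  hd2 <- hydrolysis_exposure_delta(conf, options = opts_fast)
  expect_gt(hd2$delta, 0)
})

test_that("an R4-buried fixture gains more exposure on cleavage than an
           R2-modified fixture without R1-on-module contact", {
  fx <- worked_example_fixture("Pbeta_R4C")
  d_r4c <- hydrolysis_exposure_delta(as_ensemble(fx$conformation),
                                     options = opts_fast)$delta
  r2c <- build_conformation(get_design("Pbeta_R2C"), motif = "extended")
  d_r2c <- hydrolysis_exposure_delta(as_ensemble(r2c),
                                     options = opts_fast)$delta
  expect_gt(d_r4c, d_r2c)
})

test_that("delta is non-negative on randomly perturbed fixtures", {
  set.seed(21)
  for (k in 1:6) {
    conf <- build_conformation(get_design("Pbeta"),
                               motif = sample(c("hairpin", "extended"), 1))
    ens <- perturb_ensemble(conf, runif(1, 0, 1.5), 2L,
                            seed = sample.int(1e6, 1))
    hd <- hydrolysis_exposure_delta(ens,
                                    options = sasa_options(n_points = 120))
    expect_gte(hd$delta, 0)
    expect_true(all(hd$precursor$per_frame$percent >= 0 &
                      hd$precursor$per_frame$percent <= 100 + 1e-9))
  }
})
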