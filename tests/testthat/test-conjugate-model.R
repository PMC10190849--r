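# The conjugate design model: topologies, module partition, cleavage.

test_that("the built-in Pbeta record reconstructs the published numbering", {
  top <- get_design("Pbeta")
  expect_s3_class(top, "conjugate_topology")
  expect_equal(nrow(top$residues), 18L)
  expect_equal(conjugate_sequence(top), "AVPIAQKDEVDKLVFFAE")
  expect_equal(top$modules$R1$residues, 1:11)
  expect_equal(top$modules$ASM$residues, 12:18)
  # residue labels used in the interaction analysis
  expect_equal(top$residues$code3[c(16, 14, 5, 7, 12, 11, 9)],
               c("PHE", "VAL", "ALA", "LYS", "LYS", "ASP", "GLU"))
  expect_equal(module_of(top, 12), "ASM")
  expect_equal(module_of(top, 3), "R1")
  expect_error(module_of(top, 19), "out of range")
  expect_error(module_of(top, "Cy"), "no residue or ligand")
})

test_that("ligand attachments resolve to their module", {
  r4c <- get_design("Pbeta_R4C")
  expect_equal(nrow(r4c$residues), 20L)
  expect_equal(r4c$modules$R4$residues, 19:20)
  expect_equal(module_of(r4c, "Cy"), "R4")
  # the drug site is the assembly-module lysine side chain
  d <- get_design("Pbeta_R4C_D")
  expect_equal(module_of(d, "Py"), "R3")
  expect_equal(d$ligands$L2$anchor_residue, 12L)
  expect_equal(d$residues$code3[12], "LYS")
})

test_that("design records are validated", {
  expect_error(parse_conjugate_spec(list(
    name = "bad", sequence = "AVPIAQKDEVDKLVFFAE",
    modules = list(list(id = "R1", range = c(1, 11)),
                   list(id = "ASM", range = c(10, 18))))),
    "overlap")
  expect_error(parse_conjugate_spec(list(
    name = "bad2", modules = list(list(id = "R1", sequence = "AVPI"),
                                  list(id = "ASM", sequence = "KLVFFAA")))),
    "assembly module")
  ok <- parse_conjugate_spec(list(
    name = "ok", modules = list(list(id = "ASM", sequence = "KLVFAA"))),
    allow_nonstandard_asm = TRUE)
  expect_equal(conjugate_sequence(ok), "KLVFAA")
  expect_error(parse_conjugate_spec(list(
    name = "badlig",
    modules = list(list(id = "ASM", sequence = "KLVFFAE")),
    ligands = list(list(template = "NOPE", module = "R4",
                        anchor_module = "ASM", anchor_position = 1,
                        site = "side_chain")))),
    "unknown ligand template")
  expect_error(get_design("NotADesign"), "NotADesign")
})

test_that("cleavage follows the caspase-3/7 convention", {
  top <- get_design("Pbeta")
  prods <- cleave(top)
  expect_length(prods, 2L)
  expect_equal(vapply(prods, conjugate_sequence, ""),
               c("AVPIAQKDEVD", "KLVFFAE"))
  expect_equal(names(prods[[2]]$modules), "ASM")

  # no motif: identity
  nomotif <- parse_conjugate_spec(list(
    name = "x", modules = list(list(id = "ASM", sequence = "KLVFFAE"))))
  expect_length(cleave(nomotif), 1L)
  expect_equal(conjugate_sequence(cleave(nomotif)[[1]]), "KLVFFAE")

  # two motifs: three products
  two <- parse_conjugate_spec(list(
    name = "two",
    modules = list(list(id = "R1", sequence = "GDEVDAADEVDGG"))),
    allow_nonstandard_asm = TRUE)
  expect_length(cleave(two), 3L)
  expect_equal(vapply(cleave(two), conjugate_sequence, ""),
               c("GDEVD", "AADEVD", "GG"))
})

test_that("cleavage is idempotent and concatenation restores precursors", {
  for (nm in names(design_registry())) {
    top <- get_design(nm)
    prods <- cleave(top)
    expect_equal(paste(vapply(prods, conjugate_sequence, ""),
                       collapse = ""),
                 conjugate_sequence(top), info = nm)
    for (p in prods) {
      again <- cleave(p)
      expect_length(again, 1L)
      expect_equal(conjugate_sequence(again[[1]]), conjugate_sequence(p))
    }
  }
})

test_that("ligands travel with their anchor residue on cleavage", {
  prods <- cleave(get_design("Pbeta_R4C"))
  expect_length(prods[[1]]$ligands, 0L)
  expect_equal(vapply(prods[[2]]$ligands, `[[`, "", "label"), c(L1 = "Cy"))
  # anchor re-indexed: Cys was residue 19, product 2 starts at old 12
  expect_equal(prods[[2]]$ligands$L1$anchor_residue, 8L)
  expect_equal(prods[[2]]$residues$code3[8], "CYS")
})

test_that("every atom of every design maps to exactly one module", {
  for (nm in names(design_registry())) {
    conf <- build_conformation(get_design(nm), motif = "extended")
    expect_false(anyNA(conf$atoms$module), info = nm)
    expect_true(all(conf$atoms$module %in%
                      c("R1", "R2", "ASM", "R3", "R4")), info = nm)
  }
})
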