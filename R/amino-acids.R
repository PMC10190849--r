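# Amino-acid lookup tables and per-residue chemistry flags.
# Donor/acceptor assignments are the usual heavy-atom conventions; formal
# charge groups are restricted to Lys/Arg side chains and the free termini
# (cationic) and Asp/Glu side chains plus the free C-terminus (anionic).

.AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_three <- function(code1) {
  out <- .AA1[code1]
  if (anyNA(out)) stop("unknown residue code: ",
                       paste(code1[is.na(out)], collapse = ", "),
                       call. = FALSE)
  unname(out)
}

# side-chain hydrogen-bond donors (heavy donor atoms)
.SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1")

# side-chain hydrogen-bond acceptors
.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD")

# formal side-chain charge groups: list(resid -> list(atoms, sign))
.SC_CHARGE <- list(
  LYS = list(atoms = "NZ", sign = 1L),
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = 1L),
  ASP = list(atoms = c("OD1", "OD2"), sign = -1L),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1L))

vdw_radii_table <- function() {
  if (is.null(.pepconj_cache$radii)) {
    tab <- read.csv(pepconj_file("extdata", "vdw_radii.csv"),
                    comment.char = "#", stringsAsFactors = FALSE)
    .pepconj_cache$radii <- setNames(tab$radius, toupper(tab$element))
  }
  .pepconj_cache$radii
}

vdw_radius <- function(element) {
  tab <- vdw_radii_table()
  r <- tab[toupper(element)]
  if (anyNA(r)) stop("no van der Waals radius for element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "),
                     call. = FALSE)
  unname(r)
}

sidechain_zmat <- function() {
  if (is.null(.pepconj_cache$zmat)) {
    .pepconj_cache$zmat <- read.csv(
      pepconj_file("extdata", "sidechain_internal_coords.csv"),
      comment.char = "#", stringsAsFactors = FALSE)
  }
  .pepconj_cache$zmat
}
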