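# Multi-model PDB input/output, delegating the record format to bio3d.
# Conformations carry chemistry flags that PDB files cannot: reading an
# ensemble therefore requires the conjugate topology, whose generated atom
# table supplies radii, donor/acceptor/apolar flags and charge groups,
# matched to the file's atoms by residue number and atom name.

#' Write an ensemble as a multi-model PDB file
#'
#' Peptide atoms are written as ATOM records (chain A, 1-based contiguous
#' residue numbering); ligand atoms as HETATM records under their template
#' residue names (CYD, FIT, PYR). One MODEL/ENDMDL block per frame.
#'
#' @param ensemble a `conformation_ensemble` (or single `conformation`)
#' @param file output path; `NULL` returns the PDB text as a character
#'   vector of lines instead
#' @return the file path (invisibly), or the text lines if `file` is NULL
#' @export
write_ensemble <- function(ensemble, file = NULL) {
  if (inherits(ensemble, "conformation")) ensemble <- as_ensemble(ensemble)
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  at <- ensemble$atoms
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = tmp, xyz = ensemble$xyz,
                   type = ifelse(at$entity == "lig", "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid3,
                   eleno = at$serial, elety = at$name,
                   chain = rep("A", nrow(at)), elesy = at$element)
  # bio3d's multi-model writer emits every record as ATOM; restore HETATM
  # for ligand atoms by serial number
  lig_serial <- at$serial[at$entity == "lig"]
  lines <- readLines(tmp)
  if (length(lig_serial)) {
    is_atom <- startsWith(lines, "ATOM")
    serial <- suppressWarnings(as.integer(substr(lines, 7L, 11L)))
    fix <- is_atom & !is.na(serial) & serial %in% lig_serial
    lines[fix] <- sub("^ATOM  ", "HETATM", lines[fix])
  }
  # bio3d omits MODEL/ENDMDL for single-frame files; keep the multi-model
  # container uniform so one frame still reads back as one MODEL
  if (ensemble$n_frames == 1L && !any(startsWith(lines, "MODEL"))) {
    rec <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
    first <- which(rec)[1]; last <- max(which(rec))
    lines <- c(lines[seq_len(first - 1L)], "MODEL        1",
               lines[first:last], "ENDMDL",
               if (last < length(lines)) lines[(last + 1L):length(lines)])
  }
  writeLines(lines, tmp)
  if (is.null(file)) {
    on.exit(unlink(tmp))
    return(readLines(tmp))
  }
  invisible(file)
}

#' Read a multi-model PDB file as an ensemble bound to a topology
#'
#' Each MODEL block becomes one frame. Atoms are validated against the
#' topology's expected atom inventory (from the ideal-geometry builder's
#' naming scheme): every expected atom must be present exactly once, keyed
#' by (residue number, atom name); HETATM records map to registered ligand
#' templates by residue name. Van der Waals radii and chemistry flags are
#' assigned from the topology, not the file.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines
#' @param topology the `conjugate_topology` the coordinates belong to
#' @return a `conformation_ensemble`
#' @export
read_ensemble <- function(pdb, topology) {
  stopifnot(inherits(topology, "conjugate_topology"))
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) ||
      (!file.exists(pdb[1]) && grepl("^(ATOM|HETATM|MODEL)", pdb[1]))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n")), path)
    on.exit(unlink(path))
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  template <- build_conformation(topology)$atoms

  file_key <- paste(p$atom$resno, trimws(p$atom$elety))
  want_key <- paste(template$resno, template$name)
  hit <- match(want_key, file_key)
  if (anyNA(hit)) {
    miss <- which(is.na(hit))[1]
    stop("atom/topology mismatch: expected atom ", template$name[miss],
         " of ", template$entity_label[miss], " not found in PDB")
  }
  extra <- setdiff(seq_along(file_key), hit)
  if (length(extra))
    stop("atom/topology mismatch: PDB atom ", trimws(p$atom$elety[extra[1]]),
         " of residue ", p$atom$resid[extra[1]], p$atom$resno[extra[1]],
         " has no counterpart in topology ", topology$name)
  bad_resid <- which(p$atom$resid[hit] != template$resid3)
  if (length(bad_resid)) {
    b <- bad_resid[1]
    stop("residue name mismatch at residue ", template$resno[b],
         ": file says ", p$atom$resid[hit[b]], ", topology says ",
         template$resid3[b])
  }

  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * hit - 2L, 3L * hit - 1L, 3L * hit))
  xyz <- xyz[, cols, drop = FALSE]
  if (any(!is.finite(xyz))) stop("malformed (non-finite) coordinates in PDB")
  new_ensemble(template, xyz, topology)
}

#' Export per-frame scalar series as CSV
#'
#' Convenience wrapper used by the screening pipeline for RMSD/RGYR/count
#' series; one row per frame.
#'
#' @param series a data frame with a `frame` column
#' @param file output path
#' @return the file path, invisibly
#' @export
write_series_csv <- function(series, file) {
  stopifnot(is.data.frame(series), "frame" %in% names(series))
  write.csv(series, file, row.names = FALSE)
  invisible(file)
}
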