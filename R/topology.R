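# Conjugate topologies: the designed molecule as an ordered residue chain
# partitioned into named modules (R1/R2/ASM/R3/R4) with ligand attachments
# and a cleavage rule.

.MODULE_IDS <- c("R1", "R2", "ASM", "R3", "R4")
.ASM_SEQ <- "KLVFFAE"

#' Parse a declarative conjugate design record into a topology
#'
#' A design record lists the modules of a peptide-drug conjugate in N-to-C
#' order, either as per-module sequences or as a full sequence plus explicit
#' residue ranges, together with ligand attachments. Residues are numbered
#' contiguously from 1 at the N-terminus.
#'
#' @param spec a design record: a named list (see the bundled
#'   `designs.yaml` for the schema) or the path to a YAML file containing
#'   one record.
#' @param allow_nonstandard_asm if `FALSE` (default) the assembly module
#'   sequence must equal `KLVFFAE`.
#' @return an object of class `conjugate_topology` with components
#'   `name`, `residues` (data frame: `index`, `code`, `code3`, `module`,
#'   `is_N_terminal`, `is_C_terminal`), `modules` (per-module residue
#'   indices and ligand ids), `ligands` (attachment list), `cleavage`
#'   (recognition motif) and `motif` (default backbone recipe, if given).
#' @seealso [design_registry()], [cleave()], [module_of()]
#' @examples
#' top <- get_design("Pbeta")
#' conjugate_sequence(top)
#' module_of(top, 12)
#' @export
parse_conjugate_spec <- function(spec, allow_nonstandard_asm = FALSE) {
  if (is.character(spec) && length(spec) == 1L) {
    spec <- yaml::read_yaml(spec)
  }
  stopifnot(is.list(spec))
  name <- spec$name
  if (is.null(name) || !nzchar(name)) stop("design record has no name")
  mods <- spec$modules
  if (is.null(mods) || !length(mods)) stop("design record lists no modules")

  ids <- vapply(mods, function(m) as.character(m$id), "")
  if (anyDuplicated(ids)) stop("duplicated module id in design ", name)
  bad <- setdiff(ids, .MODULE_IDS)
  if (length(bad)) stop("unknown module id(s): ", paste(bad, collapse = ", "))

  if (!is.null(spec$sequence)) {
    # full sequence + explicit closed 1-based ranges
    seq1 <- strsplit(spec$sequence, "")[[1]]
    n <- length(seq1)
    covered <- integer(0)
    res_module <- rep(NA_character_, n)
    for (m in mods) {
      rg <- as.integer(m$range)
      if (length(rg) != 2L || any(is.na(rg)) || rg[1] > rg[2] ||
          rg[1] < 1L || rg[2] > n)
        stop("invalid range for module ", m$id, " in design ", name)
      idx <- seq.int(rg[1], rg[2])
      if (any(idx %in% covered))
        stop("module spans overlap in design ", name, " (module ", m$id, ")")
      covered <- c(covered, idx)
      res_module[idx] <- m$id
    }
    if (length(covered) != n)
      stop("module spans do not cover every residue in design ", name)
  } else {
    seqs <- vapply(mods, function(m) {
      s <- m$sequence
      if (is.null(s)) "" else as.character(s)
    }, "")
    seq1 <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    res_module <- rep(ids, nchar(seqs))
  }
  n <- length(seq1)
  if (n < 1L) stop("design ", name, " has no residues")
  code3 <- aa_three(seq1)

  asm_idx <- which(res_module == "ASM")
  if (length(asm_idx)) {
    asm_seq <- paste(seq1[asm_idx], collapse = "")
    if (!identical(asm_seq, .ASM_SEQ) && !allow_nonstandard_asm)
      stop("assembly module sequence is ", asm_seq, ", not ", .ASM_SEQ,
           "; set allow_nonstandard_asm = TRUE to override")
  }

  residues <- data.frame(
    index = seq_len(n), code = seq1, code3 = code3, module = res_module,
    is_N_terminal = c(TRUE, rep(FALSE, n - 1L)),
    is_C_terminal = c(rep(FALSE, n - 1L), TRUE),
    stringsAsFactors = FALSE)

  modules <- lapply(setNames(nm = unique(res_module)), function(id)
    list(residues = which(res_module == id), ligands = character(0)))

  # ligand attachments
  ligs <- list()
  templates <- ligand_registry()
  lig_specs <- spec$ligands
  if (!is.null(lig_specs) && length(lig_specs)) {
    for (k in seq_along(lig_specs)) {
      ls <- lig_specs[[k]]
      tmpl <- ls$template
      if (is.null(tmpl) || is.null(templates[[tmpl]]))
        stop("unknown ligand template: ", if (is.null(tmpl)) "<missing>" else tmpl)
      site <- match.arg(ls$site, c("side_chain", "C_term", "N_term"))
      mod_id <- as.character(ls$module)
      if (!mod_id %in% .MODULE_IDS)
        stop("unknown module id for ligand: ", mod_id)
      anchor_mod <- as.character(ls$anchor_module)
      amod <- modules[[anchor_mod]]
      if (is.null(amod) || !length(amod$residues))
        stop("ligand anchor module ", anchor_mod, " has no residues in design ",
             name)
      pos <- as.integer(ls$anchor_position)
      if (is.na(pos) || pos < 1L || pos > length(amod$residues))
        stop("ligand anchor position out of range in design ", name)
      anchor <- amod$residues[pos]
      label <- templates[[tmpl]]$label
      if (any(vapply(ligs, function(l) identical(l$label, label), TRUE)))
        label <- paste0(label, k)
      id <- paste0("L", k)
      if (mod_id == "R3" &&
          !(identical(code3[anchor], "LYS") && site == "side_chain"))
        stop("drug (R3) ligands must anchor on a lysine side-chain amine")
      ligs[[id]] <- list(id = id, template = tmpl, label = label,
                         module = mod_id, anchor_residue = anchor,
                         site = site)
      if (is.null(modules[[mod_id]]))
        modules[[mod_id]] <- list(residues = integer(0),
                                  ligands = character(0))
      modules[[mod_id]]$ligands <- c(modules[[mod_id]]$ligands, id)
    }
  }

  # keep canonical module ordering for reporting
  modules <- modules[intersect(.MODULE_IDS, names(modules))]

  cleav <- spec$cleavage
  motif <- if (is.null(cleav$motif)) "DEVD" else as.character(cleav$motif)
  if (!nzchar(motif)) stop("cleavage motif must be non-empty")

  structure(list(
    name = name,
    residues = residues,
    modules = modules,
    ligands = ligs,
    cleavage = list(motif = motif),
    motif = spec$motif,
    provenance = spec$provenance
  ), class = "conjugate_topology")
}

#' @export
print.conjugate_topology <- function(x, ...) {
  cat("<conjugate_topology> ", x$name, "\n", sep = "")
  cat("  sequence: ", conjugate_sequence(x), " (", nrow(x$residues),
      " residues)\n", sep = "")
  for (id in names(x$modules)) {
    m <- x$modules[[id]]
    rng <- if (length(m$residues))
      paste0("residues ", min(m$residues), "-", max(m$residues)) else "no residues"
    lig <- if (length(m$ligands))
      paste0(", ligands: ", paste(vapply(m$ligands, function(l)
        x$ligands[[l]]$label, ""), collapse = ", ")) else ""
    cat("  ", format(id, width = 4), rng, lig, "\n", sep = "")
  }
  cat("  cleavage motif: ", x$cleavage$motif, "\n", sep = "")
  invisible(x)
}

#' One-letter sequence of a conjugate topology
#' @param topology a `conjugate_topology`
#' @return a single string
#' @export
conjugate_sequence <- function(topology) {
  paste(topology$residues$code, collapse = "")
}

#' Map a residue or ligand to its module
#'
#' @param topology a `conjugate_topology`
#' @param ref a residue index (numeric) or ligand label/id (character)
#' @return the module id (one of `R1`, `R2`, `ASM`, `R3`, `R4`)
#' @export
module_of <- function(topology, ref) {
  stopifnot(inherits(topology, "conjugate_topology"))
  if (is.numeric(ref)) {
    ref <- as.integer(ref)
    if (length(ref) != 1L || is.na(ref) || ref < 1L ||
        ref > nrow(topology$residues))
      stop("residue index out of range: ", ref)
    return(topology$residues$module[ref])
  }
  for (l in topology$ligands)
    if (identical(l$label, ref) || identical(l$id, ref)) return(l$module)
  stop("no residue or ligand matches reference: ", ref)
}

#' Cleave a conjugate at every occurrence of its recognition motif
#'
#' Implements the caspase-3/7 convention: the chain is cut on the C-terminal
#' side of the last residue of each motif occurrence (P1 aspartate for the
#' default `DEVD`). Ligands travel with their anchor residue; module spans
#' are re-indexed per product. A topology without the motif is returned
#' unchanged as a single product, so cleavage is idempotent on its own
#' products.
#'
#' @param topology a `conjugate_topology`
#' @param rule optional cleavage rule, a list with element `motif`
#'   (defaults to the topology's own rule)
#' @return a list of `conjugate_topology` products in N-to-C order
#' @examples
#' prods <- cleave(get_design("Pbeta"))
#' vapply(prods, conjugate_sequence, "")
#' @export
cleave <- function(topology, rule = NULL) {
  stopifnot(inherits(topology, "conjugate_topology"))
  motif <- if (is.null(rule)) topology$cleavage$motif else rule$motif
  if (is.null(motif) || !nzchar(motif)) stop("cleavage motif must be non-empty")
  seqstr <- conjugate_sequence(topology)
  hits <- gregexpr(motif, seqstr, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(list(topology))
  cuts <- as.integer(hits) + nchar(motif) - 1L   # cut after this index
  cuts <- cuts[cuts < nchar(seqstr)]             # motif at C-terminus: no cut
  if (!length(cuts)) return(list(topology))
  bounds <- c(0L, cuts, nchar(seqstr))

  out <- vector("list", length(bounds) - 1L)
  for (p in seq_along(out)) {
    idx <- seq.int(bounds[p] + 1L, bounds[p + 1L])
    res <- topology$residues[idx, , drop = FALSE]
    old_index <- res$index
    res$index <- seq_along(idx)
    # precursor numbering retained so products can be mapped back onto
    # precursor coordinates (frozen-geometry post-cleavage analysis)
    res$parent_index <- old_index
    res$is_N_terminal <- c(TRUE, rep(FALSE, nrow(res) - 1L))
    res$is_C_terminal <- c(rep(FALSE, nrow(res) - 1L), TRUE)
    rownames(res) <- NULL

    ligs <- Filter(function(l) l$anchor_residue %in% old_index,
                   topology$ligands)
    ligs <- lapply(ligs, function(l) {
      l$anchor_residue <- match(l$anchor_residue, old_index)
      l
    })

    modules <- list()
    for (id in names(topology$modules)) {
      m <- topology$modules[[id]]
      keep <- match(intersect(m$residues, old_index), old_index)
      lkeep <- intersect(m$ligands, names(ligs))
      if (length(keep) || length(lkeep))
        modules[[id]] <- list(residues = sort(keep), ligands = lkeep)
    }

    out[[p]] <- structure(list(
      name = paste0(topology$name, if (length(out) > 1L) paste0(":", p) else ""),
      residues = res,
      modules = modules,
      ligands = ligs,
      cleavage = topology$cleavage,
      motif = topology$motif,
      provenance = topology$provenance
    ), class = "conjugate_topology")
  }
  out
}
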