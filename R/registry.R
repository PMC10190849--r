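# Bundled registries: ligand templates and built-in conjugate designs.

#' Ligand template registry
#'
#' Returns the bundled ligand templates (coarse synthetic models of the Cy
#' dye, FITC and pyrene) or templates loaded from a user file with the same
#' schema. Each template carries local atom coordinates, element, apolar,
#' donor/acceptor flags, formal charge groups and the link atom through
#' which the ligand is grafted onto the peptide.
#'
#' @param path optional path to a YAML file overriding the bundled registry
#' @return a named list of templates
#' @export
ligand_registry <- function(path = NULL) {
  if (!is.null(path)) return(.load_ligand_templates(path))
  if (is.null(.pepconj_cache$ligands)) {
    .pepconj_cache$ligands <-
      .load_ligand_templates(pepconj_file("extdata", "ligand_templates.yaml"))
  }
  .pepconj_cache$ligands
}

.load_ligand_templates <- function(path) {
  raw <- yaml::read_yaml(path)$templates
  if (is.null(raw) || !length(raw)) stop("no ligand templates in ", path)
  if (anyDuplicated(names(raw))) stop("duplicated ligand template names")
  lapply(raw, function(t) {
    at <- do.call(rbind, lapply(t$atoms, function(a) {
      data.frame(name = a$name, element = a$element,
                 x = a$cx, y = a$cy, z = a$cz,
                 apolar = isTRUE(a$apolar), donor = isTRUE(a$donor),
                 acceptor = isTRUE(a$acceptor),
                 group = if (is.null(a$group)) NA_character_ else a$group,
                 sign = if (is.null(a$sign)) 0L else as.integer(a$sign),
                 stringsAsFactors = FALSE)
    }))
    if (nrow(at) < 1L) stop("ligand template ", t$label, " has no atoms")
    grp <- unique(at$group[!is.na(at$group)])
    for (g in grp) if (!sum(at$group %in% g))
      stop("empty charge group in template ", t$label)
    if (!t$link_atom %in% at$name)
      stop("link atom ", t$link_atom, " not among template atoms")
    list(label = t$label, atoms = at, link_atom = t$link_atom,
         link_bond = if (is.null(t$link_bond)) 1.8 else t$link_bond,
         description = t$description)
  })
}

#' Built-in conjugate design registry
#'
#' The eight designs screened in the source study, reconstructed as
#' described in each record's provenance note: the Palpha/Pbeta platforms
#' (targeting heptapeptide + DEVD substrate + KLVFFAE assembly module) and
#' their R2/R4/drug-loaded variants.
#'
#' @param path optional path to a YAML design file with the same schema as
#'   the bundled `designs.yaml`
#' @return a named list of `conjugate_topology` objects
#' @export
design_registry <- function(path = NULL) {
  if (!is.null(path)) return(.load_designs(path))
  if (is.null(.pepconj_cache$designs)) {
    .pepconj_cache$designs <-
      .load_designs(pepconj_file("extdata", "designs.yaml"))
  }
  .pepconj_cache$designs
}

.load_designs <- function(path) {
  raw <- yaml::read_yaml(path)
  cleav <- raw$cleavage
  out <- lapply(raw$designs, function(d) {
    if (is.null(d$cleavage)) d$cleavage <- cleav
    parse_conjugate_spec(d)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) stop("duplicated design names in ", path)
  out
}

#' Fetch one built-in design by name
#' @param name design name, e.g. `"Pbeta"` or `"Pbeta_R4C"`
#' @return a `conjugate_topology`
#' @export
get_design <- function(name) {
  reg <- design_registry()
  if (!name %in% names(reg))
    stop("unknown design: ", name, " (available: ",
         paste(names(reg), collapse = ", "), ")")
  reg[[name]]
}
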