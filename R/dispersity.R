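# The design statistic: solvent exposure of the assembly module (%SASA),
# the dispersity threshold classifier, and the pre/post-cleavage exposure
# comparison.

#' Solvent exposure of a module (%SASA)
#'
#' For each frame, the numerator is the summed solvent-accessible surface
#' area of the module's atoms in the context of the whole molecule; the
#' denominator is the same atoms' area with every other atom deleted at
#' identical coordinates (the isolated-module baseline). The statistic is
#' `100 * numerator / denominator`, averaged over frames (the per-frame
#' series and the alternative percent-of-means aggregate are retained).
#' Occluder-removal monotonicity bounds the value in \[0, 100\].
#'
#' @param ensemble a `conformation_ensemble` (or a `conformation`, treated
#'   as a one-frame ensemble)
#' @param module_id module whose exposure is scored (default `"ASM"`, the
#'   assembly module)
#' @param options a [sasa_options()] list
#' @param atom_subset optional logical/integer subset of atoms forming the
#'   molecular context (used by the cleavage analysis; default all atoms)
#' @return an object of class `exposure_result`: `percent_sasa` (mean of
#'   per-frame percents), `percent_of_means`, `per_frame` data frame,
#'   `numerator_mean`, `denominator_mean` (Angstrom^2), `molecule`,
#'   `module`, `options` and `denominator_mode`
#' @examples
#' ens <- as_ensemble(build_conformation(get_design("Pbeta")))
#' percent_sasa(ens, options = sasa_options(n_points = 120))
#' @export
percent_sasa <- function(ensemble, module_id = "ASM",
                         options = sasa_options(), atom_subset = NULL) {
  if (inherits(ensemble, "conformation")) ensemble <- as_ensemble(ensemble)
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  at <- ensemble$atoms
  keep <- if (is.null(atom_subset)) seq_len(nrow(at))
          else seq_len(nrow(at))[atom_subset]
  mod_atoms <- intersect(which(at$module == module_id), keep)
  if (!length(mod_atoms)) stop("module ", module_id,
                               " has no atoms in this context")
  nf <- ensemble$n_frames
  num <- den <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ensemble, f)
    ctx <- sasa(xyz[keep, , drop = FALSE], options,
                radii = at$radius[keep])
    num[f] <- sum(ctx[match(mod_atoms, keep)])
    den[f] <- sum(sasa(xyz[mod_atoms, , drop = FALSE], options,
                       radii = at$radius[mod_atoms]))
  }
  pct <- 100 * num / den
  structure(list(
    molecule = if (!is.null(ensemble$topology)) ensemble$topology$name
               else NA_character_,
    module = module_id,
    percent_sasa = mean(pct),
    percent_of_means = 100 * mean(num) / mean(den),
    numerator_mean = mean(num),
    denominator_mean = mean(den),
    per_frame = data.frame(frame = seq_len(nf), numerator = num,
                           denominator = den, percent = pct),
    options = options,
    denominator_mode = "isolated_module_same_coordinates"
  ), class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat("<exposure_result> ", x$molecule, " module ", x$module, ": %SASA = ",
      format(x$percent_sasa, digits = 4), " (", nrow(x$per_frame),
      " frame", if (nrow(x$per_frame) > 1L) "s", ", baseline: isolated ",
      "module at identical coordinates)\n", sep = "")
  invisible(x)
}

#' Dispersity classification by the %SASA threshold
#'
#' Designs whose assembly module remains largely solvent-exposed
#' (%SASA strictly above the threshold, default 75) are classified
#' `assembly_prone`; values at or below the threshold give `dispersed`.
#'
#' @param exposure an `exposure_result` or a bare percent value
#' @param threshold percent threshold in (0, 100)
#' @return `"assembly_prone"` or `"dispersed"`
#' @examples
#' classify_dispersity(88.6)   # assembly_prone
#' classify_dispersity(45.3)   # dispersed
#' @export
classify_dispersity <- function(exposure, threshold = 75) {
  stopifnot(threshold > 0, threshold < 100)
  pct <- if (inherits(exposure, "exposure_result")) exposure$percent_sasa
         else as.numeric(exposure)
  ifelse(pct > threshold, "assembly_prone", "dispersed")
}

#' Exposure change on enzymatic cleavage (frozen geometry)
#'
#' Cleaves the topology at its recognition motif, locates the product that
#' retains the assembly module, and recomputes %SASA on the same ensemble
#' coordinates with the cleaved-away atoms deleted — a frozen-geometry
#' simplification (no relaxation of the product). Because removing
#' occluders can never reduce accessibility, `delta >= 0` always, with
#' equality exactly when no removed atom is within occlusion range
#' (`r1 + r2 + 2 * probe`) of any module atom.
#'
#' @param ensemble a `conformation_ensemble` bound to a cleavable topology
#' @param rule optional cleavage rule (see [cleave()])
#' @param module_id module whose exposure is tracked (default `"ASM"`)
#' @param options a [sasa_options()] list
#' @return list with `precursor` and `product` (`exposure_result`s) and
#'   `delta` (product minus precursor percent)
#' @export
hydrolysis_exposure_delta <- function(ensemble, rule = NULL,
                                      module_id = "ASM",
                                      options = sasa_options()) {
  if (inherits(ensemble, "conformation")) ensemble <- as_ensemble(ensemble)
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  topology <- ensemble$topology
  if (is.null(topology)) stop("ensemble carries no topology")
  products <- cleave(topology, rule)
  has_mod <- vapply(products, function(p) module_id %in% names(p$modules),
                    TRUE)
  if (!any(has_mod))
    stop("no cleavage product contains module ", module_id)
  prod <- products[[which(has_mod)[1]]]

  at <- ensemble$atoms
  keep_res <- prod$residues$parent_index %||% prod$residues$index
  keep_lig <- vapply(prod$ligands, `[[`, "", "label")
  keep <- (at$entity == "res" & at$resno %in% keep_res) |
          (at$entity == "lig" & at$entity_label %in% keep_lig)

  precursor <- percent_sasa(ensemble, module_id, options)
  product <- percent_sasa(ensemble, module_id, options, atom_subset = keep)
  product$molecule <- paste0(precursor$molecule, " (product)")
  list(precursor = precursor, product = product,
       delta = product$percent_sasa - precursor$percent_sasa)
}
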