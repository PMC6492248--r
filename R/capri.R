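#' Fraction of native contacts (FNAT)
#'
#' Native contacts are receptor-residue x ligand-residue pairs of the
#' reference structure with any heavy-atom pair closer than 5 Angstrom.
#' FNAT is the fraction of these reproduced by the model (using the model's
#' own coordinates under the same criterion). Residues are mapped between
#' model and reference by `(chain, residue number + insertion code)`
#' identity. Hydrogens are excluded for reproducibility across models built
#' with and without them.
#'
#' @param model,reference [complex_structure()] objects over the same chains.
#' @param cutoff contact cutoff, Angstrom (default 5, strict `<`).
#' @return value in `[0, 1]`.
#' @export
fnat <- function(model, reference, cutoff = 5) {
  ref_ct <- residue_contact_keys(reference, cutoff)
  if (length(ref_ct) == 0L)
    stop("reference structure has no interface contacts")
  mod_ct <- residue_contact_keys(model, cutoff)
  check_residue_mapping(model, reference)
  length(intersect(ref_ct, mod_ct)) / length(ref_ct)
}

# receptor-residue x ligand-residue contact keys under an any-heavy-atom
# distance criterion
residue_contact_keys <- function(structure, cutoff) {
  at <- structure$atoms
  heavy <- toupper(substr(at$elem, 1L, 1L)) != "H"
  ra <- at[heavy & at$chain %in% structure$receptor_chains, , drop = FALSE]
  la <- at[heavy & at$chain %in% structure$ligand_chains, , drop = FALSE]
  dm <- cross_dist(coords(ra), coords(la))
  hit <- which(dm < cutoff, arr.ind = TRUE)
  unique(paste(residue_keys(ra)[hit[, 1L]], residue_keys(la)[hit[, 2L]],
               sep = "--"))
}

check_residue_mapping <- function(model, reference) {
  mk <- ca_atoms(model, "all")$key
  rk <- ca_atoms(reference, "all")$key
  unmapped <- setdiff(rk, mk)
  if (length(unmapped) > 0L)
    stop("reference residues unmappable to the model: ",
         paste(utils::head(unmapped, 10L), collapse = ", "),
         if (length(unmapped) > 10L) " ..." else "")
  invisible(TRUE)
}

# matched C-alpha coordinate matrices (model, reference) for one group,
# ordered by the reference's residue keys
matched_ca <- function(model, reference, group) {
  mca <- ca_atoms(model, group)
  rca <- ca_atoms(reference, group)
  common <- rca$key[rca$key %in% mca$key]
  if (length(setdiff(rca$key, mca$key)) > 0L)
    stop("model is missing ", group, " residues: ",
         paste(utils::head(setdiff(rca$key, mca$key), 10L), collapse = ", "))
  mi <- match(common, mca$key); ri <- match(common, rca$key)
  list(model = coords(mca)[mi, , drop = FALSE],
       reference = coords(rca)[ri, , drop = FALSE],
       keys = common)
}

#' Ligand RMSD (LRMSD)
#'
#' C-alpha RMSD over the ligand after optimally superposing the model's
#' receptor C-alpha atoms onto the reference receptor ([kabsch_superpose()]);
#' the fitted transform is applied to the whole model, and the ligand
#' deviation is measured without further fitting.
#'
#' @inheritParams fnat
#' @return LRMSD in Angstrom.
#' @export
lrmsd <- function(model, reference) {
  rec <- matched_ca(model, reference, "receptor")
  lig <- matched_ca(model, reference, "ligand")
  fit <- kabsch_superpose(rec$model, rec$reference)
  lig_fitted <- apply_transform(lig$model, fit$rotation, fit$translation)
  rmsd(lig_fitted, lig$reference)
}

#' Interface RMSD (IRMSD)
#'
#' Interface residues are defined on the reference structure: a receptor and
#' a ligand residue are interface partners when any of their heavy atoms are
#' closer than `interface_cutoff` (10 Angstrom). The C-alpha atoms of all
#' interface residues are optimally superposed between model and reference,
#' and the post-fit RMSD over those same atoms is returned.
#'
#' @inheritParams fnat
#' @param interface_cutoff any-atom interface cutoff on the reference,
#'   Angstrom (default 10, strict `<`).
#' @return IRMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interface_cutoff = 10) {
  keys <- interface_residue_keys(reference, interface_cutoff)
  if (length(keys) == 0L) stop("reference structure has an empty interface")
  rec <- matched_ca(model, reference, "receptor")
  lig <- matched_ca(model, reference, "ligand")
  mk <- c(rec$keys, lig$keys)
  sel <- mk %in% keys
  mpos <- rbind(rec$model, lig$model)[sel, , drop = FALSE]
  rpos <- rbind(rec$reference, lig$reference)[sel, , drop = FALSE]
  kabsch_superpose(mpos, rpos)$rmsd
}

# residue keys (both sides) of the reference-defined interface
interface_residue_keys <- function(structure, cutoff) {
  at <- structure$atoms
  heavy <- toupper(substr(at$elem, 1L, 1L)) != "H"
  ra <- at[heavy & at$chain %in% structure$receptor_chains, , drop = FALSE]
  la <- at[heavy & at$chain %in% structure$ligand_chains, , drop = FALSE]
  dm <- cross_dist(coords(ra), coords(la))
  hit <- which(dm < cutoff, arr.ind = TRUE)
  unique(c(residue_keys(ra)[hit[, 1L]], residue_keys(la)[hit[, 2L]]))
}

#' CAPRI quality class from the three metrics
#'
#' Standard CAPRI assessment thresholds, evaluated from high downward:
#' \itemize{
#'   \item high: `fnat >= 0.5` and (`lrmsd <= 1` or `irmsd <= 1`)
#'   \item medium: `fnat >= 0.3` and (`lrmsd <= 5` or `irmsd <= 2`)
#'   \item acceptable: `fnat >= 0.1` and (`lrmsd <= 10` or `irmsd <= 4`)
#'   \item otherwise incorrect.
#' }
#' The classification is monotone: improving any one metric never lowers the
#' class.
#'
#' @param fnat fraction of native contacts in `[0, 1]`.
#' @param lrmsd,irmsd Angstrom.
#' @return one of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
capri_class <- function(fnat, lrmsd, irmsd) {
  stopifnot(fnat >= 0, fnat <= 1, lrmsd >= 0, irmsd >= 0)
  if (fnat >= 0.5 && (lrmsd <= 1 || irmsd <= 1)) return("high")
  if (fnat >= 0.3 && (lrmsd <= 5 || irmsd <= 2)) return("medium")
  if (fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

#' Assess a model against a reference structure
#'
#' Computes FNAT, LRMSD and IRMSD plus the CAPRI class; when a starting
#' model is supplied, deltas relative to it (refined minus start; negative
#' RMSD deltas and positive FNAT deltas are improvements) are included.
#'
#' @param model,reference [complex_structure()] objects.
#' @param start optional starting [complex_structure()] assessed against the
#'   same reference.
#' @return object of class `quality_report`: list with `fnat`, `lrmsd`,
#'   `irmsd`, `capri_class` and optionally `deltas` (named vector
#'   `dfnat`, `dlrmsd`, `dirmsd`) and `improved` (logical vector).
#' @export
assess_model <- function(model, reference, start = NULL) {
  rep_ <- list(fnat = fnat(model, reference),
               lrmsd = lrmsd(model, reference),
               irmsd = irmsd(model, reference))
  rep_$capri_class <- capri_class(rep_$fnat, rep_$lrmsd, rep_$irmsd)
  if (!is.null(start)) {
    s <- assess_model(start, reference)
    rep_$deltas <- delta_report(rep_, s)
    rep_$improved <- c(fnat = rep_$deltas[["dfnat"]] > 0,
                       lrmsd = rep_$deltas[["dlrmsd"]] < 0,
                       irmsd = rep_$deltas[["dirmsd"]] < 0)
  }
  class(rep_) <- "quality_report"
  rep_
}

#' Metric deltas between a refined and a starting model report
#'
#' `delta = refined - start` for each metric; negative LRMSD/IRMSD deltas and
#' positive FNAT deltas indicate improvement over the starting model.
#'
#' @param refined,start `quality_report`s (or lists with `fnat`, `lrmsd`,
#'   `irmsd`) computed against the same reference.
#' @return named numeric vector `dfnat`, `dlrmsd`, `dirmsd`.
#' @export
delta_report <- function(refined, start) {
  c(dfnat = refined$fnat - start$fnat,
    dlrmsd = refined$lrmsd - start$lrmsd,
    dirmsd = refined$irmsd - start$irmsd)
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("FNAT %.3f | LRMSD %.2f A | IRMSD %.2f A | class: %s\n",
              x$fnat, x$lrmsd, x$irmsd, x$capri_class))
  if (!is.null(x$deltas))
    cat(sprintf("vs start: dFNAT %+.3f | dLRMSD %+.2f | dIRMSD %+.2f\n",
                x$deltas[["dfnat"]], x$deltas[["dlrmsd"]],
                x$deltas[["dirmsd"]]))
  invisible(x)
}
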