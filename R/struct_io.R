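#' Construct a two-group protein-protein complex
#'
#' A `complex_structure` holds the atoms of a docked complex together with the
#' partition of its chains into a receptor group and a ligand group. All
#' geometric operations in the package (contact detection, CAPRI metrics,
#' model averaging) work on this container. Chain groups may contain several
#' chains, but single-chain receptor and ligand is the usual configuration.
#'
#' @param atoms data.frame with columns `chain`, `resno` (author numbering,
#'   integer), `insert` (insertion code, `""` when absent), `resid` (3-letter
#'   residue name), `elety` (atom name), `eleno` (atom serial), `elem`
#'   (element symbol), `x`, `y`, `z` (orthogonal coordinates, Angstrom).
#' @param receptor_chains character vector of receptor chain identifiers.
#' @param ligand_chains character vector of ligand chain identifiers.
#' @param label free-text label for reports.
#'
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, receptor_chains, ligand_chains,
                              label = "complex") {
  receptor_chains <- unique(as.character(receptor_chains))
  ligand_chains <- unique(as.character(ligand_chains))
  if (length(receptor_chains) == 0L || length(ligand_chains) == 0L)
    stop("receptor and ligand chain groups must both be non-empty")
  if (length(intersect(receptor_chains, ligand_chains)) > 0L)
    stop("receptor and ligand chain groups overlap: ",
         paste(intersect(receptor_chains, ligand_chains), collapse = ", "))
  req <- c("chain", "resno", "insert", "resid", "elety", "eleno",
           "elem", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L)
    stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("atoms table is empty")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elety))) stop("empty atom names present")
  known <- atoms$chain %in% c(receptor_chains, ligand_chains)
  if (!all(known)) {
    atoms <- atoms[known, , drop = FALSE]
    if (nrow(atoms) == 0L) stop("no atoms left after chain selection")
  }
  x <- structure(
    list(atoms = atoms, receptor_chains = receptor_chains,
         ligand_chains = ligand_chains, label = label),
    class = "complex_structure")
  for (grp in c("receptor", "ligand")) {
    if (nrow(ca_atoms(x, grp)) < 1L)
      stop("no C-alpha atoms in ", grp, " group")
  }
  x
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf(
    "complex_structure '%s': %d atoms | receptor [%s] %d res | ligand [%s] %d res\n",
    x$label, nrow(x$atoms),
    paste(x$receptor_chains, collapse = ","), nrow(ca_atoms(x, "receptor")),
    paste(x$ligand_chains, collapse = ","), nrow(ca_atoms(x, "ligand"))))
  invisible(x)
}

#' Residue keys (chain:resno+insert) for an atom table
#' @param atoms atom data.frame as in [complex_structure()].
#' @return character vector of residue identifiers, one per atom.
#' @keywords internal
residue_keys <- function(atoms) {
  if (nrow(atoms) == 0L) return(character(0))
  paste0(atoms$chain, ":", atoms$resno, atoms$insert)
}

#' Extract C-alpha atoms of one chain group
#'
#' @param structure a [complex_structure()].
#' @param group `"receptor"`, `"ligand"` or `"all"`.
#' @return data.frame of CA atom records, with a `key` column of residue
#'   identifiers.
#' @export
ca_atoms <- function(structure, group = c("receptor", "ligand", "all")) {
  group <- match.arg(group)
  at <- structure$atoms
  chains <- switch(group,
                   receptor = structure$receptor_chains,
                   ligand = structure$ligand_chains,
                   all = c(structure$receptor_chains, structure$ligand_chains))
  sel <- at$elety == "CA" & at$chain %in% chains
  out <- at[sel, , drop = FALSE]
  out$key <- residue_keys(out)
  # keep the first CA per residue (guards against stray duplicates)
  out[!duplicated(out$key), , drop = FALSE]
}

#' Coordinate matrix of an atom table
#' @param atoms atom data.frame.
#' @return numeric matrix n x 3.
#' @keywords internal
coords <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Read a docked complex from a PDB file
#'
#' Reads ATOM records of the first model (first alternate location kept) and
#' partitions the named chains into receptor and ligand groups. HETATM records
#' (waters, ions, ligand cofactors from simulations) are excluded unless
#' `include_het = TRUE`. Hydrogens are kept if present; downstream operations
#' name their atom selections explicitly.
#'
#' @param path PDB file path.
#' @param receptor_chains,ligand_chains chain identifier vectors.
#' @param include_het keep HETATM records (default `FALSE`).
#' @param label label for the returned structure (default: file name).
#' @return A [complex_structure()].
#' @export
read_pdb <- function(path, receptor_chains, ligand_chains,
                     include_het = FALSE, label = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  avail <- unique(at$chain)
  missing <- setdiff(c(receptor_chains, ligand_chains), avail)
  if (length(missing) > 0L)
    stop("chain(s) not found in ", path, ": ",
         paste(missing, collapse = ", "),
         " (available: ", paste(avail, collapse = ", "), ")")
  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    eleno = at$eleno,
    elem = ifelse(is.na(at$elesy), substr(trimws(at$elety), 1L, 1L), at$elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  complex_structure(atoms, receptor_chains, ligand_chains, label = label)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one [complex_structure()] frame, in file order.
#' All models must share the same atom topology.
#'
#' @inheritParams read_pdb
#' @return list of [complex_structure()] frames.
#' @export
read_pdb_trajectory <- function(path, receptor_chains, ligand_chains,
                                include_het = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  first <- read_pdb(path, receptor_chains, ligand_chains,
                    include_het = include_het, label = basename(path))
  keep <- if (include_het) rep(TRUE, nrow(pdb$atom)) else pdb$atom$type == "ATOM"
  keep <- keep & pdb$atom$chain %in% c(receptor_chains, ligand_chains)
  idx <- which(keep)
  lapply(seq_len(nrow(xyz)), function(i) {
    fr <- first
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)[idx, , drop = FALSE]
    fr$atoms$x <- m[, 1L]; fr$atoms$y <- m[, 2L]; fr$atoms$z <- m[, 3L]
    fr$label <- sprintf("%s#%d", basename(path), i)
    fr
  })
}

#' Write a complex to a PDB file
#'
#' Standard ATOM records; coordinates round-trip through [read_pdb()] to the
#' 3-decimal precision of the PDB format.
#'
#' @param structure a [complex_structure()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  if (nrow(at) == 0L) stop("cannot write an empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords(at))),
    resno = at$resno,
    resid = at$resid,
    eleno = at$eleno,
    elety = at$elety,
    chain = at$chain,
    insert = ifelse(nzchar(at$insert), at$insert, NA),
    elesy = at$elem)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of `mobile` onto `target` with a proper
#' rotation (det = +1). Points are rows; the fitted coordinates are
#' `mobile %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,target numeric n x 3 matrices, n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (post-fit RMSD, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("point sets differ in size")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop("degenerate (rank-deficient) point configuration")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- ct - as.numeric(cm %*% R)
  fitted <- sweep(mobile %*% R, 2L, tr, "+")
  list(rotation = R, translation = tr, rmsd = rmsd(fitted, target))
}

#' Apply a rigid transform to points (row convention)
#' @param pts n x 3 matrix.
#' @param rotation 3 x 3 matrix; @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(pts, rotation, translation) {
  sweep(as.matrix(pts) %*% rotation, 2L, translation, "+")
}

#' Root-mean-square deviation without fitting
#'
#' @param a,b numeric n x 3 matrices of paired points (Angstrom).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("point sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Validate and assemble an ensemble of docked solutions
#'
#' All members must share the same receptor and ligand C-alpha residue keys
#' (identical residue topology); atom counts may differ elsewhere.
#'
#' @param members list of [complex_structure()].
#' @return the list, validated, with class `complex_ensemble`.
#' @export
complex_ensemble <- function(members) {
  if (length(members) < 1L) stop("ensemble needs at least one member")
  keys <- lapply(members, function(m) ca_atoms(m, "all")$key)
  ref <- keys[[1L]]
  for (i in seq_along(keys)) {
    if (!identical(sort(keys[[i]]), sort(ref)))
      stop("ensemble member ", i, " differs in residue topology")
  }
  structure(members, class = "complex_ensemble")
}
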