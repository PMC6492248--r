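#' Surrogate interface energy score (ZRANK-style, lower = better)
#'
#' A deterministic, additive stand-in for an empirical protein-protein
#' scoring function, computed over heavy atoms within 10 Angstrom across the
#' receptor-ligand interface:
#' \itemize{
#'   \item a soft Lennard-Jones term (`epsilon` = 0.2 kJ/mol,
#'     `sigma` = 3.5 Angstrom) with the repulsive branch linearized below
#'     2.5 Angstrom so that clashes are penalized but finite;
#'   \item a distance-screened Coulomb term between side-chain charge centers
#'     (ARG/LYS/HIS +1 on CB-like atoms, ASP/GLU -1), screening length
#'     8 Angstrom;
#'   \item a desolvation proxy of -0.2 kJ/mol per residue-residue contact
#'     (any heavy-atom pair < 5 Angstrom), rewarding buried interface.
#' }
#' The score depends only on interatomic distances, so it is invariant under
#' rigid transforms of the whole complex. An external scorer's output can be
#' used instead anywhere a score table is accepted.
#'
#' @param structure a [complex_structure()].
#' @param cutoff interface pair cutoff, Angstrom (default 10).
#' @return scalar score (arbitrary units, lower = better). When no interface
#'   atom pair falls within the cutoff a worst-case sentinel (`1e6`) is
#'   returned with a warning.
#' @export
surrogate_interface_score <- function(structure, cutoff = 10) {
  at <- structure$atoms
  heavy <- toupper(substr(at$elem, 1L, 1L)) != "H"
  rsel <- heavy & at$chain %in% structure$receptor_chains
  lsel <- heavy & at$chain %in% structure$ligand_chains
  ra <- at[rsel, , drop = FALSE]; la <- at[lsel, , drop = FALSE]
  dm <- cross_dist(coords(ra), coords(la))
  within <- dm < cutoff
  if (!any(within)) {
    warning("no interface atoms within ", cutoff, " A; returning sentinel")
    return(1e6)
  }
  r <- dm[within]
  # soft Lennard-Jones: linearized repulsion below r_soft keeps clashes finite
  eps <- 0.2; sig <- 3.5; r_soft <- 2.5
  lj_at <- function(rr) {
    sr6 <- (sig / rr)^6
    4 * eps * (sr6^2 - sr6)
  }
  lj <- ifelse(r >= r_soft,
               lj_at(pmax(r, 1e-6)),
               lj_at(r_soft) + (r_soft - r) * 50)   # 50 kJ/mol/A slope
  e_lj <- sum(lj)
  # screened Coulomb between charge-carrying side-chain atoms
  qr <- residue_charges(ra); ql <- residue_charges(la)
  e_coul <- 0
  if (any(qr != 0) && any(ql != 0)) {
    qi <- which(qr != 0); qj <- which(ql != 0)
    dq <- dm[qi, qj, drop = FALSE]
    qq <- outer(qr[qi], ql[qj])
    keep <- dq < cutoff
    if (any(keep))
      e_coul <- sum((138.935 * qq[keep] / pmax(dq[keep], 1)) *
                      exp(-dq[keep] / 8))
  }
  # desolvation proxy: count residue-residue contacts (any heavy atom < 5 A)
  rk <- residue_keys(ra); lk <- residue_keys(la)
  hit <- which(dm < 5, arr.ind = TRUE)
  n_contacts <- length(unique(paste(rk[hit[, 1L]], lk[hit[, 2L]])))
  e_lj + e_coul - 0.2 * n_contacts
}

# +/-1 side-chain charges by residue name, placed on the CB (or first
# side-chain) atom; zero elsewhere
residue_charges <- function(atoms) {
  q <- numeric(nrow(atoms))
  carrier <- atoms$elety == "CB"
  q[carrier & atoms$resid %in% c("ARG", "LYS", "HIS")] <- 1
  q[carrier & atoms$resid %in% c("ASP", "GLU")] <- -1
  q
}

#' Normalize scores to the unit interval (1 = best)
#'
#' Affine map of a score vector onto `[0, 1]` such that the best value under
#' the stated orientation maps to 1 and the worst to 0. With this convention
#' a higher combined score [cs_alpha()] always means a better snapshot. A
#' constant vector maps to all 0.5 (documented degenerate rule; keeps the
#' combined score defined).
#'
#' @param values numeric vector, finite.
#' @param orientation `"lower_is_better"` (energy convention, default) or
#'   `"higher_is_better"`.
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_01 <- function(values,
                         orientation = c("lower_is_better",
                                         "higher_is_better")) {
  orientation <- match.arg(orientation)
  if (length(values) == 0L) stop("empty score vector")
  if (any(!is.finite(values)))
    stop("non-finite scores at positions: ",
         paste(which(!is.finite(values)), collapse = ", "))
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(values)))
  u <- (values - rng[1L]) / (rng[2L] - rng[1L])
  if (orientation == "lower_is_better") 1 - u else u
}

#' Mixed score CS_alpha
#'
#' Convex combination of the 0-1 normalized external (ZRANK-style) score and
#' the 0-1 normalized free-energy score:
#' `CS_alpha = alpha * zrank_eta + (1 - alpha) * fes_eta`.
#' `alpha = 1` reduces to the external score alone, `alpha = 0` to the free
#' energy alone. Higher CS_alpha = better snapshot.
#'
#' @param zrank_eta,fes_eta numeric vectors in `[0, 1]`, equal length.
#' @param alpha weighting factor in `[0, 1]`.
#' @return numeric vector of combined scores.
#' @export
cs_alpha <- function(zrank_eta, fes_eta, alpha) {
  if (length(zrank_eta) != length(fes_eta))
    stop("score vectors differ in length")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  alpha * zrank_eta + (1 - alpha) * fes_eta
}

#' Attach free-energy values to snapshot records
#'
#' Linear interpolation of the reconstructed free energy surface at each
#' snapshot's CV value. CV values outside the grid are clamped to the nearest
#' edge; a warning reports how many were clamped.
#'
#' @param records data.frame with a `cv` column (one row per snapshot).
#' @param fes an `fes_profile` from [reconstruct_fes()].
#' @return the records with a `fes_kjmol` column added/overwritten.
#' @export
attach_fes <- function(records, fes) {
  if (is.null(fes$grid) || length(fes$grid) == 0L) stop("empty FES")
  cv <- records$cv
  n_out <- sum(cv < min(fes$grid) | cv > max(fes$grid))
  if (n_out > 0L)
    warning(n_out, " CV value(s) outside the FES grid; clamped to the edge")
  records$fes_kjmol <- stats::approx(fes$grid, fes$free_energy, xout = cv,
                                     rule = 2)$y
  records
}

#' Build a per-snapshot score table
#'
#' Assembles the full scoring record for a set of trajectory snapshots:
#' CMS value, external (ZRANK-style) score, free energy, the two 0-1
#' normalized scores and the combined CS_alpha. Normalization is performed
#' over all rows passed in (by default all replicas of a target pooled
#' together); pass per-replica subsets for per-replica normalization.
#'
#' @param frames list of [complex_structure()] snapshots.
#' @param replica integer vector, replica index per frame.
#' @param time_ps numeric vector, snapshot time per frame.
#' @param cmap optional `contact_map` for CMS values (else `cv = NA`).
#' @param fes optional `fes_profile` (or list of per-replica profiles, one
#'   per replica index) for free-energy scores.
#' @param external_scores optional numeric vector of external scores (lower =
#'   better); when `NULL` the [surrogate_interface_score()] is computed.
#' @param reference optional reference [complex_structure()]; when given, a
#'   `lrmsd` column is added via [lrmsd()].
#' @param alpha weighting for the combined score (default 0.5).
#' @return data.frame of class `score_table` with columns `replica`,
#'   `time_ps`, `cv`, `external_score`, `fes_kjmol`, `zrank_eta`, `fes_eta`,
#'   `cs_alpha` (and `lrmsd` when a reference is given).
#' @export
score_table <- function(frames, replica, time_ps, cmap = NULL, fes = NULL,
                        external_scores = NULL, reference = NULL,
                        alpha = 0.5) {
  n <- length(frames)
  stopifnot(length(replica) == n, length(time_ps) == n)
  tab <- data.frame(replica = as.integer(replica), time_ps = time_ps)
  tab$cv <- if (is.null(cmap)) NA_real_ else
    vapply(frames, cms_value, numeric(1L), cmap = cmap)
  tab$external_score <- if (is.null(external_scores))
    vapply(frames, surrogate_interface_score, numeric(1L)) else {
      stopifnot(length(external_scores) == n)
      external_scores
    }
  if (!is.null(fes)) {
    if (inherits(fes, "fes_profile")) {
      tab <- attach_fes(tab, fes)
    } else {
      tab$fes_kjmol <- NA_real_
      for (r in unique(tab$replica)) {
        sel <- tab$replica == r
        tab$fes_kjmol[sel] <- attach_fes(tab[sel, , drop = FALSE],
                                         fes[[r]])$fes_kjmol
      }
    }
  } else tab$fes_kjmol <- NA_real_
  if (!is.null(reference))
    tab$lrmsd <- vapply(frames, lrmsd, numeric(1L), reference = reference)
  tab$zrank_eta <- normalize_01(tab$external_score, "lower_is_better")
  tab$fes_eta <- if (all(is.na(tab$fes_kjmol))) NA_real_ else
    normalize_01(tab$fes_kjmol, "lower_is_better")
  tab$cs_alpha <- if (all(is.na(tab$fes_eta))) tab$zrank_eta else
    cs_alpha(tab$zrank_eta, tab$fes_eta, alpha)
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Read an external score table (TSV: replica, time_ps, score)
#'
#' For plugging in scores from a real external scorer in place of the
#' surrogate. Columns `replica`, `time_ps`, `score` (lower = better).
#'
#' @param path TSV file path with a header line.
#' @return data.frame with those columns.
#' @export
read_external_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("replica", "time_ps", "score")
  if (!all(need %in% names(df)))
    stop("external score table must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' Write a score table as TSV
#' @param tab a `score_table`; @param path file path.
#' @export
write_score_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
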