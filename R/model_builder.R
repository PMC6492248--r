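#' Select the best-scored snapshots from a score table
#'
#' Top-`n` rows by descending selection score, pooled over replicas.
#' The default selection score is the normalized external score
#' (`zrank_eta`); `by = "cs_alpha"` uses the mixed score instead. Ties are
#' broken by `time_ps` then `replica` for determinism.
#'
#' @param tab a [score_table()] (or data.frame with the named columns).
#' @param n number of snapshots to select (default 14).
#' @param by `"zrank"` (default) or `"cs_alpha"`.
#' @return integer vector of selected row indices, best first.
#' @export
select_snapshots <- function(tab, n = 14L, by = c("zrank", "cs_alpha")) {
  by <- match.arg(by)
  if (nrow(tab) < n)
    stop("only ", nrow(tab), " snapshots available; need n = ", n)
  score <- switch(by, zrank = tab$zrank_eta, cs_alpha = tab$cs_alpha)
  ord <- order(-score, tab$time_ps, tab$replica)
  ord[seq_len(n)]
}

#' Average equivalent atomic coordinates over snapshots
#'
#' Every snapshot is first rigidly superposed onto the first one in the list
#' (in model building: the best-scored snapshot) using receptor C-alpha
#' atoms, then each atom's Cartesian coordinates are arithmetically averaged.
#' All snapshots must share an identical atom topology.
#'
#' @param snapshots list of [complex_structure()] with identical topology.
#' @return a [complex_structure()] with averaged coordinates (label
#'   `"averaged"`).
#' @export
average_structure <- function(snapshots) {
  if (length(snapshots) < 1L) stop("no snapshots to average")
  ref <- snapshots[[1L]]
  ids <- function(s) paste(s$atoms$chain, s$atoms$resno, s$atoms$insert,
                           s$atoms$elety)
  ref_ids <- ids(ref)
  ref_rec_ca <- coords(ca_atoms(ref, "receptor"))
  acc <- matrix(0, nrow(ref$atoms), 3L)
  for (i in seq_along(snapshots)) {
    s <- snapshots[[i]]
    di <- ids(s)
    if (length(di) != length(ref_ids) || any(di != ref_ids)) {
      first <- if (length(di) != length(ref_ids)) 1L else which(di != ref_ids)[1L]
      stop("snapshot ", i, " differs in atom topology (first mismatch: atom ",
           first, ")")
    }
    fit <- kabsch_superpose(coords(ca_atoms(s, "receptor")), ref_rec_ca)
    acc <- acc + apply_transform(coords(s$atoms), fit$rotation,
                                 fit$translation)
  }
  avg <- ref
  m <- acc / length(snapshots)
  avg$atoms$x <- m[, 1L]; avg$atoms$y <- m[, 2L]; avg$atoms$z <- m[, 3L]
  avg$label <- "averaged"
  avg
}

# non-bonded heavy-atom pair list of a structure: all pairs except
# same-residue pairs and consecutive-residue backbone (CA-CA) links
nonbonded_pairs <- function(structure) {
  at <- structure$atoms
  heavy <- which(toupper(substr(at$elem, 1L, 1L)) != "H")
  res <- residue_keys(at)[heavy]
  n <- length(heavy)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same_res <- res[ij[, 1L]] == res[ij[, 2L]]
  ca <- at$elety[heavy] == "CA"
  chain <- at$chain[heavy]; resno <- at$resno[heavy]
  backbone <- ca[ij[, 1L]] & ca[ij[, 2L]] &
    chain[ij[, 1L]] == chain[ij[, 2L]] &
    abs(resno[ij[, 1L]] - resno[ij[, 2L]]) == 1L
  list(i = heavy[ij[!same_res & !backbone, 1L]],
       j = heavy[ij[!same_res & !backbone, 2L]])
}

#' Count heavy-atom clashes
#'
#' Non-bonded heavy-atom pairs (different residues, excluding the
#' consecutive-residue C-alpha link) closer than `cutoff` (default 2.0
#' Angstrom).
#'
#' @param structure a [complex_structure()].
#' @param cutoff clash distance, Angstrom.
#' @return integer clash count.
#' @export
clash_count <- function(structure, cutoff = 2.0) {
  nb <- nonbonded_pairs(structure)
  p <- coords(structure$atoms)
  d <- sqrt(rowSums((p[nb$i, , drop = FALSE] - p[nb$j, , drop = FALSE])^2))
  sum(d < cutoff)
}

#' Relax an averaged structure by steepest descent
#'
#' Resolves non-physical local geometry (atom clashes produced by coordinate
#' averaging) with a lightweight restrained minimization: a soft-sphere
#' repulsion between non-bonded heavy atoms (`(r_c - r)^2` for `r < r_c`,
#' `r_c` = 2.8 Angstrom), a harmonic tether of every atom to its input
#' position, and flat-bottom restraints holding bonded distances (within-
#' residue pairs and consecutive C-alpha links) near their input values.
#' Steepest descent with backtracking line search; the energy sequence is
#' non-increasing and the heavy-atom clash count never ends above its
#' initial value. A clash-free input has zero repulsion gradient and is
#' returned unchanged.
#'
#' @param structure a [complex_structure()].
#' @param max_steps step cap (default 200).
#' @param k_repulsion,k_tether,k_bond force constants (kJ/mol/A^2).
#' @param r_clash soft-sphere onset distance, Angstrom (default 2.8).
#' @param f_tol maximum-force convergence threshold.
#' @return relaxed [complex_structure()] with attributes `relax_steps`,
#'   `clash_before`, `clash_after`.
#' @export
relax <- function(structure, max_steps = 200L, k_repulsion = 10,
                  k_tether = 0.5, k_bond = 5, r_clash = 2.8, f_tol = 0.05) {
  at <- structure$atoms
  x0 <- coords(at)
  nb <- nonbonded_pairs(structure)
  # bonded list: within-residue heavy-atom pairs + consecutive CA-CA
  heavy <- which(toupper(substr(at$elem, 1L, 1L)) != "H")
  res <- residue_keys(at)[heavy]
  bi <- integer(0); bj <- integer(0)
  for (r in split(heavy, res)) {
    if (length(r) > 1L) {
      cmb <- utils::combn(r, 2L)
      bi <- c(bi, cmb[1L, ]); bj <- c(bj, cmb[2L, ])
    }
  }
  ca_idx <- which(at$elety == "CA")
  for (ch in unique(at$chain)) {
    ci <- ca_idx[at$chain[ca_idx] == ch]
    ci <- ci[order(at$resno[ci])]
    if (length(ci) > 1L) {
      bi <- c(bi, ci[-length(ci)]); bj <- c(bj, ci[-1L])
    }
  }
  b0 <- sqrt(rowSums((x0[bi, , drop = FALSE] - x0[bj, , drop = FALSE])^2))
  bond_tol <- 0.1  # flat bottom half-width, Angstrom

  energy_grad <- function(x) {
    g <- matrix(0, nrow(x), 3L)
    e <- 0
    dv <- x[nb$i, , drop = FALSE] - x[nb$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    viol <- which(d < r_clash)
    if (length(viol) > 0L) {
      dd <- pmax(d[viol], 1e-6)
      e <- e + k_repulsion * sum((r_clash - dd)^2)
      f <- (-2 * k_repulsion * (r_clash - dd)) / dd  # dE/dd / d
      gi <- dv[viol, , drop = FALSE] * f
      for (k in seq_along(viol)) {
        ii <- nb$i[viol[k]]; jj <- nb$j[viol[k]]
        g[ii, ] <- g[ii, ] + gi[k, ]
        g[jj, ] <- g[jj, ] - gi[k, ]
      }
    }
    dt <- x - x0
    e <- e + k_tether * sum(dt^2)
    g <- g + 2 * k_tether * dt
    bv <- x[bi, , drop = FALSE] - x[bj, , drop = FALSE]
    bd <- sqrt(rowSums(bv^2))
    dev <- bd - b0
    out <- which(abs(dev) > bond_tol)
    if (length(out) > 0L) {
      ex <- dev[out] - sign(dev[out]) * bond_tol
      e <- e + k_bond * sum(ex^2)
      f <- (2 * k_bond * ex) / pmax(bd[out], 1e-6)
      gb <- bv[out, , drop = FALSE] * f
      for (k in seq_along(out)) {
        ii <- bi[out[k]]; jj <- bj[out[k]]
        g[ii, ] <- g[ii, ] + gb[k, ]
        g[jj, ] <- g[jj, ] - gb[k, ]
      }
    }
    list(e = e, g = g)
  }

  x <- x0
  clash0 <- clash_count(structure)
  best_x <- x; best_e <- Inf
  eg <- energy_grad(x)
  step <- 0L
  while (step < max_steps) {
    fmax <- max(abs(eg$g))
    if (fmax < f_tol) break
    gamma <- 0.1 / max(fmax, 1)   # initial step scaled to max force
    accepted <- FALSE
    for (ls in 1:20) {
      xn <- x - gamma * eg$g
      egn <- energy_grad(xn)
      if (egn$e <= eg$e) { accepted <- TRUE; break }
      gamma <- gamma / 2
    }
    if (!accepted) break
    x <- xn; eg <- egn
    if (eg$e < best_e) { best_e <- eg$e; best_x <- x }
    step <- step + 1L
  }
  out <- structure
  out$atoms$x <- best_x[, 1L]; out$atoms$y <- best_x[, 2L]
  out$atoms$z <- best_x[, 3L]
  clash1 <- clash_count(out)
  if (clash1 > clash0) {
    warning("relaxation could not reduce clash count; returning input")
    out <- structure
    clash1 <- clash0
  }
  attr(out, "relax_steps") <- step
  attr(out, "clash_before") <- clash0
  attr(out, "clash_after") <- clash1
  out
}

#' Build a refined model from scored trajectory snapshots
#'
#' The ensemble-averaging model building strategy: select the `n` best-scored
#' snapshots (default: by the normalized external score) pooled over all
#' replicas, superpose them onto the best-scored one via receptor C-alpha
#' atoms, average equivalent atomic coordinates, and relax the average to
#' resolve non-physical local geometry.
#'
#' @param frames list of [complex_structure()] snapshots, aligned with the
#'   rows of `tab`.
#' @param tab a [score_table()] for those frames.
#' @param n number of snapshots to average (default 14).
#' @param by selection score: `"zrank"` (default) or `"cs_alpha"`.
#' @param relax_args list of arguments passed on to [relax()].
#' @return list with `model` (the relaxed [complex_structure()]) and
#'   `report` (selected row indices, their replica/time/scores, and clash
#'   counts before/after relaxation).
#' @export
build_model <- function(frames, tab, n = 14L, by = c("zrank", "cs_alpha"),
                        relax_args = list()) {
  by <- match.arg(by)
  if (length(frames) != nrow(tab))
    stop("frames and score table differ in length")
  sel <- select_snapshots(tab, n = n, by = by)
  avg <- average_structure(frames[sel])
  relaxed <- do.call(relax, c(list(structure = avg), relax_args))
  report <- list(
    n = n, selection = by,
    snapshots = data.frame(row = sel,
                           replica = tab$replica[sel],
                           time_ps = tab$time_ps[sel],
                           external_score = tab$external_score[sel],
                           zrank_eta = tab$zrank_eta[sel],
                           cs_alpha = tab$cs_alpha[sel]),
    clash_before = attr(relaxed, "clash_before"),
    clash_after = attr(relaxed, "clash_after"),
    relax_steps = attr(relaxed, "relax_steps"))
  list(model = relaxed, report = report)
}

#' Write a build report as JSON
#' @param report the `report` element of [build_model()]'s result.
#' @param path file path.
#' @export
write_build_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
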