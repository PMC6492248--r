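#' Rodrigues rotation matrix from axis and angle
#' @param axis length-3 vector (normalized internally).
#' @param angle radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3L], a[2L],
                a[3L], 0, -a[1L],
                -a[2L], a[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# axis-angle (rotation vector, radians) from a proper rotation matrix
axis_angle <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-9) return(c(0, 0, 0))
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L],
          R[2L, 1L] - R[1L, 2L]) / (2 * sin(ang))
  ax * ang
}

random_unit_vector <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Generate a toy two-chain complex
#'
#' Deterministic synthetic complex for testing: receptor chain A and ligand
#' chain B built as gently curved bead chains (or idealized helices) with
#' exact 3.8 Angstrom C-alpha spacing, placed so the two chains run roughly
#' parallel 6.2 Angstrom apart and share a designed interface with at least
#' 10 C-alpha pairs under 8 Angstrom. Each residue carries a C-alpha plus
#' pseudo side-chain heavy atoms (CB, O) so that any-atom contact criteria
#' and the surrogate interface score are exercised separately from the
#' C-alpha-only geometry. Residue names cycle through a fixed set that
#' includes charged types. Not physically realistic; topology and geometry
#' are the point.
#'
#' @param n_res_receptor,n_res_ligand residues per chain (>= 5).
#' @param geometry `"bead"` (default) or `"helix"`.
#' @param jitter per-atom Gaussian jitter, Angstrom (default 0).
#' @param seed RNG seed for the jitter (and nothing else); the zero-jitter
#'   structure is seed-independent.
#' @return a [complex_structure()] (receptor chain `"A"`, ligand `"B"`).
#' @export
make_toy_complex <- function(n_res_receptor = 30L, n_res_ligand = 20L,
                             geometry = c("bead", "helix"), jitter = 0,
                             seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_res_receptor >= 5L, n_res_ligand >= 5L, jitter >= 0)
  resnames <- c("ALA", "ARG", "GLU", "LEU", "LYS", "ASP", "SER", "VAL")

  chain_ca <- function(n, origin, phase) {
    if (geometry == "bead") {
      pos <- matrix(0, n, 3L)
      pos[1L, ] <- origin
      for (i in seq_len(n - 1L)) {
        phi <- 0.12 * sin(0.35 * i + phase)
        pos[i + 1L, ] <- pos[i, ] + 3.8 * c(cos(phi), 0, sin(phi))
      }
      pos
    } else {
      r <- 2.3; dtheta <- 100 * pi / 180
      chord <- 2 * r * sin(dtheta / 2)
      rise <- sqrt(3.8^2 - chord^2)
      th <- phase + dtheta * (seq_len(n) - 1L)
      cbind(origin[1L] + rise * (seq_len(n) - 1L),
            origin[2L] + r * cos(th) - r,
            origin[3L] + r * sin(th))
    }
  }

  rec_ca <- chain_ca(n_res_receptor, c(0, 0, 0), 0)
  # stagger the ligand by half a bond so atoms interleave across the gap
  lig_x0 <- 3.8 * (n_res_receptor - n_res_ligand) / 2 + 1.9
  lig_ca <- chain_ca(n_res_ligand, c(lig_x0, 4.8, 0), 1)

  # Receptor CB atoms reach into the interface and pair with the ligand
  # backbone at ~3.8 A in the native pose: well inside the 5 A any-atom
  # contact criterion and near the Lennard-Jones optimum of the surrogate
  # score. Ligand side chains point away, so its interface contacts ride on
  # the C-alpha trace and degrade smoothly with any rigid-body motion.
  build_chain <- function(ca, chain, cb_y, o_y) {
    n <- nrow(ca)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      p <- ca[i, ]
      cb <- p + c(0, 1.5 * cb_y, 0.4)
      o <- p + c(0.8, 0.8 * o_y, -1.1)
      rows[[i]] <- data.frame(
        chain = chain,
        resno = i, insert = "",
        resid = resnames[(i - 1L) %% length(resnames) + 1L],
        elety = c("CA", "CB", "O"),
        eleno = 0L,
        elem = c("C", "C", "O"),
        x = c(p[1L], cb[1L], o[1L]),
        y = c(p[2L], cb[2L], o[2L]),
        z = c(p[3L], cb[3L], o[3L]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  atoms <- rbind(build_chain(rec_ca, "A", cb_y = +1, o_y = -1),
                 build_chain(lig_ca, "B", cb_y = +1, o_y = +1))
  atoms$eleno <- seq_len(nrow(atoms))
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(seed, {
      as.matrix(atoms[, c("x", "y", "z")]) +
        matrix(stats::rnorm(3L * nrow(atoms), sd = jitter), ncol = 3L)
    })
  }
  complex_structure(atoms, "A", "B",
                    label = sprintf("toy-%s-%dx%d", geometry,
                                    n_res_receptor, n_res_ligand))
}

#' Apply a rigid transform to the ligand group only
#'
#' Rotation about the ligand centroid followed by a translation; the
#' receptor is untouched. This is the elementary move for decoy generation
#' and synthetic trajectories.
#'
#' @param structure a [complex_structure()].
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 vector, Angstrom (default zero).
#' @return the transformed [complex_structure()].
#' @export
transform_ligand <- function(structure, rotation = diag(3L),
                             translation = c(0, 0, 0)) {
  sel <- structure$atoms$chain %in% structure$ligand_chains
  p <- coords(structure$atoms[sel, , drop = FALSE])
  ctr <- colMeans(p)
  pn <- sweep(sweep(p, 2L, ctr) %*% rotation, 2L, ctr + translation, "+")
  structure$atoms$x[sel] <- pn[, 1L]
  structure$atoms$y[sel] <- pn[, 2L]
  structure$atoms$z[sel] <- pn[, 3L]
  structure
}

#' Add Gaussian coordinate jitter to every atom
#' @param structure a [complex_structure()].
#' @param sigma jitter standard deviation, Angstrom.
#' @param seed RNG seed.
#' @return jittered [complex_structure()].
#' @export
jitter_structure <- function(structure, sigma, seed = 1L) {
  p <- with_seed(seed, coords(structure$atoms) +
                   matrix(stats::rnorm(3L * nrow(structure$atoms),
                                       sd = sigma), ncol = 3L))
  structure$atoms$x <- p[, 1L]
  structure$atoms$y <- p[, 2L]
  structure$atoms$z <- p[, 3L]
  structure
}

#' Generate a graded decoy ensemble of known quality
#'
#' Rigid ligand perturbations of increasing magnitude about the true
#' complex: for each requested magnitude the ligand is rotated about a
#' random axis (2 degrees per Angstrom of magnitude) and translated by the
#' magnitude along a random direction, with optional per-atom jitter. The
#' true LRMSD of every decoy is computed with [lrmsd()] and returned in a
#' manifest, giving a monotone quality ladder.
#'
#' @param truth the reference [complex_structure()].
#' @param magnitudes translation magnitudes per grade, Angstrom
#'   (default `c(1, 3, 6, 12)`).
#' @param n_per_grade decoys per grade (default 1).
#' @param jitter per-atom jitter, Angstrom (default 0).
#' @param seed RNG seed; generation is deterministic per seed.
#' @return list with `members` (list of [complex_structure()]) and
#'   `manifest` (data.frame `id`, `grade`, `magnitude`, `lrmsd`).
#' @export
make_decoy_ensemble <- function(truth, magnitudes = c(1, 3, 6, 12),
                                n_per_grade = 1L, jitter = 0, seed = 1L) {
  with_seed(seed, {
    members <- list()
    rows <- list()
    id <- 0L
    for (gi in seq_along(magnitudes)) {
      for (k in seq_len(n_per_grade)) {
        id <- id + 1L
        mag <- magnitudes[gi]
        dec <- transform_ligand(
          truth,
          rotation = rotation_matrix(random_unit_vector(),
                                     mag * 2 * pi / 180),
          translation = mag * random_unit_vector())
        if (jitter > 0)
          dec <- jitter_structure(dec, jitter,
                                  seed = stats::runif(1L, 1, 2^30))
        dec$label <- sprintf("decoy-%d", id)
        members[[id]] <- dec
        rows[[id]] <- data.frame(id = id, grade = gi, magnitude = mag,
                                 lrmsd = lrmsd(dec, truth))
      }
    }
    list(members = members, manifest = do.call(rbind, rows))
  })
}

#' Generate a synthetic refinement trajectory
#'
#' Stand-in for a production metadynamics trajectory: the ligand pose
#' (rotation vector + translation, measured relative to the true complex)
#' performs an Ornstein-Uhlenbeck walk attracted toward the native pose,
#' starting from a given decoy. With positive `funnel_strength` the walk
#' drifts down the binding funnel; with zero attraction and zero noise the
#' frames are constant. Frames are rigid-ligand copies of the truth topology
#' at a fixed time spacing; the per-frame true LRMSD is returned.
#'
#' @param truth reference [complex_structure()].
#' @param start a decoy sharing the truth's topology (the starting model).
#' @param n_frames number of frames (default 100).
#' @param spacing_ps time between frames, ps (default 50).
#' @param funnel_strength fractional pull toward the native pose per frame,
#'   in `[0, 1]` (default 0.05).
#' @param noise translation noise per frame, Angstrom (rotation noise is
#'   scaled as 0.02 rad per Angstrom; default 0.3).
#' @param seed RNG seed.
#' @return list with `frames` (list of [complex_structure()]), `time_ps`,
#'   and `lrmsd` (numeric, per frame).
#' @export
make_synthetic_trajectory <- function(truth, start, n_frames = 100L,
                                      spacing_ps = 50, funnel_strength = 0.05,
                                      noise = 0.3, seed = 1L) {
  stopifnot(funnel_strength >= 0, funnel_strength <= 1, noise >= 0)
  lsel <- truth$atoms$chain %in% truth$ligand_chains
  p_truth <- coords(truth$atoms[lsel, , drop = FALSE])
  p_start <- coords(start$atoms[start$atoms$chain %in%
                                  start$ligand_chains, , drop = FALSE])
  if (nrow(p_truth) != nrow(p_start))
    stop("start decoy does not share the truth's ligand topology")
  ctr <- colMeans(p_truth)
  fit <- kabsch_superpose(sweep(p_truth, 2L, ctr),
                          sweep(p_start, 2L, colMeans(p_start)))
  w <- axis_angle(fit$rotation)
  v <- colMeans(p_start) - ctr
  with_seed(seed, {
    frames <- vector("list", n_frames)
    lr <- numeric(n_frames)
    for (k in seq_len(n_frames)) {
      fr <- truth
      pn <- sweep(sweep(p_truth, 2L, ctr) %*%
                    rotation_matrix(if (sum(w^2) > 0) w else c(1, 0, 0),
                                    sqrt(sum(w^2))),
                  2L, ctr + v, "+")
      fr$atoms$x[lsel] <- pn[, 1L]
      fr$atoms$y[lsel] <- pn[, 2L]
      fr$atoms$z[lsel] <- pn[, 3L]
      fr$label <- sprintf("frame-%d", k)
      frames[[k]] <- fr
      lr[k] <- lrmsd(fr, truth)
      w <- w * (1 - funnel_strength) + stats::rnorm(3L, sd = noise * 0.02)
      v <- v * (1 - funnel_strength) + stats::rnorm(3L, sd = noise)
    }
    list(frames = frames, time_ps = spacing_ps * seq_len(n_frames),
         lrmsd = lr)
  })
}

#' Quartic double-well test potential
#'
#' `U(s) = barrier * ((s/a)^2 - 1)^2` with minima at `s = -a, +a`
#' (`a = minima_separation / 2`), `U(min) = 0` and a barrier of exactly
#' `barrier` kJ/mol at `s = 0`. The analytic gradient is included; this is
#' the standard test bed for the metadynamics engine. The default separation
#' of 6 CV units keeps the landscape features several kernel widths wide for
#' the usual sigma = 0.5, mirroring the production regime where that kernel
#' width sits on a collective variable spanning tens of units.
#'
#' @param barrier barrier height, kJ/mol (> 0).
#' @param minima_separation distance between the two minima (default 6).
#' @return list with `potential` (function), `gradient` (function),
#'   `minima` (length-2 vector) and `barrier`.
#' @export
double_well <- function(barrier, minima_separation = 6) {
  stopifnot(barrier > 0, minima_separation > 0)
  a <- minima_separation / 2
  list(
    potential = function(s) barrier * ((s / a)^2 - 1)^2,
    gradient = function(s) 4 * barrier * s * ((s / a)^2 - 1) / a^2,
    minima = c(-a, a),
    barrier = barrier)
}
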