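#' Boltzmann constant in kJ/(mol K)
#' @keywords internal
KB_KJMOL <- 0.008314462618

#' Create an empty well-tempered metadynamics bias
#'
#' Holds the ordered list of deposited Gaussian kernels plus the well-tempered
#' parameters. The bias factor gamma is the ratio between the effective
#' temperature of the collective variable and the system temperature;
#' `gamma = Inf` gives standard (non-tempered) metadynamics with constant
#' kernel heights.
#'
#' @param bias_factor well-tempered bias factor gamma (> 1, may be `Inf`).
#' @param temperature system temperature, K.
#' @param pace_ps deposition interval, ps.
#' @return object of class `bias_potential` with numeric vectors `center`,
#'   `sigma`, `height` (kJ/mol), `time` (ps).
#' @export
bias_potential <- function(bias_factor = 10, temperature = 300, pace_ps = 2) {
  if (!(bias_factor > 1)) stop("bias_factor must be > 1")
  if (!(temperature > 0)) stop("temperature must be positive")
  structure(list(center = numeric(0), sigma = numeric(0),
                 height = numeric(0), time = numeric(0),
                 bias_factor = bias_factor, temperature = temperature,
                 pace_ps = pace_ps),
            class = "bias_potential")
}

#' @export
print.bias_potential <- function(x, ...) {
  cat(sprintf("bias_potential: %d kernels | gamma=%g | T=%g K | pace=%g ps\n",
              length(x$center), x$bias_factor, x$temperature, x$pace_ps))
  invisible(x)
}

#' Accumulated bias energy at CV value(s)
#'
#' Exact summation over all deposited kernels:
#' `V(s) = sum_k h_k exp(-(s - c_k)^2 / (2 sigma_k^2))`. An empty bias gives 0.
#'
#' @param bias a [bias_potential()].
#' @param s CV value(s).
#' @return bias energy, kJ/mol (vectorized over `s`).
#' @export
bias_energy <- function(bias, s) {
  if (length(bias$center) == 0L) return(rep(0, length(s)))
  vapply(s, function(si) {
    sum(bias$height * exp(-(si - bias$center)^2 / (2 * bias$sigma^2)))
  }, numeric(1L))
}

#' Deposit a well-tempered Gaussian kernel
#'
#' Appends a kernel at CV value `s` with the standard well-tempered height
#' damping `h = h0 * exp(-V(s) / (kB * dT))`, where `dT = (gamma - 1) * T`.
#' The first deposit therefore has height exactly `h0`; heights at a
#' revisited point decay as bias accumulates. In the `gamma -> Inf` limit
#' heights stay constant at `h0` (standard metadynamics).
#'
#' @param bias a [bias_potential()].
#' @param s CV value of the deposit.
#' @param t simulation time, ps.
#' @param initial_height h0, kJ/mol (default 5).
#' @param sigma kernel width in CV units (default 0.5).
#' @return the updated `bias_potential`.
#' @export
deposit <- function(bias, s, t, initial_height = 5, sigma = 0.5) {
  if (!(sigma > 0) || !(initial_height > 0))
    stop("sigma and initial_height must be positive")
  dT <- (bias$bias_factor - 1) * bias$temperature
  damp <- if (is.infinite(dT)) 1 else exp(-bias_energy(bias, s) / (KB_KJMOL * dT))
  bias$center <- c(bias$center, s)
  bias$sigma <- c(bias$sigma, sigma)
  bias$height <- c(bias$height, initial_height * damp)
  bias$time <- c(bias$time, t)
  bias
}

#' Reconstruct the free energy surface from the accumulated bias
#'
#' Standard well-tempered estimator `F(s) = -(gamma / (gamma - 1)) * V(s)`,
#' shifted so that the minimum over the grid is exactly 0. For
#' `gamma = Inf` the prefactor is 1.
#'
#' @param bias a [bias_potential()] with at least one kernel.
#' @param grid strictly increasing CV grid.
#' @return object of class `fes_profile`: list with `grid` and `free_energy`
#'   (kJ/mol, min 0).
#' @export
reconstruct_fes <- function(bias, grid) {
  if (length(bias$center) == 0L) stop("bias has no kernels")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  g <- bias$bias_factor
  pref <- if (is.infinite(g)) 1 else g / (g - 1)
  # vectorized over the grid: outer(grid, centers)
  V <- exp(-outer(grid, bias$center, "-")^2 /
             matrix(2 * bias$sigma^2, length(grid), length(bias$center),
                    byrow = TRUE)) %*% bias$height
  fe <- -pref * as.numeric(V)
  structure(list(grid = grid, free_energy = fe - min(fe)),
            class = "fes_profile")
}

#' Analytic toy system for the surrogate sampler
#'
#' A one-dimensional stand-in for the solvated MD system: a scalar coordinate
#' moving in an analytic potential under overdamped Langevin dynamics.
#'
#' @param potential function `U(s)` returning kJ/mol.
#' @param gradient function `dU/ds(s)`.
#' @param friction friction coefficient, 1/ps.
#' @param temperature K.
#' @param timestep ps. The defaults (friction 1/ps, timestep 0.02 ps) keep
#'   the stiffness ratio `U'' * dt / friction` at or below ~0.75 on the
#'   reference double-well while letting a million steps cover 20 ns.
#' @param s0 initial coordinate.
#' @param seed integer RNG seed; the sampler is deterministic given the seed.
#' @return object of class `toy_system`.
#' @export
toy_system <- function(potential, gradient, friction = 1, temperature = 300,
                       timestep = 0.02, s0 = 0, seed = 1L) {
  if (!(timestep > 0)) stop("timestep must be positive")
  if (!(friction > 0)) stop("friction must be positive")
  structure(list(potential = potential, gradient = gradient,
                 friction = friction, temperature = temperature,
                 timestep = timestep, s0 = s0, seed = as.integer(seed)),
            class = "toy_system")
}

#' Run the surrogate metadynamics sampler on a toy system
#'
#' Overdamped Langevin dynamics on the scalar coordinate:
#' `s <- s - (dU/ds + dV_bias/ds) * dt / friction + noise`, where the noise
#' term uses the Leimkuhler-Matthews scheme - the average of the current and
#' previous Gaussian increments of variance `2 kB T dt / friction` - which
#' samples the configurational distribution with second-order accuracy at
#' the cost of a plain Euler step. When `bias_settings` is non-NULL,
#' well-tempered Gaussians are deposited
#' every `pace_ps`. For speed, the bias energy and force felt by the walker
#' are interpolated from a cached uniform grid that is updated at every
#' deposit; the cached energies agree with exact kernel summation at the grid
#' nodes to floating-point precision (the deposit heights themselves use
#' exact summation). The returned `bias_potential` holds the exact kernels.
#'
#' @param system a [toy_system()].
#' @param bias_settings `NULL` for unbiased dynamics, or a list with elements
#'   `sigma` (default 0.5), `height` (kJ/mol, default 5), `bias_factor`
#'   (default 10), `pace_ps` (default 2).
#' @param n_steps number of integration steps (>= 1).
#' @param grid_range range of the cached bias grid (the walker may leave it;
#'   bias outside is extrapolated from the edge).
#' @param grid_spacing spacing of the cached grid, CV units.
#' @param record_stride record every this-many steps (default 1).
#' @return list with `trajectory` (data.frame `time`, `s`, `bias`), `bias`
#'   (a [bias_potential()], empty when unbiased), and the final cache as
#'   `grid` / `bias_grid` (bias energy at the grid nodes; agrees with exact
#'   kernel summation to floating-point precision).
#' @export
run_toy_sampler <- function(system, bias_settings = NULL, n_steps,
                            grid_range = c(-15, 15), grid_spacing = 0.05,
                            record_stride = 1L) {
  stopifnot(n_steps >= 1)
  bs <- if (is.null(bias_settings)) NULL else
    utils::modifyList(list(sigma = 0.5, height = 5, bias_factor = 10,
                           pace_ps = 2), bias_settings)
  dt <- system$timestep
  fr <- system$friction
  kT <- KB_KJMOL * system$temperature
  noise_sd <- sqrt(2 * kT * dt / fr)
  grad <- system$gradient

  g0 <- grid_range[1L]; dx <- grid_spacing
  grid <- seq(grid_range[1L], grid_range[2L], by = dx)
  ng <- length(grid)
  Vg <- numeric(ng)            # cached bias energy on grid
  Fg <- numeric(ng)            # cached bias force (-dV/ds) on grid
  pace_steps <- if (is.null(bs)) Inf else max(1L, round(bs$pace_ps / dt))
  dT <- if (is.null(bs)) Inf else (bs$bias_factor - 1) * system$temperature

  n_dep_max <- if (is.null(bs)) 0L else floor(n_steps / pace_steps) + 1L
  kc <- numeric(n_dep_max); kh <- numeric(n_dep_max); kt <- numeric(n_dep_max)
  ndep <- 0L

  nrec <- floor((n_steps - 1) / record_stride) + 1L
  rec_t <- numeric(nrec); rec_s <- numeric(nrec); rec_v <- numeric(nrec)
  irec <- 0L

  s <- system$s0
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(system$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  chunk <- 10000L
  noise <- stats::rnorm(min(chunk, n_steps), sd = noise_sd)
  ni <- 0L
  xi_prev <- stats::rnorm(1L, sd = noise_sd)

  for (step in seq_len(n_steps)) {
    ni <- ni + 1L
    if (ni > length(noise)) {
      noise <- stats::rnorm(min(chunk, n_steps - step + 1L), sd = noise_sd)
      ni <- 1L
    }
    # cached bias force/energy by linear interpolation (clamped at edges)
    if (ndep > 0L) {
      u <- (s - g0) / dx
      i <- floor(u)
      if (i < 0) { i <- 0; u <- 0 } else if (i >= ng - 1L) { i <- ng - 2L; u <- ng - 1L }
      w <- u - i
      fb <- Fg[i + 1L] * (1 - w) + Fg[i + 2L] * w
      vb <- Vg[i + 1L] * (1 - w) + Vg[i + 2L] * w
    } else { fb <- 0; vb <- 0 }
    s <- s + (-grad(s) + fb) * dt / fr + (xi_prev + noise[ni]) / 2
    xi_prev <- noise[ni]
    if (!is.finite(s)) stop("sampler diverged; reduce timestep")

    if (!is.null(bs) && step %% pace_steps == 0L) {
      # exact bias energy at s for the well-tempered height
      vex <- if (ndep > 0L)
        sum(kh[seq_len(ndep)] *
              exp(-(s - kc[seq_len(ndep)])^2 / (2 * bs$sigma^2))) else 0
      h <- bs$height * (if (is.infinite(dT)) 1 else exp(-vex / (KB_KJMOL * dT)))
      ndep <- ndep + 1L
      kc[ndep] <- s; kh[ndep] <- h; kt[ndep] <- step * dt
      dgv <- h * exp(-(grid - s)^2 / (2 * bs$sigma^2))
      Vg <- Vg + dgv
      Fg <- Fg + dgv * (grid - s) / bs$sigma^2   # -dV/ds of the new kernel
    }
    if ((step - 1L) %% record_stride == 0L) {
      irec <- irec + 1L
      rec_t[irec] <- step * dt; rec_s[irec] <- s; rec_v[irec] <- vb
    }
  }

  bias <- if (is.null(bs)) bias_potential(bias_factor = 10,
                                          temperature = system$temperature)
  else {
    b <- bias_potential(bias_factor = bs$bias_factor,
                        temperature = system$temperature,
                        pace_ps = bs$pace_ps)
    b$center <- kc[seq_len(ndep)]
    b$sigma <- rep(bs$sigma, ndep)
    b$height <- kh[seq_len(ndep)]
    b$time <- kt[seq_len(ndep)]
    b
  }
  list(trajectory = data.frame(time = rec_t[seq_len(irec)],
                               s = rec_s[seq_len(irec)],
                               bias = rec_v[seq_len(irec)]),
       bias = bias, grid = grid, bias_grid = Vg)
}

#' Run independent replicas of the surrogate sampler
#'
#' Each replica is an independent [run_toy_sampler()] run with its own seed
#' and its own bias state (five replicas by default).
#'
#' @inheritParams run_toy_sampler
#' @param n_replicas number of replicas (default 5).
#' @param seeds integer seeds, one per replica (default `seed + 0:(n-1)`).
#' @param ... passed to [run_toy_sampler()].
#' @return list of per-replica results (each as from [run_toy_sampler()]).
#' @export
run_replicas <- function(system, bias_settings = NULL, n_steps,
                         n_replicas = 5L, seeds = NULL, ...) {
  stopifnot(n_replicas >= 1L)
  if (is.null(seeds)) seeds <- system$seed + seq_len(n_replicas) - 1L
  if (length(seeds) != n_replicas) stop("need one seed per replica")
  if (anyDuplicated(seeds)) warning("duplicate replica seeds")
  lapply(seeds, function(sd) {
    sys_i <- system
    sys_i$seed <- as.integer(sd)
    run_toy_sampler(sys_i, bias_settings = bias_settings,
                    n_steps = n_steps, ...)
  })
}

#' Read a PLUMED HILLS file into a bias potential
#'
#' Expects the standard `#! FIELDS time <cv> sigma_<cv> height biasf` header
#' written by PLUMED's METAD action, so free energy surfaces can also be
#' reconstructed from production runs.
#'
#' @param path HILLS file path.
#' @param temperature system temperature, K (not stored in HILLS files).
#' @return a [bias_potential()].
#' @export
read_hills <- function(path, temperature = 300) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#! FIELDS")]
  if (length(hdr) == 0L) stop("no '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(sub("^#! FIELDS", "", hdr[1L])), "\\s+")[[1L]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  colnames(m) <- fields[seq_len(ncol(m))]
  need <- c("time", "height")
  if (!all(need %in% colnames(m))) stop("HILLS file missing time/height")
  sig_col <- grep("^sigma_", colnames(m), value = TRUE)[1L]
  cv_col <- sub("^sigma_", "", sig_col)
  gamma <- if ("biasf" %in% colnames(m)) unname(m[1L, "biasf"]) else Inf
  b <- bias_potential(bias_factor = gamma, temperature = temperature,
                      pace_ps = if (nrow(m) > 1L) diff(m[1:2, "time"]) else 2)
  b$center <- unname(m[, cv_col])
  b$sigma <- unname(m[, sig_col])
  b$height <- unname(m[, "height"])
  b$time <- unname(m[, "time"])
  b
}

#' Write a trajectory as TSV
#' @param result result of [run_toy_sampler()]; @param path file path.
#' @export
write_trajectory_tsv <- function(result, path) {
  utils::write.table(result$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
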