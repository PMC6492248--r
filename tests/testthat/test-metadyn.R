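test_that("bias energy is exact Gaussian summation", {
  b <- bias_potential()
  expect_equal(bias_energy(b, c(-1, 0, 3)), c(0, 0, 0))
  b1 <- deposit(b, s = 0, t = 2)
  expect_equal(bias_energy(b1, 0), 5)
  expect_equal(bias_energy(b1, 0.5), 5 * exp(-0.5^2 / (2 * 0.25)))
  # 100 random kernels vs direct summation oracle
  set.seed(10)
  b$center <- runif(100, -5, 5)
  b$sigma <- runif(100, 0.1, 1)
  b$height <- runif(100, 0.5, 5)
  b$time <- seq_len(100) * 2
  s <- runif(20, -6, 6)
  oracle <- sapply(s, function(si) {
    tot <- 0
    for (k in 1:100)
      tot <- tot + b$height[k] * exp(-(si - b$center[k])^2 / (2 * b$sigma[k]^2))
    tot
  })
  expect_equal(bias_energy(b, s), oracle, tolerance = 1e-10)
})

test_that("well-tempered deposits damp heights by the accumulated bias", {
  b <- bias_potential(bias_factor = 10, temperature = 300)
  b <- deposit(b, s = 1.3, t = 2)
  expect_identical(b$height[1L], 5)      # first deposit: V = 0
  b <- deposit(b, s = 1.3, t = 4)
  dT <- 9 * 300
  expect_equal(b$height[2L], 5 * exp(-5 / (KB_KJMOL * dT)), tolerance = 1e-12)
  # heights at a revisited point are non-increasing
  for (t in seq(6, 40, by = 2)) b <- deposit(b, 1.3, t)
  expect_true(all(diff(b$height) < 0))
  # standard-metadynamics limit: constant heights
  binf <- bias_potential(bias_factor = Inf)
  for (t in c(2, 4, 6)) binf <- deposit(binf, 0, t)
  expect_equal(binf$height, rep(5, 3))
})

test_that("FES reconstruction is the scaled negative bias, min-shifted to 0", {
  b <- deposit(bias_potential(bias_factor = 10), s = 1, t = 2)
  grid <- seq(-3, 5, by = 0.05)
  fes <- reconstruct_fes(b, grid)
  expect_equal(min(fes$free_energy), 0)
  expect_equal(grid[which.min(fes$free_energy)], 1, tolerance = 0.05)
  # inverted Gaussian shape: symmetric around the kernel center
  left <- fes$free_energy[which.min(abs(grid - 0))]
  right <- fes$free_energy[which.min(abs(grid - 2))]
  expect_equal(left, right, tolerance = 1e-9)
  # doubling all heights doubles the unshifted profile
  b2 <- b; b2$height <- 2 * b2$height
  g <- 10 / 9
  expect_equal(max(reconstruct_fes(b2, grid)$free_energy),
               2 * max(fes$free_energy), tolerance = 1e-9)
  expect_equal(max(fes$free_energy), g * bias_energy(b, 1), tolerance = 1e-9)
  expect_error(reconstruct_fes(bias_potential(), grid), "no kernels")
})

test_that("toy sampler descends to the minimum at zero temperature", {
  sys <- toy_system(function(s) 0.5 * 10 * (s - 2)^2,
                    function(s) 10 * (s - 2),
                    temperature = 1e-12, s0 = -3, seed = 1L)
  res <- run_toy_sampler(sys, NULL, n_steps = 2000L)
  expect_equal(tail(res$trajectory$s, 1L), 2, tolerance = 1e-6)
})

test_that("the sampler is deterministic given the seed", {
  dw <- double_well(20)
  sys <- toy_system(dw$potential, dw$gradient, s0 = dw$minima[1L], seed = 99L)
  a <- run_toy_sampler(sys, list(), n_steps = 5000L)
  b <- run_toy_sampler(sys, list(), n_steps = 5000L)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$bias$height, b$bias$height)
})

test_that("cached bias grid agrees with exact kernel summation", {
  dw <- double_well(20)
  sys <- toy_system(dw$potential, dw$gradient, s0 = dw$minima[1L], seed = 3L)
  res <- run_toy_sampler(sys, list(), n_steps = 20000L)
  expect_gt(length(res$bias$center), 50L)
  on_grid <- abs(res$grid) <= 8    # restrict to a window around the action
  exact <- bias_energy(res$bias, res$grid[on_grid])
  expect_lt(max(abs(res$bias_grid[on_grid] - exact)), 1e-6)
})

test_that("sampler equilibrium in a harmonic well matches kB*T/k", {
  k <- 10
  sys <- toy_system(function(s) 0.5 * k * s^2, function(s) k * s,
                    s0 = 0, seed = 7L)
  res <- run_toy_sampler(sys, NULL, n_steps = 1e6, record_stride = 10L)
  expect_equal(var(res$trajectory$s), KB_KJMOL * 300 / k, tolerance = 0.1)
})

test_that("metadynamics crosses a 15 kBT barrier that unbiased dynamics
          cannot", {
  dw <- double_well(15 * KB_KJMOL * 300)
  both <- function(biased, seed) {
    sys <- toy_system(dw$potential, dw$gradient, s0 = dw$minima[1L],
                      seed = seed)
    res <- run_toy_sampler(sys, if (biased) list() else NULL,
                           n_steps = 2e5L, record_stride = 10L)
    s <- res$trajectory$s
    (min(s) < dw$minima[1L] + 1) && (max(s) > dw$minima[2L] - 1)
  }
  with_bias <- vapply(1:10, function(sd) both(TRUE, sd), logical(1L))
  without <- vapply(1:10, function(sd) both(FALSE, sd), logical(1L))
  expect_gte(median(with_bias), 1)     # majority of biased runs cross
  expect_lte(median(without), 0)       # majority of unbiased runs do not
})

test_that("replicas are independent and bookkeeping adds up", {
  dw <- double_well(20)
  sys <- toy_system(dw$potential, dw$gradient, s0 = dw$minima[1L], seed = 1L)
  reps <- run_replicas(sys, list(), n_steps = 2000L, record_stride = 10L)
  expect_length(reps, 5L)              # default replica count
  expect_false(identical(reps[[1L]]$trajectory$s, reps[[2L]]$trajectory$s))
  total <- sum(vapply(reps, function(r) nrow(r$trajectory), integer(1L)))
  expect_equal(total, 5L * 200L)
  expect_warning(run_replicas(sys, NULL, n_steps = 100L, n_replicas = 2L,
                              seeds = c(1L, 1L)), "duplicate")
})

test_that("HILLS-format files round-trip into a bias potential", {
  b <- bias_potential(bias_factor = 10)
  for (t in c(2, 4, 6, 8)) b <- deposit(b, rnorm(1), t)
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#! FIELDS time cms sigma_cms height biasf",
               sprintf("%10.3f %12.6f %8.3f %12.6f %6.1f",
                       b$time, b$center, b$sigma, b$height, 10)), f)
  back <- read_hills(f)
  expect_equal(back$center, b$center, tolerance = 1e-5)
  expect_equal(back$height, b$height, tolerance = 1e-5)
  expect_equal(back$bias_factor, 10)
  grid <- seq(-4, 4, by = 0.1)
  expect_equal(reconstruct_fes(back, grid)$free_energy,
               reconstruct_fes(b, grid)$free_energy, tolerance = 1e-4)
})
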