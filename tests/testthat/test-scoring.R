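test_that("surrogate score penalizes clashes and rewards native packing", {
  tc <- toy()
  relaxed_score <- surrogate_interface_score(tc)
  clashed <- transform_ligand(tc, diag(3L), c(0, -5.5, 0))  # overlap chains
  expect_gt(surrogate_interface_score(clashed), relaxed_score)
  # rigid invariance
  set.seed(12)
  for (i in 1:5) {
    tr <- random_transform()
    expect_equal(surrogate_interface_score(transform_complex(tc, tr$R, tr$t)),
                 relaxed_score, tolerance = 1e-8)
  }
  # far-separated complex: sentinel with warning
  apart <- transform_ligand(tc, diag(3L), c(0, 100, 0))
  expect_warning(s <- surrogate_interface_score(apart), "sentinel")
  expect_gte(s, 1e6)
})

test_that("surrogate score correlates positively with decoy LRMSD", {
  tc <- toy(jitter = 0.15, seed = 31L)
  dec <- make_decoy_ensemble(tc, magnitudes = c(0.5, 1, 2, 3, 4, 6, 8, 10),
                             n_per_grade = 2L, seed = 7L)
  # distant decoys may fall outside the interface cutoff: the sentinel is the
  # intended worst-case score there
  scores <- suppressWarnings(
    vapply(dec$members, surrogate_interface_score, numeric(1L)))
  expect_gt(spearman(scores, dec$manifest$lrmsd), 0)
})

test_that("normalization maps best to 1 and worst to 0", {
  expect_equal(normalize_01(c(10, 20), "lower_is_better"), c(1, 0))
  expect_equal(normalize_01(c(10, 20), "higher_is_better"), c(0, 1))
  expect_equal(normalize_01(rep(3.3, 5)), rep(0.5, 5))
  expect_error(normalize_01(c(1, NA, 3)), "2")
  set.seed(13)
  for (i in 1:100) {
    v <- rnorm(sample(3:30, 1L))
    lo <- normalize_01(v, "lower_is_better")
    hi <- normalize_01(v, "higher_is_better")
    expect_true(all(lo >= 0 & lo <= 1))
    expect_equal(lo[which.min(v)], 1)
    expect_equal(lo[which.max(v)], 0)
    expect_equal(lo, 1 - hi)
    expect_identical(order(lo), rev(order(hi)))
  }
  # idempotence on already-normalized input
  v <- c(0, 0.25, 0.6, 1)
  expect_equal(normalize_01(v, "higher_is_better"), v, tolerance = 1e-12)
})

test_that("CS_alpha endpoints and interpolation behave per definition", {
  set.seed(14)
  z <- runif(50); f <- runif(50)
  expect_identical(cs_alpha(z, f, 1), z)
  expect_identical(cs_alpha(z, f, 0), f)
  expect_equal(cs_alpha(1, 0, 0.49), 0.49)
  cs <- cs_alpha(z, f, 0.3)
  expect_true(all(cs >= pmin(z, f) - 1e-12 & cs <= pmax(z, f) + 1e-12))
  expect_error(cs_alpha(z, f, 1.2), "alpha")
  expect_error(cs_alpha(z, f[-1L], 0.5), "length")
})

test_that("FES attachment interpolates linearly and clamps out-of-grid", {
  fes <- structure(list(grid = c(0, 1, 2), free_energy = c(0, 2, 1)),
                   class = "fes_profile")
  rec <- data.frame(cv = c(0, 0.5, 1.5, 2))
  out <- attach_fes(rec, fes)
  expect_equal(out$fes_kjmol, c(0, 1, 1.5, 1))
  expect_warning(attach_fes(data.frame(cv = 3), fes), "clamped")
  expect_equal(suppressWarnings(attach_fes(data.frame(cv = 3), fes))$fes_kjmol,
               1)
  # two-resolution comparison: coarse interpolation close to dense oracle
  dense_grid <- seq(-3, 3, by = 0.001)
  fe_fun <- function(s) (s^2 - 1)^2
  dense <- structure(list(grid = dense_grid, free_energy = fe_fun(dense_grid)),
                     class = "fes_profile")
  coarse_grid <- seq(-3, 3, by = 0.05)
  coarse <- structure(list(grid = coarse_grid,
                           free_energy = fe_fun(coarse_grid)),
                      class = "fes_profile")
  set.seed(15)
  cvs <- runif(200, -2.9, 2.9)
  dv <- attach_fes(data.frame(cv = cvs), dense)$fes_kjmol
  cv2 <- attach_fes(data.frame(cv = cvs), coarse)$fes_kjmol
  # linear interpolation error bound: h^2/8 * max|f''|
  bound <- 0.05^2 / 8 * max(abs(12 * coarse_grid^2 - 4)) + 1e-9
  expect_lt(max(abs(dv - cv2)), bound)
})

test_that("score tables combine CMS, surrogate score and FES coherently", {
  tc <- toy()
  cm <- build_cmif(list(tc))
  dec <- make_decoy_ensemble(tc, magnitudes = c(0.3, 1, 2, 3), seed = 3L)
  frames <- dec$members
  fes <- structure(list(grid = seq(0, 50, by = 0.5),
                        free_energy = seq(0, 50, by = 0.5) * 0.3),
                   class = "fes_profile")
  tab <- score_table(frames, replica = rep(1L, 4L), time_ps = 1:4 * 50,
                     cmap = cm, fes = fes, reference = tc, alpha = 0.49)
  expect_s3_class(tab, "score_table")
  expect_true(all(c("cv", "external_score", "fes_kjmol", "zrank_eta",
                    "fes_eta", "cs_alpha", "lrmsd") %in% names(tab)))
  expect_true(all(tab$zrank_eta >= 0 & tab$zrank_eta <= 1))
  expect_true(all(tab$fes_eta >= 0 & tab$fes_eta <= 1))
  # CS_alpha lies between its two components, row by row
  expect_true(all(tab$cs_alpha >= pmin(tab$zrank_eta, tab$fes_eta) - 1e-12))
  expect_true(all(tab$cs_alpha <= pmax(tab$zrank_eta, tab$fes_eta) + 1e-12))
  # ranking by CS_1.0 equals ranking by the external score alone
  tab1 <- score_table(frames, rep(1L, 4L), 1:4 * 50, cmap = cm, fes = fes,
                      alpha = 1)
  expect_identical(order(-tab1$cs_alpha), order(tab1$external_score))
  # external scores can be supplied instead of the surrogate
  tab2 <- score_table(frames, rep(1L, 4L), 1:4 * 50,
                      external_scores = c(4, 3, 2, 1))
  expect_equal(tab2$zrank_eta, c(0, 1 / 3, 2 / 3, 1))
})

test_that("external score tables read from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("replica\ttime_ps\tscore", "1\t50\t-12.5", "1\t100\t-10"), f)
  df <- read_external_scores(f)
  expect_equal(df$score, c(-12.5, -10))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(read_external_scores(bad), "columns")
})
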