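# two CA atoms at a prescribed interface distance
two_residue_complex <- function(d) {
  atoms <- data.frame(
    chain = c("A", "B"), resno = 1L, insert = "", resid = "ALA",
    elety = "CA", eleno = 1:2, elem = "C",
    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE)
  complex_structure(atoms, "A", "B")
}

test_that("contact criterion is strictly below the cutoff", {
  expect_equal(nrow(detect_interface_contacts(two_residue_complex(7.9))), 1L)
  expect_equal(nrow(detect_interface_contacts(two_residue_complex(8.0))), 0L)
})

test_that("contact detection equals the brute-force double loop", {
  tc <- toy(jitter = 0.4, seed = 21L)
  got <- detect_interface_contacts(tc)
  got_keys <- sort(paste0(got$rchain, ":", got$rres, "--",
                          got$lchain, ":", got$lres))
  rca <- ca_atoms(tc, "receptor"); lca <- ca_atoms(tc, "ligand")
  want <- character(0)
  for (i in seq_len(nrow(rca))) {
    for (j in seq_len(nrow(lca))) {
      d <- sqrt((rca$x[i] - lca$x[j])^2 + (rca$y[i] - lca$y[j])^2 +
                  (rca$z[i] - lca$z[j])^2)
      if (d < 8) want <- c(want, paste0(rca$key[i], "--", lca$key[j]))
    }
  }
  expect_identical(got_keys, sort(want))
})

test_that("build_cmif pools supports and reference distances over members", {
  tc <- toy()
  single <- build_cmif(list(tc))
  direct <- detect_interface_contacts(tc)
  expect_equal(nrow(single$contacts), nrow(direct))
  expect_true(all(single$contacts$support == 1L))
  expect_equal(cms_value(tc, single), 0, tolerance = 1e-12)

  # 5-member ensemble: support and mean distances match brute-force recompute
  members <- c(list(tc), lapply(1:4, function(i) {
    set.seed(100 + i)
    transform_ligand(tc, rotation_matrix(rnorm(3), 0.05),
                     runif(3, -1, 1))
  }))
  cm <- build_cmif(members)
  per <- lapply(members, detect_interface_contacts)
  key_of <- function(d) paste(d$rchain, d$rres, d$lchain, d$lres)
  all_keys <- unique(unlist(lapply(per, key_of)))
  expect_setequal(paste(cm$contacts$rchain, cm$contacts$rres,
                        cm$contacts$lchain, cm$contacts$lres), all_keys)
  for (k in sample(all_keys, 10L)) {
    ds <- unlist(lapply(per, function(d) d$dist[key_of(d) == k]))
    row <- cm$contacts[paste(cm$contacts$rchain, cm$contacts$rres,
                             cm$contacts$lchain, cm$contacts$lres) == k, ]
    expect_equal(row$support, length(ds))
    expect_equal(row$r0, mean(ds), tolerance = 1e-12)
  }
  # min_support filters
  cm2 <- build_cmif(members, min_support = 5L)
  expect_true(all(cm2$contacts$support >= 5L))
  expect_lt(nrow(cm2$contacts), nrow(cm$contacts) + 1L)
})

test_that("switching function hits its analytic anchor points", {
  expect_identical(switching_D(8, 8), 0.6)      # removable singularity limit
  expect_identical(switching_D(3.17, 3.17), 0.6)
  expect_equal(switching_D(0, 5), 1.0)
  expect_equal(switching_D(2, 1), 63 / 1023)    # (1-2^6)/(1-2^10)
  expect_error(switching_D(1, 0), "positive")
  expect_error(switching_D(1, 1, n = 10, m = 6), "m > n")
})

test_that("switching function is continuous at x = 1 and strictly decreasing", {
  for (eps in c(1e-7, -1e-7))
    expect_lt(abs(switching_D(1 + eps, 1) - 0.6), 1e-5)
  grid <- seq(0.05, 25, by = 0.05)
  v <- switching_D(grid, 8)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
})

test_that("CMS is zero at the reference and invariant under rigid motion", {
  tc <- toy(jitter = 0.2, seed = 5L)
  cm <- build_cmif(list(tc))
  expect_equal(cms_value(tc, cm), 0, tolerance = 1e-12)
  dec <- transform_ligand(tc, rotation_matrix(c(1, 1, 0), 0.2), c(1, 2, 0))
  v0 <- cms_value(dec, cm)
  expect_gt(v0, 0)
  set.seed(6)
  for (i in 1:5) {
    tr <- random_transform()
    expect_equal(cms_value(transform_complex(dec, tr$R, tr$t), cm), v0,
                 tolerance = 1e-9)
  }
})

test_that("a single contact at zero distance contributes (1 - 0.6)^2", {
  tc <- two_residue_complex(5)
  cm <- build_cmif(list(tc))
  collapsed <- tc
  collapsed$atoms$x[2L] <- 0       # r = 0 -> D = 1
  expect_equal(cms_value(collapsed, cm), 0.16, tolerance = 1e-12)
})

test_that("CMS increases monotonically once the ligand moves past all r0", {
  tc <- toy()
  cm <- build_cmif(list(tc))
  vals <- vapply(seq(0.5, 6, by = 0.5), function(d) {
    cms_value(transform_ligand(tc, diag(3L), c(0, d, 0)), cm)
  }, numeric(1L))
  expect_true(all(diff(vals) > 0))
})

test_that("unresolvable contact residues are fatal with the offending keys", {
  tc <- toy()
  cm <- build_cmif(list(tc))
  chopped <- tc
  chopped$atoms <- chopped$atoms[!(chopped$atoms$chain == "B" &
                                     chopped$atoms$resno == 1L), ]
  expect_error(cms_value(chopped, cm), "B:1")
})

test_that("PLUMED export contains the bias parameters and parses line-wise", {
  tc <- toy()
  cm <- build_cmif(list(tc))
  txt <- export_plumed(cm, tc)
  expect_length(grep("METAD", txt), 1L)
  expect_true(any(grepl("SIGMA=0.5", txt, fixed = TRUE)))
  expect_true(any(grepl("HEIGHT=5", txt, fixed = TRUE)))
  expect_true(any(grepl("BIASFACTOR=10", txt, fixed = TRUE)))
  expect_equal(sum(grepl("^  ATOMS", txt)), nrow(cm$contacts))
  # every KEY=VALUE token is well-formed
  body <- txt[!startsWith(txt, "#")]
  tokens <- unlist(strsplit(trimws(body), "\\s+"))
  tokens <- tokens[grepl("=", tokens)]
  expect_true(all(grepl("^[A-Za-z_0-9.]+=\\{?[-A-Za-z_0-9.,={} ]+\\}?$",
                        tokens)))
  # 1-contact map: exactly one pair entry
  one <- build_cmif(list(two_residue_complex(5)))
  txt1 <- export_plumed(one, two_residue_complex(5))
  expect_equal(sum(grepl("^  ATOMS", txt1)), 1L)
})

test_that("contact map TSV serialization round-trips", {
  tc <- toy(jitter = 0.1, seed = 9L)
  cm <- build_cmif(list(tc))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cmif_tsv(cm, f)
  back <- read_cmif_tsv(f)
  expect_equal(back$contacts$r0, cm$contacts$r0, tolerance = 1e-6)
  expect_identical(back$n_exponent, cm$n_exponent)
  expect_equal(cms_value(tc, back), 0, tolerance = 1e-9)
})
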