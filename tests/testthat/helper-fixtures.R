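# shared fixtures, built in code at test time

toy <- function(...) make_toy_complex(...)

# a random rigid transform (proper rotation + translation), seeded by caller
random_transform <- function(max_shift = 20) {
  ax <- stats::rnorm(3L)
  R <- rotation_matrix(ax, stats::runif(1L, 0, 2 * pi))
  list(R = R, t = stats::runif(3L, -max_shift, max_shift))
}

# apply a rigid transform to a whole complex
transform_complex <- function(structure, R, t) {
  p <- apply_transform(
    cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z), R, t)
  structure$atoms$x <- p[, 1L]
  structure$atoms$y <- p[, 2L]
  structure$atoms$z <- p[, 3L]
  structure
}

# brute-force residue-residue contact enumeration (independent of the
# package's vectorized path): any-atom version used for FNAT-style oracles
brute_residue_contacts <- function(structure, cutoff, heavy_only = TRUE) {
  at <- structure$atoms
  if (heavy_only) at <- at[toupper(substr(at$elem, 1L, 1L)) != "H", ]
  ra <- at[at$chain %in% structure$receptor_chains, ]
  la <- at[at$chain %in% structure$ligand_chains, ]
  out <- character(0)
  for (rk in unique(paste0(ra$chain, ":", ra$resno, ra$insert))) {
    rs <- ra[paste0(ra$chain, ":", ra$resno, ra$insert) == rk, ]
    for (lk in unique(paste0(la$chain, ":", la$resno, la$insert))) {
      ls <- la[paste0(la$chain, ":", la$resno, la$insert) == lk, ]
      found <- FALSE
      for (i in seq_len(nrow(rs))) {
        for (j in seq_len(nrow(ls))) {
          d <- sqrt((rs$x[i] - ls$x[j])^2 + (rs$y[i] - ls$y[j])^2 +
                      (rs$z[i] - ls$z[j])^2)
          if (d < cutoff) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) out <- c(out, paste(rk, lk, sep = "--"))
    }
  }
  out
}

# simple Spearman rank correlation
spearman <- function(x, y) stats::cor(rank(x), rank(y))
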