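#' Detect interface contacts of a complex
#'
#' A receptor residue and a ligand residue form an interface contact when
#' their C-alpha atoms are strictly closer than `cutoff` (default 8 Angstrom).
#'
#' @param structure a [complex_structure()].
#' @param cutoff contact cutoff in Angstrom; strict `<`.
#' @return data.frame with columns `rchain`, `rres`, `lchain`, `lres`
#'   (chain id and residue identifier, author numbering with insertion code)
#'   and `dist` (C-alpha distance, Angstrom). May have zero rows.
#' @export
detect_interface_contacts <- function(structure, cutoff = 8) {
  rca <- ca_atoms(structure, "receptor")
  lca <- ca_atoms(structure, "ligand")
  dm <- cross_dist(coords(rca), coords(lca))
  hit <- which(dm < cutoff, arr.ind = TRUE)
  data.frame(
    rchain = rca$chain[hit[, 1L]],
    rres = paste0(rca$resno, rca$insert)[hit[, 1L]],
    lchain = lca$chain[hit[, 2L]],
    lres = paste0(lca$resno, lca$insert)[hit[, 2L]],
    dist = dm[hit],
    stringsAsFactors = FALSE)
}

# all-pairs Euclidean distance between two point sets (rows)
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Build the interface contact map CM_if from a docked ensemble
#'
#' The union of per-member interface contacts. Each contact carries a support
#' count (number of members exhibiting it) and a reference distance `r0`
#' pooled over the supporting members. Contacts seen in fewer than
#' `min_support` members are dropped.
#'
#' @param ensemble a [complex_ensemble()] or list of [complex_structure()].
#' @param cutoff C-alpha contact cutoff, Angstrom (strict `<`).
#' @param min_support minimum number of supporting members (default 1: union).
#' @param r0_method how to pool the reference distance over supporting
#'   members: `"mean"` (default) or `"median"`.
#' @param n_exponent,m_exponent switching function exponents (defaults 6, 10).
#' @return An object of class `contact_map`: list with `contacts` (data.frame
#'   `rchain`, `rres`, `lchain`, `lres`, `r0`, `support`), `cutoff`,
#'   `n_exponent`, `m_exponent` and `d_ref` (= n/m, the reference value of the
#'   switching function).
#' @export
build_cmif <- function(ensemble, cutoff = 8, min_support = 1L,
                       r0_method = c("mean", "median"),
                       n_exponent = 6L, m_exponent = 10L) {
  r0_method <- match.arg(r0_method)
  if (!(m_exponent > n_exponent && n_exponent > 0))
    stop("exponents must satisfy m > n > 0")
  members <- if (inherits(ensemble, "complex_ensemble")) ensemble
             else complex_ensemble(ensemble)
  per <- lapply(members, detect_interface_contacts, cutoff = cutoff)
  all <- do.call(rbind, per)
  if (is.null(all) || nrow(all) == 0L)
    stop("no interface detected in any ensemble member")
  key <- paste(all$rchain, all$rres, all$lchain, all$lres, sep = "|")
  pool <- switch(r0_method, mean = mean, median = stats::median)
  agg <- lapply(split(seq_len(nrow(all)), key), function(ix) {
    c(r0 = pool(all$dist[ix]), support = length(ix))
  })
  keys <- names(agg)
  m <- do.call(rbind, agg)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  contacts <- data.frame(
    rchain = parts[, 1L], rres = parts[, 2L],
    lchain = parts[, 3L], lres = parts[, 4L],
    r0 = m[, "r0"], support = as.integer(m[, "support"]),
    stringsAsFactors = FALSE, row.names = NULL)
  contacts <- contacts[contacts$support >= min_support, , drop = FALSE]
  if (nrow(contacts) == 0L)
    stop("no interface detected (all contacts below min_support)")
  contacts <- contacts[order(contacts$rchain, contacts$rres,
                             contacts$lchain, contacts$lres), , drop = FALSE]
  row.names(contacts) <- NULL
  structure(list(contacts = contacts, cutoff = cutoff,
                 n_exponent = as.integer(n_exponent),
                 m_exponent = as.integer(m_exponent),
                 d_ref = n_exponent / m_exponent),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d contacts | cutoff %g A | n=%d m=%d (D_ref=%g)\n",
              nrow(x$contacts), x$cutoff, x$n_exponent, x$m_exponent, x$d_ref))
  invisible(x)
}

#' Rational switching function quantifying contact formation
#'
#' `D(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with integer exponents
#' `m > n > 0`. The singularity at `r = r0` is removable; the function is
#' evaluated through the equivalent geometric-sum form
#' `(1 + x + ... + x^(n-1)) / (1 + x + ... + x^(m-1))`, which is exact at
#' `x = 1` (value `n/m`, i.e. 0.6 for the default exponents) and free of the
#' catastrophic cancellation of the naive form near `x = 1`.
#'
#' @param r contact distance(s), Angstrom (>= 0).
#' @param r0 reference distance, Angstrom (> 0).
#' @param n,m exponents, `m > n > 0` (defaults 6 and 10).
#' @return dimensionless value(s) in (0, 1]; decreasing in `r`.
#' @export
switching_D <- function(r, r0, n = 6L, m = 10L) {
  if (any(r0 <= 0)) stop("r0 must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  if (!(m > n && n > 0)) stop("exponents must satisfy m > n > 0")
  x <- r / r0
  num <- rep(0, length(x)); den <- rep(0, length(x))
  xk <- rep(1, length(x))
  for (k in seq_len(m)) {           # k-th term is x^(k-1)
    if (k <= n) num <- num + xk
    den <- den + xk
    xk <- xk * x
  }
  num / den
}

#' Contact-map-space (CMS) collective variable
#'
#' The scalar CMS coordinate of a structure relative to a contact map:
#' `CMS(R) = sum over contacts of (D(r) - D_ref)^2`, where `D` is
#' [switching_D()] with the map's exponents and `D_ref = n/m` (the switching
#' value at `r = r0`, 0.6 for the defaults). CMS is 0 iff every contact
#' distance equals its reference distance, and grows as the interface departs
#' from the reference contact pattern.
#'
#' @param structure a [complex_structure()].
#' @param cmap a `contact_map` from [build_cmif()].
#' @return non-negative dimensionless scalar.
#' @export
cms_value <- function(structure, cmap) {
  d <- contact_distances(structure, cmap)
  D <- switching_D(d, cmap$contacts$r0, cmap$n_exponent, cmap$m_exponent)
  sum((D - cmap$d_ref)^2)
}

# current C-alpha distances of a structure for each contact in a map
contact_distances <- function(structure, cmap) {
  ca <- ca_atoms(structure, "all")
  pos <- coords(ca)
  rownames(pos) <- ca$key
  rkey <- paste0(cmap$contacts$rchain, ":", cmap$contacts$rres)
  lkey <- paste0(cmap$contacts$lchain, ":", cmap$contacts$lres)
  bad <- unique(c(setdiff(rkey, ca$key), setdiff(lkey, ca$key)))
  if (length(bad) > 0L)
    stop("contact residues not resolvable to C-alpha atoms: ",
         paste(bad, collapse = ", "))
  sqrt(rowSums((pos[rkey, , drop = FALSE] - pos[lkey, , drop = FALSE])^2))
}

#' Export a PLUMED input biasing the CMS collective variable
#'
#' Emits a `CONTACTMAP ... CMDIST` collective variable over the C-alpha atom
#' serial numbers of the contact pairs (rational switching function with the
#' map's exponents and per-contact `R_0`, reference value `D_ref`) followed by
#' a well-tempered `METAD` block, for use in a production metadynamics run
#' with PLUMED2 and an MD engine. Lengths are emitted in Angstrom via a
#' `UNITS` directive.
#'
#' @param cmap a `contact_map`.
#' @param structure the [complex_structure()] providing atom serial numbers.
#' @param params list of bias settings: `sigma` (CV units, default 0.5),
#'   `height` (kJ/mol, default 5), `bias_factor` (default 10), `pace_ps`
#'   (default 2), `timestep_ps` (MD timestep used to convert the pace to
#'   steps, default 0.002), `temperature` (K, default 300).
#' @param path optional file to write; when `NULL` the text is returned only.
#' @return character vector of PLUMED input lines, invisibly when written.
#' @export
export_plumed <- function(cmap, structure, params = list(), path = NULL) {
  p <- utils::modifyList(list(sigma = 0.5, height = 5, bias_factor = 10,
                              pace_ps = 2, timestep_ps = 0.002,
                              temperature = 300), params)
  if (nrow(cmap$contacts) == 0L) stop("contact map is empty")
  ca <- ca_atoms(structure, "all")
  serial <- ca$eleno
  names(serial) <- ca$key
  if (anyDuplicated(ca$eleno))
    stop("atom serial collision among C-alpha atoms")
  rkey <- paste0(cmap$contacts$rchain, ":", cmap$contacts$rres)
  lkey <- paste0(cmap$contacts$lchain, ":", cmap$contacts$lres)
  bad <- unique(c(setdiff(rkey, ca$key), setdiff(lkey, ca$key)))
  if (length(bad) > 0L)
    stop("contact residues without C-alpha serials: ",
         paste(bad, collapse = ", "))
  nc <- nrow(cmap$contacts)
  pairs <- sprintf(
    "ATOMS%d=%d,%d SWITCH%d={RATIONAL R_0=%.4f NN=%d MM=%d} REFERENCE%d=%.4f",
    seq_len(nc), serial[rkey], serial[lkey],
    seq_len(nc), cmap$contacts$r0, cmap$n_exponent, cmap$m_exponent,
    seq_len(nc), cmap$d_ref)
  pace_steps <- max(1L, round(p$pace_ps / p$timestep_ps))
  lines <- c(
    "# PLUMED input generated by cmsrefine: CMS collective variable + well-tempered metadynamics",
    "UNITS LENGTH=A",
    "cms: CONTACTMAP ...",
    paste0("  ", pairs),
    "  CMDIST",
    "...",
    sprintf("metad: METAD ARG=cms PACE=%d SIGMA=%g HEIGHT=%g BIASFACTOR=%g TEMP=%g FILE=HILLS",
            pace_steps, p$sigma, p$height, p$bias_factor, p$temperature),
    sprintf("PRINT ARG=cms,metad.bias STRIDE=%d FILE=COLVAR", pace_steps))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write / read a contact map as TSV
#'
#' Columns: `rchain`, `rres`, `lchain`, `lres`, `r0`, `support`. Header lines
#' starting with `#` record the cutoff and exponents.
#'
#' @param cmap a `contact_map`; @param path file path.
#' @return `read_cmif_tsv` returns a `contact_map`.
#' @export
write_cmif_tsv <- function(cmap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff=%g n=%d m=%d", cmap$cutoff,
                     cmap$n_exponent, cmap$m_exponent), con)
  utils::write.table(cmap$contacts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cmif_tsv
#' @export
read_cmif_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("cutoff=([0-9.]+) n=([0-9]+) m=([0-9]+)", hdr))[[1L]]
  if (length(m) != 4L) stop("malformed contact map header in ", path)
  contacts <- utils::read.table(path, sep = "\t", header = TRUE,
                                comment.char = "#",
                                colClasses = c("character", "character",
                                               "character", "character",
                                               "numeric", "integer"))
  structure(list(contacts = contacts, cutoff = as.numeric(m[2L]),
                 n_exponent = as.integer(m[3L]),
                 m_exponent = as.integer(m[4L]),
                 d_ref = as.integer(m[3L]) / as.integer(m[4L])),
            class = "contact_map")
}
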