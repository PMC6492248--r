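#' Reference ranks of snapshots by LRMSD
#'
#' Rank 1 is the snapshot with the lowest LRMSD to the reference crystal
#' structure. Ties are broken deterministically by `(replica, time_ps)`
#' order.
#'
#' @param lrmsd numeric vector of LRMSD values (no missing values).
#' @param replica,time_ps tie-break keys (default: input order).
#' @return integer vector of ranks (a permutation of `1..n`).
#' @export
reference_ranks <- function(lrmsd, replica = seq_along(lrmsd),
                            time_ps = seq_along(lrmsd)) {
  if (any(is.na(lrmsd))) stop("missing LRMSD values")
  ord <- order(lrmsd, replica, time_ps)
  rk <- integer(length(lrmsd))
  rk[ord] <- seq_along(lrmsd)
  rk
}

#' Cap a rank at a maximum value
#'
#' Ranks beyond `max_rank` all count as `max_rank`, so that a handful of very
#' poor selections cannot dominate the ranking-error statistic.
#'
#' @param rank integer rank(s), >= 1.
#' @param max_rank cap.
#' @return `min(rank, max_rank)` elementwise.
#' @export
capped_rank <- function(rank, max_rank) {
  if (any(rank < 1)) stop("ranks start at 1")
  pmin(rank, max_rank)
}

#' Ranking error of a snapshot selection
#'
#' For each target, the `n` top snapshots by predicted score (higher = better;
#' ties broken by `time_ps` then `replica`) are selected and their capped
#' reference ranks are summed. The raw error `epsilon` is the total over all
#' targets; it is normalized to
#' `epsilon_eta = (epsilon - rank_min) / (rank_max - rank_min)` with
#' `rank_min = |TR| * n(n+1)/2` (perfect selection) and
#' `rank_max = |TR| * (max_rank + 1) * n`.
#'
#' @param df data.frame with columns `target`, `lrmsd`, `score` (predicted,
#'   higher = better), `replica`, `time_ps`.
#' @param n selection depth (snapshots per target).
#' @param max_rank rank cap (default 100).
#' @return list with `epsilon` (integer), `epsilon_eta`, `per_target_errors`
#'   (named integer vector), `rank_min`, `rank_max`.
#' @export
ranking_error <- function(df, n, max_rank = 100L) {
  need <- c("target", "lrmsd", "score", "replica", "time_ps")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  stopifnot(n >= 1, max_rank >= n)
  targets <- unique(df$target)
  per <- vapply(targets, function(tg) {
    d <- df[df$target == tg, , drop = FALSE]
    if (nrow(d) < n)
      stop("target ", tg, " has fewer than n = ", n, " snapshots")
    ref <- reference_ranks(d$lrmsd, d$replica, d$time_ps)
    pred_ord <- order(-d$score, d$time_ps, d$replica)
    sum(capped_rank(ref[pred_ord[seq_len(n)]], max_rank))
  }, numeric(1L))
  names(per) <- targets
  eps <- sum(per)
  rank_min <- length(targets) * n * (n + 1) / 2
  rank_max <- length(targets) * (max_rank + 1) * n
  list(epsilon = eps,
       epsilon_eta = (eps - rank_min) / (rank_max - rank_min),
       per_target_errors = per,
       rank_min = rank_min, rank_max = rank_max)
}

#' Sweep of the normalized ranking error over alpha and selection depth
#'
#' Evaluates `epsilon_eta` for every combination of the mixing weight `alpha`
#' (applied to per-target `zrank_eta`/`fes_eta` columns through [cs_alpha()])
#' and selection depth `n`, and reports the best alpha for each depth.
#'
#' @param df data.frame with columns `target`, `lrmsd`, `zrank_eta`,
#'   `fes_eta`, `replica`, `time_ps`.
#' @param alphas numeric grid in `[0, 1]`.
#' @param n_values integer grid of selection depths.
#' @param max_rank rank cap (default 100).
#' @return list with `epsilon_eta` (matrix, rows = alphas, cols = n_values)
#'   and `best_alpha` (data.frame `n`, `alpha`, `epsilon_eta`).
#' @export
alpha_n_sweep <- function(df, alphas = seq(0, 1, by = 0.01),
                          n_values = 1:100, max_rank = 100L) {
  need <- c("target", "lrmsd", "zrank_eta", "fes_eta", "replica", "time_ps")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  mat <- matrix(NA_real_, length(alphas), length(n_values),
                dimnames = list(alpha = alphas, n = n_values))
  for (ai in seq_along(alphas)) {
    d <- df
    d$score <- cs_alpha(df$zrank_eta, df$fes_eta, alphas[ai])
    for (ni in seq_along(n_values)) {
      mat[ai, ni] <- ranking_error(d, n_values[ni], max_rank)$epsilon_eta
    }
  }
  best <- data.frame(
    n = n_values,
    alpha = alphas[apply(mat, 2L, which.min)],
    epsilon_eta = apply(mat, 2L, min))
  list(epsilon_eta = mat, best_alpha = best)
}

#' Write an alpha x n sweep as TSV
#'
#' The matrix with alphas as rows plus the per-n best-alpha column block.
#' @param sweep result of [alpha_n_sweep()]; @param path file path.
#' @export
write_sweep_tsv <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(cbind(alpha = rownames(sweep$epsilon_eta),
                           as.data.frame(sweep$epsilon_eta)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  utils::write.table(sweep$best_alpha, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
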