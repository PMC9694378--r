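# Rank-by-rank consensus rescoring. Heterogeneous score columns are
# min-max normalized to [0, 1] (1 = best), ranked per column (1 = best,
# average ranks on ties), and the consensus rank of a compound is the
# arithmetic mean of its per-column ranks.

#' Min-max normalize one score column
#'
#' `(s - min) / (max - min)`; columns where lower scores are better are
#' sign-flipped first, so 1 always means best. A constant column yields
#' all 0.5 with a warning (the normalization is undefined there).
#'
#' @param column Numeric scores (>= 2 finite values).
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_scores <- function(column,
                             orientation = c("higher_better",
                                             "lower_better")) {
  orientation <- match.arg(orientation)
  s <- column
  if (sum(is.finite(s)) < 2) stop("need >= 2 finite scores")
  if (orientation == "lower_better") s <- -s
  rng <- range(s, finite = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant score column: normalized to 0.5")
    return(rep(0.5, length(s)))
  }
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Rank normalized scores, 1 = best
#'
#' Descending order; ties receive fractional (average) ranks, preserving
#' the rank-sum identity n(n+1)/2.
#'
#' @param normalized Numeric vector (higher = better).
#' @return Numeric ranks.
#' @export
rank_scores <- function(normalized) {
  stopifnot(all(is.finite(normalized)))
  rank(-normalized, ties.method = "average")
}

#' Rank-by-rank consensus over K score columns
#'
#' @param scores data.frame or matrix of K score columns (rows =
#'   compounds, aligned across columns).
#' @param orientations Character vector of length K
#'   (`"higher_better"`/`"lower_better"`), recycled if length 1.
#' @param compound_id Optional compound identifiers (used for
#'   deterministic tie-breaking of the final ordering).
#' @return A data.frame with per-column normalized scores (`norm.<col>`),
#'   per-column ranks (`rank.<col>`), `consensus_rank` (mean of the K
#'   ranks) and `consensus_order` (1 = best; ties broken by the first
#'   column's rank, then compound_id).
#' @export
consensus_rank <- function(scores, orientations = "higher_better",
                           compound_id = NULL) {
  scores <- as.data.frame(scores)
  K <- ncol(scores)
  if (K < 1) stop("consensus needs >= 1 score column")
  orientations <- rep_len(orientations, K)
  compound_id <- compound_id %||% as.character(seq_len(nrow(scores)))

  norm <- mapply(normalize_scores, scores, orientations,
                 SIMPLIFY = FALSE)
  ranks <- lapply(norm, rank_scores)
  rk <- do.call(cbind, ranks)
  cons <- rowMeans(rk)

  out <- data.frame(compound_id = compound_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[paste0("norm.", names(scores)[k])]] <- norm[[k]]
  for (k in seq_len(K)) out[[paste0("rank.", names(scores)[k])]] <- rk[, k]
  out$consensus_rank <- cons
  ord <- order(cons, rk[, 1], compound_id)
  out$consensus_order <- integer(nrow(out))
  out$consensus_order[ord] <- seq_len(nrow(out))
  out
}

#' Keep the best pose of each compound
#'
#' @param table data.frame with at least `compound_id` and the score
#'   column named by `by_column`.
#' @param by_column Score column used for selection.
#' @param orientation Orientation of `by_column`.
#' @return The input rows restricted to one best pose per compound (first
#'   occurrence wins on ties), in input order of first appearance.
#' @export
best_pose_per_compound <- function(table, by_column,
                                   orientation = c("higher_better",
                                                   "lower_better")) {
  orientation <- match.arg(orientation)
  if (!by_column %in% names(table))
    stop("no column '", by_column, "' in score table")
  s <- table[[by_column]]
  if (orientation == "lower_better") s <- -s
  best <- tapply(seq_len(nrow(table)), table$compound_id,
                 function(idx) idx[which.max(s[idx])])
  idx <- sort(unname(unlist(best)))
  table[idx, , drop = FALSE]
}
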