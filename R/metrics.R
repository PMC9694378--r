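# Virtual-screening evaluation: ROC AUC (Mann-Whitney), enrichment
# factors at a fraction of the ranked list, and BEDROC (Truchon & Bayly)
# with exponential early-rank weighting.

.check_two_class <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (!any(labels == 1) || !any(labels == 0))
    stop("metric undefined: both classes must be present")
}

#' ROC AUC via the Mann-Whitney statistic
#'
#' Equals P(score_active > score_inactive) + 0.5 P(tie).
#'
#' @param labels 0/1 vector (1 = active).
#' @param scores Numeric scores.
#' @param higher_better Score orientation (default TRUE).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores, higher_better = TRUE) {
  .check_two_class(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  s <- if (higher_better) scores else -scores
  r <- rank(s, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic ranking used by EF and BEDROC: best first, ties broken by
# compound_id for reproducibility
.screen_order <- function(scores, higher_better, ids) {
  s <- if (higher_better) -scores else scores
  order(s, ids)
}

#' Enrichment factor at a fraction of the ranked list
#'
#' `EF_chi = (a_chi / n_chi) / (A / N)` with `n_chi = ceiling(chi * N)`
#' top-ranked compounds, `a_chi` actives among them, `A` actives and `N`
#' compounds overall.
#'
#' @inheritParams roc_auc
#' @param fraction Screened fraction chi in (0, 1].
#' @param ids Optional identifiers for deterministic tie-breaking at the
#'   cutoff.
#' @return Enrichment factor (>= 0).
#' @export
enrichment_factor <- function(labels, scores, fraction,
                              higher_better = TRUE, ids = NULL) {
  .check_two_class(labels)
  stopifnot(fraction > 0, fraction <= 1)
  N <- length(labels)
  ids <- ids %||% as.character(seq_len(N))
  n_chi <- ceiling(fraction * N)
  top <- .screen_order(scores, higher_better, ids)[seq_len(n_chi)]
  a_chi <- sum(labels[top] == 1)
  (a_chi / n_chi) / (sum(labels == 1) / N)
}

#' BEDROC early-recognition metric (Truchon-Bayly)
#'
#' The robust initial enhancement `RIE = mean(exp(-alpha r_i / N))`-based
#' statistic mapped to \[0, 1\]: 1 for all actives ranked first, 0 for all
#' ranked last. `alpha` controls how strongly early ranks are weighted
#' (default 20, weighting roughly the top 8%).
#'
#' @inheritParams enrichment_factor
#' @param alpha Early-recognition weight (> 0), default 20.
#' @return BEDROC in \[0, 1\].
#' @export
bedroc <- function(labels, scores, alpha = 20, higher_better = TRUE,
                   ids = NULL) {
  .check_two_class(labels)
  stopifnot(alpha > 0)
  N <- length(labels)
  n <- sum(labels == 1)
  ids <- ids %||% as.character(seq_len(N))
  ord <- .screen_order(scores, higher_better, ids)
  r <- which(labels[ord] == 1)              # ranks of actives, 1 = best
  Ra <- n / N
  rie <- sum(exp(-alpha * r / N)) /
    (n / N * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Screening metrics for one score column
#'
#' @inheritParams enrichment_factor
#' @param fractions Enrichment fractions (default 1% and 5%).
#' @param alpha BEDROC alpha (default 20).
#' @return A `screen_metrics`: list with `auc`, `ef` (named by fraction),
#'   `bedroc`, `alpha`, `n_actives`, `n_total`.
#' @export
screen_metrics <- function(labels, scores, higher_better = TRUE,
                           fractions = c(0.01, 0.05), alpha = 20,
                           ids = NULL) {
  ef <- vapply(fractions, function(f)
    enrichment_factor(labels, scores, f, higher_better, ids), 0)
  names(ef) <- paste0("EF", fractions * 100, "%")
  structure(list(auc = roc_auc(labels, scores, higher_better),
                 ef = ef,
                 bedroc = bedroc(labels, scores, alpha, higher_better, ids),
                 alpha = alpha,
                 n_actives = sum(labels == 1), n_total = length(labels)),
            class = "screen_metrics")
}

#' Screening report over several score columns
#'
#' @param labels 0/1 vector.
#' @param score_columns data.frame of score columns.
#' @param orientations Orientation per column (`TRUE` = higher better),
#'   recycled.
#' @inheritParams screen_metrics
#' @return data.frame, one row per column: method, auc, one EF column per
#'   fraction, bedroc.
#' @export
screen_report <- function(labels, score_columns, orientations = TRUE,
                          fractions = c(0.01, 0.05), alpha = 20,
                          ids = NULL) {
  score_columns <- as.data.frame(score_columns)
  if (!ncol(score_columns)) stop("need >= 1 score column")
  orientations <- rep_len(orientations, ncol(score_columns))
  rows <- lapply(seq_len(ncol(score_columns)), function(k) {
    m <- screen_metrics(labels, score_columns[[k]], orientations[k],
                        fractions, alpha, ids)
    c(auc = m$auc, m$ef, bedroc = m$bedroc)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(data.frame(method = names(score_columns),
                   stringsAsFactors = FALSE), out)
}
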