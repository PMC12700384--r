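# Consensus evidence scoring. For each miRNA-gene pair the prediction score
# (P) is the fraction of tools that predicted it, n / n_tools_total; the
# experimental score (E) adds one point when the pair is validated in at
# least one curated database; their sum is the cumulative score (C). A
# miRNA's total score (T) averages its C-scores over the whole gene panel:
#
#   T = (1 / G) * sum_i ( n_i / n_tools_total + E_i )
#
# With five tools and a unit experimental point, C lies in {0} U [0.2, 2.0]
# and T in [0, 2]. C-scores are then exact multiples of 1/5, so totals are
# accumulated as scaled integers to keep printed one-decimal inputs summing
# exactly — 20 C-scores ending in .4 and .6 must give the published total
# to the last printed digit, not to within floating drift.

#' Scoring configuration
#'
#' @param n_tools_total Total number of prediction tools in the consensus
#'   (the P-score denominator). Default 5.
#' @param e_score_value Experimental point awarded to a validated pair.
#'   Default 1.
#' @param t_threshold Shortlisting threshold on the T-score; retention is
#'   strict (`T > t_threshold`). Default 1.0, the value at which a miRNA on
#'   average either carries experimental evidence for each panel gene or is
#'   predicted by every tool.
#' @return A list of class `"scoring_config"`.
#' @export
scoring_config <- function(n_tools_total = 5L, e_score_value = 1,
                           t_threshold = 1.0) {
  if (n_tools_total < 1) {
    ml_abort("n_tools_total must be at least 1", "mirlink_config_error")
  }
  if (e_score_value < 0) {
    ml_abort("e_score_value must be non-negative", "mirlink_config_error")
  }
  structure(list(n_tools_total = as.integer(n_tools_total),
                 e_score_value = e_score_value,
                 t_threshold = t_threshold),
            class = "scoring_config")
}

#' Prediction score: fraction of tools predicting a pair
#'
#' @param n Number of predicting tools, `0 <= n <= n_tools_total`
#'   (vectorized).
#' @param cfg A [scoring_config()].
#' @return `n / n_tools_total`.
#' @export
p_score <- function(n, cfg = scoring_config()) {
  stopifnot(inherits(cfg, "scoring_config"))
  if (any(n < 0) || any(n > cfg$n_tools_total)) {
    ml_abort(sprintf("n must lie in [0, %d]", cfg$n_tools_total),
             "mirlink_validation_error")
  }
  n / cfg$n_tools_total
}

#' Cumulative score of a miRNA-gene pair
#'
#' Sum of the prediction score and the experimental point:
#' `n / n_tools_total + e_score_value * validated`.
#'
#' @param n_tools Number of predicting tools (vectorized).
#' @param validated Logical; pair validated in at least one database.
#' @param cfg A [scoring_config()].
#' @return Numeric C-score(s).
#' @export
c_score <- function(n_tools, validated, cfg = scoring_config()) {
  p_score(n_tools, cfg) + cfg$e_score_value * as.numeric(validated)
}

#' Total score of a miRNA over a gene panel
#'
#' Sums the C-scores across the full panel (genes without evidence
#' contribute 0 and stay in the denominator) and divides by the panel size.
#' When every C-score is an exact multiple of `1/n_tools_total` — as it is
#' under an integer experimental point — the sum is accumulated in scaled
#' integers, so one-decimal inputs reproduce published totals exactly.
#'
#' @param c_scores Numeric vector of C-scores, one per panel gene.
#' @param cfg A [scoring_config()].
#' @param panel_size Panel size `G`; defaults to `length(c_scores)`.
#' @return A list with `total` and `t_score`.
#' @export
t_score <- function(c_scores, cfg = scoring_config(),
                    panel_size = length(c_scores)) {
  stopifnot(inherits(cfg, "scoring_config"))
  scale <- cfg$n_tools_total
  scaled <- c_scores * scale
  if (all(abs(scaled - round(scaled)) < 1e-6)) {
    s <- sum(round(scaled))
    list(total = s / scale, t_score = s / (scale * panel_size))
  } else {
    s <- sum(c_scores)
    list(total = s, t_score = s / panel_size)
  }
}

#' Score every miRNA in an evidence set over a gene panel
#'
#' Produces one score card per miRNA: its C-score for each panel gene
#' (0 where the pair has no evidence), the total, and the panel-averaged
#' T-score. Column order follows the panel.
#'
#' @param pairs Evidence tibble from [build_evidence()].
#' @param panel Gene panel.
#' @param cfg A [scoring_config()].
#' @return A tibble with columns `mirna`, one column per panel gene, `total`,
#'   `t_score`.
#' @export
score_mirnas <- function(pairs, panel, cfg = scoring_config()) {
  panel <- gene_panel(panel)
  stopifnot(inherits(cfg, "scoring_config"))
  if (nrow(pairs) == 0) {
    out <- tibble(mirna = character())
    for (g in panel) out[[g]] <- numeric(0)
    out$total <- numeric(0)
    out$t_score <- numeric(0)
    return(out)
  }
  n_tools <- if ("n_tools" %in% names(pairs)) pairs$n_tools else lengths(pairs$tools)
  cvals <- c_score(n_tools, pairs$validated, cfg)
  mirnas <- sort(unique(pairs$mirna))
  mat <- matrix(0, nrow = length(mirnas), ncol = length(panel),
                dimnames = list(mirnas, panel))
  mat[cbind(match(pairs$mirna, mirnas), match(pairs$gene, panel))] <- cvals
  scores <- apply(mat, 1, t_score, cfg = cfg, panel_size = length(panel))
  out <- as_tibble(mat, rownames = "mirna")
  out$total <- unname(vapply(scores, `[[`, numeric(1), "total"))
  out$t_score <- unname(vapply(scores, `[[`, numeric(1), "t_score"))
  out
}

#' Shortlist and rank score cards
#'
#' Retains miRNAs whose T-score strictly exceeds the threshold ("exceeds"
#' means `>`, so a card at exactly the threshold is excluded and logged) and
#' ranks them by T-score descending, ties broken by total descending then
#' miRNA id ascending, so the ordering is deterministic.
#'
#' @param cards Score-card tibble from [score_mirnas()].
#' @param cfg A [scoring_config()].
#' @return The retained rows, ranked.
#' @export
shortlist_mirnas <- function(cards, cfg = scoring_config()) {
  stopifnot(inherits(cfg, "scoring_config"))
  if (nrow(cards) == 0) return(cards)
  at_boundary <- cards$t_score == cfg$t_threshold
  if (any(at_boundary)) {
    message(sprintf("shortlist_mirnas: %d card(s) at exactly the threshold were excluded: %s",
                    sum(at_boundary), paste(cards$mirna[at_boundary], collapse = ", ")))
  }
  cards |>
    dplyr::filter(.data$t_score > cfg$t_threshold) |>
    dplyr::arrange(dplyr::desc(.data$t_score), dplyr::desc(.data$total), .data$mirna)
}
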