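# Over-representation analysis: one-sided upper-tail hypergeometric test of
# a query gene list against named gene sets, Benjamini-Hochberg FDR control,
# a set-size filter, and per-category top-k reporting. Also the
# differential-expression overlap bookkeeping used to check a shortlist
# against independent case-control DE tables.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes in a query of size `n` drawn
#' without replacement from a background of `N` genes of which `K` carry the
#' annotation. Evaluated through the stable distribution-function routine in
#' base R rather than by naive summation of density terms.
#'
#' @param k Observed overlap.
#' @param K Gene-set size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return The one-sided p-value in `(0, 1]`.
#' @export
hypergeom_p <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(n, K)
  if (any(!ok)) {
    ml_abort("inconsistent hypergeometric counts: need 0 <= k <= min(n, K), K <= N, n <= N",
             "mirlink_validation_error")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    ml_abort("p-values must lie in [0,1]", "mirlink_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests the query against every gene set whose within-background size lies
#' in `[min_size, max_size]`, adjusts p-values per category with
#' Benjamini-Hochberg, retains rows with `fdr < fdr_cut`, ranks them within
#' each category by overlap count descending (ties by FDR ascending, then
#' set name) and truncates to `top_k` per category. Query genes outside the
#' background are dropped with a warning; gene sets are intersected with
#' the background before sizing.
#'
#' @param query Character vector of query gene symbols.
#' @param collections Tibble with columns `name`, `genes` (list-column), and
#'   optionally `category`; [read_gmt()] output qualifies (one category).
#' @param background Character vector of background genes; defaults to the
#'   union of all collection genes.
#' @param min_size,max_size Inclusive bounds on the within-background
#'   gene-set size (defaults 2 and 5000).
#' @param fdr_cut FDR significance threshold (default 0.05, strict `<`).
#' @param top_k Rows reported per category (default 10).
#' @return A tibble with columns `term`, `category`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `fold_enrichment`.
#' @export
enrich <- function(query, collections, background = NULL,
                   min_size = 2L, max_size = 5000L,
                   fdr_cut = 0.05, top_k = 10L) {
  if (!("category" %in% names(collections))) collections$category <- "geneset"
  query <- unique(normalize_ids(query, "gene"))
  sets <- lapply(collections$genes, function(g) unique(normalize_ids(g, "gene")))
  background <- unique(normalize_ids(
    background %||% unlist(sets), "gene"))
  if (length(background) == 0) {
    ml_abort("empty background", "mirlink_validation_error")
  }
  off <- setdiff(query, background)
  if (length(off) > 0) {
    warning(sprintf("enrich: %d query gene(s) outside the background dropped: %s",
                    length(off), paste(off, collapse = ", ")), call. = FALSE)
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  sets <- lapply(sets, intersect, background)
  K <- lengths(sets)
  testable <- K >= min_size & K <= max_size
  if (!any(testable)) {
    return(tibble(term = character(), category = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric(),
                  fold_enrichment = numeric()))
  }
  res <- tibble(
    term = collections$name[testable],
    category = collections$category[testable],
    k = vapply(sets[testable], function(s) length(intersect(s, query)), integer(1)),
    K = K[testable], n = n, N = N
  )
  res$p_value <- hypergeom_p(res$k, res$K, res$n, res$N)
  res <- res |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(fold_enrichment = ifelse(.data$n > 0,
                                           (.data$k / .data$n) / (.data$K / .data$N), 0))
  res |>
    dplyr::filter(.data$fdr < fdr_cut) |>
    dplyr::group_by(.data$category) |>
    dplyr::arrange(dplyr::desc(.data$k), .data$fdr, .data$term, .by_group = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup()
}

#' Shortlist overlap with differential-expression tables
#'
#' Counts, for a shortlist of miRNAs and a stack of per-dataset DE records,
#' how many shortlisted miRNAs are significantly dysregulated (FDR below
#' `alpha`) in at least one dataset, in all datasets, and in none. A
#' shortlisted miRNA absent from a dataset is treated as not significant
#' there and logged.
#'
#' @param shortlist Character vector of miRNA ids.
#' @param de_tables DE tibble (`mirna`, `fdr`, `dataset`, ...) as from
#'   [read_de_table()] or [simulate_de_tables()].
#' @param alpha Significance threshold on the FDR column (default 0.05,
#'   strict `<`).
#' @return A list with `per_dataset` (named integer: significant shortlist
#'   members per dataset), `shortlist_size`, `n_any`, `n_all`, `n_none`,
#'   and `membership` (logical tibble, one row per shortlisted miRNA).
#' @export
overlap_summary <- function(shortlist, de_tables, alpha = 0.05) {
  shortlist <- unique(normalize_ids(shortlist, "mirna"))
  datasets <- unique(de_tables$dataset)
  member <- matrix(FALSE, nrow = length(shortlist), ncol = length(datasets),
                   dimnames = list(shortlist, datasets))
  for (d in datasets) {
    sub <- de_tables[de_tables$dataset == d, , drop = FALSE]
    absent <- setdiff(shortlist, sub$mirna)
    if (length(absent) > 0) {
      message(sprintf("overlap_summary: %d shortlisted miRNA(s) absent from dataset %s (treated as not significant)",
                      length(absent), d))
    }
    sig <- unique(sub$mirna[sub$fdr < alpha])
    member[, d] <- shortlist %in% sig
  }
  any_sig <- if (length(datasets) > 0) rowSums(member) > 0 else rep(FALSE, length(shortlist))
  all_sig <- if (length(datasets) > 0) rowSums(member) == length(datasets) else rep(FALSE, length(shortlist))
  list(
    per_dataset = setNames(as.integer(colSums(member)), datasets),
    shortlist_size = length(shortlist),
    n_any = sum(any_sig),
    n_all = if (length(datasets) > 0) sum(all_sig) else 0L,
    n_none = sum(!any_sig),
    membership = as_tibble(member, rownames = "mirna")
  )
}
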