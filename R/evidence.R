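# Evidence aggregation: collapse raw prediction and validation records into
# one evidence pair per (miRNA, gene), applying the consensus-screen
# filtering rules, and tabulate per-gene evidence counts.

#' Prediction filtering policy
#'
#' Encodes the filtering rules of a consensus target-prediction screen: a
#' confidence-score cut-off applied to the tools that emit comparable scores
#' (default 0.80, inclusive, for miRDB, miRmap and DIANA-microT), and a
#' conservation requirement for tools that flag target-site conservation
#' (default TargetScan). Records from other tools pass unconditionally.
#'
#' @param score_cutoff Minimum score, in `[0, 1]`; the boundary is kept
#'   (a record scoring exactly the cut-off survives).
#' @param score_cutoff_tools Tools the cut-off applies to.
#' @param require_conserved_tools Tools for which `conserved = TRUE` is
#'   required.
#' @param species Informational species label.
#' @param tools Configured tool universe; the two subsets must lie within it.
#' @return A list of class `"filter_policy"`.
#' @export
filter_policy <- function(score_cutoff = 0.80,
                          score_cutoff_tools = c("miRDB", "miRmap", "microT"),
                          require_conserved_tools = "TargetScan",
                          species = "Homo sapiens",
                          tools = default_tools()) {
  if (score_cutoff < 0 || score_cutoff > 1) {
    ml_abort("score_cutoff must lie in [0,1]", "mirlink_config_error")
  }
  stray <- setdiff(c(score_cutoff_tools, require_conserved_tools), tools)
  if (length(stray) > 0) {
    ml_abort(sprintf("policy names tool(s) outside the configured list: %s",
                     paste(stray, collapse = ", ")), "mirlink_config_error")
  }
  structure(list(score_cutoff = score_cutoff,
                 score_cutoff_tools = score_cutoff_tools,
                 require_conserved_tools = require_conserved_tools,
                 species = species, tools = tools),
            class = "filter_policy")
}

#' Filter prediction records under a policy
#'
#' A record from a cut-off tool survives iff its score is present and at
#' least the cut-off; a record from a conservation-required tool survives
#' iff `conserved` is `TRUE`. Records from other tools pass unconditionally.
#' Output order is stable. A cut-off-tool record lacking a score is rejected
#' with a warning, not an error.
#'
#' @param records Prediction tibble as from [read_predictions()].
#' @param policy A [filter_policy()].
#' @return Filtered prediction tibble.
#' @export
apply_filters <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(records) == 0) return(records)
  keep <- rep(TRUE, nrow(records))

  in_cut <- records$tool %in% policy$score_cutoff_tools
  no_score <- in_cut & is.na(records$score)
  if (any(no_score)) {
    warning(sprintf("apply_filters: %d record(s) from score-cutoff tools lack a score and were dropped",
                    sum(no_score)), call. = FALSE)
  }
  keep[in_cut] <- !is.na(records$score[in_cut]) &
    records$score[in_cut] >= policy$score_cutoff

  in_cons <- records$tool %in% policy$require_conserved_tools
  keep[in_cons] <- keep[in_cons] &
    !is.na(records$conserved[in_cons]) & records$conserved[in_cons]

  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("apply_filters: dropped %d of %d record(s)", dropped, nrow(records)))
  }
  records[keep, , drop = FALSE]
}

#' Collapse records into one evidence pair per (miRNA, gene)
#'
#' Builds exactly one row per pair with at least one surviving evidence
#' item. `tools` is the deduplicated set of predicting tools (its size is
#' the `n` of the P-score); `validated` is `TRUE` iff the pair appears in
#' at least one validation database — validation in several databases still
#' yields a single experimental point ("either" semantics). Pairs with no
#' prediction but with validation are retained (`n = 0`, validated): either
#' evidence channel suffices on its own. Genes outside the panel are
#' dropped with a log message.
#'
#' @param predictions Filtered prediction tibble.
#' @param validations Validation tibble.
#' @param panel Gene panel (character vector, see [gene_panel()]).
#' @return Tibble with columns `mirna`, `gene`, `tools` (list-column),
#'   `n_tools`, `validated`.
#' @export
build_evidence <- function(predictions, validations, panel) {
  panel <- gene_panel(panel)
  off_panel <- sum(!(predictions$gene %in% panel)) +
    sum(!(validations$gene %in% panel))
  if (off_panel > 0) {
    message(sprintf("build_evidence: dropped %d off-panel record(s)", off_panel))
  }
  predictions <- predictions[predictions$gene %in% panel, , drop = FALSE]
  validations <- validations[validations$gene %in% panel, , drop = FALSE]

  pred_pairs <- predictions |>
    dplyr::group_by(.data$mirna, .data$gene) |>
    dplyr::summarise(tools = list(sort(unique(.data$tool))), .groups = "drop")
  val_pairs <- dplyr::distinct(validations, .data$mirna, .data$gene) |>
    dplyr::mutate(validated = TRUE)

  out <- dplyr::full_join(pred_pairs, val_pairs, by = c("mirna", "gene"))
  out$tools[vapply(out$tools, is.null, logical(1))] <- list(character(0))
  out$validated[is.na(out$validated)] <- FALSE
  out |>
    dplyr::mutate(n_tools = lengths(.data$tools)) |>
    dplyr::select("mirna", "gene", "tools", "n_tools", "validated") |>
    dplyr::arrange(.data$mirna, .data$gene)
}

#' Per-gene evidence counts
#'
#' For every panel gene (in panel order): the number of distinct miRNAs
#' predicted by each tool, the size of the union of tool-predicted miRNAs
#' (`predicted_total`), the union of validated miRNAs
#' (`experimental_total`), and the union of both (`overall_total`). Genes
#' with no records get all-zero counts.
#'
#' @param predictions Filtered prediction tibble.
#' @param validations Validation tibble.
#' @param panel Gene panel.
#' @param tools Tool labels defining the per-tool count columns.
#' @return Tibble with one row per panel gene.
#' @export
count_gene_evidence <- function(predictions, validations, panel,
                                tools = default_tools()) {
  panel <- gene_panel(panel)
  predictions <- predictions[predictions$gene %in% panel, , drop = FALSE]
  validations <- validations[validations$gene %in% panel, , drop = FALSE]

  rows <- lapply(panel, function(g) {
    p <- predictions[predictions$gene == g, , drop = FALSE]
    v <- validations[validations$gene == g, , drop = FALSE]
    per_tool <- vapply(tools, function(tl) {
      length(unique(p$mirna[p$tool == tl]))
    }, integer(1))
    predicted <- unique(p$mirna)
    experimental <- unique(v$mirna)
    c(list(gene = g), as.list(per_tool),
      list(predicted_total = length(predicted),
           experimental_total = length(experimental),
           overall_total = length(union(predicted, experimental))))
  })
  dplyr::bind_rows(rows)
}
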