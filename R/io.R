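# Readers and writers for the tabular and network formats the pipeline
# touches. Every reader validates and normalizes identifiers so downstream
# modules only ever see typed, canonical records. Rejected rows are logged
# (message to stderr) and counted, never silently dropped.

#' Normalize miRNA and gene identifiers
#'
#' Gene symbols are upper-cased with surrounding whitespace stripped. miRNA
#' identifiers are stripped of whitespace and given a lower-case `"hsa-"`
#' species prefix when absent; the internal case of the name (family number,
#' mature-arm suffix) is preserved so `"miR-15a-5p"` becomes
#' `"hsa-miR-15a-5p"`. Normalization is idempotent.
#'
#' @param x Character vector of raw identifiers.
#' @param kind `"gene"` or `"mirna"`.
#' @return Character vector of canonical identifiers.
#' @examples
#' normalize_ids("insr", "gene")
#' normalize_ids("miR-15a-5p", "mirna")
#' @export
normalize_ids <- function(x, kind = c("gene", "mirna")) {
  kind <- match.arg(kind)
  x <- trimws(as.character(x))
  if (any(is.na(x)) || any(!nzchar(x))) {
    ml_abort("empty identifier after whitespace stripping", "mirlink_validation_error")
  }
  if (kind == "gene") {
    return(toupper(x))
  }
  has_prefix <- grepl("^hsa-", x, ignore.case = TRUE)
  x[has_prefix] <- sub("^hsa-", "hsa-", x[has_prefix], ignore.case = TRUE)
  x[!has_prefix] <- paste0("hsa-", x[!has_prefix])
  x
}

# internal: check that a data frame carries the required columns
require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    ml_abort(
      sprintf("%s: missing required column(s): %s", path, paste(missing, collapse = ", ")),
      "mirlink_format_error"
    )
  }
  invisible(tab)
}

#' Read a miRNA target-prediction table
#'
#' Expects a UTF-8 tab-separated file with header columns `mirna`, `gene`,
#' `tool`, `score`, `conserved`. `score` and `conserved` may be empty: not
#' every prediction tool emits a confidence score or a conservation flag.
#' Rows whose score falls outside `[0, 1]` are rejected with a logged reason;
#' an unrecognized tool label is an error (it indicates a misconfigured run,
#' not a bad row).
#'
#' @param path Path to the TSV file.
#' @param tools Character vector of allowed tool labels.
#' @return A tibble with columns `mirna`, `gene`, `tool`, `score`, `conserved`.
#' @export
read_predictions <- function(path, tools = default_tools()) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(tab, c("mirna", "gene", "tool", "score", "conserved"), path)
  score <- suppressWarnings(as.numeric(tab$score))
  bad_num <- !is.na(tab$score) & is.na(score)
  conserved <- as.logical(toupper(tab$conserved))

  unknown <- !(tab$tool %in% tools)
  if (any(unknown)) {
    ml_abort(
      sprintf("%s: unknown tool label(s) %s at row(s) %s", path,
              paste(unique(tab$tool[unknown]), collapse = ", "),
              paste(which(unknown), collapse = ", ")),
      "mirlink_validation_error"
    )
  }

  out_of_range <- !is.na(score) & (score < 0 | score > 1)
  reject <- out_of_range | bad_num
  if (any(reject)) {
    message(sprintf("read_predictions: rejected %d row(s) with score outside [0,1]: row(s) %s",
                    sum(reject), paste(which(reject), collapse = ", ")))
  }
  keep <- !reject
  tibble(
    mirna = normalize_ids(tab$mirna[keep], "mirna"),
    gene = normalize_ids(tab$gene[keep], "gene"),
    tool = tab$tool[keep],
    score = score[keep],
    conserved = conserved[keep]
  )
}

#' Read an experimentally-validated interaction table
#'
#' TSV with header columns `mirna`, `gene`, `database`. Duplicate rows are
#' returned as-is; deduplication is the evidence module's job.
#'
#' @param path Path to the TSV file.
#' @param databases Character vector of allowed validation-database labels.
#' @return A tibble with columns `mirna`, `gene`, `database`.
#' @export
read_validations <- function(path, databases = default_databases()) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(tab, c("mirna", "gene", "database"), path)
  if (nrow(tab) == 0) {
    return(tibble(mirna = character(), gene = character(), database = character()))
  }
  unknown <- !(tab$database %in% databases)
  if (any(unknown)) {
    ml_abort(
      sprintf("%s: unknown database label(s) %s at row(s) %s", path,
              paste(unique(tab$database[unknown]), collapse = ", "),
              paste(which(unknown), collapse = ", ")),
      "mirlink_validation_error"
    )
  }
  tibble(
    mirna = normalize_ids(tab$mirna, "mirna"),
    gene = normalize_ids(tab$gene, "gene"),
    database = tab$database
  )
}

#' Construct a validated gene panel
#'
#' A gene panel is the fixed, ordered list of pathway genes over which
#' T-scores are averaged; its order defines score-table column order.
#'
#' @param genes Character vector of gene symbols.
#' @return Normalized character vector; errors on duplicates.
#' @export
gene_panel <- function(genes) {
  genes <- normalize_ids(genes, "gene")
  if (anyDuplicated(genes)) {
    ml_abort(sprintf("duplicate gene symbol(s) in panel: %s",
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")),
             "mirlink_validation_error")
  }
  if (length(genes) < 1) ml_abort("gene panel is empty", "mirlink_validation_error")
  genes
}

#' Read a gene panel from a TSV file with a `gene` column
#'
#' @param path Path to the TSV file.
#' @return Normalized character vector of panel genes (order preserved).
#' @export
read_gene_panel <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(tab, "gene", path)
  gene_panel(tab$gene)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene...`.
#' The description field is discarded; genes are normalized and deduplicated
#' within each set. Line order is preserved.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `name` (character) and `genes` (list of
#'   character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    ml_abort(sprintf("%s: GMT line(s) with fewer than 3 fields: line %s",
                     path, paste(short, collapse = ", ")),
             "mirlink_format_error")
  }
  tibble(
    name = vapply(fields, `[[`, character(1), 1L),
    genes = lapply(fields, function(f) unique(normalize_ids(f[-(1:2)], "gene")))
  )
}

#' Read a protein-protein interaction edge list
#'
#' TSV with columns `protein1`, `protein2`, `combined_score`. STRING exports
#' encode the combined score as an integer 0-999 (milli scale); other sources
#' use the unit interval. In `"auto"` mode a file whose maximum score exceeds
#' 1 is treated as milli-scaled and divided by 1000 (a monotone rescaling).
#' Self-loops are dropped with a log message.
#'
#' @param path Path to the TSV file.
#' @param score_scale `"auto"`, `"unit"` or `"milli"`.
#' @return A tibble with columns `protein_a`, `protein_b`, `combined_score`
#'   (unit scale).
#' @export
read_edge_list <- function(path, score_scale = c("auto", "unit", "milli")) {
  score_scale <- match.arg(score_scale)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(tab, c("protein1", "protein2", "combined_score"), path)
  score <- suppressWarnings(as.numeric(tab$combined_score))
  if (any(is.na(score))) {
    ml_abort(sprintf("%s: non-numeric combined_score", path), "mirlink_format_error")
  }
  if (any(score < 0)) {
    ml_abort(sprintf("%s: negative combined_score", path), "mirlink_format_error")
  }
  if (any(score > 1000)) {
    ml_abort(sprintf("%s: combined_score above 1000", path), "mirlink_format_error")
  }
  milli <- switch(score_scale,
    milli = TRUE,
    unit = FALSE,
    auto = length(score) > 0 && max(score) > 1
  )
  if (!milli && any(score > 1)) {
    ml_abort(sprintf("%s: combined_score above 1 on unit scale", path), "mirlink_format_error")
  }
  if (milli) score <- score / 1000
  a <- normalize_ids(tab$protein1, "gene")
  b <- normalize_ids(tab$protein2, "gene")
  loops <- a == b
  if (any(loops)) {
    message(sprintf("read_edge_list: dropped %d self-loop(s)", sum(loops)))
  }
  tibble(protein_a = a[!loops], protein_b = b[!loops], combined_score = score[!loops])
}

#' Read a differential-expression result table for miRNAs
#'
#' TSV with columns `mirna`, `log_fold_change`, `p_value`, `fdr`, `dataset`.
#' These tables are consumed, not computed: the differential-expression fit
#' itself is upstream of this package.
#'
#' @param path Path to the TSV file.
#' @return A tibble of validated DE records.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(tab, c("mirna", "log_fold_change", "p_value", "fdr", "dataset"), path)
  p <- as.numeric(tab$p_value)
  fdr <- as.numeric(tab$fdr)
  if (any(is.na(p)) || any(p < 0) || any(p > 1) || any(is.na(fdr)) || any(fdr < 0) || any(fdr > 1)) {
    ml_abort(sprintf("%s: p_value/fdr outside [0,1]", path), "mirlink_format_error")
  }
  tibble(
    mirna = normalize_ids(tab$mirna, "mirna"),
    log_fold_change = as.numeric(tab$log_fold_change),
    p_value = p, fdr = fdr, dataset = tab$dataset
  )
}

#' Write prediction, validation or edge tables back to TSV
#'
#' Inverse of the corresponding readers; writing then reading a table of
#' valid records reproduces the records exactly.
#'
#' @param records Tibble as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
write_validations <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
write_edge_list <- function(records, path) {
  out <- tibble(protein1 = records$protein_a, protein2 = records$protein_b,
                combined_score = records$combined_score)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a typed network to GraphML or SIF
#'
#' Nodes carry a `type` attribute (`"mirna"` or `"gene"`), edges a numeric
#' `weight`. GraphML output is written through igraph and parseable by
#' standard graph tools (Cytoscape, igraph, networkx); SIF writes one
#' `source  interaction  target` line per edge plus bare lines for isolated
#' nodes.
#'
#' @param nodes Tibble with columns `id`, `type`.
#' @param edges Tibble with columns `from`, `to`, `weight`.
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @param relation SIF interaction label (default `"targets"`).
#' @return `path`, invisibly.
#' @export
export_network <- function(nodes, edges, path, format = c("graphml", "sif"),
                           relation = "targets") {
  format <- tryCatch(match.arg(format),
                     error = function(e) ml_abort(
                       sprintf("unknown export format: %s", format[1]), "mirlink_usage_error"))
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = as.data.frame(edges[, c("from", "to", "weight")]),
      directed = FALSE,
      vertices = as.data.frame(nodes[, c("id", "type")])
    )
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- character(0)
    if (nrow(edges) > 0) {
      lines <- paste(edges$from, relation, edges$to, sep = "\t")
    }
    isolated <- setdiff(nodes$id, c(edges$from, edges$to))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
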