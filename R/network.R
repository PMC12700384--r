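# Downstream network analysis: intersect shortlisted miRNAs' targets with a
# pathway gene set, build the confidence-thresholded PPI graph, extract
# top-k hubs by degree, and assemble the bipartite miRNA-gene network.

#' Per-miRNA pathway target hits
#'
#' For each shortlisted miRNA and each interaction source, intersects that
#' source's targets with the pathway gene set; `total_hits` is the size of
#' the union over sources. Also returns the consolidated non-redundant gene
#' list across all miRNAs (attribute `"consolidated_genes"`). A shortlisted
#' miRNA absent from every source yields a zero-hit row with a warning.
#'
#' @param shortlist Character vector of miRNA ids.
#' @param interactions Long tibble with columns `source`, `mirna`, `gene`.
#' @param pathway_genes Character vector: the pathway gene set.
#' @return A tibble with columns `mirna`, one hit-count column per source,
#'   `total_hits`, and a list-column `genes` holding each miRNA's union hit
#'   set; attribute `"consolidated_genes"` carries the overall union.
#' @export
pathway_hits <- function(shortlist, interactions, pathway_genes) {
  shortlist <- normalize_ids(shortlist, "mirna")
  pathway_genes <- unique(normalize_ids(pathway_genes, "gene"))
  sources <- unique(interactions$source)
  missing <- setdiff(shortlist, unique(interactions$mirna))
  if (length(missing) > 0) {
    warning(sprintf("pathway_hits: miRNA(s) absent from all sources: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(shortlist, function(m) {
    sub <- interactions[interactions$mirna == m, , drop = FALSE]
    per_source <- lapply(sources, function(s) {
      intersect(unique(sub$gene[sub$source == s]), pathway_genes)
    })
    names(per_source) <- sources
    hit_union <- sort(unique(unlist(per_source)))
    c(list(mirna = m), lapply(per_source, length),
      list(total_hits = length(hit_union), genes = list(hit_union)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "consolidated_genes") <- sort(unique(unlist(out$genes)))
  out
}

#' Build a confidence-thresholded PPI graph
#'
#' Keeps edges whose combined score is at least the threshold (inclusive)
#' and, when a node whitelist is given, whose both endpoints lie in it.
#' Duplicate and reversed edges collapse to a single undirected edge keeping
#' the maximum score; self-loops are dropped. Isolated whitelist nodes are
#' retained as degree-0 vertices.
#'
#' @param edges Edge tibble from [read_edge_list()] or [simulate_ppi()].
#' @param whitelist Optional character vector of allowed nodes; `NULL`
#'   admits every endpoint.
#' @param threshold High-confidence score threshold on `[0, 1]`
#'   (default 0.7).
#' @return An undirected simple igraph with edge attribute `combined_score`
#'   and graph attribute `threshold`.
#' @export
build_ppi <- function(edges, whitelist = NULL, threshold = 0.7) {
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  keep <- a != b & edges$combined_score >= threshold
  if (!is.null(whitelist)) {
    whitelist <- unique(normalize_ids(whitelist, "gene"))
    keep <- keep & a %in% whitelist & b %in% whitelist
  }
  ed <- tibble(a = a[keep], b = b[keep], combined_score = edges$combined_score[keep])
  if (nrow(ed) > 0) {
    ed <- ed |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop")
  }
  vertices <- if (is.null(whitelist)) sort(unique(c(ed$a, ed$b))) else whitelist
  g <- igraph::graph_from_data_frame(as.data.frame(ed), directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Extract top-k hub nodes by degree
#'
#' Ranks nodes of the (unweighted, undirected, simple) graph by degree
#' descending, ties broken by node name ascending. If a degree tie spans the
#' k-th boundary, a warning lists the excluded tied nodes; if `k` exceeds
#' the node count, all nodes are returned with a warning.
#'
#' @param graph An igraph, e.g. from [build_ppi()].
#' @param k Number of hubs to report (default 10).
#' @return A tibble with columns `gene`, `degree`, `rank` (1..k), degrees
#'   non-increasing.
#' @export
degree_hubs <- function(graph, k = 10L) {
  deg <- igraph::degree(graph)
  tb <- tibble(gene = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
  if (k > nrow(tb)) {
    warning(sprintf("degree_hubs: k = %d exceeds node count %d; returning all nodes",
                    k, nrow(tb)), call. = FALSE)
    k <- nrow(tb)
  }
  if (k < nrow(tb) && k > 0 && tb$degree[k] == tb$degree[k + 1]) {
    tied <- tb$gene[tb$degree == tb$degree[k]]
    excluded <- setdiff(tied, tb$gene[seq_len(k)])
    warning(sprintf("degree_hubs: degree tie at rank %d; excluded tied node(s): %s",
                    k, paste(excluded, collapse = ", ")), call. = FALSE)
  }
  out <- tb[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  out
}

#' Assemble a bipartite miRNA-gene network
#'
#' Builds node and edge lists connecting miRNA nodes to gene nodes only —
#' no miRNA-miRNA or gene-gene edges — with the supplied edge weights
#' (typically C-scores or hit counts), ready for [export_network()].
#'
#' @param links Tibble with columns `mirna`, `gene`, `weight`.
#' @param mirnas,genes Optional node universes; default to the ids present
#'   in `links`. Supplying them keeps isolated nodes (e.g. a shortlisted
#'   miRNA with no hub hits) in the network.
#' @return A list with `nodes` (tibble `id`, `type`) and `edges` (tibble
#'   `from`, `to`, `weight`).
#' @export
bipartite_network <- function(links, mirnas = unique(links$mirna),
                              genes = unique(links$gene)) {
  mirnas <- unique(c(mirnas, links$mirna))
  genes <- unique(c(genes, links$gene))
  clash <- intersect(mirnas, genes)
  if (length(clash) > 0) {
    ml_abort(sprintf("identifier(s) appear both as miRNA and gene: %s",
                     paste(clash, collapse = ", ")), "mirlink_validation_error")
  }
  list(
    nodes = dplyr::bind_rows(
      tibble(id = mirnas, type = "mirna"),
      tibble(id = genes, type = "gene")
    ),
    edges = tibble(from = links$mirna, to = links$gene, weight = links$weight)
  )
}
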