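test_that("pathway_hits intersects per source and unions across sources", {
  interactions <- tibble::tibble(
    source = c("TarBase", "TarBase", "miRTarBase", "miRTarBase"),
    mirna = "hsa-miR-1-5p",
    gene = c("A", "B", "B", "C")
  )
  hits <- pathway_hits("hsa-miR-1-5p", interactions, c("A", "B", "C", "D"))
  expect_equal(hits$TarBase, 2)
  expect_equal(hits$miRTarBase, 2)
  expect_equal(hits$total_hits, 3)
  expect_setequal(hits$genes[[1]], c("A", "B", "C"))

  none <- pathway_hits("hsa-miR-1-5p", interactions, c("X", "Y"))
  expect_equal(none$total_hits, 0)
})

test_that("pathway_hits consolidates a non-redundant union and flags absentees", {
  interactions <- tibble::tibble(
    source = "TarBase",
    mirna = c("hsa-miR-1-5p", "hsa-miR-1-5p", "hsa-miR-2-5p", "hsa-miR-2-5p"),
    gene = c("A", "B", "B", "C")
  )
  hits <- pathway_hits(c("hsa-miR-1-5p", "hsa-miR-2-5p"), interactions,
                       c("A", "B", "C"))
  expect_equal(attr(hits, "consolidated_genes"), c("A", "B", "C"))

  expect_warning(
    zero <- pathway_hits(c("hsa-miR-1-5p", "hsa-miR-9-5p"), interactions,
                         c("A", "B", "C")),
    "absent from all sources"
  )
  expect_equal(zero$total_hits[zero$mirna == "hsa-miR-9-5p"], 0)
})

test_that("pathway_hits unions are invariant to input row order", {
  set.seed(55)
  interactions <- tibble::tibble(
    source = sample(c("S1", "S2"), 40, replace = TRUE),
    mirna = sample(sprintf("hsa-miR-%d-5p", 1:4), 40, replace = TRUE),
    gene = sample(LETTERS[1:8], 40, replace = TRUE)
  )
  pathway <- LETTERS[1:5]
  sl <- sprintf("hsa-miR-%d-5p", 1:4)
  a <- pathway_hits(sl, interactions, pathway)
  b <- pathway_hits(sl, interactions[sample(40), ], pathway)
  expect_equal(a$total_hits, b$total_hits)
  expect_equal(attr(a, "consolidated_genes"), attr(b, "consolidated_genes"))
})

test_that("build_ppi collapses reversed duplicates and thresholds inclusively", {
  edges <- tibble::tibble(
    protein_a = c("A", "B", "A", "C"),
    protein_b = c("B", "A", "X", "D"),
    combined_score = c(0.71, 0.69, 0.9, 0.7)
  )
  g <- build_ppi(edges, whitelist = c("A", "B", "C", "D"), threshold = 0.7)
  expect_equal(igraph::ecount(g), 2)  # A-B (max 0.71) and C-D (0.70 kept)
  ed <- igraph::as_data_frame(g, what = "edges")
  ab <- ed[(ed$from == "A" & ed$to == "B") | (ed$from == "B" & ed$to == "A"), ]
  expect_equal(ab$combined_score, 0.71)

  # empty edge list leaves isolated whitelist nodes
  g0 <- build_ppi(edges[0, ], whitelist = c("A", "B"))
  expect_equal(igraph::vcount(g0), 2)
  expect_equal(igraph::ecount(g0), 0)
})

test_that("degree_hubs matches closed forms and breaks ties by name", {
  star <- tibble::tibble(protein_a = "H", protein_b = paste0("L", 1:5),
                         combined_score = 1)
  g <- build_ppi(star, threshold = 0)
  expect_equal(degree_hubs(g, 1),
               tibble::tibble(gene = "H", degree = 5L, rank = 1L))

  path <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "C"),
                         combined_score = 1)
  hubs <- degree_hubs(build_ppi(path, threshold = 0), 3)
  expect_equal(hubs$gene, c("B", "A", "C"))
  expect_equal(hubs$degree, c(2L, 1L, 1L))
  expect_equal(hubs$rank, 1:3)
})

test_that("degree_hubs warns on k overflow and on ties spanning the boundary", {
  path <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "C"),
                         combined_score = 1)
  g <- build_ppi(path, threshold = 0)
  expect_warning(all_nodes <- degree_hubs(g, 10), "exceeds node count")
  expect_equal(nrow(all_nodes), 3)
  expect_warning(two <- degree_hubs(g, 2), "tie at rank 2")
  expect_equal(two$gene, c("B", "A"))
})

test_that("degree_hubs agrees with brute-force adjacency counts", {
  for (s in 1:10) {
    set.seed(300 + s)
    n <- sample(5:50, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- runif(nrow(idx)) < 0.15
    edges <- tibble::tibble(protein_a = nodes[idx[pick, 1]],
                            protein_b = nodes[idx[pick, 2]],
                            combined_score = 1)
    g <- build_ppi(edges, whitelist = nodes, threshold = 0)
    hubs <- suppressWarnings(degree_hubs(g, n))
    expected <- oracle_degrees(edges, nodes)
    expect_equal(setNames(hubs$degree, hubs$gene)[nodes], expected)
    expect_true(all(diff(hubs$degree) <= 0))
  }
})

test_that("raising the PPI threshold never increases any degree", {
  sim <- simulate_ppi(sim_config(seed = 8))
  lo <- igraph::degree(build_ppi(sim$edges, whitelist = sim$nodes, threshold = 0.5))
  hi <- igraph::degree(build_ppi(sim$edges, whitelist = sim$nodes, threshold = 0.8))
  expect_true(all(hi[names(lo)] <= lo))
})

test_that("bipartite_network separates miRNA and gene layers", {
  links <- tidyr::expand_grid(mirna = c("hsa-miR-1-5p", "hsa-miR-2-5p"),
                              gene = c("GAPDH", "GSK3B")) |>
    dplyr::mutate(weight = c(2, 1.4, 1, 0.2))
  net <- bipartite_network(links)
  expect_equal(nrow(net$edges), 4)
  expect_setequal(net$nodes$type[net$nodes$id %in% links$mirna], "mirna")
  expect_setequal(net$nodes$type[net$nodes$id %in% links$gene], "gene")
  expect_true(all(net$edges$from %in% net$nodes$id[net$nodes$type == "mirna"]))
  expect_true(all(net$edges$to %in% net$nodes$id[net$nodes$type == "gene"]))
  expect_true(all(net$edges$weight == 0 |
                    (net$edges$weight >= 0.2 & net$edges$weight <= 2)))

  empty <- bipartite_network(links[0, ], mirnas = "hsa-miR-1-5p",
                             genes = "GAPDH")
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 2)

  clash <- tibble::tibble(mirna = "X", gene = "X", weight = 1)
  expect_error(bipartite_network(clash), class = "mirlink_validation_error")
})
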