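make_pred <- function(mirna, gene, tool, score = NA_real_, conserved = NA) {
  tibble::tibble(mirna = mirna, gene = gene, tool = tool,
                 score = score, conserved = conserved)
}

test_that("score cut-off is inclusive at the boundary and tool-scoped", {
  recs <- dplyr::bind_rows(
    make_pred("hsa-miR-1-5p", "INSR", "miRDB", score = 0.80),
    make_pred("hsa-miR-1-5p", "INSR", "miRmap", score = 0.79),
    make_pred("hsa-miR-1-5p", "INSR", "miRTar2GO", score = 0.10),
    make_pred("hsa-miR-1-5p", "INSR", "TargetScan", conserved = TRUE),
    make_pred("hsa-miR-2-5p", "INSR", "TargetScan", conserved = FALSE)
  )
  kept <- suppressMessages(apply_filters(recs, filter_policy()))
  expect_equal(kept$tool, c("miRDB", "miRTar2GO", "TargetScan"))
  expect_equal(kept$mirna[3], "hsa-miR-1-5p")
})

test_that("cut-off tool records without a score are dropped with a warning", {
  recs <- make_pred("hsa-miR-1-5p", "INSR", "miRDB")
  expect_warning(kept <- apply_filters(recs, filter_policy()), "lack a score")
  expect_equal(nrow(kept), 0)
})

test_that("filtering preserves record order and empty input passes through", {
  recs <- dplyr::bind_rows(
    make_pred("hsa-miR-3-5p", "IRS1", "miRTar2GO"),
    make_pred("hsa-miR-1-5p", "INSR", "miRDB", score = 0.9),
    make_pred("hsa-miR-2-5p", "GSK3B", "miRmap", score = 0.99)
  )
  kept <- apply_filters(recs, filter_policy())
  expect_equal(kept$mirna, c("hsa-miR-3-5p", "hsa-miR-1-5p", "hsa-miR-2-5p"))
  expect_equal(nrow(apply_filters(recs[0, ], filter_policy())), 0)
})

test_that("build_evidence deduplicates tools and applies either-validation", {
  panel <- gene_panel(c("INSR", "IRS1", "GSK3B"))
  preds <- dplyr::bind_rows(
    make_pred("hsa-miR-1-5p", "INSR", "miRDB", score = 0.9),
    make_pred("hsa-miR-1-5p", "INSR", "miRDB", score = 0.85),
    make_pred("hsa-miR-1-5p", "INSR", "miRmap", score = 0.95)
  )
  vals <- tibble::tibble(
    mirna = c("hsa-miR-1-5p", "hsa-miR-1-5p", "hsa-miR-2-5p"),
    gene = c("INSR", "INSR", "IRS1"),
    database = c("TarBase", "miRTarBase", "TarBase")
  )
  ev <- build_evidence(preds, vals, panel)
  expect_equal(nrow(ev), 2)

  insr <- ev[ev$gene == "INSR", ]
  expect_equal(insr$tools[[1]], c("miRDB", "miRmap"))
  expect_equal(insr$n_tools, 2)
  expect_true(insr$validated)  # one flag, however many databases agree

  # validation-only pair survives with n = 0
  irs1 <- ev[ev$gene == "IRS1", ]
  expect_equal(irs1$n_tools, 0)
  expect_true(irs1$validated)
})

test_that("off-panel genes are dropped with a log message", {
  panel <- gene_panel("INSR")
  preds <- make_pred("hsa-miR-1-5p", "FOXO3", "miRDB", score = 0.9)
  vals <- tibble::tibble(mirna = character(), gene = character(),
                         database = character())
  expect_message(ev <- build_evidence(preds, vals, panel), "off-panel")
  expect_equal(nrow(ev), 0)
})

test_that("build_evidence is idempotent under re-expansion of its output", {
  set.seed(101)
  panel <- gene_panel(sprintf("GENE%02d", 1:6))
  sim <- simulate_evidence(sim_config(seed = 31, n_mirnas = 8, panel_size = 6))
  ev <- build_evidence(sim$predictions, sim$validations, sim$panel)

  expanded_preds <- ev |>
    dplyr::filter(.data$n_tools > 0) |>
    tidyr::unnest(tools) |>
    dplyr::transmute(mirna, gene, tool = tools,
                     score = NA_real_, conserved = NA)
  expanded_vals <- ev |>
    dplyr::filter(.data$validated) |>
    dplyr::transmute(mirna, gene, database = "TarBase")
  again <- build_evidence(expanded_preds, expanded_vals, sim$panel)
  expect_equal(again, ev)
})

test_that("count_gene_evidence computes per-tool and union counts", {
  panel <- gene_panel(c("INSR", "IRS1"))
  preds <- dplyr::bind_rows(
    make_pred(c("hsa-miR-1-5p", "hsa-miR-2-5p"), "INSR", "miRDB", score = 0.9),
    make_pred(c("hsa-miR-2-5p", "hsa-miR-3-5p"), "INSR", "miRmap", score = 0.9)
  )
  vals <- tibble::tibble(mirna = c("hsa-miR-3-5p", "hsa-miR-4-5p"),
                         gene = "INSR", database = "TarBase")
  counts <- count_gene_evidence(preds, vals, panel)
  insr <- counts[counts$gene == "INSR", ]
  expect_equal(insr$miRDB, 2)
  expect_equal(insr$miRmap, 2)
  expect_equal(insr$predicted_total, 3)   # union {m1, m2, m3}
  expect_equal(insr$experimental_total, 2)
  expect_equal(insr$overall_total, 4)     # union {m1..m4}

  # gene with no records gets all-zero counts, in panel order
  irs1 <- counts[counts$gene == "IRS1", ]
  expect_true(all(unlist(irs1[, -1]) == 0))
  expect_equal(counts$gene, panel)
})

test_that("union bounds hold on simulated corpora across seeds", {
  for (s in 1:5) {
    sim <- simulate_evidence(sim_config(seed = s, n_mirnas = 25, panel_size = 12))
    filt <- suppressMessages(suppressWarnings(apply_filters(sim$predictions)))
    counts <- count_gene_evidence(filt, sim$validations, sim$panel)
    per_tool <- as.matrix(counts[, default_tools()])
    expect_true(all(counts$predicted_total <= rowSums(per_tool)))
    expect_true(all(apply(per_tool, 1, max) <= counts$predicted_total))
    expect_true(all(counts$overall_total <=
                      counts$predicted_total + counts$experimental_total))
    expect_true(all(counts$overall_total >=
                      pmax(counts$predicted_total, counts$experimental_total)))
  }
})

test_that("adding a prediction record never decreases counts or tool sets", {
  set.seed(77)
  panel <- gene_panel(c("INSR", "IRS1", "GSK3B"))
  base <- dplyr::bind_rows(
    make_pred("hsa-miR-1-5p", "INSR", "miRDB", score = 0.9),
    make_pred("hsa-miR-2-5p", "IRS1", "miRmap", score = 0.9)
  )
  vals <- tibble::tibble(mirna = "hsa-miR-1-5p", gene = "GSK3B",
                         database = "TarBase")
  before <- count_gene_evidence(base, vals, panel)
  ev_before <- build_evidence(base, vals, panel)

  extra <- make_pred("hsa-miR-3-5p", "INSR", "microT", score = 0.95)
  after <- count_gene_evidence(dplyr::bind_rows(base, extra), vals, panel)
  ev_after <- build_evidence(dplyr::bind_rows(base, extra), vals, panel)

  num_cols <- setdiff(names(before), "gene")
  expect_true(all(as.matrix(after[, num_cols]) >= as.matrix(before[, num_cols])))
  shared <- paste(ev_before$mirna, ev_before$gene)
  expect_true(all(shared %in% paste(ev_after$mirna, ev_after$gene)))
})

test_that("filter_policy validates its configuration", {
  expect_error(filter_policy(score_cutoff = 1.2), class = "mirlink_config_error")
  expect_error(filter_policy(score_cutoff_tools = "PicTar"),
               class = "mirlink_config_error")
})
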