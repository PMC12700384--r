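# Synthetic-data generator with planted ground truth. Emulates the *shape*
# of a multi-tool prediction corpus (per-tool detection and false-positive
# rates, tool-specific score distributions, incomplete validation coverage)
# and of a confidence-scored PPI graph with planted hubs — not any specific
# tool's algorithm. One global seed drives independent per-component
# generators through fixed offsets, so evidence, PPI and DE outputs are
# individually reproducible when other parts of the config change.

SEED_OFFSET_EVIDENCE <- 0L
SEED_OFFSET_PPI <- 1L
SEED_OFFSET_DE <- 2L

#' Simulation configuration
#'
#' Defines the generative model behind [simulate_evidence()],
#' [simulate_ppi()] and [simulate_de_tables()]. A small set of miRNAs is
#' "planted" with true regulatory interactions across most of the gene
#' panel; every tool detects a true pair with probability `detection_prob`
#' and emits a false prediction for a non-true pair with probability
#' `fp_prob`. True and false predictions draw confidence scores from two
#' Beta distributions: true pairs from a high mode with most mass above the
#' conventional 0.8 confidence cut-off, false pairs from a low mode, so
#' score filtering is exercised meaningfully. Validation records are
#' generated only for true pairs, at incomplete coverage — modelling the
#' fact that curated databases never contain every real interaction.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_mirnas Number of miRNAs in the simulated corpus.
#' @param panel_size Number of genes in the panel (`G`).
#' @param tools,databases Source labels (defaults mirror a five-tool,
#'   two-database consensus screen).
#' @param detection_prob Per-tool probability a true pair is predicted;
#'   scalar or one value per tool.
#' @param fp_prob Per-tool false-positive probability for non-true pairs.
#' @param validation_coverage Probability a true pair appears in at least
#'   one validation database.
#' @param n_planted Number of planted high-evidence miRNAs.
#' @param planted_fraction Fraction of panel genes a planted miRNA truly
#'   targets.
#' @param background_target_rate Probability a non-planted (miRNA, gene)
#'   pair is a true interaction.
#' @param true_score_shape,false_score_shape Beta shape pairs for
#'   true/false prediction scores.
#' @param conserved_prob_true,conserved_prob_false Probability a
#'   true/false prediction is flagged as conserved.
#' @param ppi_n_nodes,ppi_edge_prob,ppi_n_hubs,hub_degree_boost PPI graph:
#'   node count, background edge probability, number of planted hubs, and
#'   extra distinct neighbors granted to each hub.
#' @param n_background_mirnas Non-shortlisted miRNAs added to simulated DE
#'   tables.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 60L,
                       panel_size = 20L,
                       tools = default_tools(),
                       databases = default_databases(),
                       detection_prob = 0.9,
                       fp_prob = 0.01,
                       validation_coverage = 0.9,
                       n_planted = 3L,
                       planted_fraction = 1,
                       background_target_rate = 0.05,
                       true_score_shape = c(12, 2),
                       false_score_shape = c(2, 8),
                       conserved_prob_true = 0.95,
                       conserved_prob_false = 0.5,
                       ppi_n_nodes = 100L,
                       ppi_edge_prob = 0.05,
                       ppi_n_hubs = 5L,
                       hub_degree_boost = 15L,
                       n_background_mirnas = 100L) {
  if (length(tools) < 1 || panel_size < 1 || n_mirnas < 1) {
    ml_abort("degenerate config: need at least one tool, one gene and one miRNA",
             "mirlink_config_error")
  }
  if (n_planted > n_mirnas) {
    ml_abort("n_planted exceeds n_mirnas", "mirlink_config_error")
  }
  if (hub_degree_boost >= ppi_n_nodes) {
    ml_abort("hub_degree_boost must be smaller than ppi_n_nodes", "mirlink_config_error")
  }
  if (ppi_n_nodes < 2) ml_abort("ppi_n_nodes must be at least 2", "mirlink_config_error")
  detection_prob <- rep_len(detection_prob, length(tools))
  fp_prob <- rep_len(fp_prob, length(tools))
  probs <- c(detection_prob, fp_prob, validation_coverage, planted_fraction,
             background_target_rate, conserved_prob_true, conserved_prob_false,
             ppi_edge_prob)
  if (any(probs < 0) || any(probs > 1)) {
    ml_abort("all probabilities must lie in [0,1]", "mirlink_config_error")
  }
  structure(list(
    seed = as.integer(seed),
    n_mirnas = as.integer(n_mirnas),
    panel_size = as.integer(panel_size),
    tools = tools,
    databases = databases,
    detection_prob = setNames(detection_prob, tools),
    fp_prob = setNames(fp_prob, tools),
    validation_coverage = validation_coverage,
    n_planted = as.integer(n_planted),
    planted_fraction = planted_fraction,
    background_target_rate = background_target_rate,
    true_score_shape = true_score_shape,
    false_score_shape = false_score_shape,
    conserved_prob_true = conserved_prob_true,
    conserved_prob_false = conserved_prob_false,
    ppi_n_nodes = as.integer(ppi_n_nodes),
    ppi_edge_prob = ppi_edge_prob,
    ppi_n_hubs = as.integer(ppi_n_hubs),
    hub_degree_boost = as.integer(hub_degree_boost),
    n_background_mirnas = as.integer(n_background_mirnas)
  ), class = "sim_config")
}

#' Simulate a prediction/validation evidence corpus with known ground truth
#'
#' For each true (miRNA, gene) pair and each tool, a prediction is emitted
#' with the tool's detection probability and a score from the true-score
#' distribution; non-true pairs emit false predictions at the tool's
#' false-positive rate with scores from the false distribution. Validation
#' records cover true pairs at the configured coverage and are never
#' generated for non-true pairs, so ground truth stays unambiguous.
#' Deterministic under a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `predictions`, `validations`, `panel`
#'   (character vector), and `truth` (list with `true_pairs`, `planted`).
#' @export
simulate_evidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + SEED_OFFSET_EVIDENCE, {
    G <- config$panel_size
    panel <- sprintf("GENE%03d", seq_len(G))
    mirnas <- sprintf("hsa-miR-%04d-5p", seq_len(config$n_mirnas))
    planted <- head(mirnas, config$n_planted)

    pairs <- tidyr::expand_grid(mirna = mirnas, gene = panel)
    n_target <- ceiling(config$planted_fraction * G)
    planted_targets <- lapply(planted, function(m) sample(panel, n_target))
    names(planted_targets) <- planted
    is_planted_pair <- mapply(
      function(m, g) m %in% planted && g %in% planted_targets[[m]],
      pairs$mirna, pairs$gene
    )
    background_true <- !(pairs$mirna %in% planted) &
      (runif(nrow(pairs)) < config$background_target_rate)
    pairs$true <- is_planted_pair | background_true

    preds <- lapply(config$tools, function(tl) {
      p_emit <- ifelse(pairs$true, config$detection_prob[[tl]], config$fp_prob[[tl]])
      emit <- runif(nrow(pairs)) < p_emit
      if (!any(emit)) return(NULL)
      sub <- pairs[emit, , drop = FALSE]
      score <- numeric(nrow(sub))
      score[sub$true] <- rbeta(sum(sub$true), config$true_score_shape[1],
                               config$true_score_shape[2])
      score[!sub$true] <- rbeta(sum(!sub$true), config$false_score_shape[1],
                                config$false_score_shape[2])
      p_cons <- ifelse(sub$true, config$conserved_prob_true, config$conserved_prob_false)
      tibble(mirna = sub$mirna, gene = sub$gene, tool = tl,
             score = score, conserved = runif(nrow(sub)) < p_cons)
    })
    predictions <- dplyr::bind_rows(preds)
    if (nrow(predictions) == 0) {
      predictions <- tibble(mirna = character(), gene = character(),
                            tool = character(), score = numeric(),
                            conserved = logical())
    }

    true_pairs <- pairs[pairs$true, c("mirna", "gene")]
    covered <- runif(nrow(true_pairs)) < config$validation_coverage
    vals <- NULL
    if (any(covered)) {
      cov <- true_pairs[covered, , drop = FALSE]
      db_hits <- matrix(runif(nrow(cov) * length(config$databases)) < 0.6,
                        nrow = nrow(cov))
      none <- rowSums(db_hits) == 0
      if (any(none)) {  # coverage means at least one database has the record
        db_hits[cbind(which(none),
                      sample.int(length(config$databases), sum(none), replace = TRUE))] <- TRUE
      }
      vals <- dplyr::bind_rows(lapply(seq_along(config$databases), function(j) {
        hit <- db_hits[, j]
        tibble(mirna = cov$mirna[hit], gene = cov$gene[hit],
               database = config$databases[j])
      }))
    }
    validations <- vals %||% tibble(mirna = character(), gene = character(),
                                    database = character())

    list(
      predictions = predictions,
      validations = validations,
      panel = panel,
      truth = list(true_pairs = as_tibble(true_pairs), planted = planted)
    )
  })
}

#' Simulate a confidence-scored PPI graph with planted hubs
#'
#' Background edges appear independently with `ppi_edge_prob` and carry
#' scores uniform on `[0.4, 1]` (so a 0.7 high-confidence threshold prunes
#' about half of them, as it does for real STRING exports). Each planted hub
#' then gains `hub_degree_boost` extra distinct neighbors whose edges score
#' at least 0.7, so confidence thresholding preserves the planted structure.
#' Deterministic under a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with `edges` (tibble `protein_a`, `protein_b`,
#'   `combined_score`), `nodes` (character), and `truth` (list with `hubs`).
#' @export
simulate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + SEED_OFFSET_PPI, {
    n <- config$ppi_n_nodes
    nodes <- sprintf("PROT%03d", seq_len(n))
    hubs <- head(nodes, config$ppi_n_hubs)

    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    present <- runif(nrow(idx)) < config$ppi_edge_prob
    edges <- tibble(
      protein_a = nodes[idx[present, 1]],
      protein_b = nodes[idx[present, 2]],
      combined_score = runif(sum(present), 0.4, 1)
    )

    for (h in hubs) {
      nbr <- c(edges$protein_b[edges$protein_a == h],
               edges$protein_a[edges$protein_b == h])
      candidates <- setdiff(nodes, c(h, nbr))
      extra <- sample(candidates, min(config$hub_degree_boost, length(candidates)))
      if (length(extra) > 0) {
        edges <- dplyr::bind_rows(edges, tibble(
          protein_a = h, protein_b = extra,
          combined_score = runif(length(extra), 0.7, 1)
        ))
      }
    }
    list(edges = edges, nodes = nodes, truth = list(hubs = hubs))
  })
}

#' Simulate miRNA differential-expression result tables
#'
#' Emulates case-control miRNA DE lists from independent datasets: each
#' shortlisted miRNA is significant (`fdr < 0.05`) in each dataset with
#' probability `dysregulation_prob`; background miRNAs are significant at a
#' low base rate. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @param shortlist Character vector of miRNA ids to track.
#' @param n_datasets Number of independent datasets (at least 1).
#' @param dysregulation_prob Per-dataset probability a shortlisted miRNA is
#'   significantly dysregulated.
#' @param background_sig_rate Significance rate among background miRNAs.
#' @return A tibble of DE records (`mirna`, `log_fold_change`, `p_value`,
#'   `fdr`, `dataset`).
#' @export
simulate_de_tables <- function(config, shortlist, n_datasets = 2L,
                               dysregulation_prob = 0.7,
                               background_sig_rate = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  if (length(shortlist) < 1) {
    ml_abort("shortlist must be non-empty", "mirlink_config_error")
  }
  if (n_datasets < 1) {
    ml_abort("n_datasets must be at least 1", "mirlink_config_error")
  }
  shortlist <- normalize_ids(shortlist, "mirna")
  withr::with_seed(config$seed + SEED_OFFSET_DE, {
    background <- sprintf("hsa-miR-bg%03d-5p", seq_len(config$n_background_mirnas))
    mirnas <- c(shortlist, setdiff(background, shortlist))
    sig_prob <- c(rep(dysregulation_prob, length(shortlist)),
                  rep(background_sig_rate, length(mirnas) - length(shortlist)))
    dplyr::bind_rows(lapply(seq_len(n_datasets), function(d) {
      sig <- runif(length(mirnas)) < sig_prob
      fdr <- ifelse(sig, runif(length(mirnas), 1e-6, 0.049),
                    runif(length(mirnas), 0.05, 1))
      p <- fdr * runif(length(mirnas), 0.3, 1)
      lfc <- rnorm(length(mirnas), mean = 0, sd = 0.5) +
        ifelse(sig, sample(c(-1.5, 1.5), length(mirnas), replace = TRUE), 0)
      tibble(mirna = mirnas, log_fold_change = lfc, p_value = p, fdr = fdr,
             dataset = sprintf("DS%d", d))
    }))
  })
}
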