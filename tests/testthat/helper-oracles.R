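# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (term-wise loops, exhaustive enumeration) so they can
# cross-check the vectorized implementations.

# term-wise T-score: enumerate panel genes and apply the evidence formula
# per pair with plain double arithmetic
oracle_t_score <- function(pairs, panel, n_tools_total = 5, e_value = 1) {
  mirnas <- sort(unique(pairs$mirna))
  vapply(mirnas, function(m) {
    s <- 0
    for (g in panel) {
      sub <- pairs[pairs$mirna == m & pairs$gene == g, , drop = FALSE]
      if (nrow(sub) == 1) {
        n <- length(unique(sub$tools[[1]]))
        s <- s + n / n_tools_total + e_value * as.numeric(sub$validated)
      }
    }
    s / length(panel)
  }, numeric(1))
}

# degree by adjacency enumeration over a simple undirected edge table
oracle_degrees <- function(edges, nodes) {
  vapply(nodes, function(v) {
    sum((edges$protein_a == v & edges$protein_b != v) |
          (edges$protein_b == v & edges$protein_a != v))
  }, numeric(1))
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
oracle_hypergeom <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Benjamini-Hochberg step-up by definition: for each i (sorted order),
# min over j >= i of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(sorted[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random small evidence table for property tests
random_evidence <- function(n_mirnas, panel, tools = default_tools()) {
  pairs <- tidyr::expand_grid(
    mirna = sprintf("hsa-miR-t%02d-5p", seq_len(n_mirnas)),
    gene = panel
  )
  pairs <- pairs[runif(nrow(pairs)) < 0.6, , drop = FALSE]
  pairs$tools <- lapply(seq_len(nrow(pairs)), function(i) {
    sort(sample(tools, sample(0:length(tools), 1)))
  })
  pairs$n_tools <- lengths(pairs$tools)
  pairs$validated <- runif(nrow(pairs)) < 0.5
  pairs[pairs$n_tools > 0 | pairs$validated, , drop = FALSE]
}

extdata <- function(name) {
  system.file("extdata", name, package = "mirlink", mustWork = TRUE)
}
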