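---
title: "Consensus evidence scoring and network analysis with mirlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus evidence scoring and network analysis with mirlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The model

`mirlink` ranks candidate miRNA regulators of a pathway by integrating two
evidence channels per miRNA–gene pair. The prediction channel counts how many
independent target-prediction algorithms report the interaction; with
`n_tools_total` tools the **P-score** is `n / n_tools_total`, i.e. each tool
contributes one fifth of a point in the default five-tool configuration. The
experimental channel awards a single point (**E-score**, `e_score_value = 1`)
when the pair is validated in at least one curated interaction database —
agreement between several databases does not stack, because curation overlap
between databases is largely redundant evidence about the same wet-lab
experiments. The per-pair **C-score** is their sum, and a miRNA's **T-score**
averages its C-scores across the *entire* gene panel:

$$T = \frac{1}{G}\sum_{i=1}^{G}\left(\frac{n_i}{n_\text{tools}} + E_i\right)$$

Two modelling commitments deserve emphasis. First, genes with no evidence
contribute a C-score of 0 but remain in the denominator `G`: the T-score
measures breadth of regulation across the panel, not average strength over
the targeted subset. Second, either evidence channel suffices on its own — a
pair with a validation record but no surviving prediction is retained with
`n = 0, E = 1`, and a pair predicted by a single tool without validation is
retained at `C = 0.2`. Consequently the minimum C-score *among pairs with at
least one predicting tool* is 0.2, while untargeted genes still show explicit
zeros in the score matrix.

Shortlisting retains miRNAs with `T > t_threshold` (strictly; cards exactly
at the threshold are logged and excluded). The default threshold of 1.0 marks
the point where a miRNA is, on average, either validated against each panel
gene or unanimously predicted; the analytic floor for a miRNA with one
predicting tool plus validation on every gene is `T = 1.2`.

## Filtering

Before aggregation, tool outputs pass a `filter_policy()`: an inclusive score
cut-off (default 0.80) for the tools whose confidence scores are comparable
on the unit interval (defaults: miRDB, miRmap, DIANA-microT), and a
`conserved = TRUE` requirement for tools that flag target-site conservation
(default: TargetScan). The boundary is inclusive — "cut-off kept at 0.80"
idiom — and boundary records therefore survive; records from cut-off tools
that lack a score are dropped with a warning rather than an error, since real
exports mix scored and unscored rows. Tools outside both subsets pass
unfiltered: no published score cut-off exists for TargetScan context scores
or miRTar2GO outputs, so the defaults leave them uncut (configurable).

Identifier handling follows one canonical dialect: gene symbols upper-cased,
miRNA names given a lower-case `hsa-` prefix when absent with internal case
preserved. This makes mixed sources joinable, since the same mature miRNA
commonly appears both with and without the species prefix. The gene symbol
`PDK1` is taken verbatim from the shipped insulin-resistance panel (Entrez
5163, pyruvate dehydrogenase kinase 1); whether the insulin-signalling
kinase PDPK1 was intended by the panel's curators is not resolvable from the
panel itself, so the printed symbol is used unchanged.

## Numerical choices

C-scores under the default configuration are exact multiples of
`1/n_tools_total`. `t_score()` therefore accumulates totals as scaled
integers (multiplying by `n_tools_total` and rounding away representation
error below `1e-6`) and divides once at the end, so a published one-decimal
score table sums to its printed totals exactly rather than to within
floating drift; inputs that are not such multiples fall back to plain
summation. Ranking is made deterministic by breaking T-score ties on the
total and then the miRNA identifier; degree ties in hub extraction break on
the gene symbol. Both tie-breaks are conventions of this package — published
rankings rarely document theirs — and ties spanning the top-k boundary are
reported in a warning so the truncation is auditable.

## Downstream network analysis

`pathway_hits()` intersects each shortlisted miRNA's per-source target sets
with a pathway gene set and reports per-source counts plus the union, along
with the consolidated non-redundant gene list across miRNAs — the union
semantics mean a per-miRNA total is never larger than the sum of its
per-source counts, an invariant the tests exercise on simulated corpora and
on the shipped published count tables. `build_ppi()` thresholds a
combined-score edge list at ≥ 0.7 (inclusive, the conventional
high-confidence STRING level) on the unit scale; STRING's integer 0–999
exports are auto-detected and rescaled by `read_edge_list()`, with an
explicit override because both dialects occur in the wild. The graph is
undirected and simple: reversed duplicates collapse keeping the maximum
score, and hub extraction uses unweighted degree — matching the common
"degree" hub criterion — rather than any score-weighted variant. By default
only whitelisted nodes (the consolidated target list) enter the graph;
passing `whitelist = NULL` admits external interactors.

`enrich()` replaces web-based over-representation analysis with a native
one-sided upper-tail hypergeometric test (via the stable distribution
routine in base R), per-category Benjamini–Hochberg adjustment, the
conventional set-size window of 2–5000 within-background genes, and
per-category top-10 reporting ranked primarily by overlap count (ties by
FDR, then name). The background defaults to the union of all loaded
collection genes and is overridable: web tools' internal backgrounds are
generally unrecoverable, so results are only comparable across runs that fix
the background explicitly. BH is assumed for the FDR column throughout, and
only over-representation is tested — depletion is out of scope. The BH
adjustment per category mirrors how GO domains are conventionally tested as
separate families.

`overlap_summary()` performs the bookkeeping for checking a shortlist against
independent differential-expression tables: a shortlisted miRNA counts as
dysregulated in a dataset iff its FDR there is below `alpha` (0.05, applied
to the FDR column since the upstream fits are FDR-corrected), and miRNAs
absent from a dataset count as not significant there.

## What the synthetic generator emulates — and what it does not

`sim_config()` plants `n_planted` miRNAs that truly target a
`planted_fraction` of the panel; each tool detects a true pair with
probability `detection_prob` (default 0.9) and emits a false prediction for
a non-true pair with probability `fp_prob` (default 0.01). True predictions
draw scores from Beta(12, 2) — most mass above the 0.80 cut-off, so
filtering passes most but not all true records — and false predictions from
Beta(2, 8), so the cut-off removes almost all of them. Validation records
are generated *only* for true pairs, at `validation_coverage` (default 0.9):
incomplete database coverage is modelled, database false positives are not,
which keeps the planted ground truth unambiguous. Non-planted miRNAs pick up
true targets at a low background rate (0.05 per gene) so the ranking problem
is not trivially separable. The PPI generator plants hubs by granting extra
distinct neighbors whose edges score ≥ 0.7 on top of a sparse background
(edge probability 0.05, scores uniform on [0.4, 1] so thresholding prunes
about half), and the DE generator marks shortlisted miRNAs significant per
dataset with a configurable probability.

One global seed drives the evidence, PPI and DE components through fixed
offsets, so regenerating one component does not perturb the others. All
defaults were fixed once at design time to the regime the recovery
invariants describe.

What passing recovery tests therefore shows: the pipeline's filtering,
aggregation, scoring and ranking machinery recovers a strong multi-gene
signal embedded in realistic per-tool noise. What it does not show: anything
about the biological accuracy of real prediction tools, whose errors are
correlated across tools and across genes (shared seed-match logic, shared
3'UTR annotations) in ways the independent-Bernoulli model deliberately
ignores; nor about curation biases of validation databases, which
over-represent well-studied miRNAs. Problem sizes in the tests (40–60
miRNAs, 20-gene panels, 100-node PPI graphs, 100 replicates) were chosen as
the smallest at which the binomial tolerances of the recovery invariants are
meaningful.

## Known limitations

- The pipeline operates at gene-symbol level; transcript selection is
  treated as upstream (it happens inside the prediction tools).
- No sequence-level simulation: the generator mimics evidence *structure*,
  not any specific tool's algorithm or score distribution.
- No GO-DAG redundancy reduction in enrichment, and no depletion testing.
- Published hub identities and per-gene interaction counts depend on live
  database contents and are not reproduction targets; the package
  guarantees the *operations* (union counting, thresholding, degree
  ranking) and verifies published tables against their structural
  invariants instead.
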