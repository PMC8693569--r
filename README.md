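# deview

Interactive, portable dashboards for exploring RNA-seq results. `deview`
takes the three tables every differential-expression (DE) workflow already
produces — a gene × sample count matrix, a sample covariate table, and a
per-gene statistics table (logFC, average expression, p-values) — and turns
them into linked interactive views exported as fully self-contained HTML:

* **MDS view** — samples embedded by classical multidimensional scaling of
  *leading log-fold-change* distances, with dropdowns to plot any pair of
  dimensions and to colour, shape and size points by any covariate, next to
  a variance-explained bar panel;
* **Summary-expression views** — an MA plot (logFC *M* vs average log-CPM
  *A*), a volcano plot (−log10 *p* vs logFC), or a generic XY plot, linked
  to a per-sample expression panel for the selected gene and a searchable
  statistics table, with multi-gene selection, CSV export (selected subset
  or all genes) and PNG/SVG plot saving.

The rendered file inlines all data, styling and the rendering runtime, so a
collaborator can open it in any browser with no server, network, or
analysis environment. It is aimed at analysts who want to hand exploration
to biologists without handing over a compute environment.

## The statistics inside

The numeric substrate is implemented in the package (and cross-checked in
the tests against independent references):

* log-CPM with a prior count: `log2((c + p) / (L + 2p) * 1e6)`, prior
  `p = 0.5` by default;
* leading-logFC distance between samples: root-mean-square of the `top`
  (default 500) largest absolute log-CPM differences, chosen per pair
  (`pairwise`) or from one common top-variance gene set (`common`);
* classical (Torgerson) MDS: eigendecomposition of `-1/2 J D² J`, positive
  eigenvalues only, deterministic sign convention, variance explained
  `λ_k / Σ λ⁺`;
* Benjamini–Hochberg step-up adjustment and DE status calling
  (`status = sign(logFC)` where `q < α` and `|logFC| ≥ lfc_min`, with an
  explicit status vector always winning);
* a seeded negative-binomial count simulator with planted effects, for
  fixtures and end-to-end validation.

The linked-view behaviour is specified as a small state machine (modes
`IDLE` and `GRAPH_SELECT`, one toggle semantic for plot and table clicks,
search as an orthogonal filter) that is implemented identically in R and in
the embedded JavaScript runtime, and tested exhaustively in R.

## Worked example

```r
library(deview)

# a simulated 2-group bulk experiment: 1000 genes, 3 + 3 samples,
# 100 genes with a planted |log2 FC| of 2
sim  <- simulate_counts(n_genes = 1000, n_de = 100, lfc_magnitude = 2,
                        seed = 42)
expr <- sim$expr
expr
#> ExpressionData: 1000 genes x 6 samples
#>   sample covariates: sample_id, group
#>   gene annotations:  gene_id, symbol

mds <- run_mds(expr)
mds
#> MDSResult: 6 samples, 5 retained dimensions
#>   variance explained (%): 73.2, 9.7, 6.6 ...
round(head(mds$coordinates[, 1:2]), 3)
#>      dim1   dim2
#> A1 -0.510 -0.040
#> A2 -0.473  0.023
#> A3 -0.494  0.000
#> B1  0.467 -0.068
#> B2  0.473  0.344
#> B3  0.538 -0.260
render_standalone(build_mds_widget(mds, expr$samples), "mds.html")
```

Dimension 1 carries 73% of the variance and cleanly separates the two
groups (negative coordinates for group A, positive for B) — exactly what
the planted effects should produce. For the DE views:

```r
de     <- fixture_de_test(expr)            # simple t-test fixture
status <- decide_status(de, alpha = 0.05)  # BH at 5%, sign of logFC
table(status)
#> status
#>  -1   0   1
#>  37 911  52

doc <- build_summary_widget("volcano", de, expr, group_col = "group",
                            status = status)
doc
#> WidgetDoc <volcano>: tables [table: 1000, summary: 1000, expression: 6000], 6 controls
render_standalone(doc, "volcano.html")   # ~405 KB, self-contained
```

89 of the 100 planted genes are called (52 up, 37 down) and the widget
embeds the full statistics table, the per-gene expression values, and the
interaction contract. `extract_payload("volcano.html")` recovers the
document bit-exactly from the file.

## Command line

A thin wrapper over the same functions ships in `exec/`:

```sh
deview simulate --n-genes 1000 --n-de 100 --seed 42 --out-dir data
deview mds     --counts data/sim_counts.tsv --samples data/sim_samples.tsv --out mds.html
deview volcano --de de.tsv --counts data/sim_counts.tsv \
               --samples data/sim_samples.tsv --group-col group --out volcano.html
```

Subcommands: `mds`, `ma`, `volcano`, `xy` (requires `--x-col`/`--y-col`),
`simulate`. Exit codes: 0 success, 2 usage error, 1 validation failure.

## Not in scope

Ingestion of R-native fit objects (export their statistics to a table
first), server-side reactivity, UMAP/tSNE embeddings, configurable
panel-linking, and pixel-level guarantees for the saved PNG/SVG images
(delegated to the browser).
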