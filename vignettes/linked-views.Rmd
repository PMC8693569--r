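---
title: "Methods behind deview: linked interactive views for RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind deview: linked interactive views for RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deview)
```

## What the package computes

`deview` turns a gene-by-sample count matrix, a sample covariate table and a
table of per-gene differential-expression (DE) statistics into portable
interactive dashboards: a multidimensional scaling (MDS) view of sample
similarity, and linked summary-expression views (MA, volcano, generic XY)
where a gene-level scatter, a per-sample expression panel and a searchable
statistics table all share one selection. Everything a widget needs — data,
encodings, controls, the interaction contract, and the rendering runtime —
is inlined into a single HTML file, so results can be shared and explored
with no analysis environment behind them.

This vignette documents the statistical and numerical choices.

## Expression units: log-CPM

All expression displays use log2 counts-per-million with a prior count:

$$\mathrm{logCPM}_{gs} = \log_2\!\left(\frac{c_{gs} + p}{L_s + 2p}\times 10^6\right),$$

where $c_{gs}$ is the count, $L_s$ the library size (column total) and $p$
the prior count, default $p = 0.5$. The prior keeps zero counts finite; the
matching $2p$ offset in the denominator keeps the transform consistent as
library size varies. The prior is exposed as a parameter (`prior`) on every
function that computes log-CPM because reasonable workflows differ in it;
0.5 is the convention of the standard limma-style workflow this package
interoperates with. The transform is strictly increasing in the count at
fixed library size, so within-sample expression ranks are never distorted.

## Sample distances: leading logFC

The MDS view embeds samples from the *leading log-fold-change* distance.
For samples $i$ and $j$,

$$d_{ij} = \sqrt{\tfrac{1}{t}\sum_{g \in T_{ij}} (x_{gi} - x_{gj})^2},$$

where $x$ is log-CPM and $T_{ij}$ is the set of the $t$ genes with the
largest absolute differences ($t$ = `top`, default 500, capped at the gene
count). Two gene-selection modes are exposed:

* `pairwise` (default): $T_{ij}$ is chosen separately for every pair —
  most sensitive to structure carried by different gene sets in different
  contrasts;
* `common`: one gene set, the `top` genes with the largest log-CPM variance
  across all samples, shared by every pair — cheaper and sometimes easier
  to interpret.

Only between-sample differences enter, so adding any per-gene constant to
the expression matrix leaves all distances unchanged. The test suite checks
both modes against a brute-force sort-and-RMS oracle and against the
reference implementation of this plot in the wider ecosystem, which agrees
to machine precision.

## Classical MDS and variance explained

Distances are embedded by Torgerson's classical scaling: with squared
distances $D^2$ and centering operator $J = I - \tfrac{1}{n}\mathbf{1}
\mathbf{1}^\top$, the Gram matrix $B = -\tfrac12 J D^2 J$ is
eigendecomposed, and coordinates are eigenvectors scaled by the square
roots of the positive eigenvalues. Choices worth stating:

* **Requested dimensions.** `run_mds()` asks for $n-1$ dimensions (the most
  a distance matrix on $n$ points supports) and the widget exposes *all*
  retained dimensions in its axis dropdowns, rather than a fixed number.
* **Positive eigenvalues only.** Leading-logFC distances are not guaranteed
  Euclidean; eigenvalues that are negative (beyond a relative tolerance of
  $10^{-12}$ of the spectral radius) are dropped from both the coordinates
  and the variance-explained proportions, with a note reporting their total
  magnitude. Variance explained for dimension $k$ is
  $\lambda_k / \sum_{\lambda_i > 0} \lambda_i$, non-increasing and summing
  to one.
* **Sign determinism.** Eigenvector signs are arbitrary; each coordinate
  column is flipped so its largest-magnitude entry is positive. This makes
  rendered documents byte-reproducible, which the export tests rely on.
* **Degenerate input.** A configuration with no positive eigenvalue (all
  points coincident) is an error, not a silent empty result. Asymmetry
  beyond $10^{-8}$ and nonzero diagonals are rejected.

## Significance calling

The summary plots colour genes by a status in $\{-1, 0, 1\}$. The automatic
call uses Benjamini–Hochberg adjustment on the raw p-values — implemented
in the package as the explicit step-up (sort ascending, $q_{(i)} =
p_{(i)} m / i$, enforce monotonicity from the largest rank, cap at one) and
cross-checked against `stats::p.adjust` — unless the DE table already
carries an `adj_p` column, which then takes precedence. A gene is called up
or down when $q < \alpha$ (default $\alpha = 0.05$) and $|\mathrm{logFC}|
\ge$ `lfc_min` (default 0: no fold-change floor, since imposing one changes
the error-rate guarantee and should be the user's explicit decision). An
explicitly supplied status vector always overrides the automatic call, so
upstream pipelines that already decided significance keep the last word.

Volcano y-values are $-\log_{10} p$. Exact zeros are clamped to half the
smallest nonzero p-value in the vector before transforming (fallback
$10^{-300}$ if all are zero): this keeps axes finite without inventing a
fixed ceiling that would misrepresent how extreme the zeros are relative to
the rest of the data.

## The widget document and the interaction contract

A widget is a declarative JSON document: embedded column-oriented tables,
field-to-channel encodings, control descriptors, and a reference to the
interaction contract. The document is the single source of truth — the
HTML renderer consumes it unchanged, and `extract_payload()` recovers it
bit-exactly from a rendered file (the data island escapes `</` sequences
with the legal JSON escape `<\/`, so no embedded string can terminate the
script tag).

The linked-view behaviour is modeled as a two-mode state machine so the
response to any input sequence is well-defined and can be enumerated in
tests: `IDLE` (no selection; the table shows all genes, subject to the
search text) and `GRAPH_SELECT` (at least one gene selected; the table is
filtered to the selection). Plot clicks and table-row clicks share a single
toggle semantic; the expression panel follows the most recently selected
gene, falling back to the most recent remaining one on deselection; search
is an orthogonal filter that never changes the selection; hover tooltips
stay active in both modes. The R model (`apply_event()`) and the JavaScript
runtime implement the same transition function, and the suite verifies the
R model exhaustively against a toggle-parity oracle over all event
sequences up to length four.

Other interface decisions that were genuinely open:

* Shape encodings accept only discrete covariates and at most 8 categories
  — the number of glyphs the runtime guarantees; more categories are an
  error rather than silent glyph recycling. Continuous covariates offered
  for shape raise an error suggesting discretization.
* Colour schemes: named discrete palettes for discrete covariates and
  continuous ramps for numeric ones, with the defaults (`category10`,
  `viridis`) recorded in the document's metadata for reproducibility.
* When `max_y_axis` fixes the expression panel's upper bound, the lower
  bound is 0 or the data minimum, whichever is lower; only the maximum is
  pinned.
* Genes with missing annotation fields are shown as empty table cells, not
  dropped.
* Expression x-axis tick labels are rotated 45° anticlockwise so many-group
  designs stay readable.

## Rendering

`render_standalone()` inlines the package's own vanilla-JavaScript runtime
(scatter and bar panels as SVG, the linked table, selection strip, search,
PNG/SVG save buttons via client-side serialization, and CSV export scoped
to the selection or all genes) together with its stylesheet and the JSON
data island. Files contain no external references and no timestamps, so
rendering the same document twice is byte-identical, and file size grows
linearly with the embedded data. `render_fragment()` emits the same content
with a unique container id per fragment so several widgets can share one
notebook page; the runtime guards itself against double definition.
Rasterization fidelity of the saved PNG/SVG is the browser's concern, not
verified here.

## The count simulator

`simulate_counts()` generates the fixtures used throughout the tests and
examples, emulating a small bulk RNA-seq comparison:

* baseline relative expression drawn log-uniformly over 0.5–500 (three
  orders of magnitude, right-skewed as real transcriptomes are);
* `n_de` genes receive a planted log2 effect of ±`lfc_magnitude` in the
  second group, signs split at random;
* library sizes drawn uniformly from `libsize_range` (default
  0.5–2 × 10⁶, which at the default 1000 genes reproduces the per-gene
  depth of a genome-wide library of a few tens of millions of reads);
* counts are negative-binomial with dispersion = BCV², default 0.01
  (BCV 0.1, the canonical value for replicates of genetically identical
  model organisms, matching the inbred-mouse style of design the plots are
  typically used on).

Expected means are scaled against the *baseline* composition rather than
renormalized per sample, so genes without a planted effect have exactly
zero true fold change in concentration units; the realized library size
then deviates from the drawn one only by the small net effect of the DE
genes. All draws flow through a single generator stream seeded once, and
the caller's RNG state is restored afterwards, so every fixture is
bit-reproducible from its seed.

`fixture_de_test()` produces structurally realistic DE tables from such
simulations: per-gene pooled-variance two-sample t-tests on log-CPM, with
effective library sizes computed by median-of-ratios so that the planted
minority of changed genes does not shift the apparent expression of every
null gene through the column totals (the classic compositional bias that
TMM-style normalization addresses; `2^x` is convex, so random ± signs do
not cancel in the totals). Zero-variance genes get p = 1 when the group
means agree and p = 0 otherwise, keeping the output total. This tester
guards plumbing; it is deliberately simple and is not a recommended DE
method.

What the simulator does **not** emulate: between-sample normalization
artifacts beyond composition (no TMM factors are simulated), gene–gene
correlation, outlier samples, batch structure, or single-cell zero
inflation. Passing tests therefore demonstrate that the pipeline computes
its quantities correctly under clean negative-binomial conditions, not that
any particular DE method is powerful on real data.

## Problem sizes used in the checks

The routine checks run at desk scale, chosen to exercise every code path
while keeping the whole suite fast: oracle comparisons on 50-gene ×
6-sample matrices (100 replicates; `top` ∈ {1, 5, 50, 10⁶}), BH against
`stats::p.adjust` on 1000 random vectors of length up to 50, exhaustive
state-machine enumeration over 3 genes and sequences up to length 4, and
twenty simulated 1000-gene, 2 × 3-sample datasets with 100 planted effects
of |logFC| = 2 for the end-to-end recovery checks (dimension-1 group
separation; recall and empirical FDR of the fixture tester at α = 0.05).

## Known limitations

* Widget payloads embed the full expression matrix; for cell-level inputs
  use `subsample_columns()` to keep files tractable (sub-sampling size is
  left to the caller).
* The MDS widget embeds coordinates for all retained dimensions, but the
  distance itself is fixed at construction; changing `top` or the
  gene-selection mode requires re-rendering.
* The table view renders the first 500 visible rows for responsiveness;
  search and selection always operate on the full table.
* R-native upstream objects (fit objects, container classes of other
  packages) are not ingested directly; export their statistics to the
  tabular form first.
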