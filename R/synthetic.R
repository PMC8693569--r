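# All draws in this module flow through one generator stream seeded once, so
# every fixture is bit-reproducible from its seed. The caller's RNG state is
# saved and restored.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single numeric seed is required", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Simulate negative-binomial RNA-seq counts with planted group effects
#'
#' Generates a gene-by-sample count matrix emulating a bulk RNA-seq
#' experiment: baseline relative expression is drawn log-uniformly across
#' genes, a chosen number of genes receive a planted log2 fold change of
#' `± lfc_magnitude` in the second group (signs split at random), per-sample
#' library sizes are drawn uniformly from `libsize_range`, and counts are
#' drawn from a negative-binomial distribution with the stated dispersion
#' around means scaled to each library. The result is fully reproducible
#' from the seed.
#'
#' @param n_genes Number of genes.
#' @param groups Character vector of group labels (at least 2; effects are
#'   planted in the second group).
#' @param samples_per_group Replicates per group.
#' @param n_de Number of differentially expressed genes (`<= n_genes`).
#' @param lfc_magnitude Absolute planted log2 fold change.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`), the square of the biological coefficient of
#'   variation; the default 0.01 (BCV 0.1) is the canonical value for bulk
#'   replicates of genetically identical model organisms.
#' @param libsize_range Length-2 range for uniform library-size draws.
#' @param seed Integer seed; required.
#' @return List with `expr` (an [expression_data()] with `group` in its
#'   sample table) and `truth` (a `SimTruth`: `de_flags`, `true_lfc`,
#'   `params`).
#' @export
simulate_counts <- function(n_genes = 1000, groups = c("A", "B"),
                            samples_per_group = 3, n_de = 100,
                            lfc_magnitude = 2, dispersion = 0.01,
                            libsize_range = c(5e5, 2e6), seed) {
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (length(groups) < 2 || anyDuplicated(groups)) {
    stop("at least 2 distinct group labels are required", call. = FALSE)
  }
  if (samples_per_group < 1) stop("samples_per_group must be >= 1", call. = FALSE)
  if (n_de < 0 || n_de > n_genes) {
    stop("n_de must lie in 0..n_genes", call. = FALSE)
  }
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2]) {
    stop("libsize_range must be an increasing pair of positive numbers",
         call. = FALSE)
  }
  with_seed(seed, {
    n_groups <- length(groups)
    n_s <- n_groups * samples_per_group
    group <- rep(as.character(groups), each = samples_per_group)
    gene_ids <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
    sample_ids <- paste0(rep(groups, each = samples_per_group),
                         rep(seq_len(samples_per_group), times = n_groups))

    # baseline relative expression, log-uniform over ~3 orders of magnitude
    base <- exp(stats::runif(n_genes, log(0.5), log(500)))
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    true_lfc <- numeric(n_genes)
    if (n_de > 0) {
      true_lfc[de_idx] <- lfc_magnitude *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    lib <- stats::runif(n_s, libsize_range[1], libsize_range[2])

    # per-group expected relative expression; effect planted in groups[2].
    # Means are scaled against the baseline composition (not per-sample
    # totals), so null genes have exactly zero fold change in concentration
    # units; realized library sizes then deviate from the draw only by the
    # small net effect of the DE genes.
    rel <- matrix(base, n_genes, n_s)
    in_alt <- group == groups[2]
    rel[, in_alt] <- rel[, in_alt] * 2^true_lfc
    mu <- (rel / sum(base)) %*% diag(lib)
    counts <- matrix(
      stats::rnbinom(n_genes * n_s, size = 1 / dispersion, mu = as.vector(mu)),
      n_genes, n_s, dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "double"

    expr <- expression_data(
      counts,
      sample_table = data.frame(sample_id = sample_ids, group = group,
                                stringsAsFactors = FALSE),
      gene_table = data.frame(gene_id = gene_ids,
                              symbol = toupper(gene_ids),
                              stringsAsFactors = FALSE))
    truth <- structure(
      list(de_flags = as.integer(true_lfc != 0),
           true_lfc = true_lfc,
           params = list(n_genes = n_genes, groups = groups,
                         samples_per_group = samples_per_group, n_de = n_de,
                         lfc_magnitude = lfc_magnitude,
                         dispersion = dispersion,
                         libsize_range = libsize_range, seed = seed)),
      class = "SimTruth")
    list(expr = expr, truth = truth)
  })
}

#' Per-gene two-group fixture test
#'
#' A deliberately simple per-gene comparison used to produce structurally
#' realistic `DEResult` fixtures from simulated counts: logFC is the
#' difference of group means of log-CPM (second contrast level minus first),
#' the p-value comes from a pooled-variance two-sample t-test on log-CPM, and
#' `ave_expr` is the overall mean log-CPM. The log-CPM uses effective library
#' sizes computed by median-of-ratios, so that a minority of truly changed
#' genes does not shift the apparent expression of every null gene through
#' the column totals (raw totals fall back in when no gene is observed in
#' every sample). Genes with zero pooled variance get p = 1 when the group
#' means agree (no evidence) and p = 0 otherwise, keeping the result total.
#' This is fixture plumbing, not a recommended differential-expression
#' method.
#'
#' @param expr An [expression_data()] object.
#' @param group_col Grouping column in `expr$samples`.
#' @param contrast Pair of group labels `c(reference, alternative)`; each
#'   needs at least 2 samples. Defaults to the first two groups present.
#' @param prior Prior count for [log_cpm()].
#' @return A [de_result()] table over all genes.
#' @export
fixture_de_test <- function(expr, group_col = "group", contrast = NULL,
                            prior = 0.5) {
  stopifnot(inherits(expr, "ExpressionData"))
  if (!group_col %in% names(expr$samples)) {
    stop("grouping column '", group_col, "' not found; available: ",
         paste(names(expr$samples), collapse = ", "), call. = FALSE)
  }
  group <- as.character(expr$samples[[group_col]])
  if (is.null(contrast)) contrast <- unique(group)[1:2]
  if (length(contrast) != 2 || !all(contrast %in% group)) {
    stop("contrast must name two groups present in the data", call. = FALSE)
  }
  a <- group == contrast[1]
  b <- group == contrast[2]
  if (sum(a) < 2 || sum(b) < 2) {
    stop("each contrast group needs at least 2 samples (",
         contrast[1], ": ", sum(a), ", ", contrast[2], ": ", sum(b), ")",
         call. = FALSE)
  }
  lcpm <- log_cpm(expr, prior = prior,
                  lib_sizes = effective_lib_sizes(expr$counts))
  xa <- lcpm[, a, drop = FALSE]
  xb <- lcpm[, b, drop = FALSE]
  na <- sum(a); nb <- sum(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  logfc <- mb - ma
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, logfc / se, 0)
  p <- 2 * stats::pt(abs(tstat), df = na + nb - 2, lower.tail = FALSE)
  degenerate <- se == 0
  p[degenerate & logfc == 0] <- 1
  p[degenerate & logfc != 0] <- 0
  de_result(rownames(lcpm), logfc, p, ave_expr = rowMeans(lcpm))
}

# Median-of-ratios effective library sizes: per-sample median of the ratio
# to the per-gene geometric mean, over genes observed in every sample,
# rescaled to the overall depth so values stay on the column-total scale.
effective_lib_sizes <- function(counts) {
  raw <- colSums(counts)
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (sum(use) < 10) return(raw)
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - lg[use]))
  })
  sf * exp(mean(log(raw) - log(sf)))
}

#' Randomly sub-sample columns of an ExpressionData object
#'
#' Uniform without-replacement selection of `n` samples, preserving the
#' original column order and subsetting the sample table consistently; used
#' to keep single-cell-scale inputs tractable in interactive payloads while
#' remaining informative about the distribution of the full set.
#'
#' @param expr An [expression_data()] object.
#' @param n Number of columns to keep (`<= n_samples(expr)`).
#' @param seed Integer seed; the same seed always yields the same subset.
#' @return The subset `ExpressionData`.
#' @export
subsample_columns <- function(expr, n, seed) {
  stopifnot(inherits(expr, "ExpressionData"))
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  n_s <- n_samples(expr)
  if (n < 1 || n > n_s) {
    stop("n must lie in 1..", n_s, " (requested ", n, ")", call. = FALSE)
  }
  keep <- with_seed(seed, sort(sample.int(n_s, n)))
  expression_data(expr$counts[, keep, drop = FALSE],
                  sample_table = expr$samples[keep, , drop = FALSE],
                  gene_table = expr$genes)
}

#' Write a simulated dataset to disk
#'
#' Emits the counts (TSV), the sample and gene tables (TSV) and the
#' simulation truth table next to each other, as produced by the CLI
#' `simulate` subcommand.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             samples = file.path(dir, paste0(prefix, "_samples.tsv")),
             genes = file.path(dir, paste0(prefix, "_genes.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_counts(sim$expr, paths[["counts"]], format = "tsv")
  utils::write.table(sim$expr$samples, paths[["samples"]], sep = "\t",
                     quote = TRUE, row.names = FALSE)
  utils::write.table(sim$expr$genes, paths[["genes"]], sep = "\t",
                     quote = TRUE, row.names = FALSE)
  truth_df <- data.frame(gene_id = sim$expr$genes$gene_id,
                         de_flag = sim$truth$de_flags,
                         true_lfc = as.character(sim$truth$true_lfc),
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths[["truth"]], sep = "\t", quote = TRUE,
                     row.names = FALSE)
  invisible(paths)
}
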