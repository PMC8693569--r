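# Shared fixtures and independent oracles used across the test files.

toy_counts <- function(n_genes = 6, n_samples = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 50), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

toy_expr <- function(n_genes = 6, n_samples = 4, seed = 42,
                     groups = rep(c("A", "B"), length.out = n_samples)) {
  m <- toy_counts(n_genes, n_samples, seed)
  expression_data(m,
                  sample_table = data.frame(sample_id = colnames(m),
                                            group = groups,
                                            stringsAsFactors = FALSE))
}

toy_de <- function(expr, seed = 1) {
  set.seed(seed)
  n <- n_genes(expr)
  de_result(rownames(expr$counts),
            logfc = rnorm(n), p_value = runif(n),
            ave_expr = rowMeans(log_cpm(expr)))
}

# Orthogonal Procrustes residual after optimal rotation/reflection of Y onto
# X (both centered); no scaling, since exact distance matrices are compared.
procrustes_rms <- function(X, Y) {
  Xc <- scale(as.matrix(X), scale = FALSE)
  Yc <- scale(as.matrix(Y), scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# Brute-force leading-logFC distance: rank the squared differences explicitly
# per pair (or pick the common top-variance set), no shared code with the
# implementation's vectorized path.
brute_leading_distance <- function(logcpm, top, gene_selection) {
  n <- ncol(logcpm)
  t_n <- min(top, nrow(logcpm))
  if (gene_selection == "common") {
    v <- apply(logcpm, 1, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(t_n)]
  }
  D <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- abs(logcpm[, i] - logcpm[, j])
      sel <- if (gene_selection == "common") keep else {
        order(d, decreasing = TRUE)[seq_len(t_n)]
      }
      D[i, j] <- sqrt(sum(d[sel]^2) / t_n)
    }
  }
  D
}

random_widget_doc <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  expr <- toy_expr(n_genes = n, n_samples = 4, seed = seed)
  de <- toy_de(expr, seed = seed)
  kind <- sample(c("ma", "volcano"), 1)
  build_summary_widget(kind, de, expr, group_col = "group",
                       max_y_axis = if (runif(1) < 0.5) round(runif(1, 5, 15), 2))
}
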