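#' Leading log-fold-change distance between samples
#'
#' For each pair of samples, the root-mean-square of the `top` largest
#' absolute log-CPM differences across genes. With
#' `gene_selection = "pairwise"` the top genes are chosen separately for every
#' pair (the default, most sensitive to subgroup structure); with `"common"` a
#' single gene set — the `top` genes with largest log-CPM variance across all
#' samples — is used for every pair. Adding a per-gene constant to the input
#' leaves the distances unchanged, since only between-sample differences
#' enter.
#'
#' @param logcpm Gene-by-sample matrix of log-CPM values.
#' @param top Number of genes entering each distance (default 500, capped at
#'   the number of genes).
#' @param gene_selection `"pairwise"` or `"common"`.
#' @return Symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
leading_logfc_distance <- function(logcpm, top = 500,
                                   gene_selection = c("pairwise", "common")) {
  gene_selection <- match.arg(gene_selection)
  logcpm <- as.matrix(logcpm)
  n <- ncol(logcpm)
  if (n < 2) stop("at least 2 samples are required", call. = FALSE)
  if (!is.numeric(top) || length(top) != 1 || top < 1) {
    stop("top must be a positive integer", call. = FALSE)
  }
  t_n <- min(as.integer(top), nrow(logcpm))
  D <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  if (gene_selection == "common") {
    mu <- rowMeans(logcpm)
    rv <- rowSums((logcpm - mu)^2) / (n - 1)
    keep <- order(rv, decreasing = TRUE)[seq_len(t_n)]
    sub <- logcpm[keep, , drop = FALSE]
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- sqrt(mean((sub[, i] - sub[, j])^2))
      }
    }
  } else {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d2 <- sort((logcpm[, i] - logcpm[, j])^2, decreasing = TRUE)
        D[i, j] <- D[j, i] <- sqrt(mean(d2[seq_len(t_n)]))
      }
    }
  }
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances, `B = -1/2 J D^2 J` with `J` the
#' centering operator, eigendecomposes `B`, and returns coordinates scaled by
#' the square roots of the positive eigenvalues, truncated to
#' `min(k, number of positive eigenvalues)`. Each coordinate column's sign is
#' fixed so that its largest-magnitude entry is positive — MDS is otherwise
#' sign-ambiguous, and the deterministic choice keeps exported widget
#' documents byte-reproducible. Negative eigenvalues (non-Euclidean
#' distances) are dropped from the coordinates, with a note reporting their
#' total magnitude.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal
#'   (asymmetry beyond 1e-8 is an error).
#' @param k Number of requested dimensions.
#' @return List with `coordinates` (samples by retained dimensions, columns
#'   `dim1`, `dim2`, ...) and `eigenvalues` (all, sorted descending).
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is asymmetric beyond tolerance 1e-8", call. = FALSE)
  }
  if (any(D < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(diag(D))) > 1e-8) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  D <- (D + t(D)) / 2
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values
  tol <- max(abs(lambda), 0) * 1e-12
  pos <- which(lambda > tol)
  if (length(pos) == 0) {
    stop("no positive eigenvalue: degenerate (coincident) configuration",
         call. = FALSE)
  }
  neg_mass <- sum(abs(lambda[lambda < -tol]))
  if (neg_mass > 0) {
    message("dropping negative eigenvalues (non-Euclidean distances), total magnitude ",
            format(neg_mass, digits = 4))
  }
  k_eff <- min(as.integer(k), length(pos))
  idx <- pos[seq_len(k_eff)]
  coords <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(lambda[idx]), nrow = k_eff)
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(rownames(D), paste0("dim", seq_len(k_eff)))
  list(coordinates = coords, eigenvalues = lambda)
}

#' Proportion of variance explained per MDS dimension
#'
#' Each positive eigenvalue divided by the sum of all positive eigenvalues,
#' in descending order; negative eigenvalues are excluded from both numerator
#' and denominator. The proportions are non-increasing and sum to 1.
#'
#' @param eigenvalues Numeric vector of eigenvalues (any order).
#' @return Proportions, one per positive eigenvalue, descending.
#' @export
variance_explained <- function(eigenvalues) {
  tol <- max(abs(eigenvalues), 0) * 1e-12
  pos <- eigenvalues[eigenvalues > tol]
  if (length(pos) == 0) {
    stop("no positive eigenvalue: degenerate configuration", call. = FALSE)
  }
  pos <- sort(pos, decreasing = TRUE)
  pos / sum(pos)
}

#' Run the full MDS pipeline on expression data
#'
#' Composition of [log_cpm()], [leading_logfc_distance()] and
#' [classical_mds()] with `k = n_samples - 1` requested dimensions (the
#' maximum a distance matrix on n points supports). Dimensions are labeled
#' from 1; the retained count may be smaller when some eigenvalues are not
#' positive.
#'
#' @param expr An [expression_data()] object with at least 2 samples; with
#'   exactly 2 the single trivial dimension is returned with a warning.
#' @param top,gene_selection Passed to [leading_logfc_distance()].
#' @param prior Prior count for [log_cpm()].
#' @return An object of class `MDSResult`: list with `coordinates`
#'   (sample-by-dimension), `eigenvalues`, `var_explained` (over all positive
#'   eigenvalues) and `params` (top, gene_selection, prior, library sizes).
#' @export
run_mds <- function(expr, top = 500, gene_selection = c("pairwise", "common"),
                    prior = 0.5) {
  stopifnot(inherits(expr, "ExpressionData"))
  gene_selection <- match.arg(gene_selection)
  n <- n_samples(expr)
  if (n < 2) stop("MDS requires at least 2 samples", call. = FALSE)
  if (n == 2) {
    warning("2-sample MDS has a single trivial dimension", call. = FALSE)
  }
  lcpm <- log_cpm(expr, prior = prior)
  D <- leading_logfc_distance(lcpm, top = top, gene_selection = gene_selection)
  fit <- classical_mds(D, k = n - 1)
  structure(
    list(coordinates = fit$coordinates,
         eigenvalues = fit$eigenvalues,
         var_explained = variance_explained(fit$eigenvalues),
         params = list(top = top, gene_selection = gene_selection,
                       prior = prior, library_sizes = library_sizes(expr))),
    class = "MDSResult")
}

#' @export
print.MDSResult <- function(x, ...) {
  cat("MDSResult:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "retained dimensions\n")
  ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$var_explained) > 3) "..." else "", "\n")
  invisible(x)
}
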