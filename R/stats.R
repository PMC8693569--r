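#' Per-sample library sizes
#'
#' Column sums of the count matrix, in sample order. All-zero libraries are
#' permitted; downstream log-CPM stays finite through its prior-count offset.
#'
#' @param expr An [expression_data()] object or a bare counts matrix.
#' @return Named numeric vector of totals, one per sample.
#' @export
library_sizes <- function(expr) {
  counts <- if (inherits(expr, "ExpressionData")) expr$counts else as.matrix(expr)
  colSums(counts)
}

#' log2 counts-per-million with a prior count
#'
#' Computes `log2((count + prior) / (libsize + 2 * prior) * 1e6)` per cell,
#' the standard moderated log-CPM transform: the prior count keeps zeros
#' finite, and the matching `2 * prior` offset in the denominator keeps the
#' transform consistent as library size varies. A count of 0 in a library of
#' size `1e6 - 1` with the default prior gives exactly -1.
#'
#' @param expr An [expression_data()] object or gene-by-sample counts matrix.
#' @param prior Positive prior count added to each observation (default 0.5).
#' @param lib_sizes Optional library sizes to use instead of column sums
#'   (e.g. when transforming a gene subset against full-library depth).
#' @return Matrix of log2-CPM values, same dimensions and dimnames as the
#'   counts.
#' @export
log_cpm <- function(expr, prior = 0.5, lib_sizes = NULL) {
  counts <- if (inherits(expr, "ExpressionData")) expr$counts else as.matrix(expr)
  if (!is.numeric(prior) || length(prior) != 1 || !is.finite(prior) || prior <= 0) {
    stop("prior must be a single positive number", call. = FALSE)
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes must have one entry per sample", call. = FALSE)
  }
  denom <- lib_sizes + 2 * prior
  log2(sweep(counts + prior, 2, denom, "/") * 1e6)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The step-up procedure: sort p-values ascending, compute
#' `q_(i) = p_(i) * m / i`, enforce monotonicity from the largest rank down,
#' cap at 1, and return in the input order. Output is elementwise no smaller
#' than the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- check_pvalues(p, "p")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))   # step-up: q_(i) <- min over j >= i
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Call per-gene DE status
#'
#' Auto-highlighting rule behind the summary plots: a gene is called up (+1)
#' or down (-1) when its adjusted p-value falls below `alpha` and its absolute
#' log fold change reaches `lfc_min`, and 0 otherwise. Adjusted p-values are
#' taken from the table's `adj_p` column when present, otherwise computed with
#' [bh_adjust()] on the raw p-values. An explicitly supplied `status` vector
#' overrides the automatic call entirely.
#'
#' @param de A [de_result()] table (must contain `logfc` and `p_value`).
#' @param alpha Significance cutoff in (0, 1\]; default 0.05.
#' @param lfc_min Minimum absolute log2 fold change required for a nonzero
#'   call; default 0 (no floor).
#' @param status Optional explicit status vector in {-1, 0, 1}; returned
#'   unchanged when given.
#' @return Numeric vector in {-1, 0, 1}, one element per gene.
#' @export
decide_status <- function(de, alpha = 0.05, lfc_min = 0, status = NULL) {
  if (!is.null(status)) {
    status <- as.numeric(status)
    if (length(status) != nrow(de)) {
      stop("explicit status has length ", length(status), ", expected ",
           nrow(de), call. = FALSE)
    }
    if (!all(status %in% c(-1, 0, 1))) {
      stop("status values must be -1, 0 or 1", call. = FALSE)
    }
    return(status)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(lfc_min) || length(lfc_min) != 1 || lfc_min < 0) {
    stop("lfc_min must be >= 0", call. = FALSE)
  }
  if (is.null(de$logfc)) stop("DE table has no logfc column", call. = FALSE)
  if (is.null(de$p_value)) stop("DE table has no p_value column", call. = FALSE)
  q <- if (!is.null(de$adj_p)) de$adj_p else bh_adjust(de$p_value)
  ifelse(q < alpha & abs(de$logfc) >= lfc_min, sign(de$logfc), 0)
}

#' Negative log10 p-values for volcano plots
#'
#' Maps p-values to `-log10(p)`. Exact zeros would be infinite, so they are
#' clamped to half the smallest nonzero p-value in the vector before
#' transforming; a vector of all zeros falls back to `1e-300`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of the same length; higher means more significant.
#' @export
neglog10_p <- function(p) {
  p <- check_pvalues(p, "p")
  if (length(p) == 0) return(numeric(0))
  zero <- p == 0
  if (any(zero)) {
    nz <- p[!zero]
    eps <- if (length(nz)) min(nz) / 2 else 1e-300
    p[zero] <- eps
  }
  -log10(p)
}
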