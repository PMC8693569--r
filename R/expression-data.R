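#' Construct an ExpressionData object
#'
#' `ExpressionData` is the package's universal input container: a gene-by-sample
#' matrix of non-negative counts together with an aligned per-sample covariate
#' table and a per-gene annotation table. Genes are rows, samples are columns;
#' the orientation is fixed and readers reject anything ambiguous rather than
#' guessing.
#'
#' Counts may be fractional (upstream quantifiers emit expected counts);
#' non-negativity and finiteness are the only value constraints. Row and column
#' names are mandatory and must be unique, since every downstream view keys on
#' them.
#'
#' @param counts Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty `rownames` (gene ids) and `colnames` (sample ids).
#' @param sample_table Optional data frame with a `sample_id` column matching
#'   `colnames(counts)`; arbitrary additional covariate columns are carried
#'   through. Defaults to a bare table of sample ids.
#' @param gene_table Optional data frame with a `gene_id` column matching
#'   `rownames(counts)`; optional annotation columns (symbol, chromosome, ...)
#'   are carried through. Defaults to a bare table of gene ids.
#' @return An object of class `ExpressionData`: a list with elements `counts`,
#'   `samples` and `genes`.
#' @seealso [read_counts()], [attach_tables()], [log_cpm()]
#' @export
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' expr <- expression_data(m)
#' n_genes(expr); n_samples(expr)
expression_data <- function(counts, sample_table = NULL, gene_table = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  validate_counts(counts)
  expr <- structure(
    list(counts = counts,
         samples = data.frame(sample_id = colnames(counts),
                              stringsAsFactors = FALSE),
         genes = data.frame(gene_id = rownames(counts),
                            stringsAsFactors = FALSE)),
    class = "ExpressionData")
  if (!is.null(sample_table) || !is.null(gene_table)) {
    expr <- attach_tables(expr, sample_table, gene_table)
  }
  expr
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) {
    stop("counts must be numeric; found mode '", mode(counts), "'",
         call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts)) ||
      anyNA(rownames(counts)) || anyNA(colnames(counts)) ||
      any(rownames(counts) == "") || any(colnames(counts) == "")) {
    stop("counts must carry non-empty gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(counts)[bad[1, 1]]
    s <- colnames(counts)[bad[1, 2]]
    stop("invalid count (", format(counts[bad[1, 1], bad[1, 2]]),
         ") at gene '", g, "', sample '", s,
         "': counts must be non-negative and finite", call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.ExpressionData <- function(x, ...) {
  cat("ExpressionData:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  sample covariates:", paste(names(x$samples), collapse = ", "), "\n")
  cat("  gene annotations: ", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' Dimensions of an ExpressionData object
#'
#' @param expr An [expression_data()] object.
#' @return Integer count of genes (rows) or samples (columns).
#' @export
n_genes <- function(expr) nrow(expr$counts)

#' @rdname n_genes
#' @export
n_samples <- function(expr) ncol(expr$counts)

#' Read a count matrix from disk
#'
#' Supports three dialects: tab-delimited (`tsv`) and comma-delimited (`csv`)
#' tables with a header row of sample ids and gene ids in the first column,
#' and MatrixMarket coordinate triplets (`mtx`) with sidecar row-name and
#' column-name files (one id per line). Entries absent from a triplet file are
#' zeros. Any negative, missing or non-numeric cell is a validation error that
#' names the offending gene and sample.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @param genes,samples For `format = "mtx"`, the sidecar name files; default
#'   `<path>.genes` and `<path>.samples`.
#' @return An [expression_data()] object (tables attach separately via
#'   [attach_tables()]).
#' @seealso [write_counts()] for the inverse operation.
#' @export
read_counts <- function(path, format = c("tsv", "csv", "mtx"),
                        genes = paste0(path, ".genes"),
                        samples = paste0(path, ".samples")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    for (f in c(genes, samples)) {
      if (!file.exists(f)) stop("sidecar name file not found: ", f, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(genes)
    cn <- readLines(samples)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("sidecar name files do not match matrix dimensions (",
           nrow(m), "x", ncol(m), " vs ", length(rn), " genes, ",
           length(cn), " samples)", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
    return(expression_data(m))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, row.names = NULL,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) {
    stop("expected gene ids in the first column and at least one sample column",
         call. = FALSE)
  }
  rn <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric count ('", vals[bad[1, 1], bad[1, 2]], "') at gene '",
         rn[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]], "'",
         call. = FALSE)
  }
  dimnames(num) <- list(rn, colnames(vals))
  expression_data(num)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; numeric values are written in their shortest
#' round-trip decimal representation so that write/read is lossless.
#'
#' @param expr An [expression_data()] object (or bare named matrix).
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(expr, path, format = c("tsv", "csv", "mtx"),
                         genes = paste0(path, ".genes"),
                         samples = paste0(path, ".samples")) {
  format <- match.arg(format)
  counts <- if (inherits(expr, "ExpressionData")) expr$counts else as.matrix(expr)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), genes)
    writeLines(colnames(counts), samples)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  chr <- apply(counts, 2, as.character)
  dim(chr) <- dim(counts)
  out <- data.frame(gene_id = rownames(counts), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("gene_id", colnames(counts))
  utils::write.table(out, path, sep = sep, quote = TRUE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Attach sample and gene tables to an ExpressionData object
#'
#' Tables are reordered to match the count matrix's column and row name order.
#' A sample or gene present on one side but not the other is an error (the
#' names are listed), never a silent drop. The operation is idempotent and
#' insensitive to the input row order of either table.
#'
#' @param expr An [expression_data()] object.
#' @param sample_table Data frame with a `sample_id` key column, or `NULL` to
#'   leave the current table untouched.
#' @param gene_table Data frame with a `gene_id` key column, or `NULL`.
#' @return The updated `ExpressionData`.
#' @export
attach_tables <- function(expr, sample_table = NULL, gene_table = NULL) {
  stopifnot(inherits(expr, "ExpressionData"))
  if (!is.null(sample_table)) {
    expr$samples <- align_table(as.data.frame(sample_table), "sample_id",
                                colnames(expr$counts), "sample")
  }
  if (!is.null(gene_table)) {
    expr$genes <- align_table(as.data.frame(gene_table), "gene_id",
                              rownames(expr$counts), "gene")
  }
  expr
}

align_table <- function(tab, key, ids, what) {
  if (!key %in% names(tab)) {
    stop(what, " table must contain a '", key, "' column; found: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  keys <- as.character(tab[[key]])
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    stop("duplicate ", key, " in ", what, " table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  missing_in_tab <- setdiff(ids, keys)
  extra_in_tab <- setdiff(keys, ids)
  if (length(missing_in_tab) || length(extra_in_tab)) {
    msg <- character(0)
    if (length(missing_in_tab)) {
      msg <- c(msg, paste0(length(missing_in_tab), " ", what,
                           "(s) in counts missing from table: ",
                           paste(utils::head(missing_in_tab, 5), collapse = ", ")))
    }
    if (length(extra_in_tab)) {
      msg <- c(msg, paste0(length(extra_in_tab), " ", what,
                           "(s) in table absent from counts: ",
                           paste(utils::head(extra_in_tab, 5), collapse = ", ")))
    }
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  out <- tab[match(ids, keys), , drop = FALSE]
  rownames(out) <- NULL
  out[[key]] <- as.character(out[[key]])
  out
}
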