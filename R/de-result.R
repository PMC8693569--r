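#' Construct a DEResult table
#'
#' Per-gene differential-expression summary statistics: log2 fold change,
#' average log-CPM, p-value, and optionally an adjusted p-value and a status
#' call in {-1, 0, 1} (down, non-DE, up). Missing p-values are rejected rather
#' than imputed, because every downstream view sorts and filters on them.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param logfc Numeric log2 fold changes.
#' @param p_value Numeric p-values in \[0, 1\], no missing values.
#' @param ave_expr Optional mean log-CPM per gene.
#' @param adj_p Optional adjusted p-values in \[0, 1\].
#' @param status Optional per-gene call, each element in `c(-1, 0, 1)`.
#' @param annotations Optional data frame of extra per-gene columns (carried
#'   through to table views untouched).
#' @return A data frame of class `DEResult` with one row per gene.
#' @export
de_result <- function(gene_id, logfc, p_value, ave_expr = NULL, adj_p = NULL,
                      status = NULL, annotations = NULL) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (n == 0) stop("DEResult must contain at least one gene", call. = FALSE)
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene_id in DE table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  check_len <- function(x, nm) {
    if (!is.null(x) && length(x) != n) {
      stop("'", nm, "' has length ", length(x), ", expected ", n, call. = FALSE)
    }
  }
  check_len(logfc, "logfc"); check_len(p_value, "p_value")
  check_len(ave_expr, "ave_expr"); check_len(adj_p, "adj_p")
  check_len(status, "status")
  logfc <- as.numeric(logfc)
  if (anyNA(logfc)) stop("logfc contains missing values", call. = FALSE)
  p_value <- check_pvalues(p_value, "p_value")
  if (!is.null(adj_p)) adj_p <- check_pvalues(adj_p, "adj_p")
  if (!is.null(status)) {
    status <- as.numeric(status)
    if (!all(status %in% c(-1, 0, 1))) {
      stop("status values must be -1, 0 or 1", call. = FALSE)
    }
  }
  de <- data.frame(gene_id = gene_id, logfc = logfc, p_value = p_value,
                   stringsAsFactors = FALSE)
  if (!is.null(ave_expr)) de$ave_expr <- as.numeric(ave_expr)
  if (!is.null(adj_p)) de$adj_p <- adj_p
  if (!is.null(status)) de$status <- status
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != n) {
      stop("annotations has ", nrow(annotations), " rows, expected ", n,
           call. = FALSE)
    }
    keep <- setdiff(names(annotations), names(de))
    de <- cbind(de, annotations[, keep, drop = FALSE])
  }
  class(de) <- c("DEResult", "data.frame")
  de
}

check_pvalues <- function(p, nm) {
  p <- as.numeric(p)
  if (anyNA(p)) stop("'", nm, "' contains missing values", call. = FALSE)
  if (any(p < 0 | p > 1)) {
    stop("'", nm, "' must lie in [0, 1]; offending value: ",
         format(p[which(p < 0 | p > 1)[1]]), call. = FALSE)
  }
  p
}

#' Read a DE statistics table from disk
#'
#' Expects a delimited table with a header containing at least `gene_id`,
#' `logfc` and `p_value` columns; `ave_expr`, `adj_p` and `status` are picked
#' up when present, and any other columns are kept as gene annotations.
#'
#' @param path Path to the table.
#' @param format `"tsv"` or `"csv"`.
#' @return A [de_result()] object.
#' @export
read_de <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  need <- c("gene_id", "logfc", "p_value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("DE table is missing required column(s): ",
         paste(miss, collapse = ", "), "; found: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  opt <- function(nm) if (nm %in% names(tab)) tab[[nm]] else NULL
  extra <- setdiff(names(tab),
                   c("gene_id", "logfc", "p_value", "ave_expr", "adj_p", "status"))
  de_result(tab$gene_id, tab$logfc, tab$p_value, ave_expr = opt("ave_expr"),
            adj_p = opt("adj_p"), status = opt("status"),
            annotations = if (length(extra)) tab[, extra, drop = FALSE])
}

#' Pair a DEResult with an ExpressionData object
#'
#' Genes are matched by id and the DE table is reordered so that the pair
#' shares the expression object's gene order. Cardinality or id-set mismatches
#' are errors that report how many ids are unmatched on each side; duplicated
#' ids abort before any matching.
#'
#' @param de A [de_result()] table.
#' @param expr An [expression_data()] object.
#' @return A list of class `DEPair` with elements `de` (reordered) and `expr`.
#' @export
align_de <- function(de, expr) {
  stopifnot(inherits(de, "DEResult"), inherits(expr, "ExpressionData"))
  ids <- rownames(expr$counts)
  missing_de <- setdiff(ids, de$gene_id)
  extra_de <- setdiff(de$gene_id, ids)
  if (length(missing_de) || length(extra_de)) {
    stop("gene sets do not match: ", length(missing_de),
         " gene(s) missing from DE table (e.g. ",
         paste(utils::head(missing_de, 3), collapse = ", "), "), ",
         length(extra_de), " gene(s) in DE table absent from expression data",
         call. = FALSE)
  }
  out <- de[match(ids, de$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(de)
  structure(list(de = out, expr = expr), class = "DEPair")
}

#' Export DE statistics concatenated with expression values as CSV
#'
#' Produces one row per in-scope gene with gene annotation columns first,
#' then the DE statistics, then one column per sample of expression values
#' (log-CPM in the widget workflow). Fields containing delimiters, quotes or
#' newlines are quoted so that re-parsing recovers them verbatim; numbers are
#' written in their shortest round-trip decimal representation.
#'
#' @param de A [de_result()] table (assumed in the same gene order as
#'   `expr_values`).
#' @param expr_values Gene-by-sample numeric matrix (e.g. [log_cpm()] output)
#'   with rownames equal to `de$gene_id` in order.
#' @param gene_table Optional per-gene annotation data frame (same order);
#'   defaults to a bare `gene_id` column derived from `de`.
#' @param selection Character vector of selected gene ids (used when
#'   `scope = "selected"`). Must be a subset of the gene ids.
#' @param scope `"all"` or `"selected"`; `"selected"` with an empty selection
#'   is an error instructing `scope = "all"`.
#' @param file Optional path; when given the CSV is written there.
#' @return The CSV document as a single character string (invisibly when
#'   `file` is given).
#' @export
export_csv <- function(de, expr_values, gene_table = NULL,
                       selection = character(0), scope = c("all", "selected"),
                       file = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(de, "DEResult"))
  expr_values <- as.matrix(expr_values)
  if (nrow(expr_values) != nrow(de) ||
      !identical(rownames(expr_values), de$gene_id)) {
    stop("expr_values rows must equal de$gene_id in order", call. = FALSE)
  }
  if (is.null(gene_table)) {
    gene_table <- data.frame(gene_id = de$gene_id, stringsAsFactors = FALSE)
  }
  gene_table <- as.data.frame(gene_table)
  if (nrow(gene_table) != nrow(de)) {
    stop("gene_table must have one row per gene", call. = FALSE)
  }
  bad_sel <- setdiff(selection, de$gene_id)
  if (length(bad_sel)) {
    stop("selection contains unknown gene id(s): ",
         paste(utils::head(bad_sel, 5), collapse = ", "), call. = FALSE)
  }
  if (scope == "selected" && length(selection) == 0) {
    stop("scope = 'selected' requires a non-empty selection; use scope = 'all'",
         call. = FALSE)
  }
  stats_cols <- setdiff(names(de), c("gene_id", names(gene_table)))
  out <- cbind(gene_table,
               as.data.frame(de)[, stats_cols, drop = FALSE],
               as.data.frame(expr_values, check.names = FALSE))
  if (scope == "selected") {
    out <- out[de$gene_id %in% selection, , drop = FALSE]
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], as.character)
  con <- textConnection("csv_lines", "w", local = TRUE)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  close(con)
  txt <- paste0(paste(csv_lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}
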