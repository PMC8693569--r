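#' Build an interactive MDS widget document
#'
#' Packages an [run_mds()] result and the sample covariates into a
#' self-describing declarative document: embedded sample coordinates for every
#' retained dimension, the variance-explained bar series, dropdown controls
#' for the x/y dimension pair (any combination), point colour, shape and size
#' by covariate, a colour-scheme selector, and a save-plot button for each of
#' the two panels. When the MDS result carries library sizes they are added as
#' a `library_size` covariate automatically.
#'
#' Shape is restricted to discrete covariates, and to at most
#' `r SHAPE_GLYPH_LIMIT` categories (the number of glyphs the embedded
#' runtime guarantees); a continuous shape request errors with a suggestion
#' to discretize.
#'
#' @param mds An `MDSResult` from [run_mds()] (or a compatible list).
#' @param sample_table Data frame with a `sample_id` column matching the MDS
#'   coordinate rows, plus arbitrary covariates.
#' @param x_dim,y_dim Default dimensions shown on the axes (1-based).
#' @param colour_by,shape_by,size_by Default covariate names; sensible
#'   defaults are picked from the table when `NULL`.
#' @param scheme Default colour scheme name; discrete schemes apply to
#'   discrete covariates and continuous ramps to numeric ones.
#' @return A `WidgetDoc` of kind `"mds"`.
#' @export
build_mds_widget <- function(mds, sample_table, x_dim = 1, y_dim = 2,
                             colour_by = NULL, shape_by = NULL,
                             size_by = NULL, scheme = NULL) {
  coords <- as.matrix(mds$coordinates)
  k <- ncol(coords)
  sample_table <- align_table(as.data.frame(sample_table), "sample_id",
                              rownames(coords), "sample")
  if (!is.null(mds$params$library_sizes) &&
      !"library_size" %in% names(sample_table)) {
    sample_table$library_size <- as.numeric(mds$params$library_sizes)
  }
  covars <- setdiff(names(sample_table), "sample_id")
  if (length(covars) == 0) {
    sample_table$sample <- sample_table$sample_id
    covars <- "sample"
  }
  discrete <- covars[vapply(sample_table[covars], is_discrete, logical(1))]
  numeric_cov <- setdiff(covars, discrete)

  pick <- function(given, pool, what) {
    if (is.null(given)) return(if (length(pool)) pool[[1]] else NULL)
    if (!given %in% covars) {
      stop(what, " covariate '", given, "' not found in sample table; ",
           "available: ", paste(covars, collapse = ", "), call. = FALSE)
    }
    given
  }
  colour_by <- pick(colour_by, c(discrete, numeric_cov), "colour")
  shape_by <- pick(shape_by, discrete, "shape")
  if (!is.null(shape_by) && !shape_by %in% discrete) {
    stop("shape covariate '", shape_by, "' is continuous; discretize it ",
         "(e.g. cut into bins) before shaping points by it", call. = FALSE)
  }
  if (!is.null(shape_by)) {
    n_cat <- length(unique(sample_table[[shape_by]]))
    if (n_cat > SHAPE_GLYPH_LIMIT) {
      stop("shape covariate '", shape_by, "' has ", n_cat,
           " categories; the runtime guarantees ", SHAPE_GLYPH_LIMIT,
           " glyphs", call. = FALSE)
    }
  }
  size_by <- pick(size_by,
                  c(intersect("library_size", numeric_cov),
                    setdiff(numeric_cov, "library_size"), discrete),
                  "size")

  if (x_dim < 1 || x_dim > k || y_dim < 1 || y_dim > k) {
    stop("default dimensions must lie in 1..", k, call. = FALSE)
  }
  colour_discrete <- is.null(colour_by) || colour_by %in% discrete
  schemes <- if (colour_discrete) DISCRETE_SCHEMES else CONTINUOUS_SCHEMES
  if (is.null(scheme)) scheme <- schemes[[1]]
  if (!scheme %in% c(DISCRETE_SCHEMES, CONTINUOUS_SCHEMES)) {
    stop("unknown colour scheme '", scheme, "'", call. = FALSE)
  }

  samples_df <- cbind(sample_table,
                      as.data.frame(coords, check.names = FALSE))
  ve <- mds$var_explained
  data <- list(
    samples = embed_table(samples_df),
    variance = list(dimension = I(seq_along(ve)),
                    proportion = I(as.numeric(ve))))

  dims <- paste0("dim", seq_len(k))
  enc_main <- list(
    x = list(table = "samples", field = dims[x_dim],
             label = axis_label(x_dim, ve)),
    y = list(table = "samples", field = dims[y_dim],
             label = axis_label(y_dim, ve)),
    tooltip = list(table = "samples", fields = I(names(samples_df))))
  if (!is.null(colour_by)) {
    enc_main$colour <- list(table = "samples", field = colour_by,
                            scheme = scheme)
  }
  if (!is.null(shape_by)) {
    enc_main$shape <- list(table = "samples", field = shape_by)
  }
  if (!is.null(size_by)) {
    enc_main$size <- list(table = "samples", field = size_by)
  }
  encodings <- list(
    main = enc_main,
    variance = list(x = list(table = "variance", field = "dimension",
                             label = "Dimension"),
                    y = list(table = "variance", field = "proportion",
                             label = "Variance explained")))

  controls <- list(
    control("x_dim", "dropdown", "x-axis dimension", dims, dims[x_dim]),
    control("y_dim", "dropdown", "y-axis dimension", dims, dims[y_dim]),
    control("colour_by", "dropdown", "colour by", covars, colour_by),
    control("size_by", "dropdown", "size by", covars, size_by),
    control("scheme", "dropdown", "colour scheme", schemes, scheme),
    control("save_mds_plot", "button", "Save Plot", c("png", "svg")),
    control("save_variance_plot", "button", "Save Plot", c("png", "svg")))
  if (length(discrete)) {
    controls <- append(controls,
                       list(control("shape_by", "dropdown", "shape by",
                                    discrete, shape_by)),
                       after = 3)
  }

  meta <- list(
    created_by = "deview",
    palettes = list(discrete = I(DISCRETE_SCHEMES),
                    continuous = I(CONTINUOUS_SCHEMES)),
    shape_glyph_limit = SHAPE_GLYPH_LIMIT,
    params = list(top = mds$params$top,
                  gene_selection = mds$params$gene_selection,
                  prior = mds$params$prior,
                  n_dimensions = k))
  meta$params <- meta$params[!vapply(meta$params, is.null, logical(1))]

  new_widget_doc("mds", data, encodings, controls, meta)
}

axis_label <- function(dim, ve) {
  if (dim <= length(ve)) {
    sprintf("Dimension %d (%s%%)", dim, format(round(100 * ve[dim], 1)))
  } else {
    sprintf("Dimension %d", dim)
  }
}

STATUS_COLOURS <- c(`-1` = "#1f77b4", `0` = "#b4b4b4", `1` = "#d62728")
STATUS_LABELS <- c(`-1` = "downregulated", `0` = "non-DE", `1` = "upregulated")

#' Build a linked summary-expression widget document
#'
#' The summary-expression dashboard pairs a gene-level summary scatter (MA,
#' volcano, or a generic XY plot of user-supplied vectors) with a per-sample
#' expression panel for the most recently selected gene, above a searchable
#' statistics table. Axis mapping by kind: `ma` shows logFC (M) against
#' average log-CPM (A); `volcano` shows -log10 p-value against logFC; `xy`
#' shows the supplied `x` and `y` vectors, which must match the number of
#' genes. Points are coloured by DE status (-1 down, 0 non-DE, 1 up), called
#' automatically with [decide_status()] unless an explicit `status` vector is
#' given. The expression panel plots log-CPM stratified by `group_col`, with
#' x tick labels rotated 45 degrees anticlockwise; `max_y_axis` fixes its
#' y-axis upper bound in place of per-gene auto-scaling.
#'
#' @param kind `"ma"`, `"volcano"` or `"xy"`.
#' @param de A [de_result()] table.
#' @param expr An [expression_data()] object covering the same genes.
#' @param group_col Name of the grouping column in `expr$samples`.
#' @param status Optional explicit status vector (overrides the automatic
#'   call).
#' @param sample_colours Optional per-sample colours for the expression
#'   panel, length `n_samples(expr)`.
#' @param max_y_axis Optional fixed upper bound for the expression y-axis.
#' @param x,y Required for `kind = "xy"`: numeric vectors, one value per gene.
#' @param x_label,y_label Axis labels for `kind = "xy"`.
#' @param alpha,lfc_min Passed to [decide_status()] for the automatic call.
#' @param prior Prior count for [log_cpm()].
#' @return A `WidgetDoc` of the requested kind.
#' @export
build_summary_widget <- function(kind = c("ma", "volcano", "xy"), de, expr,
                                 group_col, status = NULL,
                                 sample_colours = NULL, max_y_axis = NULL,
                                 x = NULL, y = NULL,
                                 x_label = "x", y_label = "y",
                                 alpha = 0.05, lfc_min = 0, prior = 0.5) {
  kind <- match.arg(kind)
  pair <- align_de(de, expr)
  de <- pair$de
  expr <- pair$expr
  n_g <- n_genes(expr)
  n_s <- n_samples(expr)

  if (!group_col %in% names(expr$samples)) {
    stop("grouping column '", group_col, "' not found; available: ",
         paste(names(expr$samples), collapse = ", "), call. = FALSE)
  }
  group <- as.character(expr$samples[[group_col]])
  if (!is.null(sample_colours) && length(sample_colours) != n_s) {
    stop("sample_colours has length ", length(sample_colours),
         ", expected one per sample (", n_s, ")", call. = FALSE)
  }
  if (kind == "xy") {
    if (is.null(x) || is.null(y)) {
      stop("kind = 'xy' requires both x and y vectors", call. = FALSE)
    }
    if (length(x) != n_g || length(y) != n_g) {
      stop("xy vectors must have one value per gene: length(x) = ", length(x),
           ", length(y) = ", length(y), ", n_genes = ", n_g, call. = FALSE)
    }
  }

  lcpm <- log_cpm(expr, prior = prior)
  if (is.null(de$ave_expr)) de$ave_expr <- rowMeans(lcpm)
  status <- decide_status(de, alpha = alpha, lfc_min = lfc_min, status = status)

  axes <- switch(kind,
    ma = list(x = de$ave_expr, y = de$logfc,
              x_label = "average log-CPM", y_label = "logFC"),
    volcano = list(x = de$logfc, y = neglog10_p(de$p_value),
                   x_label = "logFC", y_label = "-log10(p-value)"),
    xy = list(x = as.numeric(x), y = as.numeric(y),
              x_label = x_label, y_label = y_label))

  label_field <- if ("symbol" %in% names(expr$genes)) "symbol" else "gene_id"
  labels <- as.character(expr$genes[[label_field]])
  labels[is.na(labels) | labels == ""] <- de$gene_id[is.na(labels) | labels == ""]

  table_df <- cbind(expr$genes,
                    as.data.frame(de)[, setdiff(names(de),
                                                c("gene_id", names(expr$genes))),
                                      drop = FALSE])
  table_df$status <- status

  expr_colour <- if (is.null(sample_colours)) group else as.character(sample_colours)
  expression_df <- data.frame(
    gene_id = rep(de$gene_id, each = n_s),
    sample = rep(colnames(expr$counts), times = n_g),
    group = rep(group, times = n_g),
    colour = rep(expr_colour, times = n_g),
    value = as.numeric(t(lcpm)),
    stringsAsFactors = FALSE)

  data <- list(
    table = embed_table(table_df),
    summary = embed_table(data.frame(gene_id = de$gene_id,
                                     x = axes$x, y = axes$y,
                                     status = status, label = labels,
                                     stringsAsFactors = FALSE)),
    expression = embed_table(expression_df))

  y_domain <- if (is.null(max_y_axis)) {
    "auto"
  } else {
    list(min = min(0, min(lcpm)), max = as.numeric(max_y_axis))
  }
  encodings <- list(
    summary = list(
      x = list(table = "summary", field = "x", label = axes$x_label),
      y = list(table = "summary", field = "y", label = axes$y_label),
      colour = list(table = "summary", field = "status",
                    domain = I(c(-1, 0, 1)),
                    range = I(unname(STATUS_COLOURS)),
                    legend = list(title = "status",
                                  labels = I(unname(STATUS_LABELS)))),
      label = list(table = "summary", field = "label"),
      tooltip = list(table = "table", fields = I(names(table_df)))),
    expression = list(
      x = list(table = "expression", field = "group", label = group_col,
               label_rotation = -45),
      y = list(table = "expression", field = "value", label = "log-CPM",
               domain = y_domain),
      colour = list(table = "expression", field = "colour",
                    literal = !is.null(sample_colours)),
      tooltip = list(table = "expression", fields = I(c("sample", "value")))))

  controls <- list(
    control("search", "search", "Search gene table", "contains", ""),
    control("max_y_axis", "numeric", "max y-axis",
            c("auto", "fixed"),
            if (is.null(max_y_axis)) "auto" else "fixed",
            value = if (is.null(max_y_axis)) NULL else as.numeric(max_y_axis)),
    control("clear_selection", "button", "Clear selection", "clear"),
    control("save_summary_plot", "button", "Save Plot", c("png", "svg")),
    control("save_expression_plot", "button", "Save Plot", c("png", "svg")),
    control("save_data", "button", "Save Data", c("selected", "all")))

  meta <- list(
    created_by = "deview",
    layout = I(c("summary", "expression", "selection_strip", "table")),
    group_col = group_col,
    params = list(alpha = alpha, lfc_min = lfc_min, prior = prior,
                  n_genes = n_g, n_samples = n_s))

  new_widget_doc(kind, data, encodings, controls, meta)
}
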