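#' @importFrom jsonlite toJSON fromJSON
NULL

WIDGET_SCHEMA <- "linked-widget/1"
WIDGET_KINDS <- c("mds", "ma", "volcano", "xy")

# Number of point glyphs the embedded runtime guarantees; shape encodings
# with more categories are rejected rather than recycled.
SHAPE_GLYPH_LIMIT <- 8L

DISCRETE_SCHEMES <- c("category10", "accent", "dark2", "paired", "set2")
CONTINUOUS_SCHEMES <- c("viridis", "plasma", "inferno", "blues", "greens")

#' Serialize a widget document to canonical JSON
#'
#' Widget documents are plain nested lists; this produces the single canonical
#' JSON text for a document (fixed key order as constructed, scalars unboxed,
#' vectors wrapped as arrays, numbers at full shortest-round-trip precision).
#' [parse_widget()] inverts it, and serialize-parse-serialize is
#' byte-identical — the property the HTML data island relies on.
#'
#' @param doc A widget document (from [build_mds_widget()] or
#'   [build_summary_widget()]).
#' @return A single JSON character string.
#' @export
serialize_widget <- function(doc) {
  as.character(jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' Parse a widget document from JSON
#'
#' @param json JSON text produced by [serialize_widget()] (possibly recovered
#'   from an HTML data island).
#' @return A `WidgetDoc` object equivalent to the serialized one.
#' @export
parse_widget <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc <- canonicalize_node(x)
  class(doc) <- "WidgetDoc"
  validate_widget(doc)
  doc
}

# Rebuild the construction-time shape from fromJSON's raw lists: JSON arrays
# of homogeneous scalars become atomic vectors (AsIs, so length-1 arrays stay
# arrays), objects stay named lists.
canonicalize_node <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x))) {
    out <- lapply(x, canonicalize_node)
    return(out)
  }
  elems <- lapply(x, canonicalize_node)
  if (length(elems) == 0) return(I(list()))
  scalar <- vapply(elems, function(e) !is.list(e) && length(e) == 1 &&
                     is.null(attr(e, "class")), logical(1))
  if (all(scalar)) {
    types <- vapply(elems, typeof, character(1))
    if (length(unique(types)) == 1) return(I(unlist(elems, use.names = FALSE)))
    # mixed int/double arrays still collapse to numeric
    if (all(types %in% c("integer", "double"))) {
      return(I(as.numeric(unlist(elems, use.names = FALSE))))
    }
  }
  elems
}

#' Validate a widget document
#'
#' Checks the structural contract: known kind, every encoding field present in
#' the embedded table it references, non-empty option lists for every control,
#' and an interaction contract reference.
#'
#' @param doc A `WidgetDoc`.
#' @return `doc`, invisibly; errors describe the first violation.
#' @export
validate_widget <- function(doc) {
  need <- c("schema", "kind", "data", "encodings", "controls", "interaction",
            "meta")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("widget document is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(doc$schema), WIDGET_SCHEMA)) {
    stop("unknown widget schema: ", doc$schema, call. = FALSE)
  }
  if (!doc$kind %in% WIDGET_KINDS) {
    stop("unknown widget kind: ", doc$kind, call. = FALSE)
  }
  check_enc <- function(enc, where) {
    if (!is.list(enc)) return(invisible())
    if (!is.null(enc$table)) {
      tab <- doc$data[[enc$table]]
      if (is.null(tab)) {
        stop("encoding ", where, " references unknown table '", enc$table, "'",
             call. = FALSE)
      }
      fields <- c(enc$field, unlist(enc$fields, use.names = FALSE))
      bad <- setdiff(fields, names(tab))
      if (length(bad)) {
        stop("encoding ", where, " references field(s) absent from table '",
             enc$table, "': ", paste(bad, collapse = ", "), call. = FALSE)
      }
    } else {
      for (nm in names(enc)) check_enc(enc[[nm]], paste0(where, ".", nm))
    }
    invisible()
  }
  for (nm in names(doc$encodings)) check_enc(doc$encodings[[nm]], nm)
  for (ctl in doc$controls) {
    if (is.null(ctl$id) || is.null(ctl$type)) {
      stop("every control needs an id and a type", call. = FALSE)
    }
    opts <- unlist(ctl$options, use.names = FALSE)
    if (length(opts) == 0) {
      stop("control '", ctl$id, "' has an empty option list", call. = FALSE)
    }
  }
  if (is.null(doc$interaction$contract)) {
    stop("widget document lacks an interaction contract", call. = FALSE)
  }
  invisible(doc)
}

#' @export
print.WidgetDoc <- function(x, ...) {
  tabs <- vapply(x$data, function(t) length(t[[1]]), numeric(1))
  cat("WidgetDoc <", x$kind, ">: tables [",
      paste(sprintf("%s: %d", names(tabs), tabs), collapse = ", "),
      "], ", length(x$controls), " controls\n", sep = "")
  invisible(x)
}

widget_equal <- function(a, b) {
  identical(serialize_widget(a), serialize_widget(b))
}

# column-oriented embedded table: every column wrapped AsIs so that length-1
# columns still serialize as JSON arrays
embed_table <- function(df) {
  cols <- lapply(df, function(col) {
    if (is.factor(col)) col <- as.character(col)
    I(col)
  })
  cols
}

new_widget_doc <- function(kind, data, encodings, controls, meta) {
  doc <- list(
    schema = WIDGET_SCHEMA,
    version = "1.0.0",
    kind = kind,
    data = data,
    encodings = encodings,
    controls = controls,
    interaction = list(contract = "selection-toggle/1",
                       modes = I(c("IDLE", "GRAPH_SELECT"))),
    meta = meta)
  class(doc) <- "WidgetDoc"
  validate_widget(doc)
  doc
}

control <- function(id, type, label, options, default = NULL, value = NULL) {
  ctl <- list(id = id, type = type, label = label, options = I(options))
  if (!is.null(default)) ctl$default <- default
  if (!is.null(value)) ctl$value <- value
  ctl
}

is_discrete <- function(x) {
  is.character(x) || is.factor(x) || is.logical(x)
}
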