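.deview_env <- new.env(parent = emptyenv())
.deview_env$fragment_counter <- 0L

runtime_assets <- function() {
  js <- system.file("runtime", "widget.js", package = "deview", mustWork = TRUE)
  css <- system.file("runtime", "widget.css", package = "deview", mustWork = TRUE)
  list(js = paste(readLines(js, warn = FALSE), collapse = "\n"),
       css = paste(readLines(css, warn = FALSE), collapse = "\n"))
}

# JSON destined for a <script> data island: escape "</" so no embedded string
# can close the tag; "\/" is a legal JSON escape, so recovery is bit-exact.
escape_island <- function(json) gsub("</", "<\\\\/", json)

#' Render a widget as a standalone HTML file
#'
#' Produces a single fully self-contained HTML document: the runtime script,
#' interaction glue and styles are inlined, and the widget document is
#' embedded as a JSON data island, so the file can be opened and shared with
#' no server, network access or analysis environment. Rendering the same
#' document twice yields byte-identical files (fixed version strings, no
#' timestamps). Save-plot buttons in the rendered widget export the current
#' view as PNG or SVG; the save-data button downloads the gene table joined
#' with expression values as CSV, scoped to the selection or to all genes.
#'
#' @param doc A `WidgetDoc` from [build_mds_widget()] or
#'   [build_summary_widget()].
#' @param path Optional output path; when given the document is written there.
#' @param title Page title (defaults to the widget kind).
#' @return A `RenderedWidget`: list with `html_text`, `embedded_payload`
#'   (the source document), `assets_inlined = TRUE` and `standalone = TRUE`.
#' @seealso [render_fragment()], [extract_payload()]
#' @export
render_standalone <- function(doc, path = NULL, title = NULL) {
  validate_widget(doc)
  assets <- runtime_assets()
  if (is.null(title)) title <- paste0("deview ", doc$kind, " widget")
  json <- escape_island(serialize_widget(doc))
  html <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n",
    "<meta charset=\"utf-8\"/>\n",
    "<title>", escape_html(title), "</title>\n",
    "<style>\n", assets$css, "\n</style>\n",
    "</head>\n<body>\n",
    "<div id=\"dv-widget\" class=\"dv-widget\"></div>\n",
    "<script type=\"application/json\" id=\"dv-widget-data\">", json,
    "</script>\n",
    "<script>\n", assets$js, "\n</script>\n",
    "<script>deviewRender(\"dv-widget\", \"dv-widget-data\");</script>\n",
    "</body>\n</html>\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(html), con)
  }
  structure(list(html_text = html, embedded_payload = doc,
                 assets_inlined = TRUE, standalone = TRUE, path = path),
            class = "RenderedWidget")
}

#' Render a widget as an embeddable HTML fragment
#'
#' Emits a fragment (container, data island, runtime and init call) with a
#' unique container id, so several widgets can coexist in one notebook or
#' page; the runtime script guards itself against double definition.
#'
#' @inheritParams render_standalone
#' @return A `RenderedWidget` with `standalone = FALSE`.
#' @export
render_fragment <- function(doc) {
  validate_widget(doc)
  assets <- runtime_assets()
  .deview_env$fragment_counter <- .deview_env$fragment_counter + 1L
  id <- paste0("dv-widget-", .deview_env$fragment_counter)
  json <- escape_island(serialize_widget(doc))
  html <- paste0(
    "<div id=\"", id, "\" class=\"dv-widget\"></div>\n",
    "<script type=\"application/json\" id=\"", id, "-data\">", json,
    "</script>\n",
    "<script>\n", assets$js, "\n</script>\n",
    "<script>deviewRender(\"", id, "\", \"", id, "-data\");</script>\n")
  structure(list(html_text = html, embedded_payload = doc,
                 assets_inlined = TRUE, standalone = FALSE,
                 container_id = id),
            class = "RenderedWidget")
}

#' Recover the widget document from rendered HTML
#'
#' Parses the HTML (file or text), locates the JSON data island and returns
#' the widget document it contains — the exact inverse of rendering, used by
#' the round-trip tests and by anyone who wants the data back out of a shared
#' file.
#'
#' @param html A path to an HTML file, a `RenderedWidget`, or HTML text.
#' @return The embedded `WidgetDoc`.
#' @export
extract_payload <- function(html) {
  if (inherits(html, "RenderedWidget")) html <- html$html_text
  page <- if (length(html) == 1 && !grepl("<", html, fixed = TRUE) &&
              file.exists(html)) {
    xml2::read_html(html)
  } else {
    xml2::read_html(paste(html, collapse = "\n"))
  }
  node <- xml2::xml_find_first(page, "//script[@type='application/json']")
  if (inherits(node, "xml_missing")) {
    stop("no JSON data island found in the document", call. = FALSE)
  }
  parse_widget(xml2::xml_text(node))
}

#' Count external resource references in an HTML document
#'
#' A standalone widget must not reach out to the network: this counts
#' `script[src]`, `link[href]` and `img[src]` references, which must be zero
#' for files rendered with [render_standalone()].
#'
#' @inheritParams extract_payload
#' @return Integer count of external references.
#' @export
external_references <- function(html) {
  if (inherits(html, "RenderedWidget")) html <- html$html_text
  page <- if (length(html) == 1 && !grepl("<", html, fixed = TRUE) &&
              file.exists(html)) {
    xml2::read_html(html)
  } else {
    xml2::read_html(paste(html, collapse = "\n"))
  }
  refs <- xml2::xml_find_all(page,
    "//script[@src] | //link[@href] | //img[@src]")
  length(refs)
}

escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @export
print.RenderedWidget <- function(x, ...) {
  cat("RenderedWidget (", if (x$standalone) "standalone" else "fragment",
      "): ", nchar(x$html_text), " characters, kind '",
      x$embedded_payload$kind, "'\n", sep = "")
  invisible(x)
}
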