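#' Selection state for linked summary-expression views
#'
#' The front-end interaction contract is modeled as a small state machine so
#' that the response to any sequence of user inputs is well-defined and can
#' be tested exhaustively. Two modes exist: `IDLE` (no genes selected, table
#' shows all genes subject to the search filter) and `GRAPH_SELECT` (at least
#' one gene selected, table filtered to the selection). Point clicks and
#' table-row clicks share one toggle semantic; search is an orthogonal filter
#' that never changes the selection.
#'
#' @return A fresh `SelectionState`: mode `IDLE`, empty ordered selection,
#'   no last-selected gene, empty search text.
#' @seealso [apply_event()]
#' @export
selection_state <- function() {
  structure(list(mode = "IDLE", selected = character(0), last_selected = NULL,
                 search_text = ""),
            class = "SelectionState")
}

#' Interaction events
#'
#' Constructors for the four event types the state machine accepts: clicking
#' a point on the summary plot, clicking a row of the gene table (both toggle
#' that gene's selection), typing in the search box, and clearing the
#' selection.
#'
#' @param gene A gene identifier.
#' @param text Search text (substring filter over the table).
#' @return An event object for [apply_event()].
#' @export
event_point_click <- function(gene) list(type = "point_click", gene = gene)

#' @rdname event_point_click
#' @export
event_row_click <- function(gene) list(type = "row_click", gene = gene)

#' @rdname event_point_click
#' @export
event_search <- function(text) list(type = "search", text = as.character(text))

#' @rdname event_point_click
#' @export
event_clear <- function() list(type = "clear")

#' Apply an interaction event to a selection state
#'
#' Click events toggle the gene's membership in the ordered selection;
#' `last_selected` becomes the clicked gene on addition, or the most recently
#' added remaining gene on removal. The machine is in `GRAPH_SELECT` exactly
#' when the selection is non-empty. Alongside the new state, view directives
#' describe what the linked panels show: the table is filtered to the
#' selection in `GRAPH_SELECT` and to the search text otherwise, and the
#' expression panel shows the most recently selected gene.
#'
#' @param state A [selection_state()].
#' @param event An event from [event_point_click()] and friends.
#' @param gene_ids Character vector of known gene ids; a click on an unknown
#'   gene is an error and leaves the state unchanged.
#' @return List with elements `state` (the new `SelectionState`) and
#'   `directives` (list: `table_filter` one of `"selection"`/`"search"`/
#'   `"none"`, `search_text`, `expression_gene`, `highlighted`).
#' @export
apply_event <- function(state, event, gene_ids) {
  stopifnot(inherits(state, "SelectionState"))
  if (!is.list(event) || is.null(event$type)) {
    stop("malformed event", call. = FALSE)
  }
  if (event$type %in% c("point_click", "row_click")) {
    g <- event$gene
    if (length(g) != 1 || !g %in% gene_ids) {
      stop("unknown gene id: ", g, call. = FALSE)
    }
    if (g %in% state$selected) {
      state$selected <- setdiff(state$selected, g)
      state$last_selected <- if (length(state$selected)) {
        state$selected[[length(state$selected)]]
      }
    } else {
      state$selected <- c(state$selected, g)
      state$last_selected <- g
    }
  } else if (event$type == "search") {
    state$search_text <- event$text
  } else if (event$type == "clear") {
    state$selected <- character(0)
    state$last_selected <- NULL
  } else {
    stop("unknown event type: ", event$type, call. = FALSE)
  }
  state$mode <- if (length(state$selected)) "GRAPH_SELECT" else "IDLE"
  directives <- list(
    table_filter = if (state$mode == "GRAPH_SELECT") {
      "selection"
    } else if (nzchar(state$search_text)) "search" else "none",
    search_text = state$search_text,
    expression_gene = state$last_selected,
    highlighted = state$selected)
  list(state = state, directives = directives)
}

#' @export
print.SelectionState <- function(x, ...) {
  cat("SelectionState <", x$mode, ">: ", length(x$selected),
      " gene(s) selected", sep = "")
  if (length(x$selected)) cat(", last:", x$last_selected)
  cat("\n")
  invisible(x)
}
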