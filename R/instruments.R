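#' Declare a questionnaire instrument
#'
#' An instrument specification describes a scale declaratively: its ordered
#' items, the ordinal response range, optional named subscales, and the short
#' node labels used for its items in the symptom network. The built-in
#' specifications (ITQ, PHQ-9, GAD-7, and the two victimization screens) are
#' available through [default_instruments()].
#'
#' @param name Scale identifier, e.g. `"itq"`.
#' @param items Character vector of ordered item identifiers. These double as
#'   the column suffixes in panel data (`t1_<item>`, `t2_<item>`) unless the
#'   items are unwaved screening columns.
#' @param response_min,response_max Integer bounds of the ordinal response
#'   scale (inclusive).
#' @param subscales Named list of character vectors grouping items into
#'   subscales. Every item may belong to at most one subscale.
#' @param node_labels Per-item labels used in network output; defaults to
#'   `items`.
#'
#' @return An object of class `instrument_spec`.
#' @export
#' @examples
#' phq <- instrument_spec("phq9", paste0("dep", 1:9), 0, 3)
#' phq
instrument_spec <- function(name, items, response_min, response_max,
                            subscales = list(), node_labels = items) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(items), length(items) >= 1L)
  if (anyDuplicated(items)) abort_clpnet("duplicate item identifiers")
  if (!is_scalar_number(response_min) || !is_scalar_number(response_max) ||
      response_min >= response_max) {
    abort_clpnet("`response_min` must be strictly less than `response_max`")
  }
  subscales <- as.list(subscales)
  all_sub <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(all_sub)) {
    abort_clpnet("an item may belong to at most one subscale")
  }
  if (length(setdiff(all_sub, items))) {
    abort_clpnet(sprintf("subscale items not in the item set: %s",
                         paste(setdiff(all_sub, items), collapse = ", ")))
  }
  if (length(node_labels) != length(items)) {
    abort_clpnet("`node_labels` must have one label per item")
  }
  structure(
    list(name = name, items = items,
         response_min = as.integer(response_min),
         response_max = as.integer(response_max),
         subscales = subscales, node_labels = node_labels),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s: %d items scored %d-%d, %d subscale(s)\n",
              x$name, length(x$items), x$response_min, x$response_max,
              length(x$subscales)))
  invisible(x)
}

#' Read instrument definitions from a YAML file
#'
#' @param path Path to a YAML file laid out like the bundled
#'   `extdata/instruments.yaml`.
#' @return Named list of [instrument_spec()] objects.
#' @export
read_instruments <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    instrument_spec(nm, entry$items, entry$response_min, entry$response_max,
                    subscales = entry$subscales %||% list())
  })
  stats::setNames(specs, names(raw))
}

#' Built-in instrument specifications
#'
#' Returns the bundled scale definitions: `itq` (12 CPTSD items, 0-4, six
#' two-item dimensions), `phq9` (9 depression items, 0-3), `gad7` (7 anxiety
#' items, 0-3), `bpbq_victim` (10-item victimization screen, 0-4) and
#' `delaware_victim` (17-item victimization screen, 1-6).
#'
#' @return Named list of [instrument_spec()] objects.
#' @export
#' @examples
#' names(default_instruments())
default_instruments <- function() {
  read_instruments(system.file("extdata", "instruments.yaml",
                               package = "clpnet", mustWork = TRUE))
}

#' Symptom node labels of the 28-node CPTSD/depression/anxiety network
#'
#' The canonical node set: 12 ITQ items, 9 PHQ-9 items, 7 GAD-7 items,
#' in instrument order.
#'
#' @return Character vector of length 28.
#' @export
symptom_nodes <- function() {
  ins <- default_instruments()
  c(ins$itq$items, ins$phq9$items, ins$gad7$items)
}
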