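#' Construct an interactome from canonical edge rows
#'
#' An `interactome` is a tibble of undirected edges over positive-integer gene
#' identifiers (the field convention is NCBI Gene IDs), one row per distinct
#' interaction, with columns `from` and `to` in canonical order
#' (`from < to`), an optional numeric `score`, and optional support columns
#' (`support`, `networks`) added by composite construction. The node set is
#' implied by the edge list: a gene belongs to the network iff it has at
#' least one edge.
#'
#' @param edges data frame with integer columns `from`, `to` (already
#'   canonical: `from < to`, no self-loops, no duplicates) and optionally
#'   `score` and support columns.
#' @param name network name.
#' @param classification optional label, one of `"experimental"`,
#'   `"curated"`, `"composite"`.
#' @return an `interactome` tibble.
#' @seealso [standardize_network()] which builds one from raw records.
#' @export
new_interactome <- function(edges, name = "net", classification = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) >= 0 && all(c("from", "to") %in% names(edges))) {
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
  }
  if (nrow(edges) > 0) {
    stopifnot(is.numeric(edges$from), is.numeric(edges$to))
    if (any(edges$from >= edges$to)) {
      stop("edges must be canonical: from < to (no self-loops)", call. = FALSE)
    }
    if (anyDuplicated(edge_key(edges$from, edges$to)) > 0) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
    if (any(edges$from < 1)) stop("gene identifiers must be >= 1", call. = FALSE)
  }
  structure(
    edges,
    class = c("interactome", class(tibble::tibble())),
    net_name = name,
    classification = classification
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf(
    "# Interactome '%s': %d nodes, %d edges%s\n",
    net_name(x), length(interactome_nodes(x)), nrow(x),
    if (!is.null(attr(x, "classification"))) {
      paste0(" (", attr(x, "classification"), ")")
    } else ""
  ))
  NextMethod()
}

#' Network name of an interactome
#' @param net an `interactome`.
#' @return the name as a string.
#' @export
net_name <- function(net) attr(net, "net_name") %||% "net"

#' Node set of an interactome
#'
#' Edge-list semantics: the node set is the set of edge endpoints, so every
#' node has degree at least one.
#'
#' @param net an `interactome`.
#' @return sorted integer vector of gene identifiers.
#' @export
interactome_nodes <- function(net) {
  sort(unique(c(net$from, net$to)))
}

#' Node degrees of an interactome
#' @param net an `interactome`.
#' @return named integer vector (names are gene identifiers).
#' @export
interactome_degrees <- function(net) {
  nodes <- interactome_nodes(net)
  d <- table(factor(c(net$from, net$to), levels = nodes))
  stats::setNames(as.integer(d), nodes)
}

# canonical string key for an undirected edge; used for set operations
edge_key <- function(from, to) paste(from, to, sep = "|")

interactome_edge_keys <- function(net) edge_key(net$from, net$to)

# canonicalize a two-column pair table: drop self pairs, order endpoints
canonical_pairs <- function(a, b) {
  keep <- a != b
  tibble::tibble(from = pmin(a[keep], b[keep]), to = pmax(a[keep], b[keep]))
}

#' Convert an interactome to an igraph graph
#' @param net an `interactome`.
#' @return an undirected simple `igraph` graph whose vertex names are the
#'   gene identifiers.
#' @export
as_igraph <- function(net) {
  nodes <- interactome_nodes(net)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net$from), to = as.character(net$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

has_col <- function(df, col) col %in% names(df)
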