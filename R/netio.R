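#' Read a raw edge-list file
#'
#' Reads a columnar interaction file (TSV by default) into raw identifier
#' records, with no standardization applied. Lines starting with the comment
#' character are skipped; a leading header line can be skipped explicitly.
#'
#' @param path file path.
#' @param col_a,col_b 1-based indices of the two identifier columns.
#' @param col_score optional 1-based index of a numeric score column.
#' @param sep field separator (default tab).
#' @param comment_char lines starting with this character are skipped.
#' @param skip number of leading non-comment lines to skip (e.g. a header).
#' @return tibble with character columns `id_a`, `id_b` and, when
#'   `col_score` is given, numeric `score`, in file order.
#' @export
read_edge_list <- function(path, col_a = 1, col_b = 2, col_score = NULL,
                           sep = "\t", comment_char = "#", skip = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  line_no <- seq_along(lines)
  keep <- !startsWith(trimws(lines, "left"), comment_char) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (skip > 0 && length(lines) > 0) {
    drop <- seq_len(min(skip, length(lines)))
    lines <- lines[-drop]
    line_no <- line_no[-drop]
  }
  if (length(lines) == 0) {
    out <- tibble::tibble(id_a = character(), id_b = character())
    if (!is.null(col_score)) out$score <- numeric()
    return(out)
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  need <- max(col_a, col_b, col_score %||% 0)
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d: expected at least %d columns", line_no[bad[1]], need),
         call. = FALSE)
  }
  out <- tibble::tibble(
    id_a = vapply(fields, `[[`, "", col_a),
    id_b = vapply(fields, `[[`, "", col_b)
  )
  if (!is.null(col_score)) {
    out$score <- as.numeric(vapply(fields, `[[`, "", col_score))
  }
  out
}

#' Read an identifier-mapping table
#'
#' Two-column TSV: raw identifier, integer gene id. Raw identifiers mapping
#' to more than one gene id are an error (the mapping must be many-to-one).
#'
#' @param path file path.
#' @return named integer vector: `map[raw_id] -> gene id`.
#' @export
read_id_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = c("character", "character"),
                           col.names = c("raw", "gene"))
  if (anyDuplicated(raw$raw) > 0) {
    dups <- unique(raw$raw[duplicated(raw$raw)])
    stop("raw identifier maps to more than one gene id: ",
         paste(utils::head(dups, 3), collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.integer(raw$gene), raw$raw)
}

#' Map raw identifiers in edge records to integer gene ids
#'
#' Records with any unmappable endpoint are dropped and counted, not fatal.
#' The default mapping interprets identifiers as integer text directly.
#'
#' @param records tibble from [read_edge_list()].
#' @param idmap named integer vector (`raw -> gene id`), or `NULL` for the
#'   identity mapping of integer-text identifiers.
#' @return list with `records` (tibble: integer `a`, `b`, optional `score`)
#'   and `n_unmapped` (count of dropped records).
#' @export
map_identifiers <- function(records, idmap = NULL) {
  if (is.null(idmap)) {
    a <- suppressWarnings(as.integer(records$id_a))
    b <- suppressWarnings(as.integer(records$id_b))
  } else {
    a <- unname(idmap[records$id_a])
    b <- unname(idmap[records$id_b])
  }
  ok <- !is.na(a) & !is.na(b)
  out <- tibble::tibble(a = a[ok], b = b[ok])
  if (has_col(records, "score")) out$score <- records$score[ok]
  list(records = out, n_unmapped = sum(!ok))
}

#' Standardize raw interaction records into an interactome
#'
#' Applies the standardization rules used throughout the package: remove
#' self-interactions, expand any n-ary record into all pairwise edges,
#' convert to undirected canonical order (`from < to`), and collapse
#' duplicates. When duplicate edges carry scores, the maximum score is kept
#' (strongest-evidence retention).
#'
#' @param records either a tibble with integer columns `a`, `b` and optional
#'   `score` (as returned by [map_identifiers()]), or a list of integer
#'   membership vectors for n-ary records (each expanded to all pairs).
#' @param name network name.
#' @param classification optional network classification label.
#' @return an `interactome`; empty (with a warning) if no edge survives.
#' @export
standardize_network <- function(records, name = "net", classification = NULL) {
  if (is.data.frame(records)) {
    pairs <- tibble::tibble(a = as.integer(records$a), b = as.integer(records$b))
    score <- if (has_col(records, "score")) as.numeric(records$score) else NULL
  } else {
    # n-ary records: expand each member vector to all C(n,2) pairs
    expanded <- purrr::map(records, function(members) {
      members <- unique(as.integer(members))
      if (length(members) < 2) return(NULL)
      cmb <- utils::combn(members, 2)
      tibble::tibble(a = cmb[1, ], b = cmb[2, ])
    })
    pairs <- dplyr::bind_rows(expanded)
    score <- NULL
  }
  if (nrow(pairs) == 0) {
    warning("no edges after standardization of '", name, "'", call. = FALSE)
    return(new_interactome(tibble::tibble(from = integer(), to = integer()),
                           name = name, classification = classification))
  }
  keep <- pairs$a != pairs$b
  edges <- tibble::tibble(
    from = pmin(pairs$a[keep], pairs$b[keep]),
    to = pmax(pairs$a[keep], pairs$b[keep])
  )
  if (!is.null(score)) edges$score <- score[keep]
  if (nrow(edges) == 0) {
    warning("no edges after standardization of '", name, "'", call. = FALSE)
    return(new_interactome(tibble::tibble(from = integer(), to = integer()),
                           name = name, classification = classification))
  }
  if (has_col(edges, "score")) {
    edges <- edges |>
      dplyr::summarise(score = max(.data$score), .by = c("from", "to"))
  } else {
    edges <- dplyr::distinct(edges, .data$from, .data$to)
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  new_interactome(edges, name = name, classification = classification)
}

#' Retain the top-scoring fraction of edges
#'
#' Keeps the `ceiling(fraction * |E|)` highest-scoring edges (the rule used
#' to trim very large scored source networks to their top 10%). Ties at the
#' cutoff are broken deterministically by a stable sort on
#' (score descending, edge lexicographic ascending). Nodes isolated by the
#' filter are dropped (edge-list semantics).
#'
#' @param net a scored `interactome`.
#' @param fraction fraction of edges to retain, in (0, 1].
#' @return the filtered `interactome`.
#' @export
filter_top_fraction <- function(net, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!has_col(net, "score") || anyNA(net$score)) {
    stop("filter_top_fraction requires a score on every edge", call. = FALSE)
  }
  n_keep <- ceiling(fraction * nrow(net))
  ord <- order(-net$score, net$from, net$to)
  kept <- tibble::as_tibble(net)[ord[seq_len(n_keep)], ] |>
    dplyr::arrange(.data$from, .data$to)
  new_interactome(kept, name = net_name(net),
                  classification = attr(net, "classification"))
}

#' Jaccard similarity of two interactomes' edge sets
#'
#' @param net_a,net_b standardized `interactome`s.
#' @return |E_A intersect E_B| / |E_A union E_B|.
#' @export
network_jaccard <- function(net_a, net_b) {
  ka <- interactome_edge_keys(net_a)
  kb <- interactome_edge_keys(net_b)
  u <- length(union(ka, kb))
  if (u == 0) stop("both networks are empty", call. = FALSE)
  length(intersect(ka, kb)) / u
}

#' Summary statistics of an interactome
#'
#' @param net an `interactome`.
#' @return list with `n_nodes`, `n_edges`, `degrees` (named, sorted
#'   descending), and `log10_edges` (the network-size covariate S used by
#'   the recovery parameter formulas; `NA` for an empty network).
#' @export
network_summary <- function(net) {
  d <- interactome_degrees(net)
  list(
    n_nodes = length(d),
    n_edges = nrow(net),
    degrees = sort(d, decreasing = TRUE),
    log10_edges = if (nrow(net) > 0) log10(nrow(net)) else NA_real_
  )
}

#' Write an interactome as a TSV edge list
#'
#' Canonical edges with a header line; optionally includes composite support
#' columns (integer support count and semicolon-joined supporting network
#' names). Round-trips losslessly through [read_edge_list()] +
#' [standardize_network()].
#'
#' @param net an `interactome`.
#' @param path output path.
#' @param include_support include `support`/`networks` columns when present.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(net, path, include_support = FALSE) {
  out <- tibble::as_tibble(net)
  cols <- c("from", "to", intersect("score", names(out)))
  if (include_support) cols <- c(cols, intersect(c("support", "networks"), names(out)))
  out <- out[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT-style gene-set file
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path file path.
#' @return tibble with columns `set` (name), `source` (the description
#'   field), `gene` (integer), one row per membership.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(line, 1, 40), call. = FALSE)
    tibble::tibble(set = f[1], source = f[2],
                   gene = unique(as.integer(f[-(1:2)])))
  })
  dplyr::bind_rows(rows)
}

#' Write gene sets to a GMT-style file
#'
#' @param gene_sets tibble with columns `set`, `gene`, optional `source`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  src <- if (has_col(gene_sets, "source")) gene_sets$source else rep("na", nrow(gene_sets))
  split_sets <- split(gene_sets$gene, gene_sets$set)
  split_src <- vapply(split(src, gene_sets$set), `[[`, "", 1)
  lines <- vapply(names(split_sets), function(nm) {
    paste(c(nm, split_src[[nm]], split_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
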