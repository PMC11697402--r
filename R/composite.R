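#' Count per-edge support across a corpus of interactomes
#'
#' Indexes every canonical edge appearing in at least one network with the
#' number and names of the networks containing it. Networks must carry
#' distinct names.
#'
#' @param networks list of standardized `interactome`s (named, or carrying
#'   distinct `net_name()`s).
#' @return tibble with columns `from`, `to`, `support` (integer count),
#'   `networks` (semicolon-joined supporting names), sorted by canonical
#'   edge.
#' @export
count_edge_support <- function(networks) {
  nms <- names(networks) %||% purrr::map_chr(networks, net_name)
  if (is.null(names(networks))) names(networks) <- nms
  if (anyDuplicated(nms) > 0) stop("duplicate network names", call. = FALSE)
  all_edges <- purrr::imap(networks, function(net, nm) {
    tibble::tibble(from = net$from, to = net$to, network = nm)
  }) |>
    dplyr::bind_rows()
  all_edges |>
    dplyr::summarise(support = dplyr::n(),
                     networks = paste(sort(.data$network), collapse = ";"),
                     .by = c("from", "to")) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Global composite network by minimum support
#'
#' Keeps every interaction present in at least `k` of the corpus networks
#' (`k = 1` is the plain union). Support annotations are carried on the
#' output edges.
#'
#' @param support a support index from [count_edge_support()].
#' @param k minimum number of supporting networks.
#' @param name output network name.
#' @return a composite `interactome` with `support` and `networks` columns.
#' @export
global_composite <- function(support, k, name = sprintf("G_k%d", k)) {
  stopifnot(k >= 1)
  kept <- support |> dplyr::filter(.data$support >= k)
  new_interactome(kept, name = name, classification = "composite")
}

#' Ranked composite network from the top-k networks
#'
#' Counts support only within the `k` best-performing networks of a
#' pre-ranked corpus (best first) and keeps interactions supported by at
#' least `m` of them. The ranking is part of the input contract — it is
#' typically the overall centralized-rank ordering of size-adjusted
#' gene-set recovery performance from [benchmark_recovery()].
#'
#' @param networks list of `interactome`s sorted best-first.
#' @param k number of top networks to consider.
#' @param m minimum support among the top `k`.
#' @param name output network name.
#' @param max_edges optional cap on the number of output interactions;
#'   edges are retained highest-support-first, then by canonical edge
#'   order, until the cap is met.
#' @return a composite `interactome` with `support` and `networks` columns.
#' @export
ranked_composite <- function(networks, k, m, name = sprintf("R_k%d_m%d", k, m),
                             max_edges = NULL) {
  stopifnot(m >= 1, m <= k, k <= length(networks))
  support <- count_edge_support(networks[seq_len(k)])
  kept <- support |> dplyr::filter(.data$support >= m)
  if (!is.null(max_edges) && nrow(kept) > max_edges) {
    ord <- order(-kept$support, kept$from, kept$to)
    kept <- kept[sort(ord[seq_len(max_edges)]), ]
  }
  new_interactome(kept, name = name, classification = "composite")
}

#' Named ranked-composite presets
#'
#' Configuration aliases for the published consensus constructions:
#' `PCNet2.0` (top 15 networks, support >= 2), `PCNet2.1` (top 8, support
#' >= 2, capped at 2e6 interactions), `PCNet2.2` (top 10 of a
#' co-citation-free ranking, support >= 2). Applying a preset to a user
#' corpus reproduces the construction rule, not any specific published
#' network (that requires the original source corpus).
#'
#' @param preset one of `"PCNet2.0"`, `"PCNet2.1"`, `"PCNet2.2"`.
#' @return list with `k`, `m`, and optional `max_edges`.
#' @export
composite_preset <- function(preset = c("PCNet2.0", "PCNet2.1", "PCNet2.2")) {
  preset <- match.arg(preset)
  switch(preset,
    "PCNet2.0" = list(k = 15, m = 2, max_edges = NULL),
    "PCNet2.1" = list(k = 8, m = 2, max_edges = 2e6),
    "PCNet2.2" = list(k = 10, m = 2, max_edges = NULL)
  )
}
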