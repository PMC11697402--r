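#' Read a communities file
#'
#' TSV with a community id and a comma-joined member list per line — the
#' flat output format of hierarchical community detection tools.
#'
#' @param path file path.
#' @return tibble with columns `community`, `gene` (integer), one row per
#'   membership.
#' @export
read_communities <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  rows <- purrr::map(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed community line: ", substr(line, 1, 40),
                            call. = FALSE)
    tibble::tibble(community = f[1],
                   gene = unique(as.integer(strsplit(f[2], ",", fixed = TRUE)[[1]])))
  })
  dplyr::bind_rows(rows)
}

#' Recover reference complexes from predicted communities
#'
#' A reference complex is recovered when some community reaches a set
#' Jaccard similarity of at least `threshold` with it.
#'
#' @param communities tibble with columns `community`, `gene`.
#' @param complexes tibble with columns `complex`, `gene`.
#' @param threshold Jaccard recovery threshold (default 0.5).
#' @return list with `n_recovered` and `matches` (tibble: complex,
#'   best_community, jaccard, recovered).
#' @export
recover_complexes <- function(communities, complexes, threshold = 0.5) {
  comm_sets <- split(communities$gene, communities$community)
  cplx_sets <- split(complexes$gene, complexes$complex)
  stopifnot(length(comm_sets) > 0, length(cplx_sets) > 0)
  matches <- purrr::imap(cplx_sets, function(members, nm) {
    js <- vapply(comm_sets, jaccard_sets, 0, b = members)
    best <- which.max(js)
    tibble::tibble(complex = nm, best_community = names(comm_sets)[best],
                   jaccard = js[[best]], recovered = js[[best]] >= threshold)
  }) |>
    dplyr::bind_rows()
  list(n_recovered = sum(matches$recovered), matches = matches)
}

#' Build a term-based semantic-similarity provider
#'
#' Reference provider backed by a gene-to-term association table, one per
#' annotation branch (e.g. process/function/component). Pairwise similarity
#' is either the Jaccard index of the two genes' term sets or the shared
#' term count; genes without annotation score 0 against everything.
#'
#' @param associations named list of (branch name -> tibble with columns
#'   `term`, `gene`); typically three branches.
#' @param method `"jaccard"` or `"overlap"`.
#' @return a function `f(u, v)` returning a named numeric vector of
#'   per-branch similarities.
#' @export
term_similarity_provider <- function(associations, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  branch_sets <- purrr::map(associations, function(assoc) {
    split(assoc$term, assoc$gene)
  })
  function(u, v) {
    vapply(branch_sets, function(sets) {
      tu <- sets[[as.character(u)]]
      tv <- sets[[as.character(v)]]
      if (is.null(tu) || is.null(tv)) return(0)
      switch(method,
             jaccard = jaccard_sets(tu, tv),
             overlap = length(intersect(tu, tv)))
    }, 0)
  }
}

#' Functional-coherence score of a community
#'
#' Sums, over all unordered member pairs, the per-branch semantic
#' similarities supplied by the provider, and scales the total by 1/3 (the
#' number of annotation branches). As a pair-summed total the value grows
#' with community size, so the per-pair mean is reported alongside it.
#' Communities at or above `max_size` members are skipped (returned as
#' `NA`), since pairwise similarity becomes uninformative and quadratic in
#' cost for very large assemblies.
#'
#' @param members integer vector of community gene ids (>= 2).
#' @param provider pairwise similarity function from
#'   [term_similarity_provider()] (or any `f(u, v)` returning a numeric
#'   vector of branch similarities).
#' @param max_size size threshold above which the score is skipped.
#' @return list with `go_score` (the 1/3-scaled pair total) and
#'   `go_score_per_pair` (the per-pair mean).
#' @export
community_go_score <- function(members, provider, max_size = 200) {
  members <- unique(members)
  if (length(members) < 2) stop("community must have >= 2 members", call. = FALSE)
  if (length(members) >= max_size) {
    return(list(go_score = NA_real_, go_score_per_pair = NA_real_))
  }
  pairs <- utils::combn(members, 2)
  totals <- vapply(seq_len(ncol(pairs)), function(p) {
    sum(provider(pairs[1, p], pairs[2, p]))
  }, 0)
  list(go_score = sum(totals) / 3,
       go_score_per_pair = mean(totals) / 3)
}

#' Mean local clustering coefficient of a community
#'
#' Average local clustering coefficient over the community members, computed
#' on the subgraph induced by the community in the network. Members with
#' fewer than two neighbors in the induced subgraph, or absent from the
#' network entirely, contribute 0.
#'
#' @param members integer vector of community gene ids (>= 2).
#' @param net an `interactome`.
#' @param max_size size threshold above which the score is skipped (`NA`).
#' @return mean clustering coefficient in \[0, 1\] (or `NA` if skipped).
#' @export
community_clustering <- function(members, net, max_size = 200) {
  members <- unique(members)
  if (length(members) < 2) stop("community must have >= 2 members", call. = FALSE)
  if (length(members) >= max_size) return(NA_real_)
  sub <- tibble::as_tibble(net)[net$from %in% members & net$to %in% members,
                                c("from", "to")]
  if (nrow(sub) == 0) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$from), to = as.character(sub$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(members))
  )
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(cc)
}

#' Score all communities of a detection run
#'
#' Per-community functional-coherence and topology scores plus reference
#' complex recovery for a whole communities table.
#'
#' @param communities tibble with columns `community`, `gene`.
#' @param net an `interactome`.
#' @param complexes optional tibble with columns `complex`, `gene`.
#' @param provider optional semantic-similarity provider.
#' @param max_size size threshold for the per-community scores.
#' @return list with `communities` (tibble: community, size, clustering,
#'   go_score, go_score_per_pair) and `recovery` (from
#'   [recover_complexes()], or `NULL`).
#' @export
score_assemblies <- function(communities, net, complexes = NULL,
                             provider = NULL, max_size = 200) {
  per_comm <- communities |>
    dplyr::summarise(
      size = dplyr::n_distinct(.data$gene),
      clustering = community_clustering(.data$gene, net, max_size = max_size),
      go_score = if (is.null(provider)) NA_real_ else {
        community_go_score(.data$gene, provider, max_size = max_size)$go_score
      },
      go_score_per_pair = if (is.null(provider)) NA_real_ else {
        community_go_score(.data$gene, provider, max_size = max_size)$go_score_per_pair
      },
      .by = "community"
    )
  recovery <- if (!is.null(complexes)) recover_complexes(communities, complexes)
  list(communities = per_comm, recovery = recovery)
}
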