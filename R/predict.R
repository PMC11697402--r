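#' Neighborhood Jaccard similarity of two nodes
#'
#' `J(u, v) = |N(u) n N(v)| / |N(u) u N(v)|` over direct neighbors; 0 when
#' both neighborhoods are empty.
#'
#' @param net an `interactome`.
#' @param u,v gene ids present in the network.
#' @return similarity in \[0, 1\].
#' @export
node_jaccard <- function(net, u, v) {
  adj <- adjacency_list(net)
  jaccard_sets(adj[[as.character(u)]], adj[[as.character(v)]])
}

jaccard_sets <- function(a, b) {
  un <- length(union(a, b))
  if (un == 0) return(0)
  length(intersect(a, b)) / un
}

# named list: gene id (character) -> integer neighbor vector
adjacency_list <- function(net) {
  nodes <- interactome_nodes(net)
  ends <- c(net$from, net$to)
  nbr <- c(net$to, net$from)
  split(nbr, factor(ends, levels = nodes))
}

#' Maximum topological similarity of a candidate pair
#'
#' The MPS primary score: the best neighborhood Jaccard between any
#' neighbor of `x` and `y`, plus the best between any neighbor of `y` and
#' `x` — high when one endpoint resembles the other's interactors.
#'
#' @param net an `interactome`.
#' @param x,y gene ids with degree >= 1.
#' @return `max_{a in N(x)} J(a, y) + max_{b in N(y)} J(b, x)`.
#' @export
max_similarity <- function(net, x, y) {
  adj <- adjacency_list(net)
  max_similarity_adj(adj, as.character(x), as.character(y))
}

max_similarity_adj <- function(adj, x, y) {
  nx <- adj[[x]]
  ny <- adj[[y]]
  if (length(nx) == 0 || length(ny) == 0) return(NA_real_)
  t1 <- max(vapply(as.character(nx), function(a) {
    jaccard_sets(adj[[a]], ny)
  }, 0))
  t2 <- max(vapply(as.character(ny), function(b) {
    jaccard_sets(adj[[b]], nx)
  }, 0))
  t1 + t2
}

#' Preferential attachment score
#'
#' The MPS secondary score: the product of the two node degrees.
#'
#' @param net an `interactome`.
#' @param x,y gene ids present in the network.
#' @return `degree(x) * degree(y)`.
#' @export
preferential_attachment <- function(net, x, y) {
  d <- interactome_degrees(net)
  unname(d[as.character(x)] * d[as.character(y)])
}

#' L3 path-count interaction scores
#'
#' Scores a candidate pair (X, Y) by the number of length-3 paths
#' X-U-V-Y, each weighted by `1 / sqrt(k_U k_V)` to damp paths through
#' hubs. Computed for all non-adjacent pairs via the sparse product
#' `A D^(-1/2) A D^(-1/2) A`; candidates are returned sorted by score
#' descending with deterministic lexicographic tie-breaking on the
#' canonical edge.
#'
#' @param net a standardized `interactome`.
#' @param candidates optional tibble of pairs (`from`, `to`) to score;
#'   default: all non-adjacent pairs with at least one length-3 path.
#' @return tibble with columns `from`, `to`, `score`, `rank`.
#' @export
l3_scores <- function(net, candidates = NULL) {
  nodes <- interactome_nodes(net)
  n <- length(nodes)
  i <- match(net$from, nodes)
  j <- match(net$to, nodes)
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  dinv <- Matrix::Diagonal(n, 1 / sqrt(Matrix::rowSums(a)))
  l3 <- a %*% dinv %*% a %*% dinv %*% a
  if (is.null(candidates)) {
    tl <- Matrix::summary(methods::as(Matrix::drop0(l3), "TsparseMatrix"))
    keep <- tl$i < tl$j
    cand <- tibble::tibble(from = nodes[tl$i[keep]], to = nodes[tl$j[keep]])
    # drop existing edges
    cand <- cand[!(edge_key(cand$from, cand$to) %in% interactome_edge_keys(net)), ]
  } else {
    cand <- canonical_pairs(as.integer(candidates$from), as.integer(candidates$to))
  }
  idx_a <- match(cand$from, nodes)
  idx_b <- match(cand$to, nodes)
  score <- as.numeric(l3[cbind(idx_a, idx_b)])
  out <- tibble::tibble(from = cand$from, to = cand$to, score = score)
  out <- out[order(-out$score, out$from, out$to), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' MPS candidate ranking
#'
#' Ranks candidate non-edges by maximum topological similarity
#' ([max_similarity()], primary key) and preferential attachment
#' ([preferential_attachment()], secondary key), both descending, with
#' lexicographic canonical-edge tie-breaking. Candidates with an isolated
#' endpoint (undefined similarity) are skipped.
#'
#' @param net a standardized `interactome`.
#' @param candidates optional tibble of pairs (`from`, `to`); default: all
#'   non-adjacent node pairs.
#' @return tibble with columns `from`, `to`, `score` (max similarity),
#'   `secondary` (preferential attachment), `rank`.
#' @export
mps_rank <- function(net, candidates = NULL) {
  nodes <- interactome_nodes(net)
  adj <- adjacency_list(net)
  if (is.null(candidates)) {
    cmb <- utils::combn(nodes, 2)
    cand <- tibble::tibble(from = cmb[1, ], to = cmb[2, ])
    cand <- cand[!(edge_key(cand$from, cand$to) %in% interactome_edge_keys(net)), ]
  } else {
    cand <- canonical_pairs(as.integer(candidates$from), as.integer(candidates$to))
    cand <- cand[cand$from %in% nodes & cand$to %in% nodes, ]
  }
  deg <- lengths(adj)
  sims <- vapply(seq_len(nrow(cand)), function(r) {
    max_similarity_adj(adj, as.character(cand$from[r]), as.character(cand$to[r]))
  }, 0)
  pa <- unname(deg[as.character(cand$from)] * deg[as.character(cand$to)])
  out <- tibble::tibble(from = cand$from, to = cand$to, score = sims,
                        secondary = as.numeric(pa))
  out <- out[!is.na(out$score), ]
  out <- out[order(-out$score, -out$secondary, out$from, out$to), ]
  out$rank <- seq_len(max(nrow(out), 0))
  out
}

#' Precision among the top-k ranked candidates
#'
#' The fraction of the first `k` candidates of a ranked prediction list
#' that are true positives. Selection of the top `k` uses a partial sort on
#' the score keys, so the full candidate list is never fully ordered.
#'
#' @param ranked tibble of ranked candidates (`from`, `to`, `score`,
#'   optional `secondary`), or one already carrying a `rank` column.
#' @param positives tibble of positive pairs (`from`, `to`), canonical.
#' @param k number of top predictions to assess; if the list is shorter,
#'   all available predictions are used with a warning.
#' @return precision in \[0, 1\].
#' @export
precision_at_k <- function(ranked, positives, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (nrow(ranked) < k) {
    warning("fewer ranked candidates (", nrow(ranked), ") than k = ", k)
    k <- nrow(ranked)
  }
  top <- top_k_candidates(ranked, k)
  mean(edge_key(top$from, top$to) %in% edge_key(positives$from, positives$to))
}

# partial selection of the top k by (score desc, secondary desc, edge lexico)
top_k_candidates <- function(ranked, k) {
  if ("rank" %in% names(ranked) && !is.unsorted(ranked$rank)) {
    return(ranked[seq_len(k), ])
  }
  score <- ranked$score
  if (k < nrow(ranked)) {
    # partial sort to find the score cutoff, then order only the head
    cutoff <- -sort(-score, partial = k)[k]
    head_idx <- which(score >= cutoff)
  } else {
    head_idx <- seq_len(nrow(ranked))
  }
  head <- ranked[head_idx, ]
  if (!has_col(head, "secondary")) {
    ord <- order(-head$score, head$from, head$to)
  } else {
    ord <- order(-head$score, -head$secondary, head$from, head$to)
  }
  head[ord[seq_len(k)], ]
}

#' Cross-validated precision@k of an interaction-prediction algorithm
#'
#' Splits the edge set into `n_folds` folds (edges shuffled under `seed`),
#' scores candidates with the training graph (90% of edges), and evaluates
#' precision@k against the held-out 10%, with `k` set to the evaluable
#' test-set size. Held-out edges with an endpoint of degree zero in the
#' training graph cannot be predicted from topology and are excluded from
#' both the positives and `k`.
#'
#' @param net a standardized `interactome`.
#' @param algorithm `"l3"` or `"mps"`.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return a `cv_precision` tibble: one row per evaluated fold with
#'   columns `fold`, `k`, `n_excluded`, `p_at_k`, plus attribute
#'   `mean_p_at_k`.
#' @export
cross_validate <- function(net, algorithm = c("l3", "mps"), n_folds = 10,
                           seed = 1) {
  algorithm <- match.arg(algorithm)
  m <- nrow(net)
  if (m < n_folds) stop("need at least n_folds edges", call. = FALSE)
  fold_of <- withr::with_seed(seed, {
    sample(rep(seq_len(n_folds), length.out = m))
  })
  rows <- purrr::map(seq_len(n_folds), function(f) {
    test <- tibble::as_tibble(net)[fold_of == f, c("from", "to")]
    train <- new_interactome(
      tibble::as_tibble(net)[fold_of != f, c("from", "to")],
      name = paste0(net_name(net), "_fold", f)
    )
    train_nodes <- interactome_nodes(train)
    evaluable <- test$from %in% train_nodes & test$to %in% train_nodes
    k <- sum(evaluable)
    if (k == 0) {
      warning("fold ", f, " has no evaluable test edges; skipped")
      return(NULL)
    }
    ranked <- switch(algorithm, l3 = l3_scores(train), mps = mps_rank(train))
    tibble::tibble(fold = f, k = k, n_excluded = sum(!evaluable),
                   p_at_k = precision_at_k(ranked, test[evaluable, ], k))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cv_precision", class(tibble::tibble())),
            mean_p_at_k = mean(out$p_at_k), algorithm = algorithm)
}

#' Precision@k against an external interaction set
#'
#' Scores candidates with the full network and evaluates against an
#' external positive set (e.g. complex- or pathway-derived interactions).
#' External edges already present in the network are excluded, as are edges
#' with an endpoint absent from the network (prediction impossible);
#' `k` is the number of remaining positives.
#'
#' @param net a standardized `interactome`.
#' @param external tibble of canonical positive edges (`from`, `to`).
#' @param algorithm `"l3"` or `"mps"`.
#' @return list with `k`, `n_excluded`, `p_at_k`.
#' @export
evaluate_external <- function(net, external, algorithm = c("l3", "mps")) {
  algorithm <- match.arg(algorithm)
  nodes <- interactome_nodes(net)
  in_net <- edge_key(external$from, external$to) %in% interactome_edge_keys(net)
  has_nodes <- external$from %in% nodes & external$to %in% nodes
  evaluable <- !in_net & has_nodes
  k <- sum(evaluable)
  if (k == 0) stop("nothing to evaluate: no external edge is both novel and predictable",
                   call. = FALSE)
  ranked <- switch(algorithm, l3 = l3_scores(net), mps = mps_rank(net))
  list(k = k, n_excluded = sum(!evaluable),
       p_at_k = precision_at_k(ranked, external[evaluable, ], k))
}

#' Corpus support of top predictions
#'
#' Annotates the top `top_n` predictions with the number of corpus networks
#' that already contain each predicted interaction; predictions with zero
#' coverage are flagged previously unreported.
#'
#' @param ranked ranked candidate tibble (`from`, `to`, ...).
#' @param networks list of corpus `interactome`s.
#' @param top_n number of top predictions to annotate (default 100).
#' @return tibble of the top predictions with `support` and
#'   `previously_unreported` columns.
#' @export
prediction_coverage <- function(ranked, networks, top_n = 100) {
  if (top_n > nrow(ranked)) {
    warning("fewer predictions (", nrow(ranked), ") than top_n = ", top_n)
    top_n <- nrow(ranked)
  }
  top <- top_k_candidates(ranked, top_n)
  support <- count_edge_support(networks)
  idx <- match(edge_key(top$from, top$to), edge_key(support$from, support$to))
  top$support <- ifelse(is.na(idx), 0L, support$support[idx])
  top$previously_unreported <- top$support == 0L
  top
}
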