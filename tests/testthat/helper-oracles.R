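# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, full enumeration) and share no code
# with the implementations they verify.

# random small interactome for property tests
random_net <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(seq_len(n_nodes), 2))
    pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    new_interactome(
      tibble::tibble(from = pairs[pick, 1], to = pairs[pick, 2]) |>
        dplyr::arrange(from, to),
      name = paste0("rand", seed)
    )
  })
}

neighbors_of <- function(net, x) {
  sort(unique(c(net$to[net$from == x], net$from[net$to == x])))
}

# L3 by explicit path enumeration: sum over u in N(x), v in N(y), u~v
brute_l3 <- function(net, x, y) {
  deg <- interactome_degrees(net)
  keys <- paste(net$from, net$to)
  has_edge <- function(a, b) paste(min(a, b), max(a, b)) %in% keys
  total <- 0
  for (u in neighbors_of(net, x)) {
    for (v in neighbors_of(net, y)) {
      if (u != v && has_edge(u, v)) {
        total <- total + 1 / sqrt(deg[[as.character(u)]] * deg[[as.character(v)]])
      }
    }
  }
  total
}

brute_jaccard <- function(net, u, v) {
  nu <- neighbors_of(net, u)
  nv <- neighbors_of(net, v)
  if (length(union(nu, nv)) == 0) return(0)
  length(intersect(nu, nv)) / length(union(nu, nv))
}

brute_max_similarity <- function(net, x, y) {
  nx <- neighbors_of(net, x)
  ny <- neighbors_of(net, y)
  if (length(nx) == 0 || length(ny) == 0) return(NA_real_)
  max(vapply(nx, function(a) brute_jaccard(net, a, y), 0)) +
    max(vapply(ny, function(b) brute_jaccard(net, b, x), 0))
}

# quadratic-time AUPRC from the step PR curve: precision at each positive rank
brute_auprc <- function(scores, is_positive) {
  ord <- order(-scores)
  pos <- is_positive[ord]
  p_at <- numeric(0)
  for (i in seq_along(pos)) {
    if (pos[i]) p_at <- c(p_at, sum(pos[seq_len(i)]) / i)
  }
  mean(p_at)
}

# brute-force composite membership: per-edge counting over the corpus
brute_composite_edges <- function(networks, k) {
  all_keys <- unique(unlist(lapply(networks, function(n) paste(n$from, n$to))))
  counts <- vapply(all_keys, function(key) {
    sum(vapply(networks, function(n) key %in% paste(n$from, n$to), TRUE))
  }, 0L)
  sort(all_keys[counts >= k])
}
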