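#' Generate a synthetic interactome
#'
#' Random simple graphs for pipeline testing at desk scale: an
#' Erdos-Renyi model, or a heavy-tailed configuration-style model whose
#' expected degrees follow a power law (giving the hub structure real
#' interactomes show). Output is standardized and bit-reproducible under
#' the seed. Defaults (1000 nodes, ~10000 edges) are large enough for
#' stable statistics and small enough for seconds-scale runs.
#'
#' @param n_nodes number of nodes.
#' @param model `"erdos_renyi"` or `"powerlaw_configuration"`.
#' @param n_edges target edge count (realized count can be slightly lower
#'   after simplification in the power-law model).
#' @param power exponent of the power-law expected-degree sequence.
#' @param seed RNG seed.
#' @param name network name.
#' @return an `interactome` over gene ids `1..n_nodes` (nodes left isolated
#'   by the draw are absent, per edge-list semantics).
#' @export
generate_network <- function(n_nodes = 1000,
                             model = c("erdos_renyi", "powerlaw_configuration"),
                             n_edges = 10000, power = 2.2, seed = 1,
                             name = "synthetic") {
  model <- match.arg(model)
  stopifnot(n_nodes >= 2, n_edges >= 1)
  if (n_edges > choose(n_nodes, 2)) stop("requested density exceeds 1", call. = FALSE)
  edges <- withr::with_seed(seed, {
    if (model == "erdos_renyi") {
      g <- igraph::sample_gnm(n_nodes, n_edges)
    } else {
      w <- (seq_len(n_nodes))^(-1 / (power - 1))
      g <- igraph::sample_fitness(n_edges, fitness.out = w)
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    canonical_pairs(as.integer(el[, 1]), as.integer(el[, 2]))
  })
  edges <- dplyr::distinct(edges) |> dplyr::arrange(.data$from, .data$to)
  new_interactome(edges, name = name)
}

#' Plant a densified module in a network
#'
#' Picks `size` member nodes and raises their internal edge density to
#' `multiplier` times the background density (clipped at 1 with a warning),
#' by adding random internal edges. The member list is returned as ground
#' truth for recovery benchmarking.
#'
#' @param net an `interactome`.
#' @param size module size.
#' @param multiplier target internal density as a multiple of the
#'   background density (>= 1).
#' @param seed RNG seed.
#' @return list with `net` (the densified `interactome`, with the module
#'   members recorded in attribute `planted`) and `members`.
#' @export
plant_module <- function(net, size, multiplier = 10, seed = 1) {
  stopifnot(multiplier >= 1)
  nodes <- interactome_nodes(net)
  stopifnot(size <= length(nodes), size >= 2)
  n <- length(nodes)
  p_bg <- nrow(net) / choose(n, 2)
  p_target <- multiplier * p_bg
  if (p_target > 1) {
    warning("requested internal density > 1; clipped to 1")
    p_target <- 1
  }
  if (multiplier == 1) {
    members <- withr::with_seed(seed, sort(sample(nodes, size)))
    out_net <- net
    attr(out_net, "planted") <- members
    return(list(net = out_net, members = members))
  }
  out <- withr::with_seed(seed, {
    members <- sort(sample(nodes, size))
    cmb <- utils::combn(members, 2)
    internal <- tibble::tibble(from = cmb[1, ], to = cmb[2, ])
    existing <- edge_key(net$from, net$to)
    is_new <- !(edge_key(internal$from, internal$to) %in% existing)
    n_have <- sum(!is_new)
    n_want <- round(p_target * ncol(cmb))
    n_add <- max(n_want - n_have, 0)
    add <- internal[is_new, ][sample(sum(is_new), min(n_add, sum(is_new))), ]
    edges <- dplyr::bind_rows(
      tibble::as_tibble(net)[, c("from", "to")], add
    ) |>
      dplyr::arrange(.data$from, .data$to)
    list(edges = edges, members = members)
  })
  planted_net <- new_interactome(out$edges, name = net_name(net))
  attr(planted_net, "planted") <- out$members
  list(net = planted_net, members = out$members)
}

#' Generate synthetic gene sets over a network
#'
#' Three modes: `planted` returns the network's planted-module ground
#' truth; `random_uniform` samples members uniformly from the nodes;
#' `degree_matched_random` samples members whose degrees match a reference
#' profile (by quintile-of-degree bins), so recovery nulls are not
#' confounded by degree.
#'
#' @param net an `interactome`.
#' @param n_sets number of sets.
#' @param size_range integer range `c(min, max)` of set sizes.
#' @param mode `"planted"`, `"random_uniform"`, or
#'   `"degree_matched_random"`.
#' @param reference integer vector of reference genes for degree matching
#'   (defaults to the network's planted module, if any).
#' @param seed RNG seed.
#' @return tibble with columns `set`, `source`, `gene`.
#' @export
generate_gene_sets <- function(net, n_sets = 5, size_range = c(20, 30),
                               mode = c("random_uniform", "planted",
                                        "degree_matched_random"),
                               reference = NULL, seed = 1) {
  mode <- match.arg(mode)
  nodes <- interactome_nodes(net)
  if (n_sets == 0) {
    return(tibble::tibble(set = character(), source = character(),
                          gene = integer()))
  }
  if (mode == "planted") {
    members <- attr(net, "planted")
    if (is.null(members)) stop("network carries no planted module", call. = FALSE)
    return(tibble::tibble(set = "planted_1", source = "synthetic",
                          gene = members))
  }
  stopifnot(max(size_range) <= length(nodes))
  deg <- interactome_degrees(net)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_sets), function(s) {
      size_pool <- seq(size_range[1], size_range[2])
      size <- size_pool[sample.int(length(size_pool), 1)]
      genes <- if (mode == "random_uniform") {
        sample(nodes, size)
      } else {
        ref <- reference %||% attr(net, "planted")
        if (is.null(ref)) stop("degree matching needs a reference gene set",
                               call. = FALSE)
        degree_matched_sample(deg, ref, size)
      }
      tibble::tibble(set = sprintf("%s_%d", mode, s), source = "synthetic",
                     gene = genes)
    })
    dplyr::bind_rows(rows)
  })
}

# sample genes whose degree distribution matches the reference profile:
# quintile bins of the reference degrees, sampled proportionally
degree_matched_sample <- function(deg, reference, size) {
  ref_deg <- deg[as.character(intersect(reference, as.integer(names(deg))))]
  br <- unique(stats::quantile(deg, probs = seq(0, 1, 0.2)))
  all_bin <- cut(deg, breaks = br, include.lowest = TRUE)
  ref_bin <- cut(ref_deg, breaks = br, include.lowest = TRUE)
  want <- round(size * table(ref_bin) / length(ref_bin))
  picked <- integer(0)
  for (b in levels(all_bin)) {
    pool <- as.integer(names(deg))[all_bin == b]
    k <- min(want[[b]], length(pool))
    if (k > 0) picked <- c(picked, pool[sample.int(length(pool), k)])
  }
  # top up from anywhere if rounding left us short
  if (length(picked) < size) {
    pool <- setdiff(as.integer(names(deg)), picked)
    picked <- c(picked, pool[sample.int(length(pool), size - length(picked))])
  }
  picked[seq_len(size)]
}

#' Generate a synthetic gene annotation table
#'
#' Citation counts and mean expression values whose rank correlation with
#' node degree is controlled through a Gaussian copula — emulating the
#' literature/expression skew of real annotation data, where well-studied,
#' highly expressed genes also have more recorded interactions.
#'
#' @param net an `interactome`.
#' @param correlation_with_degree target rank correlation in \[-1, 1\].
#' @param seed RNG seed.
#' @return tibble with columns `gene`, `citations` (non-negative integer),
#'   `mean_tpm` (non-negative), `abundance` (in \[0, 3\]), `chromosome`.
#' @export
generate_annotations <- function(net, correlation_with_degree = 0.5, seed = 1) {
  stopifnot(abs(correlation_with_degree) <= 1)
  nodes <- interactome_nodes(net)
  deg <- interactome_degrees(net)
  n <- length(nodes)
  rho <- correlation_with_degree
  withr::with_seed(seed, {
    z_deg <- stats::qnorm(rank(deg, ties.method = "random") / (n + 1))
    draw <- function() rho * z_deg + sqrt(max(1 - rho^2, 0)) * stats::rnorm(n)
    tibble::tibble(
      gene = nodes,
      citations = as.integer(round(exp(2 + 1.2 * draw()))),
      mean_tpm = exp(1 + draw()),
      abundance = pmin(pmax(1.5 + 0.75 * draw(), 0), 3),
      chromosome = sprintf("chr%d", 1 + (nodes %% 22))
    )
  })
}

#' Generate a synthetic structure-score background
#'
#' Right-skewed ipTM samples in \[0, 1\] emulating the score distribution
#' of randomly paired proteins (most pairs score low, a thin high tail).
#'
#' @param n_pairs sample size (>= 20; the full-scale background used 1779).
#' @param shape1,shape2 beta-distribution shapes (defaults give positive
#'   skew with mass near 0.1).
#' @param constant if not `NULL`, return a degenerate all-`constant` sample.
#' @param seed RNG seed.
#' @return numeric vector of `n_pairs` ipTM values.
#' @export
generate_af_background <- function(n_pairs = 1779, shape1 = 1.5, shape2 = 10,
                                   constant = NULL, seed = 1) {
  stopifnot(n_pairs >= 20)
  if (!is.null(constant)) return(rep(constant, n_pairs))
  withr::with_seed(seed, stats::rbeta(n_pairs, shape1, shape2))
}

#' Write a full synthetic benchmark scenario to disk
#'
#' Emits the file set the readers consume — network edge list, gene sets
#' (GMT), annotation TSV, and a ground-truth JSON-like TSV — so every file
#' path of the pipeline is exercisable end-to-end.
#'
#' @param dir output directory (created if needed).
#' @param n_nodes,n_edges network scale.
#' @param module_size,multiplier planted-module shape.
#' @param seed RNG seed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synth_scenario <- function(dir, n_nodes = 500, n_edges = 4000,
                                 module_size = 25, multiplier = 10, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(n_nodes, "erdos_renyi", n_edges, seed = seed)
  planted <- plant_module(net, module_size, multiplier, seed = seed + 1)
  sets <- dplyr::bind_rows(
    generate_gene_sets(planted$net, mode = "planted"),
    generate_gene_sets(planted$net, n_sets = 3, size_range = c(20, 30),
                       mode = "random_uniform", seed = seed + 2)
  )
  annot <- generate_annotations(planted$net, 0.5, seed = seed + 3)
  paths <- c(
    net = file.path(dir, "net.tsv"),
    sets = file.path(dir, "sets.gmt"),
    annot = file.path(dir, "annot.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_edge_list(planted$net, paths["net"])
  write_gene_sets(sets, paths["sets"])
  utils::write.table(annot, paths["annot"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene = planted$members), paths["truth"], sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
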