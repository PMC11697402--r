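#' Degree-normalized adjacency operator for network propagation
#'
#' Builds the symmetric degree normalization `A_norm = D^(-1/2) A D^(-1/2)`
#' of the interactome's adjacency matrix. Its spectral radius is at most 1,
#' so the closed-form random-walk-with-restart solution exists for every
#' restart-complement `alpha < 1`.
#'
#' @param net a non-empty `interactome`.
#' @return a `propagation_operator`: list with `nodes` (ordered gene ids)
#'   and `a_norm` (sparse symmetric matrix).
#' @export
normalize_adjacency <- function(net) {
  if (nrow(net) == 0) stop("cannot normalize an empty network", call. = FALSE)
  nodes <- interactome_nodes(net)
  i <- match(net$from, nodes)
  j <- match(net$to, nodes)
  n <- length(nodes)
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  d <- Matrix::rowSums(a)
  dinv <- 1 / sqrt(d)
  a_norm <- Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv)
  structure(list(nodes = nodes, a_norm = a_norm),
            class = "propagation_operator")
}

#' Random-walk-with-restart propagation (closed form)
#'
#' Solves `F = (1 - alpha) F0 (I - alpha A_norm)^(-1)`, the closed form of
#' the random walk with restart: `alpha` is the propagation constant (the
#' probability of continuing the walk), `F0` the binary seed indicator, and
#' `F` the stationary visitation score of every network gene.
#'
#' @param op a `propagation_operator` from [normalize_adjacency()].
#' @param f0 numeric seed vector in node order (or a matrix with one seed
#'   configuration per column).
#' @param alpha propagation constant in (0, 1).
#' @return numeric vector (or matrix, matching `f0`) of propagation scores,
#'   named by gene id when `f0` is a vector.
#' @export
propagate <- function(op, f0, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  n <- length(op$nodes)
  m <- Matrix::Diagonal(n) - alpha * op$a_norm
  # A_norm is symmetric, so the row-vector closed form is a linear solve
  if (is.matrix(f0)) {
    stopifnot(nrow(f0) == n)
    as.matrix((1 - alpha) * Matrix::solve(m, f0))
  } else {
    stopifnot(length(f0) == n)
    f <- as.numeric((1 - alpha) * Matrix::solve(m, f0))
    stats::setNames(f, op$nodes)
  }
}

#' Iterative random-walk-with-restart propagation
#'
#' Power iteration `F <- alpha F A_norm + (1 - alpha) F0` run to a fixed
#' point; converges to the closed form of [propagate()]. Mainly useful for
#' very large operators and as an independent check of the direct solve.
#'
#' @inheritParams propagate
#' @param tol convergence tolerance on the max absolute update.
#' @param max_iter iteration cap.
#' @return named numeric vector of propagation scores.
#' @export
propagate_iterative <- function(op, f0, alpha, tol = 1e-12, max_iter = 10000) {
  stopifnot(alpha > 0, alpha < 1)
  f <- (1 - alpha) * f0
  for (it in seq_len(max_iter)) {
    f_new <- as.numeric(alpha * (op$a_norm %*% f)) + (1 - alpha) * f0
    if (max(abs(f_new - f)) < tol) {
      return(stats::setNames(f_new, op$nodes))
    }
    f <- f_new
  }
  warning("propagation did not converge in ", max_iter, " iterations")
  stats::setNames(f, op$nodes)
}

#' Average-precision AUPRC of a ranking
#'
#' Area under the precision-recall curve in its average-precision form: the
#' mean over positives of the precision at each positive's rank. `scores`
#' ranks all candidates (higher first); ties are broken by the order of the
#' input, so callers that need unbiased tie handling should pre-permute.
#'
#' @param scores numeric vector of candidate scores.
#' @param is_positive logical vector marking the true positives.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive), any(is_positive))
  ord <- order(-scores)
  pos <- is_positive[ord]
  hits <- cumsum(pos)
  precision_at_hit <- (hits / seq_along(pos))[pos]
  mean(precision_at_hit)
}

#' Subsampled gene-set recovery by network propagation
#'
#' For each of `n_samples` repetitions: draw a seed fraction `rho` of the
#' gene set's network members without replacement (seed count
#' `round(rho * n)` clamped to `[1, n - 1]`), propagate from the seeds, rank
#' all non-seed network genes by propagation score (gene order randomly
#' permuted before a stable sort so score ties carry no identifier bias),
#' and compute the AUPRC for recovering the held-out members. Returns the
#' per-sample AUPRCs and their mean.
#'
#' @param net an `interactome`.
#' @param gene_set integer vector of gene ids.
#' @param rho seed fraction in (0, 1).
#' @param alpha propagation constant in (0, 1).
#' @param n_samples number of subsampling repetitions (the full-scale
#'   convention is 50).
#' @param seed RNG seed.
#' @param op optional precomputed `propagation_operator` for `net`.
#' @return list with `mean_auprc` and `auprcs` (length `n_samples`).
#' @export
recover_gene_set <- function(net, gene_set, rho = 0.3, alpha = 0.5,
                             n_samples = 50, seed = 1, op = NULL) {
  if (is.null(op)) op <- normalize_adjacency(net)
  members <- intersect(gene_set, op$nodes)
  n <- length(members)
  if (n < 2) stop("insufficient coverage: gene set has fewer than 2 network genes",
                  call. = FALSE)
  n_seed <- min(max(round(rho * n), 1L), n - 1L)
  n_nodes <- length(op$nodes)
  member_idx <- match(members, op$nodes)

  aups <- withr::with_seed(seed, {
    # draw all seed samples up front, then propagate with one multi-RHS solve
    seed_sets <- lapply(seq_len(n_samples), function(s) {
      sample(member_idx, n_seed)
    })
    perms <- lapply(seq_len(n_samples), function(s) sample.int(n_nodes))
    f0 <- matrix(0, n_nodes, n_samples)
    for (s in seq_len(n_samples)) f0[seed_sets[[s]], s] <- 1
    f_mat <- propagate(op, f0, alpha)
    vapply(seq_len(n_samples), function(s) {
      seeds <- seed_sets[[s]]
      holdout <- setdiff(member_idx, seeds)
      candidates <- setdiff(perms[[s]], seeds)  # permuted order for ties
      auprc(f_mat[candidates, s], candidates %in% holdout)
    }, 0)
  })
  list(mean_auprc = mean(aups), auprcs = aups)
}

#' Degree-preserving edge shuffle
#'
#' Randomizes an interactome by repeated double-edge swaps
#' (`(a,b),(c,d) -> (a,d),(c,b)`), rejecting swaps that would create a
#' self-loop or duplicate edge, so the degree of every node is exactly
#' preserved. Attempts `n_swap_factor * |E|` swaps.
#'
#' @param net an `interactome` with at least 2 edges.
#' @param seed RNG seed.
#' @param n_swap_factor swap attempts per edge (default 10).
#' @return a shuffled `interactome` with the same degree sequence. If no
#'   swap is possible (e.g. a star), the input edge set is returned with a
#'   warning.
#' @export
shuffle_network <- function(net, seed = 1, n_swap_factor = 10) {
  m <- nrow(net)
  if (m < 2) stop("need at least 2 edges to shuffle", call. = FALSE)
  g <- as_igraph(net)
  rewired <- withr::with_seed(seed, {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = n_swap_factor * m))
  })
  el <- igraph::as_edgelist(rewired, names = TRUE)
  edges <- canonical_pairs(as.integer(el[, 1]), as.integer(el[, 2])) |>
    dplyr::arrange(.data$from, .data$to)
  if (identical(edges$from, net$from) && identical(edges$to, net$to)) {
    warning("no degree-preserving swap changed the network; returning the input edges")
  }
  new_interactome(edges, name = paste0(net_name(net), "_shuffled"),
                  classification = attr(net, "classification"))
}

#' Null distribution of recovery performance on shuffled networks
#'
#' Recomputes [recover_gene_set()]'s mean AUPRC on `n_null` degree-matched
#' shuffled versions of the network (seeds re-drawn per null network from
#' derived substreams), giving the null sample against which observed
#' performance is scored.
#'
#' @inheritParams recover_gene_set
#' @param n_null number of shuffled networks (the full-scale convention is 50).
#' @return numeric vector of `n_null` null mean AUPRCs.
#' @export
null_performance <- function(net, gene_set, rho = 0.3, alpha = 0.5,
                             n_samples = 50, n_null = 50, seed = 1) {
  vapply(seq_len(n_null), function(b) {
    shuffled <- shuffle_network(net, seed = derive_seed(seed, 7001L, b))
    recover_gene_set(shuffled, gene_set, rho = rho, alpha = alpha,
                     n_samples = n_samples,
                     seed = derive_seed(seed, 7003L, b))$mean_auprc
  }, 0)
}

# deterministic substream seeds below 2^31, spread by large coprime strides
derive_seed <- function(master, stream, counter) {
  as.integer((as.double(master) * 2654435761 + stream * 97003 + counter * 101) %%
               2147483647)
}

#' Robust-Z performance score against a null sample
#'
#' The performance score is the robust Z-statistic of the observed mean
#' AUPRC against the null sample: `(observed - median(null)) / (c * MAD)`,
#' with `c = 1.4826` by default so the scale estimate is consistent for
#' Gaussian nulls (`c = 1` gives the raw MAD convention). The performance
#' gain is the observed excess over the null median, relative to the null
#' median.
#'
#' @param observed observed mean AUPRC.
#' @param null_sample numeric vector of null mean AUPRCs (length >= 3).
#' @param mad_constant consistency constant for the MAD.
#' @return tibble with one row: `z`, `gain`. `z` is signed `Inf` (with a
#'   warning) when the null MAD is 0; `gain` is `NA` when the null median
#'   is 0.
#' @export
score_performance <- function(observed, null_sample, mad_constant = 1.4826) {
  stopifnot(length(null_sample) >= 3)
  med <- stats::median(null_sample)
  raw_mad <- stats::median(abs(null_sample - med))
  if (raw_mad == 0) {
    warning("null MAD is 0; performance Z reported as signed infinity")
    z <- sign(observed - med) * Inf
    if (observed == med) z <- 0
  } else {
    z <- (observed - med) / (mad_constant * raw_mad)
  }
  gain <- if (med == 0) NA_real_ else (observed - med) / med
  tibble::tibble(z = z, gain = gain)
}

#' Size-adjusted performance residuals
#'
#' Regresses performance on network size (`log10` edge count) separately for
#' each gene set across networks; the residual is the size-adjusted
#' performance, i.e. how much better or worse a network does than expected
#' for its size.
#'
#' @param performance tibble with columns `network`, `gene_set`, `z`, and
#'   `log10_edges`.
#' @return the input with a `residual` column appended.
#' @export
size_adjust <- function(performance) {
  performance |>
    dplyr::mutate(
      residual = {
        if (dplyr::n() < 3) stop("need >= 3 networks per gene set", call. = FALSE)
        if (stats::sd(.data$log10_edges) == 0) {
          stop("degenerate size adjustment: all networks have equal size",
               call. = FALSE)
        }
        unname(stats::resid(stats::lm(z ~ log10_edges,
                                      data = data.frame(z = .data$z,
                                                        log10_edges = .data$log10_edges))))
      },
      .by = "gene_set"
    )
}

#' Centralized ranks of scores
#'
#' Ranks `m` scores (best = rank 1, ties get average rank) and centers the
#' ranks by `(m + 1) / 2`, so they always sum to zero and a negative value
#' means top-half performance regardless of how many networks were
#' evaluable for the gene set.
#'
#' @param scores numeric vector; higher is better.
#' @return numeric vector of centralized ranks.
#' @export
centralized_rank <- function(scores) {
  m <- length(scores)
  rank(-scores, ties.method = "average") - (m + 1) / 2
}

#' Recovery parameters from the fitted size/coverage formulas
#'
#' Sets the subsampling fraction and propagation constant from network size
#' and gene-set coverage using the fitted linear formulas
#' `rho = 0.44 + 0.0093 S - 0.0013 C` (clamped to \[0.1, 0.8\]) and
#' `alpha = 0.59 + 0.24 mean_rho - 0.058 S + 0.00036 mean_C` (clamped to
#' \[0.2, 0.9\]), where `S` is the log10 interaction count, `C` the
#' coverage (gene-set members present in the network), and `mean_rho`,
#' `mean_C` are means over the gene-set collection. The coefficients are
#' constants of the tool (fitted upstream on held-out pathway collections),
#' not refit here.
#'
#' @param s log10 edge count of the network.
#' @param c_coverage gene-set coverage count.
#' @param mean_rho mean subsampling fraction across the collection.
#' @param mean_c mean coverage across the collection.
#' @return list with `rho` and (when `mean_rho`/`mean_c` are given) `alpha`.
#' @export
set_parameters <- function(s, c_coverage, mean_rho = NULL, mean_c = NULL) {
  rho <- clamp(0.44 + 0.0093 * s - 0.0013 * c_coverage, 0.1, 0.8)
  out <- list(rho = rho)
  if (!is.null(mean_rho) && !is.null(mean_c)) {
    out$alpha <- clamp(0.59 + 0.24 * mean_rho - 0.058 * s + 0.00036 * mean_c,
                       0.2, 0.9)
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Filter a gene-set collection against a network panel
#'
#' Drops sets larger than `max_size`, and sets with fewer than
#' `min_all_networks` members in any panel network; marks, per network, the
#' sets with at least `min_present` members there as evaluable. Returns the
#' coverage table used downstream.
#'
#' @param gene_sets tibble with columns `set`, `gene` (optional `source`).
#' @param networks named list of `interactome`s.
#' @param min_present minimum members present for a (set, network) pair to
#'   be evaluated.
#' @param max_size maximum set size.
#' @param min_all_networks minimum members required in every network.
#' @return list with `gene_sets` (filtered membership tibble) and
#'   `coverage` (tibble: set, network, coverage, evaluable).
#' @export
prepare_gene_sets <- function(gene_sets, networks, min_present = 20,
                              max_size = 500, min_all_networks = 5) {
  sizes <- gene_sets |> dplyr::distinct(.data$set, .data$gene) |>
    dplyr::count(.data$set, name = "size")
  keep <- sizes$set[sizes$size <= max_size]
  members <- gene_sets |> dplyr::filter(.data$set %in% keep)
  node_sets <- purrr::map(networks, interactome_nodes)
  coverage <- purrr::imap(node_sets, function(nodes, nm) {
    members |>
      dplyr::summarise(coverage = sum(unique(.data$gene) %in% nodes), .by = "set") |>
      dplyr::mutate(network = nm)
  }) |>
    dplyr::bind_rows()
  ok_everywhere <- coverage |>
    dplyr::summarise(min_cov = min(.data$coverage), .by = "set") |>
    dplyr::filter(.data$min_cov >= min_all_networks)
  coverage <- coverage |>
    dplyr::filter(.data$set %in% ok_everywhere$set) |>
    dplyr::mutate(evaluable = .data$coverage >= min_present) |>
    dplyr::select("set", "network", "coverage", "evaluable")
  members <- members |> dplyr::filter(.data$set %in% ok_everywhere$set)
  if (nrow(members) == 0) warning("no gene sets survive filtering")
  list(gene_sets = members, coverage = coverage)
}

#' Reduce gene sets to members present in every panel network
#'
#' Builds the maximal subset of each gene set whose members appear in all
#' panel networks, then drops reduced sets below `min_size`. Members removed
#' here are excluded from downstream evaluation entirely (they are neither
#' seeds, holdouts, nor false positives).
#'
#' @param gene_sets tibble with columns `set`, `gene`.
#' @param networks named list of panel `interactome`s.
#' @param min_size minimum reduced-set size (the full-scale conventions are
#'   30 for literature sets and 15 for genetic sets).
#' @return filtered membership tibble of the reduced sets.
#' @export
reduce_gene_sets <- function(gene_sets, networks, min_size = 15) {
  common <- Reduce(intersect, purrr::map(networks, interactome_nodes))
  reduced <- gene_sets |> dplyr::filter(.data$gene %in% common)
  sizes <- reduced |> dplyr::distinct(.data$set, .data$gene) |>
    dplyr::count(.data$set, name = "size")
  reduced |> dplyr::filter(.data$set %in% sizes$set[sizes$size >= min_size])
}

#' Benchmark gene-set recovery across networks
#'
#' Full recovery benchmark: for every evaluable (network, gene set) pair,
#' computes the observed mean AUPRC, the degree-matched shuffled null
#' sample, the robust-Z performance and gain, then size-adjusted residuals
#' and centralized ranks across networks. Parameters `rho`/`alpha` may be
#' fixed numbers or `"auto"` to use the fitted formulas of
#' [set_parameters()].
#'
#' @param networks named list of `interactome`s.
#' @param gene_sets tibble with columns `set`, `gene`.
#' @param rho,alpha numeric, or `"auto"`.
#' @param n_samples,n_null subsampling and null-model counts.
#' @param seed master RNG seed; every (network, set, replicate) cell uses a
#'   derived substream.
#' @param min_present,max_size,min_all_networks filters passed to
#'   [prepare_gene_sets()].
#' @return a `recovery_benchmark`: list with `results` (tibble: network,
#'   gene_set, coverage, rho, alpha, mean_auprc, null_median, z, gain,
#'   residual, centralized_rank) and `networks` (tibble: network,
#'   log10_edges, overall_rank).
#' @export
benchmark_recovery <- function(networks, gene_sets, rho = "auto",
                               alpha = "auto", n_samples = 10, n_null = 10,
                               seed = 1, min_present = 5, max_size = 500,
                               min_all_networks = 2) {
  prep <- prepare_gene_sets(gene_sets, networks, min_present = min_present,
                            max_size = max_size,
                            min_all_networks = min_all_networks)
  eval_pairs <- prep$coverage |> dplyr::filter(.data$evaluable)
  members_by_set <- split(prep$gene_sets$gene, prep$gene_sets$set)
  net_sizes <- purrr::map_dbl(networks, ~ log10(nrow(.x)))

  # the null model is per network: each shuffled replicate is built once and
  # every gene set is scored against the same n_null randomized networks
  rows <- purrr::imap(networks, function(net, nm) {
    pairs <- eval_pairs[eval_pairs$network == nm, ]
    if (nrow(pairs) == 0) return(NULL)
    s <- net_sizes[[nm]]
    mean_c <- mean(pairs$coverage)
    mean_rho <- mean(set_parameters(s, pairs$coverage)$rho)
    net_id <- match(nm, names(networks))
    op <- normalize_adjacency(net)
    params <- purrr::map(seq_len(nrow(pairs)), function(r) {
      list(
        rho = if (identical(rho, "auto")) set_parameters(s, pairs$coverage[r])$rho else rho,
        alpha = if (identical(alpha, "auto")) {
          set_parameters(s, pairs$coverage[r], mean_rho = mean_rho,
                         mean_c = mean_c)$alpha
        } else alpha
      )
    })
    observed <- purrr::map_dbl(seq_len(nrow(pairs)), function(r) {
      recover_gene_set(net, members_by_set[[pairs$set[r]]],
                       rho = params[[r]]$rho, alpha = params[[r]]$alpha,
                       n_samples = n_samples,
                       seed = derive_seed(seed, 11L, net_id * 1000L + r),
                       op = op)$mean_auprc
    })
    nulls <- matrix(NA_real_, n_null, nrow(pairs))
    for (b in seq_len(n_null)) {
      shuffled <- shuffle_network(net, seed = derive_seed(seed, 13L, net_id * 1000L + b))
      op_b <- normalize_adjacency(shuffled)
      for (r in seq_len(nrow(pairs))) {
        nulls[b, r] <- recover_gene_set(
          shuffled, members_by_set[[pairs$set[r]]],
          rho = params[[r]]$rho, alpha = params[[r]]$alpha,
          n_samples = n_samples,
          seed = derive_seed(seed, 17L, net_id * 100000L + b * 100L + r),
          op = op_b
        )$mean_auprc
      }
    }
    purrr::map(seq_len(nrow(pairs)), function(r) {
      perf <- score_performance(observed[r], nulls[, r])
      tibble::tibble(network = nm, gene_set = pairs$set[r],
                     coverage = pairs$coverage[r],
                     rho = params[[r]]$rho, alpha = params[[r]]$alpha,
                     log10_edges = s, mean_auprc = observed[r],
                     null_median = stats::median(nulls[, r]),
                     z = perf$z, gain = perf$gain)
    }) |>
      dplyr::bind_rows()
  })
  results <- dplyr::bind_rows(rows)
  n_networks_per_set <- results |> dplyr::count(.data$gene_set)
  adjustable <- n_networks_per_set$gene_set[n_networks_per_set$n >= 3]
  results$residual <- NA_real_
  if (length(adjustable) > 0) {
    adj <- size_adjust(results[results$gene_set %in% adjustable,
                               c("network", "gene_set", "z", "log10_edges")])
    results$residual[results$gene_set %in% adjustable] <- adj$residual
  }
  results <- results |>
    dplyr::mutate(centralized_rank = centralized_rank(.data$z), .by = "gene_set")
  overall <- results |>
    dplyr::summarise(overall_rank = mean(.data$centralized_rank),
                     log10_edges = .data$log10_edges[1], .by = "network") |>
    dplyr::arrange(.data$overall_rank)
  structure(list(results = results, networks = overall),
            class = "recovery_benchmark")
}

#' @export
print.recovery_benchmark <- function(x, ...) {
  cat(sprintf("# Gene-set recovery benchmark: %d networks x %d gene sets\n",
              nrow(x$networks), length(unique(x$results$gene_set))))
  print(x$networks)
  invisible(x)
}

#' Tidy a recovery benchmark
#'
#' @param x a `recovery_benchmark`.
#' @param ... unused.
#' @return the per-(network, gene set) results tibble.
#' @export
tidy.recovery_benchmark <- function(x, ...) x$results

#' One-row-per-network summary of a recovery benchmark
#'
#' @param x a `recovery_benchmark`.
#' @param ... unused.
#' @return tibble with per-network mean z, mean gain, and overall
#'   centralized rank (lower is better).
#' @export
glance.recovery_benchmark <- function(x, ...) {
  x$results |>
    dplyr::summarise(mean_z = mean(.data$z), mean_gain = mean(.data$gain),
                     mean_auprc = mean(.data$mean_auprc),
                     overall_rank = mean(.data$centralized_rank),
                     n_gene_sets = dplyr::n(), .by = "network") |>
    dplyr::arrange(.data$overall_rank)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
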