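test_that("degree normalization has the hand-computed entries", {
  single <- new_interactome(tibble::tibble(from = 1, to = 2))
  op <- normalize_adjacency(single)
  expect_equal(as.matrix(op$a_norm)[1, 2], 1)

  star <- new_interactome(tibble::tibble(from = c(1, 1, 1), to = 2:4))
  a <- as.matrix(normalize_adjacency(star)$a_norm)
  expect_equal(a[1, 2], 1 / sqrt(3))

  tri <- new_interactome(tibble::tibble(from = c(1, 1, 2), to = c(2, 3, 3)))
  at <- as.matrix(normalize_adjacency(tri)$a_norm)
  expect_equal(at[1, 2], 1 / 2)
  expect_equal(at, t(at))

  empty <- new_interactome(tibble::tibble(from = integer(), to = integer()))
  expect_error(normalize_adjacency(empty), "empty")
})

test_that("closed-form propagation matches limits and the iterative oracle", {
  net <- random_net(30, 60, seed = 5)
  op <- normalize_adjacency(net)
  n <- length(op$nodes)
  f0 <- as.numeric(seq_len(n) <= 3)

  expect_equal(unname(propagate(op, rep(0, n), 0.5)), rep(0, n))
  # alpha -> 0: scores collapse to the seed vector
  expect_equal(unname(propagate(op, f0, 1e-9)), f0, tolerance = 1e-6)

  for (alpha in c(0.2, 0.5, 0.9)) {
    f_closed <- propagate(op, f0, alpha)
    f_iter <- propagate_iterative(op, f0, alpha, tol = 1e-14)
    expect_equal(f_closed, f_iter, tolerance = 1e-10)
    expect_true(all(f_closed >= -1e-12))
  }
})

test_that("average-precision AUPRC matches the quadratic reference", {
  # perfect ranking
  expect_equal(auprc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(5:40, 1)
      scores <- stats::runif(n)
      pos <- seq_len(n) %in% sample(n, sample(1:4, 1))
      expect_equal(auprc(scores, pos), brute_auprc(scores, pos))
    }
  })
  # invariant to non-positive labels; strictly increases when a positive
  # moves up one rank past a negative
  scores <- c(10, 9, 8, 7)
  low <- auprc(scores, c(FALSE, TRUE, FALSE, TRUE))
  high <- auprc(scores, c(TRUE, FALSE, FALSE, TRUE))
  expect_gt(high, low)
})

test_that("gene-set recovery ranks planted modules above chance", {
  net <- generate_network(300, "erdos_renyi", 1500, seed = 2)
  pl <- plant_module(net, 20, 12, seed = 3)
  expect_error(recover_gene_set(pl$net, c(1L)), "insufficient")

  obs <- recover_gene_set(pl$net, pl$members, rho = 0.4, alpha = 0.5,
                          n_samples = 8, seed = 4)
  expect_length(obs$auprcs, 8)
  expect_true(all(obs$auprcs >= 0 & obs$auprcs <= 1))

  rand_set <- withr::with_seed(5, sample(interactome_nodes(pl$net), 20))
  rnd <- recover_gene_set(pl$net, rand_set, rho = 0.4, alpha = 0.5,
                          n_samples = 8, seed = 4)
  expect_gt(obs$mean_auprc, rnd$mean_auprc)
})

test_that("random holdouts score near prevalence", {
  # seeds placed in an unstructured network: mean AUPRC for a random set is
  # close to the holdout prevalence among non-seed genes
  net <- generate_network(200, "erdos_renyi", 2000, seed = 7)
  rand_set <- withr::with_seed(8, sample(interactome_nodes(net), 30))
  res <- recover_gene_set(net, rand_set, rho = 0.5, alpha = 0.5,
                          n_samples = 40, seed = 9)
  prevalence <- 15 / (200 - 15)
  expect_lt(abs(res$mean_auprc - prevalence), 0.1)
})

test_that("shuffling preserves degree sequences and is seed-deterministic", {
  for (s in 1:10) {
    net <- random_net(20, 35, seed = s)
    sh <- suppressWarnings(shuffle_network(net, seed = s))
    expect_equal(interactome_degrees(sh), interactome_degrees(net))
  }
  net <- random_net(30, 60, seed = 42)
  s1 <- shuffle_network(net, seed = 7)
  s2 <- shuffle_network(net, seed = 7)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))

  star <- new_interactome(tibble::tibble(from = rep(1, 5), to = 2:6))
  expect_warning(shuffle_network(star, seed = 1), "swap")
  expect_error(shuffle_network(new_interactome(tibble::tibble(from = 1, to = 2))),
               "2 edges")
})

test_that("null distributions have the configured size and reproduce", {
  net <- random_net(40, 120, seed = 3)
  genes <- interactome_nodes(net)[1:10]
  n1 <- null_performance(net, genes, rho = 0.4, alpha = 0.5,
                         n_samples = 3, n_null = 3, seed = 10)
  expect_length(n1, 3)
  n2 <- null_performance(net, genes, rho = 0.4, alpha = 0.5,
                         n_samples = 3, n_null = 3, seed = 10)
  expect_identical(n1, n2)
})

test_that("robust-Z scoring matches hand arithmetic and handles degeneracy", {
  expect_equal(score_performance(0.2, c(0.1, 0.2, 0.3))$z, 0)
  expect_equal(score_performance(0.2, c(0.1, 0.2, 0.3))$gain, 0)

  hand <- score_performance(0.4, c(0.1, 0.2, 0.3), mad_constant = 1)
  expect_equal(hand$z, 2)          # (0.4 - 0.2) / 0.1
  expect_equal(hand$gain, 1)       # (0.4 - 0.2) / 0.2
  scaled <- score_performance(0.4, c(0.1, 0.2, 0.3))
  expect_equal(scaled$z, 2 / 1.4826)

  expect_warning(res <- score_performance(0.5, c(0.2, 0.2, 0.2)), "MAD")
  expect_identical(res$z, Inf)
  expect_true(is.na(score_performance(0.1, c(-0.1, 0, 0.1))$gain))

  # affine invariance: same positive rescale + shift of observed and null
  a <- score_performance(0.4, c(0.1, 0.2, 0.35))
  b <- score_performance(0.4 * 3 + 1, c(0.1, 0.2, 0.35) * 3 + 1)
  expect_equal(a$z, b$z)
})

test_that("robust Z approximates the classical z on Gaussian nulls", {
  withr::with_seed(21, {
    errs <- replicate(30, {
      null <- stats::rnorm(400, mean = 0.5, sd = 0.05)
      obs <- 0.62
      z_rob <- score_performance(obs, null)$z
      z_cls <- (obs - mean(null)) / stats::sd(null)
      z_rob - z_cls
    })
    expect_lt(abs(mean(errs)), 0.15)
  })
})

test_that("size adjustment returns OLS residuals per gene set", {
  tbl <- tibble::tibble(
    network = rep(c("a", "b", "c"), 2),
    gene_set = rep(c("s1", "s2"), each = 3),
    log10_edges = rep(c(3, 4, 5), 2),
    z = c(1, 2, 3,      # exactly linear in size
          5, 5, 5)      # independent of size
  )
  adj <- size_adjust(tbl)
  expect_equal(adj$residual[adj$gene_set == "s1"], rep(0, 3), tolerance = 1e-12)
  expect_equal(adj$residual[adj$gene_set == "s2"], rep(0, 3), tolerance = 1e-12)

  tbl2 <- tibble::tibble(network = c("a", "b", "c"), gene_set = "s",
                         log10_edges = c(3, 4, 5), z = c(2, 1, 6))
  fit <- stats::lm(z ~ log10_edges, data = tbl2)
  expect_equal(size_adjust(tbl2)$residual, unname(stats::resid(fit)))
  expect_equal(sum(size_adjust(tbl2)$residual), 0, tolerance = 1e-12)

  degenerate <- tibble::tibble(network = c("a", "b", "c"), gene_set = "s",
                               log10_edges = c(3, 3, 3), z = 1:3)
  expect_error(size_adjust(degenerate), "degenerate")
})

test_that("centralized ranks center on zero with average-rank ties", {
  expect_equal(sort(centralized_rank(c(3, 2, 1))), c(-1, 0, 1))
  expect_equal(sort(centralized_rank(c(4, 3, 2, 1))), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(centralized_rank(5), 0)
  expect_equal(centralized_rank(c(2, 2)), c(0, 0))  # tie -> average rank
  for (s in 1:20) {
    x <- withr::with_seed(s, stats::rnorm(sample(1:12, 1)))
    expect_equal(sum(centralized_rank(x)), 0)
  }
})

test_that("parameter formulas reproduce hand-computed values and clamps", {
  expect_equal(set_parameters(6, 50)$rho, 0.44 + 0.0093 * 6 - 0.0013 * 50)
  expect_equal(set_parameters(6, 50)$rho, 0.4308)
  expect_equal(set_parameters(0, 400)$rho, 0.1)   # raw -0.08 clamped up
  expect_equal(set_parameters(60, 0)$rho, 0.8)    # clamped down
  p <- set_parameters(6, 50, mean_rho = 0.3, mean_c = 100)
  expect_equal(p$alpha, 0.59 + 0.24 * 0.3 - 0.058 * 6 + 0.00036 * 100)
  expect_equal(p$alpha, 0.35, tolerance = 1e-12)
  expect_equal(set_parameters(0, 0, mean_rho = 0.8, mean_c = 500)$alpha, 0.9)
  expect_equal(set_parameters(20, 0, mean_rho = 0.1, mean_c = 0)$alpha, 0.2)
})

test_that("gene-set preparation applies the size and coverage filters", {
  nets <- list(
    x = random_net(30, 80, seed = 1),   # nodes 1..30
    y = random_net(20, 40, seed = 2)    # nodes 1..20
  )
  sets <- dplyr::bind_rows(
    tibble::tibble(set = "big", gene = 1:600),
    tibble::tibble(set = "thin", gene = c(1:4, 100:120)),  # <5 in net y
    tibble::tibble(set = "good", gene = 1:12)
  )
  prep <- prepare_gene_sets(sets, nets, min_present = 10, max_size = 500,
                            min_all_networks = 5)
  expect_setequal(unique(prep$gene_sets$set), "good")
  cov <- prep$coverage
  expect_true(all(cov$set == "good"))
  expect_equal(cov$evaluable, cov$coverage >= 10)
})

test_that("reduced sets keep only members common to the whole panel", {
  nets <- list(a = random_net(30, 100, seed = 4), b = random_net(20, 60, seed = 5))
  common <- intersect(interactome_nodes(nets$a), interactome_nodes(nets$b))
  sets <- tibble::tibble(set = "s", gene = c(common[1:10], 900:905))
  red <- reduce_gene_sets(sets, nets, min_size = 10)
  expect_setequal(red$gene, common[1:10])
  expect_equal(nrow(reduce_gene_sets(sets, nets, min_size = 11)), 0)
})

test_that("benchmark_recovery assembles a coherent result table", {
  net1 <- plant_module(generate_network(150, "erdos_renyi", 700, seed = 1),
                       15, 12, seed = 2)
  net2 <- generate_network(150, "erdos_renyi", 900, seed = 3)
  sets <- dplyr::bind_rows(
    tibble::tibble(set = "planted", gene = net1$members),
    tibble::tibble(set = "rand",
                   gene = withr::with_seed(4, sample(interactome_nodes(net2), 15)))
  )
  bm <- benchmark_recovery(list(one = net1$net, two = net2), sets,
                           rho = 0.4, alpha = 0.5, n_samples = 4, n_null = 4,
                           seed = 6, min_present = 5, min_all_networks = 2)
  res <- tidy(bm)
  expect_setequal(res$network, c("one", "two"))
  expect_true(all(res$mean_auprc >= 0 & res$mean_auprc <= 1))
  expect_equal(sum(res$centralized_rank), 0)
  expect_gt(res$z[res$network == "one" & res$gene_set == "planted"],
            res$z[res$network == "one" & res$gene_set == "rand"])
  g <- glance(bm)
  expect_equal(nrow(g), 2)
  expect_true(all(c("mean_z", "overall_rank") %in% names(g)))
})
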