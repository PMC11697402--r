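test_that("transcript consolidation means same-magnitude values, else takes max", {
  expr <- tibble::tibble(
    gene = c(1, 1, 2, 2, 3),
    tissue = "brain",
    tpm = c(2, 4, 0, 5, 7)
  )
  out <- consolidate_transcript_expression(expr)$by_tissue
  expect_equal(out$tpm[out$gene == 1], 3)   # both above 1e-4: mean
  expect_equal(out$tpm[out$gene == 2], 5)   # mixed magnitude: max
  expect_equal(out$tpm[out$gene == 3], 7)   # single transcript
  expect_error(consolidate_transcript_expression(
    tibble::tibble(gene = 1, tissue = "a", tpm = -1)
  ), "negative")

  multi <- tibble::tibble(gene = 1, tissue = c("a", "b"), tpm = c(2, 4))
  expect_equal(consolidate_transcript_expression(multi)$overall$mean_tpm, 3)
})

test_that("protein abundance encoding drops Uncertain and small tissues", {
  ab <- tibble::tibble(
    gene = c(1, 1, 2, 2, 3),
    tissue = c("liver", "brain", "liver", "brain", "tiny"),
    level = c("High", "Low", "Medium", "Medium", "High"),
    reliability = c("Supported", "Supported", "Uncertain", "Supported", "Supported")
  )
  out <- encode_protein_abundance(ab, min_tissue_obs = 2)
  expect_equal(out$abundance[out$gene == 1], 2)       # (3 + 1) / 2
  expect_equal(out$abundance[out$gene == 2], 2)       # Uncertain dropped
  expect_false(3 %in% out$gene)                       # only in excluded tissue
  expect_error(encode_protein_abundance(
    tibble::tibble(gene = 1, tissue = "a", level = "Huge", reliability = "Supported"),
    min_tissue_obs = 1
  ), "unknown")
})

test_that("permutation median test floors p and applies Bonferroni", {
  background <- tibble::tibble(gene = 1:200, value = c(rep(0, 180), rep(100, 20)))
  # network holding exactly the high-value genes: no permuted median exceeds
  res <- permutation_median_test(181:200, background, n_perm = 500,
                                 n_networks_tested = 45, seed = 1)
  expect_equal(res$p, 1 / 500)
  expect_equal(res$q, min(45 / 500, 1))
  expect_equal(res$observed_median, 100)

  # q = min(45 p, 1) caps at 1
  res2 <- permutation_median_test(1:180, background, n_perm = 200,
                                  n_networks_tested = 45, seed = 2)
  expect_equal(res2$q, min(45 * res2$p, 1))

  # unbiased network sample: p is moderate, not significant
  cont <- tibble::tibble(gene = 1:200,
                         value = withr::with_seed(30, stats::runif(200)))
  res3 <- permutation_median_test(
    withr::with_seed(31, sample(1:200, 100)), cont, n_perm = 400, seed = 3
  )
  expect_gt(res3$p, 0.05)

  expect_error(permutation_median_test(900:910, background, n_perm = 10),
               "background")
})

test_that("percentile20 binning merges the bottom fifth into one bin", {
  annot <- tibble::tibble(gene = 1:100, value = 1:100)
  b <- bin_genes(annot, "percentile20")
  counts <- table(b$bin)
  expect_equal(length(counts), 17)
  expect_equal(max(counts), 20)            # merged bottom bin
  expect_equal(sort(unique(as.integer(counts))), c(5L, 20L))
  # bottom 20 genes all share the merged bin
  expect_equal(length(unique(b$bin[b$gene <= 20])), 1)
})

test_that("citation50 binning keeps tied values together", {
  annot <- tibble::tibble(gene = 1:50, value = rep(7, 50))
  expect_equal(length(unique(bin_genes(annot, "citation50")$bin)), 1)

  vals <- c(1:45, rep(50, 10), 51:95)
  annot <- tibble::tibble(gene = seq_along(vals), value = vals)
  b <- bin_genes(annot, "citation50")
  expect_equal(length(unique(b$bin[annot$value == 50])), 1)
  sizes <- table(b$bin)
  expect_true(all(sizes >= 1))
  expect_equal(sum(sizes), length(vals))
})

test_that("interaction density follows the pair-count normalization", {
  # complete graph on one 4-gene bin: saturation
  bins <- bin_genes(tibble::tibble(gene = 1:4, value = "A"), "chromosome")
  cmb <- utils::combn(1:4, 2)
  edges <- tibble::tibble(from = cmb[1, ], to = cmb[2, ])
  dm <- interaction_density(edges, bins)
  expect_equal(dm$D["A", "A"], 1)

  # |A| = 2, |B| = 3 disjoint: denominator |A||B|/2 = 3
  bins2 <- bin_genes(
    tibble::tibble(gene = 1:5, value = c("A", "A", "B", "B", "B")), "chromosome"
  )
  e3 <- tibble::tibble(from = c(1, 1, 2), to = c(3, 4, 5))
  dm2 <- interaction_density(e3, bins2)
  expect_equal(dm2$D["A", "B"], 1)
  expect_equal(dm2$D["A", "B"], dm2$D["B", "A"])
  # all 6 cross pairs present: density 2 (off-diagonal convention)
  e6 <- tidyr::expand_grid(from = 1:2, to = 3:5)
  dm6 <- interaction_density(e6, bins2)
  expect_equal(dm6$D["A", "B"], 2)

  # empty edge set: all-zero counts, and adding an edge never decreases cells
  dm0 <- interaction_density(e3[0, ], bins2)
  expect_true(all(dm0$n == 0))
  dm1 <- interaction_density(e3[1, , drop = FALSE], bins2)
  expect_true(all(dm1$n >= dm0$n))
})

test_that("overlapping term bins use unique cross-pair denominators", {
  assoc <- tibble::tibble(term = c("T1", "T1", "T1", "T2", "T2"),
                          gene = c(1L, 2L, 3L, 3L, 4L))
  bins <- bin_genes(assoc, "term")
  dm <- interaction_density(tibble::tibble(from = 1L, to = 4L), bins)
  # enumerate unique unordered cross pairs {u in T1, v in T2, u != v} by hand:
  # {1,3},{1,4},{2,3},{2,4},{3,4} -> 5
  expect_equal(dm$possible["T1", "T2"], 5)
  expect_equal(dm$D["T1", "T2"], 1 / 5)
})

test_that("tissue classification follows the precedence rules", {
  prof <- function(v) tibble::tibble(gene = 1, tissue = paste0("t", seq_along(v)),
                                     value = v)
  expect_equal(classify_tissue_specificity(prof(c(0.5, 0.5, 0.5)))$class, "low")
  expect_equal(classify_tissue_specificity(prof(c(50, 5, 5)))$class, "tissue_enriched")
  cls <- classify_tissue_specificity(prof(c(10, 10, 1, 1)))
  expect_equal(cls$class, "group_enriched")
  expect_equal(cls$tissues, "t1,t2")
  expect_equal(classify_tissue_specificity(prof(c(26, 6, 5, 4)))$class,
               "tissue_enhanced")  # 26 < 5*6 but 26 >= 5 * mean(6,5,4)
  expect_equal(classify_tissue_specificity(prof(c(5, 4, 3)))$class, "broad")

  # protein convention: three-fold, low cutoff 0.5
  expect_equal(
    classify_tissue_specificity(prof(c(0.4, 0.3)), fold = 3, low_cutoff = 0.5)$class,
    "low"
  )

  # exhaustive and mutually exclusive over genes with data
  profs <- tidyr::expand_grid(gene = 1:50, tissue = paste0("t", 1:4)) |>
    dplyr::mutate(value = withr::with_seed(9, stats::rexp(200, 0.2)))
  out <- classify_tissue_specificity(profs)
  expect_equal(nrow(out), 50)
  expect_true(all(out$class %in% c("low", "tissue_enriched", "group_enriched",
                                   "tissue_enhanced", "broad")))
})

test_that("term propagation closes over ancestors and is idempotent", {
  assoc <- tibble::tibble(term = "C", gene = 7L)
  parents <- tibble::tibble(child = c("C", "B"), parent = c("B", "A"))
  closed <- propagate_term_annotations(assoc, parents)
  expect_setequal(closed$term, c("A", "B", "C"))
  expect_equal(propagate_term_annotations(closed, parents), closed)

  unchanged <- propagate_term_annotations(assoc, parents[0, ])
  expect_equal(unchanged, assoc)

  loop <- tibble::tibble(child = c("A", "B"), parent = c("B", "A"))
  expect_error(propagate_term_annotations(assoc, loop), "cycle")

  # monotone: associations only grow
  expect_true(all(paste(assoc$term, assoc$gene) %in%
                    paste(closed$term, closed$gene)))
})

test_that("slim-term selection applies the size range then parent exclusion", {
  assoc <- dplyr::bind_rows(
    tibble::tibble(term = "A", gene = 1:150),
    tibble::tibble(term = "B", gene = 1:120),
    tibble::tibble(term = "C", gene = 201:500),
    tibble::tibble(term = "D", gene = 1:50)
  )
  parents <- tibble::tibble(child = "B", parent = "A")
  kept <- select_slim_terms(assoc, parents, min_genes = 100, max_genes = 4000)
  expect_setequal(kept, c("B", "C"))  # A excluded as parent of B; D too small
})

test_that("Fisher enrichment matches the exact hypergeometric oracle", {
  background <- 1:20
  term_sets <- tibble::tibble(term = "T", gene = 1:10)
  res <- enrich_gene_sets(1:10, term_sets, background)
  # maximally enriched 2x2 table [[10,0],[0,10]]: two-sided p = 2 / C(20,10)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$n_overlap, 10)

  # BH q is monotone in p across independent terms
  sets <- dplyr::bind_rows(
    tibble::tibble(term = "T1", gene = 1:10),
    tibble::tibble(term = "T2", gene = c(1:5, 11:15)),
    tibble::tibble(term = "T3", gene = 11:20)
  )
  multi <- enrich_gene_sets(1:10, sets, background)
  expect_false(is.unsorted(multi$q[order(multi$p)]))
  expect_error(enrich_gene_sets(1:3, sets, integer()), "background")
})
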