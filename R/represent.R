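#' Consolidate per-transcript expression into per-gene values
#'
#' For each gene and tissue, transcript TPM values are averaged when they all
#' lie on the same side of 1e-4 (all above or all at/below, i.e. of similar
#' magnitude); otherwise the maximum is taken, so a single expressed
#' transcript is not washed out by silent isoforms. The overall per-gene
#' level is the mean across tissues.
#'
#' @param expr tibble with columns `gene`, `tissue`, `tpm` (one row per
#'   transcript observation; `transcript` column optional).
#' @param magnitude_cutoff the similar-magnitude threshold (default 1e-4 TPM).
#' @return list with `by_tissue` (tibble: gene, tissue, tpm) and `overall`
#'   (tibble: gene, mean_tpm).
#' @export
consolidate_transcript_expression <- function(expr, magnitude_cutoff = 1e-4) {
  if (any(expr$tpm < 0)) stop("negative TPM values", call. = FALSE)
  by_tissue <- expr |>
    dplyr::summarise(
      tpm = {
        side <- .data$tpm > magnitude_cutoff
        if (all(side) || all(!side)) mean(.data$tpm) else max(.data$tpm)
      },
      .by = c("gene", "tissue")
    )
  overall <- by_tissue |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), .by = "gene")
  list(by_tissue = by_tissue, overall = overall)
}

#' Encode categorical protein abundance as per-gene numeric values
#'
#' Categorical tissue-level abundance calls are encoded Not detected = 0,
#' Low = 1, Medium = 2, High = 3. Entries flagged "Uncertain" reliability are
#' excluded, as are tissues with fewer than `min_tissue_obs` total
#' observations; the per-gene value is the mean over the retained tissue
#' entries.
#'
#' @param abundance tibble with columns `gene`, `tissue`, `level`
#'   (character), `reliability` (character; `"Uncertain"` rows dropped).
#' @param min_tissue_obs minimum observations for a tissue to be retained.
#' @return tibble with columns `gene`, `abundance` (in \[0, 3\]); genes with
#'   no retained entries are absent.
#' @export
encode_protein_abundance <- function(abundance, min_tissue_obs = 1000) {
  levels_map <- c("Not detected" = 0, "Low" = 1, "Medium" = 2, "High" = 3)
  unknown <- setdiff(unique(abundance$level), names(levels_map))
  if (length(unknown) > 0) {
    stop("unknown abundance category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tissue_n <- abundance |> dplyr::count(.data$tissue)
  keep_tissues <- tissue_n$tissue[tissue_n$n >= min_tissue_obs]
  abundance |>
    dplyr::filter(.data$reliability != "Uncertain",
                  .data$tissue %in% keep_tissues) |>
    dplyr::mutate(value = unname(levels_map[.data$level])) |>
    dplyr::summarise(abundance = mean(.data$value), .by = "gene")
}

#' Permutation test for annotation skew of a network's genes
#'
#' Tests whether the genes of a network have a higher median annotation value
#' (citation count, expression, abundance, conservation, ...) than random
#' gene samples of the same size drawn without replacement from the
#' background. One-sided for enrichment of high values; the empirical p is
#' the fraction of permuted medians strictly greater than the observed
#' median, floored at 1/n_perm when none exceed it. The q-value is the
#' Bonferroni correction over the number of networks tested.
#'
#' @param network_genes integer vector of the network's gene ids.
#' @param annotation tibble with columns `gene`, `value` covering the
#'   background (e.g. all protein-coding genes with the annotation).
#' @param n_perm number of permutations (default 10000).
#' @param n_networks_tested multiplier for the Bonferroni q.
#' @param seed RNG seed.
#' @return tibble with one row: `n` (intersection size), `observed_median`,
#'   `p`, `q`.
#' @export
permutation_median_test <- function(network_genes, annotation, n_perm = 10000,
                                    n_networks_tested = 1, seed = 1) {
  values <- annotation$value
  in_net <- annotation$gene %in% network_genes
  n <- sum(in_net)
  if (n == 0) stop("no network genes in the annotation background", call. = FALSE)
  observed <- stats::median(values[in_net])
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::median(values[sample.int(length(values), n)])
    }, 0)
  })
  n_greater <- sum(perm > observed)
  p <- max(n_greater, 1) / n_perm
  tibble::tibble(n = n, observed_median = observed, p = p,
                 q = min(n_networks_tested * p, 1))
}

#' Assign genes to annotation bins
#'
#' Supported schemes:
#' * `percentile20`: 20 equal-count bins; the lowest four are merged into a
#'   single bottom-20% bin (appropriate for annotations with a large
#'   near-zero mass such as mRNA expression), giving 17 bins.
#' * `citation50`: 50 approximately equal-count bins with the constraint
#'   that all genes sharing a value land in the same bin.
#' * `chromosome`: one bin per label in the `value` column.
#' * `term`: multi-assignment straight from a (term, gene) association
#'   table; genes may carry several bins.
#'
#' @param annotation for numeric schemes a tibble with `gene`, `value`; for
#'   `chromosome` a tibble with `gene`, `value` (labels); for `term` a
#'   tibble with `term`, `gene`.
#' @param kind one of `"percentile20"`, `"citation50"`, `"chromosome"`,
#'   `"term"`.
#' @return a `bin_scheme`: tibble with columns `gene`, `bin` (character) and
#'   attributes `kind`, `overlapping` (whether genes may have several bins).
#' @export
bin_genes <- function(annotation, kind = c("percentile20", "citation50",
                                           "chromosome", "term")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    percentile20 = {
      b20 <- equal_count_bins(annotation$value, 20)
      merged <- pmax(b20 - 3L, 1L)  # bins 1..4 -> 1, 5 -> 2, ..., 20 -> 17
      tibble::tibble(gene = annotation$gene, bin = sprintf("p%02d", merged))
    },
    citation50 = {
      tibble::tibble(gene = annotation$gene,
                     bin = sprintf("c%02d", tied_equal_count_bins(annotation$value, 50)))
    },
    chromosome = tibble::tibble(gene = annotation$gene,
                                bin = as.character(annotation$value)),
    term = tibble::tibble(gene = annotation$gene,
                          bin = as.character(annotation$term))
  )
  out <- dplyr::distinct(out)
  structure(out, class = c("bin_scheme", class(tibble::tibble())),
            kind = kind, overlapping = kind == "term")
}

# equal-count bins by rank; returns integers 1..n_bins (fewer when n < n_bins)
equal_count_bins <- function(values, n_bins) {
  n <- length(values)
  r <- rank(values, ties.method = "first")
  pmin(ceiling(r / n * n_bins), n_bins)
}

# approximately equal-count bins where tied values share a bin: fill bins
# greedily over distinct values in ascending order
tied_equal_count_bins <- function(values, n_bins) {
  n <- length(values)
  target <- n / n_bins
  vals <- sort(unique(values))
  counts <- as.integer(table(factor(values, levels = vals)))
  bin_of_val <- integer(length(vals))
  bin <- 1L
  filled <- 0
  for (i in seq_along(vals)) {
    if (filled >= target * bin && bin < n_bins) {
      bin <- bin + 1L
    }
    bin_of_val[i] <- bin
    filled <- filled + counts[i]
  }
  bin_of_val[match(values, vals)]
}

#' Interaction-density matrix between annotation bins
#'
#' For bins A, B of a scheme, the density is the number of distinct
#' interactions with one endpoint in A and the other in B, normalized by the
#' number of possible interactions: `D_AB = n_AB / (|A||B|/2)` off-diagonal
#' and `D_AA = n_AA / choose(|A|, 2)` on the diagonal. The off-diagonal
#' denominator halves the pair count, so off-diagonal densities can exceed
#' 1; the matrix is still useful as a relative measure and the convention is
#' kept as stated. For overlapping (term) schemes the denominator is instead
#' the number of unique unordered cross-bin gene pairs, which accounts for
#' genes shared between bins.
#'
#' @param edges tibble of canonical edges (`from`, `to`), e.g. the union of
#'   a corpus's edge sets.
#' @param bins a `bin_scheme` from [bin_genes()].
#' @return a `density_matrix`: list with `bins` (labels), `D`, `n`,
#'   `possible` (bin x bin matrices).
#' @export
interaction_density <- function(edges, bins) {
  labels <- sort(unique(bins$bin))
  nb <- length(labels)
  genes_by_bin <- split(bins$gene, factor(bins$bin, levels = labels))
  sizes <- lengths(genes_by_bin)
  overlapping <- isTRUE(attr(bins, "overlapping"))

  # count distinct interactions per unordered bin pair
  n_mat <- matrix(0, nb, nb, dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    ef <- dplyr::inner_join(edges, bins, by = c(from = "gene"),
                            relationship = "many-to-many") |>
      dplyr::rename(bin_from = "bin")
    eft <- dplyr::inner_join(ef, bins, by = c(to = "gene"),
                             relationship = "many-to-many") |>
      dplyr::rename(bin_to = "bin")
    cells <- eft |>
      dplyr::mutate(bin_a = pmin(.data$bin_from, .data$bin_to),
                    bin_b = pmax(.data$bin_from, .data$bin_to)) |>
      dplyr::distinct(.data$from, .data$to, .data$bin_a, .data$bin_b) |>
      dplyr::count(.data$bin_a, .data$bin_b)
    for (r in seq_len(nrow(cells))) {
      i <- match(cells$bin_a[r], labels)
      j <- match(cells$bin_b[r], labels)
      n_mat[i, j] <- n_mat[i, j] + cells$n[r]
      if (i != j) n_mat[j, i] <- n_mat[j, i] + cells$n[r]
    }
  }

  possible <- matrix(0, nb, nb, dimnames = list(labels, labels))
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      if (i == j) {
        possible[i, j] <- choose(sizes[i], 2)
      } else if (overlapping) {
        possible[i, j] <- possible[j, i] <- n_cross_pairs(genes_by_bin[[i]], genes_by_bin[[j]])
      } else {
        possible[i, j] <- possible[j, i] <- sizes[i] * sizes[j] / 2
      }
    }
  }
  D <- ifelse(possible > 0, n_mat / possible, NA_real_)
  structure(list(bins = labels, D = D, n = n_mat, possible = possible),
            class = "density_matrix")
}

# unique unordered pairs {u, v}, u in A, v in B, u != v, counted once
n_cross_pairs <- function(a, b) {
  shared <- length(intersect(a, b))
  only_a <- length(a) - shared
  only_b <- length(b) - shared
  only_a * only_b + shared * (only_a + only_b) + choose(shared, 2)
}

#' Classify tissue specificity of expression profiles
#'
#' HPA-style classes with precedence: `low` (below `low_cutoff` in every
#' tissue), `tissue_enriched` (one tissue at least `fold` times every other
#' tissue), `group_enriched` (a group of 2-7 tissues each at least `fold`
#' times every non-group tissue, found greedily over tissues sorted
#' descending), `tissue_enhanced` (one tissue at least `fold` times the mean
#' of the others), else `broad`. Defaults are the mRNA convention
#' (`fold = 5`, `low_cutoff = 1` TPM); protein abundance uses `fold = 3`,
#' `low_cutoff = 0.5`.
#'
#' @param profiles tibble with columns `gene`, `tissue`, `value`.
#' @param fold fold-change threshold.
#' @param low_cutoff below this in all tissues the gene is class `low`.
#' @param max_group_size maximum group size for `group_enriched`.
#' @return tibble with columns `gene`, `class`, `tissues` (comma-joined
#'   enriched tissues, `NA` for low/broad). Genes with all-missing profiles
#'   are absent.
#' @export
classify_tissue_specificity <- function(profiles, fold = 5, low_cutoff = 1,
                                        max_group_size = 7) {
  profiles |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(
      cls = list(classify_one_profile(.data$value, .data$tissue, fold,
                                      low_cutoff, max_group_size)),
      .by = "gene"
    ) |>
    tidyr::unnest_wider("cls")
}

classify_one_profile <- function(v, tissues, fold, low_cutoff, max_group_size) {
  if (all(v < low_cutoff)) return(list(class = "low", tissues = NA_character_))
  ord <- order(v, decreasing = TRUE)
  v <- v[ord]
  tissues <- tissues[ord]
  k <- length(v)
  if (k >= 2 && v[1] >= fold * v[2]) {
    return(list(class = "tissue_enriched", tissues = tissues[1]))
  }
  # greedy group search: grow from the top; accept the first group of 2..max
  # whose minimum is fold x the largest non-group tissue
  if (k >= 3) {
    for (g in 2:min(max_group_size, k - 1)) {
      if (v[g] >= fold * v[g + 1]) {
        return(list(class = "group_enriched",
                    tissues = paste(tissues[seq_len(g)], collapse = ",")))
      }
    }
  }
  for (i in seq_len(k)) {
    if (v[i] >= fold * mean(v[-i])) {
      return(list(class = "tissue_enhanced", tissues = tissues[i]))
    }
  }
  list(class = "broad", tissues = NA_character_)
}

#' Propagate term annotations up a term hierarchy
#'
#' Every gene associated with a term becomes associated with all ancestors
#' of that term. The parent relation must be acyclic. Idempotent.
#'
#' @param associations tibble with columns `term`, `gene`.
#' @param parents tibble with columns `child`, `parent` (may be empty).
#' @return tibble with columns `term`, `gene`, closed under the ancestor
#'   relation.
#' @export
propagate_term_annotations <- function(associations, parents) {
  if (nrow(parents) == 0) return(dplyr::distinct(associations, .data$term, .data$gene))
  anc <- term_ancestors(parents)
  extra <- associations |>
    dplyr::inner_join(anc, by = c(term = "child"),
                      relationship = "many-to-many") |>
    dplyr::transmute(term = .data$ancestor, gene = .data$gene)
  dplyr::distinct(dplyr::bind_rows(associations[, c("term", "gene")], extra))
}

# transitive closure of the child -> parent relation; errors on cycles
term_ancestors <- function(parents) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(parents$child),
               to = as.character(parents$parent)),
    directed = TRUE
  )
  if (!igraph::is_dag(g)) stop("cycle in term parent edges", call. = FALSE)
  nodes <- igraph::V(g)$name
  rows <- purrr::map(nodes, function(nd) {
    up <- setdiff(names(igraph::subcomponent(g, nd, mode = "out")), nd)
    if (length(up) == 0) return(NULL)
    tibble::tibble(child = nd, ancestor = up)
  })
  dplyr::bind_rows(rows)
}

#' Select slim terms by size with parent exclusion
#'
#' Keeps terms whose (closed) gene count lies in `[min_genes, max_genes]`,
#' then drops any kept term that is an ancestor of another kept term, so the
#' surviving terms are the most specific in-range ones.
#'
#' @param associations closed (term, gene) associations, e.g. from
#'   [propagate_term_annotations()].
#' @param parents tibble with columns `child`, `parent`.
#' @param min_genes,max_genes inclusive size range.
#' @return character vector of term ids.
#' @export
select_slim_terms <- function(associations, parents, min_genes = 100,
                              max_genes = 4000) {
  sizes <- associations |> dplyr::distinct(.data$term, .data$gene) |>
    dplyr::count(.data$term)
  kept <- sizes$term[sizes$n >= min_genes & sizes$n <= max_genes]
  if (length(kept) <= 1 || nrow(parents) == 0) return(sort(kept))
  anc <- term_ancestors(parents)
  is_parent_of_kept <- unique(anc$ancestor[anc$child %in% kept])
  sort(setdiff(kept, is_parent_of_kept))
}

#' Term enrichment of a gene set by Fisher's exact test
#'
#' Two-sided Fisher's exact test of each term set against the target over
#' the background, with Benjamini-Hochberg correction across terms.
#'
#' @param target integer vector of target gene ids (subset of background).
#' @param term_sets tibble with columns `term`, `gene`.
#' @param background integer vector of background gene ids.
#' @return tibble with columns `term`, `n_overlap`, `odds_ratio`, `p`, `q`.
#' @export
enrich_gene_sets <- function(target, term_sets, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  target <- intersect(unique(target), background)
  res <- term_sets |>
    dplyr::distinct(.data$term, .data$gene) |>
    dplyr::filter(.data$gene %in% background) |>
    dplyr::summarise(stats = list({
      in_term <- .data$gene
      a <- length(intersect(target, in_term))
      b <- length(target) - a
      c_ <- length(in_term) - a
      d <- length(background) - a - b - c_
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      tibble::tibble(n_overlap = a, odds_ratio = unname(ft$estimate), p = ft$p.value)
    }), .by = "term") |>
    tidyr::unnest("stats")
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
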