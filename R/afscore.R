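#' Structure-model confidence score
#'
#' The standard multimer model confidence `0.8 * ipTM + 0.2 * pTM`,
#' weighting the interface score over the global fold score.
#'
#' @param iptm interface predicted template-modeling score in \[0, 1\].
#' @param ptm predicted template-modeling score in \[0, 1\].
#' @return confidence in \[0, 1\]; vectorized.
#' @export
model_confidence <- function(iptm, ptm) {
  if (any(iptm < 0 | iptm > 1 | ptm < 0 | ptm > 1)) {
    stop("ipTM and pTM must lie in [0, 1]", call. = FALSE)
  }
  0.8 * iptm + 0.2 * ptm
}

#' Select the best model per pair by confidence
#'
#' Keeps, for every modeled pair, the record with the highest
#' [model_confidence()]; confidence ties resolve to the lowest model id.
#'
#' @param scores tibble with columns `pair`, `model`, `iptm`, `ptm`.
#' @return tibble with one row per pair: `pair`, `model`, `iptm`, `ptm`,
#'   `confidence`.
#' @export
select_best_model <- function(scores) {
  if (nrow(scores) == 0) stop("no model scores supplied", call. = FALSE)
  scores |>
    dplyr::mutate(confidence = model_confidence(.data$iptm, .data$ptm)) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$model) |>
    dplyr::slice_head(n = 1, by = "pair")
}

#' Support threshold from a background score distribution
#'
#' The stated percentile of the background ipTM distribution (linear
#' interpolation between order statistics, R quantile type 7); scores above
#' it are flagged structurally supported. The threshold is always derived
#' from the supplied background, never a fixed constant, because percentile
#' cutoffs are only meaningful relative to their own background sample.
#'
#' @param background numeric vector of background ipTM values (>= 20).
#' @param percentile percentile in \[0, 100\] (default 95).
#' @return the threshold value.
#' @export
support_threshold <- function(background, percentile = 95) {
  if (length(background) < 20) {
    stop("background too small for percentile estimation (need >= 20)",
         call. = FALSE)
  }
  unname(stats::quantile(background, percentile / 100, type = 7))
}

#' Compare score groups to a background distribution
#'
#' Two-sided Mann-Whitney U test of each group's ipTM scores against the
#' background, with Benjamini-Hochberg correction across groups. Groups
#' with fewer than `min_n` values are skipped with a warning.
#'
#' @param groups named list of numeric score vectors.
#' @param background numeric vector of background scores.
#' @param min_n minimum group size (default 3).
#' @return tibble with columns `group`, `n`, `median`, `u`, `p`, `q`.
#' @export
compare_to_background <- function(groups, background, min_n = 3) {
  keep <- lengths(groups) >= min_n
  if (any(!keep)) {
    warning("skipping undersized groups: ",
            paste(names(groups)[!keep], collapse = ", "))
  }
  groups <- groups[keep]
  rows <- purrr::imap(groups, function(x, nm) {
    wt <- suppressWarnings(stats::wilcox.test(x, background, exact = FALSE))
    tibble::tibble(group = nm, n = length(x), median = stats::median(x),
                   u = unname(wt$statistic), p = wt$p.value)
  }) |>
    dplyr::bind_rows()
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows
}

#' Read a model-score TSV
#'
#' Flat records of externally produced structure-model scores: columns
#' `pair`, `model`, `iptm`, `ptm`.
#'
#' @param path file path.
#' @return tibble with those columns.
#' @export
read_model_scores <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("pair", "model", "iptm", "ptm")
  if (!all(need %in% names(raw))) {
    stop("model-score file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(raw[, need])
}

#' Structural-support report for modeled pairs
#'
#' Best-model selection, data-derived support threshold, and per-pair
#' supported flags in one call.
#'
#' @param scores tibble with columns `pair`, `model`, `iptm`, `ptm`.
#' @param background numeric background ipTM vector.
#' @param percentile support percentile (default 95).
#' @return list with `threshold` and `report` (tibble: pair, model, iptm,
#'   ptm, confidence, supported).
#' @export
af_support_report <- function(scores, background, percentile = 95) {
  best <- select_best_model(scores)
  thr <- support_threshold(background, percentile)
  best$supported <- best$iptm > thr
  list(threshold = thr, report = best)
}
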