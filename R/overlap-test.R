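#' Number of query exons regulated by a dataset
#'
#' Size of the coordinate-identity intersection between a (possibly
#' coordinate-only) input list and a dataset's regulated exons.
#'
#' @param inputExons GRanges exon records.
#' @param dataset an [SFDataset-class].
#' @return integer count N.
#' @export
countRegulated <- function(inputExons, dataset) {
  sum(exonKey(inputExons) %in% exonKey(exons(dataset)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values; order-preserving with the
#' input, monotone, capped at 1. Thin wrapper over [stats::p.adjust()] so the
#' correction used across the package is a single documented choice.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same order as input.
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Coordinate-only overlap randomization test for one dataset
#'
#' Tests whether the number N of input exons regulated by a dataset is
#' enriched or impoverished relative to chance. `nControlSets` control sets
#' of the same size as the (retained) input are sampled uniformly without
#' replacement from the exon universe, the regulated count is computed for
#' each, and the empirical p-value is
#' `p_emp = (min(k, l) + 1) / (nControlSets + 1)`, where `k` is the number of
#' control sets with count >= N and `l` the number with count <= N (both
#' inclusive, so control sets hitting exactly N contribute to both). The
#' direction label compares N to the control median: above = enriched, below
#' = depleted, at the median = none.
#'
#' Note the statistic is a two-sided empirical tail without doubling; see the
#' package vignette for its calibration properties.
#'
#' @param inputExons GRanges input exon records; records outside the universe
#'   are dropped with a warning.
#' @param dataset an [SFDataset-class].
#' @param universe character vector of exon identity keys (or GRanges),
#'   typically [registryUniverse()]. Must be at least as large as the input.
#' @param nControlSets number of control sets (default 10^4).
#' @param seed optional integer seed.
#' @param controlCounts optional precomputed matrix-free shortcut: integer
#'   vector of control counts for this dataset (used by [runQueryMode2()] to
#'   share one batch of control sets across all datasets).
#' @return one-row data.frame: `n_observed`, `expected_count`, `k`, `l`,
#'   `p_emp`, `direction`.
#' @export
randomizationTest <- function(inputExons, dataset, universe,
                              nControlSets = 10000, seed = NULL,
                              controlCounts = NULL) {
  if (is(universe, "GRanges")) universe <- exonKey(universe)
  if (anyDuplicated(universe)) universe <- unique(universe)
  keys <- exonKey(inputExons)
  if (length(universe) < length(keys))
    stop("universe smaller than the input list")
  inside <- keys %in% universe
  if (!all(inside)) {
    warning(sprintf("%d input exon(s) outside the universe were dropped",
                    sum(!inside)))
    keys <- keys[inside]
  }
  m <- length(keys)
  member <- universe %in% exonKey(exons(dataset))
  N <- sum(keys %in% exonKey(exons(dataset)))
  if (is.null(controlCounts)) {
    controlCounts <- withSeed(seed, {
      vapply(seq_len(nControlSets),
             function(i) sum(member[sample.int(length(universe), m)]),
             numeric(1))
    })
  }
  k <- sum(controlCounts >= N)
  l <- sum(controlCounts <= N)
  med <- stats::median(controlCounts)
  data.frame(
    n_observed = N, expected_count = mean(controlCounts), k = k, l = l,
    p_emp = (min(k, l) + 1) / (length(controlCounts) + 1),
    direction = if (N > med) "enriched" else if (N < med) "depleted" else "none",
    stringsAsFactors = FALSE)
}

#' Mode-2 query: overlap randomization across the registry
#'
#' Runs the coordinate-only randomization test against every dataset (or
#' against per-SF unions of datasets with `sfUnion = TRUE`), sharing one batch
#' of sampled control sets across all tests, then applies Benjamini-Hochberg
#' correction across that family.
#'
#' @param query GRanges input exon records (statistics not required).
#' @param registry a [SpliceRegistry-class].
#' @param nControlSets number of control sets (default 10^4).
#' @param seed optional integer seed.
#' @param universe sampling frame as identity keys or GRanges; default = all
#'   distinct exons present in at least one registry dataset.
#' @param sfUnion if TRUE, datasets of the same SF are merged (union of exon
#'   identities) and tested once per SF.
#' @return data.frame with one row per dataset (or SF), columns `sf_name`,
#'   `cell_line`, `dataset`, `n_observed`, `expected_count`, `k`, `l`,
#'   `p_emp`, `q_bh`, `direction`, ordered by `p_emp`.
#' @export
runQueryMode2 <- function(query, registry, nControlSets = 10000, seed = NULL,
                          universe = NULL, sfUnion = FALSE) {
  if (!length(registry)) stop("empty registry")
  if (is.null(universe)) universe <- registryUniverse(registry)
  if (is(universe, "GRanges")) universe <- exonKey(universe)
  universe <- unique(universe)
  keys <- unique(exonKey(query))
  if (length(universe) < length(keys))
    stop("universe smaller than the input list")
  inside <- keys %in% universe
  if (!all(inside)) {
    warning(sprintf("%d query exon(s) outside the universe were dropped",
                    sum(!inside)))
    keys <- keys[inside]
  }
  m <- length(keys)
  if (m == 0L) stop("no query exons inside the universe")

  targets <- if (sfUnion) {
    sfs <- vapply(datasets(registry), sfName, character(1))
    lapply(split(names(registry), sfs), function(ids) {
      list(label = paste(ids, collapse = ","),
           sf = sfName(registry[[ids[1]]]), cell = "union",
           keys = unique(unlist(lapply(ids, function(id)
             exonKey(exons(registry[[id]]))))))
    })
  } else {
    lapply(names(registry), function(id)
      list(label = id, sf = sfName(registry[[id]]),
           cell = cellLine(registry[[id]]),
           keys = exonKey(exons(registry[[id]]))))
  }

  # one batch of control sets, reused for every SF
  idx <- withSeed(seed, {
    matrix(unlist(lapply(seq_len(nControlSets),
                         function(i) sample.int(length(universe), m))),
           nrow = m, ncol = nControlSets)
  })
  rows <- lapply(targets, function(tg) {
    member <- universe %in% tg$keys
    counts <- colSums(matrix(member[idx], nrow = m))
    N <- sum(keys %in% tg$keys)
    k <- sum(counts >= N); l <- sum(counts <= N)
    med <- stats::median(counts)
    data.frame(sf_name = tg$sf, cell_line = tg$cell, dataset = tg$label,
               n_observed = N, expected_count = mean(counts), k = k, l = l,
               p_emp = (min(k, l) + 1) / (nControlSets + 1),
               direction = if (N > med) "enriched"
                           else if (N < med) "depleted" else "none",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_bh <- bhAdjust(res$p_emp)
  res <- res[order(res$p_emp, res$dataset), , drop = FALSE]
  rownames(res) <- NULL
  res
}
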