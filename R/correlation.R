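#' Shared-exon delta-PSI pairs between a query and a dataset
#'
#' Exons are matched by coordinate identity ([exonKey()]); the returned pairs
#' are ordered by genomic coordinate, so downstream statistics are
#' deterministic.
#'
#' @param query GRanges exon records carrying `delta_psi`.
#' @param dataset an [SFDataset-class].
#' @return list with `pairs` (data.frame: `key`, `query_dpsi`, `dataset_dpsi`)
#'   and `n_shared`.
#' @export
sharedPairs <- function(query, dataset) {
  dex <- exons(dataset)
  qk <- exonKey(query)
  if (anyDuplicated(qk)) stop("duplicate exon identities in query")
  hit <- match(qk, exonKey(dex))
  sel <- which(!is.na(hit))
  ord <- sel[order(as.character(seqnames(query))[sel], start(query)[sel],
                   end(query)[sel])]
  pairs <- data.frame(
    key = qk[ord],
    query_dpsi = mcols(query)$delta_psi[ord],
    dataset_dpsi = mcols(dex)$delta_psi[hit[ord]],
    stringsAsFactors = FALSE)
  list(pairs = pairs, n_shared = nrow(pairs))
}

#' Pearson correlation of delta-PSI over shared exons
#'
#' @param pairs result of [sharedPairs()].
#' @param minShared minimum number of shared exons required (default 10);
#'   below this, or with zero variance on either side, the correlation is not
#'   computable and NA is returned.
#' @return Pearson r, or NA_real_ when not computable.
#' @export
pearsonDeltaPsi <- function(pairs, minShared = 10) {
  x <- pairs$pairs$query_dpsi
  y <- pairs$pairs$dataset_dpsi
  if (length(x) < max(minShared, 3L)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
allPermutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    shifted <- sub + (sub >= k)
    cbind(rep.int(k, nrow(sub)), shifted, deparse.level = 0)
  }))
}

#' Directional empirical p-values for the delta-PSI correlation
#'
#' The null of "randomly associated exons" is simulated by shuffling the
#' pairing between the query and dataset delta-PSI values within the shared
#' set (label permutation, preserving both marginals). `p_pos` is the
#' probability of a permuted correlation as high or higher than the observed
#' one; `p_neg` uses as low or lower. Both comparisons are inclusive and the
#' p-values are floored at the resolution 1/`nPermutations` (so 1e-4 at the
#' default 10^4 permutations).
#'
#' @param pairs result of [sharedPairs()].
#' @param nPermutations number of random shuffles (default 10^4).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param method `"sample"` draws `nPermutations` uniform random shuffles;
#'   `"exhaustive"` enumerates all n! distinct pairings (n <= 9) and returns
#'   the exact permutation tail probabilities (the observed pairing is one of
#'   the n!, so the floor is automatic).
#' @param minShared passed to the computability rule of [pearsonDeltaPsi()].
#' @return named numeric: `p_pos`, `p_neg` (NA when r is not computable).
#' @export
empiricalPvalues <- function(pairs, nPermutations = 10000, seed = NULL,
                             method = c("sample", "exhaustive"),
                             minShared = 10) {
  method <- match.arg(method)
  robs <- pearsonDeltaPsi(pairs, minShared = minShared)
  if (is.na(robs)) return(c(p_pos = NA_real_, p_neg = NA_real_))
  x <- pairs$pairs$query_dpsi
  y <- pairs$pairs$dataset_dpsi
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  eps <- 1e-9
  if (method == "exhaustive") {
    if (n > 9L) stop("exhaustive enumeration limited to 9 shared exons")
    perms <- allPermutations(n)
    rperm <- vapply(seq_len(nrow(perms)), function(i)
      sum(xs[perms[i, ]] * ys) / (n - 1), numeric(1))
    return(c(p_pos = sum(rperm >= robs - eps) / nrow(perms),
             p_neg = sum(rperm <= robs + eps) / nrow(perms)))
  }
  stopifnot(nPermutations >= 1)
  rperm <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i)
      sum(xs[sample.int(n)] * ys) / (n - 1), numeric(1))
  })
  c(p_pos = max(sum(rperm >= robs - eps), 1L) / nPermutations,
    p_neg = max(sum(rperm <= robs + eps), 1L) / nPermutations)
}

#' Overlap fractions between a query list and a dataset
#'
#' `percent.sig.input` is the percentage of significantly regulated query
#' exons that are also present in the dataset; `percent.sig.SF` is the
#' percentage of the dataset's (significant, by construction) exons present
#' in the query list. `percent.common.query` / `percent.common.SF` are the
#' same membership fractions computed over all listed exons, ignoring
#' significance. Empty denominators yield 0 with attribute
#' `emptyDenominator = TRUE`.
#'
#' @param query GRanges exon records (with statistics).
#' @param dataset an [SFDataset-class].
#' @param deltaPsiThreshold,pvalueThreshold significance rule applied to the
#'   query side.
#' @return named numeric of the four percentages in \[0, 100\].
#' @export
overlapFractions <- function(query, dataset, deltaPsiThreshold = 10,
                             pvalueThreshold = 0.05) {
  dk <- exonKey(exons(dataset))
  qk <- exonKey(query)
  sig <- significantSubset(query, deltaPsiThreshold, pvalueThreshold)
  sk <- exonKey(sig)
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  out <- c(
    percent.sig.input = pct(sum(sk %in% dk), length(sk)),
    percent.sig.SF = pct(sum(dk %in% qk), length(dk)),
    percent.common.query = pct(sum(qk %in% dk), length(qk)),
    percent.common.SF = pct(sum(dk %in% qk), length(dk)))
  attr(out, "emptyDenominator") <-
    length(sk) == 0 || length(dk) == 0 || length(qk) == 0
  out
}

#' Composite confidence Score
#'
#' The arithmetic mean of `1 - pvalue`, `percent.sig.input / 100` and
#' `percent.sig.SF / 100`; it ranges between 0 and 1 and summarizes, per
#' dataset, how strongly (and how extensively) the query's regulation matches
#' the dataset's.
#'
#' @param pvalue directional empirical p-value in \[0, 1\].
#' @param percentSigInput,percentSigSF percentages in \[0, 100\].
#' @return Score in \[0, 1\].
#' @export
compositeScore <- function(pvalue, percentSigInput, percentSigSF) {
  (1 - pvalue + percentSigInput / 100 + percentSigSF / 100) / 3
}

#' Direction-aware breakdown of shared exons
#'
#' Shared exons are partitioned by the sign of their regulation ("up" = more
#' included upon knockdown, dPSI > 0; "down" = dPSI < 0) on each side.
#' Percentages are relative to the query's up and down subset sizes over the
#' full query list. Exons with dPSI exactly 0 on either side belong to
#' neither class and are counted separately.
#'
#' @param query GRanges exon records with `delta_psi`.
#' @param dataset an [SFDataset-class].
#' @return one-row data.frame with counts `n_up_up`, `n_up_down`,
#'   `n_down_up`, `n_down_down` (query direction first), matching
#'   percentages `pct_*`, the query subset sizes and `n_zero_excluded`.
#' @export
updownBreakdown <- function(query, dataset) {
  sp <- sharedPairs(query, dataset)$pairs
  qUpTotal <- sum(mcols(query)$delta_psi > 0)
  qDownTotal <- sum(mcols(query)$delta_psi < 0)
  zero <- sp$query_dpsi == 0 | sp$dataset_dpsi == 0
  sp <- sp[!zero, , drop = FALSE]
  n <- function(qs, ds) sum(sign(sp$query_dpsi) == qs &
                            sign(sp$dataset_dpsi) == ds)
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  data.frame(
    n_up_up = n(1, 1), n_up_down = n(1, -1),
    n_down_up = n(-1, 1), n_down_down = n(-1, -1),
    pct_up_up = pct(n(1, 1), qUpTotal),
    pct_up_down = pct(n(1, -1), qUpTotal),
    pct_down_up = pct(n(-1, 1), qDownTotal),
    pct_down_down = pct(n(-1, -1), qDownTotal),
    n_query_up = qUpTotal, n_query_down = qDownTotal,
    n_zero_excluded = sum(zero))
}

#' Compare a query list against one dataset (mode-1 core)
#'
#' Computes the full per-dataset comparison: Pearson r on shared exons,
#' directional empirical p-values, both directional Scores, overlap
#' fractions and the up/down breakdown. Datasets sharing fewer than
#' `minShared` exons with the query are flagged not computable rather than
#' dropped (r, p and Scores are NA).
#'
#' @inheritParams empiricalPvalues
#' @inheritParams overlapFractions
#' @return one-row data.frame (a ComparisonResult).
#' @export
compareDatasets <- function(query, dataset, nPermutations = 10000,
                            seed = NULL, minShared = 10,
                            deltaPsiThreshold = 10, pvalueThreshold = 0.05) {
  sp <- sharedPairs(query, dataset)
  r <- pearsonDeltaPsi(sp, minShared = minShared)
  pv <- empiricalPvalues(sp, nPermutations = nPermutations, seed = seed,
                         minShared = minShared)
  fr <- overlapFractions(query, dataset, deltaPsiThreshold, pvalueThreshold)
  ud <- updownBreakdown(query, dataset)
  computable <- !is.na(r)
  sp_ <- if (computable)
    c(compositeScore(pv["p_pos"], fr["percent.sig.input"], fr["percent.sig.SF"]),
      compositeScore(pv["p_neg"], fr["percent.sig.input"], fr["percent.sig.SF"]))
  else c(NA_real_, NA_real_)
  cbind(data.frame(
    dataset = datasetId(dataset), sf_name = sfName(dataset),
    cell_line = cellLine(dataset),
    pearson_r = r, p_pos = unname(pv["p_pos"]), p_neg = unname(pv["p_neg"]),
    score_pos = unname(sp_[1]), score_neg = unname(sp_[2]),
    n_shared = sp$n_shared, n_dataset_exons = length(exons(dataset)),
    percent.common.query = unname(fr["percent.common.query"]),
    percent.common.SF = unname(fr["percent.common.SF"]),
    percent.sig.input = unname(fr["percent.sig.input"]),
    percent.sig.SF = unname(fr["percent.sig.SF"]),
    computable = computable,
    stringsAsFactors = FALSE), ud)
}

#' Mode-1 query: correlation scoring against every registry dataset
#'
#' Runs [compareDatasets()] for each dataset and sorts the result by
#' `max(score_pos, score_neg)` descending (ties broken by dataset id;
#' not-computable rows sort last but are kept). Given a seed the output is
#' fully reproducible: each dataset's permutation stream is derived
#' deterministically from the seed and the dataset's position.
#'
#' @param query GRanges exon records with statistics.
#' @param registry a [SpliceRegistry-class].
#' @param queryBuild optional genome build tag of the query; if supplied and
#'   different from the registry's, the comparison is refused (no liftover).
#' @inheritParams compareDatasets
#' @return data.frame of ComparisonResults, one row per dataset.
#' @export
runQueryMode1 <- function(query, registry, nPermutations = 10000, seed = NULL,
                          minShared = 10, deltaPsiThreshold = 10,
                          pvalueThreshold = 0.05, queryBuild = NULL) {
  if (!length(registry)) stop("empty registry")
  if (!is.null(queryBuild) && !identical(queryBuild, registry@build))
    stop(sprintf("query build '%s' differs from registry build '%s'; %s",
                 queryBuild, registry@build,
                 "convert coordinates before querying"))
  ids <- sort(names(registry))
  rows <- lapply(seq_along(ids), function(i) {
    dseed <- if (is.null(seed)) NULL else (seed + i) %% 2147483647L
    compareDatasets(query, registry[[ids[i]]], nPermutations = nPermutations,
                    seed = dseed, minShared = minShared,
                    deltaPsiThreshold = deltaPsiThreshold,
                    pvalueThreshold = pvalueThreshold)
  })
  res <- do.call(rbind, rows)
  best <- pmax(res$score_pos, res$score_neg)
  ord <- order(-ifelse(is.na(best), -Inf, best), res$dataset)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
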