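#' Write the mode-1 Scores table
#'
#' Emits the per-dataset scoring table with exactly the columns of the Scores
#' report: `dataset, sf_name, cell_line, score_pos, p_pos, score_neg, p_neg,
#' n_dataset_exons, percent.common.query, percent.common.SF,
#' percent.sig.input, percent.sig.SF`, TSV, with a provenance header
#' (package version, config string, config hash). Output is colourless:
#' significance is conveyed by the columns.
#'
#' @param results data.frame from [runQueryMode1()].
#' @param path output path (written atomically).
#' @param config named list recorded in the provenance header (seed, counts).
#' @return `path`, invisibly.
#' @export
writeScoresTable <- function(results, path, config = list()) {
  cols <- c("dataset", "sf_name", "cell_line", "score_pos", "p_pos",
            "score_neg", "p_neg", "n_dataset_exons", "percent.common.query",
            "percent.common.SF", "percent.sig.input", "percent.sig.SF")
  atomicWrite(tsvLines(results[, cols, drop = FALSE], config), path)
}

#' Write the up/down details table
#'
#' One row per dataset: the direction-aware counts and fractions of shared
#' exons ([updownBreakdown()] columns), alongside dataset identity.
#'
#' @inheritParams writeScoresTable
#' @export
writeUpDownTable <- function(results, path, config = list()) {
  cols <- c("dataset", "sf_name", "cell_line", "n_shared",
            "n_up_up", "pct_up_up", "n_up_down", "pct_up_down",
            "n_down_up", "pct_down_up", "n_down_down", "pct_down_down",
            "n_query_up", "n_query_down", "n_zero_excluded")
  atomicWrite(tsvLines(results[, cols, drop = FALSE], config), path)
}

#' Write the shared delta-PSI pairs for one dataset (scatter data)
#'
#' @param pairs result of [sharedPairs()].
#' @param path output path.
#' @param config provenance config list.
#' @export
writePairsTable <- function(pairs, path, config = list()) {
  atomicWrite(tsvLines(pairs$pairs, config), path)
}

#' Write the mode-2 overlap test table
#'
#' @param results data.frame from [runQueryMode2()].
#' @inheritParams writeScoresTable
#' @export
writeOverlapTable <- function(results, path, config = list()) {
  cols <- c("sf_name", "cell_line", "dataset", "n_observed",
            "expected_count", "k", "l", "p_emp", "q_bh", "direction")
  atomicWrite(tsvLines(results[, cols, drop = FALSE], config), path)
}
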