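#' @import methods
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SFDataset: one splicing-factor knockdown dataset
#'
#' A named collection of significantly regulated cassette exons from a single
#' SF-knockdown experiment. Exons are held as a [GenomicRanges::GRanges] with
#' metadata columns `gene_symbol`, `exon_number`, `delta_psi` (percent, in
#' \[-100, 100\]) and `adj_pvalue`. A dataset only stores exons that pass the
#' differential-inclusion filter |dPSI| >= `deltaPsiThreshold` and
#' adj. p <= `pvalueThreshold` (defaults 10 and 0.05), and no two records may
#' share the same coordinate identity key (see [exonKey()]).
#'
#' @slot datasetId character(1), unique registry key.
#' @slot sfName character(1), splicing-factor symbol.
#' @slot cellLine character(1).
#' @slot perturbation character(1), e.g. "siRNA" or "shRNA".
#' @slot build character(1), genome build tag; cross-build comparisons are
#'   refused rather than lifted over.
#' @slot exons GRanges with the metadata columns described above.
#' @slot deltaPsiThreshold,pvalueThreshold numeric(1), the significance filter
#'   the stored exons satisfy.
#'
#' @seealso [SFDataset()] for construction, [SpliceRegistry-class]
#' @export
setClass("SFDataset",
  slots = c(
    datasetId = "character",
    sfName = "character",
    cellLine = "character",
    perturbation = "character",
    build = "character",
    exons = "GRanges",
    deltaPsiThreshold = "numeric",
    pvalueThreshold = "numeric"
  )
)

setValidity("SFDataset", function(object) {
  msg <- character()
  ex <- object@exons
  need <- c("gene_symbol", "exon_number", "delta_psi", "adj_pvalue")
  missing_cols <- setdiff(need, colnames(mcols(ex)))
  if (length(missing_cols)) {
    return(paste("exons lack metadata column(s):",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(object@datasetId) != 1L || !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be a single non-empty string")
  if (anyDuplicated(exonKey(ex)))
    msg <- c(msg, "duplicate exon identity keys in dataset")
  dp <- mcols(ex)$delta_psi
  pv <- mcols(ex)$adj_pvalue
  if (anyNA(dp) || anyNA(pv))
    msg <- c(msg, "dataset exons must carry delta_psi and adj_pvalue")
  else {
    if (any(abs(dp) > 100)) msg <- c(msg, "delta_psi outside [-100, 100]")
    if (any(pv < 0 | pv > 1)) msg <- c(msg, "adj_pvalue outside [0, 1]")
    if (any(abs(dp) < object@deltaPsiThreshold - 1e-9) ||
        any(pv > object@pvalueThreshold + 1e-12))
      msg <- c(msg, "dataset contains exons failing the significance filter")
  }
  if (any(!as.character(strand(ex)) %in% c("+", "-")))
    msg <- c(msg, "exon strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' SpliceRegistry: a collection of SFDataset objects
#'
#' Holds the SF-knockdown datasets a query is compared against, plus an
#' optional exon annotation table (a GRanges with `gene_symbol` and
#' `exon_number` metadata columns). All datasets must share one genome build.
#'
#' @slot datasets named list of [SFDataset-class] objects (names = datasetId).
#' @slot annotation GRanges annotation table (may be empty).
#' @slot build character(1) genome build shared by all datasets.
#' @export
setClass("SpliceRegistry",
  slots = c(datasets = "list", annotation = "GRanges", build = "character")
)

setValidity("SpliceRegistry", function(object) {
  msg <- character()
  ds <- object@datasets
  if (length(ds)) {
    if (!all(vapply(ds, is, logical(1), class2 = "SFDataset")))
      msg <- c(msg, "all registry entries must be SFDataset objects")
    else {
      ids <- unname(vapply(ds, function(d) d@datasetId, character(1)))
      if (!identical(names(ds), ids))
        msg <- c(msg, "registry list names must equal dataset ids")
      if (anyDuplicated(ids)) msg <- c(msg, "duplicate dataset ids")
      builds <- unique(vapply(ds, function(d) d@build, character(1)))
      if (length(builds) > 1L)
        msg <- c(msg, paste("registry mixes genome builds:",
                            paste(builds, collapse = ", ")))
      else if (length(builds) == 1L && !identical(builds, object@build))
        msg <- c(msg, "registry build tag disagrees with its datasets")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ValidationReport: classification of a query list against the annotation
#'
#' Partitions an input exon list into records whose coordinates and labels
#' match the annotation (`recognized`), records whose coordinates match but
#' whose gene symbol / exon number differ (`corrected`, with the annotation's
#' identity as the proposed fix) and records not found at all (`unknown`).
#'
#' @slot recognized GRanges of exact matches.
#' @slot corrected data.frame of mismatched records with proposal columns
#'   `proposed_gene_symbol`, `proposed_exon_number`.
#' @slot unknown GRanges of coordinate misses.
#' @slot inputSize integer(1), number of records classified.
#' @export
setClass("ValidationReport",
  slots = c(recognized = "GRanges", corrected = "data.frame",
            unknown = "GRanges", inputSize = "integer")
)

setValidity("ValidationReport", function(object) {
  n <- length(object@recognized) + nrow(object@corrected) +
    length(object@unknown)
  if (n != object@inputSize)
    return("recognized/corrected/unknown do not partition the input")
  TRUE
})

#' MotifModel: an RNA-binding-protein binding motif
#'
#' Either a position probability matrix (rows = positions, columns A/C/G/T,
#' rows summing to 1) or an IUPAC consensus string, or both. RNA alphabets are
#' mapped to DNA (U -> T) at read time.
#'
#' @slot name character(1), typically the SF symbol the motif belongs to.
#' @slot matrix position probability matrix or NULL.
#' @slot consensus IUPAC consensus string (NA if only a matrix is given).
#' @slot source character(1) free-text provenance tag.
#' @export
setClass("MotifModel",
  slots = c(name = "character", matrix = "matrixOrNULL",
            consensus = "character", source = "character")
)

setValidity("MotifModel", function(object) {
  msg <- character()
  m <- object@matrix
  if (!is.null(m)) {
    if (!identical(colnames(m), c("A", "C", "G", "T")))
      msg <- c(msg, "matrix columns must be A, C, G, T")
    else if (any(abs(rowSums(m) - 1) > 1e-6))
      msg <- c(msg, "matrix rows must each sum to 1 (tol 1e-6)")
  }
  if (is.null(m) && is.na(object@consensus))
    msg <- c(msg, "motif needs a matrix or a consensus")
  if (!is.na(object@consensus)) {
    bad <- setdiff(strsplit(object@consensus, "")[[1]],
                   names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
      msg <- c(msg, paste("non-IUPAC letters in consensus:",
                          paste(bad, collapse = "")))
  }
  if (length(msg)) msg else TRUE
})

#' RegistrySpec: parameters for the synthetic registry generator
#'
#' Describes the statistical structure of a synthetic dataset collection:
#' pairwise target overlap fractions and target Pearson correlations of
#' delta-PSI on the shared exons. Both matrices must be symmetric with unit
#' diagonal. Defaults reflect a desk-scale version of an SF-knockdown
#' collection: 500-exon datasets over a universe of a few thousand detected
#' exons, |dPSI| in the 10 to 60 percent band.
#'
#' @slot nSF integer(1) number of datasets.
#' @slot exonsPerDataset integer(1).
#' @slot universeSize integer(1) size of the detected-exon universe.
#' @slot overlap numeric matrix of pairwise shared-exon target fractions.
#' @slot correlation numeric matrix of target Pearson r on shared exons.
#' @slot signFraction numeric(1) fraction of negative (skipped) exons.
#' @slot magnitudeRange numeric(2) |dPSI| range, minimum >= the significance
#'   threshold so generated datasets always satisfy SFDataset validity.
#' @slot seed integer(1).
#' @export
setClass("RegistrySpec",
  slots = c(nSF = "integer", exonsPerDataset = "integer",
            universeSize = "integer", overlap = "matrix",
            correlation = "matrix", signFraction = "numeric",
            magnitudeRange = "numeric", seed = "integer")
)

setValidity("RegistrySpec", function(object) {
  msg <- character()
  n <- object@nSF
  for (nm in c("overlap", "correlation")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) msg <- c(msg, paste(nm, "must be nSF x nSF"))
    else {
      if (max(abs(m - t(m))) > 1e-12) msg <- c(msg, paste(nm, "must be symmetric"))
      if (any(abs(diag(m) - 1) > 1e-12)) msg <- c(msg, paste(nm, "needs unit diagonal"))
    }
  }
  if (any(object@overlap < 0 | object@overlap > 1))
    msg <- c(msg, "overlap fractions outside [0, 1]")
  if (any(abs(object@correlation) > 1))
    msg <- c(msg, "correlations outside [-1, 1]")
  if (object@magnitudeRange[1] < 10)
    msg <- c(msg, "magnitudeRange minimum below the 10-percent filter")
  if (object@magnitudeRange[1] >= object@magnitudeRange[2] ||
      object@magnitudeRange[2] > 100)
    msg <- c(msg, "magnitudeRange must be increasing and <= 100")
  if (object@exonsPerDataset > object@universeSize)
    msg <- c(msg, "exonsPerDataset exceeds universeSize")
  if (length(msg)) msg else TRUE
})
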