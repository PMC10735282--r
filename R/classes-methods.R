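#' Construct an SFDataset
#'
#' Builds a dataset from a GRanges of exon records (see [readExonTable()]).
#' When `filter = TRUE` (default) the records are first reduced to the
#' significant subset, mirroring how knockdown datasets are stored: only
#' differentially included exons (|dPSI| >= 10 percent, adjusted p <= 0.05 by
#' default) are kept.
#'
#' @param exons GRanges with `gene_symbol`, `exon_number`, `delta_psi`,
#'   `adj_pvalue` metadata columns.
#' @param sfName splicing-factor symbol.
#' @param datasetId unique registry key; default `"<sfName>_<cellLine>"`.
#' @param cellLine,perturbation,build free-text experiment descriptors.
#' @param deltaPsiThreshold,pvalueThreshold significance filter, percent and
#'   probability.
#' @param filter apply [significantSubset()] before storing.
#' @return an [SFDataset-class] object.
#' @export
SFDataset <- function(exons, sfName, cellLine = "NA", perturbation = "siRNA",
                      build = "synth1",
                      datasetId = paste(sfName, cellLine, sep = "_"),
                      deltaPsiThreshold = 10, pvalueThreshold = 0.05,
                      filter = TRUE) {
  if (filter)
    exons <- significantSubset(exons, deltaPsiThreshold, pvalueThreshold)
  exons <- exons[order(as.character(seqnames(exons)), start(exons),
                       end(exons), as.character(strand(exons)))]
  new("SFDataset", datasetId = datasetId, sfName = sfName,
      cellLine = cellLine, perturbation = perturbation, build = build,
      exons = exons, deltaPsiThreshold = deltaPsiThreshold,
      pvalueThreshold = pvalueThreshold)
}

#' Construct a SpliceRegistry
#'
#' @param datasets list of [SFDataset-class] objects.
#' @param annotation optional GRanges annotation table.
#' @return a [SpliceRegistry-class].
#' @export
SpliceRegistry <- function(datasets = list(), annotation = GRanges()) {
  ids <- vapply(datasets, datasetId, character(1))
  names(datasets) <- ids
  build <- if (length(datasets)) datasets[[1L]]@build else "synth1"
  new("SpliceRegistry", datasets = datasets, annotation = annotation,
      build = build)
}

#' @describeIn SFDataset accessor for the exon GRanges.
#' @param object,x an SFDataset.
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname SFDataset
#' @export
setMethod("exons", "SFDataset", function(x) x@exons)

#' @describeIn SFDataset the splicing-factor symbol.
#' @export
setGeneric("sfName", function(x) standardGeneric("sfName"))

#' @rdname SFDataset
#' @export
setMethod("sfName", "SFDataset", function(x) x@sfName)

#' @describeIn SFDataset the unique dataset key.
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname SFDataset
#' @export
setMethod("datasetId", "SFDataset", function(x) x@datasetId)

#' @describeIn SFDataset the cell line.
#' @export
setGeneric("cellLine", function(x) standardGeneric("cellLine"))

#' @rdname SFDataset
#' @export
setMethod("cellLine", "SFDataset", function(x) x@cellLine)

#' @describeIn SpliceRegistry accessor for the dataset list.
#' @param x a SpliceRegistry.
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))

#' @rdname SpliceRegistry
#' @export
setMethod("datasets", "SpliceRegistry", function(x) x@datasets)

#' @describeIn SpliceRegistry accessor for the annotation table.
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' @rdname SpliceRegistry
#' @export
setMethod("annotation", "SpliceRegistry", function(x) x@annotation)

#' @rdname SpliceRegistry
#' @export
setMethod("length", "SpliceRegistry", function(x) length(x@datasets))

#' @rdname SpliceRegistry
#' @export
setMethod("names", "SpliceRegistry", function(x) names(x@datasets))

#' @rdname SpliceRegistry
#' @param i dataset id or index.
#' @export
setMethod("[[", "SpliceRegistry", function(x, i) x@datasets[[i]])

#' Universe of exon identities covered by a registry
#'
#' The default sampling frame for the coordinate-only randomization test: all
#' distinct exons present in at least one registry dataset. If the registry
#' carries an annotation table, that wider set can be requested instead.
#'
#' @param registry a [SpliceRegistry-class].
#' @param useAnnotation if TRUE and an annotation is present, return all
#'   annotated exons rather than the union over datasets.
#' @return GRanges of distinct exons (identity keys unique).
#' @export
registryUniverse <- function(registry, useAnnotation = FALSE) {
  if (useAnnotation && length(annotation(registry)))
    return(unique(annotation(registry)))
  grl <- lapply(datasets(registry), function(d) {
    g <- exons(d)
    mcols(g) <- mcols(g)[, c("gene_symbol", "exon_number"), drop = FALSE]
    g
  })
  if (!length(grl)) return(GRanges())
  all <- suppressWarnings(do.call(c, unname(grl)))
  all[!duplicated(exonKey(all))]
}

setMethod("show", "SFDataset", function(object) {
  cat(sprintf("SFDataset %s: %s knockdown (%s) in %s [%s]\n",
              object@datasetId, object@sfName, object@perturbation,
              object@cellLine, object@build))
  dp <- mcols(object@exons)$delta_psi
  cat(sprintf("  %d significant exons (|dPSI| >= %g, adj.p <= %g); %d up / %d down\n",
              length(object@exons), object@deltaPsiThreshold,
              object@pvalueThreshold, sum(dp > 0), sum(dp < 0)))
})

setMethod("show", "SpliceRegistry", function(object) {
  cat(sprintf("SpliceRegistry [%s]: %d dataset(s), %d annotated exon(s)\n",
              object@build, length(object@datasets),
              length(object@annotation)))
  for (id in utils::head(names(object@datasets), 8L))
    cat(sprintf("  %s (%d exons)\n", id, length(object@datasets[[id]]@exons)))
  if (length(object@datasets) > 8L) cat("  ...\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d input record(s)\n", object@inputSize))
  cat(sprintf("  recognized: %d, corrected: %d, unknown: %d\n",
              length(object@recognized), nrow(object@corrected),
              length(object@unknown)))
})

setMethod("show", "MotifModel", function(object) {
  w <- if (!is.null(object@matrix)) nrow(object@matrix)
       else nchar(object@consensus)
  cat(sprintf("MotifModel %s: width %d, %s%s\n", object@name, w,
              if (is.null(object@matrix)) "consensus" else "PPM",
              if (!is.na(object@consensus))
                paste0(" (consensus ", object@consensus, ")") else ""))
})
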