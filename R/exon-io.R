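#' Read an exon table (dataset or query list)
#'
#' Parses the tab-separated exon-list dialect used throughout the package:
#' columns `gene_symbol exon_number chrom start end strand` plus, in
#' `with_stats` mode, `delta_psi` (percent, \[-100, 100\]) and `adj_pvalue`.
#' Lines starting with `#` are headers/comments and are skipped. Coordinates
#' in the file are 1-based inclusive and map directly onto the internal
#' GRanges convention; BED input (0-based half-open) is converted by
#' [readPeakBed()] instead.
#'
#' @param path file path.
#' @param mode `"with_stats"` (8 columns) or `"coords_only"` (6 columns). In
#'   coords-only mode `delta_psi`/`adj_pvalue` are set to NA: the two are
#'   always both present or both absent on a record.
#' @return GRanges with metadata columns `gene_symbol`, `exon_number`,
#'   `delta_psi`, `adj_pvalue`.
#' @seealso [writeExonTable()], [significantSubset()]
#' @export
readExonTable <- function(path, mode = c("with_stats", "coords_only")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol_expect <- if (mode == "with_stats") 8L else 6L
  parseNum <- function(x, what, i) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop(sprintf("line %d: malformed %s '%s'", i, what, x[is.na(v)][1]))
    v
  }
  recs <- lapply(seq_along(rows), function(j) {
    f <- rows[[j]]
    i <- lineno[j]
    if (length(f) != ncol_expect)
      stop(sprintf("line %d: expected %d tab-separated fields, got %d (mode %s)",
                   i, ncol_expect, length(f), mode))
    exn <- parseNum(f[2], "exon_number", i)
    if (exn < 1 || exn != round(exn))
      stop(sprintf("line %d: exon_number must be a positive integer, got '%s'",
                   i, f[2]))
    if (!nzchar(f[3])) stop(sprintf("line %d: empty chromosome name", i))
    st <- parseNum(f[4], "start", i); en <- parseNum(f[5], "end", i)
    if (st > en)
      stop(sprintf("line %d: start %s > end %s", i, f[4], f[5]))
    if (!f[6] %in% c("+", "-"))
      stop(sprintf("line %d: strand must be '+' or '-', got '%s'", i, f[6]))
    dp <- NA_real_; pv <- NA_real_
    if (mode == "with_stats") {
      dp <- parseNum(f[7], "delta_psi", i)
      pv <- parseNum(f[8], "adj_pvalue", i)
      if (abs(dp) > 100)
        stop(sprintf("line %d: delta_psi %g outside [-100, 100]", i, dp))
      if (pv < 0 || pv > 1)
        stop(sprintf("line %d: adj_pvalue %g outside [0, 1]", i, pv))
    }
    list(gene = f[1], exn = as.integer(exn), chrom = f[3],
         start = as.integer(st), end = as.integer(en), strand = f[6],
         dp = dp, pv = pv)
  })
  if (!length(recs)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(gene_symbol = character(),
                                      exon_number = integer(),
                                      delta_psi = numeric(),
                                      adj_pvalue = numeric())
    return(gr)
  }
  GRanges(
    seqnames = vapply(recs, `[[`, character(1), "chrom"),
    ranges = IRanges(vapply(recs, `[[`, integer(1), "start"),
                     vapply(recs, `[[`, integer(1), "end")),
    strand = vapply(recs, `[[`, character(1), "strand"),
    gene_symbol = vapply(recs, `[[`, character(1), "gene"),
    exon_number = vapply(recs, `[[`, integer(1), "exn"),
    delta_psi = vapply(recs, `[[`, numeric(1), "dp"),
    adj_pvalue = vapply(recs, `[[`, numeric(1), "pv"))
}

#' Write an exon table
#'
#' Inverse of [readExonTable()]: emits the tab-separated dialect with a
#' `#`-prefixed column header. Statistics columns are written only when
#' present (any non-NA delta_psi).
#'
#' @param exons GRanges as returned by [readExonTable()].
#' @param path output file path (written atomically).
#' @param provenance optional named list recorded in the file header.
#' @return `path`, invisibly.
#' @export
writeExonTable <- function(exons, path, provenance = NULL) {
  withStats <- length(exons) > 0 && !anyNA(mcols(exons)$delta_psi)
  cols <- c("gene_symbol", "exon_number", "chrom", "start", "end", "strand")
  if (withStats) cols <- c(cols, "delta_psi", "adj_pvalue")
  body <- if (length(exons)) {
    df <- data.frame(
      gene_symbol = mcols(exons)$gene_symbol,
      exon_number = mcols(exons)$exon_number,
      chrom = as.character(seqnames(exons)),
      start = start(exons), end = end(exons),
      strand = as.character(strand(exons)),
      stringsAsFactors = FALSE)
    if (withStats) {
      df$delta_psi <- mcols(exons)$delta_psi
      df$adj_pvalue <- mcols(exons)$adj_pvalue
    }
    do.call(paste, c(unname(df), sep = "\t"))
  } else character()
  header <- c(
    if (!is.null(provenance)) provenanceHeader(provenance),
    paste0("#", paste(cols, collapse = "\t")))
  atomicWrite(c(header, body), path)
}

#' Read / write an annotation table
#'
#' The annotation table maps exon identities (gene symbol, exon number) to
#' genomic intervals over all annotated exons; it drives input validation and
#' correction. Format: the 6-column coords-only exon dialect.
#'
#' @param path file path.
#' @return GRanges with `gene_symbol` and `exon_number` metadata columns.
#' @export
readAnnotationTable <- function(path) {
  gr <- readExonTable(path, mode = "coords_only")
  mcols(gr) <- mcols(gr)[, c("gene_symbol", "exon_number"), drop = FALSE]
  gr
}

#' @rdname readAnnotationTable
#' @param annotation GRanges annotation table.
#' @export
writeAnnotationTable <- function(annotation, path) {
  gr <- annotation
  mcols(gr)$delta_psi <- NA_real_
  mcols(gr)$adj_pvalue <- NA_real_
  writeExonTable(gr, path)
}

#' Filter exon records by the differential-inclusion significance rule
#'
#' An exon is significantly regulated iff |dPSI| >= `deltaPsiThreshold` and
#' adjusted p-value <= `pvalueThreshold` (both boundaries inclusive). The
#' defaults, 10 percent and 0.05, are the rule used to populate knockdown
#' datasets. Idempotent.
#'
#' @param records GRanges exon records carrying `delta_psi` and `adj_pvalue`.
#' @param deltaPsiThreshold percent, default 10.
#' @param pvalueThreshold probability, default 0.05.
#' @return the subset of `records` passing the filter.
#' @export
significantSubset <- function(records, deltaPsiThreshold = 10,
                              pvalueThreshold = 0.05) {
  dp <- mcols(records)$delta_psi
  pv <- mcols(records)$adj_pvalue
  if (anyNA(dp) || anyNA(pv))
    stop("significance undefined without delta_psi / adj_pvalue ",
         "(coords-only records)")
  records[abs(dp) >= deltaPsiThreshold & pv <= pvalueThreshold]
}

#' Validate a query list against the annotation
#'
#' Coordinates are the authoritative identity: a record whose coordinates
#' match an annotated exon but whose gene symbol or exon number differ is not
#' rejected; it is reported as correctable, with the annotation's identity as
#' the proposal. Exact matches are recognized; coordinate misses are unknown.
#' Every input record is classified (the three parts partition the input).
#'
#' @param records GRanges query exon records.
#' @param annotation GRanges annotation table ([readAnnotationTable()]).
#' @return a [ValidationReport-class].
#' @export
validateAgainstAnnotation <- function(records, annotation) {
  hit <- match(exonKey(records), exonKey(annotation))
  found <- !is.na(hit)
  sameGene <- rep(FALSE, length(records))
  sameExn <- rep(FALSE, length(records))
  sameGene[found] <- mcols(records)$gene_symbol[found] ==
    mcols(annotation)$gene_symbol[hit[found]]
  sameExn[found] <- mcols(records)$exon_number[found] ==
    mcols(annotation)$exon_number[hit[found]]
  exact <- found & sameGene & sameExn
  fixable <- found & !exact
  corrected <- data.frame(
    gene_symbol = mcols(records)$gene_symbol[fixable],
    exon_number = mcols(records)$exon_number[fixable],
    chrom = as.character(seqnames(records))[fixable],
    start = start(records)[fixable], end = end(records)[fixable],
    strand = as.character(strand(records))[fixable],
    proposed_gene_symbol = mcols(annotation)$gene_symbol[hit[fixable]],
    proposed_exon_number = mcols(annotation)$exon_number[hit[fixable]],
    stringsAsFactors = FALSE)
  new("ValidationReport", recognized = records[exact], corrected = corrected,
      unknown = records[!found], inputSize = length(records))
}

#' Read / write a dataset registry directory
#'
#' A registry is a directory of exon-table TSVs plus a `manifest.tsv` with
#' one row per dataset: `dataset_id sf_name cell_line perturbation build
#' path` (path relative to the directory). An optional `annotation.tsv` is
#' loaded as the annotation table.
#'
#' @param dir registry directory.
#' @param deltaPsiThreshold,pvalueThreshold significance filter applied when
#'   loading dataset files.
#' @return a [SpliceRegistry-class].
#' @export
readRegistry <- function(dir, deltaPsiThreshold = 10, pvalueThreshold = 0.05) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest)) stop("no manifest.tsv under ", dir)
  lines <- readLines(manifest)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ds <- lapply(rows, function(f) {
    if (length(f) != 6L)
      stop("manifest rows need 6 fields: dataset_id sf_name cell_line ",
           "perturbation build path")
    SFDataset(readExonTable(file.path(dir, f[6]), mode = "with_stats"),
              sfName = f[2], cellLine = f[3], perturbation = f[4],
              build = f[5], datasetId = f[1],
              deltaPsiThreshold = deltaPsiThreshold,
              pvalueThreshold = pvalueThreshold)
  })
  annPath <- file.path(dir, "annotation.tsv")
  ann <- if (file.exists(annPath)) readAnnotationTable(annPath) else GRanges()
  SpliceRegistry(ds, annotation = ann)
}

#' @rdname readRegistry
#' @param registry a [SpliceRegistry-class] to serialize.
#' @export
writeRegistry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(datasets(registry), function(d) {
    fn <- paste0(datasetId(d), ".tsv")
    writeExonTable(exons(d), file.path(dir, fn))
    paste(datasetId(d), sfName(d), cellLine(d), d@perturbation, d@build, fn,
          sep = "\t")
  }, character(1))
  atomicWrite(c("#dataset_id\tsf_name\tcell_line\tperturbation\tbuild\tpath",
                rows), file.path(dir, "manifest.tsv"))
  if (length(annotation(registry)))
    writeAnnotationTable(annotation(registry), file.path(dir, "annotation.tsv"))
  invisible(dir)
}
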