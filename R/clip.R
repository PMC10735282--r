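#' Read CLIP peaks from BED
#'
#' Standard BED (0-based half-open) via rtracklayer; converted to the internal
#' 1-based closed GRanges convention on import. The strand column is read but
#' peak overlap is strand-agnostic by default (see [enrichmentCell()]).
#'
#' @param path BED file path.
#' @return GRanges of peaks.
#' @export
readPeakBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Merge CLIP peak files into one PeakSet
#'
#' Peaks from experiments targeting the same SF are pooled and coalesced:
#' overlapping and abutting intervals become one (the BEDtools-merge default),
#' strand ignored. The result is sorted and non-overlapping.
#'
#' @param x list of BED file paths, or a GRanges / list of GRanges.
#' @return GRanges of merged, sorted, disjoint peaks.
#' @export
mergePeaks <- function(x) {
  if (is(x, "GRanges")) x <- list(x)
  grl <- lapply(x, function(el) {
    g <- if (is.character(el)) readPeakBed(el) else el
    strand(g) <- "*"
    mcols(g) <- NULL
    g
  })
  pooled <- suppressWarnings(do.call(c, unname(grl)))
  m <- GenomicRanges::reduce(pooled)
  m[order(as.character(seqnames(m)), start(m))]
}

#' Regulated and control exon classes for one SF
#'
#' Pools all knockdown samples of one SF: `up` is the union of exons with
#' dPSI > 0 in at least one sample, `down` the union with dPSI < 0. Exons
#' significantly regulated in opposite directions in different samples are
#' conflicted and excluded from every class, including the controls. Controls
#' are all other detected exons. An SF is usable for enrichment panels only
#' with at least `minClassSize` exons in *both* regulated classes (default
#' 100).
#'
#' @param datasetsForSF list of [SFDataset-class] objects, all for one SF.
#' @param allDetected GRanges of all detected exons (e.g.
#'   [registryUniverse()] over the full registry).
#' @param minClassSize usability cutoff per class.
#' @return list with GRanges `up`, `down`, `control`, character `conflicted`
#'   (keys), `sf_name` and logical `usable`.
#' @export
buildRegulatedClasses <- function(datasetsForSF, allDetected,
                                  minClassSize = 100) {
  stopifnot(length(datasetsForSF) >= 1)
  sf <- sfName(datasetsForSF[[1]])
  if (!all(vapply(datasetsForSF, sfName, character(1)) == sf))
    stop("datasetsForSF must all belong to one SF")
  keyDir <- lapply(datasetsForSF, function(d) {
    g <- exons(d)
    data.frame(key = exonKey(g), up = mcols(g)$delta_psi > 0)
  })
  kd <- do.call(rbind, keyDir)
  upKeys <- unique(kd$key[kd$up])
  downKeys <- unique(kd$key[!kd$up])
  conflicted <- intersect(upKeys, downKeys)
  upKeys <- setdiff(upKeys, conflicted)
  downKeys <- setdiff(downKeys, conflicted)
  allKeys <- exonKey(allDetected)
  ctrlKeys <- setdiff(allKeys, c(upKeys, downKeys, conflicted))
  pick <- function(keys) allDetected[match(keys, allKeys)]
  list(sf_name = sf,
       up = pick(intersect(allKeys, upKeys)),
       down = pick(intersect(allKeys, downKeys)),
       control = pick(ctrlKeys),
       conflicted = conflicted,
       usable = length(upKeys) >= minClassSize &&
                length(downKeys) >= minClassSize)
}

#' Exon-body and flanking 100-nt windows
#'
#' For each exon, the exon body plus three consecutive `windowSize`-nt windows
#' immediately 5' ("up3 up2 up1 exon") and three immediately 3'
#' ("exon down1 down2 down3") of the exon on its strand; up1/down1 are
#' adjacent to the exon and on the minus strand up/down are mirrored in
#' genomic space. Windows are truncated at position 1 (and at the chromosome
#' end if `seqlengths` are set); fully truncated windows come back zero-width.
#'
#' @param exonGr GRanges of exons.
#' @param windowSize window width in nt (default 100).
#' @return named list of seven GRanges (`exon_body`, `up1`..`up3`,
#'   `down1`..`down3`), each parallel to `exonGr`.
#' @export
regionWindows <- function(exonGr, windowSize = 100) {
  stopifnot(windowSize >= 1)
  chr <- as.character(seqnames(exonGr))
  minus <- as.character(strand(exonGr)) == "-"
  sl <- GenomeInfoDb::seqlengths(exonGr)[chr]
  bound <- ifelse(is.na(sl), Inf, sl)
  s <- start(exonGr); e <- end(exonGr)
  clip <- function(ws, we) {
    ws2 <- pmax(ws, 1)
    we2 <- pmin(we, bound)
    empty <- ws2 > we2
    # zero-width placeholders for fully truncated windows
    ws2[empty] <- 1; we2[empty] <- 0
    GRanges(chr, IRanges(ws2, we2), strand = strand(exonGr),
            seqinfo = GenomeInfoDb::seqinfo(exonGr))
  }
  win <- function(k, side) {
    # side +1 = genomically right of the exon, -1 = left
    left_s <- s - k * windowSize
    left_e <- s - (k - 1) * windowSize - 1
    right_s <- e + (k - 1) * windowSize + 1
    right_e <- e + k * windowSize
    ws <- ifelse(side > 0, right_s, left_s)
    we <- ifelse(side > 0, right_e, left_e)
    clip(ws, we)
  }
  out <- list(exon_body = clip(s, e))
  for (k in 1:3) {
    # upstream = 5' of the exon on its strand: genomic left for +, right for -
    out[[paste0("up", k)]] <- win(k, ifelse(minus, 1, -1))
    out[[paste0("down", k)]] <- win(k, ifelse(minus, -1, 1))
  }
  out[c("exon_body", "up1", "up2", "up3", "down1", "down2", "down3")]
}

# two-sided test for a difference between two overlap proportions:
# logistic regression (Wald test on the class coefficient), falling back to
# Fisher's exact test when any cell of the 2x2 table is empty (separation).
proportionTest <- function(regHit, ctrlHit) {
  nReg <- length(regHit); nCtrl <- length(ctrlHit)
  tab <- matrix(c(sum(regHit), nReg - sum(regHit),
                  sum(ctrlHit), nCtrl - sum(ctrlHit)), nrow = 2)
  if (any(tab == 0))
    return(stats::fisher.test(tab)$p.value)
  fit <- stats::glm(c(regHit, ctrlHit) ~ rep(c(1, 0), c(nReg, nCtrl)),
                    family = stats::binomial())
  stats::coef(summary(fit))[2, 4]
}

#' One CLIP-enrichment cell
#'
#' For one (exon class, region) cell: the fraction of regulated exons whose
#' region window overlaps a peak by at least one basepair (P_reg), the same
#' fraction over control exons (P_ctrl), the pseudocounted log-ratio
#' `R = log2((P_reg + 0.01) / (P_ctrl + 0.01))`, and a two-sided
#' logistic-regression (Wald) p-value for P_reg != P_ctrl, with a Fisher
#' exact fallback under separation. Peak overlap ignores strand unless
#' `strandSpecific`.
#'
#' @param regExons,ctrlExons GRanges of regulated and control exons.
#' @param peaks GRanges of merged peaks ([mergePeaks()]).
#' @param region one of `"exon_body"`, `"up1"`..`"up3"`, `"down1"`..`"down3"`.
#' @param windowSize flanking window width (default 100 nt).
#' @param strandSpecific restrict overlap to matching strand.
#' @return one-row data.frame: `region`, `n_reg`, `n_ctrl`, `p_reg`,
#'   `p_ctrl`, `r_value`, `pvalue`.
#' @export
enrichmentCell <- function(regExons, ctrlExons, peaks, region = "exon_body",
                           windowSize = 100, strandSpecific = FALSE) {
  if (length(regExons) == 0 || length(ctrlExons) == 0)
    return(data.frame(region = region, n_reg = length(regExons),
                      n_ctrl = length(ctrlExons), p_reg = NA_real_,
                      p_ctrl = NA_real_, r_value = NA_real_,
                      pvalue = NA_real_, stringsAsFactors = FALSE))
  hitIn <- function(gr) {
    w <- regionWindows(gr, windowSize)[[region]]
    GenomicRanges::countOverlaps(w, peaks,
                                 ignore.strand = !strandSpecific) > 0
  }
  regHit <- hitIn(regExons)
  ctrlHit <- hitIn(ctrlExons)
  pReg <- mean(regHit); pCtrl <- mean(ctrlHit)
  data.frame(region = region, n_reg = length(regExons),
             n_ctrl = length(ctrlExons), p_reg = pReg, p_ctrl = pCtrl,
             r_value = log2((pReg + 0.01) / (pCtrl + 0.01)),
             pvalue = proportionTest(regHit, ctrlHit),
             stringsAsFactors = FALSE)
}

#' CLIP-enrichment panel across a registry
#'
#' For every SF with both a peak set and usable regulated classes, computes
#' the full (class x region) grid of [enrichmentCell()] values and applies
#' Benjamini-Hochberg correction across all cells of the run (one heat-map
#' family). SFs whose classes are too small are reported with
#' `usable = FALSE` and no cells.
#'
#' @param registry a [SpliceRegistry-class].
#' @param peakSets named list of merged peak GRanges, names = SF symbols; or
#'   a data.frame manifest with columns `sf_name`, `path` (BED files, merged
#'   per SF).
#' @param minClassSize usability cutoff per regulated class (default 100).
#' @param windowSize flanking window width (default 100).
#' @param alpha significance level on the adjusted values (default 0.05).
#' @param strandSpecific restrict peak overlap to matching strand.
#' @return data.frame of cells: `sf_name`, `exon_class`, `region`, counts,
#'   proportions, `r_value`, `pvalue`, `q_bh`, `significant`.
#' @export
runClipPanel <- function(registry, peakSets, minClassSize = 100,
                         windowSize = 100, alpha = 0.05,
                         strandSpecific = FALSE) {
  if (is.data.frame(peakSets)) {
    stopifnot(all(c("sf_name", "path") %in% colnames(peakSets)))
    peakSets <- lapply(split(peakSets$path, peakSets$sf_name), mergePeaks)
  }
  universe <- registryUniverse(registry)
  sfs <- vapply(datasets(registry), sfName, character(1))
  regions <- c("exon_body", "up1", "up2", "up3", "down1", "down2", "down3")
  rows <- list()
  for (sf in intersect(unique(sfs), names(peakSets))) {
    cls <- buildRegulatedClasses(datasets(registry)[sfs == sf], universe,
                                 minClassSize = minClassSize)
    if (!cls$usable) next
    for (class in c("up", "down")) {
      for (rg in regions) {
        cell <- enrichmentCell(cls[[class]], cls$control, peakSets[[sf]],
                               region = rg, windowSize = windowSize,
                               strandSpecific = strandSpecific)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(sf_name = sf, exon_class = class,
                           stringsAsFactors = FALSE), cell)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sf_name = character(), exon_class = character(),
                      region = character(), n_reg = integer(),
                      n_ctrl = integer(), p_reg = numeric(),
                      p_ctrl = numeric(), r_value = numeric(),
                      pvalue = numeric(), q_bh = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q_bh <- bhAdjust(res$pvalue)
  res$significant <- !is.na(res$q_bh) & res$q_bh <= alpha
  rownames(res) <- NULL
  res
}
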