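# Shared fixture builders: everything is generated in code, no stored data.

# quick GRanges of exon records
makeExons <- function(chrom, start, end, strand = "+", gene = "GENE1",
                      exn = seq_along(start), dpsi = NA_real_,
                      pval = NA_real_) {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand,
    gene_symbol = rep_len(gene, length(start)),
    exon_number = as.integer(rep_len(exn, length(start))),
    delta_psi = rep_len(dpsi, length(start)),
    adj_pvalue = rep_len(pval, length(start)))
}

# dataset over the first `n` exons of an annotation, with given delta-PSI
datasetFromAnnotation <- function(ann, idx, dpsi, sf = "SFX", id = NULL,
                                  pval = 0.01) {
  ex <- ann[idx]
  S4Vectors::mcols(ex)$delta_psi <- dpsi
  S4Vectors::mcols(ex)$adj_pvalue <- rep_len(pval, length(idx))
  SFDataset(ex, sfName = sf, cellLine = "SYN",
            datasetId = if (is.null(id)) paste0(sf, "_SYN") else id,
            filter = FALSE)
}

# write exon records to a temp TSV and return the path
writeTempExons <- function(exons) {
  path <- tempfile(fileext = ".tsv")
  writeExonTable(exons, path)
  path
}

# independent permutation enumerator (oracle): all pairings of y against x,
# Pearson via cor(); deliberately different from the package's implementation
oraclePermutationP <- function(x, y) {
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  robs <- cor(x, y)
  rs <- vapply(permute(seq_along(x)), function(p) cor(x[p], y), numeric(1))
  c(p_pos = mean(rs >= robs - 1e-12), p_neg = mean(rs <= robs + 1e-12))
}

# independent BH step-up (oracle)
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# O(n^2) interval merge oracle (abutting intervals coalesce)
oracleMerge <- function(starts, ends, chrom) {
  df <- data.frame(chrom = chrom, start = starts, end = ends)
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j] &&
            df$start[j] <= df$end[i] + 1 && df$end[j] >= df$start[i] - 1) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df[order(df$chrom, df$start), ]
}
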