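# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Coordinate identity key of exon records
#'
#' Exons are matched across datasets by their genomic coordinates, not by
#' gene/exon labels: the key is `"chrom:start-end:strand"` on the internal
#' 1-based, closed-interval convention. Labels travel along as annotation.
#'
#' @param x a GRanges of exon records.
#' @return character vector of identity keys, one per range.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200), "+")
#' exonKey(gr)
#' @export
exonKey <- function(x) {
  sprintf("%s:%d-%d:%s", as.character(seqnames(x)), start(x), end(x),
          as.character(strand(x)))
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits (provenance tag).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256), so stay in doubles
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime; split h into 16-bit halves so
    # intermediate products stay exactly representable in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Write a table atomically: build in a sibling temp file, then rename.
atomicWrite <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Provenance header lines for output files.
provenanceHeader <- function(config = list()) {
  cfg <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = "; ")
  c(sprintf("# spliceScore %s",
            as.character(utils::packageVersion("spliceScore"))),
    sprintf("# config: %s", cfg),
    sprintf("# config_hash: %s", fnv1a(cfg)))
}

# Format a data.frame as provenance-headed TSV lines (column header '#'-prefixed).
tsvLines <- function(df, config = list()) {
  body <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(df[i, , drop = FALSE], function(v)
      if (is.numeric(v)) format(v, digits = 12, scientific = FALSE, trim = TRUE)
      else as.character(v), character(1)), collapse = "\t"),
    character(1))
  c(provenanceHeader(config),
    paste0("#", paste(colnames(df), collapse = "\t")), body)
}
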