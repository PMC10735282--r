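#' Construct a MotifModel
#'
#' @param name motif name, typically the SF symbol.
#' @param consensus IUPAC consensus string (RNA alphabets accepted; U mapped
#'   to T).
#' @param matrix position probability matrix, positions x A/C/G/T (or
#'   A/C/G/U). When only a matrix is given, a consensus is derived: at each
#'   position, the IUPAC code of the letters with probability >= 0.25.
#' @param source free-text provenance tag.
#' @return a [MotifModel-class].
#' @export
motifModel <- function(name, consensus = NULL, matrix = NULL,
                       source = "user") {
  if (!is.null(matrix)) {
    cn <- toupper(colnames(matrix))
    cn[cn == "U"] <- "T"
    colnames(matrix) <- cn
    matrix <- matrix[, c("A", "C", "G", "T"), drop = FALSE]
  }
  if (is.null(consensus) && !is.null(matrix))
    consensus <- derivedConsensus(matrix)
  if (!is.null(consensus)) consensus <- toupper(chartr("uU", "tT", consensus))
  new("MotifModel", name = name, matrix = matrix,
      consensus = if (is.null(consensus)) NA_character_ else consensus,
      source = source)
}

# IUPAC consensus of a PPM: letters with probability >= minProb per position
derivedConsensus <- function(ppm, minProb = 0.25) {
  revMap <- stats::setNames(
    names(Biostrings::IUPAC_CODE_MAP),
    vapply(Biostrings::IUPAC_CODE_MAP, function(s)
      paste(sort(strsplit(s, "")[[1]]), collapse = ""), character(1)))
  paste(apply(ppm, 1L, function(p) {
    lset <- colnames(ppm)[p >= minProb]
    if (!length(lset)) lset <- colnames(ppm)[which.max(p)]
    revMap[[paste(sort(lset), collapse = "")]]
  }), collapse = "")
}

#' Read motifs in MEME minimal format
#'
#' Parses the minimal motif exchange format: `MOTIF <name>` stanzas followed
#' by a `letter-probability matrix:` block of per-position A/C/G/T (or
#' A/C/G/U) probabilities. The alphabet is taken from the `ALPHABET=` line
#' when present (RNA is mapped to DNA).
#'
#' @param path MEME motif file.
#' @return named list of [MotifModel-class] objects.
#' @export
readMemeMotifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  alpha <- c("A", "C", "G", "T")
  al <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (length(al)) {
    letters_ <- strsplit(toupper(sub("^ALPHABET\\s*=\\s*", "", al[1])), "")[[1]]
    letters_[letters_ == "U"] <- "T"
    if (length(letters_) == 4) alpha <- letters_
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF stanza in ", path)
  out <- list()
  for (si in seq_along(starts)) {
    i <- starts[si]
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    to <- if (si < length(starts)) starts[si + 1] - 1 else length(lines)
    block <- lines[i:to]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr))
      stop("motif ", name, ": no letter-probability matrix block")
    w <- suppressWarnings(
      as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- block[-seq_len(hdr[1])]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    if (!is.na(w)) rows <- utils::head(rows, w)
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (is.null(m) || ncol(m) != 4)
      stop("motif ", name, ": malformed probability rows")
    colnames(m) <- alpha
    out[[name]] <- motifModel(name, matrix = m, source = path)
  }
  out
}

#' Extract exon sequences extended by a flank
#'
#' For each exon, the genomic sequence of the exon extended by `flank` nt on
#' both sides, truncated at the chromosome bounds, and reverse-complemented
#' for minus-strand exons (sequences are returned 5' to 3' on the exon's
#' strand).
#'
#' @param exonGr GRanges of exons.
#' @param genome named [Biostrings::DNAStringSet] (names = chromosomes).
#' @param flank extension in nt on each side (default 200).
#' @return DNAStringSet named by exon identity key.
#' @export
extractExtendedSequences <- function(exonGr, genome, flank = 200) {
  chroms <- as.character(seqnames(exonGr))
  missingChrom <- setdiff(unique(chroms), names(genome))
  if (length(missingChrom))
    stop("chromosome(s) missing from genome: ",
         paste(missingChrom, collapse = ", "), "; affected exons: ",
         paste(utils::head(exonKey(exonGr)[chroms %in% missingChrom], 5),
               collapse = ", "))
  seqs <- lapply(seq_along(exonGr), function(i) {
    chr <- chroms[i]
    s <- max(1L, start(exonGr)[i] - flank)
    e <- min(length(genome[[chr]]), end(exonGr)[i] + flank)
    sq <- Biostrings::subseq(genome[[chr]], s, e)
    if (as.character(strand(exonGr))[i] == "-")
      sq <- Biostrings::reverseComplement(sq)
    sq
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- exonKey(exonGr)
  out
}

# log2-odds PWM of a PPM against a 0-order background, with pseudocount
logOddsPwm <- function(ppm, background, pseudo = 0.01) {
  background <- background / sum(background)
  p <- sweep(ppm + pseudo, 1, rowSums(ppm + pseudo), "/")
  t(log2(sweep(p, 2, background[colnames(p)], "/")))  # 4 x w, rows ACGT
}

# score threshold with expected <= maxHitsPerKb motif hits per 1000 background nt
calibratePwmThreshold <- function(pwm, backgroundSeqs, maxHitsPerKb = 1) {
  w <- ncol(pwm)
  scores <- unlist(lapply(seq_along(backgroundSeqs), function(i) {
    sq <- backgroundSeqs[[i]]
    np <- length(sq) - w + 1L
    if (np < 1L) return(numeric())
    Biostrings::PWMscoreStartingAt(pwm, sq, starting.at = seq_len(np))
  }))
  if (!length(scores)) stop("background too short to calibrate the PWM")
  stats::quantile(scores, probs = 1 - maxHitsPerKb / 1000, names = FALSE,
                  type = 1)
}

#' Sequence-level motif containment
#'
#' Flags, per sequence, whether it contains at least one motif match. In
#' consensus mode a match is an exact IUPAC-degenerate hit of the consensus
#' string. In PWM mode a match is a log-odds score (against a 0-order
#' background estimated from `backgroundSeqs`) above a threshold calibrated
#' so that background sequences yield at most `maxHitsPerKb` expected hits
#' per 1000 nt. Sequences shorter than the motif count as non-matching, with
#' a warning.
#'
#' @param seqs DNAStringSet to scan.
#' @param motif a [MotifModel-class].
#' @param mode `"consensus"` or `"pwm"`.
#' @param backgroundSeqs DNAStringSet used in PWM mode for the background
#'   composition and threshold calibration (typically the control set).
#' @param maxHitsPerKb PWM calibration rate (default 1 hit / kb).
#' @return logical vector, one per sequence.
#' @export
motifContainment <- function(seqs, motif, mode = c("consensus", "pwm"),
                             backgroundSeqs = NULL, maxHitsPerKb = 1) {
  mode <- match.arg(mode)
  w <- if (mode == "consensus") nchar(motif@consensus) else nrow(motif@matrix)
  short <- Biostrings::width(seqs) < w
  if (any(short))
    warning(sprintf("%d sequence(s) shorter than the motif counted as %s",
                    sum(short), "non-matching"))
  hits <- rep(FALSE, length(seqs))
  ok <- which(!short)
  if (!length(ok)) return(hits)
  if (mode == "consensus") {
    if (is.na(motif@consensus)) stop("motif has no consensus")
    cnt <- Biostrings::vcountPattern(motif@consensus, seqs[ok], fixed = FALSE)
    hits[ok] <- cnt > 0
  } else {
    if (is.null(motif@matrix)) stop("motif has no matrix")
    if (is.null(backgroundSeqs))
      stop("PWM mode needs backgroundSeqs for calibration")
    bg <- Biostrings::letterFrequency(backgroundSeqs, c("A", "C", "G", "T"))
    bgp <- pmax(colSums(bg), 1)
    pwm <- logOddsPwm(motif@matrix, bgp / sum(bgp))
    thr <- calibratePwmThreshold(pwm, backgroundSeqs, maxHitsPerKb)
    hits[ok] <- vapply(ok, function(i)
      Biostrings::countPWM(pwm, seqs[[i]], min.score = thr) > 0, logical(1))
  }
  hits
}

#' One-sided motif enrichment p-value
#'
#' Sequence-level enrichment: the fraction of primary sequences containing at
#' least one motif match is compared to the control fraction with a one-sided
#' Fisher exact test (alternative: primary fraction greater). Depletion is
#' obtained by swapping the roles of primary and control.
#'
#' @param primary,control DNAStringSet sequence sets.
#' @param motif a [MotifModel-class].
#' @inheritParams motifContainment
#' @return one-sided p-value.
#' @export
motifEnrichmentPvalue <- function(primary, control, motif,
                                  mode = c("consensus", "pwm"),
                                  maxHitsPerKb = 1) {
  mode <- match.arg(mode)
  stopifnot(length(primary) > 0, length(control) > 0)
  bg <- if (mode == "pwm") control else NULL
  ph <- motifContainment(primary, motif, mode, backgroundSeqs = bg,
                         maxHitsPerKb = maxHitsPerKb)
  ch <- motifContainment(control, motif, mode, backgroundSeqs = bg,
                         maxHitsPerKb = maxHitsPerKb)
  tab <- matrix(c(sum(ph), length(ph) - sum(ph),
                  sum(ch), length(ch) - sum(ch)), nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Signed V statistic for motif enrichment/depletion
#'
#' Combines an enrichment p-value `pE` (motif over-represented in regulated
#' sequences) and an impoverishment p-value `pI` (the same test with the
#' sequence roles swapped) into one signed value in \[-1, 1\]: positive =
#' enriched, negative = depleted, |v| close to 1 = significant. The sign is
#' `s = -1` if `pI < pE`, `s = +1` if `pI > pE`; at a tie `s = +1` and the
#' result is flagged ambiguous.
#'
#' Two variants are provided. `"consistent"` (default) computes
#' `v = (1 - min(pE, pI)) * s`, so a strong effect in either direction drives
#' |v| towards 1 and the 0.95 display threshold is attainable.
#' `"as_printed"` computes `v = min(1 - pE, 1 - pI) * s`; note that under
#' this form a maximally significant enrichment (pE -> 0 forces pI -> 1)
#' drives v towards 0, so the display threshold is unreachable — it is kept
#' for comparison. See the vignette.
#'
#' @param pE,pI enrichment and impoverishment p-values.
#' @param variant `"consistent"` or `"as_printed"`.
#' @return list with `v`, `s` and logical `ambiguous`.
#' @export
vStatistic <- function(pE, pI, variant = c("consistent", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(pE >= 0, pE <= 1, pI >= 0, pI <= 1)
  s <- if (pI < pE) -1 else 1
  v <- switch(variant,
    consistent = (1 - min(pE, pI)) * s,
    as_printed = min(1 - pE, 1 - pI) * s)
  list(v = v, s = s, ambiguous = pE == pI)
}

#' Motif enrichment panel across a registry
#'
#' For each SF with a motif, the up- and down-regulated exon classes
#' ([buildRegulatedClasses()]) are turned into extended sequences (exon
#' +/- `flank` nt), control sequences are all other detected exons excluding
#' the SF's regulated ones, and a V value is computed per (SF, class) cell.
#' Display coding follows the heat-map convention: red for v > `vThreshold`,
#' blue for v < -`vThreshold`, grey otherwise, and white (v not computed) for
#' classes with fewer than `minClassSize` exons.
#'
#' @param registry a [SpliceRegistry-class].
#' @param genome named DNAStringSet.
#' @param motifs named list of [MotifModel-class] (names = SF symbols); SFs
#'   without a motif are skipped with a warning.
#' @param minClassSize white-out cutoff per class (default 100).
#' @param flank sequence extension (default 200 nt).
#' @param variant V-statistic variant, see [vStatistic()].
#' @param mode motif matching mode, see [motifContainment()].
#' @param vThreshold display threshold (default 0.95).
#' @return data.frame with one row per (SF, class): `sf_name`, `exon_class`,
#'   `n_class`, `p_e`, `p_i`, `s`, `v`, `display`, `ambiguous`.
#' @export
runMotifPanel <- function(registry, genome, motifs, minClassSize = 100,
                          flank = 200, variant = c("consistent", "as_printed"),
                          mode = c("consensus", "pwm"), vThreshold = 0.95) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  universe <- registryUniverse(registry)
  sfs <- vapply(datasets(registry), sfName, character(1))
  rows <- list()
  for (sf in unique(sfs)) {
    if (!sf %in% names(motifs)) {
      warning("no motif for SF ", sf, "; skipped")
      next
    }
    cls <- buildRegulatedClasses(datasets(registry)[sfs == sf], universe,
                                 minClassSize = minClassSize)
    ctrlSeq <- NULL
    for (class in c("up", "down")) {
      gr <- cls[[class]]
      if (length(gr) < minClassSize) {
        rows[[length(rows) + 1L]] <- data.frame(
          sf_name = sf, exon_class = class, n_class = length(gr),
          p_e = NA_real_, p_i = NA_real_, s = NA_real_, v = NA_real_,
          display = "white", ambiguous = NA, stringsAsFactors = FALSE)
        next
      }
      if (is.null(ctrlSeq))
        ctrlSeq <- extractExtendedSequences(cls$control, genome, flank)
      regSeq <- extractExtendedSequences(gr, genome, flank)
      pE <- motifEnrichmentPvalue(regSeq, ctrlSeq, motifs[[sf]], mode = mode)
      pI <- motifEnrichmentPvalue(ctrlSeq, regSeq, motifs[[sf]], mode = mode)
      vs <- vStatistic(pE, pI, variant = variant)
      rows[[length(rows) + 1L]] <- data.frame(
        sf_name = sf, exon_class = class, n_class = length(gr),
        p_e = pE, p_i = pI, s = vs$s, v = vs$v,
        display = if (vs$v > vThreshold) "red"
                  else if (vs$v < -vThreshold) "blue" else "grey",
        ambiguous = vs$ambiguous, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sf_name = character(), exon_class = character(),
                      n_class = integer(), p_e = numeric(), p_i = numeric(),
                      s = numeric(), v = numeric(), display = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
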