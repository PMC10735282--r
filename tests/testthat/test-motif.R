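test_that("motif models map RNA to DNA and derive IUPAC consensi", {
  m <- motifModel("SF1", consensus = "ugcaug")
  expect_equal(m@consensus, "TGCATG")
  ppm <- matrix(c(1, 0, 0, 0,
                  0, 0.5, 0.5, 0,
                  0.1, 0.1, 0.1, 0.7), ncol = 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "U")))
  m2 <- motifModel("SF2", matrix = ppm)
  expect_equal(m2@consensus, "AST")  # C/G ambiguity = S
  expect_error(motifModel("SF3", consensus = "ACGTX"), "non-IUPAC")
  bad <- ppm; bad[1, 1] <- 0.5
  expect_error(motifModel("SF4", matrix = bad), "sum to 1")
})

test_that("MEME minimal format parses into motif models", {
  path <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "MOTIF SF1_mot", "letter-probability matrix: alength= 4 w= 3 nsites= 20",
               " 0.97 0.01 0.01 0.01",
               " 0.01 0.01 0.97 0.01",
               " 0.25 0.25 0.25 0.25",
               "", "MOTIF SF2_mot",
               "letter-probability matrix: alength= 4 w= 2",
               " 0.01 0.97 0.01 0.01",
               " 0.01 0.01 0.01 0.97"), path)
  mots <- readMemeMotifs(path)
  expect_equal(names(mots), c("SF1_mot", "SF2_mot"))
  expect_equal(nrow(mots$SF1_mot@matrix), 3)
  expect_equal(colnames(mots$SF1_mot@matrix), c("A", "C", "G", "T"))
  expect_equal(mots$SF2_mot@consensus, "CT")
  expect_equal(mots$SF1_mot@consensus, "AGN")
})

test_that("extended sequence extraction is strand-aware and bound-truncated", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 500), collapse = "")))
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100), "+")
  s <- extractExtendedSequences(ex, genome, flank = 200)
  expect_equal(Biostrings::width(s), 500)  # 100-nt exon + 2 x 200
  exM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100), "-")
  sM <- extractExtendedSequences(exM, genome, flank = 200)
  expect_equal(as.character(sM[[1]]),
               as.character(Biostrings::reverseComplement(s[[1]])))
  # truncation at chromosome start
  exT <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 149), "+")
  sT <- extractExtendedSequences(exT, genome, flank = 200)
  expect_equal(Biostrings::width(sT), 149 + 200 - 0)
  expect_error(extractExtendedSequences(
    GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10), "+"), genome, 10),
    "chrZ")
})

test_that("consensus and PWM matching agree on exact consensus hits", {
  set.seed(41)
  bg <- Biostrings::DNAStringSet(vapply(1:80, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1)))
  cons <- "TGCATGTC"
  ppm <- diag(4)[match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")), ]
  ppm <- 0.94 * ppm + 0.015  # rows: 0.94 + 4 * 0.015 = 1
  colnames(ppm) <- c("A", "C", "G", "T")
  mot <- motifModel("SFX", consensus = cons, matrix = ppm)
  # plant the exact consensus into half the sequences
  primary <- bg
  for (i in 1:40)
    primary[[i]] <- Biostrings::replaceAt(primary[[i]],
                                          IRanges::IRanges(100, 107), cons)
  hitC <- motifContainment(primary, mot, mode = "consensus")
  expect_true(all(hitC[1:40]))
  hitP <- motifContainment(primary, mot, mode = "pwm", backgroundSeqs = bg)
  expect_true(all(hitP[1:40]))
  # sequences shorter than the motif count as non-matching, with a warning
  shorty <- Biostrings::DNAStringSet(c("ACGT", as.character(primary[[1]])))
  expect_warning(hS <- motifContainment(shorty, mot, mode = "consensus"),
                 "shorter")
  expect_false(hS[1]); expect_true(hS[2])
})

test_that("enrichment p-values reflect planted contingency tables", {
  set.seed(43)
  mkSeqs <- function(n, plant, cons) {
    Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
      if (i <= plant) s <- paste0(substr(s, 1, 99), cons,
                                  substr(s, 100 + nchar(cons), 250))
      s
    }, character(1)))
  }
  cons <- "TGCATGTC"
  mot <- motifModel("SFX", consensus = cons)
  primary <- mkSeqs(100, 80, cons)
  control <- mkSeqs(100, 10, cons)
  p <- motifEnrichmentPvalue(primary, control, mot)
  expect_lt(p, 1e-10)
  # identical sets: no enrichment either way
  pSame <- motifEnrichmentPvalue(primary, primary, mot)
  expect_gt(pSame, 0.4)
  expect_equal(motifEnrichmentPvalue(primary, primary, mot),
               motifEnrichmentPvalue(primary, primary, mot))
  # motif absent everywhere: p = 1
  none <- mkSeqs(50, 0, cons)
  expect_equal(motifEnrichmentPvalue(none, none, mot), 1)
})

test_that("the V statistic follows the sign rule in both variants", {
  v1 <- vStatistic(0.01, 0.99, variant = "consistent")
  expect_equal(v1$v, 0.99)
  expect_equal(v1$s, 1)
  v2 <- vStatistic(0.99, 0.01, variant = "consistent")
  expect_equal(v2$v, -0.99)
  # tie: positive sign, flagged ambiguous
  v3 <- vStatistic(0.5, 0.5)
  expect_equal(v3$v, 0.5)
  expect_true(v3$ambiguous)
  # printed variant: min of the complements
  v4 <- vStatistic(0.01, 0.99, variant = "as_printed")
  expect_equal(v4$v, min(1 - 0.01, 1 - 0.99) * 1)
  # properties over random pairs: v in [-1,1], role swap flips the sign label
  set.seed(47)
  for (i in 1:200) {
    pe <- runif(1); pi_ <- runif(1)
    a <- vStatistic(pe, pi_)
    b <- vStatistic(pi_, pe)
    expect_true(abs(a$v) <= 1)
    if (pe != pi_) expect_equal(a$s, -b$s)
    expect_equal(abs(a$v), abs(b$v))
  }
})

test_that("the motif panel whites out small classes and skips motif-less SFs", {
  gen <- generateRegistry(registrySpec(nSF = 2, exonsPerDataset = 60,
                                       universeSize = 300, overlap = 0.1,
                                       correlation = 0.3, seed = 8))
  reg <- gen$registry
  genome <- generateMotifFixture(gen$annotation, list(),
                                 motifModel("x", consensus = "ACGTACGT"),
                                 seed = 1)$genome
  mots <- list(SF01 = motifModel("SF01", consensus = "TGCATGTC"),
               SF02 = motifModel("SF02", consensus = "GGACGGAC"))
  panel <- runMotifPanel(reg, genome, mots, minClassSize = 100)
  expect_equal(nrow(panel), 4)
  expect_true(all(panel$display == "white"))  # 60-exon datasets: ~30 per class
  expect_true(all(is.na(panel$v)))
  expect_warning(
    runMotifPanel(reg, genome, mots["SF01"], minClassSize = 100),
    "no motif for SF SF02")
})
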