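test_that("peak merging coalesces overlapping and abutting intervals like a pairwise oracle", {
  # overlap and abutment (1-based closed: [11,20] + [21,25] are adjacent)
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 16), c(20, 30)))
  m1 <- mergePeaks(g1)
  expect_equal(start(m1), 11); expect_equal(end(m1), 30)
  g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 21), c(20, 25)))
  m2 <- mergePeaks(g2)
  expect_length(m2, 1)
  expect_equal(end(m2), 25)
  # 500 random intervals vs the O(n^2) oracle
  set.seed(13)
  st <- sample(1:5000, 500, replace = TRUE)
  en <- st + sample(1:200, 500, replace = TRUE)
  ch <- sample(c("chr1", "chr2"), 500, replace = TRUE)
  merged <- mergePeaks(GenomicRanges::GRanges(ch, IRanges::IRanges(st, en)))
  oracle <- oracleMerge(st, en, ch)
  expect_equal(length(merged), nrow(oracle))
  expect_equal(start(merged), oracle$start)
  expect_equal(end(merged), oracle$end)
  expect_equal(as.character(seqnames(merged)), oracle$chrom)
  # result is disjoint and non-abutting
  expect_true(all(start(merged)[-1] - end(merged)[-length(merged)] > 1 |
                  as.character(seqnames(merged))[-1] !=
                    as.character(seqnames(merged))[-length(merged)]))
})

test_that("BED peaks are read on the internal 1-based convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk1\t0\t+",
               "chr1\t300\t350\tpk2\t0\t-"), bed)
  g <- readPeakBed(bed)
  expect_equal(start(g), c(101, 301))  # BED is 0-based half-open
  expect_equal(end(g), c(200, 350))
  expect_error(readPeakBed(tempfile()), "not found")
})

test_that("region windows walk outward from the exon on its strand", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200), "+")
  w <- regionWindows(ex, 100)
  expect_equal(unname(start(w$exon_body)), 1001)
  expect_equal(c(start(w$up1), end(w$up1)), c(901, 1000))
  expect_equal(c(start(w$up2), end(w$up2)), c(801, 900))
  expect_equal(c(start(w$up3), end(w$up3)), c(701, 800))
  expect_equal(c(start(w$down1), end(w$down1)), c(1201, 1300))
  expect_equal(c(start(w$down3), end(w$down3)), c(1401, 1500))
  # minus strand: upstream is genomically right of the exon
  exM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200), "-")
  wM <- regionWindows(exM, 100)
  expect_equal(c(start(wM$up1), end(wM$up1)), c(1201, 1300))
  expect_equal(c(start(wM$down1), end(wM$down1)), c(901, 1000))
  # truncation at the chromosome start: partial then empty windows
  exT <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150), "+")
  wT <- regionWindows(exT, 100)
  expect_equal(c(start(wT$up1), end(wT$up1)), c(1, 50))
  expect_equal(IRanges::width(wT$up2), 0)
  expect_equal(IRanges::width(wT$up3), 0)
})

test_that("regulated classes drop conflicted exons and enforce the 100-exon rule", {
  ann <- generateAnnotation(500, seed = 4)
  # sample A: exons 1..200 up, 201..400 down; sample B flips exon 1
  dA <- datasetFromAnnotation(ann, 1:400, dpsi = c(rep(15, 200), rep(-15, 200)),
                              sf = "SF1", id = "SF1_A")
  dB <- datasetFromAnnotation(ann, 1, dpsi = -12, sf = "SF1", id = "SF1_B")
  cls <- buildRegulatedClasses(list(dA, dB), ann, minClassSize = 100)
  expect_equal(cls$conflicted, exonKey(ann[1]))
  expect_equal(length(cls$up), 199)
  expect_equal(length(cls$down), 200)
  expect_equal(length(cls$control), 100)  # 500 - 199 - 200 - 1
  # pairwise disjoint, conflicted nowhere
  keys <- list(exonKey(cls$up), exonKey(cls$down), exonKey(cls$control))
  expect_equal(length(unique(unlist(keys))), length(unlist(keys)))
  expect_false(cls$conflicted %in% unlist(keys))
  expect_true(cls$usable)
  # 99 in one class: discarded
  d99 <- datasetFromAnnotation(ann, 1:199, dpsi = c(rep(15, 99), rep(-15, 100)),
                               sf = "SF2", id = "SF2_A")
  expect_false(buildRegulatedClasses(list(d99), ann, 100)$usable)
})

test_that("enrichment cells follow the pseudocounted log-ratio and its bounds", {
  ann <- generateAnnotation(300, seed = 5)
  reg <- ann[1:100]
  ctrl <- ann[101:300]
  # equal planted proportions: R = 0 (formula symmetry), even at odd values
  fx <- generateClipFixture(reg, ctrl, 1, 1, seed = 1)
  cell <- enrichmentCell(reg, ctrl, fx$peaks)
  expect_equal(cell$r_value, 0)
  # maximal contrast saturates at the pseudocount bound
  fx2 <- generateClipFixture(reg, ctrl, 1, 0, seed = 2)
  cell2 <- enrichmentCell(reg, ctrl, fx2$peaks)
  expect_equal(cell2$p_reg, 1)
  expect_equal(cell2$p_ctrl, 0)
  expect_equal(cell2$r_value, log2(1.01 / 0.01))
  expect_lte(abs(cell2$r_value), log2(1.01 / 0.01) + 1e-12)
  expect_lt(cell2$pvalue, 1e-6)  # Fisher fallback under separation
  # antisymmetry under swapping regulated and control roles
  fx3 <- generateClipFixture(reg, ctrl, 0.7, 0.25, seed = 3)
  a <- enrichmentCell(reg, ctrl, fx3$peaks)
  b <- enrichmentCell(ctrl, reg, fx3$peaks)
  expect_equal(a$r_value, -b$r_value, tolerance = 1e-12)
  # degenerate inputs are flagged, not errors
  empty <- enrichmentCell(reg[0], ctrl, fx3$peaks)
  expect_true(is.na(empty$r_value))
})

test_that("Wald and Fisher agree on the direction of proportion differences", {
  set.seed(31)
  agree <- 0L
  nCells <- 200L
  for (i in seq_len(nCells)) {
    n1 <- sample(100:300, 1); n2 <- sample(100:300, 1)
    p1 <- runif(1, 0.05, 0.9); p2 <- runif(1, 0.05, 0.9)
    h1 <- runif(n1) < p1; h2 <- runif(n2) < p2
    if (sum(h1) %in% c(0, n1) || sum(h2) %in% c(0, n2)) { agree <- agree + 1L; next }
    wald <- spliceScore:::proportionTest(h1, h2)
    fish <- fisher.test(matrix(c(sum(h1), n1 - sum(h1),
                                 sum(h2), n2 - sum(h2)), 2))$p.value
    # same side of 0.5 counts as directional agreement of evidence strength
    if ((wald < 0.5) == (fish < 0.5) || abs(wald - fish) < 0.1)
      agree <- agree + 1L
  }
  expect_gte(agree / nCells, 0.99)
})

test_that("the CLIP panel grid covers classes x regions with one BH family", {
  gen <- generateRegistry(registrySpec(nSF = 2, exonsPerDataset = 250,
                                       universeSize = 900, overlap = 0.1,
                                       correlation = 0.3, seed = 6))
  reg <- gen$registry
  universe <- registryUniverse(reg)
  cls <- buildRegulatedClasses(datasets(reg)[1], universe, minClassSize = 100)
  fx <- generateClipFixture(cls$up, cls$control, 0.6, 0.2, seed = 7)
  panel <- runClipPanel(reg, list(SF01 = fx$peaks, SF02 = fx$peaks),
                        minClassSize = 100)
  expect_equal(nrow(panel), 2 * 2 * 7)  # 2 SFs x 2 classes x 7 regions
  expect_setequal(unique(panel$region),
                  c("exon_body", "up1", "up2", "up3", "down1", "down2", "down3"))
  expect_equal(panel$q_bh, bhAdjust(panel$pvalue))
  planted <- panel[panel$sf_name == "SF01" & panel$exon_class == "up" &
                   panel$region == "exon_body", ]
  expect_true(planted$significant)
  expect_gt(planted$r_value, 1)
  # an SF below the class-size rule contributes no cells
  panelSmall <- runClipPanel(reg, list(SF01 = fx$peaks, SF02 = fx$peaks),
                             minClassSize = 1000)
  expect_equal(nrow(panelSmall), 0)
})
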