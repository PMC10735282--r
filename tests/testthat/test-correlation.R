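test_that("sharedPairs intersects by coordinate identity", {
  ann <- generateAnnotation(40, seed = 1)
  d <- datasetFromAnnotation(ann, 1:20, dpsi = rep(c(20, -20), 10))
  q <- ann[16:25]
  S4Vectors::mcols(q)$delta_psi <- 15
  S4Vectors::mcols(q)$adj_pvalue <- 0.01
  sp <- sharedPairs(q, d)
  expect_equal(sp$n_shared, 5)
  expect_true(all(sp$pairs$key %in% exonKey(exons(d))))
  # disjoint
  expect_equal(sharedPairs(ann[30:35], d)$n_shared, 0)
  # identity
  expect_equal(sharedPairs(exons(d), d)$n_shared, 20)
})

test_that("pearsonDeltaPsi matches the covariance formula and flags degenerate input", {
  mk <- function(x, y) list(pairs = data.frame(key = paste0("k", seq_along(x)),
                                               query_dpsi = x,
                                               dataset_dpsi = y),
                            n_shared = length(x))
  x <- c(12, -15, 30, 44, -22, 18, -35, 27, 11, -40)
  expect_equal(pearsonDeltaPsi(mk(x, x)), 1)
  expect_equal(pearsonDeltaPsi(mk(x, -x)), -1)
  y <- c(10, -22, 35, 20, -18, 25, -30, 15, 14, -33)
  # direct covariance / sd*sd formula, written out independently
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonDeltaPsi(mk(x, y)), rOracle, tolerance = 1e-12)
  # below minShared or zero variance: not computable
  expect_true(is.na(pearsonDeltaPsi(mk(x[1:5], y[1:5]))))
  expect_false(is.na(pearsonDeltaPsi(mk(x[1:5], y[1:5]), minShared = 5)))
  expect_true(is.na(pearsonDeltaPsi(mk(rep(10, 10), y), minShared = 5)))
})

test_that("empirical p-values hit the resolution floor and the opposite tail", {
  mk <- function(x, y) list(pairs = data.frame(key = paste0("k", seq_along(x)),
                                               query_dpsi = x,
                                               dataset_dpsi = y),
                            n_shared = length(x))
  set.seed(11)
  x <- runif(60, 10, 60) * sample(c(-1, 1), 60, TRUE)
  p <- empiricalPvalues(mk(x, x), nPermutations = 10000, seed = 3)
  expect_equal(unname(p["p_pos"]), 1e-4)  # floor = the stated resolution
  # perfectly anti-correlated: no permutation is as low, every one is higher
  p2 <- empiricalPvalues(mk(x, -x), nPermutations = 10000, seed = 3)
  expect_equal(unname(p2["p_neg"]), 1e-4)
  expect_equal(unname(p2["p_pos"]), 1)
})

test_that("permutation p at 5 shared exons equals exhaustive enumeration", {
  mk <- function(x, y) list(pairs = data.frame(key = paste0("k", seq_along(x)),
                                               query_dpsi = x,
                                               dataset_dpsi = y),
                            n_shared = length(x))
  set.seed(21)
  for (trial in 1:5) {
    x <- runif(5, -60, 60)
    y <- 0.6 * x + runif(5, -20, 20)
    exact <- oraclePermutationP(x, y)
    got <- empiricalPvalues(mk(x, y), method = "exhaustive", minShared = 5)
    expect_equal(unname(got["p_pos"]), unname(exact["p_pos"]), tolerance = 1e-12)
    expect_equal(unname(got["p_neg"]), unname(exact["p_neg"]), tolerance = 1e-12)
    # sampled permutations converge on the exact tail
    samp <- empiricalPvalues(mk(x, y), nPermutations = 4000, seed = trial,
                             minShared = 5)
    mcErr <- 4 * sqrt(exact["p_pos"] * (1 - exact["p_pos"]) / 4000) + 1e-3
    expect_lt(abs(samp["p_pos"] - exact["p_pos"]), mcErr)
  }
})

test_that("overlap fractions separate significant and common membership", {
  ann <- generateAnnotation(120, seed = 6)
  d <- datasetFromAnnotation(ann, 1:50, dpsi = rep(c(25, -25), 25))
  # 20-exon query: 5 significant of which 3 inside the dataset,
  # 15 non-significant (p too large) all outside the dataset
  q <- c(ann[c(1:3, 60, 61)], ann[70:84])
  S4Vectors::mcols(q)$delta_psi <- c(rep(30, 5), rep(30, 15))
  S4Vectors::mcols(q)$adj_pvalue <- c(rep(0.01, 5), rep(0.5, 15))
  fr <- overlapFractions(q, d)
  expect_equal(unname(fr["percent.sig.input"]), 60)    # 3 of 5
  expect_equal(unname(fr["percent.sig.SF"]), 6)        # 3 of 50
  expect_equal(unname(fr["percent.common.query"]), 15) # 3 of 20
  # identity: everything 100
  frI <- overlapFractions(exons(d), d)
  expect_true(all(frI == 100))
  # disjoint: everything 0
  q0 <- ann[100:110]
  S4Vectors::mcols(q0)$delta_psi <- 20
  S4Vectors::mcols(q0)$adj_pvalue <- 0.01
  expect_true(all(overlapFractions(q0, d) == 0))
})

test_that("composite Score is the arithmetic mean of its three components", {
  expect_equal(compositeScore(0.5, 50, 30), (0.5 + 0.5 + 0.3) / 3)
  expect_equal(compositeScore(1, 0, 0), 0)
  expect_equal(round(compositeScore(1e-4, 100, 100)), 1)
})

test_that("up/down breakdown partitions shared exons by direction", {
  ann <- generateAnnotation(30, seed = 8)
  # 8 shared exons with hand-picked signs
  qSigns <- c(1, 1, 1, 1, -1, -1, -1, -1)
  dSigns <- c(1, 1, -1, 1, -1, -1, 1, -1)
  d <- datasetFromAnnotation(ann, 1:8, dpsi = 20 * dSigns)
  q <- ann[1:8]
  S4Vectors::mcols(q)$delta_psi <- 25 * qSigns
  S4Vectors::mcols(q)$adj_pvalue <- 0.01
  ud <- updownBreakdown(q, d)
  expect_equal(ud$n_up_up, 3)
  expect_equal(ud$n_up_down, 1)
  expect_equal(ud$n_down_up, 1)
  expect_equal(ud$n_down_down, 3)
  expect_equal(ud$pct_up_up, 75)
  expect_equal(ud$pct_down_down, 75)
  # identity: all same-direction
  udI <- updownBreakdown(exons(d), d)
  expect_equal(udI$n_up_down + udI$n_down_up, 0)
  expect_equal(udI$pct_up_up, 100)
  expect_equal(udI$pct_down_down, 100)
  # flipped signs: all opposite
  qF <- exons(d)
  S4Vectors::mcols(qF)$delta_psi <- -S4Vectors::mcols(qF)$delta_psi
  udF <- updownBreakdown(qF, d)
  expect_equal(udF$n_up_up + udF$n_down_down, 0)
  expect_equal(udF$pct_up_down, 100)
  # zero delta-PSI belongs to neither class
  qZ <- exons(d)[1:3]
  S4Vectors::mcols(qZ)$delta_psi <- c(0, 15, -15)
  expect_equal(updownBreakdown(qZ, d)$n_zero_excluded, 1)
})

test_that("mode-1 run is deterministic, sorted, and keeps not-computable rows", {
  gen <- generateRegistry(registrySpec(nSF = 3, exonsPerDataset = 80,
                                       universeSize = 400, overlap = 0.3,
                                       correlation = 0.6, seed = 9))
  reg <- gen$registry
  q <- exons(reg[[1]])
  r1 <- runQueryMode1(q, reg, nPermutations = 500, seed = 17)
  r2 <- runQueryMode1(q, reg, nPermutations = 500, seed = 17)
  expect_identical(r1, r2)
  best <- pmax(r1$score_pos, r1$score_neg)
  expect_true(all(diff(ifelse(is.na(best), -Inf, best)) <= 1e-12))
  expect_equal(r1$dataset[1], datasetId(reg[[1]]))
  # a dataset sharing too few exons is flagged, not dropped
  lonely <- datasetFromAnnotation(gen$annotation, 396:400,
                                  dpsi = c(20, -20, 30, -30, 40),
                                  sf = "SFLN", id = "SFLN_SYN")
  reg2 <- SpliceRegistry(c(datasets(reg), list(lonely)))
  r3 <- runQueryMode1(q, reg2, nPermutations = 200, seed = 1)
  row <- r3[r3$dataset == "SFLN_SYN", ]
  expect_false(row$computable)
  expect_true(is.na(row$score_pos))
  expect_equal(nrow(r3), 4)
})
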