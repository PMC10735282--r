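#' Specification for a synthetic dataset registry
#'
#' Scalar `overlap` / `correlation` values are expanded into exchangeable
#' matrices (that value everywhere off the diagonal).
#'
#' @param nSF number of datasets.
#' @param exonsPerDataset exons per dataset (default 500).
#' @param universeSize detected-exon universe size (default 3000).
#' @param overlap pairwise target shared-exon fraction: scalar or nSF x nSF
#'   symmetric matrix with unit diagonal.
#' @param correlation target Pearson r of delta-PSI on shared exons: scalar
#'   or matrix, same shape rules.
#' @param signFraction fraction of skipped (dPSI < 0) exons, default 0.5.
#' @param magnitudeRange |dPSI| range in percent, default c(10, 60); the
#'   minimum may not go below the 10-percent significance filter.
#' @param seed integer seed.
#' @return a [RegistrySpec-class].
#' @export
registrySpec <- function(nSF = 5, exonsPerDataset = 500, universeSize = 3000,
                         overlap = 0.2, correlation = 0.5,
                         signFraction = 0.5, magnitudeRange = c(10, 60),
                         seed = 1) {
  expand <- function(x) {
    if (is.matrix(x)) return(x)
    m <- matrix(x, nSF, nSF)
    diag(m) <- 1
    m
  }
  new("RegistrySpec", nSF = as.integer(nSF),
      exonsPerDataset = as.integer(exonsPerDataset),
      universeSize = as.integer(universeSize),
      overlap = expand(overlap), correlation = expand(correlation),
      signFraction = signFraction, magnitudeRange = magnitudeRange,
      seed = as.integer(seed))
}

#' Generate a synthetic exon annotation
#'
#' Places `n` non-overlapping exons on synthetic chromosomes with realistic
#' cassette-exon lengths (50-300 nt) and inter-exon gaps of at least 700 nt,
#' so the three 100-nt windows on each side of an exon never reach into a
#' neighbour. Exons are grouped into genes of 5-15 exons; each gene sits on
#' one strand.
#'
#' @param n number of exons.
#' @param seed integer seed.
#' @param exonsPerChrom exons per synthetic chromosome (default 1000).
#' @return GRanges annotation table with `gene_symbol`, `exon_number`.
#' @export
generateAnnotation <- function(n, seed = 1, exonsPerChrom = 1000) {
  withSeed(seed, {
    chromOf <- paste0("chrS", (seq_len(n) - 1L) %/% exonsPerChrom + 1L)
    lens <- sample(50:300, n, replace = TRUE)
    gaps <- 700L + sample(0:800, n, replace = TRUE)
    starts <- integer(n)
    pos <- 1000L
    for (i in seq_len(n)) {
      if (i > 1L && chromOf[i] != chromOf[i - 1L]) pos <- 1000L
      starts[i] <- pos
      pos <- pos + lens[i] + gaps[i]
    }
    # genes of 5-15 consecutive exons, one strand per gene
    geneSizes <- integer()
    total <- 0L
    while (total < n) {
      g <- sample(5:15, 1L)
      geneSizes <- c(geneSizes, g)
      total <- total + g
    }
    geneIdx <- rep(seq_along(geneSizes), geneSizes)[seq_len(n)]
    exnum <- unlist(lapply(geneSizes, seq_len))[seq_len(n)]
    geneStrand <- sample(c("+", "-"), length(geneSizes), replace = TRUE)
    GRanges(chromOf, IRanges(starts, starts + lens - 1L),
            strand = geneStrand[geneIdx],
            gene_symbol = sprintf("GENE%04d", geneIdx),
            exon_number = exnum)
  })
}

# Latent Gaussian correlation required so that, after the monotone map of
# Phi(z) onto the delta-PSI scale, the realized Pearson correlation equals the
# target. Uses the Hermite expansion of g(Phi(z)): for bivariate normal with
# correlation rho, corr(g(Z1), g(Z2)) = sum_k a_k^2 rho^k / sum_k a_k^2 with
# a_k = E[g(Z) He_k(Z)] / sqrt(k!). Coefficients are computed by quadrature,
# the monotone polynomial is inverted with uniroot.
latentCorrelation <- function(target, signFraction, magnitudeRange, K = 60) {
  if (target == 0) return(0)
  z <- seq(-8, 8, length.out = 8001)
  wgt <- stats::dnorm(z) * (z[2] - z[1])
  g <- uniformToDeltaPsi(stats::pnorm(z), signFraction, magnitudeRange)
  g <- g - sum(g * wgt)
  varg <- sum(g^2 * wgt)
  # normalized Hermite recurrence h_k = He_k / sqrt(k!) keeps values moderate
  hPrev <- rep(1, length(z))
  hCur <- z
  a2 <- numeric(K)
  a2[1] <- sum(g * hCur * wgt)^2
  for (k in 2:K) {
    hNext <- (z * hCur - sqrt(k - 1) * hPrev) / sqrt(k)
    hPrev <- hCur
    hCur <- hNext
    a2[k] <- sum(g * hCur * wgt)^2
  }
  f <- function(rho) sum(a2 * rho^(1:K)) / varg - target
  sgn <- sign(target)
  if (f(sgn * 0.999999) * sgn < 0) return(sgn * 0.999999)
  stats::uniroot(f, interval = sort(c(0, sgn * 0.999999)), tol = 1e-12)$root
}

# map a uniform variate to delta-PSI percent: monotone, sign split at
# signFraction, magnitudes spanning magnitudeRange
uniformToDeltaPsi <- function(u, signFraction, magnitudeRange) {
  lo <- magnitudeRange[1]; hi <- magnitudeRange[2]
  neg <- u < signFraction
  out <- numeric(length(u))
  out[neg] <- -(lo + (hi - lo) * (signFraction - u[neg]) / signFraction)
  out[!neg] <- lo + (hi - lo) * (u[!neg] - signFraction) / (1 - signFraction)
  out
}

#' Generate a synthetic SF-dataset registry
#'
#' Builds an annotation universe and `nSF` datasets whose pairwise shared-exon
#' fractions and shared-exon delta-PSI correlations approximate the targets in
#' the spec. Membership is constructed greedily (dataset i draws its target
#' share from each earlier dataset, filling up from untouched universe exons),
#' and delta-PSI correlation is induced by a Gaussian one-factor copula: each
#' exon carries a global latent value, dataset i mixes it with idiosyncratic
#' noise with loading `a_i`, so shared-exon correlations realize `a_i * a_j`.
#' Loadings are fitted to the target matrix (exact for exchangeable or rank-1
#' patterns) and the latent correlation is calibrated by inverting the Hermite
#' expansion of the monotone map onto the delta-PSI scale, so the margin
#' transform does not attenuate the target.
#' Realized values land within about +/-2 percentage points (overlap)
#' and +/-0.05 (correlation) of the targets at the default sizes; the
#' realized matrices are returned as ground truth.
#'
#' Adjusted p-values are drawn uniformly below the 0.05 filter, so every
#' generated dataset satisfies the SFDataset invariants by construction.
#'
#' @param spec a [RegistrySpec-class] from [registrySpec()].
#' @return list with `registry` (a [SpliceRegistry-class]), `annotation`, and
#'   `truth` (list: per-dataset keys, realized overlap and correlation
#'   matrices).
#' @export
generateRegistry <- function(spec) {
  stopifnot(is(spec, "RegistrySpec"))
  validObject(spec)
  n <- spec@nSF
  size <- spec@exonsPerDataset
  if (max(spec@overlap[upper.tri(spec@overlap)] * size, 0) > spec@universeSize)
    stop("infeasible spec: overlap * size exceeds the universe")
  # fresh-exon budget of the greedy construction: each dataset needs at least
  # size - (what it can share with earlier datasets) untouched universe exons
  cumulative <- size
  if (n > 1) for (i in 2:n) {
    shared_i <- min(sum(round(spec@overlap[i, seq_len(i - 1L)] * size)), size)
    cumulative <- cumulative + (size - shared_i)
  }
  if (cumulative > spec@universeSize)
    stop("infeasible spec: universe too small for the requested ",
         "dataset sizes and overlaps")
  ann <- generateAnnotation(spec@universeSize, seed = spec@seed)
  withSeed(spec@seed + 1L, {
    U <- spec@universeSize
    members <- vector("list", n)
    members[[1]] <- sort(sample.int(U, size))
    if (n > 1) for (i in 2:n) {
      chosen <- integer()
      for (j in seq_len(i - 1L)) {
        want <- round(spec@overlap[i, j] * size)
        need <- want - sum(chosen %in% members[[j]])
        if (need > 0) {
          pool <- setdiff(members[[j]], chosen)
          # prefer exons exclusive to dataset j, to limit overlap spillover
          others <- unique(unlist(members[seq_len(i - 1L)[-j]]))
          poolExcl <- setdiff(pool, others)
          resample <- function(x) x[sample.int(length(x))]
          take <- utils::head(c(resample(poolExcl),
                                resample(pool[pool %in% others])),
                              min(need, length(pool)))
          chosen <- c(chosen, take)
        }
      }
      fresh <- setdiff(seq_len(U), unique(c(unlist(members[seq_len(i - 1L)]),
                                            chosen)))
      extra <- size - length(chosen)
      if (extra > length(fresh))
        stop("infeasible spec: universe too small for the requested ",
             "dataset sizes and overlaps")
      members[[i]] <- sort(c(chosen, fresh[sample.int(length(fresh), extra)]))
    }

    # one-factor loadings approximating the latent target correlations
    latentTarget <- spec@correlation
    off <- upper.tri(latentTarget)
    latentTarget[off] <- vapply(latentTarget[off], latentCorrelation,
                                numeric(1), signFraction = spec@signFraction,
                                magnitudeRange = spec@magnitudeRange)
    latentTarget[lower.tri(latentTarget)] <- t(latentTarget)[
      lower.tri(latentTarget)]
    loadings <- rep(0, n)
    off <- latentTarget[upper.tri(latentTarget)]
    if (n == 1 || all(off == 0)) {
      loadings <- rep(0, n)
    } else if (length(unique(round(off, 10))) == 1L) {
      loadings <- rep(sqrt(max(unique(off), 0)), n)
    } else {
      # least squares on logs where possible, else first-eigenvector fit
      A <- abs(latentTarget)
      diag(A) <- NA
      eig <- eigen(ifelse(is.na(A), mean(A, na.rm = TRUE), A),
                   symmetric = TRUE)
      v <- abs(eig$vectors[, 1]) * sqrt(max(eig$values[1], 0))
      loadings <- pmin(v, 0.999)
    }
    gLatent <- stats::rnorm(U)
    datasetsList <- lapply(seq_len(n), function(i) {
      a <- loadings[i]
      gi <- gLatent[members[[i]]]
      ei <- stats::rnorm(size)
      # variance reduction: make the idiosyncratic part exactly orthogonal to
      # the factor in-sample and standardize both, so the dataset-level
      # loading is realized exactly and pairwise correlations track a_i * a_j
      gi <- (gi - mean(gi)) / stats::sd(gi)
      ei <- ei - mean(ei) - sum(ei * gi) / sum(gi^2) * gi
      ei <- ei / stats::sd(ei)
      z <- a * gi + sqrt(max(1 - a^2, 0)) * ei
      dpsi <- uniformToDeltaPsi(stats::pnorm(z), spec@signFraction,
                                spec@magnitudeRange)
      ex <- ann[members[[i]]]
      mcols(ex)$delta_psi <- dpsi
      mcols(ex)$adj_pvalue <- stats::runif(size, 5e-4, 0.05)
      SFDataset(ex, sfName = sprintf("SF%02d", i), cellLine = "SYN",
                perturbation = "siRNA", build = "synth1",
                datasetId = sprintf("SF%02d_SYN", i), filter = FALSE)
    })
    registry <- SpliceRegistry(datasetsList, annotation = ann)
    keys <- lapply(datasetsList, function(d) exonKey(exons(d)))
    realizedOverlap <- diag(1, n)
    realizedR <- diag(1, n)
    if (n > 1) for (i in 2:n) for (j in seq_len(i - 1L)) {
      shared <- intersect(keys[[i]], keys[[j]])
      realizedOverlap[i, j] <- realizedOverlap[j, i] <- length(shared) / size
      if (length(shared) >= 3) {
        di <- mcols(exons(datasetsList[[i]]))$delta_psi[
          match(shared, keys[[i]])]
        dj <- mcols(exons(datasetsList[[j]]))$delta_psi[
          match(shared, keys[[j]])]
        realizedR[i, j] <- realizedR[j, i] <-
          if (stats::sd(di) > 0 && stats::sd(dj) > 0) stats::cor(di, dj)
          else NA_real_
      } else realizedR[i, j] <- realizedR[j, i] <- NA_real_
    }
    list(registry = registry, annotation = ann,
         truth = list(memberKeys = keys, realizedOverlap = realizedOverlap,
                      realizedCorrelation = realizedR, loadings = loadings))
  })
}

#' Derive a query list from a dataset
#'
#' Convenience generator for ranking-recovery experiments: takes a fraction
#' of a dataset's exons (optionally re-noising delta-PSI towards a target
#' correlation with the source) plus unrelated exons from the annotation.
#'
#' @param dataset source [SFDataset-class].
#' @param annotation GRanges universe to draw unrelated exons from.
#' @param keepFraction fraction of query exons taken from the dataset.
#' @param targetR target correlation between query and dataset delta-PSI on
#'   the kept exons (1 = copy).
#' @param size query size (default: dataset size).
#' @param seed integer seed.
#' @param signFraction,magnitudeRange delta-PSI marginal for the unrelated
#'   exons.
#' @return GRanges query exon records with statistics.
#' @export
generateQueryFromDataset <- function(dataset, annotation, keepFraction = 0.5,
                                     targetR = 1, size = NULL, seed = 1,
                                     signFraction = 0.5,
                                     magnitudeRange = c(10, 60)) {
  withSeed(seed, {
    dex <- exons(dataset)
    if (is.null(size)) size <- length(dex)
    nKeep <- round(keepFraction * size)
    stopifnot(nKeep <= length(dex))
    keep <- sample(seq_along(dex), nKeep)
    kept <- dex[keep]
    if (targetR < 1) {
      rl <- latentCorrelation(targetR, signFraction, magnitudeRange)
      z0 <- stats::qnorm(pmin(pmax(stats::pnorm(
        stats::qnorm(rank(mcols(kept)$delta_psi) / (nKeep + 1))), 1e-9),
        1 - 1e-9))
      z <- rl * z0 + sqrt(1 - rl^2) * stats::rnorm(nKeep)
      mcols(kept)$delta_psi <- uniformToDeltaPsi(stats::pnorm(z),
                                                 signFraction, magnitudeRange)
    }
    outside <- annotation[!exonKey(annotation) %in% exonKey(dex)]
    extra <- outside[sample(length(outside), size - nKeep)]
    mcols(extra)$delta_psi <- uniformToDeltaPsi(
      stats::runif(length(extra)), signFraction, magnitudeRange)
    mcols(extra)$adj_pvalue <- stats::runif(length(extra), 5e-4, 0.05)
    if (!"adj_pvalue" %in% colnames(mcols(kept)))
      mcols(kept)$adj_pvalue <- stats::runif(nKeep, 5e-4, 0.05)
    out <- c(kept, extra)
    out[sample(length(out))]
  })
}

#' Generate a planted CLIP-peak fixture
#'
#' Every regulated exon receives a covering peak with probability
#' `pOverlapReg`, every control exon with probability `pOverlapCtrl`,
#' independently. Peaks cover the requested region window of the exon, so
#' planted rates translate directly into the overlap proportions the
#' enrichment cell should recover.
#'
#' @param regExons,ctrlExons GRanges exon sets.
#' @param pOverlapReg,pOverlapCtrl planting probabilities in \[0, 1\].
#' @param region which region window the peaks should cover (default exon
#'   body).
#' @param seed integer seed.
#' @return list with `peaks` (merged GRanges) and logical ground-truth
#'   vectors `regPlanted`, `ctrlPlanted`.
#' @export
generateClipFixture <- function(regExons, ctrlExons, pOverlapReg,
                                pOverlapCtrl, region = "exon_body",
                                seed = 1) {
  stopifnot(pOverlapReg >= 0, pOverlapReg <= 1,
            pOverlapCtrl >= 0, pOverlapCtrl <= 1)
  withSeed(seed, {
    regPlant <- stats::runif(length(regExons)) < pOverlapReg
    ctrlPlant <- stats::runif(length(ctrlExons)) < pOverlapCtrl
    w <- function(gr) regionWindows(gr, 100)[[region]]
    peaks <- c(w(regExons)[regPlant], w(ctrlExons)[ctrlPlant])
    peaks <- peaks[IRanges::width(peaks) > 0]
    list(peaks = mergePeaks(peaks), regPlanted = regPlant,
         ctrlPlanted = ctrlPlant)
  })
}

#' Generate a motif-planted genome fixture
#'
#' Builds a random background genome covering an annotation and inserts a
#' concrete instance of the motif consensus inside the extended region of
#' each exon with a per-class planting rate. For minus-strand exons the
#' reverse complement is inserted genomically, so the motif appears in the
#' stranded extracted sequence. Planted positions are returned as ground
#' truth.
#'
#' @param annotation GRanges of all exons the genome must cover.
#' @param classRates named list of (GRanges, rate) pairs — each element is a
#'   list with `exons` and `rate`; classes may overlap the annotation
#'   arbitrarily.
#' @param motif a [MotifModel-class] with a consensus.
#' @param flank extension within which the motif may be planted (default
#'   200 nt; planting stays inside `exon +/- flank`).
#' @param margin extra genome padding beyond the last exon (default 500 nt).
#' @param seed integer seed.
#' @return list with `genome` (DNAStringSet) and `planted` (data.frame of
#'   class, exon key, chromosome, position).
#' @export
generateMotifFixture <- function(annotation, classRates, motif, flank = 200,
                                 margin = 500, seed = 1) {
  stopifnot(!is.na(motif@consensus))
  withSeed(seed, {
    chroms <- unique(as.character(seqnames(annotation)))
    lens <- vapply(chroms, function(ch)
      max(end(annotation[seqnames(annotation) == ch])) + flank + margin,
      numeric(1))
    genome <- Biostrings::DNAStringSet(vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    names(genome) <- chroms
    cmap <- Biostrings::IUPAC_CODE_MAP
    concrete <- function() paste(vapply(strsplit(motif@consensus, "")[[1]],
      function(l) {
        opts <- strsplit(cmap[[l]], "")[[1]]
        opts[sample.int(length(opts), 1L)]
      }, character(1)), collapse = "")
    w <- nchar(motif@consensus)
    planted <- list()
    for (cls in names(classRates)) {
      ex <- classRates[[cls]]$exons
      rate <- classRates[[cls]]$rate
      plant <- stats::runif(length(ex)) < rate
      for (i in which(plant)) {
        chr <- as.character(seqnames(ex))[i]
        lo <- max(1L, start(ex)[i] - flank)
        hi <- min(length(genome[[chr]]), end(ex)[i] + flank) - w + 1L
        if (hi < lo) next
        pos <- sample(lo:hi, 1L)
        inst <- concrete()
        if (as.character(strand(ex))[i] == "-")
          inst <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(inst)))
        genome[[chr]] <- Biostrings::replaceAt(
          genome[[chr]], IRanges(pos, pos + w - 1L), inst)
        planted[[length(planted) + 1L]] <- data.frame(
          class = cls, key = exonKey(ex[i]), chrom = chr, position = pos,
          stringsAsFactors = FALSE)
      }
    }
    list(genome = genome,
         planted = if (length(planted)) do.call(rbind, planted)
                   else data.frame(class = character(), key = character(),
                                   chrom = character(), position = integer()))
  })
}
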