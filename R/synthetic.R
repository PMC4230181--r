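#' @include rsd.R scoring.R
#' @importFrom stats runif rnorm
NULL

# second signal of a forced-association pair: uniform within `thr` of the
# first signal, clipped to the nucleus by resampling
.forcedPartner <- function(base, thr, a, b) {
  n <- nrow(base)
  out <- matrix(NA_real_, n, 2L)
  todo <- seq_len(n)
  while (length(todo)) {
    off <- .runifEllipse(length(todo), thr, thr)
    cand <- base[todo, , drop = FALSE] + off
    ok <- (cand[, 1] / a)^2 + (cand[, 2] / b)^2 <= 1
    out[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  out
}

# jittered extra signal coordinates around a base point (elongated or
# non-cohesive observations show >1 signal); jitter stays within one signal
# radius so extra signals remain part of the same signal area
.positionsString <- function(base, count, jitterR) {
  extra <- if (count > 1L) base[rep(1L, count - 1L), , drop = FALSE] +
    .runifEllipse(count - 1L, jitterR, jitterR) else NULL
  .formatPositions(rbind(base, extra))
}

#' Generate a scored-nuclei population with known ground truth
#'
#' Simulates a flow-sorted population of nuclei scored for two FISH probes,
#' with controllable true probabilities for induced association, sister-
#' chromatid cohesion, chromatin elongation and out-looping — the
#' ground-truth envelope used to validate every scoring metric.
#'
#' Per nucleus, with probability \code{pAssoc} the two probes' primary
#' signals are placed within the association threshold of each other (the
#' first by the Random Spatial Distribution placement of \code{relation},
#' the second uniformly within the threshold disc, clipped to the nucleus);
#' otherwise both are placed independently by the RSD model, so at
#' \code{pAssoc = 0} the population reproduces the model's random
#' association frequency.  Association flags are derived from the realized
#' signal positions with the same threshold (twice the signal radius), so
#' flag-based and position-based scoring agree by construction.
#'
#' Cohesion is drawn per homolog (4C and higher: fused single signal with
#' probability \code{pCohesion}), elongation and out-looping per nucleus and
#' probe; signal counts are set consistently with the flags (an elongated
#' nucleus shows one signal more than its ploidy number).  Positions are
#' recorded for the first homolog of each probe; second-homolog signals are
#' scored categorically.
#'
#' @param nNuclei number of nuclei (>= 1).
#' @param ploidy ploidy label of the population.
#' @param pAssoc,pCohesion,pElongation,pOutloop true per-unit probabilities
#'   in \[0, 1\] (\code{pCohesion} is ignored for 2C nuclei, which carry no
#'   replicated sisters).
#' @param relation pair relation used for the random placements.
#' @param config an [RSDConfig-class]; defaults to the calibrated geometry
#'   for \code{relation}.
#' @param probes identifiers of the two probes.
#' @param tissue free-text tissue label.
#' @param seed integer RNG seed; identical parameters and seed give a
#'   byte-identical table.
#' @return A [ScoredNuclei-class].
#' @examples
#' genNucleiPopulation(10, pAssoc = 0.5, seed = 1)
#' @export
genNucleiPopulation <- function(nNuclei, ploidy = "2C", pAssoc = 0,
                                pCohesion = 0, pElongation = 0, pOutloop = 0,
                                relation = c("trans", "cis", "homologous"),
                                config = defaultRSDConfig(relation, ploidy),
                                probes = c("probeA", "probeB"),
                                tissue = "leaf", seed = 1L) {
  relation <- .matchRelation(match.arg(relation))
  validObject(config)
  nNuclei <- as.integer(nNuclei)
  stopifnot(nNuclei >= 1L, length(probes) == 2L,
            ploidy %in% .PLOIDIES)
  probs <- c(pAssoc, pCohesion, pElongation, pOutloop)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  a <- config@semiMajor; b <- config@semiMinor
  rsig <- config@signalRadius
  thr <- 2 * rsig
  plNum <- .ploidyNumber(ploidy)
  replicated <- ploidy != "2C"

  .withSeed(seed, {
    forced <- runif(nNuclei) < pAssoc
    pts <- .samplePairs(config, relation, nNuclei)
    pA <- pts[[1L]]; pB <- pts[[2L]]
    if (any(forced))
      pB[forced, ] <- .forcedPartner(pA[forced, , drop = FALSE], thr, a, b)

    # per probe x homolog cohesion; per probe x nucleus elongation/out-loop
    cohesive <- if (replicated)
      matrix(runif(nNuclei * 4L) < pCohesion, nNuclei, 4L) else
      matrix(FALSE, nNuclei, 4L)                     # A1 A2 B1 B2
    elong <- matrix(runif(nNuclei * 2L) < pElongation, nNuclei, 2L)  # A B
    outloop <- matrix(runif(nNuclei * 2L) < pOutloop, nNuclei, 2L)   # A B

    baseCount <- if (replicated) ifelse(cohesive, 1L, 2L)
                 else matrix(1L, nNuclei, 4L)
    counts <- baseCount
    # elongated nuclei show one signal more than the ploidy number; the
    # surplus is carried by homolog 1
    for (p in 1:2) {
      h1 <- (p - 1L) * 2L + 1L
      tot <- baseCount[, h1] + baseCount[, h1 + 1L]
      bump <- elong[, p]
      counts[bump, h1] <- (plNum + 1L) - baseCount[bump, h1 + 1L]
    }

    posA <- vapply(seq_len(nNuclei), function(i)
      .positionsString(pA[i, , drop = FALSE], counts[i, 1L], rsig),
      character(1))
    posB <- vapply(seq_len(nNuclei), function(i)
      .positionsString(pB[i, , drop = FALSE], counts[i, 3L], rsig),
      character(1))

    # association from realized positions (all homolog-1 signals), so flag
    # and position scoring use the same threshold
    minDist <- vapply(seq_len(nNuclei), function(i) {
      ma <- .parsePositions(posA[i]); mb <- .parsePositions(posB[i])
      dx <- outer(ma[, 1], mb[, 1], "-"); dy <- outer(ma[, 2], mb[, 2], "-")
      sqrt(min(dx^2 + dy^2))
    }, numeric(1))
    associated <- minDist <= thr

    flagStr <- function(...) {
      f <- c(...)
      if (length(f)) paste(f, collapse = ",") else NA_character_
    }
    mkFlags <- function(i, p, h) {
      f <- character()
      if (h == 1L && associated[i])
        f <- c(f, paste0("associated_with:", probes[3L - p]))
      if (replicated && cohesive[i, (p - 1L) * 2L + h]) f <- c(f, "cohesive")
      if (h == 1L && elong[i, p]) f <- c(f, "elongated")
      if (h == 1L && outloop[i, p]) f <- c(f, "outside_CT")
      flagStr(f)
    }

    nucId <- sprintf("nuc%04d", seq_len(nNuclei))
    rows <- lapply(1:2, function(p) lapply(1:2, function(h) {
      col <- (p - 1L) * 2L + h
      data.frame(
        nucleus_id = nucId, ploidy = ploidy, tissue = tissue,
        probe_id = probes[p], homolog_index = h,
        signal_count = counts[, col],
        positions = if (h == 1L) (if (p == 1L) posA else posB)
                    else NA_character_,
        flags = vapply(seq_len(nNuclei), mkFlags, character(1), p = p, h = h),
        stringsAsFactors = FALSE
      )
    }))
    df <- do.call(rbind, unlist(rows, recursive = FALSE))
    df <- df[order(df$nucleus_id, df$probe_id, df$homolog_index), ]
    rownames(df) <- NULL
    ScoredNuclei(df)
  })
}

#' Generate an expression matrix with block correlation structure
#'
#' Emulates a microarray-style intensity matrix in which genes inside each
#' block share a latent per-sample factor: on the log2 scale a block gene is
#' \code{log2(baselineMean) + lambda * F_sample + noiseSd * eps} with
#' \code{lambda = noiseSd * sqrt(rho / (1 - rho))}, so the within-block
#' Pearson correlation of log intensities is exactly
#' \code{rho = latentCorrelation} and the expected within-block Spearman
#' correlation is \code{(6 / pi) * asin(rho / 2)}.  With \code{noiseSd = 0}
#' block genes are exact monotone copies of the factor (rs = 1).  Genes
#' outside any block are independent noise.  All intensities are positive.
#'
#' @param nGenes total number of genes.
#' @param nSamples number of samples.
#' @param blockSizes integer vector of co-expression block sizes
#'   (\code{sum(blockSizes) <= nGenes}).
#' @param latentCorrelation target within-block log-scale Pearson
#'   correlation, in \[0, 1).
#' @param noiseSd per-gene independent noise SD on the log2 scale.
#' @param baselineMean baseline intensity (linear scale).
#' @param seed integer RNG seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"intensity"} and the true block assignment in
#'   \code{rowData()$block} (NA for background genes).
#' @export
genExpressionMatrix <- function(nGenes, nSamples, blockSizes = integer(),
                                latentCorrelation = 0.7, noiseSd = 1,
                                baselineMean = 100, seed = 1L) {
  nGenes <- as.integer(nGenes); nSamples <- as.integer(nSamples)
  blockSizes <- as.integer(blockSizes)
  stopifnot(nGenes >= 1L, nSamples >= 1L, all(blockSizes >= 1L),
            sum(blockSizes) <= nGenes, noiseSd >= 0, baselineMean > 0)
  if (latentCorrelation < 0 || latentCorrelation >= 1)
    stop("latentCorrelation must lie in [0, 1)", call. = FALSE)
  rho <- latentCorrelation
  lambda <- if (noiseSd > 0) noiseSd * sqrt(rho / (1 - rho)) else 1
  block <- rep(NA_integer_, nGenes)
  if (length(blockSizes))
    block[seq_len(sum(blockSizes))] <- rep(seq_along(blockSizes), blockSizes)
  .withSeed(seed, {
    logm <- matrix(rnorm(nGenes * nSamples, sd = noiseSd), nGenes, nSamples)
    for (bk in seq_along(blockSizes)) {
      f <- rnorm(nSamples)
      logm[which(block == bk), ] <- logm[which(block == bk), , drop = FALSE] +
        rep(lambda * f, each = blockSizes[bk])
    }
    m <- 2^(log2(baselineMean) + logm)
    dimnames(m) <- list(sprintf("gene%04d", seq_len(nGenes)),
                        sprintf("sample%03d", seq_len(nSamples)))
    SummarizedExperiment(
      assays = list(intensity = m),
      rowData = S4Vectors::DataFrame(block = block)
    )
  })
}

#' Generate a probe/segment annotation
#'
#' Builds a sorted, validated set of genomic segments (the stand-in for BAC
#' probe positions) as a \code{GRanges}; coordinates are taken 0-based
#' half-open, the BED convention, and stored 1-based internally as usual for
#' \code{GRanges}.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param segments data.frame with columns \code{chrom}, \code{start}
#'   (0-based), \code{length} (bp) and \code{id}.
#' @return A sorted [GenomicRanges::GRanges] with segment ids as names and
#'   seqlengths set.
#' @seealso [writeBed()], [readBed()]
#' @export
genSegmentAnnotation <- function(chromSizes, segments) {
  stopifnot(!is.null(names(chromSizes)),
            all(c("chrom", "start", "length", "id") %in% colnames(segments)))
  unknown <- setdiff(segments$chrom, names(chromSizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(segments$start < 0) || any(segments$length < 1))
    stop("segments need start >= 0 and length >= 1", call. = FALSE)
  over <- segments$start + segments$length >
    chromSizes[segments$chrom]
  if (any(over))
    stop("coordinate error: segment(s) extend beyond the chromosome end: ",
         paste(segments$id[over], collapse = ", "), call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L,
                              width = segments$length),
    seqlengths = chromSizes
  )
  names(gr) <- segments$id
  GenomicRanges::sort(gr)
}
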