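#' @include AllClasses.R
#' @importFrom stats cor pt sd
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
NULL

# accept either a genes x samples matrix or a SummarizedExperiment
.exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- assay(x, 1L)
  m <- as.matrix(x)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("expression matrix needs unique gene identifiers as row names",
         call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Read an expression matrix
#'
#' Reads a genes x samples TSV (first column gene identifiers, header row
#' sample identifiers, \code{#} comment lines allowed) into a
#' [SummarizedExperiment::SummarizedExperiment] with one assay,
#' \code{"intensity"}.
#'
#' @param path path to the TSV file.
#' @return A \code{SummarizedExperiment}.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2L)
    stop("expression table needs a gene column plus at least one sample",
         call. = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate gene identifiers in expression table", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  SummarizedExperiment(assays = list(intensity = m))
}

#' Log2 mean-normalization of signal intensities
#'
#' Divides each gene's intensities by that gene's mean across samples and
#' takes log2 — the normalization convention behind "log2 mean-normalized
#' signal intensities" in developmental expression atlases.  A gene constant
#' across samples maps to all zeros; back-transformed row means equal one by
#' construction.
#'
#' @param x a genes x samples matrix of positive intensities, or a
#'   [SummarizedExperiment::SummarizedExperiment] whose first assay holds
#'   them.
#' @return The same container type with log2 mean-normalized values (assay
#'   \code{"log2norm"} for a \code{SummarizedExperiment}).
#' @examples
#' meanNormalize(matrix(c(1, 2, 4, 4), 2, 2,
#'               dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' @export
meanNormalize <- function(x) {
  m <- .exprMatrix(x)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all intensities must be positive and finite before ",
         "mean-normalization", call. = FALSE)
  norm <- log2(m / rowMeans(m))
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment(assays = list(log2norm = norm),
                         rowData = SummarizedExperiment::rowData(x))
  else norm
}

#' Spearman rank correlation of two value sequences
#'
#' Pearson correlation of average-ranked data (ties receive average ranks):
#' +1 for a perfectly concordant pair, -1 for a perfectly discordant one.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The rank correlation rs in \[-1, 1\].
#' @examples
#' spearmanRs(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
spearmanRs <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not supported", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant sequence", call. = FALSE)
  cor(x, y, method = "spearman")
}

# cache of exact rank-correlation null distributions (untied ranks)
.spearmanNullEnv <- new.env(parent = emptyenv())

# all permutations of 1..n as an n! x n integer matrix (successive insertion)
.permutations <- function(n) {
  p <- matrix(1L)
  if (n == 1L) return(p)
  for (k in 2L:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (i in seq_len(k)) {
      idx <- ((i - 1L) * m + 1L):(i * m)
      out[idx, ] <- if (i == 1L) cbind(k, p)
        else if (i == k) cbind(p, k)
        else cbind(p[, 1:(i - 1L), drop = FALSE], k,
                   p[, i:(k - 1L), drop = FALSE])
    }
    p <- out
  }
  p
}

.spearmanNull <- function(n) {
  key <- as.character(n)
  if (is.null(.spearmanNullEnv[[key]])) {
    perms <- .permutations(n)
    ssd <- colSums((t(perms) - seq_len(n))^2)
    .spearmanNullEnv[[key]] <- 1 - 6 * ssd / (n * (n^2 - 1))
  }
  .spearmanNullEnv[[key]]
}

#' Two-sided p-value for a Spearman rank correlation
#'
#' For small samples (n <= 9) the exact two-sided permutation p-value:
#' the fraction of the n! rank permutations whose |rs| reaches that of the
#' observed pair (assuming untied ranks).  For larger n the t
#' approximation with \code{t = rs * sqrt((n - 2) / (1 - rs^2))} on n - 2
#' degrees of freedom.  A perfect correlation in the approximation branch
#' returns the smallest representable positive double rather than zero.
#'
#' @param rs rank correlation in \[-1, 1\].
#' @param n number of paired observations (>= 4).
#' @return Two-sided p-value.
#' @examples
#' spearmanPvalue(1, 5)    # exact: 2/120
#' spearmanPvalue(0.5, 20) # t approximation
#' @export
spearmanPvalue <- function(rs, n) {
  if (!is.numeric(rs) || length(rs) != 1L || is.na(rs) || abs(rs) > 1 + 1e-12)
    stop("rs must be a single correlation in [-1, 1]", call. = FALSE)
  rs <- max(-1, min(1, rs))
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("n must be >= 4", call. = FALSE)
  if (n <= 9L) {
    null <- .spearmanNull(n)
    mean(abs(null) >= abs(rs) - 1e-12)
  } else {
    if (abs(rs) >= 1) return(.Machine$double.xmin)
    t <- rs * sqrt((n - 2) / (1 - rs^2))
    min(1, 2 * pt(-abs(t), df = n - 2))
  }
}

#' Pairwise gene-to-gene co-response query
#'
#' Computes Spearman co-response (rs with its p-value) for gene pairs, in
#' the style of conditional co-response queries: \code{mode = "sGQ"} takes a
#' single reference gene against every candidate; \code{mode = "mGQ"} scores
#' all pairs among the union of reference and candidate genes.  Gene
#' identifiers absent from the matrix are reported as an error, never
#' silently dropped.
#'
#' @param x expression values (matrix or
#'   [SummarizedExperiment::SummarizedExperiment]); typically
#'   [meanNormalize()]d, though rank correlations are unaffected by
#'   monotone normalization.
#' @param referenceGenes character vector of reference gene ids (length 1
#'   for sGQ).
#' @param candidateGenes character vector of candidate gene ids.
#' @param mode \code{"sGQ"} or \code{"mGQ"}.
#' @return A [S4Vectors::DataFrame] with columns \code{gene_a},
#'   \code{gene_b}, \code{rs}, \code{p_value}, \code{n_samples}, sorted by
#'   decreasing |rs| (ties broken by gene ids).
#' @export
coresponseQuery <- function(x, referenceGenes, candidateGenes = character(),
                            mode = c("sGQ", "mGQ")) {
  mode <- match.arg(mode)
  m <- .exprMatrix(x)
  wanted <- unique(c(referenceGenes, candidateGenes))
  unknown <- setdiff(wanted, rownames(m))
  if (length(unknown))
    stop("gene id(s) not in the expression matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pairs <- if (mode == "sGQ") {
    if (length(referenceGenes) != 1L)
      stop("sGQ takes exactly one reference gene", call. = FALSE)
    cand <- setdiff(unique(candidateGenes), referenceGenes)
    if (length(cand) == 0L)
      stop("sGQ needs at least one candidate gene", call. = FALSE)
    cbind(referenceGenes, cand)
  } else {
    if (length(wanted) < 2L)
      stop("mGQ needs at least two genes", call. = FALSE)
    t(utils::combn(sort(wanted), 2L))
  }
  n <- ncol(m)
  rs <- vapply(seq_len(nrow(pairs)), function(i)
    spearmanRs(m[pairs[i, 1L], ], m[pairs[i, 2L], ]), numeric(1))
  pv <- vapply(rs, spearmanPvalue, numeric(1), n = n)
  out <- DataFrame(gene_a = pairs[, 1L], gene_b = pairs[, 2L],
                   rs = rs, p_value = pv, n_samples = n)
  out[order(-abs(out$rs), out$gene_a, out$gene_b), ]
}

#' Classify gene pairs as high / low / intermediate co-expressing
#'
#' A pair is \code{high} when rs >= \code{highThreshold}, \code{low} when
#' |rs| <= \code{lowThreshold}, and \code{intermediate} otherwise.  The
#' default cutoffs (0.7 / 0.3) are explicit conventions, not published
#' values, and should be stated alongside any result.
#'
#' @param pairs a DataFrame/data.frame with an \code{rs} column (e.g. from
#'   [coresponseQuery()]) or a numeric vector of correlations.
#' @param highThreshold,lowThreshold cutoffs with
#'   \code{0 <= lowThreshold <= highThreshold <= 1}.
#' @return A character vector of labels (\code{"high"}, \code{"low"},
#'   \code{"intermediate"}).
#' @export
classifyCoexpression <- function(pairs, highThreshold = 0.7,
                                 lowThreshold = 0.3) {
  if (!is.numeric(highThreshold) || !is.numeric(lowThreshold) ||
      lowThreshold < 0 || highThreshold > 1 || lowThreshold > highThreshold)
    stop("need 0 <= lowThreshold <= highThreshold <= 1", call. = FALSE)
  rs <- if (is.numeric(pairs)) pairs else pairs$rs
  if (is.null(rs)) stop("pairs must provide an rs column", call. = FALSE)
  ifelse(rs >= highThreshold, "high",
         ifelse(abs(rs) <= lowThreshold, "low", "intermediate"))
}

#' Mean expression per probed segment
#'
#' Summarizes the (normalized) expression of the genes residing on each
#' probed segment in one chosen sample: mean, sample standard deviation (0
#' by convention for single-gene segments) and gene count.
#'
#' @param x expression values (matrix or SummarizedExperiment), typically
#'   [meanNormalize()]d log2 units.
#' @param segmentMap a data.frame with columns \code{gene_id} and
#'   \code{segment_id}, or a character vector of segment ids named by gene
#'   id.
#' @param sample sample identifier (or column index).
#' @return A [S4Vectors::DataFrame] with one row per segment:
#'   \code{segment_id}, \code{gene_count}, \code{mean_expression},
#'   \code{sd_expression}.
#' @export
segmentMeanExpression <- function(x, segmentMap, sample = 1L) {
  m <- .exprMatrix(x)
  if (is.character(segmentMap) && !is.null(names(segmentMap)))
    segmentMap <- data.frame(gene_id = names(segmentMap),
                             segment_id = unname(segmentMap),
                             stringsAsFactors = FALSE)
  if (!all(c("gene_id", "segment_id") %in% colnames(segmentMap)))
    stop("segmentMap needs gene_id and segment_id columns", call. = FALSE)
  if (nrow(segmentMap) == 0L)
    stop("empty segment map", call. = FALSE)
  unknown <- setdiff(segmentMap$gene_id, rownames(m))
  if (length(unknown))
    stop("mapped gene(s) absent from the expression matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.character(sample) && !sample %in% colnames(m))
    stop("unknown sample: ", sample, call. = FALSE)
  v <- m[, sample]
  bySeg <- split(segmentMap$gene_id, segmentMap$segment_id)
  DataFrame(
    segment_id = names(bySeg),
    gene_count = unname(vapply(bySeg, length, integer(1))),
    mean_expression = unname(vapply(bySeg, function(g) mean(v[g]), numeric(1))),
    sd_expression = unname(vapply(bySeg, function(g)
      if (length(g) == 1L) 0 else sd(v[g]), numeric(1)))
  )
}

#' Map genes to segments by coordinate overlap
#'
#' Assigns each gene to the probed segment it overlaps, the coordinate-based
#' alternative to an explicit gene-to-segment table.
#'
#' @param genes a [GenomicRanges::GRanges] of gene positions with gene ids
#'   as names.
#' @param segments a [GenomicRanges::GRanges] of probed segments with
#'   segment/probe ids as names (e.g. from [readBed()]).
#' @return A data.frame with columns \code{gene_id}, \code{segment_id}.
#' @export
segmentMapFromRanges <- function(genes, segments) {
  stopifnot(is(genes, "GRanges"), is(segments, "GRanges"))
  hits <- GenomicRanges::findOverlaps(genes, segments)
  segNames <- names(segments)
  if (is.null(segNames)) segNames <- as.character(seq_along(segments))
  geneNames <- names(genes)
  if (is.null(geneNames)) geneNames <- as.character(seq_along(genes))
  data.frame(
    gene_id = geneNames[S4Vectors::queryHits(hits)],
    segment_id = segNames[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}
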