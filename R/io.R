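#' @include exact-tests.R coexpression.R synthetic.R
NULL

#' Read a probe/segment annotation in BED format
#'
#' BED intervals are 0-based half-open; the name column carries the probe or
#' segment identifier (strand is ignored — hybridization probes target both
#' strands).  Lines are validated before parsing so that malformed
#' coordinates are reported with their file line numbers; the actual parsing
#' is done by \code{rtracklayer}.
#'
#' @param path path to a BED file.
#' @return A [GenomicRanges::GRanges] with probe ids as names (empty file
#'   gives an empty \code{GRanges}).
#' @seealso [writeBed()], [genSegmentAnnotation()]
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  dataLine <- !grepl("^(#|track|browser|\\s*$)", lines)
  problems <- character()
  for (i in which(dataLine)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      problems <- c(problems, sprintf("line %d: fewer than 3 fields", i))
      next
    }
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      problems <- c(problems, sprintf("line %d: non-numeric coordinates", i))
    else if (s >= e)
      problems <- c(problems, sprintf("line %d: start >= end", i))
  }
  if (length(problems))
    stop("invalid BED file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  if (!any(dataLine))
    return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "bed")
  if ("name" %in% colnames(S4Vectors::mcols(gr))) names(gr) <- gr$name
  gr
}

#' Write a probe/segment annotation as BED
#'
#' @param gr a [GenomicRanges::GRanges]; names (or a \code{name} column) are
#'   written to the BED name field.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  if (is.null(gr$name) && !is.null(names(gr))) gr$name <- names(gr)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# mean cross-segment Spearman correlation between two gene sets
.crossSegmentRs <- function(m, genesA, genesB) {
  rs <- outer(genesA, genesB, Vectorize(function(g1, g2)
    spearmanRs(m[g1, ], m[g2, ])))
  mean(rs)
}

#' Run the end-to-end association analysis
#'
#' For each requested probe pair: scores the observed association frequency,
#' obtains the random expectation (published reference constants or a fresh
#' Monte-Carlo simulation of the Random Spatial Distribution model), runs
#' the two-sided exact comparison, and — when an expression matrix and a
#' gene-to-segment map are supplied — appends per-segment mean log2
#' mean-normalized expression and the cross-segment co-expression class.
#' The result is the machine-readable analogue of a per-pair association
#' summary figure.
#'
#' @param nuclei a [ScoredNuclei-class].
#' @param pairs data.frame with columns \code{probe_a}, \code{probe_b},
#'   \code{relation} (\code{"cis"}, \code{"trans"} or \code{"homologous"}).
#' @param nullSource \code{"reference"} (published 2C constants) or
#'   \code{"simulated"} (run [estimateNull()] per pair).
#' @param config [RSDConfig-class] for simulated nulls; defaults to the
#'   calibrated geometry of each pair's relation.
#' @param nTrials,seed Monte-Carlo settings for simulated nulls.
#' @param expression optional expression matrix or SummarizedExperiment of
#'   positive intensities (normalized internally with [meanNormalize()]).
#' @param segmentMap optional gene-to-segment map (see
#'   [segmentMeanExpression()]); segment ids must be the probe ids.
#' @param sample sample of the expression matrix to summarize.
#' @param method exact-test flavour passed to [compareToNull()].
#' @param highThreshold,lowThreshold co-expression class cutoffs.
#' @return A [S4Vectors::DataFrame], one row per probe pair, with observed
#'   counts and percent, the null percent, p-value and stars, and (if
#'   expression was given) \code{mean_expr_a}, \code{mean_expr_b},
#'   \code{cross_rs} and \code{coexpression}.  Empty input yields an empty
#'   report with a warning.
#' @export
runPipeline <- function(nuclei, pairs,
                        nullSource = c("reference", "simulated"),
                        config = NULL, nTrials = 1e5, seed = 1L,
                        expression = NULL, segmentMap = NULL, sample = 1L,
                        method = c("fisher", "binomial"),
                        highThreshold = 0.7, lowThreshold = 0.3) {
  nullSource <- match.arg(nullSource)
  method <- match.arg(method)
  stopifnot(is(nuclei, "ScoredNuclei"),
            all(c("probe_a", "probe_b", "relation") %in% colnames(pairs)))
  empty <- DataFrame(
    probe_a = character(), probe_b = character(), relation = character(),
    k = integer(), n = integer(), percent = numeric(),
    null_percent = numeric(), p_value = numeric(), stars = character())
  if (nrow(observations(nuclei)) == 0L) {
    warning("empty scored-nuclei table: empty report")
    return(empty)
  }
  withExpr <- !is.null(expression) && !is.null(segmentMap)
  segsum <- NULL
  norm <- NULL
  if (withExpr) {
    norm <- .exprMatrix(meanNormalize(expression))
    segsum <- segmentMeanExpression(norm, segmentMap, sample)
    if (is.character(segmentMap) && !is.null(names(segmentMap)))
      segmentMap <- data.frame(gene_id = names(segmentMap),
                               segment_id = unname(segmentMap),
                               stringsAsFactors = FALSE)
  }
  ploidy <- ploidyLabel(nuclei)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pa <- pairs$probe_a[i]; pb <- pairs$probe_b[i]
    rel <- .matchRelation(pairs$relation[i])
    obs <- associationFrequency(nuclei, pa, pb)
    nullPct <- if (nullSource == "reference") {
      if (length(ploidy) != 1L)
        stop("reference nulls need a single-ploidy population", call. = FALSE)
      referenceNull(ploidy, rel)
    } else {
      cfg <- if (is.null(config)) defaultRSDConfig(rel) else config
      percent(estimateNull(cfg, rel, nTrials = nTrials,
                           seed = seed + i - 1L))
    }
    res <- compareToNull(obs, nullPct, method = method)
    out <- DataFrame(probe_a = pa, probe_b = pb, relation = rel,
                     k = successes(obs), n = trials(obs),
                     percent = percent(obs), null_percent = nullPct,
                     p_value = pValue(res), stars = stars(res))
    if (withExpr) {
      geneA <- segmentMap$gene_id[segmentMap$segment_id == pa]
      geneB <- segmentMap$gene_id[segmentMap$segment_id == pb]
      meanA <- segsum$mean_expression[match(pa, segsum$segment_id)]
      meanB <- segsum$mean_expression[match(pb, segsum$segment_id)]
      crossRs <- if (length(geneA) && length(geneB))
        .crossSegmentRs(norm, geneA, geneB) else NA_real_
      out$mean_expr_a <- meanA
      out$mean_expr_b <- meanB
      out$cross_rs <- crossRs
      out$coexpression <- if (is.na(crossRs)) NA_character_ else
        classifyCoexpression(crossRs, highThreshold, lowThreshold)
    }
    out
  })
  do.call(rbind, rows)
}

#' Write a report table with a provenance header
#'
#' Writes any report-style table as TSV preceded by \code{#} comment lines
#' recording the package version, a hash of the run configuration and the
#' seed, so that outputs are self-describing and reruns can be verified.
#'
#' @param report a DataFrame/data.frame (e.g. from [runPipeline()]).
#' @param path output TSV path.
#' @param seed seed used for the run.
#' @param config arbitrary run configuration object; hashed into the header.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(report, path, seed = NA_integer_, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# nucassoc %s", as.character(utils::packageVersion("nucassoc"))),
    sprintf("# config_hash=%s", rlang::hash(config)),
    sprintf("# seed=%s", seed)), con)
  write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
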