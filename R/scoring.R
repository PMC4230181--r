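#' @include AllClasses.R
#' @importFrom utils read.delim write.table
NULL

# "x,y;x,y" -> n x 2 numeric matrix (NULL when absent)
.parsePositions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  m <- t(vapply(pairs, function(p) as.numeric(p), numeric(2)))
  if (anyNA(m)) stop("malformed positions string: ", s, call. = FALSE)
  m
}

.formatPositions <- function(m) {
  if (is.null(m)) return(NA_character_)
  paste(sprintf("%.6g,%.6g", m[, 1], m[, 2]), collapse = ";")
}

.flagList <- function(flags) {
  flags[is.na(flags)] <- ""
  strsplit(flags, ",", fixed = TRUE)
}

.hasFlag <- function(flags, flag) {
  vapply(.flagList(flags), function(f) flag %in% f, logical(1))
}

.ploidyNumber <- function(ploidy) as.integer(sub("C$", "", ploidy))

#' Read a scored-nuclei table
#'
#' Reads the tab-separated scored-nuclei schema: one row per nucleus x probe
#' x homolog with columns \code{nucleus_id}, \code{ploidy}, \code{tissue},
#' \code{probe_id}, \code{homolog_index}, \code{signal_count},
#' \code{positions} (optional \code{"x,y"} pairs joined by semicolons, one
#' per signal) and \code{flags} (optional, comma-separated).  Lines starting
#' with \code{#} are header comments.  Malformed rows are reported with their
#' file line numbers.
#'
#' @param path path to a TSV file.
#' @return A [ScoredNuclei-class] object (empty file yields an empty one).
#' @seealso [writeScoredNuclei()], [genNucleiPopulation()]
#' @export
readScoredNuclei <- function(path) {
  lines <- readLines(path)
  nComment <- 0L
  while (nComment < length(lines) && grepl("^(#|\\s*$)", lines[nComment + 1L]))
    nComment <- nComment + 1L
  body <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(body) <= 1L) return(ScoredNuclei(.emptyScoredFrame()))
  df <- read.delim(text = body, stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(setdiff(.SCORED_COLS, c("positions", "flags", "tissue")),
                     colnames(df))
  if (length(missing))
    stop("scored-nuclei table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lineOf <- function(i) i + nComment + 1L  # header line precedes the data
  bad <- function(rows, why) {
    if (length(rows))
      sprintf("line %d: %s", lineOf(rows), why)
    else character()
  }
  problems <- character()
  hom <- suppressWarnings(as.integer(df$homolog_index))
  cnt <- suppressWarnings(as.integer(df$signal_count))
  problems <- c(problems,
    bad(which(!df$ploidy %in% .PLOIDIES), "unknown ploidy label"),
    bad(which(is.na(hom) | hom < 1L), "homolog_index must be an integer >= 1"),
    bad(which(is.na(cnt) | cnt < 1L), "signal_count must be an integer >= 1"))
  key <- paste(df$nucleus_id, df$probe_id, df$homolog_index, sep = "\r")
  problems <- c(problems,
    bad(which(duplicated(key)), "duplicate nucleus/probe/homolog observation"))
  if (length(problems))
    stop("invalid scored-nuclei table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  df$homolog_index <- hom
  df$signal_count <- cnt
  if (!"positions" %in% colnames(df)) df$positions <- NA_character_
  if (!"flags" %in% colnames(df)) df$flags <- NA_character_
  if (!"tissue" %in% colnames(df)) df$tissue <- NA_character_
  df$positions[df$positions == ""] <- NA_character_
  df$flags[df$flags == ""] <- NA_character_
  ScoredNuclei(df)
}

.emptyScoredFrame <- function() {
  data.frame(nucleus_id = character(), ploidy = character(),
             tissue = character(), probe_id = character(),
             homolog_index = integer(), signal_count = integer(),
             positions = character(), flags = character(),
             stringsAsFactors = FALSE)
}

#' Write a scored-nuclei table
#'
#' @param x a [ScoredNuclei-class].
#' @param path output TSV path.
#' @param comments optional character vector written as leading \code{#}
#'   header lines.
#' @return Invisibly, \code{path}.
#' @export
writeScoredNuclei <- function(x, path, comments = character()) {
  stopifnot(is(x, "ScoredNuclei"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(as.data.frame(observations(x)), con, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.probeRows <- function(df, probe) df[df$probe_id == probe, , drop = FALSE]

# minimum distance between any signal position of two row sets; NA when
# positions are missing on either side
.minCrossDistance <- function(rowsA, rowsB) {
  pa <- do.call(rbind, lapply(rowsA$positions, .parsePositions))
  pb <- do.call(rbind, lapply(rowsB$positions, .parsePositions))
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  sqrt(min(dx^2 + dy^2))
}

#' Frequency of association between two probed segments
#'
#' A nucleus counts as associated when any FISH signal of \code{probeA} and
#' any of \code{probeB} are associated; the denominator is the number of
#' nuclei in which both probes were scored.  With \code{threshold = NULL}
#' (the default) the categorical \code{associated_with:<probe>} flags are
#' used; with a numeric \code{threshold} the recorded positions are used and
#' association means a minimum inter-signal distance of at most
#' \code{threshold} micrometres.  In flag mode the absence of a flag means
#' "not associated", so a table in which nothing associates scores 0%;
#' position mode raises an error when positions are missing.
#'
#' @param x a [ScoredNuclei-class].
#' @param probeA,probeB probe identifiers.
#' @param threshold \code{NULL} for flag-based scoring, or an association
#'   distance in micrometres for position-based scoring.
#' @return A [FrequencySummary-class] counting nuclei.
#' @export
associationFrequency <- function(x, probeA, probeB, threshold = NULL) {
  df <- as.data.frame(observations(x))
  rowsA <- .probeRows(df, probeA)
  rowsB <- .probeRows(df, probeB)
  if (nrow(rowsA) == 0L || nrow(rowsB) == 0L)
    stop("both probes must be scored in at least one nucleus", call. = FALSE)
  ids <- intersect(unique(rowsA$nucleus_id), unique(rowsB$nucleus_id))
  metric <- sprintf("association:%s-%s", probeA, probeB)
  if (length(ids) == 0L) return(FrequencySummary(metric, 0L, 0L))
  if (is.null(threshold)) {
    # absence of a flag means "not associated": a categorical table in
    # which no nucleus associates is a legitimate 0% observation
    hitA <- .hasFlag(rowsA$flags, paste0("associated_with:", probeB))
    hitB <- .hasFlag(rowsB$flags, paste0("associated_with:", probeA))
    assocIds <- union(rowsA$nucleus_id[hitA], rowsB$nucleus_id[hitB])
    k <- sum(ids %in% assocIds)
  } else {
    d <- vapply(ids, function(id)
      .minCrossDistance(rowsA[rowsA$nucleus_id == id, , drop = FALSE],
                        rowsB[rowsB$nucleus_id == id, , drop = FALSE]),
      numeric(1))
    if (anyNA(d))
      stop("unscorable: positions missing for ", sum(is.na(d)),
           " nuclei; use flag-based scoring instead", call. = FALSE)
    k <- sum(d <= threshold)
  }
  FrequencySummary(metric, k, length(ids))
}

#' Frequency of chromatin fiber elongation
#'
#' A nucleus counts as elongated for a probe when it shows more FISH signals
#' than expected from its ploidy (more than 2 in 2C, more than 4 in 4C and,
#' as a convention beyond those published, more than the ploidy number in
#' higher endopolyploid classes), or when the \code{elongated} flag is set.
#'
#' @param x a [ScoredNuclei-class].
#' @param probe probe identifier.
#' @param ploidy restrict to one ploidy class.  Required when the scored
#'   nuclei mix ploidies (the signal-number threshold is ploidy-specific).
#' @return A [FrequencySummary-class] counting nuclei.
#' @export
elongationFrequency <- function(x, probe, ploidy = NULL) {
  df <- as.data.frame(observations(x))
  rows <- .probeRows(df, probe)
  if (nrow(rows) == 0L) stop("probe not scored: ", probe, call. = FALSE)
  if (is.null(ploidy)) {
    pl <- unique(rows$ploidy)
    if (length(pl) > 1L)
      stop("ambiguous ploidy: nuclei mix ", paste(pl, collapse = ", "),
           "; pass `ploidy` to select one class", call. = FALSE)
    ploidy <- pl
  } else {
    rows <- rows[rows$ploidy == ploidy, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("no ", ploidy, " nuclei scored for probe ", probe, call. = FALSE)
  }
  limit <- .ploidyNumber(ploidy)
  byNuc <- split(rows, rows$nucleus_id)
  elong <- vapply(byNuc, function(r)
    sum(r$signal_count) > limit || any(.hasFlag(r$flags, "elongated")),
    logical(1))
  FrequencySummary(sprintf("elongation:%s(%s)", probe, ploidy),
                   sum(elong), length(elong))
}

#' Frequency of sister-chromatid cohesion per homolog
#'
#' In nuclei with replicated chromatids (4C and higher) a homolog counts as
#' cohesive when its sister-chromatid signals appear as one fused FISH signal
#' (\code{signal_count == 1}) or when the \code{cohesive} flag is set.  The
#' denominator is the number of scored homologs.  Unreplicated 2C nuclei
#' carry no sister chromatids, so cohesion is undefined for them.
#'
#' @param x a [ScoredNuclei-class].
#' @param probe probe identifier.
#' @return A [FrequencySummary-class] counting homologs.
#' @export
cohesionFrequency <- function(x, probe) {
  df <- as.data.frame(observations(x))
  rows <- .probeRows(df, probe)
  if (nrow(rows) == 0L) stop("probe not scored: ", probe, call. = FALSE)
  rows <- rows[rows$ploidy != "2C", , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("cohesion undefined: only 2C nuclei scored ",
         "(no replicated sister chromatids)", call. = FALSE)
  cohesive <- rows$signal_count == 1L | .hasFlag(rows$flags, "cohesive")
  FrequencySummary(sprintf("cohesion:%s", probe),
                   sum(cohesive), nrow(rows))
}

#' Frequency of positional separation of adjacent segments
#'
#' For two probes annotated as adjacent on the chromosome, a scored homolog
#' counts as separated when the \code{separated_from_adjacent} flag is set on
#' either probe's observation, or (with a numeric \code{threshold}) when the
#' minimum distance between the probes' signals exceeds \code{threshold}.
#' Denominators follow the reporting convention of the underlying assay:
#' homologs in 2C nuclei, sister chromatids in 4C nuclei (each homolog
#' contributes two chromatid units and a homolog-level call applies to both
#' sisters).
#'
#' @param x a [ScoredNuclei-class].
#' @param probeA,probeB adjacent probe identifiers.
#' @param annotation a [GenomicRanges::GRanges] of probe segments whose
#'   names contain both probe ids; the two segments must touch or overlap on
#'   the same chromosome.
#' @param threshold optional separation distance in micrometres; when
#'   \code{NULL}, flags are used.
#' @return A [FrequencySummary-class] counting homologs (2C) or sister
#'   chromatids (4C+).
#' @export
separationFrequency <- function(x, probeA, probeB, annotation,
                                threshold = NULL) {
  stopifnot(is(annotation, "GRanges"))
  nm <- names(annotation)
  if (is.null(nm) && "name" %in% colnames(S4Vectors::mcols(annotation)))
    nm <- annotation$name
  if (!all(c(probeA, probeB) %in% nm))
    stop("annotation error: both probes must appear in the annotation",
         call. = FALSE)
  grA <- annotation[match(probeA, nm)]
  grB <- annotation[match(probeB, nm)]
  dist <- suppressWarnings(GenomicRanges::distance(grA, grB))
  if (is.na(dist) || dist > 0L)
    stop("annotation error: probes ", probeA, " and ", probeB,
         " are not adjacent on the same chromosome", call. = FALSE)
  df <- as.data.frame(observations(x))
  rowsA <- .probeRows(df, probeA)
  rowsB <- .probeRows(df, probeB)
  keyA <- paste(rowsA$nucleus_id, rowsA$homolog_index)
  keyB <- paste(rowsB$nucleus_id, rowsB$homolog_index)
  shared <- intersect(keyA, keyB)
  metric <- sprintf("separation:%s-%s", probeA, probeB)
  if (length(shared) == 0L) return(FrequencySummary(metric, 0L, 0L))
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  if (is.null(threshold)) {
    sep <- .hasFlag(rowsA$flags[ia], "separated_from_adjacent") |
           .hasFlag(rowsB$flags[ib], "separated_from_adjacent")
  } else {
    d <- vapply(seq_along(shared), function(j)
      .minCrossDistance(rowsA[ia[j], , drop = FALSE],
                        rowsB[ib[j], , drop = FALSE]), numeric(1))
    if (anyNA(d))
      stop("unscorable: positions missing for ", sum(is.na(d)),
           " homolog pairs", call. = FALSE)
    sep <- d > threshold
  }
  # chromatid units: two sisters per homolog in replicated (non-2C) nuclei
  units <- ifelse(rowsA$ploidy[ia] == "2C", 1L, 2L)
  FrequencySummary(metric, sum(units * sep), sum(units))
}

#' Frequency of out-looping from the chromosome territory
#'
#' Fraction of nuclei in which a probed segment was observed outside its
#' parent chromosome territory (the \code{outside_CT} flag, scored relative
#' to a territory paint).
#'
#' @param x a [ScoredNuclei-class].
#' @param probe probe identifier of the segment.
#' @param territoryProbe identifier of the territory paint the flag was
#'   scored against (recorded in the metric name).
#' @return A [FrequencySummary-class] counting nuclei.
#' @export
outloopFrequency <- function(x, probe, territoryProbe = NULL) {
  df <- as.data.frame(observations(x))
  rows <- .probeRows(df, probe)
  if (nrow(rows) == 0L) stop("probe not scored: ", probe, call. = FALSE)
  if (all(is.na(rows$flags)))
    stop("unscorable: no flags recorded for probe ", probe, call. = FALSE)
  byNuc <- split(rows, rows$nucleus_id)
  out <- vapply(byNuc, function(r) any(.hasFlag(r$flags, "outside_CT")),
                logical(1))
  metric <- if (is.null(territoryProbe)) sprintf("outloop:%s", probe)
            else sprintf("outloop:%s/CT:%s", probe, territoryProbe)
  FrequencySummary(metric, sum(out), length(out))
}
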