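#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.RELATIONS <- c("trans", "cis", "homologous")
.PLOIDIES <- c("2C", "4C", "8C", "16C", "32C", "64C")

#' Geometry of the virtual interphase nucleus
#'
#' An \code{RSDConfig} holds the geometry of the Random Spatial Distribution
#' (RSD) null model: a flattened nucleus modelled as a 2D ellipse, disc-shaped
#' chromosome territories, and disc-shaped FISH signal areas.  Two signal
#' areas count as associated when they touch or overlap, i.e. when their
#' centre distance is at most twice the signal radius.
#'
#' All lengths are in micrometres.  Flow-sorted leaf nuclei are strongly
#' flattened, so signal configurations are evaluated in projection; the model
#' is therefore two-dimensional.
#'
#' @slot semiMajor nucleus semi-axis along the long direction (um).
#' @slot semiMinor nucleus semi-axis along the short direction (um).
#' @slot signalRadius radius of one disc-shaped signal area (um).
#' @slot territoryRadius radius of the disc standing in for a chromosome
#'   (arm) territory; constrains cis and homologous placements (um).
#' @slot ploidy ploidy label of the nuclei this geometry describes
#'   (one of "2C", "4C", "8C", "16C", "32C", "64C").
#'
#' @seealso [RSDConfig()], [defaultRSDConfig()], [estimateNull()]
#' @exportClass RSDConfig
setClass("RSDConfig",
  representation(
    semiMajor = "numeric",
    semiMinor = "numeric",
    signalRadius = "numeric",
    territoryRadius = "numeric",
    ploidy = "character"
  )
)

setValidity("RSDConfig", function(object) {
  msg <- character()
  len <- c(
    semiMajor = object@semiMajor, semiMinor = object@semiMinor,
    signalRadius = object@signalRadius,
    territoryRadius = object@territoryRadius
  )
  if (length(object@semiMajor) != 1L || length(object@semiMinor) != 1L ||
      length(object@signalRadius) != 1L || length(object@territoryRadius) != 1L)
    msg <- c(msg, "all geometry slots must be length-1 numerics")
  else {
    if (any(!is.finite(len)) || any(len <= 0))
      msg <- c(msg, "all lengths must be finite and > 0")
    else {
      if (object@semiMinor > object@semiMajor)
        msg <- c(msg, "semiMinor must not exceed semiMajor")
      if (object@signalRadius > object@territoryRadius)
        msg <- c(msg, "signalRadius must not exceed territoryRadius")
      if (object@territoryRadius > object@semiMinor)
        msg <- c(msg, "territoryRadius must not exceed semiMinor")
    }
  }
  if (length(object@ploidy) != 1L || !object@ploidy %in% .PLOIDIES)
    msg <- c(msg, sprintf("ploidy must be one of: %s",
                          paste(.PLOIDIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Create an RSD model configuration
#'
#' @param semiMajor,semiMinor nucleus semi-axes in micrometres.
#' @param signalRadius signal-area disc radius in micrometres.
#' @param territoryRadius chromosome-territory disc radius in micrometres.
#' @param ploidy ploidy label, e.g. \code{"2C"}.
#' @return A validated [RSDConfig-class] object.
#' @examples
#' cfg <- RSDConfig(semiMajor = 4, semiMinor = 2.5,
#'                  signalRadius = 0.5, territoryRadius = 1.5)
#' cfg
#' @export
RSDConfig <- function(semiMajor, semiMinor, signalRadius, territoryRadius,
                      ploidy = "2C") {
  new("RSDConfig",
    semiMajor = as.numeric(semiMajor), semiMinor = as.numeric(semiMinor),
    signalRadius = as.numeric(signalRadius),
    territoryRadius = as.numeric(territoryRadius),
    ploidy = as.character(ploidy)
  )
}

#' Monte-Carlo estimate of a random-association null frequency
#'
#' @slot relation which pair relation was simulated: \code{"trans"}
#'   (different chromosomes), \code{"cis"} (different arms of the same
#'   chromosome, constrained to one territory disc) or \code{"homologous"}.
#' @slot nTrials number of simulated nuclei (trials).
#' @slot kAssociated trials in which the two signal discs touched or
#'   overlapped.
#' @slot percent \code{100 * kAssociated / nTrials}.
#' @slot stdErrorPercent binomial standard error of \code{percent}.
#' @slot seed RNG seed the estimate was produced with.
#' @seealso [estimateNull()]
#' @exportClass NullEstimate
setClass("NullEstimate",
  representation(
    relation = "character",
    nTrials = "integer",
    kAssociated = "integer",
    percent = "numeric",
    stdErrorPercent = "numeric",
    seed = "integer"
  )
)

setValidity("NullEstimate", function(object) {
  msg <- character()
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (object@kAssociated < 0L || object@kAssociated > object@nTrials)
    msg <- c(msg, "kAssociated must be in [0, nTrials]")
  if (!object@relation %in% .RELATIONS)
    msg <- c(msg, "relation must be one of trans, cis, homologous")
  p <- object@kAssociated / object@nTrials
  if (abs(object@percent - 100 * p) > 1e-8)
    msg <- c(msg, "percent inconsistent with kAssociated/nTrials")
  if (abs(object@stdErrorPercent - 100 * sqrt(p * (1 - p) / object@nTrials)) > 1e-8)
    msg <- c(msg, "stdErrorPercent inconsistent with counts")
  if (length(msg)) msg else TRUE
})

#' Frequency of a scored per-nucleus property
#'
#' A \code{FrequencySummary} is the (k successes, n trials) count behind any
#' reported frequency: association in cis/trans, chromatin elongation,
#' sister-chromatid cohesion, adjacent-segment separation or out-looping.
#' Percentages are stored at full precision; [show()] displays them rounded
#' half-up to one decimal, the convention used for reporting.
#'
#' @slot metric identifier of the scored property.
#' @slot k number of scoring units with the property.
#' @slot n number of scoring units examined (nuclei, homologs or
#'   sister chromatids, depending on the metric).
#' @slot percent \code{100 * k / n}, full precision.
#' @exportClass FrequencySummary
setClass("FrequencySummary",
  representation(
    metric = "character",
    k = "integer",
    n = "integer",
    percent = "numeric"
  )
)

setValidity("FrequencySummary", function(object) {
  msg <- character()
  if (object@n < 0L || object@k < 0L || object@k > object@n)
    msg <- c(msg, "need 0 <= k <= n")
  if (object@n > 0L && abs(object@percent - 100 * object@k / object@n) > 1e-8)
    msg <- c(msg, "percent inconsistent with k/n")
  if (length(msg)) msg else TRUE
})

#' @rdname FrequencySummary-class
#' @param metric identifier of the scored property.
#' @param k,n success and trial counts.
#' @return A [FrequencySummary-class] object.
#' @export
FrequencySummary <- function(metric, k, n) {
  k <- as.integer(k); n <- as.integer(n)
  new("FrequencySummary",
    metric = as.character(metric), k = k, n = n,
    percent = if (n > 0L) 100 * k / n else NaN
  )
}

#' Result of an exact comparison against a null expectation
#'
#' @slot table 2x2 contingency table; row 1 = observed (associated, not
#'   associated), row 2 = expected under the null at the same sample size.
#' @slot pValue two-sided exact p-value.
#' @slot stars significance tier: \code{"***"} for p < 0.001, \code{"**"}
#'   for p < 0.01, \code{"*"} for p < 0.05, \code{""} otherwise.
#' @seealso [compareToNull()], [fisherExactTwoSided()]
#' @exportClass TestResult
setClass("TestResult",
  representation(
    table = "matrix",
    pValue = "numeric",
    stars = "character"
  )
)

setValidity("TestResult", function(object) {
  msg <- character()
  if (!identical(dim(object@table), c(2L, 2L)))
    msg <- c(msg, "table must be 2x2")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must be in [0, 1]")
  if (!object@stars %in% c("", "*", "**", "***"))
    msg <- c(msg, "stars must be one of '', '*', '**', '***'")
  if (length(msg)) msg else TRUE
})

.SCORED_COLS <- c("nucleus_id", "ploidy", "tissue", "probe_id",
                  "homolog_index", "signal_count", "positions", "flags")

#' Scored FISH configurations for a population of nuclei
#'
#' A \code{ScoredNuclei} object holds one row per nucleus x probe x homolog
#' observation: the ploidy and tissue of the nucleus, the number of FISH
#' signals seen for that probe/homolog, optional 2D signal positions (um, in
#' the image frame) and optional categorical configuration flags
#' (\code{associated_with:<probe>}, \code{cohesive},
#' \code{separated_from_adjacent}, \code{outside_CT}, \code{elongated}).
#'
#' @slot observations a [S4Vectors::DataFrame] with columns
#'   \code{nucleus_id}, \code{ploidy}, \code{tissue}, \code{probe_id},
#'   \code{homolog_index}, \code{signal_count}, \code{positions},
#'   \code{flags}.  Positions are encoded as \code{"x,y"} pairs joined with
#'   semicolons, one pair per signal; flags are comma-separated.
#' @seealso [readScoredNuclei()], [genNucleiPopulation()],
#'   [associationFrequency()]
#' @exportClass ScoredNuclei
setClass("ScoredNuclei", representation(observations = "DataFrame"))

setValidity("ScoredNuclei", function(object) {
  df <- object@observations
  msg <- character()
  missing <- setdiff(.SCORED_COLS, colnames(df))
  if (length(missing))
    return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$ploidy %in% .PLOIDIES))
    msg <- c(msg, sprintf("unknown ploidy label(s): %s",
      paste(unique(setdiff(df$ploidy, .PLOIDIES)), collapse = ", ")))
  key <- paste(df$nucleus_id, df$probe_id, df$homolog_index, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate nucleus/probe/homolog observation(s)")
  if (any(df$signal_count < 1L))
    msg <- c(msg, "signal_count must be >= 1 for detected probes")
  pl <- unique(df$ploidy[!duplicated(df$nucleus_id)])
  has_pos <- !is.na(df$positions) & nzchar(df$positions)
  if (any(has_pos)) {
    npos <- vapply(strsplit(df$positions[has_pos], ";", fixed = TRUE),
                   length, integer(1))
    if (any(npos != df$signal_count[has_pos]))
      msg <- c(msg, "positions, when present, must list one x,y pair per signal")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ScoredNuclei-class
#' @param observations a data.frame or DataFrame with the schema above.
#' @return A validated [ScoredNuclei-class] object.
#' @export
ScoredNuclei <- function(observations) {
  df <- DataFrame(observations)
  if (!"positions" %in% colnames(df)) df$positions <- NA_character_
  if (!"flags" %in% colnames(df)) df$flags <- NA_character_
  if (!"tissue" %in% colnames(df)) df$tissue <- NA_character_
  df$nucleus_id <- as.character(df$nucleus_id)
  df$ploidy <- as.character(df$ploidy)
  df$probe_id <- as.character(df$probe_id)
  df$homolog_index <- as.integer(df$homolog_index)
  df$signal_count <- as.integer(df$signal_count)
  df$positions <- as.character(df$positions)
  df$flags <- as.character(df$flags)
  new("ScoredNuclei", observations = df[, .SCORED_COLS])
}
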