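#' @include AllGenerics.R
NULL

#' Accessors for nucassoc S4 classes
#'
#' Small read (and for geometry, replace) accessors for the package's
#' central objects; use these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @param value replacement value (micrometres for radii).
#' @return The slot value; replacement forms return the modified, re-validated
#'   object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("percent", "FrequencySummary", function(x) x@percent)
#' @rdname accessors
setMethod("percent", "NullEstimate", function(x) x@percent)
#' @rdname accessors
setMethod("successes", "FrequencySummary", function(x) x@k)
#' @rdname accessors
setMethod("successes", "NullEstimate", function(x) x@kAssociated)
#' @rdname accessors
setMethod("trials", "FrequencySummary", function(x) x@n)
#' @rdname accessors
setMethod("trials", "NullEstimate", function(x) x@nTrials)
#' @rdname accessors
setMethod("pValue", "TestResult", function(x) x@pValue)
#' @rdname accessors
setMethod("stars", "TestResult", function(x) x@stars)
#' @rdname accessors
setMethod("contingencyTable", "TestResult", function(x) x@table)

#' @rdname accessors
setMethod("signalRadius", "RSDConfig", function(x) x@signalRadius)
#' @rdname accessors
setMethod("signalRadius<-", "RSDConfig", function(x, value) {
  x@signalRadius <- as.numeric(value)
  validObject(x)
  x
})
#' @rdname accessors
setMethod("territoryRadius", "RSDConfig", function(x) x@territoryRadius)
#' @rdname accessors
setMethod("territoryRadius<-", "RSDConfig", function(x, value) {
  x@territoryRadius <- as.numeric(value)
  validObject(x)
  x
})
#' @rdname accessors
setMethod("nucleusAxes", "RSDConfig",
          function(x) c(semiMajor = x@semiMajor, semiMinor = x@semiMinor))
#' @rdname accessors
setMethod("ploidyLabel", "RSDConfig", function(x) x@ploidy)

#' @rdname accessors
setMethod("observations", "ScoredNuclei", function(x) x@observations)
#' @rdname accessors
setMethod("probeIds", "ScoredNuclei",
          function(x) unique(x@observations$probe_id))
#' @rdname accessors
setMethod("nucleusIds", "ScoredNuclei",
          function(x) unique(x@observations$nucleus_id))
#' @rdname accessors
setMethod("ploidyLabel", "ScoredNuclei",
          function(x) unique(x@observations$ploidy))

#' Round a percentage half-up to one decimal for display
#'
#' Reported frequencies are conventionally printed with one decimal, rounding
#' half-up (13.55 -> 13.6).  Computations always use full precision; this
#' helper only formats.
#'
#' @param x numeric vector of percentages.
#' @return Numeric vector rounded half-up to one decimal.
#' @examples displayPercent(100 * 27 / 200)
#' @export
displayPercent <- function(x) floor(x * 10 + 0.5) / 10

setMethod("show", "RSDConfig", function(object) {
  cat(sprintf(
    "RSDConfig (%s): nucleus %.3g x %.3g um, territory r=%.4g um, signal r=%.4g um\n",
    object@ploidy, object@semiMajor, object@semiMinor,
    object@territoryRadius, object@signalRadius))
})

setMethod("show", "NullEstimate", function(object) {
  cat(sprintf(
    "NullEstimate [%s]: %.1f%% associated (%d / %d trials, SE %.2f pp, seed %d)\n",
    object@relation, displayPercent(object@percent), object@kAssociated,
    object@nTrials, object@stdErrorPercent, object@seed))
})

setMethod("show", "FrequencySummary", function(object) {
  cat(sprintf("FrequencySummary [%s]: %.1f%% (%d / %d)\n",
              object@metric, displayPercent(object@percent),
              object@k, object@n))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: observed %d/%d vs expected %d/%d, p = %.4g %s\n",
              object@table[1, 1], sum(object@table[1, ]),
              object@table[2, 1], sum(object@table[2, ]),
              object@pValue, object@stars))
})

setMethod("show", "ScoredNuclei", function(object) {
  df <- object@observations
  cat(sprintf(
    "ScoredNuclei: %d nuclei (%s), %d probes, %d observations\n",
    length(unique(df$nucleus_id)),
    paste(sort(unique(df$ploidy)), collapse = "/"),
    length(unique(df$probe_id)), nrow(df)))
})
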