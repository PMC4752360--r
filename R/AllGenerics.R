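#' Correct song measurements to their 22 degrees C equivalents
#'
#' @param x a [SongMeasurement-class] or a measurement data.frame (one row
#'   per recording, columns as produced by [asMeasurementFrame()]).
#' @param coeffs a [TempCoefficients-class]; defaults to the standard slopes
#'   (120 Hz/C, 0.4 pulses/s/C, 2.5 %/C).
#' @param ... passed on to methods.
#' @return an object of the same class as `x` with traits at 22 C and the
#'   temperature field set to 22.
#' @export
setGeneric("correctTo22", function(x, coeffs = tempCoefficients(), ...)
  standardGeneric("correctTo22"))

#' @rdname clusterAccessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterAccessors
#' @export
setGeneric("clusterCentroids", function(x, scale = c("clustering", "raw"))
  standardGeneric("clusterCentroids"))

#' @rdname clusterAccessors
#' @export
setGeneric("clusterInertia", function(x) standardGeneric("clusterInertia"))

#' @rdname divergenceAccessors
#' @export
setGeneric("divergencePairs", function(x) standardGeneric("divergencePairs"))

#' @rdname curveAccessors
#' @export
setGeneric("curveParams", function(x) standardGeneric("curveParams"))

## ---- show methods -------------------------------------------------------

setMethod("show", "SongSpec", function(object) {
  cat("SongSpec:", c("mono", "di", "tri")[object@pattern], "syllabic\n")
  cat("  fundamental (22C): ", object@fundamental22, " Hz\n", sep = "")
  cat("  syllable duration: ", object@syllableDuration22, " ms; pulse rate: ",
      object@pulseRate22, " /s\n", sep = "")
  if (length(object@periods22))
    cat("  syllable periods:  ", paste(object@periods22, collapse = ", "),
        " ms\n", sep = "")
  cat("  sentence period:   ", object@sentencePeriod22, " ms\n", sep = "")
})

setMethod("show", "TempCoefficients", function(object) {
  cat("TempCoefficients: ", object@cF, " Hz/C, ", object@cPR,
      " pulses/s/C, ", object@cDur, " %/C\n", sep = "")
})

setMethod("show", "SongMeasurement", function(object) {
  cat("SongMeasurement [", object@recordingId, "] at ",
      object@temperatureC, " C\n", sep = "")
  cat("  fundamental: ", round(object@fundamentalHz, 1), " Hz; pattern: ",
      object@pattern, "; pulse rate: ", round(object@pulseRate, 1),
      " /s\n", sep = "")
  cat("  P1/P2/P3: ", round(object@P1ms, 1), "/", round(object@P2ms, 1),
      "/", round(object@P3ms, 1), " ms; sentence period: ",
      round(object@sentencePeriodMs, 1), " ms\n", sep = "")
})

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult: k = ", object@k, ", n = ", length(object@labels),
      ", inertia = ", signif(object@inertia, 6),
      if (object@standardized) " (z-scored features)" else "", "\n", sep = "")
  print(table(cluster = object@labels))
})

setMethod("show", "DivergenceSummary", function(object) {
  cat("DivergenceSummary over L = ", object@lengthBp, " bp; ",
      nrow(object@pairs), " group pairs; between-group divergence ",
      round(object@globalMinPct, 2), "-", round(object@globalMaxPct, 2),
      "%\n", sep = "")
})

setMethod("show", "DiscoveryCurveFit", function(object) {
  cat("DiscoveryCurveFit: Nspmax = ", signif(object@Nspmax, 4),
      ", t50 = ", signif(object@t50, 4), " nights, b = ",
      signif(object@b, 4), " (R = ", round(object@fitQuality, 4),
      ")\n", sep = "")
})
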