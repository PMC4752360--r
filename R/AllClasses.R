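## Central S4 containers. Validity methods enforce the structural invariants
## the downstream stages rely on; accessors live in the module files.

#' SongSpec: parameters of a synthetic cricket calling song at 22 degrees C
#'
#' A song is a train of sentences; each sentence contains `pattern` syllables
#' (1 = monosyllabic, 2 = disyllabic, 3 = trisyllabic); each syllable is a
#' pulse train of short tone bursts at the fundamental frequency. All trait
#' values are stored at the 22 degrees C reference; [synthesizeSong()] applies
#' the forward temperature model before rendering audio.
#'
#' @slot pattern integer, syllables per sentence (1, 2 or 3).
#' @slot fundamental22 fundamental (first-harmonic) frequency in Hz at 22 C.
#' @slot syllableDuration22 syllable duration in ms at 22 C.
#' @slot pulseRate22 within-syllable pulse rate in pulses per second at 22 C.
#' @slot periods22 numeric of length `pattern - 1`: onset-to-onset periods
#'   P1..P(pattern-1) between successive syllables, in ms at 22 C.
#' @slot sentencePeriod22 onset-to-onset period of sentence repetition
#'   ("Total"), in ms at 22 C.
#' @slot tempCoeffs a [TempCoefficients-class] object.
#'
#' @seealso [songSpec()], [synthesizeSong()]
#' @exportClass SongSpec
setClass("SongSpec",
  representation(
    pattern = "integer",
    fundamental22 = "numeric",
    syllableDuration22 = "numeric",
    pulseRate22 = "numeric",
    periods22 = "numeric",
    sentencePeriod22 = "numeric",
    tempCoeffs = "ANY"
  )
)

setValidity("SongSpec", function(object) {
  msg <- character()
  if (length(object@pattern) != 1L || !object@pattern %in% 1:3)
    msg <- c(msg, "pattern must be 1, 2 or 3")
  if (object@fundamental22 <= 0)
    msg <- c(msg, "fundamental22 must be positive")
  if (object@syllableDuration22 <= 0 || object@pulseRate22 <= 0 ||
      object@sentencePeriod22 <= 0)
    msg <- c(msg, "durations, pulse rate and periods must be positive")
  if (length(object@periods22) != object@pattern - 1L)
    msg <- c(msg, "periods22 must have length pattern - 1")
  if (length(object@periods22) && any(object@periods22 <= 0))
    msg <- c(msg, "syllable periods must be positive")
  if (object@sentencePeriod22 <= sum(object@periods22))
    msg <- c(msg, "sentence period must exceed the sum of syllable periods")
  if (length(object@periods22) &&
      any(object@periods22 < object@syllableDuration22))
    msg <- c(msg, "syllable periods must be >= syllable duration (no overlap)")
  if (!is(object@tempCoeffs, "TempCoefficients"))
    msg <- c(msg, "tempCoeffs must be a TempCoefficients object")
  if (length(msg)) msg else TRUE
})

#' TempCoefficients: linear temperature standard-curve slopes
#'
#' Slopes of the linear temperature dependence of acoustic traits, used both
#' forward (synthesis at temperature T) and backward (correction to the 22 C
#' reference). Frequency and pulse rate scale additively; durations and
#' periods scale multiplicatively (percent per degree).
#'
#' @slot cF fundamental slope in Hz per degree C (default 120).
#' @slot cPR pulse-rate slope in pulses per second per degree C (default 0.4).
#' @slot cDur duration slope in percent per degree C (default 2.5), applied
#'   uniformly to syllable periods and the sentence period.
#'
#' @seealso [tempCoefficients()], [correctTo22()]
#' @exportClass TempCoefficients
setClass("TempCoefficients",
  representation(cF = "numeric", cPR = "numeric", cDur = "numeric")
)

setValidity("TempCoefficients", function(object) {
  if (length(object@cF) != 1L || length(object@cPR) != 1L ||
      length(object@cDur) != 1L)
    return("cF, cPR and cDur must be single numbers")
  TRUE
})

#' SongMeasurement: acoustic traits measured from one recording
#'
#' Holds the six standard song measurements (fundamental frequency, syllabic
#' pattern, syllable periods P1--P3, sentence repetition period) plus the
#' within-syllable pulse rate, and the air temperature at recording time.
#' Fields that do not apply (e.g. P2 for a monosyllabic song) are `NA`.
#'
#' @slot recordingId character label of the recording.
#' @slot fundamentalHz fundamental frequency in Hz (NA if no in-band peak).
#' @slot pattern integer 1--3, or NA when unclassified.
#' @slot P1ms,P2ms,P3ms onset-to-onset syllable periods in ms (NA when the
#'   pattern has no such successor syllable).
#' @slot sentencePeriodMs onset-to-onset sentence repetition period in ms
#'   (NA when fewer than two sentences were available).
#' @slot pulseRate pulses per second within syllables.
#' @slot temperatureC recording temperature in degrees C.
#'
#' @seealso [measureSong()], [correctTo22()], [asMeasurementFrame()]
#' @exportClass SongMeasurement
setClass("SongMeasurement",
  representation(
    recordingId = "character",
    fundamentalHz = "numeric",
    pattern = "integer",
    P1ms = "numeric",
    P2ms = "numeric",
    P3ms = "numeric",
    sentencePeriodMs = "numeric",
    pulseRate = "numeric",
    temperatureC = "numeric"
  )
)

setValidity("SongMeasurement", function(object) {
  msg <- character()
  if (!is.na(object@pattern) && !object@pattern %in% 1:3)
    msg <- c(msg, "pattern must be 1, 2, 3 or NA")
  if (!is.na(object@sentencePeriodMs) && object@sentencePeriodMs <= 0)
    msg <- c(msg, "sentence period must be positive")
  if (!is.na(object@fundamentalHz) && object@fundamentalHz <= 0)
    msg <- c(msg, "fundamental must be positive")
  if (length(msg)) msg else TRUE
})

#' ClusteringResult: a best-of-restarts K-means solution
#'
#' @slot labels integer cluster labels, one per row, in 1..k.
#' @slot centroids numeric matrix (k x p) on the clustering scale (z-scored
#'   when `standardized` is TRUE).
#' @slot centroidsRaw centroids back-transformed to the original trait scale.
#' @slot inertia total within-cluster sum of squared distances on the
#'   clustering scale.
#' @slot k number of clusters.
#' @slot seed RNG seed used for the restarts.
#' @slot nInit number of random restarts.
#' @slot standardized logical; were columns z-scored before clustering?
#' @slot features character vector of the feature columns used.
#'
#' @seealso [kmeansClassify()]
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(
    labels = "integer",
    centroids = "matrix",
    centroidsRaw = "matrix",
    inertia = "numeric",
    k = "integer",
    seed = "integer",
    nInit = "integer",
    standardized = "logical",
    features = "character"
  )
)

setValidity("ClusteringResult", function(object) {
  msg <- character()
  if (any(object@labels < 1L | object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (object@inertia < 0) msg <- c(msg, "inertia must be non-negative")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (length(msg)) msg else TRUE
})

#' DivergenceSummary: between-group substitution counts and percent divergence
#'
#' Percent ("absolute") divergence is the uncorrected p-distance on the full
#' alignment length L: D = 100 d / L where d is the substitution count.
#'
#' @slot pairs data.frame with one row per unordered group pair: columns
#'   `groupA`, `groupB`, `minCount`, `maxCount`, `minPct`, `maxPct`,
#'   `bothDescribed`.
#' @slot lengthBp alignment length L used as the fixed denominator.
#' @slot globalMinPct,globalMaxPct range of between-group divergence.
#'
#' @seealso [groupDivergence()], [delimitCandidates()]
#' @exportClass DivergenceSummary
setClass("DivergenceSummary",
  representation(
    pairs = "data.frame",
    lengthBp = "integer",
    globalMinPct = "numeric",
    globalMaxPct = "numeric"
  )
)

setValidity("DivergenceSummary", function(object) {
  msg <- character()
  p <- object@pairs
  if (nrow(p)) {
    if (any(p$minCount > p$maxCount)) msg <- c(msg, "min > max count")
    if (any(p$minCount < 0) || any(p$maxCount > object@lengthBp))
      msg <- c(msg, "counts must lie in [0, L]")
    if (any(abs(p$minPct - 100 * p$minCount / object@lengthBp) > 1e-9))
      msg <- c(msg, "minPct must equal 100*minCount/L")
  }
  if (length(msg)) msg else TRUE
})

#' DiscoveryCurveFit: logistic fit to a species-discovery curve
#'
#' The cumulative number of species detected after t survey nights is
#' modelled as N(t) = Nspmax / (1 + (t/t50)^b), with b < 0 for a saturating
#' curve; t50 is the effort needed to find half of the species.
#'
#' @slot Nspmax asymptotic species number.
#' @slot t50 nights to half of the species.
#' @slot b dimensionless shape (negative for saturating curves).
#' @slot fitQuality Pearson correlation R between observed and fitted N.
#' @slot R2 squared correlation.
#' @slot data the fitted series (columns `night`, `nSpecies`, `fitted`).
#'
#' @seealso [fitLogistic()], [logisticFraction()]
#' @exportClass DiscoveryCurveFit
setClass("DiscoveryCurveFit",
  representation(
    Nspmax = "numeric",
    t50 = "numeric",
    b = "numeric",
    fitQuality = "numeric",
    R2 = "numeric",
    data = "data.frame"
  )
)

setValidity("DiscoveryCurveFit", function(object) {
  msg <- character()
  if (object@Nspmax <= 0) msg <- c(msg, "Nspmax must be positive")
  if (object@t50 <= 0) msg <- c(msg, "t50 must be positive")
  if (length(msg)) msg else TRUE
})
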