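## Correction arithmetic shared by the SongMeasurement and data.frame
## methods. Sign convention: the standard curves are slopes of trait
## increase with temperature, so correction to 22 C subtracts (additive
## traits) or divides out (durations) the slope times (T - 22).
.correctTraits <- function(fund, pr, durs, temperatureC, coeffs) {
  if (any(temperatureC < 20 | temperatureC > 29))
    stop("temperature outside the supported recording window [20, 29] C")
  dT <- temperatureC - 22
  list(
    fundamental = fund - coeffs@cF * dT,
    pulseRate = pr - coeffs@cPR * dT,
    durations = lapply(durs, function(x) x / (1 + (coeffs@cDur / 100) * dT))
  )
}

#' @describeIn correctTo22 correct a single measurement; durations (P1--P3
#'   and the sentence period) are divided by the percent factor, frequency
#'   and pulse rate corrected additively. At 22 C this is the identity, and
#'   the operation is idempotent because the output temperature is 22 C.
#' @export
setMethod("correctTo22", "SongMeasurement", function(x, coeffs, ...) {
  cr <- .correctTraits(x@fundamentalHz, x@pulseRate,
                       list(P1 = x@P1ms, P2 = x@P2ms, P3 = x@P3ms,
                            sent = x@sentencePeriodMs),
                       x@temperatureC, coeffs)
  initialize(x, fundamentalHz = cr$fundamental, pulseRate = cr$pulseRate,
             P1ms = cr$durations$P1, P2ms = cr$durations$P2,
             P3ms = cr$durations$P3, sentencePeriodMs = cr$durations$sent,
             temperatureC = 22)
})

#' @describeIn correctTo22 correct a measurement data.frame (columns
#'   `fundamental_Hz`, `pulse_rate`, `P1_ms`, `P2_ms`, `P3_ms`,
#'   `sentence_period_ms`, `temperature_C`) row-wise.
#' @export
setMethod("correctTo22", "data.frame", function(x, coeffs, ...) {
  need <- c("temperature_C")
  if (!all(need %in% names(x))) stop("missing temperature_C column")
  dT <- x$temperature_C
  cr <- .correctTraits(
    if ("fundamental_Hz" %in% names(x)) x$fundamental_Hz else NA_real_,
    if ("pulse_rate" %in% names(x)) x$pulse_rate else NA_real_,
    lapply(intersect(c("P1_ms", "P2_ms", "P3_ms", "sentence_period_ms"),
                     names(x)), function(cl) x[[cl]]),
    dT, coeffs)
  if ("fundamental_Hz" %in% names(x)) x$fundamental_Hz <- cr$fundamental
  if ("pulse_rate" %in% names(x)) x$pulse_rate <- cr$pulseRate
  durCols <- intersect(c("P1_ms", "P2_ms", "P3_ms", "sentence_period_ms"),
                       names(x))
  for (i in seq_along(durCols)) x[[durCols[i]]] <- cr$durations[[i]]
  x$temperature_C <- 22
  x
})

#' Fit per-trait temperature standard curves
#'
#' Ordinary least-squares regression of each trait on temperature across
#' repeated recordings of one individual at two or more distinct
#' temperatures. Frequency and pulse-rate slopes are reported per degree C;
#' duration traits (syllable periods, sentence period) as percent per
#' degree C relative to the fitted value at 22 C.
#'
#' @param measurements data.frame with a `temperature_C` column and trait
#'   columns (any of `fundamental_Hz`, `pulse_rate`, `P1_ms`, `P2_ms`,
#'   `P3_ms`, `sentence_period_ms`).
#' @return data.frame with columns `trait`, `slope`, `unit`
#'   (`"per_C"` for additive traits, `"pct_per_C"` for durations) and
#'   `value22` (the fitted trait value at 22 C).
#' @examples
#' d <- data.frame(temperature_C = c(21, 24, 27),
#'                 fundamental_Hz = 5000 + 120 * (c(21, 24, 27) - 22))
#' fitStandardCurve(d)
#' @export
fitStandardCurve <- function(measurements) {
  if (!"temperature_C" %in% names(measurements))
    stop("missing temperature_C column")
  temps <- measurements$temperature_C
  if (length(unique(temps)) < 2)
    stop("need measurements at >= 2 distinct temperatures")
  additive <- c("fundamental_Hz", "pulse_rate")
  duration <- c("P1_ms", "P2_ms", "P3_ms", "sentence_period_ms")
  traits <- intersect(c(additive, duration), names(measurements))
  rows <- lapply(traits, function(tr) {
    y <- measurements[[tr]]
    ok <- !is.na(y)
    if (sum(ok) < 2 || length(unique(temps[ok])) < 2) return(NULL)
    fit <- lm(y[ok] ~ I(temps[ok] - 22))
    a <- coef(fit)[1]; b <- coef(fit)[2]
    if (tr %in% additive) {
      data.frame(trait = tr, slope = unname(b), unit = "per_C",
                 value22 = unname(a))
    } else {
      data.frame(trait = tr, slope = unname(100 * b / a),
                 unit = "pct_per_C", value22 = unname(a))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
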