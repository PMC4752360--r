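#' Default configuration for song measurement
#'
#' Defaults are matched to the synthetic song generator: envelope smoothing
#' of 2 ms resolves individual pulses while the 20 percent relative
#' threshold with a 5 ms merge gap keeps each syllable's pulse train as one
#' interval; sentences are split at onset gaps above 150 ms; the spectral
#' search band 2--10 kHz brackets the 4--7 kHz range observed in Indian
#' Ocean scaly crickets.
#'
#' @param smoothingMs moving-average envelope window, ms.
#' @param thresholdFrac syllable threshold as a fraction of the 95th
#'   percentile envelope amplitude (relative, hence amplitude-invariant).
#' @param minGapMs supra-threshold runs separated by gaps shorter than this
#'   are merged.
#' @param minDurMs runs shorter than this are discarded.
#' @param sentenceGapMs onset-to-onset gap starting a new sentence.
#' @param band numeric length-2, spectral search band in Hz.
#' @param welchSegment FFT segment length for the Welch periodogram.
#' @return a named list of parameters.
#' @export
measureConfig <- function(smoothingMs = 2, thresholdFrac = 0.2,
                          minGapMs = 5, minDurMs = 3, sentenceGapMs = 150,
                          band = c(2000, 10000), welchSegment = 8192L) {
  list(smoothingMs = smoothingMs, thresholdFrac = thresholdFrac,
       minGapMs = minGapMs, minDurMs = minDurMs,
       sentenceGapMs = sentenceGapMs, band = band,
       welchSegment = as.integer(welchSegment))
}

#' Amplitude envelope of a waveform
#'
#' Moving-average of the rectified signal. Linear in amplitude:
#' `computeEnvelope(a * x) == a * computeEnvelope(x)` for a > 0, which makes
#' downstream relative thresholds amplitude-invariant.
#'
#' @param wave numeric waveform.
#' @param sampleRate samples per second.
#' @param smoothingMs window length in ms (> 0).
#' @return non-negative numeric vector, same length as `wave`.
#' @export
computeEnvelope <- function(wave, sampleRate, smoothingMs = 2) {
  if (!length(wave)) stop("empty waveform")
  if (smoothingMs <= 0) stop("smoothingMs must be positive")
  n <- max(1L, round(smoothingMs / 1000 * sampleRate))
  x <- abs(wave)
  if (n == 1L) return(x)
  ## centred moving average via cumulative sums; edges use partial windows
  cs <- cumsum(c(0, x))
  half <- n %/% 2
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect syllables as supra-threshold envelope runs
#'
#' Maximal runs of the envelope above `thresholdFrac` times its 95th
#' percentile; runs separated by gaps shorter than `minGapMs` are merged
#' (so a syllable's internal pulse gaps do not split it) and merged runs
#' shorter than `minDurMs` are discarded.
#'
#' @param envelope non-negative numeric (from [computeEnvelope()]).
#' @param sampleRate samples per second.
#' @param thresholdFrac relative threshold in (0, 1).
#' @param minGapMs merge gap, ms.
#' @param minDurMs minimum syllable duration, ms.
#' @return data.frame of sorted, non-overlapping intervals with columns
#'   `onset_s`, `offset_s` (empty on silence).
#' @export
detectSyllables <- function(envelope, sampleRate, thresholdFrac = 0.2,
                            minGapMs = 5, minDurMs = 3) {
  if (thresholdFrac <= 0 || thresholdFrac >= 1)
    stop("thresholdFrac must lie in (0, 1)")
  thr <- thresholdFrac * quantile(envelope, 0.95, names = FALSE)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  if (thr <= 0) return(empty)
  above <- envelope > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  ## merge runs separated by short gaps
  minGap <- minGapMs / 1000 * sampleRate
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[i, "start"] - last["end"] - 1 < minGap) {
      last["end"] <- runs[i, "end"]
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- runs[i, ]
  }
  m <- do.call(rbind, merged)
  dur <- (m[, "end"] - m[, "start"] + 1) / sampleRate * 1000
  m <- m[dur >= minDurMs, , drop = FALSE]
  if (!nrow(m)) return(empty)
  data.frame(onset_s = (m[, "start"] - 1) / sampleRate,
             offset_s = m[, "end"] / sampleRate)
}

#' Group syllables into sentences and classify the syllabic pattern
#'
#' A new sentence starts whenever the onset-to-onset gap between successive
#' syllables exceeds `sentenceGapMs`. The pattern is the modal syllable
#' count across sentences; modal counts above 3 are unclassified (NA, with
#' a warning), since the song grammar has at most trisyllabic sentences.
#'
#' @param syllables data.frame from [detectSyllables()] (sorted by onset).
#' @param sentenceGapMs sentence-break gap in ms.
#' @return list with `sentences` (list of per-sentence interval
#'   data.frames) and `pattern` (integer 1--3 or NA).
#' @export
groupSentences <- function(syllables, sentenceGapMs = 150) {
  if (!nrow(syllables))
    return(list(sentences = list(), pattern = NA_integer_))
  on <- syllables$onset_s
  if (is.unsorted(on)) stop("syllables must be sorted by onset")
  newSentence <- c(TRUE, diff(on) * 1000 > sentenceGapMs)
  id <- cumsum(newSentence)
  sentences <- split(syllables, id)
  counts <- vapply(sentences, nrow, integer(1))
  tab <- table(counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  pattern <- modal
  if (modal > 3L) {
    warning("modal syllable count ", modal,
            " exceeds 3; pattern unclassified")
    pattern <- NA_integer_
  }
  list(sentences = unname(sentences), pattern = pattern)
}

## Welch-averaged periodogram peak within a band; returns NA when no
## in-band power. Resolution = sampleRate / segment.
dominantFrequency <- function(wave, sampleRate, band = c(2000, 10000),
                              segment = 8192L) {
  segment <- min(segment, length(wave))
  nseg <- max(1L, floor(length(wave) / segment))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segment) - 1) / (segment - 1))
  pow <- numeric(segment)
  for (i in seq_len(nseg)) {
    x <- wave[((i - 1) * segment + 1):(i * segment)] * w
    pow <- pow + Mod(fft(x))^2
  }
  freq <- (seq_len(segment) - 1) / segment * sampleRate
  inBand <- freq >= band[1] & freq <= band[2] & freq <= sampleRate / 2
  if (!any(inBand) || all(pow[inBand] <= 0)) return(NA_real_)
  freq[inBand][which.max(pow[inBand])]
}

## pulse rate within one syllable interval: peak spacing of the fine
## envelope. Rate = (npeaks-1)/(t_last - t_first); single peak falls back
## to 1/duration.
syllablePulseRate <- function(wave, sampleRate, onset_s, offset_s) {
  i0 <- max(1L, floor(onset_s * sampleRate) + 1L)
  i1 <- min(length(wave), ceiling(offset_s * sampleRate))
  seg <- wave[i0:i1]
  env <- computeEnvelope(seg, sampleRate, smoothingMs = 0.5)
  thr <- 0.5 * max(env)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ctr <- (starts[r$values] + ends[r$values]) / 2 / sampleRate
  if (length(ctr) < 2) return(1 / (offset_s - onset_s))
  (length(ctr) - 1) / (ctr[length(ctr)] - ctr[1])
}

#' Measure the standard song traits from a waveform
#'
#' Extracts the six standard measurements: fundamental frequency (dominant
#' Welch-periodogram peak within the configured band), syllabic pattern
#' (modal syllable count per sentence), onset-to-onset syllable periods
#' P1--P3 averaged across complete sentences, onset-to-onset sentence
#' repetition period, and the within-syllable pulse rate. For di- and
#' trisyllabic songs the pulse rate reported is that of the closest-spaced
#' syllable pair (averaged over its two syllables); for monosyllabic songs
#' it is the mean across syllables.
#'
#' A single supra-threshold interval spanning essentially the whole
#' recording (a continuous tone) is reported as having no syllables, since
#' a syllable must be bounded by sub-threshold gaps.
#'
#' @param wave numeric waveform.
#' @param sampleRate samples per second.
#' @param temperatureC recording temperature in degrees C (carried through
#'   to the measurement; see [correctTo22()]).
#' @param config list from [measureConfig()].
#' @param recordingId label stored in the result.
#' @return a [SongMeasurement-class]. Sentence period is NA when fewer
#'   than two sentences are present; fundamental is NA when no spectral
#'   peak lies in the band.
#' @examples
#' sg <- synthesizeSong(songSpec(pattern = 2, periods22 = 80), 22, 4)
#' measureSong(sg$wave, sg$sampleRate, 22)
#' @export
measureSong <- function(wave, sampleRate, temperatureC = 22,
                        config = measureConfig(), recordingId = "rec") {
  env <- computeEnvelope(wave, sampleRate, config$smoothingMs)
  syl <- detectSyllables(env, sampleRate, config$thresholdFrac,
                         config$minGapMs, config$minDurMs)
  totalDur <- length(wave) / sampleRate
  if (nrow(syl) == 1 && (syl$offset_s - syl$onset_s) >= 0.95 * totalDur)
    syl <- syl[0, ]                      # continuous tone: not syllabic
  fund <- dominantFrequency(wave, sampleRate, config$band,
                            config$welchSegment)
  P <- c(NA_real_, NA_real_, NA_real_)
  sentPeriod <- NA_real_
  pattern <- NA_integer_
  pr <- NA_real_
  if (nrow(syl)) {
    grp <- groupSentences(syl, config$sentenceGapMs)
    pattern <- grp$pattern
    complete <- if (!is.na(pattern))
      Filter(function(s) nrow(s) == pattern, grp$sentences)
    else grp$sentences
    if (!is.na(pattern) && pattern >= 2) {
      for (i in seq_len(min(pattern - 1L, 3L))) {
        gaps <- vapply(complete, function(s)
          (s$onset_s[i + 1] - s$onset_s[i]) * 1000, numeric(1))
        P[i] <- mean(gaps)
      }
    }
    starts <- vapply(complete, function(s) s$onset_s[1], numeric(1))
    if (length(starts) >= 2) sentPeriod <- mean(diff(starts)) * 1000
    ## pulse rate: closest-spaced syllable pair (di/tri), else all syllables
    rateOf <- function(rows) mean(vapply(seq_len(nrow(rows)), function(j)
      syllablePulseRate(wave, sampleRate, rows$onset_s[j], rows$offset_s[j]),
      numeric(1)))
    if (!is.na(pattern) && pattern >= 2 && length(complete)) {
      s1 <- complete[[1]]
      gaps <- diff(s1$onset_s)
      jmin <- which.min(gaps)
      pr <- rateOf(s1[jmin:(jmin + 1), ])
    } else {
      pr <- rateOf(syl)
    }
  }
  new("SongMeasurement", recordingId = recordingId,
      fundamentalHz = fund, pattern = pattern,
      P1ms = P[1], P2ms = P[2], P3ms = P[3],
      sentencePeriodMs = sentPeriod, pulseRate = pr,
      temperatureC = temperatureC)
}

#' Flatten song measurements into a tidy data.frame
#'
#' @param x a [SongMeasurement-class] or a list of them.
#' @return data.frame with columns `recording_id`, `fundamental_Hz`,
#'   `pattern`, `P1_ms`, `P2_ms`, `P3_ms`, `sentence_period_ms`,
#'   `pulse_rate`, `temperature_C`.
#' @export
asMeasurementFrame <- function(x) {
  if (is(x, "SongMeasurement")) x <- list(x)
  do.call(rbind, lapply(x, function(m) data.frame(
    recording_id = m@recordingId,
    fundamental_Hz = m@fundamentalHz,
    pattern = m@pattern,
    P1_ms = m@P1ms, P2_ms = m@P2ms, P3_ms = m@P3ms,
    sentence_period_ms = m@sentencePeriodMs,
    pulse_rate = m@pulseRate,
    temperature_C = m@temperatureC,
    stringsAsFactors = FALSE
  )))
}
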