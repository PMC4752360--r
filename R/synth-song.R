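#' Construct temperature standard-curve coefficients
#'
#' Defaults are the standard slopes for Indian Ocean scaly-cricket song:
#' the fundamental rises by 120 Hz per degree C, the within-syllable pulse
#' rate by 0.4 pulses/s per degree C, and durations (syllable periods and
#' the sentence period) by 2.5 percent per degree C.
#'
#' @param cF Hz per degree C.
#' @param cPR pulses per second per degree C.
#' @param cDur percent per degree C (multiplicative on durations).
#' @return a [TempCoefficients-class] object.
#' @examples
#' tempCoefficients()
#' @export
tempCoefficients <- function(cF = 120, cPR = 0.4, cDur = 2.5) {
  new("TempCoefficients", cF = cF, cPR = cPR, cDur = cDur)
}

#' Construct a synthetic song specification
#'
#' Trait values are given at the 22 degrees C reference. Defaults describe a
#' plausible monosyllabic scaly-cricket song: 5 kHz fundamental, 40 ms
#' syllables of 250 pulses/s, repeated every 500 ms. For di- and trisyllabic
#' songs supply `periods22` (onset-to-onset periods P1, P2 between
#' successive syllables within a sentence).
#'
#' @param pattern syllables per sentence (1, 2 or 3).
#' @param fundamental22 fundamental frequency in Hz at 22 C.
#' @param syllableDuration22 syllable duration in ms at 22 C.
#' @param pulseRate22 within-syllable pulse rate (pulses/s) at 22 C.
#' @param periods22 numeric of length `pattern - 1` in ms at 22 C.
#' @param sentencePeriod22 sentence repetition period in ms at 22 C.
#' @param tempCoeffs a [TempCoefficients-class].
#' @return a [SongSpec-class] object.
#' @examples
#' songSpec()                                     # monosyllabic
#' songSpec(pattern = 2, periods22 = 80)          # disyllabic, P1 = 80 ms
#' @export
songSpec <- function(pattern = 1L, fundamental22 = 5000,
                     syllableDuration22 = 40, pulseRate22 = 250,
                     periods22 = numeric(0), sentencePeriod22 = 500,
                     tempCoeffs = tempCoefficients()) {
  new("SongSpec", pattern = as.integer(pattern),
      fundamental22 = fundamental22,
      syllableDuration22 = syllableDuration22,
      pulseRate22 = pulseRate22,
      periods22 = as.numeric(periods22),
      sentencePeriod22 = sentencePeriod22,
      tempCoeffs = tempCoeffs)
}

#' Forward temperature model: trait values at a recording temperature
#'
#' Applies the linear standard curves forward: the fundamental and pulse
#' rate increase additively with temperature, durations and periods
#' multiplicatively (percent per degree). This is the exact inverse of
#' [correctTo22()], so a measurement of a song synthesized at T, corrected
#' back to 22 C, recovers the specification values.
#'
#' @param spec a [SongSpec-class].
#' @param temperatureC recording temperature in degrees C.
#' @return a named list: `fundamental`, `pulseRate`, `syllableDuration`,
#'   `periods`, `sentencePeriod` (ms / Hz / pulses/s at `temperatureC`).
#' @export
traitsAtTemperature <- function(spec, temperatureC) {
  stopifnot(is(spec, "SongSpec"))
  dT <- temperatureC - 22
  cc <- spec@tempCoeffs
  durFactor <- 1 + (cc@cDur / 100) * dT
  list(
    fundamental = spec@fundamental22 + cc@cF * dT,
    pulseRate = spec@pulseRate22 + cc@cPR * dT,
    syllableDuration = spec@syllableDuration22 * durFactor,
    periods = spec@periods22 * durFactor,
    sentencePeriod = spec@sentencePeriod22 * durFactor
  )
}

#' Synthesize a pulse-train cricket song waveform
#'
#' Renders `nSentences` sentences, each of `pattern` syllables; each
#' syllable is a train of k tone bursts at the temperature-adjusted
#' fundamental, where k = round(pulse rate x syllable duration). Bursts
#' have a 50 percent duty cycle and raised-cosine on/off ramps, giving
#' unambiguous envelope peaks for pulse-rate measurement. Optional additive
#' white Gaussian noise stands in for field noise.
#'
#' @param spec a [SongSpec-class].
#' @param temperatureC air temperature in degrees C (must lie in [20, 29],
#'   the supported recording window).
#' @param nSentences number of sentences to render (>= 1).
#' @param noiseRms RMS amplitude of additive white Gaussian noise
#'   (0 = noiseless); tone bursts have unit peak amplitude.
#' @param sampleRate samples per second; must exceed 4x the
#'   temperature-adjusted fundamental.
#' @param seed integer RNG seed for the noise (ignored when `noiseRms` = 0).
#' @return a list with `wave` (numeric vector in [-1-noise, 1+noise]),
#'   `sampleRate`, `temperatureC`, and `truth` (the trait values at
#'   `temperatureC`, from [traitsAtTemperature()], plus true syllable onset
#'   times in seconds).
#' @examples
#' sg <- synthesizeSong(songSpec(), 22, nSentences = 3)
#' length(sg$wave) / sg$sampleRate   # seconds of audio
#' @export
synthesizeSong <- function(spec, temperatureC = 22, nSentences = 5L,
                           noiseRms = 0, sampleRate = 44100, seed = 1L) {
  stopifnot(is(spec, "SongSpec"))
  if (temperatureC < 20 || temperatureC > 29)
    stop("temperatureC must lie in [20, 29]")
  if (nSentences < 1) stop("nSentences must be >= 1")
  tr <- traitsAtTemperature(spec, temperatureC)
  if (sampleRate < 4 * tr$fundamental)
    stop("sampleRate must be at least 4x the fundamental at this temperature",
         " (Nyquist margin)")

  msToSamp <- function(ms) round(ms / 1000 * sampleRate)
  sylSamp <- msToSamp(tr$syllableDuration)
  k <- max(1L, round(tr$pulseRate * tr$syllableDuration / 1000))
  pulsePeriodSamp <- sylSamp / k
  burstSamp <- max(4L, round(pulsePeriodSamp * 0.5))   # 50% duty cycle

  ## raised-cosine burst window (ramps over 25% of each end); the carrier
  ## is phase-continuous and gated by this window, so the dominant
  ## spectral line sits exactly at the fundamental rather than at a
  ## pulse-repetition comb line
  gate <- rep(1, burstSamp)
  nr <- max(2L, round(burstSamp * 0.25))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
  gate[seq_len(nr)] <- ramp
  gate[(burstSamp - nr + 1):burstSamp] <- rev(ramp)

  sylOffsets <- c(0, cumsum(tr$periods))              # within-sentence, ms
  lead <- 20                                          # ms of leading silence
  sentenceStarts <- lead + (seq_len(nSentences) - 1) * tr$sentencePeriod
  onsetsMs <- as.vector(outer(sylOffsets, sentenceStarts, "+"))
  onsetsMs <- sort(onsetsMs)

  totalSamp <- msToSamp(max(onsetsMs) + tr$syllableDuration + lead)
  env <- numeric(totalSamp)
  for (on in onsetsMs) {
    s0 <- msToSamp(on)
    for (p in seq_len(k)) {
      b0 <- s0 + round((p - 1) * pulsePeriodSamp)
      idx <- (b0 + 1):(b0 + burstSamp)
      env[idx] <- pmax(env[idx], gate)
    }
  }
  tAbs <- (seq_len(totalSamp) - 1) / sampleRate
  wave <- env * sin(2 * pi * tr$fundamental * tAbs)
  if (noiseRms > 0) {
    set.seed(as.integer(seed))
    wave <- wave + rnorm(totalSamp, sd = noiseRms)
  }
  truth <- tr
  truth$onsets_s <- onsetsMs / 1000
  truth$pattern <- spec@pattern
  truth$nPulsesPerSyllable <- k
  list(wave = wave, sampleRate = sampleRate, temperatureC = temperatureC,
       truth = truth)
}
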