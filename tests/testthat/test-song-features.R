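test_that("envelope is non-negative, linear in amplitude, zero on silence", {
  sg <- synthesizeSong(songSpec(), 22, 2)
  env <- computeEnvelope(sg$wave, sg$sampleRate, 2)
  expect_true(all(env >= 0))
  expect_equal(length(env), length(sg$wave))
  expect_equal(computeEnvelope(3 * sg$wave, sg$sampleRate, 2), 3 * env)
  expect_true(all(computeEnvelope(numeric(100) + 0, 44100, 2) == 0))
  expect_error(computeEnvelope(numeric(0), 44100, 2), "empty")
  ## constant tone: envelope approximately constant at the tone amplitude
  tone <- sin(2 * pi * 5000 * (0:22049) / 44100)
  envT <- computeEnvelope(tone, 44100, 5)
  mid <- envT[2000:20000]
  expect_lt(diff(range(mid)) / mean(mid), 0.05)
})

test_that("syllable detection merges short gaps and drops short runs", {
  sr <- 1000
  env <- numeric(1000)
  env[101:200] <- 1            # run A
  env[203:300] <- 1            # 2 ms gap from A: merged
  env[501:600] <- 1            # isolated run B
  env[801:802] <- 1            # 2 ms run: dropped (min_dur 3 ms)
  syl <- detectSyllables(env, sr, thresholdFrac = 0.2, minGapMs = 5,
                         minDurMs = 3)
  expect_equal(nrow(syl), 2)
  expect_equal(syl$onset_s, c(0.100, 0.500))
  ## silence: empty list
  expect_equal(nrow(detectSyllables(numeric(500), sr)), 0)
})

test_that("sentence grouping classifies the syllabic pattern", {
  ## 6 equally spaced syllables, break every 2 -> 3 disyllabic sentences
  on <- c(0, 0.08, 0.5, 0.58, 1.0, 1.08)
  syl <- data.frame(onset_s = on, offset_s = on + 0.04)
  grp <- groupSentences(syl, sentenceGapMs = 150)
  expect_equal(length(grp$sentences), 3)
  expect_equal(grp$pattern, 2L)
  ## single syllable: one monosyllabic sentence
  one <- groupSentences(data.frame(onset_s = 0.1, offset_s = 0.14), 150)
  expect_equal(length(one$sentences), 1)
  expect_equal(one$pattern, 1L)
  ## modal count above 3 is unclassified with a warning
  on4 <- c(0, 0.05, 0.10, 0.15, 0.5, 0.55, 0.60, 0.65)
  syl4 <- data.frame(onset_s = on4, offset_s = on4 + 0.02)
  expect_warning(g4 <- groupSentences(syl4, 150), "unclassified")
  expect_true(is.na(g4$pattern))
})

test_that("trisyllabic onsets are localized within 2 ms of ground truth", {
  sp <- songSpec(pattern = 3, periods22 = c(80, 90), sentencePeriod22 = 600)
  sg <- synthesizeSong(sp, 22, nSentences = 3)
  env <- computeEnvelope(sg$wave, sg$sampleRate, 2)
  syl <- detectSyllables(env, sg$sampleRate)
  expect_equal(nrow(syl), length(sg$truth$onsets_s))
  expect_lt(max(abs(syl$onset_s - sg$truth$onsets_s)) * 1000, 2)
})

test_that("measurement round trip recovers the generating specification", {
  ## monosyllabic: fundamental and sentence period within 1%
  sg <- synthesizeSong(songSpec(fundamental22 = 5000, sentencePeriod22 = 500),
                       22, nSentences = 4)
  m <- measureSong(sg$wave, sg$sampleRate, 22)
  expect_equal(m@pattern, 1L)
  expect_lt(abs(m@fundamentalHz - 5000) / 5000, 0.01)
  expect_lt(abs(m@sentencePeriodMs - 500) / 500, 0.01)
  expect_true(is.na(m@P1ms))
  ## disyllabic: P1 within 2 ms of the specified 80 ms
  sg2 <- synthesizeSong(songSpec(pattern = 2, periods22 = 80), 22, 4)
  m2 <- measureSong(sg2$wave, sg2$sampleRate, 22)
  expect_equal(m2@pattern, 2L)
  expect_lt(abs(m2@P1ms - 80), 2)
})

test_that("a pure continuous tone has a fundamental but no syllables", {
  tone <- sin(2 * pi * 5000 * (0:44099) / 44100)
  m <- measureSong(tone, 44100, 22)
  expect_lt(abs(m@fundamentalHz - 5000), 44100 / 8192 + 1e-9)
  expect_true(is.na(m@pattern))
  expect_true(is.na(m@sentencePeriodMs))
})

test_that("measurements are invariant to time shift and amplitude scale", {
  sg <- synthesizeSong(songSpec(pattern = 2, periods22 = 80), 22, 4)
  m0 <- measureSong(sg$wave, sg$sampleRate, 22)
  shifted <- c(numeric(round(0.3 * sg$sampleRate)), sg$wave)
  mS <- measureSong(shifted, sg$sampleRate, 22)
  mA <- measureSong(0.05 * sg$wave, sg$sampleRate, 22)
  for (m in list(mS, mA)) {
    expect_equal(m@pattern, m0@pattern)
    expect_equal(m@P1ms, m0@P1ms, tolerance = 1e-6)
    expect_equal(m@sentencePeriodMs, m0@sentencePeriodMs, tolerance = 1e-6)
    expect_equal(m@fundamentalHz, m0@fundamentalHz, tolerance = 1e-3)
  }
})

test_that("round trip holds under moderate additive noise", {
  ## noise RMS 0.05 against unit-amplitude bursts (~20 dB SNR on the tone)
  sg <- synthesizeSong(songSpec(pattern = 2, periods22 = 80), 22, 4,
                       noiseRms = 0.05, seed = 9)
  m <- measureSong(sg$wave, sg$sampleRate, 22)
  expect_equal(m@pattern, 2L)
  expect_lt(abs(m@P1ms - 80), 2)
  expect_lt(abs(m@sentencePeriodMs - 500), 2)
  expect_lt(abs(m@fundamentalHz - 5000), 44100 / 8192 + 1e-9)
})

test_that("WAV files round-trip through the reader and writer", {
  sg <- synthesizeSong(songSpec(), 22, 2)
  p16 <- tempfile(fileext = ".wav")
  pf <- tempfile(fileext = ".wav")
  writeWav(sg$wave, p16, sg$sampleRate, "pcm16")
  writeWav(sg$wave, pf, sg$sampleRate, "float32")
  r16 <- readWav(p16)
  rf <- readWav(pf)
  expect_equal(r16$sampleRate, sg$sampleRate)
  expect_lt(max(abs(r16$wave - sg$wave)), 1e-4)   # 16-bit quantization
  expect_lt(max(abs(rf$wave - sg$wave)), 1e-6)    # float32 precision
  unlink(c(p16, pf))
})
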