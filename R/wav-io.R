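## Minimal RIFF/WAVE reader and writer (PCM 16-bit and IEEE float32,
## mono or stereo). Hand-written because the pipeline only needs plain
## uncompressed WAV with no metadata chunks.

#' Write a waveform to a WAV file
#'
#' @param wave numeric vector (mono) or a 2-column matrix (stereo) with
#'   samples in [-1, 1]; values are clipped for PCM output.
#' @param path output file path.
#' @param sampleRate samples per second.
#' @param format `"pcm16"` (16-bit integer) or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(wave, path, sampleRate = 44100,
                     format = c("pcm16", "float32")) {
  format <- match.arg(format)
  if (is.null(dim(wave))) wave <- matrix(wave, ncol = 1)
  nch <- ncol(wave)
  interleaved <- as.vector(t(wave))
  bytesPer <- if (format == "pcm16") 2L else 4L
  dataSize <- length(interleaved) * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + dataSize)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16)
  w16(if (format == "pcm16") 1L else 3L)      # audio format tag
  w16(nch)
  w32(sampleRate)
  w32(sampleRate * nch * bytesPer)            # byte rate
  w16(nch * bytesPer)                         # block align
  w16(8L * bytesPer)                          # bits per sample
  writeChar("data", con, eos = NULL)
  w32(dataSize)
  if (format == "pcm16") {
    x <- pmax(-1, pmin(1, interleaved))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(interleaved), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports uncompressed PCM 16-bit and IEEE float32, mono or stereo.
#' Stereo is averaged to mono by default (acoustic measurements are
#' single-channel).
#'
#' @param path WAV file path.
#' @param toMono average channels to one?
#' @return list with `wave` (numeric in [-1, 1]; matrix if stereo kept)
#'   and `sampleRate`.
#' @export
readWav <- function(path, toMono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || !nzchar(id)) stop("no data chunk found")
    size <- r32()
    if (id == "fmt ") {
      fmt <- list(tag = r16(), nch = r16(), rate = r32())
      r32(); r16()
      fmt$bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      n <- size / (fmt$bits / 8)
      x <- if (fmt$tag == 1 && fmt$bits == 16) {
        readBin(con, "integer", n = n, size = 2, endian = "little") / 32767
      } else if (fmt$tag == 3 && fmt$bits == 32) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else stop("unsupported WAV format (tag ", fmt$tag, ", ",
                  fmt$bits, " bits)")
      wave <- if (fmt$nch > 1)
        matrix(x, ncol = fmt$nch, byrow = TRUE) else x
      if (toMono && fmt$nch > 1) wave <- rowMeans(wave)
      return(list(wave = wave, sampleRate = fmt$rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}
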