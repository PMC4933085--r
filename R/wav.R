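## RIFF WAV reading/writing. PCM 8/16/24-bit and 32/64-bit IEEE float are
## supported, which covers field-recorder output (the survey hardware this
## toolkit targets writes 16-bit PCM at 44.1 kHz).

#' Read a RIFF WAV file
#'
#' Low-level reader returning all channels. Integer PCM is scaled to
#' [-1, 1] by the signed full-scale value of the bit depth (a 16-bit sample of
#' 32767 maps to 32767/32768); float data is passed through.
#'
#' @param path Path to a WAV file.
#' @return A list with `samples` (matrix, frames x channels), `rate`,
#'   `bits`, `channels`.
#' @seealso [readAudio()] for the mono `AudioSignal` interface.
#' @export
readWave <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read WAV file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        code     = readBin(raw[1:2], "integer", 1, 2, endian = "little",
                           signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little",
                           signed = FALSE),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, endian = "little",
                           signed = FALSE))
      ## WAVE_FORMAT_EXTENSIBLE: the real code sits in the SubFormat GUID
      if (fmt$code == 65534L && size >= 40L)
        fmt$code <- readBin(raw[25:26], "integer", 1, 2, endian = "little",
                            signed = FALSE)
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))  # skip, pad to even
      next
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data))
    stop("corrupt WAV file (missing fmt/data chunk): ", path, call. = FALSE)
  if (length(data) == 0L)
    stop("zero-length audio in ", path, call. = FALSE)

  x <- decodePCM(data, fmt$code, fmt$bits, path)
  nch <- max(1L, fmt$channels)
  nfr <- length(x) %/% nch
  if (nfr < 1L) stop("zero-length audio in ", path, call. = FALSE)
  mat <- matrix(x[seq_len(nfr * nch)], nrow = nfr, ncol = nch, byrow = TRUE)
  list(samples = mat, rate = fmt$rate, bits = fmt$bits, channels = nch)
}

decodePCM <- function(data, code, bits, path) {
  n <- length(data)
  if (code == 3L) {                       # IEEE float
    bytes <- bits %/% 8L
    return(readBin(data, "double", n %/% bytes, size = bytes,
                   endian = "little"))
  }
  if (code != 1L)
    stop("unsupported WAV encoding (format code ", code, ") in ", path,
         call. = FALSE)
  if (bits == 8L) {                       # unsigned
    u <- as.integer(data)
    (u - 128) / 128
  } else if (bits == 16L) {
    readBin(data, "integer", n %/% 2L, size = 2L, endian = "little") / 32768
  } else if (bits == 24L) {
    m <- n %/% 3L
    b <- matrix(as.integer(data[seq_len(3L * m)]), nrow = 3L)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("unsupported PCM bit depth (", bits, ") in ", path, call. = FALSE)
  }
}

#' Write a WAV file
#'
#' @param samples Numeric vector (mono) or matrix (frames x channels) in
#'   [-1, 1]; values outside are clipped.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWave <- function(samples, rate, path, bits = 16L) {
  if (is.numeric(samples) && is.null(dim(samples)))
    samples <- matrix(samples, ncol = 1L)
  stopifnot(is.matrix(samples), isScalar(rate), rate > 0)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32", call. = FALSE)
  samples <- pmax(pmin(samples, 1), -1)  # argument order preserves dim
  nch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  bytes <- bits %/% 8L
  dataSize <- length(interleaved) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2L,
           endian = "little")
  writeBin(as.integer(nch), con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * nch * bytes), con, size = 4L, endian = "little")
  writeBin(as.integer(nch * bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmin(32767, pmax(-32768, round(interleaved * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read audio as a mono AudioSignal
#'
#' Loads a WAV file and mixes all channels down to mono by the per-frame
#' channel mean, preserving the sampling rate.
#'
#' @param path Path to a WAV file (PCM 8/16/24-bit or IEEE float).
#' @return An [AudioSignal-class].
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWave(sin(2 * pi * 440 * seq(0, 0.1, by = 1/8000)), 8000, f)
#' readAudio(f)
#' @export
readAudio <- function(path) {
  w <- readWave(path)
  AudioSignal(rowMeans(w$samples), w$rate)
}

#' Write an AudioSignal to a WAV file
#'
#' @param sig An [AudioSignal-class].
#' @param path Output path.
#' @param bits 16 or 32.
#' @return `path`, invisibly.
#' @export
writeAudio <- function(sig, path, bits = 16L) {
  stopifnot(is(sig, "AudioSignal"))
  writeWave(samples(sig), rate(sig), path, bits = bits)
}
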