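## Preprocessing and time-frequency representations: everything downstream
## (indices, sparse coding, latent component analysis) consumes these.

#' High-pass filter an AudioSignal
#'
#' Butterworth high-pass, as applied to field recordings to attenuate
#' low-frequency machinery and aircraft noise before index computation
#' (conventionally 500 Hz). The slope is given in dB/octave: 12 dB/octave is
#' a 2nd-order filter, 24 dB/octave a 4th-order one. The magnitude response
#' is -3 dB at the cutoff and the passband gain approaches unity well above
#' it.
#'
#' By default the filter is applied in a single forward pass. With
#' `zeroPhase = TRUE` the filter is applied forward and backward
#' (`signal::filtfilt`), which removes phase distortion but squares the
#' magnitude response (-6 dB at cutoff, doubled effective slope).
#'
#' @param sig An [AudioSignal-class].
#' @param cutoffHz Cutoff frequency in Hz; must lie below Nyquist.
#' @param slopeDbPerOctave 12 or 24.
#' @param zeroPhase Apply forward-backward filtering (default `FALSE`).
#' @return A filtered [AudioSignal-class] of the same length and rate.
#' @examples
#' sig <- AudioSignal(sin(2 * pi * 4000 * seq(0, 0.2, by = 1/44100)), 44100)
#' hp <- highpassFilter(sig, 500)
#' @export
highpassFilter <- function(sig, cutoffHz, slopeDbPerOctave = 12,
                           zeroPhase = FALSE) {
  stopifnot(is(sig, "AudioSignal"))
  if (!isScalar(cutoffHz) || cutoffHz <= 0 || cutoffHz >= rate(sig) / 2)
    stop("'cutoffHz' must lie in (0, Nyquist)", call. = FALSE)
  if (!slopeDbPerOctave %in% c(12, 24))
    stop("'slopeDbPerOctave' must be 12 or 24", call. = FALSE)
  ord <- slopeDbPerOctave / 6L
  bf <- signal::butter(ord, 2 * cutoffHz / rate(sig), type = "high")
  y <- if (zeroPhase) signal::filtfilt(bf, samples(sig))
       else as.numeric(signal::filter(bf, samples(sig)))
  AudioSignal(y, rate(sig))
}

stftWindow <- function(name, n) {
  switch(name,
    hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n),      # periodic Hann
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    rectangular = rep(1, n),
    stop("unknown window function: ", name, call. = FALSE))
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Frames of `winLen` samples are taken every `hop` samples (the last partial
#' window is dropped), windowed, and transformed. The one-sided magnitude is
#' amplitude-calibrated: a full-scale bin-centred sinusoid yields a bin value
#' of ~1, so cell levels in dB re full scale are `20*log10(values)`.
#' Frequencies are `k * rate / winLen` for `k = 0..winLen/2`; a frame's time
#' is the centre of its window.
#'
#' @param sig An [AudioSignal-class].
#' @param winLen Window length in samples (>= 2); default 512.
#' @param hop Hop size in samples (>= 1); default `winLen / 2`.
#' @param window `"hann"` (default), `"hamming"` or `"rectangular"`.
#' @return A linear-frequency [Spectrogram-class].
#' @examples
#' sig <- AudioSignal(sin(2 * pi * 86 * (44100/512) * (0:44099) / 44100), 44100)
#' sp <- stftSpectrogram(sig, 512, 256, "rectangular")
#' @export
stftSpectrogram <- function(sig, winLen = 512L, hop = winLen %/% 2L,
                            window = "hann") {
  stopifnot(is(sig, "AudioSignal"))
  winLen <- as.integer(winLen); hop <- as.integer(hop)
  if (winLen < 2L) stop("'winLen' must be >= 2", call. = FALSE)
  if (hop < 1L) stop("'hop' must be >= 1", call. = FALSE)
  x <- samples(sig)
  if (length(x) < winLen)
    stop("signal shorter than one analysis window", call. = FALSE)
  w <- stftWindow(window, winLen)
  starts <- seq.int(1L, length(x) - winLen + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + winLen - 1L)] * w,
                   numeric(winLen))
  sp <- stats::mvfft(frames)
  nb <- winLen %/% 2L + 1L
  mag <- Mod(sp[seq_len(nb), , drop = FALSE])
  ## amplitude calibration: interior bins carry half of a real sinusoid's mass
  scale <- rep(2 / sum(w), nb)
  scale[1L] <- 1 / sum(w)
  if (winLen %% 2L == 0L) scale[nb] <- 1 / sum(w)
  mag <- mag * scale
  freqs <- (seq_len(nb) - 1L) * rate(sig) / winLen
  times <- (starts - 1L + winLen / 2) / rate(sig)
  Spectrogram(mag, freqs, times, scale = "linear")
}

## Sparse spectral kernels for the constant-Q transform (Brown & Puckette
## style): per bin, the FFT of a Hann-windowed complex exponential, truncated
## to its significant band.
cqtKernels <- function(rate, fmin, binsPerOctave, nBins, thresh = 0.005) {
  Q <- 1 / (2^(1 / binsPerOctave) - 1)
  freqs <- fmin * 2^((seq_len(nBins) - 1L) / binsPerOctave)
  nMax <- ceiling(Q * rate / fmin)
  nfft <- 2^ceiling(log2(nMax))
  kernels <- vector("list", nBins)
  for (b in seq_len(nBins)) {
    nk <- ceiling(Q * rate / freqs[b])
    t0 <- (nfft - nk) %/% 2L               # centre the kernel in the frame
    n <- seq_len(nk) - 1L
    win <- (0.5 - 0.5 * cos(2 * pi * n / (nk - 1))) / nk
    tk <- complex(modulus = win,
                  argument = 2 * pi * freqs[b] * (n + t0) / rate)
    buf <- complex(real = numeric(nfft))
    buf[t0 + seq_len(nk)] <- tk
    kf <- stats::fft(buf)
    keep <- which(Mod(kf) > thresh * max(Mod(kf)))
    kernels[[b]] <- list(idx = keep, coef = Conj(kf[keep]) / nfft)
  }
  list(freqs = freqs, nfft = nfft, kernels = kernels)
}

#' Constant-Q (log-frequency) spectrogram
#'
#' Geometrically spaced analysis bins at `fmin * 2^(b / binsPerOctave)`, each
#' with constant ratio of centre frequency to bandwidth — the log-frequency
#' spectrogram used as input to the sparse-coding and latent component
#' decompositions. Implemented with FFT-domain sparse kernels.
#'
#' @param sig An [AudioSignal-class].
#' @param fmin Lowest bin centre frequency (Hz); default 110.
#' @param binsPerOctave Bins per octave; default 24.
#' @param hop Hop size in samples; default 1024.
#' @param nBins Number of bins; defaults to the largest count whose top bin
#'   stays below Nyquist.
#' @return A log-frequency [Spectrogram-class].
#' @export
constantQSpectrogram <- function(sig, fmin = 110, binsPerOctave = 24L,
                                 hop = 1024L, nBins = NULL) {
  stopifnot(is(sig, "AudioSignal"))
  if (!isScalar(fmin) || fmin <= 0) stop("'fmin' must be > 0", call. = FALSE)
  binsPerOctave <- as.integer(binsPerOctave)
  if (binsPerOctave < 1L) stop("'binsPerOctave' must be >= 1", call. = FALSE)
  nyq <- rate(sig) / 2
  maxBins <- floor(binsPerOctave * log2(nyq / fmin))
  if (maxBins < 1L)
    stop("'fmin' leaves no analysable bins below Nyquist", call. = FALSE)
  if (is.null(nBins)) nBins <- maxBins
  nBins <- as.integer(nBins)
  if (fmin * 2^((nBins - 1L) / binsPerOctave) >= nyq)
    stop("requested bins extend beyond Nyquist; reduce 'nBins' or raise 'fmin'",
         call. = FALSE)
  kk <- cqtKernels(rate(sig), fmin, binsPerOctave, nBins)
  x <- samples(sig)
  if (length(x) < kk$nfft)
    stop("signal shorter than one constant-Q analysis frame (",
         kk$nfft, " samples)", call. = FALSE)
  hop <- as.integer(hop)
  starts <- seq.int(1L, length(x) - kk$nfft + 1L, by = hop)
  vals <- matrix(0, nBins, length(starts))
  chunk <- max(1L, floor(4e6 / kk$nfft))
  for (i0 in seq.int(1L, length(starts), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(starts))
    frames <- vapply(starts[ii], function(s) x[s:(s + kk$nfft - 1L)],
                     numeric(kk$nfft))
    ff <- stats::mvfft(frames)
    for (b in seq_len(nBins)) {
      k <- kk$kernels[[b]]
      vals[b, ii] <- Mod(crossprod(k$coef, ff[k$idx, , drop = FALSE]))
    }
  }
  times <- (starts - 1L + kk$nfft / 2) / rate(sig)
  Spectrogram(vals, kk$freqs, times, scale = "log")
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the complex analytic signal, computed by one-sided spectrum
#' doubling in the frequency domain. The envelope of a constant-amplitude
#' sinusoid is (away from the edges) its amplitude.
#'
#' @param sig An [AudioSignal-class].
#' @return An [Envelope-class] of the same length and rate.
#' @export
amplitudeEnvelope <- function(sig) {
  stopifnot(is(sig, "AudioSignal"))
  x <- samples(sig)
  n <- length(x)
  if (n == 1L) return(Envelope(abs(x), rate(sig)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n %/% 2L + 1L] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  Envelope(Mod(analytic), rate(sig))
}

#' Mean spectrum of a spectrogram
#'
#' Per-bin mean magnitude over time frames — the "mean spectrum" profile on
#' which spectral entropy and the Bioacoustic Index are computed.
#'
#' @param spec A [Spectrogram-class].
#' @return A [SpectrumProfile-class].
#' @export
meanSpectrum <- function(spec) {
  stopifnot(is(spec, "Spectrogram"))
  SpectrumProfile(rowMeans(specValues(spec)), specFreqs(spec))
}

#' Export a Spectrogram as CSV
#'
#' Layout: header row `freq_hz` followed by the frame times; each subsequent
#' row is a bin frequency followed by that bin's magnitudes.
#'
#' @param spec A [Spectrogram-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSpectrogramCSV <- function(spec, path) {
  stopifnot(is(spec, "Spectrogram"))
  m <- cbind(specFreqs(spec), specValues(spec))
  colnames(m) <- c("freq_hz", format(specTimes(spec), trim = TRUE))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a Spectrogram from CSV written by [writeSpectrogramCSV()]
#'
#' @param path CSV path.
#' @param scale Frequency scale to record (`"linear"` or `"log"`).
#' @return A [Spectrogram-class].
#' @export
readSpectrogramCSV <- function(path, scale = "linear") {
  m <- utils::read.csv(path, check.names = FALSE)
  freqs <- m[[1L]]
  vals <- as.matrix(m[, -1L, drop = FALSE])
  times <- as.numeric(colnames(vals))
  dimnames(vals) <- NULL
  Spectrogram(vals, freqs, times, scale = scale)
}
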