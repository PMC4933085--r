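## Community-level acoustic indices. Each index summarises one recording; the
## shared building blocks are the Shannon entropy of a discrete distribution
## and the Gini evenness coefficient, applied to spectral or temporal energy
## distributions.

#' Shannon entropy of a discrete distribution
#'
#' `H' = -sum(p_i * ln p_i)` with `0 * ln 0 := 0`, the diversity measure
#' ecologists apply to species proportions, here applied to acoustic energy
#' distributions. Weights are normalized to sum to 1 first. With
#' `normalized = TRUE` the result is divided by `ln(R)` so it lies in [0, 1];
#' for a single category (`R = 1`) the normalized entropy is 0 by convention.
#'
#' @param p Non-negative weights (need not sum to 1).
#' @param normalized Divide by `ln(length(p))`? Default `FALSE`.
#' @return A scalar entropy in nats, or in [0, 1] if normalized.
#' @examples
#' shannonEntropy(rep(1, 10))            # ln 10
#' shannonEntropy(c(0.5, 0.25, 0.25))    # 1.5 ln 2
#' @export
shannonEntropy <- function(p, normalized = FALSE) {
  p <- asDistribution(p, "entropy weights")
  H <- entropyNats(p)
  if (normalized) {
    if (length(p) == 1L) return(0)
    H <- H / log(length(p))
  }
  H
}

#' Gini evenness coefficient
#'
#' `G = sum_ij |p_i - p_j| / (2 n sum(p))`, the mean absolute difference
#' between all pairs of weights relative to their mean — 0 for perfectly even
#' weights, approaching `1 - 1/n` when all mass sits in one category.
#' Computed via the sorted-weights identity (O(n log n)).
#'
#' @param p Non-negative weights, not all zero.
#' @return A scalar in `[0, 1 - 1/n]`.
#' @examples
#' gini(rep(1, 10))                      # 0
#' gini(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0)) # 0.9
#' @export
gini <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("'p' must be finite and non-negative", call. = FALSE)
  n <- length(p)
  s <- sum(p)
  if (n < 1L || s <= 0)
    stop("'p' must contain at least one positive weight", call. = FALSE)
  x <- sort(p)
  (2 * sum(seq_len(n) * x) - (n + 1) * s) / (n * s)
}

#' Spectral entropy sh
#'
#' Normalized Shannon entropy of the mean spectrum treated as a probability
#' distribution over frequency bins: 0 for a pure tone (all mass in one bin),
#' 1 for a flat spectrum.
#'
#' @param prof A [SpectrumProfile-class] with positive total power.
#' @return A scalar in [0, 1].
#' @export
spectralEntropy <- function(prof) {
  stopifnot(is(prof, "SpectrumProfile"))
  if (sum(prof@power) <= 0)
    stop("all-zero spectrum: spectral entropy undefined", call. = FALSE)
  shannonEntropy(prof@power, normalized = TRUE)
}

#' Temporal entropy th
#'
#' Normalized Shannon entropy of the Hilbert amplitude envelope treated as a
#' probability distribution over time samples: 0 for a single click, 1 for a
#' constant envelope.
#'
#' @param env An [Envelope-class] with positive total amplitude.
#' @return A scalar in [0, 1].
#' @export
temporalEntropy <- function(env) {
  stopifnot(is(env, "Envelope"))
  if (sum(env@values) <= 0)
    stop("all-zero envelope: temporal entropy undefined", call. = FALSE)
  shannonEntropy(env@values, normalized = TRUE)
}

#' Acoustic entropy H = sh x th
#'
#' The total acoustic entropy index: the product of the spectral entropy of
#' the mean spectrum and the temporal entropy of the Hilbert amplitude
#' envelope. Ranges from 0 for a pure tone to 1 for high-energy, evenly
#' distributed sound.
#'
#' @param sig An [AudioSignal-class], long enough for one STFT frame.
#' @param winLen,hop,window STFT parameters (see [stftSpectrogram()]).
#' @return A list with `sh`, `th` and `h`.
#' @examples
#' tone <- AudioSignal(sin(2 * pi * 86 * (8000/512) * (0:15999) / 8000), 8000)
#' acousticEntropy(tone, window = "rectangular")$h   # ~0
#' @export
acousticEntropy <- function(sig, winLen = 512L, hop = winLen %/% 2L,
                            window = "hann") {
  stopifnot(is(sig, "AudioSignal"))
  if (all(samples(sig) == 0))
    stop("silent signal: acoustic entropy undefined", call. = FALSE)
  sh <- spectralEntropy(meanSpectrum(stftSpectrogram(sig, winLen, hop, window)))
  th <- temporalEntropy(amplitudeEnvelope(sig))
  list(sh = sh, th = th, h = sh * th)
}

#' Frequency band split for NDSI
#'
#' Frequency band edges (Hz) delimiting anthropophony (human-generated,
#' conventionally 0.2-2 kHz) and biophony (biological, conventionally
#' 2-8 kHz). The assumption is habitat-dependent, so the edges are
#' configurable.
#'
#' @param anthroLo,anthroHi,bioLo,bioHi Band edges in Hz with
#'   `anthroLo < anthroHi <= bioLo < bioHi`.
#' @return A classed list of the four edges.
#' @export
bandSplit <- function(anthroLo = 200, anthroHi = 2000,
                      bioLo = 2000, bioHi = 8000) {
  if (!(anthroLo < anthroHi && anthroHi <= bioLo && bioLo < bioHi))
    stop("band edges must satisfy anthroLo < anthroHi <= bioLo < bioHi",
         call. = FALSE)
  structure(list(anthroLo = anthroLo, anthroHi = anthroHi,
                 bioLo = bioLo, bioHi = bioHi), class = "bandSplit")
}

## Integrate mean power over [lo, hi) of the frequency axis.
bandPower <- function(power, freqs, lo, hi) {
  sum(power[freqs >= lo & freqs < hi])
}

#' Normalized Difference Soundscape Index (NDSI)
#'
#' `(biophony - anthropophony) / (biophony + anthropophony)` where each term
#' is the mean STFT power integrated over its frequency band. +1 means all
#' in-band energy is biophony, -1 all anthropophony.
#'
#' @param sig An [AudioSignal-class].
#' @param bands A [bandSplit()]; edges must lie below Nyquist.
#' @param winLen,hop,window STFT parameters.
#' @return A scalar in [-1, 1].
#' @export
ndsi <- function(sig, bands = bandSplit(), winLen = 512L,
                 hop = winLen %/% 2L, window = "hann") {
  stopifnot(is(sig, "AudioSignal"), inherits(bands, "bandSplit"))
  if (bands$bioHi > rate(sig) / 2)
    stop("band edges must lie below Nyquist", call. = FALSE)
  sp <- stftSpectrogram(sig, winLen, hop, window)
  pw <- rowMeans(specValues(sp)^2)       # Welch-style mean power spectrum
  f <- specFreqs(sp)
  anthro <- bandPower(pw, f, bands$anthroLo, bands$anthroHi)
  bio <- bandPower(pw, f, bands$bioLo, bands$bioHi)
  if (anthro + bio <= 0)
    stop("no power in either NDSI band: index undefined", call. = FALSE)
  (bio - anthro) / (bio + anthro)
}

#' Occupancy proportions across frequency bands
#'
#' Splits the spectrogram's frequency range into `nBands` equal bands and
#' computes, per band, the proportion of time-frequency cells whose level
#' exceeds `thresholdDb` (dB re full scale; in-range audio is <= 0 dBFS, so
#' the conventional threshold is -50). The per-band proportions are then
#' renormalized to a probability distribution — the `p_i` of the acoustic
#' diversity/evenness indices.
#'
#' @param spec A [Spectrogram-class] with at least `nBands` frequency rows.
#' @param nBands Number of bands; default 10.
#' @param thresholdDb Occupancy threshold in dBFS; default -50.
#' @param fmax Upper edge of the banded range (Hz); defaults to the top of the
#'   spectrogram's frequency axis.
#' @return A list with `p` (the normalized distribution) and `proportions`
#'   (raw per-band occupancy in [0, 1]).
#' @export
bandProportions <- function(spec, nBands = 10L, thresholdDb = -50, fmax = NULL) {
  stopifnot(is(spec, "Spectrogram"))
  nBands <- as.integer(nBands)
  f <- specFreqs(spec)
  if (is.null(fmax)) fmax <- max(f)
  keep <- f <= fmax
  if (sum(keep) < nBands)
    stop("spectrogram must span at least 'nBands' frequency rows", call. = FALSE)
  v <- specValues(spec)[keep, , drop = FALSE]
  f <- f[keep]
  edges <- seq(min(f), fmax, length.out = nBands + 1L)
  band <- pmin(pmax(findInterval(f, edges, rightmost.closed = TRUE), 1L), nBands)
  db <- ifelse(v > 0, 20 * log10(v), -Inf)
  above <- db > thresholdDb
  prop <- vapply(seq_len(nBands), function(b) {
    rows <- band == b
    if (!any(rows)) 0 else mean(above[rows, , drop = FALSE])
  }, numeric(1))
  if (sum(prop) <= 0)
    stop("no cell above threshold in any band: occupancy undefined",
         call. = FALSE)
  list(p = prop / sum(prop), proportions = prop)
}

#' Acoustic Diversity Index (ADI)
#'
#' Unnormalized Shannon entropy of the band occupancy distribution from
#' [bandProportions()]: 0 when a single band is occupied, `ln(nBands)` when
#' occupancy is uniform.
#'
#' @inheritParams bandProportions
#' @return A scalar in `[0, ln(nBands)]`.
#' @export
adi <- function(spec, nBands = 10L, thresholdDb = -50, fmax = NULL) {
  bp <- bandProportions(spec, nBands, thresholdDb, fmax)
  shannonEntropy(bp$p, normalized = FALSE)
}

#' Acoustic Evenness Index (AEI)
#'
#' Gini coefficient of the band occupancy proportions from
#' [bandProportions()]: 0 for perfectly even occupancy, near 1 when all
#' occupancy concentrates in one band.
#'
#' @inheritParams bandProportions
#' @return A scalar in `[0, 1 - 1/nBands]`.
#' @export
aei <- function(spec, nBands = 10L, thresholdDb = -50, fmax = NULL) {
  bp <- bandProportions(spec, nBands, thresholdDb, fmax)
  gini(bp$proportions)
}

#' Acoustic Complexity Index (ACI)
#'
#' Per frequency bin and per temporal clump, the sum of absolute differences
#' between adjacent frames divided by the total intensity in the clump,
#' summed over bins and clumps. Sensitive to intensity modulation (typical of
#' biotic sound) and by construction minimal for constant-intensity sound;
#' invariant to global amplitude scaling. Bins with zero energy in a clump
#' contribute 0.
#'
#' @param spec A [Spectrogram-class].
#' @param clumpSeconds Length of the temporal clumps (s); default 5. `Inf`
#'   treats the whole spectrogram as one clump. A trailing clump with fewer
#'   than two frames is merged into its predecessor.
#' @return A non-negative scalar.
#' @export
aci <- function(spec, clumpSeconds = 5) {
  stopifnot(is(spec, "Spectrogram"))
  v <- specValues(spec)
  tt <- specTimes(spec)
  if (ncol(v) < 2L) stop("ACI needs at least two frames", call. = FALSE)
  if (all(v == 0)) stop("silent spectrogram: ACI undefined", call. = FALSE)
  if (is.finite(clumpSeconds)) {
    idx <- floor((tt - tt[1L]) / clumpSeconds)
  } else idx <- rep(0L, length(tt))
  ## merge a trailing clump of < 2 frames into its predecessor
  tab <- table(idx)
  if (length(tab) > 1L && utils::tail(tab, 1L) < 2L)
    idx[idx == max(idx)] <- max(idx) - 1L
  total <- 0
  for (g in unique(idx)) {
    m <- v[, idx == g, drop = FALSE]
    if (ncol(m) < 2L) next
    num <- rowSums(abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]))
    den <- rowSums(m)
    ok <- den > 0
    total <- total + sum(num[ok] / den[ok])
  }
  total
}

#' Bioacoustic Index (BI)
#'
#' Area under the mean dB spectrum within the biophony band after subtracting
#' the band minimum (so flat spectra and global gain changes give 0
#' contribution). Integration is trapezoidal over frequency expressed in kHz.
#'
#' @param sig An [AudioSignal-class].
#' @param bandLo,bandHi Integration band in Hz; default 2000-8000.
#' @param winLen,hop,window STFT parameters.
#' @return A non-negative scalar (dB x kHz).
#' @export
bioacousticIndex <- function(sig, bandLo = 2000, bandHi = 8000,
                             winLen = 512L, hop = winLen %/% 2L,
                             window = "hann") {
  stopifnot(is(sig, "AudioSignal"))
  if (bandHi > rate(sig) / 2)
    stop("integration band must lie below Nyquist", call. = FALSE)
  prof <- meanSpectrum(stftSpectrogram(sig, winLen, hop, window))
  keep <- prof@freqs >= bandLo & prof@freqs <= bandHi
  p <- prof@power[keep]
  f <- prof@freqs[keep]
  if (length(p) < 2L || max(p) <= 0)
    stop("no energy in the integration band: BI undefined", call. = FALSE)
  p <- pmax(p, max(p) * 1e-6)            # floor silent bins 120 dB down
  db <- 20 * log10(p)
  trapezoid(f / 1000, db - min(db))
}

#' Configuration for an index report
#'
#' Bundles every tunable of [computeIndexReport()] with its default. All
#' defaults are recorded in the report so no parameter is ever implicit.
#'
#' @param winLen,hop,window STFT parameters shared by all spectral indices.
#' @param highpassHz Optional high-pass cutoff applied before analysis
#'   (`NULL` = none).
#' @param highpassSlope High-pass slope in dB/octave.
#' @param bands A [bandSplit()] for NDSI.
#' @param adiBands,adiThresholdDb,adiFmax ADI/AEI banding parameters.
#' @param aciClumpSeconds ACI temporal clump length (s).
#' @param biBandLo,biBandHi BI integration band (Hz).
#' @return A named list of parameters.
#' @export
indexConfig <- function(winLen = 512L, hop = 256L, window = "hann",
                        highpassHz = NULL, highpassSlope = 12,
                        bands = bandSplit(),
                        adiBands = 10L, adiThresholdDb = -50, adiFmax = 10000,
                        aciClumpSeconds = 5,
                        biBandLo = 2000, biBandHi = 8000) {
  list(winLen = as.integer(winLen), hop = as.integer(hop), window = window,
       highpassHz = highpassHz, highpassSlope = highpassSlope, bands = bands,
       adiBands = as.integer(adiBands), adiThresholdDb = adiThresholdDb,
       adiFmax = adiFmax, aciClumpSeconds = aciClumpSeconds,
       biBandLo = biBandLo, biBandHi = biBandHi)
}

#' Compute all six acoustic indices for one recording
#'
#' One shared preprocessing chain (optional high-pass, one STFT, one Hilbert
#' envelope) feeds NDSI, ADI, AEI, acoustic entropy (sh, th, H = sh x th),
#' ACI and the Bioacoustic Index. An index whose input is degenerate (e.g.
#' silence) is reported as `NA` with the reason recorded, rather than
#' aborting the report.
#'
#' @param sig An [AudioSignal-class] of at least one second.
#' @param config An [indexConfig()].
#' @return An [IndexReport-class].
#' @examples
#' set.seed(1)
#' noise <- AudioSignal(stats::rnorm(44100) * 0.2, 44100)
#' computeIndexReport(noise)
#' @export
computeIndexReport <- function(sig, config = indexConfig()) {
  stopifnot(is(sig, "AudioSignal"))
  if (duration(sig) < 1)
    stop("recording must be at least one second long", call. = FALSE)
  if (!is.null(config$highpassHz))
    sig <- highpassFilter(sig, config$highpassHz, config$highpassSlope)

  vals <- stats::setNames(rep(NA_real_, length(indexNames)), indexNames)
  errs <- stats::setNames(rep("", length(indexNames)), indexNames)
  grab <- function(name, expr) {
    tryCatch(vals[[name]] <<- expr,
             error = function(e) errs[[name]] <<- conditionMessage(e))
  }

  sp <- tryCatch(
    stftSpectrogram(sig, config$winLen, config$hop, config$window),
    error = function(e) e)
  if (inherits(sp, "error")) {
    msg <- conditionMessage(sp)
    errs[] <- msg
    return(new("IndexReport", values = vals, errors = errs,
               parameters = config))
  }

  grab("ndsi", ndsi(sig, config$bands, config$winLen, config$hop,
                    config$window))
  grab("adi", adi(sp, config$adiBands, config$adiThresholdDb, config$adiFmax))
  grab("aei", aei(sp, config$adiBands, config$adiThresholdDb, config$adiFmax))
  grab("sh", spectralEntropy(meanSpectrum(sp)))
  grab("th", temporalEntropy(amplitudeEnvelope(sig)))
  if (is.finite(vals[["sh"]]) && is.finite(vals[["th"]])) {
    vals[["h"]] <- vals[["sh"]] * vals[["th"]]
  } else errs[["h"]] <- "sh or th undefined"
  grab("aci", aci(sp, config$aciClumpSeconds))
  grab("bi", bioacousticIndex(sig, config$biBandLo, config$biBandHi,
                              config$winLen, config$hop, config$window))

  new("IndexReport", values = vals, errors = errs, parameters = config)
}
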