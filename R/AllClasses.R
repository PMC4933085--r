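#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core audio containers
## ---------------------------------------------------------------------------

#' AudioSignal: a sampled, single-channel waveform
#'
#' Container for a mono waveform with its sampling rate. Samples are
#' real-valued and expected to lie in [-1, 1] (digital full scale); stereo
#' material is mixed down on read. Construct with [AudioSignal()] or
#' [readAudio()].
#'
#' @slot samples Numeric vector of samples.
#' @slot rate Sampling rate in Hz.
#' @export
setClass("AudioSignal", representation(samples = "numeric", rate = "numeric"))

setValidity("AudioSignal", function(object) {
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("'rate' must be a single positive number (Hz)")
  if (length(object@samples) < 1L)
    return("signal must contain at least one sample")
  if (any(!is.finite(object@samples)))
    return("samples must be finite")
  TRUE
})

#' @param samples Numeric vector of samples in [-1, 1].
#' @param rate Sampling rate in Hz.
#' @rdname AudioSignal-class
#' @export
AudioSignal <- function(samples, rate) {
  new("AudioSignal", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' Spectrogram: a non-negative time-frequency magnitude matrix
#'
#' Magnitude (not power) values arranged frequency bins x time frames, with
#' per-bin centre frequencies and per-frame centre times. `scale` records
#' whether the frequency axis is linear (STFT) or logarithmic (constant-Q).
#'
#' @slot values Non-negative matrix, `length(freqs)` rows x `length(times)` cols.
#' @slot freqs Ascending bin centre frequencies (Hz).
#' @slot times Ascending frame centre times (s).
#' @slot scale `"linear"` or `"log"`.
#' @export
setClass("Spectrogram",
  representation(values = "matrix", freqs = "numeric", times = "numeric",
                 scale = "character"))

setValidity("Spectrogram", function(object) {
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0))
    return("spectrogram values must be finite and non-negative")
  if (nrow(v) != length(object@freqs) || ncol(v) != length(object@times))
    return("dim(values) must equal (length(freqs), length(times))")
  if (length(object@freqs) > 1L && any(diff(object@freqs) <= 0))
    return("'freqs' must be strictly increasing")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("'times' must be strictly increasing")
  if (!object@scale %in% c("linear", "log"))
    return("'scale' must be \"linear\" or \"log\"")
  TRUE
})

#' @param values,freqs,times,scale See slots.
#' @rdname Spectrogram-class
#' @export
Spectrogram <- function(values, freqs, times, scale = "linear") {
  new("Spectrogram", values = values, freqs = as.numeric(freqs),
      times = as.numeric(times), scale = scale)
}

#' Envelope: a non-negative amplitude envelope
#'
#' @slot values Non-negative amplitude sequence.
#' @slot rate Sampling rate of the envelope (Hz).
#' @export
setClass("Envelope", representation(values = "numeric", rate = "numeric"))

setValidity("Envelope", function(object) {
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("envelope values must be finite and non-negative")
  if (length(object@rate) != 1L || object@rate <= 0)
    return("'rate' must be a single positive number")
  TRUE
})

#' @param values,rate See slots.
#' @rdname Envelope-class
#' @export
Envelope <- function(values, rate) {
  new("Envelope", values = as.numeric(values), rate = as.numeric(rate))
}

#' SpectrumProfile: a mean (marginal) spectrum
#'
#' Per-bin mean magnitude over the frames of a spectrogram, as plotted in a
#' mean-spectrum panel.
#'
#' @slot power Non-negative per-bin mean magnitude.
#' @slot freqs Bin centre frequencies (Hz).
#' @export
setClass("SpectrumProfile", representation(power = "numeric", freqs = "numeric"))

setValidity("SpectrumProfile", function(object) {
  if (length(object@power) != length(object@freqs))
    return("'power' and 'freqs' must have equal length")
  if (any(!is.finite(object@power)) || any(object@power < 0))
    return("'power' must be finite and non-negative")
  TRUE
})

#' @param power,freqs See slots.
#' @rdname SpectrumProfile-class
#' @export
SpectrumProfile <- function(power, freqs) {
  new("SpectrumProfile", power = as.numeric(power), freqs = as.numeric(freqs))
}

## ---------------------------------------------------------------------------
## Index reporting
## ---------------------------------------------------------------------------

#' IndexReport: the six community-level acoustic indices for one recording
#'
#' Holds NDSI, ADI, AEI, spectral entropy (sh), temporal entropy (th), total
#' acoustic entropy H = sh x th, ACI and the Bioacoustic Index, together with
#' the full parameter set used to compute them. Indices whose input was
#' degenerate (e.g. digital silence) are `NA` with the reason recorded in
#' `errors`.
#'
#' @slot values Named numeric: ndsi, adi, aei, sh, th, h, aci, bi.
#' @slot errors Named character: per-index failure messages (empty if clean).
#' @slot parameters List: the full configuration used.
#' @export
setClass("IndexReport",
  representation(values = "numeric", errors = "character", parameters = "list"))

indexNames <- c("ndsi", "adi", "aei", "sh", "th", "h", "aci", "bi")

setValidity("IndexReport", function(object) {
  if (!identical(names(object@values), indexNames))
    return(paste("'values' must be named:", paste(indexNames, collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## Sparse dictionary coding
## ---------------------------------------------------------------------------

#' PatchSet: equally-shaped 2D patches tiled from a spectrogram
#'
#' @slot patches List of non-negative matrices, all of `patchShape`.
#' @slot origins Integer matrix (n x 2): 1-based (freq row, time col) origin of
#'   each patch in the source.
#' @slot patchShape Integer length-2: (rows, cols).
#' @slot sourceDim Integer length-2: dimensions of the source matrix.
#' @export
setClass("PatchSet",
  representation(patches = "list", origins = "matrix",
                 patchShape = "integer", sourceDim = "integer"))

setValidity("PatchSet", function(object) {
  ps <- object@patchShape
  if (!all(vapply(object@patches, function(p) identical(dim(p), as.integer(ps)),
                  logical(1))))
    return("all patches must share 'patchShape'")
  if (nrow(object@origins) != length(object@patches))
    return("one origin row per patch required")
  if (length(object@patches) &&
      (any(object@origins < 1L) ||
       any(object@origins[, 1] + ps[1] - 1L > object@sourceDim[1]) ||
       any(object@origins[, 2] + ps[2] - 1L > object@sourceDim[2])))
    return("patch origins must lie within the source bounds")
  TRUE
})

#' Dictionary: unit-norm 2D atoms for sparse approximation
#'
#' @slot atoms List of matrices, all of `patchShape`, each with unit L2 norm.
#' @slot patchShape Integer length-2.
#' @slot kind `"learned"` or `"gabor"`.
#' @export
setClass("Dictionary",
  representation(atoms = "list", patchShape = "integer", kind = "character"))

setValidity("Dictionary", function(object) {
  if (!length(object@atoms)) return("dictionary must contain at least one atom")
  if (!all(vapply(object@atoms,
                  function(a) identical(dim(a), object@patchShape), logical(1))))
    return("all atoms must share 'patchShape'")
  nrm <- vapply(object@atoms, function(a) sqrt(sum(a^2)), numeric(1))
  if (any(abs(nrm - 1) > 1e-6))
    return("every atom must have unit L2 norm")
  if (!object@kind %in% c("learned", "gabor"))
    return("'kind' must be \"learned\" or \"gabor\"")
  TRUE
})

#' SparseCode: per-patch OMP codes
#'
#' @slot entries List; entry i is `list(atoms = <int>, coefs = <num>)` for patch i.
#' @slot residualNorms Final residual L2 norm per patch.
#' @slot sparsity The sparsity budget s used.
#' @export
setClass("SparseCode",
  representation(entries = "list", residualNorms = "numeric",
                 sparsity = "integer"))

## ---------------------------------------------------------------------------
## Latent component models
## ---------------------------------------------------------------------------

#' PLCAModel: probabilistic latent component analysis of a normalized matrix
#'
#' The factorization V ~ W Z H: `W` holds K column distributions over
#' frequency (each column sums to 1), `H` holds K row distributions over time
#' (each row sums to 1) and `z` the mixing weights (summing to 1).
#'
#' @slot W Matrix F x K.
#' @slot H Matrix K x T.
#' @slot z Numeric length K.
#' @slot objective KL divergence trace, one value per EM iteration.
#' @slot seed The RNG seed used for initialization.
#' @export
setClass("PLCAModel",
  representation(W = "matrix", H = "matrix", z = "numeric",
                 objective = "numeric", seed = "numeric"))

setValidity("PLCAModel", function(object) {
  K <- length(object@z)
  if (ncol(object@W) != K || nrow(object@H) != K)
    return("W, H, z disagree on the number of components")
  if (any(object@W < 0) || any(object@H < 0) || any(object@z < 0))
    return("all factors must be non-negative")
  if (abs(sum(object@z) - 1) > 1e-6) return("z must sum to 1")
  if (any(abs(colSums(object@W) - 1) > 1e-6))
    return("each column of W must sum to 1")
  if (any(abs(rowSums(object@H) - 1) > 1e-6))
    return("each row of H must sum to 1")
  TRUE
})

#' SIPLCA2DModel: shift-invariant 2D latent component model
#'
#' Each component k is a 2D time-frequency kernel (a recurring spectro-temporal
#' patch, summing to 1) placed across the input by a 2D activation map over
#' (frequency shift x time, summing to 1), mixed by weight `z[k]`. The model
#' reconstruction is `sum_k z_k (kernel_k * activation_k)` (full 2D
#' convolution), which matches the normalized input in shape and total mass.
#'
#' @slot kernels List of K non-negative matrices (kernelShape), each summing to 1.
#' @slot activations List of K non-negative matrices (shiftSpan x timeSpan),
#'   each summing to 1.
#' @slot z Mixing weights, summing to 1, in descending order.
#' @slot kMax The component budget the model was fitted with.
#' @slot alpha Sparsity hyper-parameter (1 = no prior; < 1 sparser).
#' @slot kernelShape Integer length-2.
#' @slot vDim Integer length-2: dimensions of the fitted matrix V.
#' @slot objective Penalized-KL trace, one value per EM iteration.
#' @slot seed RNG seed used for initialization.
#' @export
setClass("SIPLCA2DModel",
  representation(kernels = "list", activations = "list", z = "numeric",
                 kMax = "integer", alpha = "numeric", kernelShape = "integer",
                 vDim = "integer", objective = "numeric", seed = "numeric"))

setValidity("SIPLCA2DModel", function(object) {
  K <- length(object@z)
  if (length(object@kernels) != K || length(object@activations) != K)
    return("kernels, activations and z disagree on the component count")
  if (K > object@kMax) return("more components than kMax")
  okW <- vapply(object@kernels,
                function(w) all(w >= 0) && abs(sum(w) - 1) < 1e-6, logical(1))
  okH <- vapply(object@activations,
                function(h) all(h >= 0) && abs(sum(h) - 1) < 1e-6, logical(1))
  if (!all(okW)) return("every kernel must be non-negative and sum to 1")
  if (!all(okH)) return("every activation must be non-negative and sum to 1")
  if (abs(sum(object@z) - 1) > 1e-6) return("z must sum to 1")
  if (is.unsorted(rev(object@z))) return("components must be ordered by descending z")
  TRUE
})

## ---------------------------------------------------------------------------
## Accessors & show methods
## ---------------------------------------------------------------------------

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setGeneric("rate", function(x) standardGeneric("rate"))
#' @describeIn AudioSignal-class The raw sample vector.
#' @export
setMethod("samples", "AudioSignal", function(x) x@samples)
#' @describeIn AudioSignal-class Sampling rate in Hz.
#' @export
setMethod("rate", "AudioSignal", function(x) x@rate)
#' @describeIn Envelope-class Envelope values.
#' @export
setMethod("samples", "Envelope", function(x) x@values)
#' @describeIn Envelope-class Envelope rate (Hz).
#' @export
setMethod("rate", "Envelope", function(x) x@rate)

#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @describeIn AudioSignal-class Duration in seconds.
#' @export
setMethod("duration", "AudioSignal", function(x) length(x@samples) / x@rate)

#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))
#' @export
setGeneric("specFreqs", function(x) standardGeneric("specFreqs"))
#' @export
setGeneric("specTimes", function(x) standardGeneric("specTimes"))
#' @describeIn Spectrogram-class The magnitude matrix.
#' @export
setMethod("specValues", "Spectrogram", function(x) x@values)
#' @describeIn Spectrogram-class Bin centre frequencies (Hz).
#' @export
setMethod("specFreqs", "Spectrogram", function(x) x@freqs)
#' @describeIn Spectrogram-class Frame centre times (s).
#' @export
setMethod("specTimes", "Spectrogram", function(x) x@times)

#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))
#' @describeIn IndexReport-class Named numeric vector of the eight values.
#' @export
setMethod("indexValues", "IndexReport", function(x) x@values)
#' @export
setGeneric("indexErrors", function(x) standardGeneric("indexErrors"))
#' @describeIn IndexReport-class Per-index failure messages.
#' @export
setMethod("indexErrors", "IndexReport", function(x) x@errors)
#' @export
setGeneric("reportParameters", function(x) standardGeneric("reportParameters"))
#' @describeIn IndexReport-class The configuration used.
#' @export
setMethod("reportParameters", "IndexReport", function(x) x@parameters)

#' Coerce an IndexReport to a one-row data.frame
#'
#' Columns follow the conventional reporting order: ndsi, adi, aei, sh, th, h,
#' aci, bi.
#'
#' @param x An `IndexReport`.
#' @param row.names,optional,... Passed for generic compatibility; ignored.
#' @export
as.data.frame.IndexReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  as.data.frame(as.list(x@values))
}

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @describeIn Dictionary-class The list of unit-norm atoms.
#' @export
setMethod("atoms", "Dictionary", function(x) x@atoms)
#' @export
setGeneric("patchShape", function(x) standardGeneric("patchShape"))
#' @describeIn Dictionary-class Atom shape (rows, cols).
#' @export
setMethod("patchShape", "Dictionary", function(x) x@patchShape)
#' @describeIn PatchSet-class Patch shape (rows, cols).
#' @export
setMethod("patchShape", "PatchSet", function(x) x@patchShape)
#' @export
setGeneric("patches", function(x) standardGeneric("patches"))
#' @describeIn PatchSet-class The list of patches.
#' @export
setMethod("patches", "PatchSet", function(x) x@patches)

#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))
#' @describeIn PLCAModel-class Mixing weights z.
#' @export
setMethod("mixingWeights", "PLCAModel", function(x) x@z)
#' @describeIn SIPLCA2DModel-class Mixing weights z (descending).
#' @export
setMethod("mixingWeights", "SIPLCA2DModel", function(x) x@z)
#' @export
setGeneric("kernels", function(x) standardGeneric("kernels"))
#' @describeIn SIPLCA2DModel-class The K time-frequency kernels.
#' @export
setMethod("kernels", "SIPLCA2DModel", function(x) x@kernels)
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))
#' @describeIn SIPLCA2DModel-class The K shift-time activation maps.
#' @export
setMethod("activations", "SIPLCA2DModel", function(x) x@activations)
#' @export
setGeneric("kEffective", function(x) standardGeneric("kEffective"))
#' @describeIn SIPLCA2DModel-class Number of retained components.
#' @export
setMethod("kEffective", "SIPLCA2DModel", function(x) length(x@z))
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @describeIn PLCAModel-class KL objective per EM iteration.
#' @export
setMethod("objectiveTrace", "PLCAModel", function(x) x@objective)
#' @describeIn SIPLCA2DModel-class Penalized KL per EM iteration.
#' @export
setMethod("objectiveTrace", "SIPLCA2DModel", function(x) x@objective)

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf("AudioSignal: %d samples @ %g Hz (%.3f s), range [%.3g, %.3g]\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate,
              min(object@samples), max(object@samples)))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram (%s frequency): %d bins x %d frames, %.1f-%.1f Hz, %.3f-%.3f s\n",
    object@scale, nrow(object@values), ncol(object@values),
    min(object@freqs), max(object@freqs), min(object@times), max(object@times)))
})

setMethod("show", "Envelope", function(object) {
  cat(sprintf("Envelope: %d samples @ %g Hz, peak %.3g\n",
              length(object@values), object@rate, max(object@values)))
})

setMethod("show", "SpectrumProfile", function(object) {
  cat(sprintf("SpectrumProfile: %d bins, %.1f-%.1f Hz\n",
              length(object@freqs), min(object@freqs), max(object@freqs)))
})

setMethod("show", "IndexReport", function(object) {
  cat("IndexReport\n")
  print(round(object@values, 4))
  bad <- names(object@errors)[nzchar(object@errors)]
  if (length(bad))
    cat("undefined:", paste(bad, collapse = ", "), "\n")
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %d x %d from a %d x %d matrix\n",
              length(object@patches), object@patchShape[1], object@patchShape[2],
              object@sourceDim[1], object@sourceDim[2]))
})

setMethod("show", "Dictionary", function(object) {
  cat(sprintf("Dictionary (%s): %d atoms of %d x %d%s\n", object@kind,
              length(object@atoms), object@patchShape[1], object@patchShape[2],
              if (length(object@atoms) >= prod(object@patchShape))
                " (overcomplete)" else ""))
})

setMethod("show", "SparseCode", function(object) {
  cat(sprintf("SparseCode: %d patches, sparsity <= %d, mean residual %.4g\n",
              length(object@entries), object@sparsity,
              mean(object@residualNorms)))
})

setMethod("show", "PLCAModel", function(object) {
  cat(sprintf("PLCAModel: K = %d, final KL = %.6g (%d EM iterations)\n",
              length(object@z), utils::tail(object@objective, 1),
              length(object@objective)))
  cat("z:", paste(signif(object@z, 4), collapse = " "), "\n")
})

setMethod("show", "SIPLCA2DModel", function(object) {
  cat(sprintf(
    "SIPLCA2DModel: k = %d of kMax = %d, kernel %d x %d, alpha = %g\n",
    length(object@z), object@kMax, object@kernelShape[1], object@kernelShape[2],
    object@alpha))
  cat(sprintf("final penalized KL = %.6g (%d EM iterations)\n",
              utils::tail(object@objective, 1), length(object@objective)))
  cat("z:", paste(signif(object@z, 4), collapse = " "), "\n")
})
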