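## Synthetic soundscape generator: dawn choruses with known species richness,
## call timing, frequency niches and noise floor, plus generative
## shift-invariant factor matrices with known kernels/activations/weights.
## This is the test bed standing in for field recordings: every downstream
## behaviour can be measured against ground truth.

#' Specification of one species' call
#'
#' A band-limited harmonic stack with sinusoidal frequency modulation and an
#' attack/decay amplitude envelope — the stylized songbird call unit.
#' Harmonic h has amplitude 1/h.
#'
#' @param f0 Fundamental frequency (Hz).
#' @param nHarmonics Number of harmonics (>= 1); default 2.
#' @param fmDepth FM depth (Hz); default 0 (no modulation).
#' @param fmRate FM rate (Hz); default 4.
#' @param duration Call length (s); default 0.5.
#' @param attack,decay Attack / decay fractions of the duration (linear
#'   ramps); defaults 0.15 / 0.3.
#' @param level Linear gain; default 1.
#' @return A classed list (`CallSpec`).
#' @export
callSpec <- function(f0, nHarmonics = 2L, fmDepth = 0, fmRate = 4,
                     duration = 0.5, attack = 0.15, decay = 0.3, level = 1) {
  stopifnot(isScalar(f0), f0 > 0, isScalar(duration), duration > 0,
            nHarmonics >= 1L, fmDepth >= 0, fmRate >= 0, level > 0,
            attack >= 0, decay >= 0, attack + decay <= 1)
  structure(list(f0 = f0, nHarmonics = as.integer(nHarmonics),
                 fmDepth = fmDepth, fmRate = fmRate, duration = duration,
                 attack = attack, decay = decay, level = level),
            class = "CallSpec")
}

#' Render one call to audio
#'
#' Deterministic synthesis of the harmonic FM stack described by a
#' [callSpec()], at the given rate. Errors if the highest instantaneous
#' harmonic frequency would alias.
#'
#' @param spec A [callSpec()].
#' @param rate Sampling rate (Hz).
#' @return An [AudioSignal-class] of `duration * rate` samples.
#' @export
makeCall <- function(spec, rate = 44100) {
  stopifnot(inherits(spec, "CallSpec"))
  if ((spec$f0 + spec$fmDepth) * spec$nHarmonics >= rate / 2)
    stop("call harmonics would alias: (f0 + fmDepth) * nHarmonics >= Nyquist",
         call. = FALSE)
  n <- max(1L, round(spec$duration * rate))
  t <- (seq_len(n) - 1L) / rate
  ## integral of f0 + fmDepth * sin(2 pi fmRate t)
  ph <- if (spec$fmDepth > 0 && spec$fmRate > 0)
    spec$f0 * t + spec$fmDepth * (1 - cos(2 * pi * spec$fmRate * t)) /
      (2 * pi * spec$fmRate)
  else spec$f0 * t
  x <- numeric(n)
  for (h in seq_len(spec$nHarmonics))
    x <- x + sin(2 * pi * h * ph) / h
  ## attack / decay envelope
  env <- rep(1, n)
  na <- round(spec$attack * n)
  nd <- round(spec$decay * n)
  if (na > 0) env[seq_len(na)] <- seq(0, 1, length.out = na)
  if (nd > 0) env[(n - nd + 1L):n] <- seq(1, 0, length.out = nd)
  AudioSignal(spec$level * env * x / spec$nHarmonics, rate)
}

#' Specification of a synthetic chorus scene
#'
#' @param species List of per-species entries, each
#'   `list(call = <callSpec>, period = <s>, jitter = <s>)`; may be empty
#'   (pure noise).
#' @param duration Scene length (s).
#' @param noiseKind `"white"` or `"pink"` (1/f-shaped) background.
#' @param snrDb Signal-to-noise ratio in dB: RMS of the summed calls over RMS
#'   of the noise, measured over the full duration.
#' @param rate Sampling rate (Hz); default 44100 (field-recorder standard).
#' @param seed RNG seed; identical specs render bitwise-identical audio.
#' @return A classed list (`SceneSpec`).
#' @export
sceneSpec <- function(species, duration = 20, noiseKind = "white",
                      snrDb = 30, rate = 44100, seed = 1L) {
  stopifnot(is.list(species), isScalar(duration), duration > 0,
            isScalar(snrDb), isScalar(rate), rate > 0)
  if (!noiseKind %in% c("white", "pink"))
    stop("'noiseKind' must be \"white\" or \"pink\"", call. = FALSE)
  for (sp in species)
    stopifnot(inherits(sp$call, "CallSpec"), sp$period > 0, sp$jitter >= 0)
  structure(list(species = species, duration = duration,
                 noiseKind = noiseKind, snrDb = snrDb, rate = rate,
                 seed = seed), class = "SceneSpec")
}

pinkNoise <- function(n, rate) {
  ## spectral 1/f shaping of seeded white noise
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric bin distance
  X <- X / sqrt(f)
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize a chorus with known ground truth
#'
#' Places each species' calls at `period +/- jitter` intervals, sums the
#' species tracks, adds the background noise scaled to the requested SNR and
#' peak-normalizes to 0.9 full scale. Identical scenes (including seed)
#' render bitwise-identical output.
#'
#' @param scene A [sceneSpec()].
#' @return A list with `audio` (an [AudioSignal-class]) and `truth`:
#'   `onsets` (data.frame species/onset), `bands` (data.frame of each
#'   species' frequency band), `counts`, `realizedSnrDb`.
#' @export
synthesizeChorus <- function(scene) {
  stopifnot(inherits(scene, "SceneSpec"))
  n <- round(scene$duration * scene$rate)
  if (n < 1L) stop("zero-duration scene", call. = FALSE)
  withSeed(scene$seed, {
    S <- length(scene$species)
    callMix <- numeric(n)
    onsets <- list()
    bands <- list()
    counts <- integer(S)
    for (i in seq_len(S)) {
      sp <- scene$species[[i]]
      callAudio <- samples(makeCall(sp$call, scene$rate))
      maxOnset <- scene$duration - sp$call$duration
      if (maxOnset < 0) next
      base <- seq(0, maxOnset, by = sp$period)
      jit <- if (sp$jitter > 0)
        stats::runif(length(base), -sp$jitter, sp$jitter) else 0
      on <- pmin(pmax(base + jit, 0), maxOnset)
      for (o in on) {
        s0 <- round(o * scene$rate) + 1L
        s1 <- min(s0 + length(callAudio) - 1L, n)
        callMix[s0:s1] <- callMix[s0:s1] + callAudio[seq_len(s1 - s0 + 1L)]
      }
      counts[i] <- length(on)
      onsets[[i]] <- data.frame(species = i, onset = on)
      bands[[i]] <- data.frame(
        species = i,
        lo = max(0, sp$call$f0 - sp$call$fmDepth - sp$call$fmRate),
        hi = sp$call$nHarmonics * (sp$call$f0 + sp$call$fmDepth +
                                     sp$call$fmRate))
    }
    noise <- switch(scene$noiseKind,
                    white = stats::rnorm(n),
                    pink = pinkNoise(n, scene$rate))
    callRms <- sqrt(mean(callMix^2))
    noiseRms <- sqrt(mean(noise^2))
    if (callRms > 0) {
      target <- callRms / 10^(scene$snrDb / 20)
      noise <- noise * target / noiseRms
    } else {
      noise <- noise * 0.1 / noiseRms
    }
    realizedSnr <- if (callRms > 0)
      20 * log10(callRms / sqrt(mean(noise^2))) else -Inf
    x <- callMix + noise
    peak <- max(abs(x))
    if (peak > 0) x <- 0.9 * x / peak
    list(
      audio = AudioSignal(x, scene$rate),
      truth = list(
        onsets = if (length(onsets)) do.call(rbind, onsets)
                 else data.frame(species = integer(0), onset = numeric(0)),
        bands = if (length(bands)) do.call(rbind, bands)
                else data.frame(species = integer(0), lo = numeric(0),
                                hi = numeric(0)),
        counts = counts,
        realizedSnrDb = realizedSnr))
  })
}

#' Default community of S species with non-overlapping frequency niches
#'
#' Partitions 1-10 kHz into S geometric slots and places one species'
#' fundamental at each slot centre (single-harmonic FM calls, so niches do
#' not overlap via harmonics — the acoustic-niche premise). Call tempo and
#' modulation vary per species, deterministically from the seed.
#'
#' @param S Species richness (>= 0).
#' @param seed RNG seed.
#' @param overlap Fraction in [0, 1) by which adjacent niches are allowed to
#'   overlap (0 = disjoint; larger values emulate degraded, competitive
#'   soundscapes).
#' @return A list suitable as the `species` argument of [sceneSpec()].
#' @export
chorusSpecies <- function(S, seed = 1L, overlap = 0) {
  S <- as.integer(S)
  stopifnot(S >= 0, overlap >= 0, overlap < 1)
  if (S == 0L) return(list())
  withSeed(seed, {
    edges <- exp(seq(log(1000), log(10000), length.out = S + 1L))
    lapply(seq_len(S), function(i) {
      lo <- edges[i]; hi <- edges[i + 1L]
      width <- (hi - lo) * (1 + overlap)
      f0 <- sqrt(lo * hi)                 # geometric slot centre
      fmDepth <- min(0.25 * width, 0.15 * f0) * stats::runif(1, 0.5, 1)
      list(call = callSpec(f0 = f0, nHarmonics = 1L, fmDepth = fmDepth,
                           fmRate = stats::runif(1, 2, 6),
                           duration = stats::runif(1, 0.3, 0.7),
                           attack = 0.15, decay = 0.3, level = 1),
           period = stats::runif(1, 1.5, 3),
           jitter = stats::runif(1, 0.1, 0.3))
    })
  })
}

#' Acoustic indices across a species-richness sweep
#'
#' For each richness S and replicate, draws a community with distinct
#' frequency niches, synthesizes the chorus, and computes the full index
#' report — the experiment behind the richness-entropy relationship (total
#' acoustic entropy H increasing with S, approximately linearly in ln S).
#'
#' @param SValues Integer vector of richness values.
#' @param replicates Replicates per richness; default 10.
#' @param duration,snrDb,noiseKind,rate Scene parameters (defaults: 20 s,
#'   30 dB, white, 44100 Hz).
#' @param seed Master seed; per-realization seeds are derived from it.
#' @param config An [indexConfig()] for the index computation.
#' @return A data.frame with columns `S`, `replicate`, `seed` and the eight
#'   index values.
#' @export
richnessSweep <- function(SValues, replicates = 10L, duration = 20,
                          snrDb = 30, noiseKind = "white", rate = 44100,
                          seed = 1L, config = indexConfig()) {
  if (!length(SValues)) stop("'SValues' must be non-empty", call. = FALSE)
  rows <- list()
  for (S in SValues) {
    for (r in seq_len(replicates)) {
      ## derived seed, kept within 32-bit integer range
      sd <- (as.numeric(seed) * 7919 + S * 131 + r * 17) %% 2147483647
      sc <- sceneSpec(chorusSpecies(S, seed = sd), duration = duration,
                      noiseKind = noiseKind, snrDb = snrDb, rate = rate,
                      seed = sd)
      rep <- computeIndexReport(synthesizeChorus(sc)$audio, config)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(S = S, replicate = r, seed = sd),
              as.data.frame(rep))
    }
  }
  do.call(rbind, rows)
}

#' Ground-truth shift-invariant component model with distinct chirp kernels
#'
#' Builds a K-component generative model of the kind [siplca2dFit()] is
#' meant to recover: each component's kernel is a narrow frequency ridge
#' with its own chirp slope (slopes 0, +2, -2, +1, -1 bins per frame — five
#' pairwise-distinct spectro-temporal gestures), and each activation places
#' the kernel at well-separated random positions on a coarse grid. Distinct
#' slopes matter: components whose kernels agree up to a 2D shift are, by
#' construction of the shift-invariant model, one component, and components
#' more similar than the sparsity prior's per-component description cost
#' will legitimately be fused by automatic relevance determination.
#'
#' @param K Number of components (1 to 5).
#' @param seed RNG seed (placements, per-placement gains, weights).
#' @param fBins,tFrames Dimensions of the generated matrix; defaults 48 x 140.
#' @param kernelShape Kernel box; default `c(16, 8)`.
#' @param placements Placements per component; default 2.
#' @param width Ridge cross-section (bins); default 0.55.
#' @return As [synthesizeFactorMatrix()]: a list with `V` and `truth`.
#' @export
syntheticComponentModel <- function(K, seed = 1L, fBins = 48L,
                                    tFrames = 140L,
                                    kernelShape = c(16L, 8L),
                                    placements = 2L, width = 0.55) {
  K <- as.integer(K)
  stopifnot(K >= 1L, K <= 5L)
  Fk <- kernelShape[1L]; Tk <- kernelShape[2L]
  slopes <- c(0, 2, -2, 1, -1)[seq_len(K)]
  kernels <- lapply(slopes, function(s) {
    rows <- matrix(seq_len(Fk), Fk, Tk)
    cols <- matrix(seq_len(Tk), Fk, Tk, byrow = TRUE)
    centre <- (Fk + 1) / 2 + s * (cols - (Tk + 1) / 2)
    m <- exp(-(rows - centre)^2 / (2 * width^2))
    m / sum(m)
  })
  withSeed(seed, {
    gridR <- seq(1L, fBins - Fk + 1L, by = Fk + 1L)
    gridC <- seq(1L, tFrames - Tk + 1L, by = Tk + 2L)
    cells <- expand.grid(r = gridR, c = gridC)
    pick <- cells[sample(nrow(cells), K * placements), ]
    activations <- lapply(seq_len(K), function(k) {
      a <- matrix(0, fBins - Fk + 1L, tFrames - Tk + 1L)
      idx <- pick[((k - 1L) * placements + 1L):(k * placements), ]
      a[cbind(idx$r, idx$c)] <- stats::runif(placements, 0.6, 1)
      a / sum(a)
    })
    w <- stats::runif(K, 0.7, 1.3)
    w <- sort(w / sum(w), decreasing = TRUE)
    synthesizeFactorMatrix(kernels, activations, w)
  })
}

#' Generative shift-invariant factor matrix with known truth
#'
#' Builds `V = sum_k z_k (kernel_k convolved with activation_k)`, optionally
#' corrupted by non-negative noise at a given SNR, and renormalized to sum
#' to 1 — the ground-truth counterpart of [siplca2dFit()].
#'
#' @param kernels List of non-negative matrices (equal shape).
#' @param activations List of non-negative matrices (equal shape).
#' @param weights Non-negative mixing weights summing to 1.
#' @param noiseDb SNR of additive half-normal noise in dB (`NULL` or `Inf`
#'   for noiseless). Because the matrix is a probability mass, the ratio is
#'   defined on total mass: `10 * log10(sum(signal) / sum(noise))`.
#' @param seed RNG seed for the noise.
#' @return A list with `V` (sums to 1) and `truth` (normalized kernels,
#'   activations, weights).
#' @export
synthesizeFactorMatrix <- function(kernels, activations, weights,
                                   noiseDb = NULL, seed = 1L) {
  K <- length(weights)
  stopifnot(length(kernels) == K, length(activations) == K, K >= 1)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be non-negative and sum to 1", call. = FALSE)
  kernels <- lapply(kernels, function(w) {
    if (any(w < 0)) stop("negative kernel", call. = FALSE); w / sum(w)
  })
  activations <- lapply(activations, function(h) {
    if (any(h < 0)) stop("negative activation", call. = FALSE); h / sum(h)
  })
  V <- matrix(0, nrow(kernels[[1L]]) + nrow(activations[[1L]]) - 1L,
              ncol(kernels[[1L]]) + ncol(activations[[1L]]) - 1L)
  for (k in seq_len(K))
    V <- V + weights[k] * conv2Full(kernels[[k]], activations[[k]])
  V <- pmax(V, 0)
  if (!is.null(noiseDb) && is.finite(noiseDb)) {
    withSeed(seed, {
      noise <- abs(matrix(stats::rnorm(length(V)), nrow(V)))
      noise <- noise * (sum(V) / sum(noise)) / 10^(noiseDb / 10)
      V <- V + noise
    })
  }
  list(V = V / sum(V),
       truth = list(kernels = kernels, activations = activations,
                    weights = weights))
}
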