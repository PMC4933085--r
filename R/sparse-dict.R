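## Sparse approximation of spectrogram patches: analytic (Gabor field) and
## learned (mini-batch gradient) overcomplete dictionaries, coded with
## Orthogonal Matching Pursuit.

#' Extract a regular tiling of 2D patches from a spectrogram
#'
#' Row-major tiling: origins run over frequency rows (outer) and time columns
#' (inner) at the given strides. The final row/column position is snapped to
#' the boundary so the tiling always reaches the far edges.
#'
#' @param spec A [Spectrogram-class] or a plain numeric matrix.
#' @param patchShape Integer length-2: (rows, cols) of each patch.
#' @param stride Integer length-1 or -2: step between patch origins; defaults
#'   to `patchShape` (non-overlapping tiling).
#' @return A [PatchSet-class].
#' @examples
#' m <- matrix(runif(64), 8, 8)
#' length(patches(extractPatches(m, c(4, 4), 4)))  # 4
#' length(patches(extractPatches(m, c(4, 4), 2)))  # 9
#' @export
extractPatches <- function(spec, patchShape, stride = patchShape) {
  v <- if (is(spec, "Spectrogram")) specValues(spec) else spec
  stopifnot(is.matrix(v))
  patchShape <- as.integer(patchShape)
  stride <- as.integer(stride)
  if (length(stride) == 1L) stride <- rep(stride, 2L)
  if (any(patchShape < 1L) || any(stride < 1L))
    stop("'patchShape' and 'stride' must be positive", call. = FALSE)
  if (patchShape[1L] > nrow(v) || patchShape[2L] > ncol(v))
    stop("patch larger than the spectrogram", call. = FALSE)
  rPos <- unique(c(seq.int(1L, nrow(v) - patchShape[1L] + 1L, by = stride[1L]),
                   nrow(v) - patchShape[1L] + 1L))
  cPos <- unique(c(seq.int(1L, ncol(v) - patchShape[2L] + 1L, by = stride[2L]),
                   ncol(v) - patchShape[2L] + 1L))
  origins <- cbind(rep(rPos, each = length(cPos)),
                   rep(cPos, times = length(rPos)))
  plist <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1L]; cc <- origins[i, 2L]
    v[r:(r + patchShape[1L] - 1L), cc:(cc + patchShape[2L] - 1L),
      drop = FALSE]
  })
  new("PatchSet", patches = plist, origins = origins,
      patchShape = patchShape, sourceDim = dim(v))
}

#' A single 2D Gabor atom
#'
#' A Gaussian-windowed sinusoid oriented in the time-frequency plane:
#' `g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi freq x' + phase)`
#' with `x' = x cos(theta) + y sin(theta)`. Zero modulation frequency with
#' phase 0 reduces to a pure 2D Gaussian. The atom is L2-normalized.
#'
#' @param shape Integer length-2: (rows, cols).
#' @param theta Orientation in radians.
#' @param freq Modulation frequency in cycles per pixel.
#' @param phase Phase offset in radians.
#' @param sigma Gaussian envelope scale in pixels.
#' @param gamma Aspect ratio of the envelope (1 = isotropic).
#' @return A matrix of `shape` with unit L2 norm.
#' @export
gaborAtom <- function(shape, theta = 0, freq = 0.1, phase = 0,
                      sigma = min(shape) / 4, gamma = 1) {
  shape <- as.integer(shape)
  cy <- (shape[1L] + 1) / 2
  cx <- (shape[2L] + 1) / 2
  y <- matrix(seq_len(shape[1L]) - cy, shape[1L], shape[2L])
  x <- matrix(seq_len(shape[2L]) - cx, shape[1L], shape[2L], byrow = TRUE)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  g <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * freq * xr + phase)
  nrm <- sqrt(sum(g^2))
  if (nrm <= 0) stop("degenerate Gabor atom (zero norm)", call. = FALSE)
  g / nrm
}

#' Gabor field dictionary
#'
#' A deterministic grid of 2D Gabor atoms over orientation x scale x phase.
#' Scale s uses envelope `sigma = min(shape) / 2^s` with modulation wavelength
#' `2 sigma` (one cycle per envelope width), the classic biologically informed
#' time-frequency atom family.
#'
#' @param patchShape Integer length-2.
#' @param nOrientations Orientations over [0, pi); default 8.
#' @param nScales Dyadic scales; default 4.
#' @param nPhases Phases over [0, pi); default 2.
#' @return A [Dictionary-class] of `nOrientations * nScales * nPhases` atoms.
#' @export
gaborDictionary <- function(patchShape, nOrientations = 8L, nScales = 4L,
                            nPhases = 2L) {
  patchShape <- as.integer(patchShape)
  if (nOrientations < 1L || nScales < 1L || nPhases < 1L)
    stop("atom grid counts must be >= 1", call. = FALSE)
  atoms <- list()
  for (s in seq_len(nScales)) {
    sigma <- min(patchShape) / 2^s
    freq <- 1 / (2 * sigma)
    for (o in seq_len(nOrientations)) {
      theta <- (o - 1L) * pi / nOrientations
      for (ph in seq_len(nPhases)) {
        phase <- (ph - 1L) * pi / nPhases
        atoms[[length(atoms) + 1L]] <-
          gaborAtom(patchShape, theta, freq, phase, sigma)
      }
    }
  }
  new("Dictionary", atoms = atoms, patchShape = patchShape, kind = "gabor")
}

dictMatrix <- function(dict) {
  vapply(atoms(dict), as.numeric, numeric(prod(patchShape(dict))))
}

#' Orthogonal Matching Pursuit for one patch
#'
#' Greedy sparse coding: at each step the atom with maximal absolute
#' correlation to the residual is selected (ties broken by lowest atom index)
#' and the coefficients of all selected atoms are refitted by least squares,
#' leaving the residual orthogonal to their span. Stops after `sparsity`
#' atoms, when the residual norm drops below `tol`, or when no atom
#' correlates with the residual.
#'
#' @param patch A matrix of the dictionary's `patchShape` (or a numeric
#'   vector of matching length).
#' @param dict A [Dictionary-class].
#' @param sparsity Maximum number of atoms (>= 1).
#' @param tol Residual L2 norm at which to stop; default 1e-10.
#' @return A list with `atoms` (indices), `coefs`, `residual` (vector) and
#'   `residualNorm`.
#' @export
omp <- function(patch, dict, sparsity, tol = 1e-10) {
  stopifnot(is(dict, "Dictionary"))
  sparsity <- as.integer(sparsity)
  if (sparsity < 1L) stop("'sparsity' must be >= 1", call. = FALSE)
  if (sparsity > length(atoms(dict)))
    stop("'sparsity' exceeds the number of atoms", call. = FALSE)
  D <- dictMatrix(dict)
  x <- as.numeric(patch)
  if (length(x) != nrow(D))
    stop("patch dimensionality does not match the dictionary", call. = FALSE)
  ompVec(x, D, sparsity, tol)
}

ompVec <- function(x, D, sparsity, tol = 1e-10) {
  r <- x
  sel <- integer(0)
  coefs <- numeric(0)
  for (step in seq_len(sparsity)) {
    if (sqrt(sum(r^2)) < tol) break
    corr <- abs(crossprod(D, r))
    corr[sel] <- -Inf
    j <- which.max(corr)               # first maximum = lowest index on ties
    if (corr[j] < 1e-12 * max(sqrt(sum(x^2)), 1e-300)) break
    sel <- c(sel, j)
    coefs <- qr.solve(D[, sel, drop = FALSE], x)
    r <- x - D[, sel, drop = FALSE] %*% coefs
  }
  list(atoms = sel, coefs = as.numeric(coefs), residual = as.numeric(r),
       residualNorm = sqrt(sum(r^2)))
}

#' Learn an overcomplete dictionary by mini-batch gradient descent
#'
#' Alternates OMP sparse coding of a random mini-batch with a gradient step
#' on the atoms minimizing the summed squared reconstruction error
#' `sum ||x - D a||^2`; atoms are re-normalized to unit L2 norm after every
#' step. The step size decays as `step / t` over batches. Deterministic for a
#' fixed seed.
#'
#' @param patchset A [PatchSet-class] (or list of equal-shape matrices).
#' @param nAtoms Number of atoms; default 64.
#' @param batchSize Mini-batch size; default 32.
#' @param nEpochs Passes over the data; default 30.
#' @param step Initial gradient step size; default 0.1.
#' @param sparsity OMP sparsity used during coding; default 8.
#' @param seed RNG seed (required for reproducibility).
#' @return A [Dictionary-class] of kind `"learned"`, with the per-epoch mean
#'   residual norm in `attr(, "trainError")`.
#' @export
learnDictionary <- function(patchset, nAtoms = 64L, batchSize = 32L,
                            nEpochs = 30L, step = 0.1, sparsity = 8L,
                            seed = 1L) {
  plist <- if (is(patchset, "PatchSet")) patches(patchset) else patchset
  if (!length(plist)) stop("empty patch set", call. = FALSE)
  shape <- dim(plist[[1L]])
  X <- vapply(plist, as.numeric, numeric(prod(shape)))
  if (all(X == 0))
    stop("all-zero patch set: nothing to learn", call. = FALSE)
  nAtoms <- as.integer(nAtoms)
  sparsity <- min(as.integer(sparsity), nAtoms)
  n <- ncol(X)
  batchSize <- min(as.integer(batchSize), n)

  withSeed(seed, {
    ## init: randomly drawn patches plus jitter, unit-normalized
    D <- X[, sample.int(n, nAtoms, replace = nAtoms > n), drop = FALSE]
    D <- D + matrix(stats::rnorm(length(D), sd = 0.01 * max(abs(X))),
                    nrow(D), ncol(D))
    D <- sweep(D, 2L, pmax(sqrt(colSums(D^2)), 1e-12), "/")
    trainErr <- numeric(nEpochs)
    t <- 0L
    for (epoch in seq_len(nEpochs)) {
      ord <- sample.int(n)
      resid <- 0
      for (b0 in seq.int(1L, n, by = batchSize)) {
        t <- t + 1L
        ii <- ord[b0:min(b0 + batchSize - 1L, n)]
        G <- matrix(0, nrow(D), ncol(D))
        for (i in ii) {
          code <- ompVec(X[, i], D, sparsity)
          if (length(code$atoms))
            G[, code$atoms] <- G[, code$atoms] +
              tcrossprod(code$residual, code$coefs)
          resid <- resid + code$residualNorm
        }
        D <- D + (step / t) * G / length(ii)
        D <- sweep(D, 2L, pmax(sqrt(colSums(D^2)), 1e-12), "/")
      }
      trainErr[epoch] <- resid / n
    }
    alist <- lapply(seq_len(ncol(D)), function(j) matrix(D[, j], shape[1L],
                                                         shape[2L]))
    out <- new("Dictionary", atoms = alist, patchShape = as.integer(shape),
               kind = "learned")
    attr(out, "trainError") <- trainErr
    out
  })
}

#' Sparse approximation of a spectrogram
#'
#' Tiles the spectrogram into patches, codes each with OMP against the
#' dictionary, and reassembles the coded patches by overlap-add with uniform
#' averaging of overlapping contributions. Negative reconstruction values are
#' clipped to zero so the result is again a valid magnitude spectrogram.
#'
#' @param spec A [Spectrogram-class] (or plain matrix).
#' @param dict A [Dictionary-class].
#' @param sparsity OMP sparsity per patch; default 8.
#' @param stride Tiling stride; default half the patch shape.
#' @return A list with `code` (a [SparseCode-class]), `reconstruction`
#'   (same class/shape as the input) and `relativeError`
#'   (`||V - Vhat||_F / ||V||_F`).
#' @export
approximateSpectrogram <- function(spec, dict, sparsity = 8L,
                                   stride = patchShape(dict) %/% 2L) {
  stopifnot(is(dict, "Dictionary"))
  isSpec <- is(spec, "Spectrogram")
  v <- if (isSpec) specValues(spec) else spec
  ps <- extractPatches(v, patchShape(dict), stride)
  D <- dictMatrix(dict)
  shape <- patchShape(dict)
  acc <- matrix(0, nrow(v), ncol(v))
  cnt <- matrix(0, nrow(v), ncol(v))
  entries <- vector("list", length(patches(ps)))
  rnorms <- numeric(length(entries))
  for (i in seq_along(entries)) {
    x <- as.numeric(patches(ps)[[i]])
    code <- ompVec(x, D, as.integer(sparsity))
    entries[[i]] <- list(atoms = code$atoms, coefs = code$coefs)
    rnorms[i] <- code$residualNorm
    rec <- x - code$residual
    o <- ps@origins[i, ]
    rows <- o[1L]:(o[1L] + shape[1L] - 1L)
    cols <- o[2L]:(o[2L] + shape[2L] - 1L)
    acc[rows, cols] <- acc[rows, cols] + matrix(rec, shape[1L], shape[2L])
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  recon <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  recon <- pmax(recon, 0)
  relErr <- sqrt(sum((v - recon)^2)) / max(sqrt(sum(v^2)), 1e-300)
  code <- new("SparseCode", entries = entries, residualNorms = rnorms,
              sparsity = as.integer(sparsity))
  reconstruction <- if (isSpec)
    Spectrogram(recon, specFreqs(spec), specTimes(spec), spec@scale)
  else recon
  list(code = code, reconstruction = reconstruction, relativeError = relErr)
}

#' Write a dictionary to a plain-text archive
#'
#' CSV layout: one row per atom, columns `kind`, `rows`, `cols`, then the
#' atom values flattened column-major.
#'
#' @param dict A [Dictionary-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDictionaryCSV <- function(dict, path) {
  stopifnot(is(dict, "Dictionary"))
  m <- t(dictMatrix(dict))
  df <- data.frame(kind = dict@kind, rows = patchShape(dict)[1L],
                   cols = patchShape(dict)[2L], m)
  names(df) <- c("kind", "rows", "cols",
                 paste0("v", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dictionary written by [writeDictionaryCSV()]
#'
#' @param path CSV path.
#' @return A [Dictionary-class].
#' @export
readDictionaryCSV <- function(path) {
  df <- utils::read.csv(path)
  shape <- c(df$rows[1L], df$cols[1L])
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  alist <- lapply(seq_len(nrow(vals)), function(i)
    matrix(as.numeric(vals[i, ]), shape[1L], shape[2L]))
  new("Dictionary", atoms = alist, patchShape = as.integer(shape),
      kind = df$kind[1L])
}
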