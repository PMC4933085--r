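## Probabilistic latent component analysis of normalized spectrograms, and
## its shift-invariant 2D extension with a sparsity prior that prunes
## superfluous components (automatic relevance determination).
##
## Model: V(f,t) ~ sum_k z_k sum_{phi,tau} W_k(f-phi, tau) H_k(phi, t-tau),
## i.e. each component is a time-frequency kernel W_k placed across the input
## by an activation map H_k over (frequency shift x time). All factors are
## probability distributions; EM re-estimates them by posterior-weighted
## marginalization, implemented with FFT 2D convolution/correlation.

#' Normalize a spectrogram to a probability matrix
#'
#' Divides the magnitude matrix by its total so it sums to 1, the form the
#' latent component models factorize.
#'
#' @param spec A [Spectrogram-class] or non-negative matrix with positive sum.
#' @return A non-negative matrix summing to 1.
#' @export
normalizeInput <- function(spec) {
  v <- if (is(spec, "Spectrogram")) specValues(spec) else spec
  stopifnot(is.matrix(v))
  if (any(!is.finite(v)))
    stop("input must be finite and non-negative", call. = FALSE)
  ## tolerate numerical round-off (e.g. FFT-based convolution residue)
  tolNeg <- -1e-9 * max(abs(v), 1e-300)
  if (any(v < tolNeg))
    stop("input must be finite and non-negative", call. = FALSE)
  v <- pmax(v, 0)
  s <- sum(v)
  if (s <= 0) stop("all-zero input cannot be normalized", call. = FALSE)
  v / s
}

klDivergence <- function(V, Vhat) {
  ok <- V > 0
  sum(V[ok] * log(V[ok] / pmax(Vhat[ok], 1e-300)))
}

## Numerical guards shared by the EM fitters.
##
## (1) Cells of V below 1e-12 of the maximum are round-off residue (e.g.
## FFT-built inputs); they are zeroed so they cannot act as phantom support.
## (2) A fixed uniform background of mass bgGamma is mixed into the
## reconstruction during fitting. This is exact EM for a mixture with one
## frozen component: monotonicity is untouched, and the posterior ratio
## V/Vhat stays bounded (<= max(V) * nCells / bgGamma) even when a cell's
## component mass underflows, which would otherwise destroy the precision of
## the FFT-based correlations.
bgGamma <- 1e-9

cleanV <- function(V) {
  V[V < 1e-12 * max(V)] <- 0
  V / sum(V)
}

#' Fit a (non-shift-invariant) PLCA model
#'
#' EM for `V ~ W Z H`: the E-step computes the posterior over components for
#' every time-frequency cell, the M-step re-estimates the frequency
#' distributions `w_k`, time distributions `h_k` and weights `z_k` by
#' posterior-weighted marginalization. The KL divergence `KL(V || WZH)` is
#' non-increasing at every iteration.
#'
#' @param V Non-negative matrix; normalized internally via
#'   [normalizeInput()].
#' @param K Number of components (>= 1). More components than
#'   `min(dim(V))` is permitted but warned about (overcomplete).
#' @param nIters Maximum EM iterations; default 200.
#' @param tol Relative objective change at which to stop; default 1e-5.
#' @param seed RNG seed for the strictly positive random initialization.
#' @return A [PLCAModel-class].
#' @examples
#' V <- outer(c(2, 1, 1), c(1, 3)) / 10
#' plcaFit(V, K = 1, seed = 1)
#' @export
plcaFit <- function(V, K, nIters = 200L, tol = 1e-5, seed = 1L) {
  V <- normalizeInput(V)
  if (any(is.na(V))) stop("NaN in input", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1", call. = FALSE)
  if (K > min(dim(V)))
    warning("K exceeds min(dim(V)): overcomplete factorization")
  V <- cleanV(V)
  Fn <- nrow(V); Tn <- ncol(V)
  bg <- bgGamma / (Fn * Tn)
  withSeed(seed, {
    W <- matrix(stats::runif(Fn * K, 0.5, 1.5), Fn, K)
    H <- matrix(stats::runif(K * Tn, 0.5, 1.5), K, Tn)
    W <- sweep(W, 2L, colSums(W), "/")
    H <- sweep(H, 1L, rowSums(H), "/")
    z <- rep(1 / K, K)
    obj <- numeric(0)
    for (it in seq_len(nIters)) {
      Vhat <- (1 - bgGamma) * (W %*% (z * H)) + bg
      obj <- c(obj, klDivergence(V, Vhat))
      R <- ifelse(V > 0, V / Vhat, 0)
      ## posterior-weighted marginals
      numW <- W * (R %*% t(H)) * rep(z, each = Fn)
      numH <- H * (t(W) %*% R) * z
      nk <- colSums(numW)
      zNew <- nk / sum(nk)
      W <- sweep(numW, 2L, pmax(nk, 1e-300), "/")
      H <- sweep(numH, 1L, pmax(rowSums(numH), 1e-300), "/")
      z <- zNew
      if (it > 1L) {
        d <- obj[it - 1L] - obj[it]
        if (abs(d) < tol * max(abs(obj[it]), 1e-12)) break
      }
    }
    ord <- order(z, decreasing = TRUE)
    new("PLCAModel", W = W[, ord, drop = FALSE],
        H = H[ord, , drop = FALSE], z = z[ord],
        objective = obj, seed = as.numeric(seed))
  })
}

## Hard-zero negligible activation cells. Multiplicative updates keep exact
## zeros at zero, so ownership of a placement can only move to a component
## that already gives it non-negligible mass — never to whichever slot
## happens to hold the largest sub-denormal residue.
zeroTinyCells <- function(h) {
  ## threshold relative to the map peak: losing cells decay through it in a
  ## few iterations, while the total zeroed mass (<= nCells * 1e-12 * max)
  ## perturbs the objective by well under the convergence tolerance
  h[h < 1e-12 * max(h)] <- 0
  s <- sum(h)
  if (s > 0) h / s else h
}

## Solve min_z -sum(n_k log z_k) + sum(c_k z_k) s.t. sum z = 1, z >= 0:
## z_k = n_k / (mu + c_k) with mu the root of sum_k n_k/(mu + c_k) = 1.
## This is the exact minimizer of the MM surrogate of the log-penalized
## M-step objective; with all c_k = 0 it reduces to z_k = n_k / sum(n).
solveWeightStep <- function(n, cc) {
  out <- numeric(length(n))
  nz <- which(n > 1e-300)                 # denormals count as dead
  if (!length(nz)) return(out)
  nn <- n[nz]; cn <- cc[nz]
  g <- function(mu) sum(nn / (mu + cn)) - 1
  ## g is decreasing and -> +Inf as mu -> -min(cn) from above, so a root
  ## always exists; bracket it and bisect.
  lo <- -min(cn) + 1e-300
  if (g(max(lo, 1e-12)) > 0) lo <- max(lo, 1e-12)
  hi <- max(sum(nn), 1)
  while (g(hi) > 0) hi <- hi * 2
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  x <- nn / ((lo + hi) / 2 + cn)
  if (!all(is.finite(x)) || sum(x) <= 0) x <- nn / sum(nn)
  out[nz] <- x / sum(x)                   # exact simplex projection of root
  out
}

## Best-aligned cosine between two kernels over all 2D shifts: the full
## cross-correlation maximum over the zero-padded overlap, normalized by the
## global norms. Returns the cosine and the (df, dt) shift of b relative to a.
alignedKernelCosine <- function(a, b) {
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 <= 0 || nb2 <= 0) return(list(cos = 0, df = 0L, dt = 0L))
  xc <- conv2Full(a, b[nrow(b):1, ncol(b):1, drop = FALSE])
  best <- which(xc == max(xc), arr.ind = TRUE)[1L, ]
  cosv <- max(xc) / sqrt(na2 * nb2)
  ## xc index (nrow(b), ncol(b)) corresponds to zero shift
  list(cos = cosv, df = best[1L] - nrow(b), dt = best[2L] - ncol(b))
}

shiftMatrix <- function(m, df, dt) {
  out <- matrix(0, nrow(m), ncol(m))
  sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
  fr <- sr + df; fc <- sc + dt
  ok_r <- fr >= 1 & fr <= nrow(m); ok_c <- fc >= 1 & fc <= ncol(m)
  out[fr[ok_r], fc[ok_c]] <- m[sr[ok_r], sc[ok_c]]
  out
}

## Activation-map penalty. Dead slots contribute the all-sparse floor
## nCells * log(epsH) — a constant — rather than their frozen map, so (a)
## the objective drops (never jumps) when a component dies and (b) merging
## two components does not double-count the pooled activation cells.
penaltyH <- function(Hl, alive, lambdaH, epsH) {
  if (lambdaH <= 0) return(0)
  ncell <- length(Hl[[1L]])
  s <- 0
  for (k in seq_along(Hl))
    s <- s + if (alive[k]) sum(log(Hl[[k]] + epsH)) else ncell * log(epsH)
  lambdaH * s
}

## Seed kernels from high-energy patches of V (greedy non-maximum
## suppression): each component starts attached to an actual pattern
## occurrence, so duplicates are near-identical (and cheap to merge or
## shrink) rather than arbitrary mixtures. Falls back to jittered-uniform
## patches once the energy is exhausted. Deterministic apart from the
## multiplicative jitter drawn from the caller's seeded RNG.
seedKernels <- function(V, kMax, Fk, Tk) {
  Fn <- nrow(V); Tn <- ncol(V)
  ## patch-energy map: total V mass captured by a kernel box at each origin
  score <- xcorr2Valid(V, matrix(1, Fk, Tk))
  out <- vector("list", kMax)
  floorVal <- max(V) * 1e-3
  for (k in seq_len(kMax)) {
    if (max(score) > 0) {
      idx <- which.max(score)
      f0 <- (idx - 1L) %% nrow(score) + 1L
      t0 <- (idx - 1L) %/% nrow(score) + 1L
      p <- V[f0:(f0 + Fk - 1L), t0:(t0 + Tk - 1L)] + floorVal
      ## suppress any origin whose box overlaps this one
      sr <- max(1L, f0 - Fk + 1L):min(nrow(score), f0 + Fk - 1L)
      sc <- max(1L, t0 - Tk + 1L):min(ncol(score), t0 + Tk - 1L)
      score[sr, sc] <- 0
    } else {
      p <- matrix(1, Fk, Tk)
    }
    p <- p * matrix(stats::runif(Fk * Tk, 0.95, 1.05), Fk, Tk)
    out[[k]] <- p / sum(p)
  }
  out
}

## One greedy sweep of accept-if-better component merges. `state` carries
## Wk, Hk, z, alive; returns the (possibly) updated state with `changed` and
## `objective` fields. `base` is the current penalized objective.
mergeComponentPairs <- function(state, V, base, bg, lambdaH, epsH,
                                nRefine = 10L) {
  Wk <- state$Wk; Hk <- state$Hk; z <- state$z; alive <- state$alive
  Fn <- nrow(V); Tn <- ncol(V)
  convs <- vector("list", length(z))
  for (k in which(alive)) convs[[k]] <- conv2Full(Wk[[k]], Hk[[k]])
  changed <- FALSE
  repeat {
    cand <- which(alive & z > 1e-6)
    cand <- cand[order(z[cand], decreasing = TRUE)]
    merged <- FALSE
    for (ii in seq_along(cand)) {
      for (jj in seq_along(cand)) {
        if (jj <= ii) next
        i <- cand[ii]; j <- cand[jj]
        ## two candidate alignments: matching kernels (placement splits,
        ## pool the activations) and matching activations (pattern splits,
        ## pool the kernels). Loose prefilter; the objective decides.
        alW <- alignedKernelCosine(Wk[[i]], Wk[[j]])
        alH <- alignedKernelCosine(Hk[[i]], Hk[[j]])
        shifts <- list()
        if (alW$cos >= 0.3) shifts <- c(shifts, list(c(alW$df, alW$dt)))
        if (alH$cos >= 0.3) shifts <- c(shifts, list(c(-alH$df, -alH$dt)))
        if (!length(shifts)) next
        zi <- z[i] + z[j]
        Vothers <- matrix(bg, Fn, Tn)
        for (k in which(alive))
          if (k != i && k != j)
            Vothers <- Vothers + (1 - bgGamma) * z[k] * convs[[k]]
        ## shift convention: W_j(x) ~ W_i(x + sh), so W_j pools into i's
        ## frame shifted by +sh and H_j counter-shifted by -sh. Each
        ## alignment is also tried in j's frame (roles swapped): when a
        ## counter-shifted activation cell would fall off the grid in one
        ## frame it may fit in the other.
        cands <- list()
        for (sh in unique(shifts)) {
          cands <- c(cands, list(
            list(W = z[i] * Wk[[i]] +
                   z[j] * shiftMatrix(Wk[[j]], sh[1L], sh[2L]),
                 H = z[i] * Hk[[i]] +
                   z[j] * shiftMatrix(Hk[[j]], -sh[1L], -sh[2L])),
            list(W = z[j] * Wk[[j]] +
                   z[i] * shiftMatrix(Wk[[i]], -sh[1L], -sh[2L]),
                 H = z[j] * Hk[[j]] +
                   z[i] * shiftMatrix(Hk[[i]], sh[1L], sh[2L]))))
        }
        for (cnd in cands) {
          Wc <- cnd$W; Hc <- cnd$H
          if (sum(Wc) <= 0 || sum(Hc) <= 0) next
          ## partial EM refinement of the pooled component, others fixed
          Wi <- Wc / sum(Wc); Hi <- Hc / sum(Hc)
          for (r in seq_len(nRefine)) {
            Vh <- Vothers + (1 - bgGamma) * zi * conv2Full(Wi, Hi)
            Rr <- ifelse(V > 0, V / Vh, 0)
            nw <- pmax(Wi * xcorr2Valid(Rr, Hi), 0)
            nh <- pmax(Hi * xcorr2Valid(Rr, Wi), 0)
            if (sum(nw) <= 0) break
            Wi <- nw / sum(nw)
            Hi <- zeroTinyCells(matrix(
              solveWeightStep(as.numeric(nh),
                              lambdaH / (as.numeric(Hi) + epsH)),
              nrow(Hi), ncol(Hi)))
            if (sum(Hi) <= 0) break
          }
          if (sum(Hi) <= 0) next
          zt <- z; zt[i] <- zi; zt[j] <- 0
          Ht <- Hk; Ht[[i]] <- Hi
          at <- alive; at[j] <- FALSE
          Vh <- Vothers + (1 - bgGamma) * zi * conv2Full(Wi, Hi)
          Jc <- klDivergence(V, Vh) + penaltyH(Ht, at, lambdaH, epsH)
          if (Jc <= base) {
            Wk[[i]] <- Wi; Hk <- Ht; z <- zt; alive[j] <- FALSE
            convs[[i]] <- conv2Full(Wi, Hi)
            base <- Jc
            changed <- TRUE
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  list(Wk = Wk, Hk = Hk, z = z, alive = alive, changed = changed,
       objective = base)
}

#' Fit a shift-invariant 2D PLCA model
#'
#' EM for the convolutive model
#' `V(f,t) ~ sum_k z_k sum_{phi,tau} kernel_k(f-phi, tau) activation_k(phi, t-tau)`
#' with latent variables (component k, frequency shift phi, time offset tau).
#' Every kernel, every activation map and the weight vector are probability
#' distributions (each sums to 1) after every iteration.
#'
#' With `alpha < 1` a Dirichlet-style sparsity prior is placed on the
#' activation maps: the penalized objective
#' `KL(V || Vhat) + ((1 - alpha) / 2) * sum_k sum_ij log(H_k[ij] + epsH)`
#' is minimized, the concave log penalty handled by an exact
#' minorize-maximize step inside each M-step, so the penalized objective is
#' non-increasing at every iteration. The penalty soft-thresholds the
#' expected counts, favouring few, strong placements per component (without
#' it, one near-delta kernel with a dense activation map can copy the input
#' wholesale). Components describing the same recurring patch are collapsed
#' by merge moves that pool two components' kernels and activations along
#' their best 2D alignment, refine the pooled component by a few partial EM
#' steps, and are accepted only when the penalized objective does not
#' increase. Components left with negligible weight are removed by
#' [pruneComponents()]. Together these form the automatic relevance
#' determination strategy: start with many components, keep the ones the
#' data support. `alpha = 1` is plain EM (objective = KL divergence, no
#' merges).
#'
#' @param V Non-negative matrix (or [Spectrogram-class]); normalized
#'   internally.
#' @param kMax Maximum number of components; default 16.
#' @param kernelShape Integer length-2, strictly smaller than `dim(V)`;
#'   default `(round(nrow/3), min(8, ncol-1))`.
#' @param alpha Sparsity hyper-parameter in (0, 1]; default 0.98.
#' @param nIters Maximum EM iterations; default 200.
#' @param tol Relative objective change at which to stop; default 1e-5.
#' @param seed RNG seed for the strictly positive random initialization
#'   (required, recorded in the model).
#' @return A [SIPLCA2DModel-class] with components ordered by descending z.
#' @examples
#' W <- matrix(c(4, 1, 0, 2), 2, 2); W <- W / sum(W)
#' H <- matrix(0, 3, 6); H[2, 3] <- 1
#' V <- conv2Full(W, H)
#' m <- siplca2dFit(V, kMax = 4, kernelShape = c(2, 2), nIters = 60, seed = 1)
#' @export
siplca2dFit <- function(V, kMax = 16L, kernelShape = NULL, alpha = 0.98,
                        nIters = 200L, tol = 1e-5, seed = 1L) {
  V <- normalizeInput(V)
  if (any(is.na(V))) stop("NaN in input", call. = FALSE)
  if (!isScalar(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("'kMax' must be >= 1", call. = FALSE)
  Fn <- nrow(V); Tn <- ncol(V)
  if (is.null(kernelShape))
    kernelShape <- c(max(2L, round(Fn / 3)), min(8L, Tn - 1L))
  kernelShape <- as.integer(kernelShape)
  if (kernelShape[1L] >= Fn || kernelShape[2L] >= Tn ||
      any(kernelShape < 1L))
    stop("'kernelShape' must be strictly smaller than dim(V)", call. = FALSE)
  V <- cleanV(V)
  Fk <- kernelShape[1L]; Tk <- kernelShape[2L]
  Phi <- Fn - Fk + 1L; Ta <- Tn - Tk + 1L
  ## Dirichlet-style sparsity prior on the activation maps: a concave log
  ## penalty whose exact MM step soft-thresholds expected counts, favouring
  ## few, strong placements per component. It breaks the delta-kernel
  ## degeneracy (one near-delta kernel with a dense activation copying V
  ## wholesale); together with the accept-if-better merge moves and the
  ## post-fit weight floor it forms the automatic relevance determination
  ## strategy. The mixing weights themselves follow the plain EM counts: a
  ## direct weight tax would snowball whichever component leads early and
  ## bias the recovered weights away from the posterior mass.
  sparse <- alpha < 1
  lambdaH <- (1 - alpha) / 2
  epsH <- 1e-6
  bg <- bgGamma / (Fn * Tn)

  ## FFT pad sizes reused every iteration
  prH <- goodSize(Fn + Phi - 1L); pcH <- goodSize(Tn + Ta - 1L)
  prW <- goodSize(Fn + Fk - 1L);  pcW <- goodSize(Tn + Tk - 1L)

  withSeed(seed, {
    Wk <- seedKernels(V, kMax, Fk, Tk)
    ## matched-filter activation init: each component starts concentrated
    ## where its kernel matches the data (squared to sharpen), so the first
    ## posterior competition is alignment-driven. A flat init instead lets
    ## smooth kernels out-claim sharp ones by integrating over many shifts.
    Hk <- lapply(seq_len(kMax), function(k) {
      h <- xcorr2Valid(V, Wk[[k]])^2 *
        matrix(stats::runif(Phi * Ta, 0.95, 1.05), Phi, Ta)
      h <- pmax(h, max(h) * 1e-6)
      h / sum(h)
    })
    z <- rep(1 / kMax, kMax)
    obj <- numeric(0)
    alive <- rep(TRUE, kMax)

    for (it in seq_len(nIters)) {
      Vhat <- matrix(bg, Fn, Tn)
      for (k in which(alive))
        Vhat <- Vhat + (1 - bgGamma) * z[k] * conv2Full(Wk[[k]], Hk[[k]])
      kl <- klDivergence(V, Vhat)
      pen <- if (sparse) penaltyH(Hk, alive, lambdaH, epsH) else 0
      obj <- c(obj, kl + pen)

      ## Merge step: two components carrying the same recurring patch with
      ## disjoint activation supports are a stable local optimum the
      ## multiplicative updates cannot leave. A merge candidate pools their
      ## activations with the aligning kernel shift, refines the pooled
      ## component by a few partial EM steps (others held fixed), and is
      ## accepted only if the refined penalized objective does not exceed
      ## the current one — so the recorded objective stays non-increasing.
      ## merges start only once the activation maps have sparsified: while
      ## they are still dense, flooring a killed component's map would make
      ## any merge look profitable regardless of reconstruction cost
      if (sparse && it %% 10L == 0L && it >= 20L && sum(alive) > 1L) {
        st <- list(Wk = Wk, Hk = Hk, z = z, alive = alive)
        st <- mergeComponentPairs(st, V, obj[it], bg, lambdaH, epsH)
        if (st$changed) {
          Wk <- st$Wk; Hk <- st$Hk; z <- st$z; alive <- st$alive
          Vhat <- matrix(bg, Fn, Tn)
          for (k in which(alive))
            Vhat <- Vhat + (1 - bgGamma) * z[k] * conv2Full(Wk[[k]], Hk[[k]])
        }
      }

      R <- ifelse(V > 0, V / Vhat, 0)
      fftRH <- fft2(padTo(R, prH, pcH))
      fftRW <- fft2(padTo(R, prW, pcW))
      nk <- numeric(kMax)
      newW <- Wk; newH <- Hk
      for (k in which(alive)) {
        nw <- Wk[[k]] * xcorr2Valid(R, Hk[[k]], fftBig = fftRH,
                                    pr = prH, pc = pcH) * z[k]
        nh <- Hk[[k]] * xcorr2Valid(R, Wk[[k]], fftBig = fftRW,
                                    pr = prW, pc = pcW) * z[k]
        nw <- pmax(nw, 0); nh <- pmax(nh, 0)   # guard FFT round-off
        nk[k] <- sum(nw)
        if (nk[k] > 0) {
          newW[[k]] <- nw / nk[k]
          newH[[k]] <- if (sparse) {
            zeroTinyCells(matrix(
              solveWeightStep(as.numeric(nh),
                              lambdaH / (as.numeric(Hk[[k]]) + epsH)),
              Phi, Ta))
          } else nh / max(sum(nh), 1e-300)
        }
      }
      Wk <- newW; Hk <- newH
      if (sum(nk) > 0) z <- nk / sum(nk)
      dead <- alive & z < 1e-12
      if (any(dead)) { alive[dead] <- FALSE; z[dead] <- 0; z <- z / sum(z) }
      if (it > 1L) {
        d <- obj[it - 1L] - obj[it]
        if (abs(d) < tol * max(abs(obj[it]), 1e-12)) {
          ## before declaring convergence, see whether a merge still helps
          if (sparse && sum(alive) > 1L && it < nIters) {
            Vh <- matrix(bg, Fn, Tn)
            for (k in which(alive))
              Vh <- Vh + (1 - bgGamma) * z[k] * conv2Full(Wk[[k]], Hk[[k]])
            Jcur <- klDivergence(V, Vh) +
              penaltyH(Hk, alive, lambdaH, epsH)
            st <- mergeComponentPairs(list(Wk = Wk, Hk = Hk, z = z,
                                           alive = alive),
                                      V, Jcur, bg, lambdaH, epsH)
            if (st$changed) {
              Wk <- st$Wk; Hk <- st$Hk; z <- st$z; alive <- st$alive
              next
            }
          }
          break
        }
      }
    }
    ord <- order(z, decreasing = TRUE)
    keep <- ord[z[ord] > 0]
    new("SIPLCA2DModel",
        kernels = Wk[keep], activations = Hk[keep],
        z = z[keep] / sum(z[keep]),
        kMax = kMax, alpha = alpha, kernelShape = kernelShape,
        vDim = c(Fn, Tn), objective = obj, seed = as.numeric(seed))
  })
}

#' Prune negligible components from a fitted model
#'
#' Drops components whose mixing weight falls below `zFloor` and renormalizes
#' the remaining weights — the explicit half of the automatic relevance
#' determination strategy (the sparsity prior does the shrinking, pruning
#' removes what it shrank).
#'
#' @param model A [SIPLCA2DModel-class].
#' @param zFloor Weight threshold; default 1e-3.
#' @return The pruned [SIPLCA2DModel-class].
#' @export
pruneComponents <- function(model, zFloor = 1e-3) {
  stopifnot(is(model, "SIPLCA2DModel"))
  keep <- model@z >= zFloor
  if (!any(keep))
    stop("all components below the floor: degenerate model", call. = FALSE)
  new("SIPLCA2DModel",
      kernels = model@kernels[keep], activations = model@activations[keep],
      z = model@z[keep] / sum(model@z[keep]),
      kMax = model@kMax, alpha = model@alpha,
      kernelShape = model@kernelShape, vDim = model@vDim,
      objective = model@objective, seed = model@seed)
}

#' Reconstruction of a single component
#'
#' `z_k * (kernel_k convolved with activation_k)`, in the shape of the fitted
#' matrix. The sum over all components is the full model reconstruction.
#'
#' @param model A [SIPLCA2DModel-class].
#' @param k Component index in `1..kEffective(model)`.
#' @return A non-negative matrix of `model@vDim`.
#' @export
componentReconstruction <- function(model, k) {
  stopifnot(is(model, "SIPLCA2DModel"))
  k <- as.integer(k)
  if (k < 1L || k > kEffective(model))
    stop("component index out of range", call. = FALSE)
  pmax(model@z[k] * conv2Full(model@kernels[[k]], model@activations[[k]]), 0)
}

#' Full model reconstruction
#'
#' @param model A [SIPLCA2DModel-class].
#' @return A non-negative matrix of `model@vDim` summing to ~1.
#' @export
modelReconstruction <- function(model) {
  stopifnot(is(model, "SIPLCA2DModel"))
  out <- matrix(0, model@vDim[1L], model@vDim[2L])
  for (k in seq_len(kEffective(model)))
    out <- out + componentReconstruction(model, k)
  out
}

#' Entropies of the fitted distributions
#'
#' Normalized Shannon entropy (in [0, 1]) of every kernel and every
#' activation map (flattened) and of the weight vector — the per-component
#' summary statistics returned alongside a decomposition.
#'
#' @param model A [SIPLCA2DModel-class] or [PLCAModel-class].
#' @return A list with `kernel` and `activation` (numeric per component) and
#'   `z` (scalar).
#' @export
modelEntropies <- function(model) {
  if (is(model, "PLCAModel")) {
    kern <- apply(model@W, 2L, shannonEntropy, normalized = TRUE)
    act <- apply(model@H, 1L, shannonEntropy, normalized = TRUE)
    zent <- if (length(model@z) > 1L) shannonEntropy(model@z, TRUE) else 0
    return(list(kernel = unname(kern), activation = unname(act), z = zent))
  }
  stopifnot(is(model, "SIPLCA2DModel"))
  kern <- vapply(model@kernels, function(w) shannonEntropy(as.numeric(w), TRUE),
                 numeric(1))
  act <- vapply(model@activations,
                function(h) shannonEntropy(as.numeric(h), TRUE), numeric(1))
  zent <- if (length(model@z) > 1L) shannonEntropy(model@z, TRUE) else 0
  list(kernel = kern, activation = act, z = zent)
}

#' Sample evenly spaced analysis windows and concatenate their spectrograms
#'
#' Extracts `nWindows` windows of `windowSeconds` from across the recording
#' (evenly spaced, in order), constant-Q transforms each, and concatenates
#' them along time — the protocol for summarizing a long field recording in
#' one decomposable matrix. The time axis of the result is a continuous
#' frame-index axis (windows are abutted).
#'
#' @param sig An [AudioSignal-class] at least `nWindows * windowSeconds` long.
#' @param nWindows Number of windows; default 16.
#' @param windowSeconds Window length in seconds; default 4.
#' @param fmin,binsPerOctave,hop Constant-Q parameters (see
#'   [constantQSpectrogram()]).
#' @return A log-frequency [Spectrogram-class].
#' @export
sampleAnalysisWindows <- function(sig, nWindows = 16L, windowSeconds = 4,
                                  fmin = 110, binsPerOctave = 24L,
                                  hop = 1024L) {
  stopifnot(is(sig, "AudioSignal"))
  nWindows <- as.integer(nWindows)
  win <- round(windowSeconds * rate(sig))
  n <- length(samples(sig))
  if (n < nWindows * win)
    stop("signal shorter than nWindows * windowSeconds", call. = FALSE)
  starts <- if (nWindows == 1L) 1L
            else round(seq(1L, n - win + 1L, length.out = nWindows))
  specs <- lapply(starts, function(s) {
    constantQSpectrogram(AudioSignal(samples(sig)[s:(s + win - 1L)],
                                     rate(sig)),
                         fmin, binsPerOctave, hop)
  })
  vals <- do.call(cbind, lapply(specs, specValues))
  dt <- hop / rate(sig)
  Spectrogram(vals, specFreqs(specs[[1L]]),
              (seq_len(ncol(vals)) - 1L) * dt, scale = "log")
}
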