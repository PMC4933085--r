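test_that("input normalization produces a probability matrix", {
  expect_equal(normalizeInput(matrix(1, 2, 2)), matrix(0.25, 2, 2))
  withr::with_seed(1, v <- matrix(runif(30), 5, 6))
  expect_equal(normalizeInput(v), normalizeInput(10 * v))
  expect_equal(sum(normalizeInput(v)), 1, tolerance = 1e-12)
  expect_error(normalizeInput(matrix(0, 3, 3)), "zero")
  expect_error(normalizeInput(matrix(c(1, -1, 1, 1), 2, 2)), "non-negative")
})

test_that("PLCA recovers exact low-rank structure", {
  ## rank-1: factors recovered exactly
  w <- c(0.5, 0.25, 0.25); h <- c(0.3, 0.7)
  m <- plcaFit(outer(w, h), K = 1, seed = 1)
  expect_equal(as.numeric(m@W), w, tolerance = 1e-8)
  expect_equal(as.numeric(m@H), h, tolerance = 1e-8)
  expect_lt(tail(objectiveTrace(m), 1), 1e-10)

  ## two components with disjoint supports: z recovered up to permutation
  w1 <- c(0.6, 0.4, 0, 0); h1 <- c(0.5, 0.5, 0, 0, 0)
  w2 <- c(0, 0, 0.3, 0.7); h2 <- c(0, 0, 0.2, 0.3, 0.5)
  V <- 0.6 * outer(w1, h1) + 0.4 * outer(w2, h2)
  m <- plcaFit(V, K = 2, nIters = 500L, tol = 1e-12, seed = 3)
  expect_equal(sort(m@z, decreasing = TRUE), c(0.6, 0.4), tolerance = 1e-6)

  expect_warning(plcaFit(matrix(runif(12), 3, 4), K = 5, seed = 1),
                 "overcomplete")
})

test_that("PLCA normalization invariants hold and KL never increases", {
  withr::with_seed(10, {
    for (i in 1:5) {
      V <- matrix(runif(8 * 12)^2, 8, 12)
      m <- plcaFit(V, K = 3, nIters = 80L, seed = i)
      expect_true(objectiveIsMonotone(objectiveTrace(m)))
      expect_equal(colSums(m@W), rep(1, 3), tolerance = 1e-6)
      expect_equal(rowSums(m@H), rep(1, 3), tolerance = 1e-6)
      expect_equal(sum(m@z), 1, tolerance = 1e-6)
    }
  })
})

test_that("SI-PLCA2D recovers a single planted kernel and prunes to k = 1", {
  W <- matrix(c(4, 1, 0, 2), 2, 2); W <- W / sum(W)
  H <- matrix(0, 5, 12); H[3, 4] <- 1
  V <- conv2Full(W, H)
  fit <- pruneComponents(siplca2dFit(V, kMax = 4, kernelShape = c(2, 2),
                                     nIters = 200, seed = 3))
  expect_identical(kEffective(fit), 1L)
  expect_gte(alignedCos(kernels(fit)[[1]], W), 0.99)
  expect_true(objectiveIsMonotone(objectiveTrace(fit)))
})

test_that("SI-PLCA2D model distributions stay normalized during fitting", {
  withr::with_seed(20, V <- matrix(runif(24 * 60), 24, 60))
  m <- siplca2dFit(V, kMax = 6, kernelShape = c(8, 5), nIters = 40, seed = 2)
  for (k in seq_len(kEffective(m))) {
    expect_equal(sum(kernels(m)[[k]]), 1, tolerance = 1e-6)
    expect_equal(sum(activations(m)[[k]]), 1, tolerance = 1e-6)
  }
  expect_equal(sum(mixingWeights(m)), 1, tolerance = 1e-6)
  expect_equal(sum(modelReconstruction(m)), 1, tolerance = 1e-5)
  expect_error(siplca2dFit(V, kMax = 4, kernelShape = c(30, 5), seed = 1),
               "kernelShape")
  expect_error(siplca2dFit(V, alpha = 0, seed = 1), "alpha")
})

test_that("identical seeds give identical SI-PLCA2D fits", {
  gen <- syntheticComponentModel(2, seed = 7)
  m1 <- siplca2dFit(gen$V, kMax = 8, kernelShape = c(16, 8), nIters = 40,
                    seed = 11)
  m2 <- siplca2dFit(gen$V, kMax = 8, kernelShape = c(16, 8), nIters = 40,
                    seed = 11)
  expect_identical(kernels(m1), kernels(m2))
  expect_identical(activations(m1), activations(m2))
  expect_identical(mixingWeights(m1), mixingWeights(m2))
})

test_that("pruning drops negligible components and barely moves the fit", {
  gen <- syntheticComponentModel(2, seed = 3)
  m <- siplca2dFit(gen$V, kMax = 8, kernelShape = c(16, 8), nIters = 150,
                   seed = 4)
  pruned <- pruneComponents(m, 1e-3)
  expect_lte(kEffective(pruned), kEffective(m))
  ## reconstruction change from dropping z < 1e-3 mass is tiny
  d <- sum(abs(modelReconstruction(pruned) - modelReconstruction(m)))
  expect_lt(d, 5e-3)
  expect_equal(pruneComponents(m, 0), m)

  zs <- c(0.5, 0.5, 1e-9) / sum(c(0.5, 0.5, 1e-9))
  toy <- new("SIPLCA2DModel",
             kernels = rep(list(matrix(0.25, 2, 2)), 3),
             activations = rep(list(matrix(1, 1, 1)), 3),
             z = sort(zs, decreasing = TRUE), kMax = 4L, alpha = 0.98,
             kernelShape = c(2L, 2L), vDim = c(2L, 2L),
             objective = 1, seed = 1)
  out <- pruneComponents(toy, 1e-3)
  expect_identical(kEffective(out), 2L)
  expect_equal(mixingWeights(out), c(0.5, 0.5))
  expect_error(pruneComponents(toy, 2), "degenerate")
})

test_that("component reconstructions partition the full reconstruction", {
  gen <- syntheticComponentModel(2, seed = 5)
  m <- pruneComponents(siplca2dFit(gen$V, kMax = 8, kernelShape = c(16, 8),
                                   nIters = 150, seed = 6))
  total <- Reduce(`+`, lapply(seq_len(kEffective(m)),
                              function(k) componentReconstruction(m, k)))
  expect_equal(total, modelReconstruction(m), tolerance = 1e-9)
  expect_error(componentReconstruction(m, kEffective(m) + 1L), "range")

  ## single-component model: component equals the full reconstruction
  if (kEffective(m) >= 1) {
    one <- pruneComponents(m, max(mixingWeights(m)) - 1e-9)
    expect_equal(componentReconstruction(one, 1), modelReconstruction(one))
  }
})

test_that("model entropies match the shared Shannon oracle", {
  spike <- matrix(0, 3, 3); spike[2, 2] <- 1
  toy <- new("SIPLCA2DModel",
             kernels = list(spike, matrix(1 / 9, 3, 3)),
             activations = list(matrix(1 / 12, 3, 4), matrix(1 / 12, 3, 4)),
             z = c(0.5, 0.5), kMax = 2L, alpha = 1,
             kernelShape = c(3L, 3L), vDim = c(5L, 7L),
             objective = 1, seed = 1)
  ent <- modelEntropies(toy)
  expect_equal(ent$kernel, c(0, 1))
  expect_equal(ent$activation, c(1, 1))
  expect_equal(ent$z, 1)

  gen <- syntheticComponentModel(2, seed = 9)
  m <- pruneComponents(siplca2dFit(gen$V, kMax = 8, kernelShape = c(16, 8),
                                   nIters = 100, seed = 2))
  ent <- modelEntropies(m)
  expect_equal(ent$kernel,
               vapply(kernels(m), function(w)
                 shannonEntropy(as.numeric(w), normalized = TRUE),
                 numeric(1)))
  expect_true(all(unlist(ent) >= 0 & unlist(ent) <= 1))
})

test_that("time-shifting the input leaves kernels unchanged", {
  gen <- syntheticComponentModel(2, seed = 21)
  V1 <- gen$V
  V2 <- cbind(0, V1[, -ncol(V1)])           # one-frame delay, content interior
  f1 <- pruneComponents(siplca2dFit(V1, kMax = 8, kernelShape = c(16, 8),
                                    nIters = 150, seed = 9))
  f2 <- pruneComponents(siplca2dFit(V2, kMax = 8, kernelShape = c(16, 8),
                                    nIters = 150, seed = 9))
  expect_identical(kEffective(f1), kEffective(f2))
  for (w1 in kernels(f1)) {
    best <- max(vapply(kernels(f2), alignedCos, numeric(1), a = w1))
    expect_gte(best, 0.99)
  }
})

test_that("analysis windows are sampled evenly and concatenated in order", {
  sig <- whiteNoise(4, rate = 22050, seed = 30)
  sp <- sampleAnalysisWindows(sig, nWindows = 4L, windowSeconds = 1,
                              fmin = 500, binsPerOctave = 12L, hop = 2048L)
  one <- constantQSpectrogram(AudioSignal(samples(sig)[1:22050], 22050),
                              fmin = 500, binsPerOctave = 12L, hop = 2048L)
  expect_identical(ncol(specValues(sp)), 4L * ncol(specValues(one)))
  expect_identical(sp@scale, "log")
  expect_true(all(diff(specTimes(sp)) > 0))
  ## first window equals a direct transform of the signal head
  expect_equal(specValues(sp)[, seq_len(ncol(specValues(one)))],
               specValues(one), tolerance = 1e-10)
  expect_error(sampleAnalysisWindows(sig, nWindows = 16L, windowSeconds = 4),
               "shorter")
})
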