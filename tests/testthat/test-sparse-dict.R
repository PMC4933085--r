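test_that("patch extraction tiles row-major with boundary snapping", {
  m <- matrix(seq_len(64), 8, 8)
  ps4 <- extractPatches(m, c(4, 4), 4)
  expect_length(patches(ps4), 4L)
  ps2 <- extractPatches(m, c(4, 4), 2)
  expect_length(patches(ps2), 9L)

  ## reassembling the non-overlapping tiling reproduces the source
  acc <- matrix(0, 8, 8)
  for (i in seq_along(patches(ps4))) {
    o <- ps4@origins[i, ]
    acc[o[1]:(o[1] + 3), o[2]:(o[2] + 3)] <- patches(ps4)[[i]]
  }
  expect_identical(acc, m + 0)
  expect_error(extractPatches(m, c(9, 4)), "larger")
})

test_that("Gabor atoms are unit-norm, Gaussian at zero frequency, and
           antisymmetric under a half-turn", {
  g0 <- gaborAtom(c(9, 9), theta = 0.3, freq = 0, phase = 0, sigma = 2)
  ## zero modulation, zero phase: proportional to a pure 2D Gaussian
  y <- matrix(seq_len(9) - 5, 9, 9); x <- t(y)
  gauss <- exp(-(x^2 + y^2) / (2 * 2^2))
  expect_equal(g0, gauss / sqrt(sum(gauss^2)), tolerance = 1e-12)

  dict <- gaborDictionary(c(12, 12), nOrientations = 4L, nScales = 3L,
                          nPhases = 2L)
  expect_length(atoms(dict), 24L)
  norms <- vapply(atoms(dict), function(a) sqrt(sum(a^2)), numeric(1))
  expect_true(all(abs(norms - 1) < 1e-9))

  ## orientation theta and theta + pi give the same atom up to sign/phase
  a1 <- gaborAtom(c(11, 11), theta = 0.7, freq = 0.2, phase = 0)
  a2 <- gaborAtom(c(11, 11), theta = 0.7 + pi, freq = 0.2, phase = 0)
  expect_equal(a1, a2, tolerance = 1e-10)   # cos is even: identical here
  b1 <- gaborAtom(c(11, 11), theta = 0.7, freq = 0.2, phase = pi / 2)
  b2 <- gaborAtom(c(11, 11), theta = 0.7 + pi, freq = 0.2, phase = pi / 2)
  expect_equal(b1, -b2, tolerance = 1e-10)  # sine part flips sign
})

test_that("OMP selects, refits and leaves an orthogonal residual", {
  dict <- gaborDictionary(c(8, 8), nOrientations = 6L, nScales = 3L,
                          nPhases = 2L)
  D <- vapply(atoms(dict), as.numeric, numeric(64))

  ## single-atom identity
  code <- omp(3.7 * atoms(dict)[[5]], dict, sparsity = 3)
  expect_identical(code$atoms[1], 5L)
  expect_equal(code$coefs[1], 3.7, tolerance = 1e-9)
  expect_lt(code$residualNorm, 1e-9)

  ## patch orthogonal to every atom: empty code, residual unchanged
  withr::with_seed(1, x <- qr.Q(qr(cbind(D, rnorm(64))))[, ncol(D) + 1])
  code <- omp(matrix(x, 8, 8), dict, sparsity = 3)
  expect_length(code$atoms, 0L)
  expect_equal(code$residualNorm, sqrt(sum(x^2)), tolerance = 1e-9)

  ## two near-orthogonal atoms recovered with least-squares coefficients
  i <- 1L; j <- 15L
  patch <- 2 * atoms(dict)[[i]] + 1 * atoms(dict)[[j]]
  code <- omp(patch, dict, sparsity = 2)
  expect_setequal(code$atoms, c(i, j))
  ls <- qr.solve(D[, code$atoms], as.numeric(patch))
  expect_equal(code$coefs, as.numeric(ls), tolerance = 1e-6)

  ## residual orthogonality at the final step
  withr::with_seed(2, patch <- matrix(runif(64), 8, 8))
  code <- omp(patch, dict, sparsity = 6)
  expect_lt(max(abs(crossprod(D[, code$atoms], code$residual))), 1e-8)
  expect_error(omp(patch, dict, sparsity = 100), "exceeds")
})

test_that("OMP exactly recovers sparse codes over an incoherent dictionary", {
  withr::with_seed(99, {
    d <- 256L; nAtoms <- 384L
    D <- matrix(rnorm(d * nAtoms), d, nAtoms)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    G <- abs(crossprod(D)); diag(G) <- 0
    mu <- max(G)
    ## exact recovery is guaranteed for s < (1 + 1/mu)/2
    sMax <- floor((1 + 1 / mu - 1e-9) / 2)
    expect_gte(sMax, 2L)
    alist <- lapply(seq_len(nAtoms), function(j) matrix(D[, j], 16, 16))
    dict <- new("Dictionary", atoms = alist, patchShape = c(16L, 16L),
                kind = "learned")
    for (trial in 1:25) {
      s <- sample(seq_len(sMax), 1)
      supp <- sample(nAtoms, s)
      coefs <- runif(s, 0.5, 2) * sample(c(-1, 1), s, replace = TRUE)
      x <- D[, supp, drop = FALSE] %*% coefs
      code <- omp(matrix(x, 16, 16), dict, sparsity = s)
      expect_setequal(code$atoms, supp)
      expect_lt(code$residualNorm, 1e-8)
    }
  })
})

test_that("mini-batch dictionary learning recovers planted templates", {
  tmplA <- gaborAtom(c(8, 8), theta = 0, freq = 0.25, sigma = 2)
  tmplB <- gaborAtom(c(8, 8), theta = pi / 2, freq = 0.25, sigma = 2)
  cosim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

  ## identical patches: some atom converges onto the template
  plist <- rep(list(3 * tmplA), 40)
  dict <- learnDictionary(plist, nAtoms = 4L, nEpochs = 20L, sparsity = 1L,
                          seed = 5)
  best <- max(vapply(atoms(dict), cosim, numeric(1), b = tmplA))
  expect_gte(best, 0.99)

  ## two orthogonal templates, both recovered among the atoms
  withr::with_seed(8, {
    plist <- lapply(1:60, function(i)
      if (i %% 2) tmplA * runif(1, 1, 3) else tmplB * runif(1, 1, 3))
  })
  dict <- learnDictionary(plist, nAtoms = 4L, nEpochs = 25L, sparsity = 1L,
                          seed = 6)
  bestA <- max(vapply(atoms(dict), cosim, numeric(1), b = tmplA))
  bestB <- max(vapply(atoms(dict), cosim, numeric(1), b = tmplB))
  expect_gte(bestA, 0.95)
  expect_gte(bestB, 0.95)

  ## unit norms survive learning, and identical seeds reproduce exactly
  norms <- vapply(atoms(dict), function(a) sqrt(sum(a^2)), numeric(1))
  expect_true(all(abs(norms - 1) < 1e-9))
  dict2 <- learnDictionary(plist, nAtoms = 4L, nEpochs = 25L, sparsity = 1L,
                           seed = 6)
  expect_identical(atoms(dict), atoms(dict2))
  expect_error(learnDictionary(list(matrix(0, 4, 4)), seed = 1), "zero")
})

test_that("sparse approximation reconstructs and improves with sparsity", {
  ## complete canonical basis reproduces the input exactly
  basis <- lapply(seq_len(16), function(i) {
    m <- matrix(0, 4, 4); m[i] <- 1; m
  })
  dict <- new("Dictionary", atoms = basis, patchShape = c(4L, 4L),
              kind = "learned")
  withr::with_seed(13, v <- matrix(runif(64), 8, 8))
  ap <- approximateSpectrogram(v, dict, sparsity = 16L, stride = 4L)
  expect_lt(ap$relativeError, 1e-10)
  expect_true(all(ap$reconstruction >= 0))

  ## reconstruction error non-increasing in s; Gabor dict beats s = 1
  gd <- gaborDictionary(c(8, 8), nOrientations = 6L, nScales = 3L,
                        nPhases = 2L)
  withr::with_seed(14, v16 <- matrix(runif(256), 16, 16))
  errs <- vapply(c(1L, 4L, 8L), function(s)
    approximateSpectrogram(v16, gd, sparsity = s, stride = 8L)$relativeError,
    numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[3], errs[1])
})

test_that("dictionary CSV archive round-trips", {
  dict <- gaborDictionary(c(6, 6), nOrientations = 3L, nScales = 2L,
                          nPhases = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDictionaryCSV(dict, f)
  back <- readDictionaryCSV(f)
  expect_equal(atoms(back), atoms(dict), tolerance = 1e-12)
  expect_identical(back@kind, "gabor")
})
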