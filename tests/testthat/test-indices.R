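test_that("Shannon entropy matches closed forms and the brute-force oracle", {
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(rep(1, 10)), log(10))
  expect_equal(shannonEntropy(rep(1, 10), normalized = TRUE), 1)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_equal(shannonEntropy(c(5), normalized = TRUE), 0)  # R = 1 convention

  bruteH <- function(p) {
    p <- p / sum(p)
    -sum(vapply(p, function(q) if (q > 0) q * log(q) else 0, numeric(1)))
  }
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- runif(sample(2:30, 1))^2
      expect_equal(shannonEntropy(p), bruteH(p), tolerance = 1e-12)
    }
  })
})

test_that("Gini matches the O(n^2) pairwise-difference oracle", {
  expect_equal(gini(rep(1, 7)), 0)
  p <- c(1, rep(0, 9))
  expect_equal(gini(p), 0.9)
  expect_equal(gini(c(1, 3)), 0.25)

  bruteG <- function(p) {
    n <- length(p)
    sum(outer(p, p, function(a, b) abs(a - b))) / (2 * n * sum(p))
  }
  withr::with_seed(11, {
    for (i in 1:200) {
      p <- runif(sample(2:25, 1))^2
      expect_equal(gini(p), bruteG(p), tolerance = 1e-12)
    }
  })
  expect_error(gini(c(0, 0)), "positive")
})

test_that("spectral and temporal entropies behave as normalized entropies", {
  expect_equal(spectralEntropy(SpectrumProfile(c(0, 3, 0, 0), 1:4)), 0)
  expect_equal(spectralEntropy(SpectrumProfile(rep(2, 64), 1:64)), 1)
  p <- numeric(512); p[c(10, 200)] <- 1
  expect_equal(spectralEntropy(SpectrumProfile(p, 1:512)),
               log(2) / log(512))
  expect_error(spectralEntropy(SpectrumProfile(numeric(4), 1:4)), "zero")

  expect_equal(temporalEntropy(Envelope(rep(0.3, 100), 100)), 1)
  expect_equal(temporalEntropy(Envelope(c(0, 1, 0, 0), 100)), 0)
  e <- c(2, 1, 1)
  expect_equal(temporalEntropy(Envelope(e, 10)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3))
})

test_that("acoustic entropy is ~0 for pure tones and high but <= 1 for noise", {
  tone <- binTone(86, duration = 2)
  ae <- acousticEntropy(tone, 512, 256, "rectangular")
  expect_lt(ae$h, 1e-6)
  expect_equal(ae$h, ae$sh * ae$th)

  noise <- whiteNoise(5, seed = 2)
  ae <- acousticEntropy(noise)
  expect_gt(ae$h, 0.95)
  expect_lte(ae$h, 1)

  expect_error(acousticEntropy(AudioSignal(numeric(44100), 44100)),
               "silent")
})

test_that("NDSI hits its extremes and zero by band symmetry", {
  expect_equal(ndsi(toneSignal(5000, 1)), 1, tolerance = 1e-6)
  expect_equal(ndsi(toneSignal(1000, 1)), -1, tolerance = 1e-6)

  ## equal power in both bands
  two <- AudioSignal(samples(toneSignal(1000, 1)) / 2 +
                     samples(toneSignal(5000, 1)) / 2, 44100)
  expect_equal(ndsi(two), 0, tolerance = 1e-3)
  expect_error(ndsi(toneSignal(10000, 1), bandSplit(200, 2000, 2000, 8000),
                    winLen = 512L),
               NA)  # in-band power present, no error
})

test_that("band occupancy proportions count cells above threshold", {
  ## constructed 20-bin x 10-frame spectrogram split into 2 bands:
  ## half of band 1's cells and all of band 2's cells above threshold
  v <- matrix(0, 20, 10)
  v[1:10, 1:5] <- 1          # half of band 1 above
  v[11:20, ] <- 1            # all of band 2 above
  sp <- Spectrogram(v, seq(100, 2000, length.out = 20),
                    seq(0.1, 1, length.out = 10))
  bp <- bandProportions(sp, nBands = 2L, thresholdDb = -50)
  expect_equal(bp$proportions, c(0.5, 1))
  expect_equal(bp$p, c(1 / 3, 2 / 3))

  ## uniform occupancy and single-band occupancy
  spU <- Spectrogram(matrix(1, 20, 10), seq_len(20) * 100,
                     seq_len(10) / 10)
  expect_equal(bandProportions(spU, 10L)$p, rep(0.1, 10))
  v3 <- matrix(0, 20, 10); v3[5:6, ] <- 1
  sp3 <- Spectrogram(v3, seq_len(20) * 100, seq_len(10) / 10)
  expect_equal(bandProportions(sp3, 10L)$p, c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))

  expect_error(bandProportions(Spectrogram(matrix(0, 20, 4) + 1e-10,
                                           seq_len(20) * 100,
                                           seq_len(4) / 10), 10L),
               "threshold")
})

test_that("ADI and AEI summarise occupancy by entropy and evenness", {
  spU <- Spectrogram(matrix(1, 20, 10), seq_len(20) * 100, seq_len(10) / 10)
  expect_equal(adi(spU, 10L), log(10))
  expect_equal(aei(spU, 10L), 0)

  v <- matrix(0, 20, 10); v[1:2, ] <- 1
  sp1 <- Spectrogram(v, seq_len(20) * 100, seq_len(10) / 10)
  expect_equal(adi(sp1, 10L), 0)
  expect_equal(aei(sp1, 10L), 0.9)

  ## occupancy (1/3, 2/3) over 2 bands
  v2 <- matrix(0, 20, 12)
  v2[1:10, 1:4] <- 1; v2[11:20, 1:8] <- 1
  sp2 <- Spectrogram(v2, seq_len(20) * 100, seq_len(12) / 10)
  expect_equal(adi(sp2, 2L), -(1 / 3) * log(1 / 3) - (2 / 3) * log(2 / 3))
})

test_that("ACI measures adjacent-frame variation and ignores global scale", {
  ## time-constant spectrogram -> 0
  spC <- Spectrogram(matrix(rep(runif(16), 10), 16, 10),
                     seq_len(16) * 100, seq_len(10) / 10)
  expect_equal(aci(spC), 0)

  ## one alternating row contributes sum|diff|/sum = 5/3
  v <- matrix(0, 4, 6)
  v[2, ] <- c(1, 0, 1, 0, 1, 0)
  sp <- Spectrogram(v, seq_len(4) * 100, seq_len(6) / 10)
  expect_equal(aci(sp, clumpSeconds = Inf), 5 / 3)

  ## scale invariance
  withr::with_seed(5, v <- matrix(runif(160), 16, 10))
  sp1 <- Spectrogram(v, seq_len(16) * 100, seq_len(10) / 10)
  sp7 <- Spectrogram(7 * v, seq_len(16) * 100, seq_len(10) / 10)
  expect_equal(aci(sp1), aci(sp7), tolerance = 1e-12)
})

test_that("Bioacoustic Index integrates the min-shifted band spectrum", {
  ## flat in-band spectrum -> 0 and gain invariance
  noise <- whiteNoise(2, seed = 3)
  b1 <- bioacousticIndex(noise)
  half <- AudioSignal(samples(noise) * 0.25, rate(noise))
  expect_equal(bioacousticIndex(half), b1, tolerance = 1e-9)

  ## direct trapezoid oracle on a constructed 3-bin profile
  ## trapezoid over (2,3,4) kHz of the min-shifted dB profile (0,20,0):
  ## two triangles of area 10 each
  env <- asNamespace("EcoSound")
  db <- 20 * log10(c(1, 10, 1))
  expect_equal(env$trapezoid(c(2, 3, 4), db - min(db)), 20)
  ## tone in band over a floor: BI grows with tone level
  floorSig <- whiteNoise(1, seed = 4, amplitude = 0.01)
  lo <- AudioSignal(samples(floorSig) + 0.1 * samples(toneSignal(4000, 1)),
                    44100)
  hi <- AudioSignal(samples(floorSig) + 0.5 * samples(toneSignal(4000, 1)),
                    44100)
  expect_gt(bioacousticIndex(hi), bioacousticIndex(lo))
  expect_gt(bioacousticIndex(lo), 0)
  expect_error(bioacousticIndex(AudioSignal(numeric(44100), 44100)), "BI")
})

test_that("the index report runs one shared chain and degrades gracefully", {
  rep <- computeIndexReport(whiteNoise(3, seed = 9))
  vals <- indexValues(rep)
  expect_equal(vals[["h"]], vals[["sh"]] * vals[["th"]], tolerance = 1e-12)
  expect_gt(vals[["ndsi"]], 0)              # biophony band is wider
  expect_gte(vals[["h"]], 0.95)
  expect_lt(vals[["aei"]], 0.05)
  expect_true(all(!nzchar(indexErrors(rep))))

  silent <- computeIndexReport(AudioSignal(numeric(44100 * 2), 44100))
  expect_true(all(is.na(indexValues(silent))))
  expect_true(all(nzchar(indexErrors(silent))))
  df <- as.data.frame(rep)
  expect_identical(names(df), c("ndsi", "adi", "aei", "sh", "th", "h",
                                "aci", "bi"))
})
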