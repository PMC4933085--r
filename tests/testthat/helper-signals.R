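# Deterministic signal builders shared across tests.

toneSignal <- function(freq, duration = 1, rate = 44100, amplitude = 1) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  AudioSignal(amplitude * sin(2 * pi * freq * t), rate)
}

# a tone exactly centred on STFT bin k for the given window length
binTone <- function(k, winLen = 512, duration = 1, rate = 44100,
                    amplitude = 1) {
  toneSignal(k * rate / winLen, duration, rate, amplitude)
}

whiteNoise <- function(duration = 1, rate = 44100, amplitude = 0.3,
                       seed = 1) {
  n <- round(duration * rate)
  withr::with_seed(seed, AudioSignal(amplitude * stats::rnorm(n) /
                                       3, rate))
}

rmsOf <- function(x) sqrt(mean(x^2))

# greedy best-match of fitted kernels to true kernels by aligned cosine
alignedCos <- function(a, b) {
  xc <- conv2Full(a, b[nrow(b):1, ncol(b):1, drop = FALSE])
  max(xc) / sqrt(sum(a^2) * sum(b^2))
}

objectiveIsMonotone <- function(obj, tol = 1e-9) {
  all(diff(obj) <= tol * (1 + abs(obj[-1])))
}
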