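## Internal numeric helpers shared across modules.

#' @importFrom stats fft mvfft nextn rnorm runif
NULL

## Evaluate `expr` under a deterministic RNG state without disturbing the
## caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

fft2 <- function(x) t(stats::mvfft(t(stats::mvfft(x))))

ifft2 <- function(x) Conj(fft2(Conj(x))) / length(x)

## Smallest highly-composite (2,3,5-smooth) size >= n, for fast mixed-radix FFTs.
goodSize <- function(n) {
  if (n <= 2L) return(max(n, 1L))
  stats::nextn(n, factors = c(2L, 3L, 5L))
}

padTo <- function(x, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  out
}

#' Full 2D linear convolution
#'
#' FFT-based full convolution of two matrices; the output has
#' `nrow(a) + nrow(b) - 1` rows and `ncol(a) + ncol(b) - 1` columns. This is
#' the placement operation of the shift-invariant model: a kernel convolved
#' with an activation map yields the component's contribution to the
#' reconstruction, which is why it is exported (generative test inputs are
#' built with it).
#'
#' @param a,b Numeric matrices.
#' @return The full linear convolution of `a` and `b`.
#' @export
conv2Full <- function(a, b) {
  nr <- nrow(a) + nrow(b) - 1L
  nc <- ncol(a) + ncol(b) - 1L
  pr <- goodSize(nr); pc <- goodSize(nc)
  out <- Re(ifft2(fft2(padTo(a, pr, pc)) * fft2(padTo(b, pr, pc))))
  out[seq_len(nr), seq_len(nc), drop = FALSE]
}

## Valid 2D cross-correlation of `big` with `small`:
## out[i,j] = sum_{u,v} big[i+u-1, j+v-1] * small[u, v].
## Output (nrow(big)-nrow(small)+1) x (ncol(big)-ncol(small)+1).
xcorr2Valid <- function(big, small, fftBig = NULL, pr = NULL, pc = NULL) {
  rs <- nrow(small); cs <- ncol(small)
  nr <- nrow(big) + rs - 1L
  nc <- ncol(big) + cs - 1L
  if (is.null(pr)) pr <- goodSize(nr)
  if (is.null(pc)) pc <- goodSize(nc)
  if (is.null(fftBig)) fftBig <- fft2(padTo(big, pr, pc))
  rot <- small[rs:1, cs:1, drop = FALSE]
  full <- Re(ifft2(fftBig * fft2(padTo(rot, pr, pc))))
  full[rs:nrow(big), cs:ncol(big), drop = FALSE]
}

## -sum(p log p) with 0 log 0 := 0; p assumed non-negative, summing to 1.
entropyNats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

## Normalize non-negative weights to a probability distribution.
asDistribution <- function(w, what = "weights") {
  if (any(!is.finite(w)) || any(w < 0))
    stop(what, " must be finite and non-negative", call. = FALSE)
  s <- sum(w)
  if (s <= 0)
    stop(what, " are all zero: distribution undefined", call. = FALSE)
  w / s
}

isScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
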