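## Multilevel periodized discrete wavelet transform with the 8-tap
## Daubechies-4 filter, used as a high-pass "reconstruction filter": the
## approximation coefficients at the coarsest level are zeroed and the signal
## reconstructed, which removes low-frequency content while minimizing spike
## waveform distortion. No wavelet package is available in this environment,
## so the periodized transform is implemented directly; the analysis operator
## is orthonormal and the synthesis step is its transpose, giving perfect
## reconstruction on lengths divisible by 2^level.

db4Lowpass <- c(0.23037781330885523, 0.7148465705525415,
                0.6308807679295904, -0.02798376941698385,
                -0.18703481171888114, 0.030841381835986965,
                0.032883011666982945, -0.010597401784997278)

dwtStepPeriodic <- function(x, h) {
  n <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)     # quadrature mirror high-pass
  half <- n %/% 2
  a <- numeric(half); d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + seq_along(h) - 1) %% n) + 1
    a[k] <- sum(h * x[idx])
    d[k] <- sum(g * x[idx])
  }
  list(a = a, d = d)
}

idwtStepPeriodic <- function(a, d, h) {
  n <- 2 * length(a)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  x <- numeric(n)
  for (k in seq_along(a)) {
    idx <- ((2 * (k - 1) + seq_along(h) - 1) %% n) + 1
    x[idx] <- x[idx] + h * a[k] + g * d[k]
  }
  x
}

#' Wavelet high-pass filter (multilevel decomposition/reconstruction)
#'
#' Decomposes the signal to the stated level with the Daubechies-4 wavelet,
#' zeroes the coarsest approximation coefficients and reconstructs. Signals
#' whose length is not divisible by 2^level are padded at the tail with the
#' edge value and truncated after reconstruction.
#'
#' @param x numeric signal, length >= 2^level.
#' @param level decomposition level (default 6).
#' @return filtered signal, same length as \code{x}.
#' @export
waveletHighpass <- function(x, level = 6) {
  n0 <- length(x)
  if (n0 < 2^level)
    stop("signal length ", n0, " < 2^level = ", 2^level)
  block <- 2^level
  pad <- (block - n0 %% block) %% block
  if (pad) x <- c(x, rep(x[n0], pad))
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- dwtStepPeriodic(a, db4Lowpass)
    a <- s$a
    details[[l]] <- s$d
  }
  a <- numeric(length(a))                   # drop the low-frequency band
  for (l in rev(seq_len(level)))
    a <- idwtStepPeriodic(a, details[[l]], db4Lowpass)
  a[seq_len(n0)]
}
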