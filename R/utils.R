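#' @importFrom stats rpois runif rnorm rbinom rgeom approx mad median sd var
#'   fft kmeans wilcox.test t.test aov anova runmed qnorm quantile
#' @importFrom utils head tail write.csv read.csv
NULL

## Run code under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Stable 32-bit sub-seed so adding units never perturbs existing streams.
subSeed <- function(master, index) {
  s <- (as.double(master) * 48271 + as.double(index) * 7919 + 12345) %%
    2147483647
  as.integer(s)
}

wrapPhase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  ## convention: phase in (-pi, pi], 0 at oscillation peak
  out[out == -pi] <- pi
  out
}

hannWindow <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

#' Zero-phase FFT band-pass filter
#'
#' Brick-wall band-pass in the frequency domain. Zero-phase by construction
#' (the operation is symmetric in frequency), so event edges are not shifted
#' in time. With \code{analytic = TRUE} the negative frequencies are zeroed
#' and positive ones doubled, returning the complex analytic signal whose
#' argument is the instantaneous phase (0 at the oscillation peak).
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; \code{low = 0} gives a low-pass.
#' @param analytic return the complex analytic band signal instead of the
#'   real filtered trace.
#' @return numeric (or complex) vector, same length as \code{x}.
#' @export
fftBandpass <- function(x, fs, low, high, analytic = FALSE) {
  n <- length(x)
  if (high > fs / 2) stop("band edge ", high, " Hz beyond Nyquist (", fs / 2, " Hz)")
  if (high <= low) stop("band must have positive width")
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  ## frequency of each bin, folding the upper half to negative frequencies
  fpos <- ifelse(f > fs / 2, fs - f, f)
  keep <- fpos >= low & fpos <= high
  if (analytic) {
    mult <- numeric(n)
    pos <- f > 0 & f < fs / 2
    mult[keep & pos] <- 2
    if (low <= 0) mult[1] <- 1
    X <- X * mult
    stats::fft(X, inverse = TRUE) / n
  } else {
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE) / n)
  }
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann windows, per-segment mean removal
#' and one-sided density scaling, so that \code{sum(power) * df} recovers the
#' signal variance (Parseval).
#'
#' @param x numeric signal (a single channel).
#' @param fs sampling rate, Hz.
#' @param window segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param maxFreq truncate the grid at this frequency (default Nyquist).
#' @return data.frame with columns \code{freq} (Hz) and \code{power}
#'   (units^2/Hz).
#' @export
welchPsd <- function(x, fs, window = 2, overlap = 0.5, maxFreq = NULL) {
  nseg <- round(window * fs)
  if (nseg > length(x)) stop("PSD segment longer than the recording")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- hannWindow(nseg)
  norm <- fs * sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2 / norm
  }
  acc <- acc / length(starts)
  nh <- floor(nseg / 2) + 1L
  p <- acc[seq_len(nh)]
  ## one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nh)
  dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nh] <- 1
  p <- p * dbl
  f <- (seq_len(nh) - 1) * fs / nseg
  out <- data.frame(freq = f, power = p)
  if (!is.null(maxFreq)) out <- out[out$freq <= maxFreq, , drop = FALSE]
  out
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. With \code{kappa = 0} the draw is uniform
#' on (-pi, pi].
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0). The population resultant length is
#'   \code{besselI(kappa, 1) / besselI(kappa, 0)}.
#' @return numeric vector of phases in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(wrapPhase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nacc <- sum(ok)
    if (nacc > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nacc)] <- theta
    }
    got <- got + nacc
  }
  wrapPhase(out + mu)
}

#' Analytic resultant length of a von Mises distribution
#'
#' The expected mean vector length of phases drawn with concentration
#' \code{kappa}: the Bessel ratio I1(kappa)/I0(kappa).
#'
#' @param kappa concentration parameter (>= 0).
#' @return resultant length in [0, 1).
#' @export
vonMisesResultant <- function(kappa) {
  besselI(kappa, 1) / besselI(kappa, 0)
}

## standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
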