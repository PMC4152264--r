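#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary fractional Gaussian noise with Hurst
#' exponent H (Davies-Harte): the covariance
#' \eqn{\gamma(k) = \tfrac{\sigma^2}{2}(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}
#' is embedded in a circulant matrix whose eigenvalues (obtained by FFT) are
#' non-negative for \eqn{0 < H < 1}, giving draws with the exact target
#' covariance.
#'
#' @param n number of increments.
#' @param H Hurst exponent in (0, 1); the MSD exponent is \eqn{\alpha = 2H}.
#' @param sigma standard deviation of one increment.
#' @return numeric vector of n increments.
#' @export
fgnSim <- function(n, H, sigma = 1) {
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)")
  k <- 0:n
  gamma <- sigma^2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  row1 <- c(gamma, gamma[n:2])              # circulant first row, length 2n
  lam <- Re(fft(row1))
  lam[lam < 0] <- 0                         # numerical guard; exact DH has lam >= 0
  m <- 2L * n
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  # with coefficients sqrt(lam/m), Re(fft(.)) has covariance exactly row1
  w <- fft(sqrt(lam / m) * z, inverse = FALSE)
  Re(w)[seq_len(n)]
}

#' Fractional Brownian motion path(s)
#'
#' Cumulative sums of independent fractional Gaussian noise per dimension:
#' a Gaussian, stationary-increment, non-Markovian process whose MSD grows
#' as \eqn{t^{2H}} and whose normalized increment autocorrelation at lag
#' \eqn{\delta} equals \eqn{2^{2H-1} - 1}. Used as the synthetic
#' anomalous-diffusion oracle for the estimator tests.
#'
#' @param n number of time points beyond the origin.
#' @param H Hurst exponent; MSD exponent \eqn{\alpha = 2H}.
#' @param dim spatial dimension (default 3).
#' @param sigma per-step increment standard deviation per component.
#' @param spacing time per step, ns (sets the \code{times} attribute).
#' @return matrix ((n+1) x dim) starting at the origin, with a \code{times}
#'   attribute.
#' @export
fbmPath <- function(n, H, dim = 3L, sigma = 1, spacing = 1) {
  path <- sapply(seq_len(dim), function(d) c(0, cumsum(fgnSim(n, H, sigma))))
  path <- matrix(path, ncol = dim)
  attr(path, "times") <- (0:n) * spacing
  path
}
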