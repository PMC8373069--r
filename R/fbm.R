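#' Fractional Gaussian noise by circulant embedding
#'
#' Draws one realization of standard fractional Gaussian noise (fGn), the
#' stationary increment process of fractional Brownian motion with Hurst
#' exponent `H`, on the unit grid. The autocovariance is
#' \eqn{\gamma(k) = \frac{1}{2}(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})} and
#' each increment has unit variance. Sampling uses the Davies--Harte
#' circulant-embedding construction, which is exact in distribution and
#' costs O(n log n) via the FFT.
#'
#' @param n number of increments.
#' @param H Hurst exponent in (0, 1). `H = 0.5` short-circuits to i.i.d.
#'   standard normals (ordinary Brownian increments).
#' @return numeric vector of length `n`.
#' @keywords internal
fgn_sample <- function(n, H) {
  stopifnot(n >= 1, H > 0, H < 1)
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  if (n == 1L) return(stats::rnorm(1))
  lambda <- fgn_eigenvalues(n, H)
  m <- 2L * n
  # independent normals for the half-spectrum; 2n draws in total so the
  # RNG stream advances deterministically with n
  z1 <- stats::rnorm(n + 1L)
  z2 <- stats::rnorm(n - 1L)
  a <- complex(length.out = m)
  a[1L] <- sqrt(lambda[1L] / m) * z1[1L]
  a[n + 1L] <- sqrt(lambda[n + 1L] / m) * z1[n + 1L]
  k <- 2:n
  a[k] <- sqrt(lambda[k] / (2 * m)) *
    complex(real = z1[k], imaginary = z2[k - 1L])
  a[m + 2L - k] <- Conj(a[k])
  Re(stats::fft(a))[seq_len(n)]
}

# Eigenvalues of the 2n x 2n circulant embedding of the fGn covariance.
# Nonnegative for H in (0,1); tiny negative round-off is clipped.
fgn_eigenvalues <- function(n, H) {
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(g, g[n:2])
  ev <- Re(stats::fft(row))
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("circulant embedding is not nonnegative definite; H = ", H)
  pmax(ev, 0)
}

#' Fractional Brownian motion path
#'
#' Cumulative sum of fGn increments, rescaled to physical time so that
#' \eqn{\mathrm{Var}\,B_H(t) = t^{2H}}.
#'
#' @param n number of increments (the path has `n + 1` points incl. origin).
#' @param H Hurst exponent in (0, 1).
#' @param dt time step (s).
#' @return numeric vector of length `n + 1`, starting at 0.
#' @keywords internal
fbm_path <- function(n, H, dt) {
  c(0, cumsum(fgn_sample(n, H))) * dt^H
}
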