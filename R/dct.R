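# Discrete cosine transforms used for the spectral (binned) KDE.
#
# Conventions are fixed so that ports are bit-comparable:
#  * forward: DCT-II, a_k = 2 * sum_j x_j cos(pi k (2j + 1) / (2n)),
#    k = 0, ..., n - 1 (so a_0 = 2 * sum(x));
#  * inverse: DCT-III with the k = 0 coefficient halved,
#    x_j = (1/n) * [a_0 / 2 + sum_{k>=1} a_k cos(pi k (2j + 1) / (2n))],
#    the exact inverse of the forward transform.
# Both are computed through a single complex FFT of the even/odd
# reordered sequence; n must be even (resolutions here are powers of two
# or three times a power of two).

dct2 <- function(x) {
  n <- length(x)
  if (n %% 2L != 0L) abort("DCT input length must be even.")
  v <- c(x[seq(1L, n, 2L)], x[seq(n, 2L, -2L)])
  V <- stats::fft(v)
  2 * Re(exp(complex(imaginary = -pi * (0:(n - 1)) / (2 * n))) * V)
}

idct3 <- function(a) {
  n <- length(a)
  if (n %% 2L != 0L) abort("DCT input length must be even.")
  b <- a
  b[1L] <- b[1L] / 2
  V <- b * exp(complex(imaginary = pi * (0:(n - 1)) / (2 * n)))
  u <- Re(stats::fft(V, inverse = TRUE))
  out <- numeric(n)
  out[seq(1L, n, 2L)] <- u[1:(n / 2L)]
  out[seq(2L, n, 2L)] <- u[n:(n / 2L + 1L)]
  out / n
}
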