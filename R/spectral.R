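# cache DPSS computations: eigen-decomposition of a 900x900 matrix is cheap
# but not free, and the same (n, nw) pair recurs for every subject
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `K = floor(2 * nw) - 1` DPSS tapers of length
#' `n_samples` with time-half-bandwidth product `nw`, via the eigenvectors
#' of the symmetric tridiagonal matrix that commutes with the spectral
#' concentration operator. Tapers are orthonormal; each taper's spectral
#' concentration within the half-bandwidth is attached as attribute
#' `"concentration"`.
#'
#' @param n_samples Taper length (>= 8).
#' @param nw Time-half-bandwidth product (>= 1); for an epoch of `T` seconds
#'   and half-bandwidth `W` Hz, `nw = T * W`.
#' @return Matrix of size tapers x samples.
#' @export
dpss_tapers <- function(n_samples, nw) {
  if (n_samples < 8) stop("`n_samples` must be >= 8", call. = FALSE)
  if (nw < 1) stop("`nw` must be >= 1", call. = FALSE)
  K <- floor(2 * nw) - 1L
  if (K < 1) stop("no usable tapers for this `nw`", call. = FALSE)
  key <- sprintf("n%d_nw%.6f", n_samples, nw)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  N <- as.integer(n_samples)
  W <- nw / N
  tvec <- seq_len(N) - 1
  dmain <- ((N - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * W)
  doff <- tvec[-1] * (N - tvec[-1]) / 2
  M <- matrix(0, N, N)
  diag(M) <- dmain
  M[cbind(seq_len(N - 1), seq_len(N - 1) + 1)] <- doff
  M[cbind(seq_len(N - 1) + 1, seq_len(N - 1))] <- doff
  eg <- eigen(M, symmetric = TRUE)
  tap <- t(eg$vectors[, seq_len(K), drop = FALSE])
  # sign convention: symmetric tapers have positive mean, antisymmetric ones
  # a positive initial slope
  for (k in seq_len(K)) {
    s <- sum(tap[k, ])
    if (abs(s) > 1e-10) {
      if (s < 0) tap[k, ] <- -tap[k, ]
    } else if (tap[k, 2] - tap[k, 1] < 0) {
      tap[k, ] <- -tap[k, ]
    }
  }
  # concentration lambda_k = v' S v, S_ij = sin(2 pi W (i-j)) / (pi (i-j))
  d <- outer(tvec, tvec, "-")
  S <- ifelse(d == 0, 2 * W, sin(2 * pi * W * d) / (pi * d))
  conc <- vapply(seq_len(K), function(k) {
    v <- tap[k, ]
    drop(v %*% S %*% v)
  }, 0)
  attr(tap, "concentration") <- conc
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper Fourier coefficients of epoched data
#'
#' Computes complex tapered Fourier coefficients for every epoch, taper and
#' channel, evaluated at exactly the requested grid frequencies (the default
#' grid, 1/6 to 5 Hz in steps of 1/6 Hz, equals the Rayleigh spacing of 6-s
#' epochs, giving 30 bins).
#'
#' @param epochs An `epochs` object.
#' @param freqs Frequency grid in Hz; strictly increasing, within
#'   `(0, rate/2)`, with spacing no finer than the Rayleigh frequency
#'   `1 / epoch_length`.
#' @param half_bandwidth Spectral smoothing half-bandwidth W in Hz (default
#'   0.5, giving `nw = 3` and 5 tapers on 6-s epochs).
#' @return An object of class `tapered_spectra`: list with `coeffs` (complex
#'   array epochs x tapers x channels x freqs), `freqs`, `half_bandwidth`,
#'   `rate`, `channel_names`, `channel_roles`, `condition`.
#' @export
mtm_spectra <- function(epochs, freqs = default_freq_grid(),
                        half_bandwidth = 0.5) {
  stopifnot(inherits(epochs, "epochs"))
  rayleigh <- 1 / epochs$epoch_length
  if (any(diff(freqs) <= 0)) stop("`freqs` must be strictly increasing", call. = FALSE)
  if (length(freqs) > 1 && min(diff(freqs)) < rayleigh - 1e-9)
    stop(sprintf("frequency grid step below the Rayleigh resolution; minimum step is %.4f Hz",
                 rayleigh), call. = FALSE)
  if (any(freqs <= 0) || any(freqs >= epochs$rate / 2))
    stop("`freqs` must lie inside (0, rate/2)", call. = FALSE)
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; n_s <- d[3]
  nw <- epochs$epoch_length * half_bandwidth
  tap <- dpss_tapers(n_s, nw)
  K <- nrow(tap)
  tt <- (seq_len(n_s) - 1) / epochs$rate
  basis <- exp(-2i * pi * outer(tt, freqs))          # samples x freqs
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_s)  # samples x (ep*ch)
  coeffs <- array(0i, dim = c(n_ep, K, n_ch, length(freqs)))
  for (k in seq_len(K)) {
    X <- crossprod(flat * tap[k, ], basis)           # (ep*ch) x freqs
    coeffs[, k, , ] <- array(X, dim = c(n_ep, n_ch, length(freqs)))
  }
  structure(list(coeffs = coeffs, freqs = freqs,
                 half_bandwidth = half_bandwidth, rate = epochs$rate,
                 channel_names = epochs$channel_names,
                 channel_roles = epochs$channel_roles,
                 condition = epochs$condition),
            class = "tapered_spectra")
}

#' The analysis frequency grid
#'
#' Frequencies from 1/6 Hz to 5 Hz in steps of 1/6 Hz (30 bins), the
#' Rayleigh-spaced grid of 6-s epochs covering the 0.166-5 Hz range of
#' interest for slow speech tracking.
#'
#' @param epoch_length Epoch length in seconds (default 6).
#' @param f_max Upper limit in Hz (default 5).
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freq_grid <- function(epoch_length = 6, f_max = 5) {
  seq(1 / epoch_length, f_max, by = 1 / epoch_length)
}

#' Accumulate a cross-spectral density from tapered coefficients
#'
#' Averages the per-estimate outer products `x(f) x(f)^H` over epochs and
#' tapers (equally weighted), yielding one Hermitian channels-by-channels
#' matrix per frequency and recording the effective number of independent
#' estimates `n_est = epochs * tapers`.
#'
#' @param spectra A `tapered_spectra` object.
#' @param epochs_idx Optional integer/logical index selecting a subset of
#'   epochs (e.g. one condition).
#' @return An object of class `csd`: list with `matrices` (complex array
#'   channels x channels x freqs), `n_est`, `freqs`, `channel_names`,
#'   `channel_roles`.
#' @export
accumulate_csd <- function(spectra, epochs_idx = NULL) {
  stopifnot(inherits(spectra, "tapered_spectra"))
  co <- spectra$coeffs
  if (!is.null(epochs_idx)) co <- co[epochs_idx, , , , drop = FALSE]
  d <- dim(co)
  n_est <- d[1] * d[2]
  if (n_est < 2)
    stop("need at least 2 estimates (epochs x tapers) for a usable CSD",
         call. = FALSE)
  n_ch <- d[3]; n_f <- d[4]
  mats <- array(0i, dim = c(n_ch, n_ch, n_f),
                dimnames = list(spectra$channel_names, spectra$channel_names,
                                NULL))
  for (f in seq_len(n_f)) {
    M <- matrix(co[, , , f], nrow = n_est, ncol = n_ch)
    mats[, , f] <- crossprod(Conj(M), M) / n_est
  }
  structure(list(matrices = mats, n_est = n_est, freqs = spectra$freqs,
                 channel_names = spectra$channel_names,
                 channel_roles = spectra$channel_roles),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("<csd> %d channels, %d frequencies (%.3f-%.3f Hz), n_est=%d\n",
              length(x$channel_names), length(x$freqs), min(x$freqs),
              max(x$freqs), x$n_est))
  invisible(x)
}
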