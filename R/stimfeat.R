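#' Cochlear-map equidistant band edges
#'
#' Divides the frequency range `[f_lo, f_hi]` into `n_bands` bands of equal
#' width along the basilar membrane. The frequency-position map is the
#' Liberman cat cochlear map, `f(x) = A (10^(2.1 x) - 0.8)` with `x` the
#' relative distance from the apex, frequency-scaled so that the basal end
#' of the map corresponds to the 20 kHz upper limit of human hearing
#' (`A = 456 * 20000 / (456 * (10^2.1 - 0.8)) ~= 159.88`). The map is
#' inverted at `f_lo` and `f_hi`, `n_bands + 1` equally spaced cochlear
#' positions are taken, and positions are mapped back to frequency.
#'
#' Reported integer cutoffs (`edges_hz`) take the ceiling of each mapped
#' frequency, so every lower cutoff lies strictly inside its band; the upper
#' range limit is reported as `f_hi` itself. With the default 100-10,000 Hz
#' range and nine bands this yields the cutoff list
#' 101, 220, 402, 680, 1103, 1748, 2732, 4231, 6517, 10000.
#'
#' @param f_lo,f_hi Range endpoints in Hz, `0 < f_lo < f_hi`.
#' @param n_bands Number of bands (>= 1).
#' @return An object of class `band_spec`: list with `edges` (full-precision
#'   frequencies), `edges_hz` (integer-reported cutoffs), `f_lo`, `f_hi`,
#'   `n_bands`.
#' @examples
#' cochlear_band_edges(100, 10000, 9)$edges_hz
#' @export
cochlear_band_edges <- function(f_lo, f_hi, n_bands) {
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_lo >= f_hi)
    stop("require 0 < f_lo < f_hi", call. = FALSE)
  if (n_bands < 1) stop("`n_bands` must be >= 1", call. = FALSE)
  A <- 456 * 20000 / (456 * (10^2.1 - 0.8))
  k <- 0.8
  pos <- function(f) log10(f / A + k) / 2.1   # relative distance from apex
  freq <- function(x) A * (10^(2.1 * x) - k)
  x <- seq(pos(f_lo), pos(f_hi), length.out = n_bands + 1)
  edges <- freq(x)
  edges_hz <- ceiling(edges)
  edges_hz[length(edges_hz)] <- f_hi
  structure(list(edges = edges, edges_hz = edges_hz,
                 f_lo = f_lo, f_hi = f_hi, n_bands = as.integer(n_bands)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %d bands over %g-%g Hz\n cutoffs: %s\n",
              x$n_bands, x$f_lo, x$f_hi, paste(x$edges_hz, collapse = ", ")))
  invisible(x)
}

# Reflect-pad a vector to the next 5-smooth length so FFTs stay fast for
# arbitrary (e.g. prime) input lengths; returns padded vector + true length.
pad_smooth <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  if (m == n) return(list(x = x, n = n))
  list(x = c(x, rev(x)[seq_len(m - n)]), n = n)
}

# Analytic signal via the frequency domain: positive frequencies doubled,
# negative zeroed (Nyquist/DC kept). Returns complex vector.
analytic_signal <- function(x) {
  p <- pad_smooth(x)
  x <- p$x
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n)[seq_len(p$n)]
}

# Zero-phase Butterworth bandpass applied in the frequency domain through
# the squared magnitude response of the analog prototype,
#   |H(f)|^2 = 1 / (1 + ((f^2 - f0^2) / (bw * f))^(2n)),
# which is what a forward-backward (filtfilt) application of the filter
# converges to on interior samples, without the numerical fragility of
# pole-zero recursion for very narrow low bands at audio rates.
butter_bandpass_zerophase <- function(x, rate, f_lo, f_hi, order = 4) {
  p <- pad_smooth(x)
  x <- p$x
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  f0sq <- f_lo * f_hi
  bw <- f_hi - f_lo
  u <- rep(Inf, n)
  nz <- f != 0
  u[nz] <- (f[nz]^2 - f0sq) / (bw * f[nz])
  H2 <- 1 / (1 + u^(2 * order))
  H2[!is.finite(H2)] <- 0
  (Re(stats::fft(stats::fft(x) * H2, inverse = TRUE)) / n)[seq_len(p$n)]
}

#' Extract the wide-band speech envelope through a cochlear filterbank
#'
#' Bandpass-filters the audio into cochlear-map-equidistant bands with a
#' zero-phase fourth-order Butterworth filter, takes the magnitude of the
#' analytic (Hilbert) signal in each band, averages the band envelopes with
#' equal weights, and resamples the result to `out_rate` by FFT-based
#' interpolation (after a zero-phase low-pass guard at `out_rate / 2`).
#'
#' @param audio Numeric vector, the audio waveform (mono; a matrix with one
#'   column per channel is averaged to mono).
#' @param rate Audio sampling rate, Hz; must exceed `2 * bands$f_hi`.
#' @param bands A `band_spec`, e.g. from [cochlear_band_edges()].
#' @param out_rate Output sampling rate, Hz (default 150).
#' @return A `stimulus_signal` with role `"envelope"` at `out_rate`; the band
#'   edges used are attached as attribute `"band_edges_hz"`.
#' @export
extract_envelope <- function(audio, rate, bands = cochlear_band_edges(100, 10000, 9),
                             out_rate = 150) {
  if (is.matrix(audio)) audio <- rowMeans(audio)
  audio <- as.numeric(audio)
  if (rate <= 2 * bands$f_hi)
    stop(sprintf("audio rate %g Hz too low for upper band edge %g Hz",
                 rate, bands$f_hi), call. = FALSE)
  e <- bands$edges
  env <- numeric(length(audio))
  for (b in seq_len(bands$n_bands)) {
    xb <- butter_bandpass_zerophase(audio, rate, e[b], e[b + 1])
    env <- env + Mod(analytic_signal(xb))
  }
  env <- env / bands$n_bands
  # low-pass guard before rate reduction
  if (out_rate < rate) {
    env <- zerophase_lowpass(env, rate, out_rate / 2)
  }
  out <- fft_resample_vector(env, rate, out_rate)
  out[out < 0] <- 0   # resampling ripple can dip a magnitude slightly below 0
  sig <- stimulus_signal(out, out_rate, "envelope")
  attr(sig, "band_edges_hz") <- bands$edges_hz
  sig
}

# zero-phase 4th-order Butterworth low-pass via squared magnitude response
zerophase_lowpass <- function(x, rate, cutoff, order = 4) {
  p <- pad_smooth(x)
  x <- p$x
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  H2 <- 1 / (1 + (f / cutoff)^(2 * order))
  (Re(stats::fft(stats::fft(x) * H2, inverse = TRUE)) / n)[seq_len(p$n)]
}

# Core FFT resampler on a plain vector. Zero-pads or truncates the spectrum
# so that band-limited content is preserved exactly; the shared Nyquist bin
# is split symmetrically when upsampling from an even length.
fft_resample_vector <- function(x, in_rate, out_rate) {
  n <- length(x)
  m <- round(n * out_rate / in_rate)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  if (m > n) {
    half <- floor(n / 2)
    if (n %% 2 == 0) {
      Y[1:half] <- X[1:half]
      Y[half + 1] <- X[half + 1] / 2
      Y[m - half + 1] <- X[half + 1] / 2
      if (half > 1) Y[(m - half + 2):m] <- X[(half + 2):n]
    } else {
      Y[1:(half + 1)] <- X[1:(half + 1)]
      Y[(m - half + 1):m] <- X[(half + 2):n]
    }
  } else {
    half <- floor(m / 2)
    if (m %% 2 == 0) {
      Y[1:half] <- X[1:half]
      Y[half + 1] <- Re(X[half + 1]) + Re(X[n - half + 1])
      Y[(half + 2):m] <- X[(n - half + 2):n]
    } else {
      Y[1:(half + 1)] <- X[1:(half + 1)]
      Y[(half + 2):m] <- X[(n - half + 2):n]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' FFT-based resampling of a stimulus signal
#'
#' Resamples by zero-padding (upsampling) or truncating (downsampling) the
#' discrete Fourier spectrum, the method used to bring the 50 Hz lip-area
#' signal to the 150 Hz analysis rate. Band-limited content is preserved;
#' the output length is `round(n * out_rate / in_rate)`.
#'
#' @param x A `stimulus_signal`.
#' @param out_rate Target rate in Hz (> 0).
#' @return A `stimulus_signal` at `out_rate` with the same role.
#' @export
fft_resample <- function(x, out_rate) {
  stopifnot(inherits(x, "stimulus_signal"))
  if (!is.finite(out_rate) || out_rate <= 0)
    stop("`out_rate` must be positive", call. = FALSE)
  y <- fft_resample_vector(x$samples, x$rate, out_rate)
  if (x$role == "envelope") y[y < 0] <- 0
  stimulus_signal(y, out_rate, x$role)
}

#' Modulation spectrum of a signal
#'
#' Welch-averaged power spectrum of the demeaned signal (Hann-tapered
#' segments, 50% overlap), used to locate the syllable-rate peak of a speech
#' envelope.
#'
#' @param x A `stimulus_signal` or numeric vector.
#' @param rate Sampling rate, required when `x` is a plain vector.
#' @param segment_s Segment length in seconds (default 10, i.e. 0.1 Hz
#'   resolution with heavy averaging -- a stable argmax for peak location).
#' @return A data.frame with columns `freq` (Hz) and `power`.
#' @export
modulation_spectrum <- function(x, rate = NULL, segment_s = 10) {
  if (inherits(x, "stimulus_signal")) {
    rate <- x$rate
    x <- x$samples
  }
  if (is.null(rate)) stop("`rate` is required for plain vectors", call. = FALSE)
  x <- x - mean(x)
  nseg <- min(length(x), round(segment_s * rate))
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_along(acc)]
  }
  data.frame(freq = (seq_along(acc) - 1) * rate / nseg,
             power = acc / length(starts))
}

#' Frequency of the modulation-spectrum peak in a band
#'
#' @param x A `stimulus_signal` or numeric vector.
#' @param band Numeric length-2 search band in Hz (default 2-5 Hz, the
#'   syllable-rate range).
#' @param rate Sampling rate when `x` is a plain vector.
#' @return Peak frequency in Hz.
#' @export
modulation_peak <- function(x, band = c(2, 5), rate = NULL) {
  ms <- modulation_spectrum(x, rate = rate)
  sel <- ms$freq >= band[1] & ms$freq <= band[2]
  if (!any(sel)) stop("no spectral bins inside `band`", call. = FALSE)
  ms$freq[sel][which.max(ms$power[sel])]
}
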