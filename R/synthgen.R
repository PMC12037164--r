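# Gaussian noise with a 1/f^a amplitude spectrum, unit variance.
one_over_f_noise <- function(n, exponent = 1) {
  if (exponent == 0) return(stats::rnorm(n))
  nf <- floor(n / 2)
  amp <- c(0, (seq_len(nf))^(-exponent / 2))          # DC removed
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- amp[-1] * exp(1i * ph)
  if (n %% 2 == 0) {
    spec <- c(0 + 0i, half, Conj(rev(half[-nf])))
  } else {
    spec <- c(0 + 0i, half, Conj(rev(half)))
  }
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

# White Gaussian noise confined to a frequency band, unit variance.
band_limited_noise <- function(n, rate, band) {
  x <- butter_bandpass_zerophase(stats::rnorm(n), rate, band[1], band[2])
  as.numeric(scale(x))
}

# Stereotyped biphasic blink pulse: a dominant positive lobe (~200 ms)
# followed by a smaller negative rebound, ~300 ms total.
blink_pulse <- function(rate) {
  n1 <- max(3L, round(0.2 * rate))
  n2 <- max(3L, round(0.1 * rate))
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  c(hann(n1), -0.3 * hann(n2))
}

#' Generate a synthetic speech envelope
#'
#' Builds a non-negative envelope whose modulation spectrum peaks at the
#' syllable rate and that is gated on and off at the sentence rate:
#' a quasi-periodic syllable pulse train (gamma-jittered inter-syllable
#' intervals, coefficient of variation 0.3) is convolved with a 100 ms Hann
#' kernel, multiplied by a smoothed sentence-level on/off envelope (duty
#' cycle 0.8), and a small positive noise floor is added.
#'
#' @param duration Signal duration in seconds; must exceed two sentence
#'   periods.
#' @param rate Sampling rate in Hz (default 150).
#' @param syllable_rate Mean syllable rate, Hz (default 3.3).
#' @param sentence_rate Sentence on/off rate, Hz (default 0.25).
#' @param seed Integer seed.
#' @return A `stimulus_signal` with role `"envelope"`.
#' @export
make_speech_envelope <- function(duration, rate = 150, syllable_rate = 3.3,
                                 sentence_rate = 0.25, seed = 1L) {
  if (!is.finite(duration) || duration <= 0 || !is.finite(rate) || rate <= 0)
    stop("`duration` and `rate` must be positive", call. = FALSE)
  if (duration <= 2 / sentence_rate)
    stop("`duration` must exceed two sentence periods", call. = FALSE)
  if (rate < 8 * syllable_rate)
    stop("`rate` too low to resolve the syllable rate", call. = FALSE)
  set.seed(as.integer(seed))
  n <- round(duration * rate)

  # syllable onset train: gamma-distributed intervals, CV = 0.3
  cv <- 0.3
  shape <- 1 / cv^2
  mean_isi <- 1 / syllable_rate
  t_ons <- numeric(0)
  t_cur <- stats::rexp(1, syllable_rate)  # random phase at onset
  while (t_cur < duration) {
    t_ons <- c(t_ons, t_cur)
    t_cur <- t_cur + stats::rgamma(1, shape = shape, scale = mean_isi / shape)
  }
  train <- numeric(n)
  idx <- pmin(n, floor(t_ons * rate) + 1L)
  train[idx] <- train[idx] + stats::runif(length(idx), 0.9, 1)

  # 100 ms Hann syllable kernel
  nk <- max(3L, round(0.1 * rate))
  kern <- 0.5 - 0.5 * cos(2 * pi * seq(0, nk - 1) / (nk - 1))
  syl <- stats::filter(c(train, numeric(nk)), kern, sides = 1)
  syl <- as.numeric(syl[seq_len(n) + floor(nk / 2)])
  syl[is.na(syl)] <- 0

  # sentence gating: alternating speech/pause segments with gamma-jittered
  # durations (duty cycle 0.8 on average), smoothed with a 300 ms Hann.
  # Stochastic segment lengths keep the slow modulation a broad ~sentence-
  # rate peak rather than a deterministic harmonic comb, so independent
  # realizations are incoherent.
  gate <- numeric(n)
  pos <- 0
  on_mean <- 0.8 / sentence_rate
  off_mean <- 0.2 / sentence_rate
  gshape <- 1 / 0.3^2
  on_seg <- TRUE
  while (pos < duration) {
    seg <- stats::rgamma(1, shape = gshape,
                         scale = (if (on_seg) on_mean else off_mean) / gshape)
    if (on_seg) {
      i0 <- floor(pos * rate) + 1L
      i1 <- min(n, floor((pos + seg) * rate))
      if (i1 >= i0) gate[i0:i1] <- 1
    }
    pos <- pos + seg
    on_seg <- !on_seg
  }
  ns <- max(3L, round(0.3 * rate))
  ks <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns - 1) / (ns - 1))
  ks <- ks / sum(ks)
  gate <- stats::filter(c(rep(gate[1], ns), gate, rep(gate[n], ns)), ks, sides = 2)
  gate <- as.numeric(gate[ns + seq_len(n)])

  floor_level <- 0.02 * mean(syl[syl > 0])
  env <- syl * gate + floor_level * (1 + 0.25 * abs(stats::rnorm(n)))
  env[env < 0] <- 0
  stimulus_signal(env, rate, "envelope")
}

#' Generate a lip-area signal correlated with an envelope
#'
#' Produces a 50 Hz (by default) lip-role signal whose Pearson correlation
#' with the (optionally lagged) envelope approximates `target_corr`. The
#' shared component is the envelope's syllable-rate content (its > 2.5 Hz
#' part): mouth opening co-varies with the envelope at articulation rates,
#' while the slow (< 1 Hz) sentence-level envelope power is not mirrored in
#' lip area. The remainder is an independent, spectrally matched noise
#' signal, scaled so the overall Pearson correlation with the full envelope
#' hits `target_corr`.
#'
#' @param envelope A `stimulus_signal` with role `"envelope"`.
#' @param target_corr Target correlation, in \[-1, 1\].
#' @param lag Lag applied to the envelope in seconds (positive = lip lags).
#' @param rate Output rate, Hz (default 50).
#' @param seed Integer seed.
#' @return A `stimulus_signal` with role `"lip"`.
#' @export
make_lip_signal <- function(envelope, target_corr, lag = 0, rate = 50, seed = 1L) {
  stopifnot(inherits(envelope, "stimulus_signal"))
  if (envelope$role != "envelope")
    stop("`envelope` must have role 'envelope'", call. = FALSE)
  if (abs(target_corr) > 1)
    stop("|target_corr| must not exceed 1", call. = FALSE)
  set.seed(as.integer(seed))
  ref <- fft_resample(envelope, rate)$samples
  n <- length(ref)
  sh <- round(lag * rate)
  if (sh != 0) ref <- ref[((seq_len(n) - 1 - sh) %% n) + 1]
  z <- as.numeric(scale(ref))
  if (target_corr^2 == 1) {
    lip <- sign(target_corr) * z
  } else {
    # shared part: envelope with content below the syllable range removed
    # (steep roll-off, so slow-band analyses see no shared variance even
    # through multitaper smoothing)
    hp <- as.numeric(scale(ref - zerophase_lowpass(ref, rate, 2.5, order = 8)))
    c_se <- stats::cor(hp, z)
    a <- target_corr / c_se
    # spectrally matched noise: independent envelope instance, same rates
    noise <- make_speech_envelope(signal_duration(envelope),
                                  rate = envelope$rate,
                                  seed = as.integer(seed) + 104729L)
    zn <- as.numeric(scale(fft_resample(noise, rate)$samples[seq_len(n)]))
    if (abs(a) <= 1) {
      lip <- a * hp + sqrt(1 - a^2) * zn
    } else {
      # target beyond what syllable-rate sharing can carry: fall back to
      # full-band mixing
      lip <- target_corr * z + sqrt(1 - target_corr^2) * zn
    }
  }
  stimulus_signal(lip + 3, rate, "lip")   # offset: lip area is positive
}

# Poisson blink times, optionally biased into envelope troughs (pauses):
# acceptance decreases with the percentile of the sentence-smoothed
# envelope, emulating listeners who withhold blinks while speech is on.
draw_blink_times <- function(duration, blink_rate, envelope = NULL, bias = 0) {
  if (blink_rate <= 0) return(numeric(0))
  n_ev <- stats::rpois(1, blink_rate * duration)
  if (n_ev == 0) return(numeric(0))
  if (is.null(envelope) || bias <= 0) return(sort(stats::runif(n_ev, 0, duration)))
  smooth <- zerophase_lowpass(envelope$samples, envelope$rate, 1)
  pct <- stats::ecdf(smooth)
  times <- numeric(0)
  while (length(times) < n_ev) {
    cand <- stats::runif(2 * n_ev, 0, duration)
    p_env <- pct(smooth[pmin(length(smooth),
                             floor(cand * envelope$rate) + 1L)])
    keep <- stats::runif(length(cand)) < (1 - bias * p_env)
    times <- c(times, cand[keep])
  }
  sort(times[seq_len(n_ev)])
}

#' Generate one synthetic subject recording
#'
#' Each neural channel is `strength * z(band-filtered driver) + 1/f noise`;
#' the ocular channel additionally carries a Poisson train of large biphasic
#' blink pulses. The driver is the speech envelope in the forward condition
#' and the time-reversed envelope in the backward condition, so backward
#' recordings are at chance coherence with the forward-order envelope.
#' Coupling is band-limited to `spec$coupling_band`.
#'
#' @param envelope A `stimulus_signal` (forward-order speech envelope) whose
#'   rate matches `spec$rate`.
#' @param spec A [cohort_spec()].
#' @param n_neural Number of neural channels (>= 1).
#' @param condition `"forward"` or `"backward"`.
#' @param seed Integer seed.
#' @param subject_id,group Labels stored on the recording.
#' @return A `subject_recording`.
#' @export
make_subject_recording <- function(envelope, spec, n_neural = spec$n_neural,
                                   condition = c("forward", "backward"),
                                   seed = 1L, subject_id = "s01",
                                   group = "hearing") {
  condition <- match.arg(condition)
  stopifnot(inherits(envelope, "stimulus_signal"), inherits(spec, "cohort_spec"))
  if (n_neural < 1) stop("`n_neural` must be >= 1", call. = FALSE)
  if (any(spec$coupling_band <= 0) || spec$coupling_band[2] >= envelope$rate / 2)
    stop("`coupling_band` must lie inside (0, rate/2)", call. = FALSE)
  set.seed(as.integer(seed))
  rate <- envelope$rate
  n <- length(envelope$samples)
  duration <- n / rate

  driver <- envelope$samples
  if (condition == "backward") driver <- rev(driver)
  drv <- butter_bandpass_zerophase(driver, rate,
                                   spec$coupling_band[1], spec$coupling_band[2])
  drv <- as.numeric(scale(drv))

  strength <- spec$coupling_strength[group, condition]
  data <- matrix(0, nrow = n_neural + 1L, ncol = n)
  for (ch in seq_len(n_neural)) {
    data[ch, ] <- strength * drv + one_over_f_noise(n, spec$noise_exponent)
  }
  ocular <- spec$ocular_gain * strength * drv +
    one_over_f_noise(n, spec$noise_exponent)
  bias <- if (condition == "forward") spec$blink_trough_bias else 0
  bt <- draw_blink_times(duration, spec$blink_rate,
                         envelope = stimulus_signal(driver, rate, "envelope"),
                         bias = bias)
  pulse <- blink_pulse(rate) * 8     # blinks dominate the ocular channel
  for (t0 in bt) {
    i0 <- floor(t0 * rate) + 1L
    idx <- i0:min(n, i0 + length(pulse) - 1L)
    ocular[idx] <- ocular[idx] + pulse[seq_along(idx)]
  }
  data[n_neural + 1L, ] <- ocular
  rec <- subject_recording(data, rate,
                           c(rep("neural", n_neural), "ocular"),
                           condition = condition, subject_id = subject_id,
                           group = group)
  attr(rec, "blink_times") <- bt
  rec
}

#' Generate a full synthetic cohort
#'
#' One shared stimulus (speech envelope and correlated lip signal, as in a
#' study where all participants view the same videos) and, per subject, one
#' forward and one backward recording with group-specific coupling strength
#' and independent noise.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: list with `envelope` (150 Hz),
#'   `lip` (50 Hz), `recordings` (list of `subject_recording`, two per
#'   subject), and `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$n_per_group < 2 & spec$n_per_group > 0))
    stop("groups entering the statistics need n >= 2 subjects", call. = FALSE)
  envelope <- make_speech_envelope(spec$duration, spec$rate,
                                   spec$syllable_rate, spec$sentence_rate,
                                   seed = substream_seed(spec$seed, "envelope"))
  lip <- make_lip_signal(envelope, spec$lip_corr,
                         seed = substream_seed(spec$seed, "lip"))
  recordings <- list()
  sidx <- 0L
  for (g in names(spec$n_per_group)) {
    ng <- spec$n_per_group[[g]]
    if (ng == 0) next
    for (i in seq_len(ng)) {
      sidx <- sidx + 1L
      sid <- sprintf("s%03d", sidx)
      for (cond in c("forward", "backward")) {
        recordings[[length(recordings) + 1L]] <-
          make_subject_recording(envelope, spec,
                                 condition = cond,
                                 seed = substream_seed(spec$seed,
                                                       paste(sid, cond)),
                                 subject_id = sid, group = g)
      }
    }
  }
  structure(list(envelope = envelope, lip = lip, recordings = recordings,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d recordings (%d subjects x 2 conditions), %gs @ %g Hz\n",
              length(x$recordings), length(x$recordings) / 2,
              x$spec$duration, x$spec$rate))
  invisible(x)
}

#' Common-source validation fixture for partial coherence
#'
#' Builds a recording whose two neural channels are driven by one latent
#' band-limited source plus independent noise, with the ocular channel
#' carrying the latent source itself (`shared = TRUE`), or with all three
#' channels driven by independent band-limited sources (`shared = FALSE`).
#' In the shared case, partializing the ocular channel out of a
#' neural-neural coherence removes the coherence the common drive creates;
#' in the independent case partialization leaves coherence unchanged up to
#' estimation error.
#'
#' @param duration Seconds.
#' @param rate Sampling rate, Hz.
#' @param band Numeric length-2 drive band in Hz, inside `(0, rate/2)`.
#' @param seed Integer seed.
#' @param noise_sd Independent-noise standard deviation relative to the
#'   unit-variance drive (default 0.3, giving strong in-band coherence).
#' @param shared Logical: one latent source (TRUE) or three independent
#'   sources (FALSE).
#' @return A `subject_recording` with channels `neural1`, `neural2`, `ocular`.
#' @export
make_common_source_pair <- function(duration, rate, band, seed = 1L,
                                    noise_sd = 0.3, shared = TRUE) {
  if (any(band <= 0) || band[2] >= rate / 2 || band[1] >= band[2])
    stop("`band` must lie inside (0, rate/2)", call. = FALSE)
  set.seed(as.integer(seed))
  n <- round(duration * rate)
  src <- function() band_limited_noise(n, rate, band)
  z <- src()
  mk <- function() {
    drive <- if (shared) z else src()
    drive + noise_sd * stats::rnorm(n)
  }
  oc <- if (shared) z else mk()
  data <- matrix(c(mk(), mk(), oc), nrow = 3, byrow = TRUE)
  subject_recording(data, rate, c("neural", "neural", "ocular"),
                    condition = "forward", subject_id = "fixture",
                    group = "hearing")
}
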