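#' Construct a stimulus feature time series
#'
#' A `stimulus_signal` holds one stimulus feature -- either the acoustic
#' speech envelope or the lip-area trace -- together with its sampling rate
#' and a role tag. Envelope-role signals are constrained to be non-negative
#' (the envelope is a magnitude).
#'
#' @param samples Numeric vector of samples (arbitrary units).
#' @param rate Sampling rate in Hz; must be positive.
#' @param role One of `"envelope"` or `"lip"`.
#' @return An object of class `stimulus_signal` with fields `samples`,
#'   `rate` and `role`.
#' @export
stimulus_signal <- function(samples, rate, role = c("envelope", "lip")) {
  role <- match.arg(role)
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  if (role == "envelope" && any(samples < 0))
    stop("envelope-role signals must be non-negative", call. = FALSE)
  structure(list(samples = samples, rate = rate, role = role),
            class = "stimulus_signal")
}

#' @export
print.stimulus_signal <- function(x, ...) {
  cat(sprintf("<stimulus_signal> role=%s, %d samples @ %g Hz (%.1f s)\n",
              x$role, length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a stimulus signal in seconds
#' @param x A `stimulus_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate

#' Construct a single-subject, single-condition recording
#'
#' A `subject_recording` is a channels-by-samples matrix with one row per
#' channel. Exactly one channel must carry the role `"ocular"` (the
#' blink-dominated eye-movement component); the remaining channels are
#' `"neural"` (source-level virtual channels).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate Sampling rate in Hz.
#' @param channel_roles Character vector, one of `"neural"`/`"ocular"` per row.
#' @param condition `"forward"` or `"backward"`.
#' @param subject_id Identifier string.
#' @param group One of `"hearing"`, `"dhh"`, `"congenital"`.
#' @return An object of class `subject_recording`.
#' @export
subject_recording <- function(data, rate, channel_roles,
                              condition = c("forward", "backward"),
                              subject_id = "s01",
                              group = c("hearing", "dhh", "congenital")) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  data <- as.matrix(data)
  if (length(channel_roles) != nrow(data))
    stop("one channel role per data row is required", call. = FALSE)
  if (!all(channel_roles %in% c("neural", "ocular")))
    stop("channel roles must be 'neural' or 'ocular'", call. = FALSE)
  if (sum(channel_roles == "ocular") != 1L)
    stop("exactly one ocular channel is required", call. = FALSE)
  if (is.null(rownames(data))) {
    nm <- character(nrow(data))
    nm[channel_roles == "neural"] <-
      paste0("neural", seq_len(sum(channel_roles == "neural")))
    nm[channel_roles == "ocular"] <- "ocular"
    rownames(data) <- nm
  }
  structure(list(data = data, rate = rate, channel_roles = channel_roles,
                 condition = condition, subject_id = subject_id,
                 group = group),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf(
    "<subject_recording> %s [%s/%s]: %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$group, x$condition, nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Specify a synthetic cohort
#'
#' Bundles every free parameter of the synthetic-cohort generator: group
#' sizes, stimulus timing, the frequency band in which the envelope drives
#' the recorded channels, per-group/per-condition coupling strengths, blink
#' statistics, and the background-noise spectrum.
#'
#' Defaults mirror the study conditions the pipeline is designed around:
#' group sizes 49/19/7 (hearing / acquired deaf-or-hard-of-hearing /
#' congenitally deaf), a 3.3 Hz syllable rate with a ~0.25 Hz sentence rate,
#' envelope-to-channel coupling confined to 0.33-0.83 Hz and present only in
#' the forward condition, stronger coupling for the DHH group than the
#' hearing group and none for the congenitally deaf group, a 0.2 Hz Poisson
#' blink train, and 1/f background noise.
#'
#' @param n_per_group Named integer vector `c(hearing=, dhh=, congenital=)`.
#' @param duration Seconds of recording per condition.
#' @param rate Recording/envelope sampling rate, Hz.
#' @param n_neural Number of neural-role channels per recording.
#' @param coupling_band Numeric length-2, Hz; envelope-to-channel coupling is
#'   band-limited to this range.
#' @param coupling_strength Matrix (groups x conditions, dimnames required)
#'   of coupling strengths in \[0, 1\]; rows `hearing`, `dhh`, `congenital`;
#'   columns `forward`, `backward`.
#' @param ocular_gain Multiplier applied to the coupling strength for the
#'   ocular channel (the ocular effect can differ in size from the neural one).
#' @param blink_rate Poisson blink rate, Hz.
#' @param blink_trough_bias In \[0, 1\]; 0 places blinks uniformly, values
#'   towards 1 bias forward-condition blinks into envelope troughs.
#' @param noise_exponent Spectral slope of the 1/f^a background noise.
#' @param syllable_rate,sentence_rate Envelope modulation rates, Hz.
#' @param lip_corr Target correlation between lip signal and envelope.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(hearing = 49L, dhh = 19L, congenital = 7L),
                        duration = 564,
                        rate = 150,
                        n_neural = 6L,
                        coupling_band = c(0.33, 0.83),
                        coupling_strength = default_coupling(),
                        ocular_gain = 1,
                        blink_rate = 0.2,
                        blink_trough_bias = 0,
                        noise_exponent = 1,
                        syllable_rate = 3.3,
                        sentence_rate = 0.25,
                        lip_corr = 0.5,
                        seed = 1L) {
  if (length(coupling_band) != 2L || coupling_band[1] >= coupling_band[2])
    stop("`coupling_band` must be c(f_lo, f_hi) with f_lo < f_hi", call. = FALSE)
  if (any(coupling_band <= 0) || coupling_band[2] >= rate / 2)
    stop("`coupling_band` must lie inside (0, rate/2)", call. = FALSE)
  if (any(coupling_strength < 0 | coupling_strength > 1))
    stop("coupling strengths must lie in [0, 1]", call. = FALSE)
  stopifnot(all(c("hearing", "dhh", "congenital") %in% rownames(coupling_strength)),
            all(c("forward", "backward") %in% colnames(coupling_strength)))
  if (any(n_per_group < 0)) stop("group sizes must be non-negative", call. = FALSE)
  structure(list(n_per_group = n_per_group, duration = duration, rate = rate,
                 n_neural = as.integer(n_neural),
                 coupling_band = coupling_band,
                 coupling_strength = coupling_strength,
                 ocular_gain = ocular_gain,
                 blink_rate = blink_rate,
                 blink_trough_bias = blink_trough_bias,
                 noise_exponent = noise_exponent,
                 syllable_rate = syllable_rate, sentence_rate = sentence_rate,
                 lip_corr = lip_corr, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default coupling-strength matrix
#'
#' Envelope coupling present only in the forward condition; the acquired-DHH
#' group couples more strongly than the hearing group and the congenitally
#' deaf group not at all.
#'
#' @return 3x2 matrix with dimnames (group x condition).
#' @export
default_coupling <- function() {
  m <- matrix(c(0.30, 0, 0.45, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("hearing", "dhh", "congenital"),
                              c("forward", "backward")))
  m
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n=(%s), %gs @ %g Hz, band %.2f-%.2f Hz, seed %d\n",
    paste(x$n_per_group, collapse = ","), x$duration, x$rate,
    x$coupling_band[1], x$coupling_band[2], x$seed))
  invisible(x)
}

# Derive a reproducible substream seed (< 2^31) from a master seed and a
# stream label, so e.g. changing the permutation count never perturbs the
# synthetic data.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 99991L)
}
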