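#' Detect blinks on an ocular channel
#'
#' Smooths the signal with a 150 ms window (blink pulses last ~300 ms, so
#' they survive while fast noise is suppressed), robust-z-scores it with
#' median/MAD (so the blinks themselves do not inflate the scale estimate),
#' then takes local maxima above `z_thresh`, enforcing a refractory period
#' by keeping the largest peak within each conflict.
#'
#' @param x Numeric vector (ocular channel) or a `subject_recording`, whose
#'   ocular-role channel is used.
#' @param rate Sampling rate in Hz (taken from the recording if given).
#' @param z_thresh Detection threshold in robust SD units (default 3).
#' @param refractory Minimum event separation in seconds (default 0.5).
#' @return An object of class `blink_events`: list with `times` (s,
#'   strictly increasing), `rate_hz` (events per second), `duration`,
#'   `condition` (if known).
#' @export
detect_blinks <- function(x, rate = NULL, z_thresh = 3, refractory = 0.5) {
  condition <- NA_character_
  if (inherits(x, "subject_recording")) {
    rate <- x$rate
    condition <- x$condition
    x <- x$data[x$channel_roles == "ocular", ]
  }
  if (is.null(rate)) stop("`rate` is required", call. = FALSE)
  n <- length(x)
  if (n <= refractory * rate)
    stop("signal shorter than the refractory period", call. = FALSE)
  nk <- max(3L, round(0.15 * rate))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nk - 1) / (nk - 1))
  w <- w / sum(w)
  xs <- stats::filter(c(rep(x[1], nk), x, rep(x[n], nk)), w, sides = 2)
  x <- as.numeric(xs[nk + seq_len(n)])
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv < .Machine$double.eps) {
    warning("flat signal (MAD = 0); blink detection undefined")
    return(structure(list(times = numeric(0), rate_hz = NA_real_,
                          duration = n / rate, condition = condition),
                     class = "blink_events"))
  }
  z <- (x - med) / madv
  is_peak <- z > z_thresh &
    z >= c(-Inf, z[-n]) & z > c(z[-1], -Inf)
  cand <- which(is_peak)
  # greedy refractory pruning, strongest peaks first
  keep <- logical(length(cand))
  ord <- order(z[cand], decreasing = TRUE)
  taken <- numeric(0)
  gap <- refractory * rate
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= gap)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  times <- sort((cand[keep] - 1) / rate)
  structure(list(times = times, rate_hz = length(times) / (n / rate),
                 duration = n / rate, condition = condition),
            class = "blink_events")
}

#' @export
print.blink_events <- function(x, ...) {
  cat(sprintf("<blink_events> %d events in %.1f s (%.3f Hz)\n",
              length(x$times), x$duration, x$rate_hz))
  invisible(x)
}

#' Blink rate in events per second
#'
#' @param events A `blink_events` object.
#' @param duration Observation duration in seconds (> 0); defaults to the
#'   duration recorded at detection.
#' @return Rate in Hz (`count / duration`).
#' @export
blink_rate <- function(events, duration = events$duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  length(events$times) / duration
}

#' Z-scored envelope value at blink times
#'
#' Z-scores the envelope over the whole recording and samples it at each
#' event center. A negative mean indicates blinks preferentially occur in
#' envelope troughs.
#'
#' @param events A `blink_events` object.
#' @param envelope A `stimulus_signal` covering all event times.
#' @return List with `values` (z-scored envelope at each event) and `mean`.
#' @export
envelope_at_blinks <- function(events, envelope) {
  stopifnot(inherits(envelope, "stimulus_signal"))
  dur <- signal_duration(envelope)
  if (length(events$times) && max(events$times) > dur)
    stop("event outside envelope support", call. = FALSE)
  z <- as.numeric(scale(envelope$samples))
  idx <- pmin(length(z), floor(events$times * envelope$rate) + 1L)
  vals <- z[idx]
  list(values = vals, mean = if (length(vals)) mean(vals) else NA_real_)
}
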