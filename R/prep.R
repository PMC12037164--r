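#' Zero-phase Hamming-window FIR bandpass filter (overlap-add)
#'
#' Designs a symmetric linear-phase FIR bandpass with a Hamming window and
#' applies it by overlap-add FFT convolution. The kernel length follows the
#' transition-band rule `round(6.6 / transition * rate)` (forced odd), with
#' `transition` the shortest of the two transition bands. The symmetric
#' kernel's group delay is compensated exactly, so filtering is zero-phase;
#' the input is reflect-padded by one kernel length at each end to keep
#' recording edges usable.
#'
#' @param x Numeric vector, or matrix with channels in rows.
#' @param rate Sampling rate, Hz.
#' @param hp High-pass edge, Hz (default 0.1).
#' @param lp Low-pass edge, Hz (default 12).
#' @param transition_hp,transition_lp Transition bandwidths in Hz. Defaults
#'   follow common MEG-toolbox practice: `min(hp, 2)` for the high-pass edge
#'   and `0.25 * lp` for the low-pass edge.
#' @return Filtered signal, same shape as `x`; the kernel length used is
#'   attached as attribute `"kernel_length"`.
#' @export
fir_bandpass <- function(x, rate, hp = 0.1, lp = 12,
                         transition_hp = min(hp, 2),
                         transition_lp = 0.25 * lp) {
  if (!(hp > 0 && hp < lp && lp < rate / 2))
    stop("require 0 < hp < lp < rate/2", call. = FALSE)
  transition <- min(transition_hp, transition_lp)
  L <- round(6.6 / transition * rate)
  if (L %% 2 == 0) L <- L + 1L
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < L)
    stop(sprintf("signal too short for the designed kernel: need >= %d samples (%.1f s), got %d",
                 L, L / rate, n), call. = FALSE)
  b <- signal::fir1(L - 1L, c(hp, lp) / (rate / 2), type = "pass",
                    window = signal::hamming(L))
  half <- (L - 1L) / 2L
  filt1 <- function(v) {
    pad <- c(rev(v[seq_len(min(L, n))]), v, rev(v[(n - min(L, n) + 1L):n]))
    npad <- min(L, n)
    y <- signal::fftfilt(b, c(pad, numeric(half)))
    y <- y[(half + 1L):(half + length(pad))]   # compensate group delay
    y[(npad + 1L):(npad + n)]
  }
  out <- if (is.matrix(x)) t(apply(x, 1L, filt1)) else filt1(x)
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  attr(out, "kernel_length") <- L
  out
}

#' Segment a recording (plus aligned stimulus features) into fixed epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_length` seconds; the trailing remainder is dropped. Stimulus
#' features are carried along as extra channel rows (role `"stimulus"`), so
#' stimulus/channel alignment is preserved by construction.
#'
#' @param recording A `subject_recording`.
#' @param stimuli Named list of `stimulus_signal`s at the recording rate
#'   (e.g. `list(envelope = ..., lip = ...)`); may be empty.
#' @param epoch_length Epoch duration in seconds (default 6).
#' @return An object of class `epochs`: list with `data` (array epochs x
#'   channels x samples), `rate`, `epoch_length`, `condition` (one label per
#'   epoch), `subject_id`, `group`, `channel_names`, `channel_roles`.
#' @export
epoch_segments <- function(recording, stimuli = list(), epoch_length = 6) {
  stopifnot(inherits(recording, "subject_recording"))
  dat <- recording$data
  roles <- recording$channel_roles
  nms <- rownames(dat)
  for (nm in names(stimuli)) {
    s <- stimuli[[nm]]
    if (!isTRUE(all.equal(s$rate, recording$rate)))
      stop(sprintf("stimulus '%s' rate (%g Hz) does not match recording rate (%g Hz)",
                   nm, s$rate, recording$rate), call. = FALSE)
    m <- min(ncol(dat), length(s$samples))
    dat <- rbind(dat[, seq_len(m), drop = FALSE], s$samples[seq_len(m)])
    roles <- c(roles, "stimulus")
    nms <- c(nms, nm)
  }
  nsamp <- round(epoch_length * recording$rate)
  n_ep <- floor(ncol(dat) / nsamp)
  if (n_ep < 1)
    stop("recording shorter than one epoch", call. = FALSE)
  arr <- array(NA_real_, dim = c(n_ep, nrow(dat), nsamp))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- dat[, ((e - 1L) * nsamp + 1L):(e * nsamp)]
  }
  structure(list(data = arr, rate = recording$rate,
                 epoch_length = epoch_length,
                 condition = rep(recording$condition, n_ep),
                 subject_id = recording$subject_id, group = recording$group,
                 channel_names = nms, channel_roles = roles),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf("<epochs> %s [%s]: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              x$subject_id, x$group, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3], x$epoch_length, x$rate))
  cat(" conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                    table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Combine epoched blocks, inheriting per-block condition labels
#'
#' Epochs each block (a condition-tagged `subject_recording`) and
#' concatenates the epochs; every epoch inherits the tag of its source
#' block.
#'
#' @param blocks List of `subject_recording`s from one subject.
#' @param stimuli Named list of `stimulus_signal`s carried into each block's
#'   epochs (see [epoch_segments()]).
#' @param epoch_length Epoch duration in seconds (default 6).
#' @return An `epochs` object covering all blocks.
#' @export
assign_conditions <- function(blocks, stimuli = list(), epoch_length = 6) {
  if (length(blocks) == 0) stop("no blocks supplied", call. = FALSE)
  for (b in blocks) {
    if (!inherits(b, "subject_recording") || is.null(b$condition))
      stop("every block must be a condition-tagged subject_recording",
           call. = FALSE)
  }
  eps <- lapply(blocks, epoch_segments, stimuli = stimuli,
                epoch_length = epoch_length)
  ref <- eps[[1L]]
  for (e in eps[-1L]) {
    if (!identical(e$channel_names, ref$channel_names) ||
        !isTRUE(all.equal(e$rate, ref$rate)))
      stop("blocks disagree in channels or rate", call. = FALSE)
  }
  dat <- do.call(abind1, lapply(eps, function(e) e$data))
  structure(list(data = dat, rate = ref$rate, epoch_length = epoch_length,
                 condition = unlist(lapply(eps, function(e) e$condition)),
                 subject_id = ref$subject_id, group = ref$group,
                 channel_names = ref$channel_names,
                 channel_roles = ref$channel_roles),
            class = "epochs")
}

# bind 3-d arrays along the first margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0)),
                                 d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
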