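resolve_channel <- function(csd, ch) {
  if (is.character(ch)) {
    i <- match(ch, csd$channel_names)
    if (is.na(i)) stop(sprintf("unknown channel '%s'", ch), call. = FALSE)
    i
  } else as.integer(ch)
}

#' Magnitude-squared coherence between two channels of a CSD
#'
#' `C_ab(f) = |S_ab(f)|^2 / (S_aa(f) S_bb(f))`, bounded in \[0, 1\]. For
#' independent signals the expected estimate is `1 / n_est` (the chance
#' level). Frequencies where either auto-spectrum is numerically zero are
#' returned as `NA` (undefined, not zero) and excluded downstream.
#'
#' @param csd A `csd` object.
#' @param a,b Channel names or indices; must differ.
#' @return An object of class `coherence_spectrum`: list with `values`,
#'   `freqs`, `pair`, `partialized` (NULL here), `n_est`.
#' @export
coherence <- function(csd, a, b) {
  stopifnot(inherits(csd, "csd"))
  ia <- resolve_channel(csd, a); ib <- resolve_channel(csd, b)
  if (ia == ib) stop("`a` and `b` must be different channels", call. = FALSE)
  saa <- Re(csd$matrices[ia, ia, ])
  sbb <- Re(csd$matrices[ib, ib, ])
  sab <- csd$matrices[ia, ib, ]
  denom <- saa * sbb
  vals <- rep(NA_real_, length(denom))
  ok <- denom > .Machine$double.eps
  vals[ok] <- Mod(sab[ok])^2 / denom[ok]
  vals[ok] <- pmin(1, pmax(0, vals[ok]))
  structure(list(values = vals, freqs = csd$freqs,
                 pair = c(csd$channel_names[ia], csd$channel_names[ib]),
                 partialized = NULL, n_est = csd$n_est),
            class = "coherence_spectrum")
}

#' Partial coherence, removing a third channel's linear contribution
#'
#' At each frequency the cross-spectral entries among `(a, b)` are
#' partialized on `z` with the Schur-complement form
#' `S_xy|z = S_xy - S_xz S_zz^{-1} S_zy`, and coherence is computed from the
#' partialized entries. This retains only the coherence between `a` and `b`
#' that cannot be attributed to the linear influence of `z` (e.g. brain-
#' stimulus coherence not attributable to eye movements). A zero-power `z`
#' is treated as a no-op with a warning.
#'
#' @param csd A `csd` object.
#' @param a,b Channel names or indices.
#' @param z Channel to partialize out; must differ from `a` and `b`.
#' @return A `coherence_spectrum` with `partialized` set to the name of `z`.
#' @export
partial_coherence <- function(csd, a, b, z) {
  stopifnot(inherits(csd, "csd"))
  ia <- resolve_channel(csd, a); ib <- resolve_channel(csd, b)
  iz <- resolve_channel(csd, z)
  if (iz == ia || iz == ib)
    stop("`z` must differ from `a` and `b`", call. = FALSE)
  if (ia == ib) stop("`a` and `b` must be different channels", call. = FALSE)
  szz <- Re(csd$matrices[iz, iz, ])
  if (all(szz <= .Machine$double.eps)) {
    warning("partialization channel has zero power; returning raw coherence")
    out <- coherence(csd, ia, ib)
    out$partialized <- csd$channel_names[iz]
    return(out)
  }
  saa <- Re(csd$matrices[ia, ia, ]); sbb <- Re(csd$matrices[ib, ib, ])
  sab <- csd$matrices[ia, ib, ]
  saz <- csd$matrices[ia, iz, ]; sbz <- csd$matrices[ib, iz, ]
  ok <- szz > .Machine$double.eps
  paa <- saa; pbb <- sbb; pab <- sab
  paa[ok] <- saa[ok] - Mod(saz[ok])^2 / szz[ok]
  pbb[ok] <- sbb[ok] - Mod(sbz[ok])^2 / szz[ok]
  pab[ok] <- sab[ok] - saz[ok] * Conj(sbz[ok]) / szz[ok]
  denom <- Re(paa) * Re(pbb)
  vals <- rep(NA_real_, length(denom))
  good <- ok & denom > .Machine$double.eps
  vals[good] <- Mod(pab[good])^2 / denom[good]
  vals[good] <- pmin(1, pmax(0, vals[good]))
  # bins where z was degenerate fall back to raw coherence
  if (any(!ok)) {
    raw <- coherence(csd, ia, ib)
    vals[!ok] <- raw$values[!ok]
  }
  structure(list(values = vals, freqs = csd$freqs,
                 pair = c(csd$channel_names[ia], csd$channel_names[ib]),
                 partialized = csd$channel_names[iz], n_est = csd$n_est),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  p <- if (is.null(x$partialized)) "" else sprintf(" | %s", x$partialized)
  cat(sprintf("<coherence_spectrum> %s ~ %s%s, %d freqs, n_est=%d\n",
              x$pair[1], x$pair[2], p, length(x$freqs), x$n_est))
  invisible(x)
}

#' Forward-minus-backward condition contrast
#'
#' @param coh_f,coh_b `coherence_spectrum`s for the same pair on the same
#'   frequency grid (forward and backward condition).
#' @return An object of class `contrast_spectrum` with
#'   `values = forward - backward`.
#' @export
condition_contrast <- function(coh_f, coh_b) {
  stopifnot(inherits(coh_f, "coherence_spectrum"),
            inherits(coh_b, "coherence_spectrum"))
  if (!isTRUE(all.equal(coh_f$freqs, coh_b$freqs)))
    stop("frequency grids differ", call. = FALSE)
  if (!identical(coh_f$pair, coh_b$pair))
    stop("channel pairs differ", call. = FALSE)
  structure(list(values = coh_f$values - coh_b$values, freqs = coh_f$freqs,
                 pair = coh_f$pair, partialized = coh_f$partialized),
            class = "contrast_spectrum")
}

#' Band average of a coherence or contrast spectrum
#'
#' Unweighted mean of the values at grid frequencies `f` with
#' `f_lo <= f < f_hi` (lower edge inclusive, upper exclusive, matching
#' "below 1 Hz" band summaries). `NA` (undefined) bins are excluded.
#'
#' @param spec A `coherence_spectrum` or `contrast_spectrum`.
#' @param band Numeric length-2, Hz.
#' @return Scalar mean.
#' @export
band_average <- function(spec, band) {
  tol <- 1e-9
  sel <- spec$freqs >= band[1] - tol & spec$freqs < band[2] - tol
  if (!any(sel))
    stop("band does not intersect the frequency grid", call. = FALSE)
  mean(spec$values[sel], na.rm = TRUE)
}

#' Select the ROI channel with the strongest condition effect
#'
#' Among the channels of `roi`, returns the one maximizing the band-averaged
#' forward-minus-backward contrast over `criterion_band`. Ties break
#' deterministically in favor of the earlier channel in `roi`.
#'
#' @param contrast_by_channel Named list mapping channel name to its
#'   `contrast_spectrum` (group-mean forward-backward contrast).
#' @param roi Character vector of channel names to search; non-empty.
#' @param criterion_band Numeric length-2 band in Hz (default `c(0, 1)`).
#' @return The selected channel name.
#' @export
roi_peak_select <- function(contrast_by_channel, roi,
                            criterion_band = c(0, 1)) {
  if (length(roi) == 0) stop("`roi` must be non-empty", call. = FALSE)
  missing <- setdiff(roi, names(contrast_by_channel))
  if (length(missing))
    stop(sprintf("no contrast for channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  score <- vapply(roi, function(ch)
    band_average(contrast_by_channel[[ch]], criterion_band), 0)
  roi[which.max(score)]   # which.max takes the first maximum: stable tie-break
}
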