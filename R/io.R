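#' Write a stimulus signal to delimited text with a JSON sidecar
#'
#' The samples go to a single-column TSV with a header row; rate and role go
#' to `<path>.json`.
#'
#' @param x A `stimulus_signal`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_stimulus_signal <- function(x, path) {
  stopifnot(inherits(x, "stimulus_signal"))
  df <- data.frame(value = x$samples)
  names(df) <- x$role
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rate = x$rate, role = x$role,
                            n_samples = length(x$samples)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulus signal written by [write_stimulus_signal()]
#' @param path TSV path (the `.json` sidecar must sit next to it).
#' @return A `stimulus_signal`.
#' @export
read_stimulus_signal <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stimulus_signal(df[[1]], meta$rate, meta$role)
}

#' Write a subject recording to delimited text with a JSON sidecar
#'
#' One column per channel (header row carries channel names); rate, roles,
#' condition and labels go to `<path>.json`.
#'
#' @param x A `subject_recording`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "subject_recording"))
  df <- as.data.frame(t(x$data))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rate = x$rate,
                            channel_roles = x$channel_roles,
                            channel_names = rownames(x$data),
                            condition = x$condition,
                            subject_id = x$subject_id, group = x$group),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subject recording written by [write_recording()]
#' @param path TSV path.
#' @return A `subject_recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data <- t(as.matrix(df))
  rownames(data) <- meta$channel_names
  subject_recording(data, meta$rate, meta$channel_roles,
                    condition = meta$condition,
                    subject_id = meta$subject_id, group = meta$group)
}

#' Tidy coherence table
#'
#' Flattens per-subject coherence/contrast spectra into a long data.frame
#' (subject, group, condition, pair, partialized, frequency, value), the
#' format written alongside pipeline results.
#'
#' @param specs Named or unnamed list of `coherence_spectrum` /
#'   `contrast_spectrum` objects.
#' @param subject,group,condition Recycled annotation columns.
#' @return data.frame in long format.
#' @export
coherence_table <- function(specs, subject = NA, group = NA, condition = NA) {
  if (inherits(specs, "coherence_spectrum") ||
      inherits(specs, "contrast_spectrum")) specs <- list(specs)
  rows <- lapply(specs, function(s) {
    data.frame(subject = subject, group = group, condition = condition,
               channel = s$pair[1], stimulus = s$pair[2],
               partialized = if (is.null(s$partialized)) NA_character_
                             else s$partialized,
               frequency = s$freqs, value = s$values)
  })
  do.call(rbind, rows)
}

#' Serialize cluster results to JSON
#'
#' Per cluster: member bins, member frequencies in Hz (when a frequency grid
#' is supplied), mass, sign and permutation p-value.
#'
#' @param result A `cluster_result`.
#' @param path Output JSON path.
#' @param freqs Optional frequency grid to translate member bins to Hz.
#' @return `path`, invisibly.
#' @export
write_cluster_json <- function(result, path, freqs = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  clusters <- lapply(result$clusters, function(cl) {
    out <- list(members = cl$members, mass = cl$mass, p = cl$p,
                sign = if (is.null(cl$sign)) 1L else cl$sign)
    if (!is.null(freqs)) {
      nf <- length(freqs)
      out$freq_hz <- freqs[((cl$members - 1L) %% nf) + 1L]
    }
    out
  })
  jsonlite::write_json(list(clusters = clusters,
                            n_perm = result$n_perm,
                            cluster_alpha = result$cluster_alpha,
                            threshold = result$threshold,
                            seed = result$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
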