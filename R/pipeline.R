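#' Assemble a pipeline run configuration
#'
#' Bundles every analysis parameter -- input mode, cohort specification,
#' filter settings, epoching, frequency grid, spectral smoothing, cluster
#' statistics settings and the master seed -- into one serializable object.
#' One master seed spawns named substreams (cohort generation, each
#' permutation test), so changing e.g. `n_perm` never changes the synthetic
#' data.
#'
#' @param mode `"synthetic"` (generate a cohort from `cohort`) or `"files"`
#'   (load a manifest of recordings written by [write_recording()]).
#' @param cohort A [cohort_spec()] (synthetic mode).
#' @param manifest For files mode: list with `recordings` (TSV paths),
#'   `envelope` and `lip` (stimulus TSV paths).
#' @param hp,lp Broadband FIR filter edges, Hz.
#' @param epoch_length Epoch length, s.
#' @param freqs Analysis frequency grid, Hz.
#' @param half_bandwidth Multitaper smoothing half-bandwidth, Hz.
#' @param cluster_alpha Cluster-forming threshold p-value.
#' @param n_perm Permutations per cluster test.
#' @param summary_band Band (Hz) for the ROI / ocular band-averaged
#'   summaries (default below 1 Hz).
#' @param out_dir Output directory or `NULL` for in-memory results only.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       cohort = cohort_spec(),
                       manifest = NULL,
                       hp = 0.1, lp = 12,
                       epoch_length = 6,
                       freqs = default_freq_grid(),
                       half_bandwidth = 0.5,
                       cluster_alpha = 0.01,
                       n_perm = 1000L,
                       summary_band = c(0, 1),
                       out_dir = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(manifest))
    stop("files mode needs a `manifest`", call. = FALSE)
  structure(list(mode = mode, cohort = cohort, manifest = manifest,
                 hp = hp, lp = lp, epoch_length = epoch_length,
                 freqs = freqs, half_bandwidth = half_bandwidth,
                 cluster_alpha = cluster_alpha, n_perm = as.integer(n_perm),
                 summary_band = summary_band, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(config) {
  if (config$mode == "synthetic") {
    spec <- config$cohort
    spec$seed <- substream_seed(config$seed, "cohort")
    make_cohort(spec)
  } else {
    m <- config$manifest
    structure(list(envelope = read_stimulus_signal(m$envelope),
                   lip = read_stimulus_signal(m$lip),
                   recordings = lapply(m$recordings, read_recording),
                   spec = NULL),
              class = "cohort")
  }
}

#' Run the full silent-speech tracking analysis
#'
#' Executes the three coherence steps on every subject -- (1) ocular vs
#' stimulus coherence, (2) neural-channel vs stimulus coherence, (3)
#' neural-channel vs stimulus partial coherence with the ocular channel
#' partialized out -- then the forward-minus-backward cluster permutation
#' t tests for each step, the mixed 2 x 3 ANOVA (modality x group) on the
#' contrasts when more than one group is present, and the supplementary
#' blink analysis. Intermediate tables and statistics can be written to
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A results bundle (class `strack_bundle`): coherence arrays,
#'   contrast arrays, `cluster_result`s, `anova_result`s, blink summaries,
#'   the ROI summary table, the config, and a parameter log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- load_inputs(config)
  rate <- cohort$envelope$rate
  freqs <- config$freqs
  nf <- length(freqs)

  # --- stimulus features: filter at the analysis rate; lip upsampled first.
  # The high-pass removes the envelope's mean, so the filtered feature is
  # built without the non-negativity check of stimulus_signal().
  env_f <- structure(list(
    samples = as.numeric(fir_bandpass(cohort$envelope$samples, rate,
                                      config$hp, config$lp)),
    rate = rate, role = "envelope"), class = "stimulus_signal")
  lip150 <- fft_resample(cohort$lip, rate)
  lip_f <- structure(list(
    samples = as.numeric(fir_bandpass(lip150$samples, rate,
                                      config$hp, config$lp)),
    rate = rate, role = "lip"), class = "stimulus_signal")
  stimuli <- list(envelope = env_f, lip = lip_f)

  # --- per subject/condition spectra and CSDs
  recs <- cohort$recordings
  subjects <- unique(vapply(recs, function(r) r$subject_id, ""))
  groups <- unname(vapply(subjects, function(s) {
    recs[[which(vapply(recs, function(r) r$subject_id, "") == s)[1]]]$group
  }, ""))
  n_sub <- length(subjects)
  neural_names <- NULL

  coh <- list()   # nested: [[subject]][[condition]] -> list of spectra
  blink <- list()
  for (s in subjects) {
    coh[[s]] <- list()
    blink[[s]] <- list()
    for (cond in c("forward", "backward")) {
      r <- recs[[which(vapply(recs, function(x) x$subject_id, "") == s &
                       vapply(recs, function(x) x$condition, "") == cond)[1]]]
      dat <- fir_bandpass(r$data, rate, config$hp, config$lp)
      rr <- r; rr$data <- dat
      ep <- epoch_segments(rr, stimuli, config$epoch_length)
      sp <- mtm_spectra(ep, freqs, config$half_bandwidth)
      cs <- accumulate_csd(sp)
      if (is.null(neural_names))
        neural_names <- cs$channel_names[cs$channel_roles == "neural"]
      res <- list(
        ocular_envelope = coherence(cs, "ocular", "envelope"),
        ocular_lip = coherence(cs, "ocular", "lip"),
        neural_envelope = lapply(neural_names, function(ch)
          coherence(cs, ch, "envelope")),
        neural_envelope_partial = lapply(neural_names, function(ch)
          partial_coherence(cs, ch, "envelope", "ocular")),
        n_est = cs$n_est)
      names(res$neural_envelope) <- neural_names
      names(res$neural_envelope_partial) <- neural_names
      coh[[s]][[cond]] <- res
      bl <- detect_blinks(r)
      blink[[s]][[cond]] <- list(
        rate = blink_rate(bl),
        env_z = envelope_at_blinks(bl, cohort$envelope)$mean)
    }
  }

  # --- assemble subject x condition x bins arrays
  arr2 <- function(field) {
    a <- array(NA_real_, dim = c(n_sub, 2, nf))
    for (i in seq_len(n_sub)) for (ci in 1:2) {
      a[i, ci, ] <- coh[[subjects[i]]][[c("forward", "backward")[ci]]][[field]]$values
    }
    a
  }
  arr_sp <- function(field) {   # bins flattened frequency-fastest
    a <- array(NA_real_, dim = c(n_sub, 2, nf * length(neural_names)))
    for (i in seq_len(n_sub)) for (ci in 1:2) {
      lst <- coh[[subjects[i]]][[c("forward", "backward")[ci]]][[field]]
      a[i, ci, ] <- unlist(lapply(lst, function(x) x$values))
    }
    a
  }
  oc_env <- arr2("ocular_envelope")
  oc_lip <- arr2("ocular_lip")
  ne_env <- arr_sp("neural_envelope")
  ne_env_p <- arr_sp("neural_envelope_partial")

  # --- cluster permutation t tests (forward vs backward)
  sp_adj <- grid_adjacency(nf, chain_adjacency(length(neural_names)))
  pseed <- function(nm) substream_seed(config$seed, paste0("perm_", nm))
  tests <- list(
    ocular_envelope = cluster_perm_ttest(oc_env, NULL, config$cluster_alpha,
                                         config$n_perm, pseed("oc_env")),
    ocular_lip = cluster_perm_ttest(oc_lip, NULL, config$cluster_alpha,
                                    config$n_perm, pseed("oc_lip")),
    neural_envelope = cluster_perm_ttest(ne_env, sp_adj, config$cluster_alpha,
                                         config$n_perm, pseed("ne_env")),
    neural_envelope_partial = cluster_perm_ttest(ne_env_p, sp_adj,
                                                 config$cluster_alpha,
                                                 config$n_perm,
                                                 pseed("ne_env_p")))

  # --- contrasts and group ANOVA
  contr_env <- oc_env[, 1, , drop = TRUE] - oc_env[, 2, , drop = TRUE]
  contr_lip <- oc_lip[, 1, , drop = TRUE] - oc_lip[, 2, , drop = TRUE]
  contr_env <- matrix(contr_env, nrow = n_sub)
  contr_lip <- matrix(contr_lip, nrow = n_sub)
  gtab <- table(groups)
  anova <- NULL
  point <- NULL
  if (sum(gtab >= 2) >= 2) {
    keep <- groups %in% names(gtab)[gtab >= 2]
    contrasts <- array(NA_real_, dim = c(sum(keep), 2, nf))
    contrasts[, 1, ] <- contr_lip[keep, , drop = FALSE]
    contrasts[, 2, ] <- contr_env[keep, , drop = FALSE]
    anova <- cluster_perm_mixed_anova(contrasts, groups[keep], NULL,
                                      config$cluster_alpha, config$n_perm,
                                      pseed("anova"))
    bsel <- freqs >= config$summary_band[1] & freqs < config$summary_band[2]
    vals <- cbind(rowMeans(contr_lip[keep, bsel, drop = FALSE]),
                  rowMeans(contr_env[keep, bsel, drop = FALSE]))
    point <- point_anova(vals, groups[keep])
  }

  # --- ROI summary: strongest neural channel on the mean envelope contrast
  mean_contrast <- lapply(neural_names, function(ch) {
    i <- match(ch, neural_names)
    cols <- ((i - 1) * nf + 1):(i * nf)
    vals <- colMeans(ne_env[, 1, cols, drop = FALSE] -
                     ne_env[, 2, cols, drop = FALSE])
    structure(list(values = as.numeric(vals), freqs = freqs,
                   pair = c(ch, "envelope"), partialized = NULL),
              class = "contrast_spectrum")
  })
  names(mean_contrast) <- neural_names
  roi_best <- roi_peak_select(mean_contrast, neural_names,
                              config$summary_band)

  # --- blink summary: paired t of rates and of envelope-at-blink z values
  brate <- sapply(subjects, function(s)
    c(forward = blink[[s]]$forward$rate, backward = blink[[s]]$backward$rate))
  benv <- sapply(subjects, function(s)
    c(forward = blink[[s]]$forward$env_z, backward = blink[[s]]$backward$env_z))
  blink_summary <- list(
    rate_forward = mean(brate["forward", ]),
    rate_backward = mean(brate["backward", ]),
    rate_test = posthoc_tests(NULL, paired_with = list(brate["backward", ],
                                                       brate["forward", ])),
    envz_forward = mean(benv["forward", ], na.rm = TRUE),
    envz_backward = mean(benv["backward", ], na.rm = TRUE),
    envz_test = if (!anyNA(benv))
      posthoc_tests(NULL, paired_with = list(benv["backward", ],
                                             benv["forward", ])) else NULL)

  log <- list(hp = config$hp, lp = config$lp,
              epoch_length = config$epoch_length,
              freq_grid = range(freqs), freq_step = diff(freqs[1:2]),
              half_bandwidth = config$half_bandwidth,
              cluster_alpha = config$cluster_alpha, n_perm = config$n_perm,
              seed = config$seed, n_subjects = n_sub,
              groups = as.list(gtab))

  bundle <- structure(list(
    config = config, freqs = freqs, subjects = subjects, groups = groups,
    neural_channels = neural_names,
    coherence = list(ocular_envelope = oc_env, ocular_lip = oc_lip,
                     neural_envelope = ne_env,
                     neural_envelope_partial = ne_env_p),
    contrasts = list(ocular_envelope = contr_env, ocular_lip = contr_lip),
    tests = tests, anova = anova, point_anova = point,
    roi_channel = roi_best, mean_contrast = mean_contrast,
    blink = blink_summary, log = log),
    class = "strack_bundle")

  if (!is.null(config$out_dir)) save_bundle(bundle, config$out_dir)
  bundle
}

save_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- bundle$freqs
  rows <- list()
  for (i in seq_along(bundle$subjects)) for (ci in 1:2) {
    cond <- c("forward", "backward")[ci]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = bundle$subjects[i], group = bundle$groups[i],
      condition = cond, channel = "ocular", stimulus = "envelope",
      partialized = NA_character_, frequency = freqs,
      value = bundle$coherence$ocular_envelope[i, ci, ])
    rows[[length(rows) + 1L]] <- data.frame(
      subject = bundle$subjects[i], group = bundle$groups[i],
      condition = cond, channel = "ocular", stimulus = "lip",
      partialized = NA_character_, frequency = freqs,
      value = bundle$coherence$ocular_lip[i, ci, ])
  }
  utils::write.table(do.call(rbind, rows),
                     file.path(out_dir, "ocular_coherence.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(bundle$tests)) {
    write_cluster_json(bundle$tests[[nm]],
                       file.path(out_dir, paste0("cluster_", nm, ".json")),
                       freqs = freqs)
  }
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(write_report(bundle), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

cluster_freq_range <- function(result, freqs, alpha = 0.05) {
  sig <- significant_clusters(result, alpha)
  if (!length(sig)) return(NULL)
  nf <- length(freqs)
  vapply(sig, function(cl) {
    fr <- freqs[((cl$members - 1L) %% nf) + 1L]
    sprintf("%.2f-%.2f Hz (mass %.1f, p = %.4f)", min(fr), max(fr),
            cl$mass, cl$p)
  }, "")
}

#' Human-readable summary of a pipeline results bundle
#'
#' One entry per statistical test run: significant cluster frequency ranges
#' for each coherence step, the ANOVA effects with post hoc table, the ROI
#' band summary and the blink statistics. A machine-readable JSON index is
#' written alongside when `path` is given.
#'
#' @param bundle A `strack_bundle` from [run_pipeline()].
#' @param path Optional file to write the text report to (a `.json` index
#'   is written next to it).
#' @return Character vector of report lines, invisibly when `path` is set.
#' @export
write_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "strack_bundle"))
  L <- c("silent-speech tracking report", strrep("=", 30), "")
  L <- c(L, sprintf("subjects: %d (%s)", length(bundle$subjects),
                    paste(sprintf("%s=%d", names(table(bundle$groups)),
                                  table(bundle$groups)), collapse = ", ")))
  lg <- bundle$log
  L <- c(L, sprintf("filters: %.2g-%g Hz; epochs %g s; grid %.3f-%.3f Hz step %.3f; W = %.2g Hz",
                    lg$hp, lg$lp, lg$epoch_length, lg$freq_grid[1],
                    lg$freq_grid[2], lg$freq_step, lg$half_bandwidth),
         sprintf("cluster alpha %.3g, %d permutations, seed %d",
                 lg$cluster_alpha, lg$n_perm, lg$seed), "")
  if (length(bundle$tests) == 0) {
    L <- c(L, "no tests run")
  }
  for (nm in names(bundle$tests)) {
    rng <- cluster_freq_range(bundle$tests[[nm]], bundle$freqs)
    L <- c(L, sprintf("forward vs backward, %s:", gsub("_", " ", nm)))
    if (is.null(rng)) L <- c(L, "  no significant cluster")
    else L <- c(L, paste0("  significant cluster ", rng))
  }
  if (!is.null(bundle$anova)) {
    L <- c(L, "", "mixed 2 x 3 ANOVA on forward-backward contrasts (cluster-corrected):")
    for (eff in names(bundle$anova$effects)) {
      e <- bundle$anova$effects[[eff]]
      sig <- significant_clusters(e$clusters)
      L <- c(L, sprintf("  %s: %d significant cluster(s)%s", eff, length(sig),
                        if (length(sig))
                          paste0("; smallest p = ",
                                 format(min(vapply(sig, `[[`, 0, "p")),
                                        digits = 3)) else ""))
    }
  }
  if (!is.null(bundle$point_anova)) {
    L <- c(L, "", sprintf("band-averaged (%.2g-%.2g Hz) ocular point ANOVA:",
                          bundle$config$summary_band[1],
                          bundle$config$summary_band[2]))
    for (eff in names(bundle$point_anova$effects)) {
      e <- bundle$point_anova$effects[[eff]]
      L <- c(L, sprintf("  %s: F(%d,%d) = %.2f, p = %.4f", eff, e$df1,
                        e$df2, e$F, e$p))
    }
    ph <- bundle$point_anova$posthoc
    if (!is.null(ph)) {
      L <- c(L, "  post hoc:")
      L <- c(L, sprintf("    %s: t(%.2f) = %.2f, p = %.4f [%s]",
                        ph$comparison, ph$df, ph$t, ph$p, ph$variant))
    }
  }
  L <- c(L, "", sprintf("ROI channel with strongest envelope contrast: %s",
                        bundle$roi_channel))
  bl <- bundle$blink
  L <- c(L, "", sprintf("blink rate: %.3f Hz forward, %.3f Hz backward",
                        bl$rate_forward, bl$rate_backward))
  if (!is.null(bl$envz_test)) {
    L <- c(L, sprintf("envelope z at blinks: %.3f forward, %.3f backward (paired t p = %.3f)",
                      bl$envz_forward, bl$envz_backward, bl$envz_test$p))
  }
  if (!is.null(path)) {
    writeLines(L, path)
    idx <- list(
      tests = lapply(bundle$tests, function(tt)
        lapply(significant_clusters(tt), function(cl)
          list(mass = cl$mass, p = cl$p, n_bins = length(cl$members)))),
      roi_channel = bundle$roi_channel,
      blink_rate = list(forward = bl$rate_forward,
                        backward = bl$rate_backward),
      log = bundle$log)
    jsonlite::write_json(idx, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(L))
  }
  L
}

#' @export
print.strack_bundle <- function(x, ...) {
  cat(write_report(x), sep = "\n")
  invisible(x)
}
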