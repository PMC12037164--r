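test_that("coherence is 1 for copies, bounded, and at chance for noise", {
  set.seed(21)
  x <- rnorm(9000)
  r <- subject_recording(matrix(c(x, x), nrow = 2, byrow = TRUE), 150,
                         c("neural", "ocular"))
  coh <- coherence(csd_of(r), "neural1", "ocular")
  expect_equal(coh$values, rep(1, 30), tolerance = 1e-9)

  # independent channels: mean ~ 1/n_est within +/-50% over replicates
  set.seed(22)
  means <- replicate(10, {
    cc <- csd_of(noise_recording(seed = sample.int(1e6, 1)))
    mean(coherence(cc, 1, 2)$values)
  })
  expect_gt(mean(means), 0.5 / 50)
  expect_lt(mean(means), 1.5 / 50)
  expect_true(all(means >= 0 & means <= 1))

  # common 0.5 Hz sinusoid + weak independent noise: near-1 at the 0.5 Hz bin
  tt <- (0:8999) / 150
  s <- sin(2 * pi * 0.5 * tt)
  set.seed(23)
  m <- matrix(c(s + 0.05 * rnorm(9000), s + 0.05 * rnorm(9000)),
              nrow = 2, byrow = TRUE)
  r2 <- subject_recording(m, 150, c("neural", "ocular"))
  c2 <- coherence(csd_of(r2), 1, 2)
  expect_gt(c2$values[c2$freqs == 0.5], 0.9)

  expect_error(coherence(csd_of(r2), 1, 1), "different")
})

test_that("partialization removes a common drive but not independent coupling", {
  # shared latent source: raw high, partial at chance
  r <- make_common_source_pair(120, 150, c(0.4, 0.8), seed = 3)
  cs <- csd_of(r)
  raw <- coherence(cs, "neural1", "neural2")
  par <- partial_coherence(cs, "neural1", "neural2", "ocular")
  inb <- cs$freqs >= 0.4 & cs$freqs <= 0.8
  expect_true(all(raw$values[inb] > 0.5))
  expect_true(all(par$values[inb] <= 2 / cs$n_est))

  # three independent drivers: |partial - raw| within estimation error
  r2 <- make_common_source_pair(120, 150, c(0.4, 0.8), seed = 4,
                                shared = FALSE)
  cs2 <- csd_of(r2)
  raw2 <- coherence(cs2, "neural1", "neural2")
  par2 <- partial_coherence(cs2, "neural1", "neural2", "ocular")
  # Monte-Carlo SE of a coherence estimate near chance ~ 1/n_est
  expect_lt(max(abs(par2$values - raw2$values)), 4 / cs2$n_est)
  expect_true(all(par2$values >= 0 & par2$values <= 1))

  # degenerate regressor: zero-power z acts as a no-op with a warning
  m <- rbind(r2$data[1:2, ], 0)
  r3 <- subject_recording(m, 150, c("neural", "neural", "ocular"))
  cs3 <- csd_of(r3)
  expect_warning(p3 <- partial_coherence(cs3, 1, 2, 3), "zero power")
  expect_equal(p3$values, coherence(cs3, 1, 2)$values)

  expect_error(partial_coherence(cs, "neural1", "neural2", "neural1"),
               "differ")
})

test_that("contrasts subtract backward from forward elementwise", {
  mk <- function(vals) structure(
    list(values = vals, freqs = default_freq_grid(),
         pair = c("ocular", "envelope"), partialized = NULL, n_est = 50L),
    class = "coherence_spectrum")
  a <- mk(seq(0, 1, length.out = 30)); b <- mk(rep(0.2, 30))
  expect_equal(condition_contrast(a, a)$values, rep(0, 30))
  expect_equal(condition_contrast(a, b)$values,
               -condition_contrast(b, a)$values)
  bad <- mk(rep(0.2, 30)); bad$freqs <- bad$freqs + 1
  expect_error(condition_contrast(a, bad), "grids")
  bad2 <- mk(rep(0.2, 30)); bad2$pair <- c("x", "envelope")
  expect_error(condition_contrast(a, bad2), "pairs")
})

test_that("band averages follow the half-open [lo, hi) convention", {
  s <- structure(list(values = rep(0.3, 30), freqs = default_freq_grid(),
                      pair = c("a", "b"), partialized = NULL, n_est = 50L),
                 class = "coherence_spectrum")
  expect_equal(band_average(s, c(0, 1)), 0.3)
  # bins below 1 Hz on the default grid: 1/6..5/6, i.e. 5 bins
  s2 <- s; s2$values <- seq_len(30) / 30
  expect_equal(band_average(s2, c(0, 1)), mean((1:5) / 30))
  expect_equal(band_average(s2, c(0, 1 + 1e-9)), mean((1:6) / 30))
  expect_error(band_average(s, c(8, 9)), "intersect")
})

test_that("ROI peak selection maximizes the band contrast deterministically", {
  mkc <- function(vals) structure(
    list(values = vals, freqs = default_freq_grid(),
         pair = c("x", "envelope"), partialized = NULL),
    class = "contrast_spectrum")
  cmap <- list(a = mkc(rep(0.1, 30)), b = mkc(rep(0.3, 30)),
               c = mkc(rep(0.3, 30)))
  expect_identical(roi_peak_select(cmap, "a"), "a")
  expect_identical(roi_peak_select(cmap, c("a", "b", "c")), "b")
  expect_identical(roi_peak_select(cmap, c("c", "b")), "c")  # first of ties
  expect_error(roi_peak_select(cmap, character(0)), "non-empty")
  expect_error(roi_peak_select(cmap, "zz"), "no contrast")

  # a strongly coupled channel is found in simulation
  e <- make_speech_envelope(120, 150, seed = 31)
  spec <- small_spec(coupling_strength = strength_matrix(hearing_f = 0.6))
  hits <- vapply(1:5, function(i) {
    rf <- make_subject_recording(e, spec, n_neural = 3,
                                 condition = "forward", seed = 100 + i)
    rb <- make_subject_recording(e, spec, n_neural = 3,
                                 condition = "backward", seed = 200 + i)
    # decouple channels 2 and 3 by replacing them with pure noise
    set.seed(300 + i)
    rf$data[2:3, ] <- matrix(rnorm(2 * ncol(rf$data)), nrow = 2)
    csf <- csd_of(rf, list(envelope = e))
    csb <- csd_of(rb, list(envelope = e))
    cmap <- lapply(paste0("neural", 1:3), function(ch)
      condition_contrast(coherence(csf, ch, "envelope"),
                         coherence(csb, ch, "envelope")))
    names(cmap) <- paste0("neural", 1:3)
    roi_peak_select(cmap, names(cmap)) == "neural1"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
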