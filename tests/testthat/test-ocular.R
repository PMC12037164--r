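test_that("blink detection recovers injected pulses and respects refractory", {
  rate <- 150
  set.seed(51)
  x <- rnorm(60 * rate, sd = 0.5)
  pulse <- silenttrack:::blink_pulse(rate) * 6
  true_t <- seq(2.5, 57, length.out = 12)
  for (t0 in true_t) {
    i0 <- round(t0 * rate)
    x[i0:(i0 + length(pulse) - 1)] <- x[i0:(i0 + length(pulse) - 1)] + pulse
  }
  ev <- detect_blinks(x, rate, z_thresh = 3)
  expect_gte(length(ev$times), 11L)
  expect_lte(length(ev$times), 13L)
  expect_true(all(diff(ev$times) > 0))

  # pure Gaussian noise at a high threshold: no events
  set.seed(52)
  ev0 <- detect_blinks(rnorm(60 * rate), rate, z_thresh = 6)
  expect_length(ev0$times, 0L)

  # two pulses 0.1 s apart merge under a 0.5 s refractory
  y <- rnorm(10 * rate, sd = 0.1)
  for (t0 in c(5, 5.1)) {
    i0 <- round(t0 * rate)
    y[i0:(i0 + length(pulse) - 1)] <- y[i0:(i0 + length(pulse) - 1)] + pulse
  }
  ev2 <- detect_blinks(y, rate, z_thresh = 6, refractory = 0.5)
  expect_length(ev2$times, 1L)

  expect_warning(ev3 <- detect_blinks(rep(1, 1000), rate), "flat")
  expect_length(ev3$times, 0L)
})

test_that("detected counts are monotone in threshold and refractory", {
  e <- make_speech_envelope(120, 150, seed = 61)
  spec <- small_spec()
  r <- make_subject_recording(e, spec, condition = "forward", seed = 62)
  oc <- r$data[r$channel_roles == "ocular", ]
  n_by_z <- vapply(c(2, 3, 4, 6), function(z)
    length(detect_blinks(oc, 150, z_thresh = z)$times), 0L)
  expect_true(all(diff(n_by_z) <= 0))
  n_by_r <- vapply(c(0.2, 0.5, 1, 2), function(rf)
    length(detect_blinks(oc, 150, refractory = rf)$times), 0L)
  expect_true(all(diff(n_by_r) <= 0))
})

test_that("blink rate estimates the Poisson generator rate", {
  expect_equal(blink_rate(structure(list(times = seq_len(12), duration = 60),
                                    class = "blink_events")), 0.2)
  expect_equal(blink_rate(structure(list(times = numeric(0), duration = 60),
                                    class = "blink_events")), 0)
  expect_error(blink_rate(structure(list(times = 1, duration = 60),
                                    class = "blink_events"), duration = -1),
               "positive")

  e <- make_speech_envelope(300, 150, seed = 71)
  spec <- small_spec(duration = 300)
  rates <- vapply(1:10, function(i) {
    r <- make_subject_recording(e, spec, condition = "forward",
                                seed = 700 + i)
    blink_rate(detect_blinks(r))
  }, 0)
  expect_gt(mean(rates), 0.16)
  expect_lt(mean(rates), 0.25)
})

test_that("envelope values at blinks reflect event placement", {
  e <- make_speech_envelope(120, 150, seed = 81)
  z <- as.numeric(scale(e$samples))
  # events at the deepest minima -> strongly negative mean
  troughs <- (order(z)[1:20] - 1) / 150
  ev <- structure(list(times = sort(troughs), duration = 120),
                  class = "blink_events")
  expect_lt(envelope_at_blinks(ev, e)$mean, -0.3)

  # uniformly placed events: mean near zero across replicates
  set.seed(82)
  ms <- replicate(30, {
    ev2 <- structure(list(times = sort(runif(25, 0, 119.9)), duration = 120),
                     class = "blink_events")
    envelope_at_blinks(ev2, e)$mean
  })
  expect_lt(abs(mean(ms)), 2 * sd(ms) / sqrt(30) + 0.1)

  bad <- structure(list(times = 500, duration = 600), class = "blink_events")
  expect_error(envelope_at_blinks(bad, e), "support")
})

test_that("trough-biased forward blinks yield lower envelope z than backward", {
  e <- make_speech_envelope(200, 150, seed = 91)
  spec <- small_spec(duration = 200, blink_trough_bias = 0.9)
  diffs <- vapply(1:8, function(i) {
    rf <- make_subject_recording(e, spec, condition = "forward",
                                 seed = 900 + i)
    rb <- make_subject_recording(e, spec, condition = "backward",
                                 seed = 950 + i)
    zf <- envelope_at_blinks(detect_blinks(rf), e)$mean
    zb <- envelope_at_blinks(detect_blinks(rb), e)$mean
    zf - zb
  }, 0)
  expect_gte(mean(diffs < 0), 0.7)
  expect_lt(mean(diffs), 0)
})
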