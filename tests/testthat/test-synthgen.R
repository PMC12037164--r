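test_that("speech envelope is non-negative, deterministic, and syllable-peaked", {
  e <- make_speech_envelope(60, 150, seed = 1)
  expect_s3_class(e, "stimulus_signal")
  expect_identical(e$role, "envelope")
  expect_gte(min(e$samples), 0)
  expect_length(e$samples, 60 * 150)

  e2 <- make_speech_envelope(60, 150, seed = 1)
  expect_identical(e$samples, e2$samples)
  e3 <- make_speech_envelope(60, 150, seed = 2)
  expect_false(identical(e$samples, e3$samples))

  # modulation peak near the 3.3 Hz syllable rate (per-seed band, mean tighter)
  pk <- vapply(1:5, function(s)
    modulation_peak(make_speech_envelope(120, 150, seed = s)), 0)
  expect_true(all(pk >= 2.6 & pk <= 4.0))
  expect_lt(abs(mean(pk) - 3.3), 0.35)

  expect_error(make_speech_envelope(-1, 150), "positive")
  expect_error(make_speech_envelope(60, -5), "positive")
  expect_error(make_speech_envelope(5, 150, sentence_rate = 0.25),
               "sentence")
})

test_that("lip signal hits the target correlation with the envelope", {
  e <- make_speech_envelope(120, 150, seed = 3)
  ref <- fft_resample(e, 50)$samples
  l5 <- make_lip_signal(e, 0.5, seed = 11)
  expect_identical(l5$role, "lip")
  expect_equal(l5$rate, 50)
  expect_gt(cor(l5$samples, ref), 0.4)
  expect_lt(cor(l5$samples, ref), 0.6)

  l0 <- make_lip_signal(e, 0, seed = 12)
  expect_lt(abs(cor(l0$samples, ref)), 0.15)

  l1 <- make_lip_signal(e, 1, seed = 13)
  expect_gt(cor(l1$samples, ref), 0.99)

  expect_error(make_lip_signal(e, 1.2), "target_corr")
  expect_error(make_lip_signal(l5, 0.5), "role 'envelope'")
})

test_that("subject recordings have the declared structure and coupling", {
  e <- make_speech_envelope(120, 150, seed = 7)
  spec <- small_spec(coupling_strength = strength_matrix(hearing_f = 0.6))
  r <- make_subject_recording(e, spec, n_neural = 3, condition = "forward",
                              seed = 5)
  expect_s3_class(r, "subject_recording")
  expect_equal(sum(r$channel_roles == "ocular"), 1L)
  expect_equal(nrow(r$data), 4L)
  expect_equal(ncol(r$data), length(e$samples))

  bad <- spec
  bad$coupling_band <- c(10, 80)
  expect_error(make_subject_recording(e, bad, condition = "forward"),
               "rate/2")

  # forward coupling raises in-band coherence; backward (strength 0) at chance
  coh_in_band <- function(cond, seed) {
    rr <- make_subject_recording(e, spec, n_neural = 1, condition = cond,
                                 seed = seed)
    cs <- csd_of(rr, list(envelope = e))
    mean(coherence(cs, "neural1", "envelope")$values[
      cs$freqs >= 0.4 & cs$freqs <= 0.8])
  }
  expect_gt(coh_in_band("forward", 21), 3 * coh_in_band("backward", 22))
})

test_that("blink trains are Poisson at the requested rate", {
  e <- make_speech_envelope(300, 150, seed = 5)
  spec <- small_spec(duration = 300)
  r <- make_subject_recording(e, spec, condition = "forward", seed = 9)
  n_blinks <- length(attr(r, "blink_times"))
  # Poisson(60) central 99.9% band
  expect_gt(n_blinks, 36)
  expect_lt(n_blinks, 88)
})

test_that("cohorts are reproducible with per-subject independent noise", {
  spec <- cohort_spec(n_per_group = c(hearing = 2, dhh = 2, congenital = 2),
                      duration = 24, seed = 42)
  # duration below two sentence periods would be rejected upstream; 24 s is
  # enough for generation-level checks
  co <- make_cohort(spec)
  expect_equal(length(co$recordings), 12L)   # 2 cond x 6 subjects
  co2 <- make_cohort(spec)
  expect_identical(co$recordings[[3]]$data, co2$recordings[[3]]$data)
  expect_false(identical(co$recordings[[1]]$data, co$recordings[[3]]$data))
  conds <- vapply(co$recordings, function(r) r$condition, "")
  expect_equal(sum(conds == "forward"), 6L)

  bad <- spec
  bad$n_per_group <- c(hearing = 1, dhh = 2, congenital = 2)
  expect_error(make_cohort(bad), "n >= 2")
})

test_that("generated coupling is band-limited", {
  e <- make_speech_envelope(120, 150, seed = 17)
  spec <- small_spec(coupling_strength = strength_matrix(hearing_f = 0.6))
  r <- make_subject_recording(e, spec, n_neural = 1, condition = "forward",
                              seed = 31)
  cs <- csd_of(r, list(envelope = e))
  coh <- coherence(cs, "neural1", "envelope")$values
  # outside the coupling band plus one smoothing half-bandwidth: chance-level
  out <- cs$freqs > 0.83 + 0.55
  chance <- 1 / cs$n_est
  expect_lt(mean(coh[out]), 3 * chance)
})
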