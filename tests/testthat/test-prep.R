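test_that("FIR bandpass has unit passband gain, rejects DC and stopband", {
  fs <- 150
  tt <- seq(0, 150, by = 1 / fs)
  interior <- round(30 * fs):round(120 * fs)

  s1 <- sin(2 * pi * 1 * tt)
  f1 <- fir_bandpass(s1, fs)
  expect_gt(max(abs(f1[interior])), 0.95)
  expect_lt(max(abs(f1[interior])), 1.05)

  fdc <- fir_bandpass(s1 + 5, fs)
  expect_lt(abs(mean(fdc[interior]) - mean(f1[interior])), 0.05)

  s30 <- sin(2 * pi * 30 * tt)
  expect_lt(max(abs(fir_bandpass(s30, fs)[interior])), 0.01)

  # kernel-length rule: 6.6 / transition * rate, forced odd
  expect_equal(attr(f1, "kernel_length"), 9901L)

  expect_error(fir_bandpass(rnorm(100), fs), "too short")
  expect_error(fir_bandpass(s1, fs, hp = 13, lp = 12), "hp < lp")
})

test_that("FIR filtering is linear and zero-phase on interior samples", {
  fs <- 150
  tt <- seq(0, 150, by = 1 / fs)
  interior <- round(30 * fs):round(120 * fs)
  x <- sin(2 * pi * 2 * tt)
  y <- sin(2 * pi * 0.7 * tt + 1)

  fx <- fir_bandpass(x, fs); fy <- fir_bandpass(y, fs)
  fxy <- fir_bandpass(2 * x + 3 * y, fs)
  expect_equal(fxy[interior], (2 * fx + 3 * fy)[interior], tolerance = 1e-8)

  cc <- stats::ccf(fx[interior], x[interior], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # matrix input filters each channel row
  m <- rbind(x, y)
  fm <- fir_bandpass(m, fs)
  expect_equal(fm[1, interior], fx[interior], tolerance = 1e-10)
})

test_that("epoching cuts exact non-overlapping segments and keeps values", {
  set.seed(3)
  m <- matrix(rnorm(2 * round(63 * 150)), nrow = 2)
  r <- subject_recording(m, 150, c("neural", "ocular"), condition = "forward")
  ep <- epoch_segments(r, epoch_length = 6)
  expect_equal(dim(ep$data), c(10, 2, 900))
  expect_identical(ep$data[1, 1, ], m[1, 1:900])
  expect_identical(ep$data[3, 2, ], m[2, 1801:2700])
  expect_true(all(ep$condition == "forward"))

  r6 <- subject_recording(m[, 1:900], 150, c("neural", "ocular"))
  expect_equal(dim(epoch_segments(r6)$data)[1], 1L)

  env <- stimulus_signal(abs(rnorm(ncol(m))), 150, "envelope")
  ep2 <- epoch_segments(r, list(envelope = env))
  expect_equal(dim(ep2$data)[2], 3L)
  expect_identical(ep2$channel_roles[3], "stimulus")
  expect_identical(ep2$data[2, 3, ], env$samples[901:1800])

  bad_env <- stimulus_signal(abs(rnorm(100)), 50, "envelope")
  expect_error(epoch_segments(r, list(envelope = bad_env)), "rate")
})

test_that("condition labels are inherited from source blocks", {
  set.seed(4)
  mk <- function(cond) subject_recording(
    matrix(rnorm(2 * 9000), nrow = 2), 150, c("neural", "ocular"),
    condition = cond)
  blocks <- list(mk("forward"), mk("backward"), mk("forward"), mk("backward"))
  ep <- assign_conditions(blocks)
  expect_equal(sum(ep$condition == "forward"), 20L)
  expect_equal(sum(ep$condition == "backward"), 20L)

  single <- assign_conditions(list(mk("backward")))
  expect_true(all(single$condition == "backward"))

  expect_error(assign_conditions(list()), "no blocks")
  expect_error(assign_conditions(list(1)), "condition-tagged")
})

test_that("recordings and stimuli round-trip through delimited text", {
  e <- make_speech_envelope(12, 150, seed = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_stimulus_signal(e, p)
  e2 <- read_stimulus_signal(p)
  expect_equal(e2$samples, e$samples, tolerance = 1e-12)
  expect_equal(e2$rate, e$rate)
  expect_identical(e2$role, "envelope")

  r <- noise_recording(600, seed = 8)
  r$condition <- "backward"
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_recording(r, p2)
  r2 <- read_recording(p2)
  expect_equal(r2$data, r$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(r2$condition, "backward")
  expect_identical(r2$channel_roles, r$channel_roles)
})
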