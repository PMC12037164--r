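# Shared fixtures built in code: tiny recordings, CSDs and cohort specs.

# white-noise recording with one neural + one ocular channel
noise_recording <- function(n_samples = 9000, rate = 150, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(2 * n_samples), nrow = 2, byrow = TRUE)
  subject_recording(m, rate, c("neural", "ocular"))
}

# CSD of a recording on the default grid
csd_of <- function(rec, stimuli = list(), freqs = default_freq_grid()) {
  accumulate_csd(mtm_spectra(epoch_segments(rec, stimuli), freqs))
}

# small cohort spec with a single custom strength matrix
strength_matrix <- function(hearing_f = 0.3, dhh_f = 0.45, cong_f = 0,
                            backward = 0) {
  matrix(c(hearing_f, backward, dhh_f, backward, cong_f, backward),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("hearing", "dhh", "congenital"),
                         c("forward", "backward")))
}

small_spec <- function(n = c(hearing = 2L, dhh = 0L, congenital = 0L),
                       duration = 120, seed = 1, ...) {
  cohort_spec(n_per_group = n, duration = duration, seed = seed, ...)
}
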