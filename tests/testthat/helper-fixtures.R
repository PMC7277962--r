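# Reduced-size configs and hand-built epoch sets for fast unit tests.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, resting_duration = 70,
             trial_counts = list(ldaep = 8L, mmn = 150L), ...)
}

# epoch_set built directly from a list of channels x samples matrices
make_epochs <- function(mats, channels, srate = 1000, codes = NULL,
                        window_ms = NULL) {
  n <- length(mats)
  len <- ncol(mats[[1]])
  arr <- array(0, c(n, nrow(mats[[1]]), len))
  for (i in seq_len(n)) arr[i, , ] <- mats[[i]]
  if (is.null(window_ms)) window_ms <- c(-100, len - 100)
  if (is.null(codes)) codes <- rep("all", n)
  erpmark:::new_epoch_set(arr, channels, srate, window_ms,
                          baseline_ms = NULL, codes = codes,
                          n_rejected = 0L, threshold = Inf)
}

# single-channel sinusoidal recording
sine_recording <- function(freq, amp = 1, dur = 10, fs = 1000,
                           channels = "Cz", paradigm = "resting") {
  t <- (seq_len(dur * fs) - 1) / fs
  dat <- matrix(rep(amp * sin(2 * pi * freq * t), length(channels)),
                nrow = length(channels), byrow = TRUE)
  recording(dat, channels, fs, paradigm = paradigm)
}

# covariate frame matching the analysis design
demo_covariates <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(age = stats::rnorm(n, 45, 12),
             sex = sample(c("male", "female"), n, replace = TRUE),
             baseline_hamd = stats::rnorm(n, 26, 7),
             medication = sample(c("vortioxetine", "escitalopram"), n,
                                 replace = TRUE))
}
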