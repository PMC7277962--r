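test_that("band-pass preserves the passband and rejects the stopband", {
  r5 <- bandpass(sine_recording(5, amp = 2, dur = 20), 0.1, 30)
  mid <- 5000:15000
  amp5 <- sqrt(2 * mean(r5$data[1, mid]^2))
  expect_equal(amp5, 2, tolerance = 0.01)

  r50 <- bandpass(sine_recording(50, amp = 2, dur = 20), 0.1, 30)
  amp50 <- sqrt(2 * mean(r50$data[1, mid]^2))
  expect_lt(amp50, 0.2)                     # >= 90% attenuation

  dc <- recording(matrix(7, 1, 20000), "Cz", 1000)
  expect_lt(abs(mean(bandpass(dc, 0.1, 100)$data)), 1e-8)

  expect_error(bandpass(r5, 30, 0.1), "invalid band")
  expect_error(bandpass(r5, 0.1, 600), "invalid band")
})

test_that("notch removes the line frequency and spares the passband", {
  r60 <- notch(sine_recording(60, amp = 1, dur = 10))
  mid <- 3000:7000
  expect_lt(sqrt(2 * mean(r60$data[1, mid]^2)), 0.05)

  r10 <- notch(sine_recording(10, amp = 1, dur = 10))
  expect_equal(sqrt(2 * mean(r10$data[1, mid]^2)), 1, tolerance = 0.05)

  z <- notch(recording(matrix(0, 1, 5000), "Cz", 1000))
  expect_true(all(z$data == 0))
  expect_error(notch(r10, 700), "notch frequency")
})

test_that("filtering is linear", {
  set.seed(42)
  x <- recording(matrix(rnorm(5000), 1), "Cz", 1000)
  y <- recording(matrix(rnorm(5000), 1), "Cz", 1000)
  comb <- recording(3 * x$data - 2 * y$data, "Cz", 1000)
  lhs <- bandpass(comb, 1, 40)$data
  rhs <- 3 * bandpass(x, 1, 40)$data - 2 * bandpass(y, 1, 40)$data
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("resting segmentation yields 30 clean 2048-sample epochs", {
  set.seed(1)
  rec <- recording(matrix(rnorm(2 * 70000, sd = 5), 2), c("F5", "F6"), 1000)
  ep <- segment_resting(rec)
  expect_equal(dim(ep$data), c(30, 2, 2048))
  expect_equal(ep$n_rejected, 0L)

  # a 150 uV spike rejects exactly its epoch
  rec2 <- rec
  rec2$data[1, 3000] <- 150
  ep2 <- segment_resting(rec2)
  expect_equal(ep2$n_rejected, 1L)
  expect_equal(dim(ep2$data)[1], 30)        # later epochs fill the quota
  # rejected epoch 2 replaced by epoch 31
  expect_equal(ep2$data[2, , ], rec$data[, 4097:6144])

  zero <- recording(matrix(0, 1, 70000), "Cz", 1000)
  epz <- segment_resting(zero)
  expect_true(all(epz$data == 0))
  expect_equal(dim(epz$data)[1], 30)

  short <- recording(matrix(0, 1, 30000), "Cz", 1000)
  expect_error(segment_resting(short), "clean epochs")
  expect_error(segment_resting(gen_ldaep_recording(small_cfg(), 1)),
               "resting")
})

test_that("resting rejection is idempotent", {
  set.seed(2)
  dat <- matrix(rnorm(70000, sd = 10), 1)
  dat[1, c(5000, 20000)] <- 150               # spikes reject two epochs
  rec <- recording(dat, "Cz", 1000)
  ep <- segment_resting(rec)
  expect_equal(ep$n_rejected, 2L)
  flat <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = 1)
  again <- segment_resting(recording(flat, "Cz", 1000))
  expect_equal(again$n_rejected, 0L)
  expect_equal(again$data, ep$data)
})

test_that("event epochs use half-open sample windows and zero baselines", {
  # ramp signal: sample s has value s, so windows are directly readable
  dat <- matrix(seq_len(3000), 1)
  rec <- recording(dat, "Cz", 1000, paradigm = "mmn",
                   events = data.frame(sample = 1000, code = "standard"))
  ep <- segment_events(rec, pre_ms = 100, post_ms = 600, baseline = FALSE,
                       reject_uV = Inf)
  expect_equal(dim(ep$data)[3], 700)
  expect_equal(ep$data[1, 1, ], as.numeric(900:1599))

  epb <- segment_events(rec, pre_ms = 100, post_ms = 600, reject_uV = Inf)
  expect_lt(abs(mean(epb$data[1, 1, 1:100])), 1e-9)

  # constant epochs are identically zero after baseline correction
  recc <- recording(matrix(10, 1, 3000), "Cz", 1000, paradigm = "mmn",
                    events = data.frame(sample = 1000, code = "standard"))
  epc <- segment_events(recc, post_ms = 600)
  expect_true(all(epc$data == 0))
})

test_that("event epochs exceeding 75 uV after baseline are rejected", {
  dat <- matrix(0, 1, 4000)
  dat[1, 1200:1400] <- 80                     # plateau inside epoch 1 only
  rec <- recording(dat, "Cz", 1000, paradigm = "mmn",
                   events = data.frame(sample = c(1000, 3000),
                                       code = c("standard", "standard")))
  ep <- segment_events(rec, post_ms = 600)
  expect_equal(ep$n_rejected, 1L)
  expect_equal(length(ep$codes), 1L)

  rec1 <- recording(dat[, 1:2000, drop = FALSE], "Cz", 1000,
                    paradigm = "mmn",
                    events = data.frame(sample = 1000, code = "standard"))
  expect_error(segment_events(rec1, post_ms = 600), "no surviving epochs")
  expect_error(segment_events(recording(dat, "Cz", 1000), post_ms = 600),
               "ldaep or mmn")
})
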