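# epochs with a spike pair so N1/P2 peak-to-peak equals `pp` exactly
spike_epoch <- function(pp, len = 1000, fs = 1000) {
  x <- numeric(len)
  x[201] <- -pp / 2       # 100 ms post-stimulus (epoch starts at -100 ms)
  x[301] <- pp / 2        # 200 ms
  matrix(x, 1)
}

test_that("condition averages obey basic identities", {
  m <- matrix(rnorm(500), 1)
  ep <- make_epochs(list(m, m, m), "Cz", codes = rep("a", 3))
  expect_equal(average_erp(ep, "a")$waveform, m)

  ep2 <- make_epochs(list(m, -m), "Cz", codes = c("a", "a"))
  expect_equal(average_erp(ep2, "a")$waveform, 0 * m)
  expect_error(average_erp(ep2, "zz"), "no epochs")
})

test_that("averaging noise shrinks error like 1/sqrt(n)", {
  set.seed(5)
  template <- matrix(sin(seq(0, 6 * pi, length.out = 600)), 1)
  noisy <- function(n) lapply(seq_len(n), function(i)
    template + matrix(rnorm(600), 1))
  rms <- function(n) {
    av <- average_erp(make_epochs(noisy(n), "Cz", codes = rep("a", n)), "a")
    sqrt(mean((av$waveform - template)^2))
  }
  r10 <- rms(10); r160 <- rms(160)
  expect_lt(r160, r10 / 4 * 1.8)              # expect ~ r10/4
})

test_that("peak detection finds extrema, honors boundaries and ties", {
  t <- 0:699 - 100
  y <- numeric(700); y[t == 120] <- -5
  erp1 <- structure(list(condition = "a", channels = "Cz",
                         waveform = matrix(y, 1), time_ms = t,
                         n_trials = 1), class = "erp")
  pk <- detect_peak(erp1, "Cz", c(50, 200), "negative")
  expect_equal(pk$amplitude, -5)
  expect_equal(pk$latency_ms, 120)

  ramp <- structure(list(condition = "a", channels = "Cz",
                         waveform = matrix(seq_along(t), 1), time_ms = t,
                         n_trials = 1), class = "erp")
  expect_equal(detect_peak(ramp, "Cz", c(150, 300), "positive")$latency_ms,
               300)

  y2 <- numeric(700); y2[t %in% c(200, 250)] <- 7
  tie <- structure(list(condition = "a", channels = "Cz",
                        waveform = matrix(y2, 1), time_ms = t,
                        n_trials = 1), class = "erp")
  expect_equal(detect_peak(tie, "Cz", c(150, 300), "positive")$latency_ms,
               200)

  # polarity mirror: trough of -x equals minus the peak of x
  flip <- tie; flip$waveform <- -tie$waveform
  expect_equal(detect_peak(flip, "Cz", c(150, 300), "negative")$amplitude,
               -detect_peak(tie, "Cz", c(150, 300), "positive")$amplitude)
  expect_error(detect_peak(tie, "Cz", c(800, 900), "positive"), "window")
})

test_that("ldaep slope is exact on crafted amplitudes", {
  codes <- as.character(c(60, 70, 80, 90, 100))
  ep <- make_epochs(lapply(1:5, function(i) spike_epoch(i)), "Cz",
                    codes = codes)
  res <- ldaep(ep)
  expect_equal(unname(res$amplitudes), as.numeric(1:5))
  expect_equal(res$slope, 1.0, tolerance = 1e-12)

  epc <- make_epochs(lapply(1:5, function(i) spike_epoch(2)), "Cz",
                     codes = codes)
  expect_equal(ldaep(epc)$slope, 0, tolerance = 1e-12)

  # scaling amplitudes scales the slope; adding a constant leaves it
  ep2 <- make_epochs(lapply(1:5, function(i) spike_epoch(3 * i)), "Cz",
                     codes = codes)
  expect_equal(ldaep(ep2)$slope, 3.0, tolerance = 1e-12)
  ep3 <- make_epochs(lapply(1:5, function(i) spike_epoch(i + 10)), "Cz",
                     codes = codes)
  expect_equal(ldaep(ep3)$slope, 1.0, tolerance = 1e-12)

  ep4 <- make_epochs(lapply(1:4, function(i) spike_epoch(i)), "Cz",
                     codes = codes[1:4])
  expect_error(ldaep(ep4), "100")
})

test_that("mmn composite follows the difference-wave definition", {
  chans <- mmn_sites()
  base <- matrix(rnorm(9 * 700), 9)
  ep_std <- make_epochs(list(base), chans, codes = "standard")
  ep_dev <- make_epochs(list(base - 3), chans, codes = "deviant")

  same <- mmn(make_epochs(list(base, base), chans,
                          codes = c("standard", "deviant")))
  expect_equal(same$composite, 0)

  shift <- mmn(ep_std, ep_dev)
  expect_equal(shift$composite, -3, tolerance = 1e-12)
  expect_equal(unname(shift$site_amplitudes), rep(-3, 9))

  # antisymmetry under swapping the conditions
  swapped <- mmn(ep_dev, ep_std, std_code = "deviant",
                 dev_code = "standard")
  expect_equal(swapped$composite, -shift$composite)

  ep_bad <- make_epochs(list(base[1:3, ], base[1:3, ]), chans[1:3],
                        codes = c("standard", "deviant"))
  expect_error(mmn(ep_bad), "missing MMN site")
})
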