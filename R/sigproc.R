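#' Zero-phase band-pass filter
#'
#' Per-channel zero-phase Butterworth band-pass realized as a cascade of a
#' 2nd-order high-pass (gentle slope; the low edge sits near DC where
#' higher orders are numerically fragile) and a 4th-order low-pass, each
#' applied forward and backward (`signal::filtfilt`) so the net phase is
#' zero and the effective magnitude response is squared. Channels are
#' demeaned before filtering. The band is recorded in the recording's
#' metadata.
#'
#' @param rec an [recording()].
#' @param low,high band edges in Hz, 0 < low < high < Nyquist.
#' @return the filtered recording.
#' @export
bandpass <- function(rec, low, high) {
  nyq <- rec$srate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz",
                 low, high, nyq))
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ] - mean(rec$data[i, ])
    x <- signal::filtfilt(hp, x)
    out$data[i, ] <- signal::filtfilt(lp, x)
  }
  out$meta$bandpass <- c(low = low, high = high)
  out
}

#' Zero-phase notch filter
#'
#' Biquad notch (quality factor `q`, default 30) applied with
#' `signal::filtfilt`, attenuating a narrow band around `freq` (power-line
#' interference) while leaving the rest of the passband within 5%.
#'
#' @param rec an [recording()].
#' @param freq notch frequency in Hz (0 < freq < Nyquist).
#' @param q quality factor; -3 dB bandwidth is freq/q.
#' @return the filtered recording.
#' @export
notch <- function(rec, freq = 60, q = 30) {
  nyq <- rec$srate / 2
  if (freq <= 0 || freq >= nyq)
    stop(sprintf("notch frequency %g Hz outside (0, %g)", freq, nyq))
  w0 <- 2 * pi * freq / rec$srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- signal::filtfilt(flt, rec$data[i, ])
  out$meta$notch <- c(freq = freq, q = q)
  out
}

new_epoch_set <- function(data, channels, srate, window_ms, baseline_ms,
                          codes, n_rejected, threshold) {
  structure(
    list(data = data, channels = channels, srate = srate,
         window_ms = window_ms, baseline_ms = baseline_ms,
         codes = codes, n_rejected = n_rejected,
         rejection_threshold = threshold),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<epoch_set> %d epochs x %d channels x %d samples, ",
                     "window [%g, %g) ms, %d rejected at +/-%g uV\n"),
              d[1], d[2], d[3], x$window_ms[1], x$window_ms[2],
              x$n_rejected, x$rejection_threshold))
  invisible(x)
}

#' Segment a resting recording into fixed-length epochs
#'
#' Cuts consecutive, non-overlapping epochs of `epoch_s` seconds (half-open
#' in samples, so 2.048 s at 1000 Hz is exactly 2048 samples), drops any
#' epoch whose absolute amplitude exceeds `reject_uV` on any scored
#' channel, and retains the first `max_epochs` clean epochs in temporal
#' order.
#'
#' @param rec resting [recording()].
#' @param epoch_s epoch length in seconds (default 2.048).
#' @param reject_uV absolute-amplitude rejection threshold (default 100).
#' @param max_epochs number of clean epochs to retain (default 30).
#' @param scored channels entering the rejection test (default: all).
#' @return an `epoch_set`.
#' @export
segment_resting <- function(rec, epoch_s = 2.048, reject_uV = 100,
                            max_epochs = 30, scored = rec$channels) {
  if (rec$paradigm != "resting")
    stop("segment_resting expects a resting recording")
  len <- round(epoch_s * rec$srate)
  n_cand <- floor(ncol(rec$data) / len)
  si <- chan_index(rec, scored)
  keep <- integer(0)
  n_rej <- 0L
  for (k in seq_len(n_cand)) {
    idx <- ((k - 1) * len + 1):(k * len)
    if (max(abs(rec$data[si, idx])) > reject_uV) {
      n_rej <- n_rej + 1L
    } else {
      keep <- c(keep, k)
      if (length(keep) == max_epochs) break
    }
  }
  if (length(keep) < max_epochs)
    stop(sprintf(paste0("only %d clean epochs available (%d candidates, ",
                        "%d rejected); %d required"),
                 length(keep), n_cand, n_rej, max_epochs))
  arr <- array(0, c(length(keep), nrow(rec$data), len))
  for (j in seq_along(keep)) {
    idx <- ((keep[j] - 1) * len + 1):(keep[j] * len)
    arr[j, , ] <- rec$data[, idx]
  }
  new_epoch_set(arr, rec$channels, rec$srate,
                window_ms = c(0, epoch_s * 1000), baseline_ms = NULL,
                codes = rep("resting", length(keep)),
                n_rejected = n_rej, threshold = reject_uV)
}

#' Segment an event-related recording into baseline-corrected epochs
#'
#' Windows are half-open in samples: an event at sample s with pre = 100 ms
#' and post = 600 ms at 1000 Hz covers samples s-100 .. s+599. The mean
#' over the pre-stimulus interval is subtracted channelwise, then epochs
#' whose absolute amplitude exceeds `reject_uV` on any scored channel are
#' rejected (threshold applies to the residual, baseline-corrected
#' signal). Events too close to the recording edge are dropped as
#' candidates.
#'
#' @param rec [recording()] with paradigm "ldaep" or "mmn" and events.
#' @param pre_ms pre-stimulus window, ms (default 100).
#' @param post_ms post-stimulus window, ms (900 for ldaep, 600 for mmn).
#' @param reject_uV rejection threshold, uV (default 75).
#' @param baseline subtract the pre-stimulus mean (default TRUE).
#' @param scored channels entering the rejection test (default: all).
#' @return an `epoch_set` with per-epoch condition codes.
#' @export
segment_events <- function(rec, pre_ms = 100,
                           post_ms = if (rec$paradigm == "ldaep") 900 else 600,
                           reject_uV = 75, baseline = TRUE,
                           scored = rec$channels) {
  if (!rec$paradigm %in% c("ldaep", "mmn"))
    stop("segment_events expects an ldaep or mmn recording")
  if (nrow(rec$events) == 0)
    stop("recording has no events for paradigm ", rec$paradigm)
  fs <- rec$srate
  pre_n <- round(pre_ms / 1000 * fs)
  post_n <- round(post_ms / 1000 * fs)
  len <- pre_n + post_n
  si <- chan_index(rec, scored)
  ev <- rec$events
  ok <- ev$sample - pre_n >= 1 & ev$sample + post_n - 1 <= ncol(rec$data)
  ev <- ev[ok, , drop = FALSE]
  cand_codes <- unique(ev$code)

  keep_dat <- vector("list", nrow(ev))
  keep_code <- character(0)
  n_rej <- 0L
  for (k in seq_len(nrow(ev))) {
    idx <- (ev$sample[k] - pre_n):(ev$sample[k] + post_n - 1)
    ep <- rec$data[, idx, drop = FALSE]
    if (baseline && pre_n > 0)
      ep <- ep - rowMeans(ep[, seq_len(pre_n), drop = FALSE])
    if (max(abs(ep[si, ])) > reject_uV) {
      n_rej <- n_rej + 1L
    } else {
      keep_dat[[length(keep_code) + 1L]] <- ep
      keep_code <- c(keep_code, ev$code[k])
    }
  }
  missing <- setdiff(cand_codes, unique(keep_code))
  if (length(missing))
    stop("no surviving epochs for condition(s): ",
         paste(missing, collapse = ", "))
  arr <- array(0, c(length(keep_code), nrow(rec$data), len))
  for (j in seq_along(keep_code)) arr[j, , ] <- keep_dat[[j]]
  new_epoch_set(arr, rec$channels, fs,
                window_ms = c(-pre_ms, post_ms),
                baseline_ms = if (baseline) c(-pre_ms, 0) else NULL,
                codes = keep_code, n_rejected = n_rej,
                threshold = reject_uV)
}

epoch_time_ms <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$window_ms[1] + (seq_len(n) - 1) * 1000 / epochs$srate
}
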