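#' Average evoked response for one condition
#'
#' Pointwise mean across the retained epochs of a condition.
#'
#' @param epochs an `epoch_set` from [segment_events()].
#' @param condition condition code; NULL averages all epochs.
#' @return list of class `erp`: condition, channels, waveform
#'   (channels x samples, uV), time_ms, n_trials.
#' @export
average_erp <- function(epochs, condition = NULL) {
  sel <- if (is.null(condition)) seq_along(epochs$codes) else
    which(epochs$codes == condition)
  if (!length(sel))
    stop("no epochs for condition: ", condition)
  wav <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(
    list(condition = if (is.null(condition)) "all" else condition,
         channels = epochs$channels, waveform = wav,
         time_ms = epoch_time_ms(epochs), n_trials = length(sel)),
    class = "erp")
}

#' Detect an ERP peak in a latency window
#'
#' Finds the extremum of the given polarity within a closed latency
#' window; ties are broken by the earliest latency. N1 is the most
#' negative value in 50-200 ms, P2 the most positive in 150-300 ms.
#'
#' @param erp an `erp`.
#' @param channel channel label.
#' @param window_ms c(start, end), closed interval in ms.
#' @param polarity "negative" (trough) or "positive" (peak).
#' @return list: latency_ms, amplitude (uV), window_ms, polarity.
#' @export
detect_peak <- function(erp, channel, window_ms,
                        polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  ci <- match(channel, erp$channels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  sel <- which(erp$time_ms >= window_ms[1] & erp$time_ms <= window_ms[2])
  if (!length(sel))
    stop(sprintf("window [%g, %g] ms outside epoch [%g, %g] ms",
                 window_ms[1], window_ms[2],
                 min(erp$time_ms), max(erp$time_ms)))
  y <- erp$waveform[ci, sel]
  i <- if (polarity == "negative") which.min(y) else which.max(y)
  list(latency_ms = erp$time_ms[sel[i]], amplitude = y[i],
       window_ms = window_ms, polarity = polarity)
}

#' Loudness dependence of the auditory evoked potential
#'
#' For each of the five tone intensities (60-100 dB SPL) the condition
#' average at Cz is reduced to the N1/P2 peak-to-peak amplitude (N1: most
#' negative 50-200 ms; P2: most positive 150-300 ms), and the LDAEP is
#' the ordinary-least-squares slope of amplitude on intensity/10, i.e. in
#' uV per 10 dB.
#'
#' @param epochs `epoch_set` from an ldaep recording, codes "60".."100".
#' @param channel measurement electrode, default "Cz".
#' @param n1_window,p2_window search windows in ms.
#' @return list: intensities, amplitudes (uV, named by intensity), slope
#'   (uV/10 dB), intercept, peaks (per-intensity N1/P2 detail).
#' @export
ldaep <- function(epochs, channel = "Cz",
                  n1_window = c(50, 200), p2_window = c(150, 300)) {
  intensities <- c(60, 70, 80, 90, 100)
  have <- unique(epochs$codes)
  miss <- setdiff(as.character(intensities), have)
  if (length(miss))
    stop("missing intensity condition(s): ", paste(miss, collapse = ", "))
  peaks <- lapply(as.character(intensities), function(code) {
    av <- average_erp(epochs, code)
    list(n1 = detect_peak(av, channel, n1_window, "negative"),
         p2 = detect_peak(av, channel, p2_window, "positive"))
  })
  amps <- vapply(peaks, function(p) p$p2$amplitude - p$n1$amplitude,
                 numeric(1))
  names(amps) <- intensities
  fit <- stats::lm(amps ~ I(intensities / 10))
  list(intensities = intensities, amplitudes = amps,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       peaks = stats::setNames(peaks, intensities))
}

#' Mismatch negativity from standard and deviant epochs
#'
#' Difference wave = mean(deviant) - mean(standard); per-site mean
#' amplitude over the closed 130-280 ms window at the nine frontocentral
#' sites; the composite MMN is the unweighted mean of the nine site
#' values.
#'
#' @param epochs_std,epochs_dev `epoch_set`s (or the same set twice with
#'   codes "standard"/"deviant" selected via `std_code`/`dev_code`).
#' @param std_code,dev_code condition codes to average within each set.
#' @param window_ms measurement window, default c(130, 280).
#' @param sites measurement channels, default [mmn_sites()].
#' @return list: difference (erp-like), site_amplitudes (named uV),
#'   composite (uV), window_ms.
#' @export
mmn <- function(epochs_std, epochs_dev = epochs_std,
                std_code = "standard", dev_code = "deviant",
                window_ms = c(130, 280), sites = mmn_sites()) {
  std <- average_erp(epochs_std, std_code)
  dev <- average_erp(epochs_dev, dev_code)
  if (!identical(std$channels, dev$channels))
    stop("standard and deviant channel sets differ")
  miss <- setdiff(sites, std$channels)
  if (length(miss))
    stop("missing MMN site(s): ", paste(miss, collapse = ", "))
  diff_wav <- dev$waveform - std$waveform
  t <- std$time_ms
  sel <- t >= window_ms[1] & t <= window_ms[2]
  site_amp <- vapply(sites, function(ch) {
    mean(diff_wav[match(ch, std$channels), sel])
  }, numeric(1))
  structure(
    list(difference = list(channels = std$channels, waveform = diff_wav,
                           time_ms = t,
                           n_trials = c(standard = std$n_trials,
                                        deviant = dev$n_trials)),
         site_amplitudes = site_amp,
         composite = mean(site_amp),
         window_ms = window_ms),
    class = "mmn_result")
}

#' Extract all ERP biomarkers for one subject's recordings
#'
#' Applies the full preprocessing chain of each paradigm (0.1-30 Hz
#' band-pass, epoching with 75 uV rejection and pre-stimulus baseline
#' correction) and reduces to the subject's biomarker vector.
#'
#' @param resting,ldaep_rec,mmn_rec the three recordings (any may be NULL).
#' @return one-row data.frame: faa_f5f6, faa_f7f8, ldaep, mmn.
#' @export
extract_features <- function(resting = NULL, ldaep_rec = NULL,
                             mmn_rec = NULL) {
  out <- data.frame(faa_f5f6 = NA_real_, faa_f7f8 = NA_real_,
                    ldaep = NA_real_, mmn = NA_real_)
  if (!is.null(resting)) {
    faa <- compute_faa(resting)
    out$faa_f5f6 <- faa$f5f6$value
    out$faa_f7f8 <- faa$f7f8$value
  }
  if (!is.null(ldaep_rec)) {
    ep <- segment_events(bandpass(ldaep_rec, 0.1, 30), post_ms = 900)
    out$ldaep <- ldaep(ep)$slope
  }
  if (!is.null(mmn_rec)) {
    ep <- segment_events(bandpass(mmn_rec, 0.1, 30), post_ms = 600)
    out$mmn <- mmn(ep)$composite
  }
  out
}
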