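#' Default frontocentral montage
#'
#' Ordered 10-20 channel labels covering the analysis set: the two frontal
#' asymmetry pairs (F5/F6, F7/F8) and the nine frontocentral MMN sites.
#'
#' @export
default_montage <- function() {
  c("F5", "F6", "F7", "F8", "F3", "Fz", "F4",
    "FC3", "FCz", "FC4", "C3", "Cz", "C4")
}

#' Nine frontocentral MMN measurement sites
#' @export
mmn_sites <- function() {
  c("F3", "Fz", "F4", "FC3", "FCz", "FC4", "C3", "Cz", "C4")
}

#' Frontal asymmetry channel pairs (left, right)
#' @export
faa_pairs <- function() {
  list(f5f6 = c("F5", "F6"), f7f8 = c("F7", "F8"))
}

#' Construct a multichannel EEG recording
#'
#' The basic container for raw EEG: a channels-by-samples matrix in
#' microvolts with an ordered 10-20 channel list, sampling rate, paradigm
#' tag and event table.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channels character vector of unique 10-20 labels, one per row.
#' @param srate sampling rate in Hz.
#' @param paradigm one of "resting", "ldaep", "mmn".
#' @param events data.frame with columns `sample` (1-based index) and
#'   `code` (character or numeric condition code), or NULL.
#' @param subject_id subject identifier.
#' @param meta free-form provenance list (filters applied, generator truth).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, channels, srate, paradigm = "resting",
                      events = NULL, subject_id = NA_character_,
                      meta = list()) {
  data <- as.matrix(data)
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (nrow(data) != length(channels))
    stop("data has ", nrow(data), " rows but ", length(channels),
         " channel labels were given")
  if (!paradigm %in% c("resting", "ldaep", "mmn"))
    stop("unknown paradigm: ", paradigm)
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("sample", "code") %in% names(events)))
    if (nrow(events) &&
        (min(events$sample) < 1 || max(events$sample) > ncol(data)))
      stop("event sample indices out of range 1..", ncol(data))
  } else {
    events <- data.frame(sample = integer(0), code = character(0))
  }
  structure(
    list(subject_id = subject_id, paradigm = paradigm,
         channels = as.character(channels), srate = srate,
         data = data, events = events, meta = meta),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, paradigm %s\n",
              x$subject_id, x$paradigm))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate, nrow(x$events)))
  invisible(x)
}

chan_index <- function(rec, channel) {
  i <- match(channel, rec$channels)
  if (anyNA(i))
    stop("channel(s) not in montage: ",
         paste(channel[is.na(i)], collapse = ", "))
  i
}
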