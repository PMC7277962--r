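# Minimal EDF+ support: 16-bit European Data Format with one optional
# "EDF Annotations" signal carrying event markers as time-stamped
# annotation lists (TALs). Covers continuous (EDF+C) recordings written
# by this package and plain EDF files with microvolt/millivolt/volt
# channels. Amplitudes are quantized to the 16-bit digital range on
# write.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF+ file
#'
#' Signals are scaled per channel to the full 16-bit digital range;
#' events (if any) are stored in an "EDF Annotations" signal as TALs with
#' the event code as annotation text. Physical dimension is uV. The final
#' partial data record is zero-padded.
#'
#' @param rec an [recording()].
#' @param path output path (.edf).
#' @param record_s data-record duration in seconds (default 1).
#' @return path, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  fs <- rec$srate
  spr <- round(fs * record_s)
  if (abs(spr - fs * record_s) > 1e-9)
    stop("sampling_rate x record_s must be an integer")
  n_rec <- ceiling(ncol(rec$data) / spr)
  nch <- nrow(rec$data)
  has_ann <- nrow(rec$events) > 0
  ns <- nch + as.integer(has_ann)

  # per-channel physical scaling covering the data range
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  pad <- pmax((phys_max - phys_min) * 0.01, 1e-6)
  phys_min <- phys_min - pad
  phys_max <- phys_max + pad
  dmin <- -32768; dmax <- 32767

  ann_spr <- 64                                   # 128 bytes per record
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(paste0("X X X ", rec$subject_id), 80))
  wr(edf_pad(paste0("Startdate X X X X paradigm=", rec$paradigm), 80))
  wr(edf_pad("01.01.20", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_num(256 * (1 + ns), 8))
  wr(edf_pad(if (has_ann) "EDF+C" else "", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(record_s, 8))
  wr(edf_num(ns, 4))

  labels <- c(rec$channels, if (has_ann) "EDF Annotations")
  for (lab in labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))                # transducer
  for (i in seq_len(ns))
    wr(edf_pad(if (i <= nch) "uV" else "", 8))              # dimension
  for (i in seq_len(ns))
    wr(edf_num(if (i <= nch) phys_min[i] else -1, 8))
  for (i in seq_len(ns))
    wr(edf_num(if (i <= nch) phys_max[i] else 1, 8))
  for (i in seq_len(ns)) wr(edf_num(dmin, 8))
  for (i in seq_len(ns)) wr(edf_num(dmax, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))                # prefiltering
  for (i in seq_len(ns))
    wr(edf_num(if (i <= nch) spr else ann_spr, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  gain <- (dmax - dmin) / (phys_max - phys_min)
  ev_time <- (rec$events$sample - 1) / fs
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(nch)) {
      x <- rep(0, spr)
      valid <- idx <= ncol(rec$data)
      x[valid] <- rec$data[i, idx[valid]]
      d <- round((x - phys_min[i]) * gain[i] + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, d))), con, size = 2,
               endian = "little")
    }
    if (has_ann) {
      t0 <- (r - 1) * record_s
      # one TAL per annotation, each \x00-terminated; the first TAL of a
      # record carries the record start time
      tals <- c(charToRaw(sprintf("+%g\x14\x14", t0)), as.raw(0))
      in_rec <- which(ev_time >= t0 & ev_time < t0 + record_s)
      for (k in in_rec)
        tals <- c(tals,
                  charToRaw(sprintf("+%.6f\x14%s\x14", ev_time[k],
                                    rec$events$code[k])), as.raw(0))
      if (length(tals) > 2 * ann_spr)
        stop("too many events in one data record for the annotation signal")
      writeBin(c(tals, raw(2 * ann_spr - length(tals))), con)
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file as a recording
#'
#' Parses the header, rescales digital values to physical units, converts
#' channel units to microvolts (uV kept, mV x 1000, V x 1e6) and decodes
#' event annotations from any "EDF Annotations" signal into the event
#' table.
#'
#' @param path .edf file.
#' @param paradigm paradigm tag for the returned recording; defaults to a
#'   `paradigm=` tag in the recording-identification header field, else
#'   "resting". ERP paradigms require events.
#' @return an [recording()].
#' @export
read_edf <- function(path, paradigm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                           # version
  pat <- rd(80)
  rec_field <- rd(80)
  rd(16)                                          # date, time
  rd(8)                                           # header bytes
  rd(44)                                          # reserved
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig <- lapply(seq_len(ns), function(i)
    if (is_ann[i]) raw(0) else numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        sig[[i]] <- c(sig[[i]], readBin(con, raw(), n = 2 * spr[i]))
      } else {
        d <- readBin(con, integer(), n = spr[i], size = 2,
                     endian = "little")
        sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
          (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) +
          pmin[i]
      }
    }
  }
  ch <- which(!is_ann)
  if (!length(ch)) stop("EDF file contains no signal channels")
  if (length(unique(spr[ch])) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[ch[1]] / record_s
  scale <- vapply(dims[ch], function(d)
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1000,
           "v" = 1e6, 1), numeric(1))
  dat <- do.call(rbind, lapply(seq_along(ch), function(j)
    sig[[ch[j]]] * scale[j]))

  events <- NULL
  if (any(is_ann)) {
    ann_raw <- sig[[which(is_ann)[1]]]
    # TALs are \x00-terminated; within a TAL, \x14 separates the onset
    # stamp (optionally +\x15duration) from the annotation texts
    brk <- which(ann_raw == as.raw(0))
    starts <- c(1L, brk[-length(brk)] + 1L)
    onsets <- numeric(0); codes <- character(0)
    for (j in seq_along(brk)) {
      if (starts[j] > brk[j] - 1) next
      tal <- rawToChar(ann_raw[starts[j]:(brk[j] - 1)])
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      texts <- parts[-1][nzchar(parts[-1])]
      if (!length(texts)) next                    # record timestamp TAL
      onset <- as.numeric(sub("\x15.*$", "", parts[1]))
      onsets <- c(onsets, rep(onset, length(texts)))
      codes <- c(codes, texts)
    }
    if (length(onsets))
      events <- data.frame(sample = round(onsets * fs) + 1L,
                           code = codes)
  }
  par <- paradigm
  if (is.null(par)) {
    m <- regmatches(rec_field, regexec("paradigm=([a-z]+)", rec_field))[[1]]
    par <- if (length(m) == 2) m[2] else "resting"
  }
  if (par %in% c("ldaep", "mmn") && (is.null(events) || nrow(events) == 0))
    stop("EDF file has no event annotations required for paradigm ", par)
  sid <- trimws(sub("^X X X ", "", pat))
  recording(dat, labels[ch], fs, paradigm = par, events = events,
            subject_id = sid)
}
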