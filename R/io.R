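#' Write a recording to the package container format
#'
#' The container is a JSON sidecar (`<stem>.json`: channels, sampling
#' rate, paradigm, subject, events, metadata) plus a raw little-endian
#' float64 data file (`<stem>.dat`, channel-major). The round trip is
#' lossless.
#'
#' @param rec an [recording()].
#' @param stem output path without extension.
#' @return the stem, invisibly.
#' @export
write_recording <- function(rec, stem) {
  hdr <- list(format = "erpmark-container", version = 1L,
              subject_id = rec$subject_id, paradigm = rec$paradigm,
              channels = rec$channels, srate = rec$srate,
              n_samples = ncol(rec$data),
              events = rec$events, meta = rec$meta)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  invisible(stem)
}

#' Read a recording (container or EDF)
#'
#' Dispatches on the file: `<stem>.json`/`<stem>.dat` pairs are read as
#' the package container, `*.edf` through the EDF reader. Values are
#' returned in microvolts.
#'
#' @param path container stem (or its .json file) or an .edf path.
#' @param paradigm optional expected paradigm; ERP paradigms ("ldaep",
#'   "mmn") require event annotations and error without them.
#' @return an [recording()].
#' @export
read_recording <- function(path, paradigm = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(read_edf(path, paradigm = paradigm))
  stem <- sub("\\.json$", "", path)
  jf <- paste0(stem, ".json"); df <- paste0(stem, ".dat")
  if (!file.exists(jf) || !file.exists(df))
    stop("container files not found: ", jf, " / ", df)
  hdr <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(hdr$format, "erpmark-container"))
    stop("not an erpmark container: ", jf)
  nch <- length(hdr$channels)
  con <- file(df, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = nch * hdr$n_samples, size = 8,
                  endian = "little")
  dat <- t(matrix(vals, ncol = nch))
  ev <- if (length(hdr$events)) as.data.frame(hdr$events) else NULL
  if (!is.null(ev) && nrow(ev)) {
    ev$sample <- as.integer(ev$sample)
    ev$code <- as.character(ev$code)
  }
  par <- if (is.null(paradigm)) hdr$paradigm else paradigm
  if (par %in% c("ldaep", "mmn") && (is.null(ev) || nrow(ev) == 0))
    stop("recording has no event annotations required for paradigm ", par)
  recording(dat, hdr$channels, hdr$srate, paradigm = hdr$paradigm,
            events = ev, subject_id = hdr$subject_id,
            meta = if (is.null(hdr$meta)) list() else hdr$meta)
}

#' Read and validate a clinical table
#'
#' Delimited text (comma default) with columns: subject_id, age, sex
#' (male/female), medication (vortioxetine/escitalopram), hamd_w0,
#' hamd_w2, hamd_w4, hamd_w8, hama_w0, hama_w8, core. Rows with missing
#' HAM-D entries are kept but flagged incomplete (excluded from
#' complete-case statistics by the pipeline, with a logged count).
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame with an added logical `complete` column.
#' @export
read_clinical_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("subject_id", "age", "sex", "medication",
           "hamd_w0", "hamd_w2", "hamd_w4", "hamd_w8", "core")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  hamd_cols <- c("hamd_w0", "hamd_w2", "hamd_w4", "hamd_w8")
  for (cc in hamd_cols) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad))
      stop("negative ", cc, " in row(s): ", paste(bad, collapse = ", "))
  }
  bad_sex <- which(!df$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex label in row(s): ", paste(bad_sex, collapse = ", "))
  bad_med <- which(!df$medication %in% c("vortioxetine", "escitalopram"))
  if (length(bad_med))
    stop("unknown medication label in row(s): ",
         paste(bad_med, collapse = ", "))
  df$complete <- stats::complete.cases(df[hamd_cols])
  df
}

#' Write a clinical table
#' @param clinical data.frame as produced by [gen_clinical_cohort()].
#' @param path output path (CSV).
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical[setdiff(names(clinical), "complete")],
                   path, row.names = FALSE)
  invisible(path)
}
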