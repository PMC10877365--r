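# Recording I/O: a delimited-text path (matrix + YAML sidecar) that
# round-trips exactly, and a minimal European Data Format (EDF) path so
# cohorts can be exchanged with standard EEG tooling.  The EDF code
# implements the published 16-bit EDF layout directly since no installed
# R package reads it; values survive a round trip up to the format's
# 16-bit quantisation.

#' Write / read a recording as a delimited matrix with a sidecar
#'
#' The signal matrix is written as tab-separated text (channels x samples
#' by default) and the metadata — subject id, class label, sampling rate,
#' channel names, orientation — as a YAML sidecar next to it
#' (`<path>.yaml`).
#'
#' @param rec A [recording()].
#' @param path Path of the matrix file; the sidecar is written to
#'   `paste0(path, ".yaml")`.
#' @param transpose Write samples x channels instead (recorded in the
#'   sidecar, so reading is unambiguous).
#' @return `write_recording_txt` returns `path` invisibly;
#'   `read_recording_txt` the restored `Recording`.
#' @export
write_recording_txt <- function(rec, path, transpose = FALSE) {
  stopifnot(inherits(rec, "Recording"))
  m <- if (transpose) t(rec$data) else rec$data
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(subject_id = rec$subject_id, label = rec$label,
                        sf = rec$sf, channel_names = rec$channel_names,
                        orientation = if (transpose) "samples_x_channels"
                                      else "channels_x_samples"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording_txt
#' @export
read_recording_txt <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  if (identical(meta$orientation, "samples_x_channels")) m <- t(m)
  recording(meta$subject_id, meta$label, meta$sf, m,
            channel_names = as.character(meta$channel_names))
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf("%-*s", width, x)
}

num_field <- function(x, width) {
  for (d in seq.int(width - 1L, 1L)) {
    s <- formatC(x, digits = d, width = 1, format = "g")
    if (nchar(s) <= width) return(pad_ascii(s, width))
  }
  stop("cannot format ", x, " in ", width, " characters")
}

#' Write / read a recording in European Data Format (EDF)
#'
#' Standard 16-bit EDF with one-second data records.  The subject id and
#' class label are stored in the header's patient-identification field as
#' `"<subject_id> label=<label>"`.  Any trailing partial second is
#' dropped (EDF stores whole records only), and amplitudes are quantised
#' to the channel's 16-bit physical range.
#'
#' @param rec A [recording()]; `sf` must be a whole number.
#' @param path File path (conventionally `.edf`).
#' @return `write_recording_edf` returns `path` invisibly;
#'   `read_recording_edf` the restored `Recording`.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "Recording"))
  sf <- rec$sf
  if (abs(sf - round(sf)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  sf <- as.integer(round(sf))
  nrec <- ncol(rec$data) %/% sf
  if (nrec < 1L) stop("recording shorter than one EDF data record (1 s)")
  nch <- nrow(rec$data)
  x <- rec$data[, seq_len(nrec * sf), drop = FALSE]

  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(paste0(rec$subject_id, " label=", rec$label), 80),
    pad_ascii("synthetic EEG export", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 + 256 * nch, 8),
    pad_ascii("", 44),
    pad_ascii(nrec, 8),
    pad_ascii(1, 8),
    pad_ascii(nch, 4))
  sig <- paste0(
    paste(vapply(rec$channel_names, pad_ascii, "", 16), collapse = ""),
    paste(rep(pad_ascii("", 80), nch), collapse = ""),
    paste(rep(pad_ascii("uV", 8), nch), collapse = ""),
    paste(vapply(pmin_, num_field, "", 8), collapse = ""),
    paste(vapply(pmax_, num_field, "", 8), collapse = ""),
    paste(rep(pad_ascii(dmin, 8), nch), collapse = ""),
    paste(rep(pad_ascii(dmax, 8), nch), collapse = ""),
    paste(rep(pad_ascii("", 80), nch), collapse = ""),
    paste(rep(pad_ascii(sf, 8), nch), collapse = ""),
    paste(rep(pad_ascii("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  # physical -> digital per channel, then interleave by record
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round((x - pmin_) / gain + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * sf + 1L):(r * sf)
    writeBin(as.integer(t(dig[, cols, drop = FALSE]))[seq_len(nch * sf)],
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  as.integer(rd(8))                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  for (i in seq_len(nch)) rd(80)          # transducer
  for (i in seq_len(nch)) rd(8)           # dimension
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  sf <- spr[1] / recdur

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = nch * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = nch)
    x[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
  }
  m <- regmatches(patient, regexec("^(.*) label=([01])$", patient))[[1]]
  subject_id <- if (length(m)) m[2] else patient
  label <- if (length(m)) as.integer(m[3]) else 0L
  recording(subject_id, label, sf, (x - dmin) * gain + pmin_,
            channel_names = labels)
}

#' Write a cohort to a directory
#'
#' Writes every recording of a cohort through the chosen format so the
#' synthetic path exercises the same readers as real data.
#'
#' @param recs List of [recording()]s.
#' @param dir Output directory (created if needed).
#' @param format `"txt"` (delimited + sidecar) or `"edf"`.
#' @return Character vector of written file paths, invisibly.
#' @export
write_cohort <- function(recs, dir, format = c("txt", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(recs, function(r) {
    p <- file.path(dir, paste0(r$subject_id,
                               if (format == "edf") ".edf" else ".tsv"))
    if (format == "edf") write_recording_edf(r, p)
    else write_recording_txt(r, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a cohort from a directory
#'
#' @param dir Directory holding `.tsv` + sidecar or `.edf` files.
#' @return List of `Recording`s, sorted by file name.
#' @export
read_cohort <- function(dir) {
  tsv <- sort(list.files(dir, "\\.tsv$", full.names = TRUE))
  edf <- sort(list.files(dir, "\\.edf$", full.names = TRUE))
  c(lapply(tsv, read_recording_txt), lapply(edf, read_recording_edf))
}
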