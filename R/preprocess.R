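#' Construct an EEG recording
#'
#' A `Recording` holds one subject's labelled multichannel EEG: a
#' channels-by-samples matrix in microvolts plus the metadata needed
#' downstream (subject id, binary class label, sampling rate, channel
#' names).
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param label Class label, 0 or 1.
#' @param sf Sampling rate in Hz.
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_names Character vector, one name per row of `data`.
#' @return A `Recording` object.
#' @export
recording <- function(subject_id, label, sf, data,
                      channel_names = rownames(data)) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data)))
    stop("recording data must be finite")
  if (!(sf > 0)) stop("sampling rate must be positive")
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  if (is.null(channel_names))
    stop("channel names are required")
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") != number of data rows (", nrow(data), ")")
  if (ncol(data) < 1L) stop("recording must contain at least one sample")
  rownames(data) <- channel_names
  r <- list(subject_id = as.character(subject_id), label = label,
            sf = sf, channel_names = as.character(channel_names),
            data = data)
  class(r) <- "Recording"
  r
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording %s (label %d): %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$sf,
              ncol(x$data) / x$sf))
  invisible(x)
}

#' FIR filter chain specification
#'
#' Describes the three-stage FIR chain applied to raw EEG: a high-pass that
#' removes slow drift, a low-pass that keeps everything up to the low-gamma
#' band, and a notch centred on the mains frequency.  All three are
#' Hamming-windowed-sinc (linear-phase) designs applied forward-backward,
#' so the net chain is zero-phase and waveform timing is preserved.
#'
#' Filter orders follow the usual windowed-sinc rule of thumb
#' (order ~ 3.3 / normalised transition width for a Hamming window) from
#' the requested transition bandwidths, rounded up to even so each filter
#' is type-I.
#'
#' @param hp_hz High-pass edge in Hz (default 0.5, drift removal).
#' @param lp_hz Low-pass edge in Hz (default 60, retains low gamma).
#' @param notch_hz Mains notch centre in Hz (default 50); `NULL` disables
#'   the notch stage.
#' @param hp_trans_hz,lp_trans_hz Transition bandwidths of the high- and
#'   low-pass stages (defaults 0.5 and 8 Hz).
#' @param notch_width_hz Full width of the notch stop band (default 2 Hz).
#' @return A `FilterSpec` object.
#' @export
filter_spec <- function(hp_hz = 0.5, lp_hz = 60, notch_hz = 50,
                        hp_trans_hz = 0.5, lp_trans_hz = 8,
                        notch_width_hz = 2) {
  stopifnot(hp_hz > 0, lp_hz > hp_hz)
  if (!is.null(notch_hz) &&
      (notch_hz <= hp_hz || notch_hz >= lp_hz))
    stop("notch centre must lie inside (hp_hz, lp_hz)")
  s <- list(hp_hz = hp_hz, lp_hz = lp_hz, notch_hz = notch_hz,
            hp_trans_hz = hp_trans_hz, lp_trans_hz = lp_trans_hz,
            notch_width_hz = notch_width_hz, design = "hamming-sinc")
  class(s) <- "FilterSpec"
  s
}

# Even FIR order for a Hamming window given a transition width in Hz.
fir_order <- function(trans_hz, sf) {
  n <- ceiling(3.3 * sf / trans_hz)
  n + n %% 2L
}

# Design the chain's FIR coefficient vectors for a given sampling rate.
design_filter_chain <- function(spec, sf) {
  nyq <- sf / 2
  if (spec$lp_hz >= nyq)
    stop("low-pass edge ", spec$lp_hz,
         " Hz requires sampling rate > ", 2 * spec$lp_hz, " Hz")
  filters <- list(
    hp = signal::fir1(fir_order(spec$hp_trans_hz, sf), spec$hp_hz / nyq,
                      type = "high"),
    lp = signal::fir1(fir_order(spec$lp_trans_hz, sf), spec$lp_hz / nyq,
                      type = "low")
  )
  if (!is.null(spec$notch_hz)) {
    half <- spec$notch_width_hz / 2
    edges <- c(spec$notch_hz - half, spec$notch_hz + half) / nyq
    if (edges[2] >= 1)
      stop("notch band exceeds the Nyquist frequency")
    # transition half the stop width keeps the notch tight around the mains
    filters$notch <- signal::fir1(fir_order(spec$notch_width_hz / 2, sf),
                                  edges, type = "stop")
  }
  filters
}

# Zero-phase FIR filtering by forward-backward FFT convolution.  The signal
# is reflection-padded by the filter length at both ends to suppress edge
# transients, convolved with the (linear-phase) kernel once in each
# direction, and cropped back.  FFT convolution is exact linear convolution
# here (the transform length covers signal + kernel), so this matches
# direct filtfilt up to rounding while staying fast for long kernels.
fir_filtfilt_fft <- function(x, b) {
  n <- length(x)
  k <- length(b)
  pad <- min(k, n - 1L)
  xe <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  ne <- length(xe)
  m <- stats::nextn(ne + k - 1L, 2)
  B <- fft(c(b, numeric(m - k)))
  H2 <- Mod(B)^2                      # forward+backward = |B(f)|^2, zero phase
  X <- fft(c(xe, numeric(m - ne)))
  y <- Re(fft(X * H2, inverse = TRUE)) / m
  # |B|^2 is the spectrum of b's autocorrelation, already centred at lag 0
  # (negative lags wrap into the zero tail), so no delay compensation
  y <- y[seq_len(ne)]
  y[(pad + 1L):(pad + n)]
}

#' Apply the FIR filter chain to a recording
#'
#' Filters every channel high-pass, then low-pass, then notch, each stage
#' zero-phase (forward-backward).  The output has the same shape as the
#' input.
#'
#' @param rec A [recording()].
#' @param spec A [filter_spec()]; the defaults give 0.5 Hz HP, 60 Hz LP and
#'   a 50 Hz notch.
#' @return A filtered `Recording` of identical dimensions.
#' @export
apply_filter_chain <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "Recording"))
  filters <- design_filter_chain(spec, rec$sf)
  x <- rec$data
  for (b in filters) {
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- fir_filtfilt_fft(x[ch, ], b)
  }
  rec$data <- x
  rec
}

#' Z-score normalise a recording per channel
#'
#' Centres and scales each channel independently over the whole recording
#' so every channel has mean 0 and unit standard deviation before
#' windowing.
#'
#' @param rec A [recording()].
#' @return A normalised `Recording`.
#' @export
zscore_normalize <- function(rec) {
  stopifnot(inherits(rec, "Recording"))
  mu <- rowMeans(rec$data)
  sigma <- apply(rec$data, 1L, sd)
  bad <- which(sigma == 0 | !is.finite(sigma))
  if (length(bad))
    stop("zero-variance channel(s): ",
         paste(rec$channel_names[bad], collapse = ", "))
  rec$data <- (rec$data - mu) / sigma
  rec
}

#' Flag high-amplitude segments for exclusion
#'
#' A simple amplitude-based artifact screen: the recording is scanned in
#' non-overlapping 1-second segments, and any segment in which some
#' channel's peak-to-peak amplitude exceeds `amp_uv` is flagged.  Flagged
#' samples are excluded from windowing by [segment_windows()].  Disabled by
#' default in the pipeline (an infinite threshold flags nothing).
#'
#' @param rec A [recording()].
#' @param amp_uv Peak-to-peak rejection threshold in microvolts.
#' @return The `Recording` with a logical per-sample attribute
#'   `"reject_mask"` (`TRUE` = excluded).
#' @export
reject_artifacts <- function(rec, amp_uv = Inf) {
  stopifnot(inherits(rec, "Recording"), amp_uv > 0)
  n <- ncol(rec$data)
  seg_len <- max(1L, round(rec$sf))
  mask <- logical(n)
  starts <- seq.int(1L, n, by = seg_len)
  for (s in starts) {
    e <- min(s + seg_len - 1L, n)
    seg <- rec$data[, s:e, drop = FALSE]
    p2p <- apply(seg, 1L, function(v) max(v) - min(v))
    if (any(p2p > amp_uv)) mask[s:e] <- TRUE
  }
  attr(rec, "reject_mask") <- mask
  rec
}

new_window_set <- function(windows, subject_ids, labels, channel_names,
                           sf, win_s, overlap) {
  ws <- list(windows = windows,
             subject_ids = as.character(subject_ids),
             labels = as.integer(labels),
             channel_names = as.character(channel_names),
             sf = sf, win_s = win_s, overlap = overlap)
  class(ws) <- "WindowSet"
  ws
}

#' @export
print.WindowSet <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf(
    "WindowSet: %d windows x %d channels x %d samples (%g s, %d%% overlap)\n",
    d[1], d[2], d[3], x$win_s, round(100 * x$overlap)))
  cat(sprintf("  %d subjects, labels: %s\n",
              length(unique(x$subject_ids)),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Segment recordings into fixed-length overlapping windows
#'
#' Divides each recording into windows of `win_s` seconds with fractional
#' `overlap` (default 2 s, 50 %), the unit the classifier consumes.  Each
#' window inherits its subject's id and label.  For a recording of N
#' samples with window length S and step S(1-overlap) the window count is
#' `floor((N - S)/step) + 1` when `N >= S` and 0 otherwise; trailing
#' partial windows are dropped and short recordings contribute nothing
#' (no padding).  Windows overlapping samples flagged by
#' [reject_artifacts()] are discarded.
#'
#' @param recs A `Recording` or list of them (all same sf and channels).
#' @param win_s Window length in seconds; `win_s * sf` must be integral.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return A `WindowSet`: array `windows` (n x channels x samples) plus
#'   per-window `subject_ids` and `labels`.
#' @examples
#' r <- recording("s1", 0, 128, matrix(rnorm(19 * 512), 19,
#'                dimnames = list(standard_montage()$channels, NULL)))
#' segment_windows(r)   # 3 windows of 256 samples
#' @export
segment_windows <- function(recs, win_s = 2, overlap = 0.5) {
  if (inherits(recs, "Recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1L)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)")
  sf <- recs[[1]]$sf
  chans <- recs[[1]]$channel_names
  S <- win_s * sf
  if (abs(S - round(S)) > 1e-9)
    stop("win_s * sf must be an integer number of samples")
  S <- as.integer(round(S))
  step <- S * (1 - overlap)
  if (abs(step - round(step)) > 1e-9)
    stop("window step (S * (1 - overlap)) must be integral")
  step <- as.integer(round(step))

  pieces <- list(); sub <- character(); lab <- integer()
  for (r in recs) {
    stopifnot(inherits(r, "Recording"))
    if (r$sf != sf || !identical(r$channel_names, chans))
      stop("all recordings must share sampling rate and channel names")
    N <- ncol(r$data)
    if (N < S) next
    mask <- attr(r, "reject_mask")
    starts <- seq.int(1L, N - S + 1L, by = step)
    for (s in starts) {
      if (!is.null(mask) && any(mask[s:(s + S - 1L)])) next
      pieces[[length(pieces) + 1L]] <- r$data[, s:(s + S - 1L), drop = FALSE]
      sub <- c(sub, r$subject_id)
      lab <- c(lab, r$label)
    }
  }
  n <- length(pieces)
  w <- array(0, dim = c(n, length(chans), S))
  for (i in seq_len(n)) w[i, , ] <- pieces[[i]]
  new_window_set(w, sub, lab, chans, sf, win_s, overlap)
}

#' Restrict a window set to a channel group
#'
#' Keeps only the group's channels, in canonical montage order; the number
#' of windows is unchanged.
#'
#' @param ws A `WindowSet`.
#' @param group A [channel_group()] or character vector of channel names.
#' @return A `WindowSet` over the group's channels.
#' @export
select_channels <- function(ws, group) {
  stopifnot(inherits(ws, "WindowSet"))
  members <- if (inherits(group, "ChannelGroup")) group$members
             else as.character(group)
  idx <- match(members, ws$channel_names)
  if (anyNA(idx))
    stop("channel(s) not in window set: ",
         paste(members[is.na(idx)], collapse = ", "))
  idx <- sort(idx)   # canonical order = window set's stored order
  ws$windows <- ws$windows[, idx, , drop = FALSE]
  ws$channel_names <- ws$channel_names[idx]
  ws
}

#' Number of windows a recording of given length yields
#'
#' Closed form for the sliding-window count: `floor((N - S)/step) + 1` for
#' `N >= S`, else 0.
#'
#' @param n_samples Recording length N in samples.
#' @param S Window length in samples.
#' @param step Step between window starts in samples.
#' @return Integer window count.
#' @export
window_count <- function(n_samples, S, step) {
  ifelse(n_samples >= S, (n_samples - S) %/% step + 1L, 0L)
}

#' Persist / load a window set
#'
#' Windows are saved with R's portable native serialisation together with
#' an index table (subject id, label) so a prepared tensor can be reused
#' across sessions.
#'
#' @param ws A `WindowSet`.
#' @param path File path.
#' @return `write_window_set` returns `path` invisibly; `read_window_set`
#'   the restored `WindowSet`.
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "WindowSet"))
  saveRDS(unclass(ws), path)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  ws <- readRDS(path)
  class(ws) <- "WindowSet"
  ws
}
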