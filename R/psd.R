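#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Welch) estimate of the one-sided PSD of a
#' single signal, using Hann-tapered segments with 50 % overlap.  Scaled as
#' power density (units^2/Hz): the integral of the PSD over frequency
#' recovers the signal's variance (Parseval), which is the property the
#' band-power tests rely on.
#'
#' @param x Numeric signal vector.
#' @param sf Sampling rate in Hz.
#' @param nperseg Segment length in samples (default `min(256, length(x))`).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param demean Subtract each segment's mean before tapering (default TRUE).
#' @return A list with `freq` (Hz) and `psd` (power density) vectors.
#' @export
welch_psd <- function(x, sf, nperseg = min(256L, length(x)), overlap = 0.5,
                      demean = TRUE) {
  n <- length(x)
  nperseg <- as.integer(nperseg)
  stopifnot(nperseg >= 8L, nperseg <= n)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg - 1L + 1L) /
                         (nperseg + 1L))        # periodic-ish Hann taper
  U <- sum(w^2)                                  # window power normalisation
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * U * sf)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * sf / nperseg, psd = psd * dbl)
}

#' Band power of a signal
#'
#' Integrates the Welch PSD over a frequency band by the trapezoidal rule.
#'
#' @param x Numeric signal.
#' @param sf Sampling rate in Hz.
#' @param band Length-2 numeric `c(lo, hi)` in Hz.
#' @param ... Passed to [welch_psd()].
#' @return Band power (signal units squared).
#' @export
band_power <- function(x, sf, band, ...) {
  p <- welch_psd(x, sf, ...)
  keep <- p$freq >= band[1] & p$freq <= band[2]
  if (sum(keep) < 2L) stop("band too narrow for the spectral resolution")
  f <- p$freq[keep]; y <- p$psd[keep]
  sum(diff(f) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Canonical EEG frequency bands
#'
#' Delta, theta, alpha and beta band edges in Hz, used as defaults by the
#' synthetic generator and the band-power feature extractor.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Per-window log band-power features
#'
#' Computes log band power for every window and channel of a window set —
#' the feature matrix consumed by the surrogate selection scorer.  Each
#' 2-second window is short, so a single full-length Hann periodogram per
#' window is used.
#'
#' @param ws A `WindowSet`.
#' @param bands Named list of band edges, default [eeg_bands()].
#' @return Numeric matrix, `n_windows` x (`n_channels * n_bands`); column
#'   names are `<channel>.<band>`.
#' @export
bandpower_features <- function(ws, bands = eeg_bands()) {
  stopifnot(inherits(ws, "WindowSet"))
  d <- dim(ws$windows)
  n <- d[1]; C <- d[2]; S <- d[3]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(S) / (S + 1L))
  U <- sum(w^2)
  nf <- S %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * ws$sf / S
  dbl <- rep(2, nf); dbl[1] <- 1
  if (S %% 2L == 0L) dbl[nf] <- 1
  sel <- lapply(bands, function(b) which(freq >= b[1] & freq <= b[2]))
  out <- matrix(0, n, C * length(bands))
  colnames(out) <- as.vector(outer(ws$channel_names, names(bands),
                                   paste, sep = "."))
  for (ch in seq_len(C)) {
    # all windows of one channel at once: S x n matrix through mvfft
    M <- t(ws$windows[, ch, , drop = TRUE])
    if (n == 1L) M <- matrix(ws$windows[1, ch, ], ncol = 1L)
    M <- (M - rep(colMeans(M), each = S)) * w
    P <- Mod(stats::mvfft(M)[seq_len(nf), , drop = FALSE])^2 *
      dbl / (U * ws$sf)
    for (bi in seq_along(bands)) {
      idx <- sel[[bi]]
      f <- freq[idx]
      tw <- diff(f)
      # trapezoid integral down the rows
      bp <- colSums(P[idx[-length(idx)], , drop = FALSE] * tw / 2) +
        colSums(P[idx[-1], , drop = FALSE] * tw / 2)
      out[, (bi - 1L) * C + ch] <- log(bp + 1e-12)
    }
  }
  out
}
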