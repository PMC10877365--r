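#' Specification of a synthetic two-class EEG cohort
#'
#' Describes a seeded cohort generator that emulates the shape of a
#' two-class paediatric EEG study: two balanced groups of subjects, a
#' 19-channel 10-20 montage, 128 Hz sampling, and minutes-long recordings
#' of variable length.  Each channel is a sum of band-limited Gaussian
#' oscillations (delta/theta/alpha/beta) plus 1/f background noise.  The
#' class contrast is a multiplicative band-power elevation: for class-1
#' subjects, power in `contrast_band` is scaled by `(1 + effect)` on the
#' `informative_channels` only, so the discriminative structure is fully
#' under the caller's control.  The generator makes no claim to mimic any
#' real clinical spectrum beyond this controllable structure.
#'
#' @param n_per_class Subjects per class (default 60).
#' @param sf Sampling rate in Hz (default 128).
#' @param duration_s Length-2 range of per-subject recording durations in
#'   seconds, drawn uniformly (default `c(60, 120)`).
#' @param informative_channels Channels carrying the class contrast
#'   (`ChannelGroup` or character vector).
#' @param effect Multiplicative band-power contrast delta >= 0; class-1
#'   power in the contrast band is `(1 + effect)` times class-0 power.
#' @param contrast_band Name of the band carrying the contrast (default
#'   `"theta"`).
#' @param band_power Named base band powers in uV^2 (defaults give a
#'   plausible resting-EEG profile with dominant low frequencies).
#' @param noise_exponent Spectral slope of the 1/f background (PSD
#'   proportional to `f^-noise_exponent`, default 1).
#' @param noise_power Total background noise power in uV^2 over 1 Hz to
#'   Nyquist (default 20).
#' @param subject_sd Log-normal sd of per-subject band-amplitude
#'   variability (default 0.15).
#' @param seed Master seed for the cohort.
#' @param montage The montage (default [standard_montage()]).
#' @return A `CohortSpec` object.
#' @export
cohort_spec <- function(n_per_class = 60L, sf = 128, duration_s = c(60, 120),
                        informative_channels = c("T7", "P3", "Pz"),
                        effect = 1, contrast_band = "theta",
                        band_power = c(delta = 40, theta = 30, alpha = 25,
                                       beta = 10),
                        noise_exponent = 1, noise_power = 20,
                        subject_sd = 0.15, seed = 1L,
                        montage = standard_montage()) {
  members <- if (inherits(informative_channels, "ChannelGroup"))
    informative_channels$members else as.character(informative_channels)
  stopifnot(n_per_class >= 1L, effect >= 0, sf > 0,
            length(duration_s) == 2L, duration_s[1] <= duration_s[2],
            all(members %in% montage$channels),
            contrast_band %in% names(eeg_bands()),
            all(names(band_power) %in% names(eeg_bands())))
  s <- list(n_per_class = as.integer(n_per_class), sf = sf,
            duration_s = duration_s, informative_channels = members,
            effect = effect, contrast_band = contrast_band,
            band_power = band_power, noise_exponent = noise_exponent,
            noise_power = noise_power, subject_sd = subject_sd,
            seed = as.integer(seed), montage = montage)
  class(s) <- "CohortSpec"
  s
}

# Band-limited Gaussian noise of length n with a target total power,
# built by shaping white Gaussian spectra in the frequency domain.  The
# expected periodogram equals the target PSD exactly, so Welch estimates
# of band power are unbiased for `power`.
shaped_noise <- function(n, sf, psd_fun) {
  nf <- n %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * sf / n
  # interior bins: E|X_k|^2 = psd * sf * n / 2 (one-sided convention),
  # split equally between the real and imaginary parts
  amp <- sqrt(pmax(psd_fun(freq), 0) * sf * n) / 2
  re <- rnorm(nf) * amp
  im <- rnorm(nf) * amp
  im[1] <- 0; re[1] <- re[1] * 2             # purely real bins, no doubling
  if (n %% 2L == 0L) { im[nf] <- 0; re[nf] <- re[nf] * 2 }
  spec <- complex(real = re, imaginary = im)
  mirror_from <- nf - 1L + n %% 2L
  full <- c(spec, Conj(spec[seq.int(mirror_from, 2L)]))
  Re(fft(full, inverse = TRUE)) / n
}

#' Generate one synthetic subject
#'
#' Deterministic given `(spec, class_label, subject_seed)`.  Each channel
#' is an independent draw of band-limited oscillations plus 1/f noise;
#' per-subject band amplitudes vary log-normally around the spec's base
#' powers, and class-1 subjects get the contrast-band power multiplied by
#' `(1 + effect)` on the informative channels.
#'
#' @param spec A [cohort_spec()].
#' @param class_label 0 or 1.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Optional id (default derived from seed and class).
#' @return A [recording()].
#' @export
generate_subject <- function(spec, class_label, subject_seed,
                             subject_id = sprintf("c%d_s%d", class_label,
                                                  subject_seed)) {
  stopifnot(inherits(spec, "CohortSpec"))
  bands <- eeg_bands()
  with_seed(subject_seed, {
    dur <- runif(1, spec$duration_s[1], spec$duration_s[2])
    n <- as.integer(round(dur * spec$sf))
    chans <- spec$montage$channels
    X <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
    # normalise the 1/f shape so its integral from 1 Hz to Nyquist is
    # noise_power
    f_hi <- spec$sf / 2
    slope <- spec$noise_exponent
    norm_const <- if (abs(slope - 1) < 1e-9) log(f_hi)
      else (f_hi^(1 - slope) - 1) / (1 - slope)
    for (ci in seq_along(chans)) {
      mult <- exp(rnorm(length(spec$band_power), 0, spec$subject_sd))
      names(mult) <- names(spec$band_power)
      x <- shaped_noise(n, spec$sf, function(f) {
        p <- (spec$noise_power / norm_const) * pmax(f, 0.5)^(-slope)
        p[f < 0.5] <- 0
        p
      })
      for (b in names(spec$band_power)) {
        pw <- spec$band_power[[b]] * mult[[b]]
        if (class_label == 1L && b == spec$contrast_band &&
            chans[ci] %in% spec$informative_channels)
          pw <- pw * (1 + spec$effect)
        edges <- bands[[b]]
        dens <- pw / (edges[2] - edges[1])
        x <- x + shaped_noise(n, spec$sf, function(f) {
          ifelse(f >= edges[1] & f < edges[2], dens, 0)
        })
      }
      X[ci, ] <- x
    }
    recording(subject_id, class_label, spec$sf, X)
  })
}

#' Generate a full synthetic cohort
#'
#' `n_per_class` recordings per class with unique subject ids; all
#' randomness (durations, oscillation draws, subject variability) flows
#' from `spec$seed`, so identical specs give bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return List of [recording()]s, class 0 first.
#' @examples
#' spec <- cohort_spec(n_per_class = 2, duration_s = c(10, 12), seed = 7)
#' cohort <- generate_cohort(spec)
#' length(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  recs <- vector("list", 2L * spec$n_per_class)
  i <- 0L
  for (cl in c(0L, 1L)) {
    for (s in seq_len(spec$n_per_class)) {
      i <- i + 1L
      recs[[i]] <- generate_subject(
        spec, cl, derive_seed(spec$seed, cl, s),
        subject_id = sprintf("%s%02d", c("td", "case")[cl + 1L], s))
    }
  }
  recs
}
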