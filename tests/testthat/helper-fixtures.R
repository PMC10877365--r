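# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so the whole suite runs on one CPU in minutes.

# A white-noise recording on a subset of montage channels.
noise_recording <- function(subject_id = "s1", label = 0L, sf = 128,
                            n_samples = 512L,
                            channels = c("Fp1", "Cz", "O2"), sd = 20,
                            seed = 1L) {
  set.seed(seed)
  recording(subject_id, label, sf,
            matrix(rnorm(length(channels) * n_samples, sd = sd),
                   length(channels), n_samples,
                   dimnames = list(channels, NULL)))
}

# A windowed two-class set that is linearly separable by a mean offset:
# class-1 windows sit `offset` standard deviations above class 0.
separable_window_set <- function(n_subj_per_class = 4L, sf = 16,
                                 n_seconds = 20L, offset = 1.5,
                                 channels = c("T7", "T8"), seed = 1L,
                                 id_prefix = "") {
  set.seed(seed)
  recs <- list()
  for (cl in 0:1) {
    for (s in seq_len(n_subj_per_class)) {
      x <- matrix(rnorm(length(channels) * sf * n_seconds), length(channels),
                  sf * n_seconds,
                  dimnames = list(channels, NULL)) + cl * offset
      recs[[length(recs) + 1L]] <-
        recording(sprintf("%sc%d_%d", id_prefix, cl, s), cl, sf, x)
    }
  }
  segment_windows(recs)
}

# A small fully preprocessed synthetic cohort as a window set, with the
# contrast planted on `informative`.
tiny_cohort_ws <- function(n_per_class = 6L, sf = 32, duration = c(16, 20),
                           effect = 2, informative = c("T7", "T8"),
                           seed = 5L) {
  spec <- cohort_spec(n_per_class = n_per_class, sf = sf,
                      duration_s = duration, effect = effect,
                      informative_channels = informative, seed = seed)
  fs <- filter_spec(hp_hz = 0.5, lp_hz = min(12, sf / 2 - 2),
                    notch_hz = NULL)
  segment_windows(lapply(generate_cohort(spec), function(r)
    zscore_normalize(apply_filter_chain(r, fs))))
}

# Subject ids of a cohort window set split by class, class 0 first.
subjects_by_class <- function(ws) {
  subj <- unique(data.frame(id = ws$subject_ids, label = ws$labels))
  list(subj$id[subj$label == 0L], subj$id[subj$label == 1L])
}

# Wrap a scorer with an invocation counter (used to verify the stepwise
# evaluation-count arithmetic against actual calls).
counting_scorer <- function(scorer) {
  n_calls <- 0L
  f <- function(subset) {
    n_calls <<- n_calls + 1L
    scorer(subset)
  }
  attr(f, "count") <- function() n_calls
  f
}
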