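#' Power-set and stepwise subset counts
#'
#' `powerset_size(p)` is the number of subsets of a p-channel set, `2^p` —
#' the count that makes exhaustive subset search infeasible (524288 for 19
#' channels).  `stepwise_eval_count(p)` is the number of candidate models a
#' greedy stepwise search evaluates instead, `p(p+1)/2` (190 for 19
#' channels): forward steps k = 0..p-1 evaluate p-k one-channel
#' extensions; backward evaluates the full set once and then p, p-1, ..., 2
#' one-channel removals.
#'
#' @param p Number of channels.
#' @return A count (double, since `2^p` overflows integers quickly).
#' @examples
#' powerset_size(19)        # 524288
#' stepwise_eval_count(19)  # 190
#' @export
powerset_size <- function(p) {
  stopifnot(p >= 0)
  2^p
}

#' @rdname powerset_size
#' @export
stepwise_eval_count <- function(p) {
  stopifnot(p >= 1)
  p * (p + 1) / 2
}

new_trace <- function(method, steps, chain, best_per_cardinality, total) {
  t <- list(method = method, steps = steps, chain = chain,
            best_per_cardinality = best_per_cardinality,
            total_evaluations = total)
  class(t) <- "SelectionTrace"
  t
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat(sprintf("SelectionTrace (%s): %d evaluations over %d cardinalities\n",
              x$method, x$total_evaluations, nrow(x$best_per_cardinality)))
  best <- x$best_per_cardinality[which.max(x$best_per_cardinality$score), ]
  cat(sprintf("  best: %s (%d ch, score %.4f)\n", best$subset, best$size,
              best$score))
  invisible(x)
}

# Tie rule shared by both directions: among equal scores prefer the
# candidate whose added/removed channel comes first in canonical order.
# `channels` is already in canonical order, and candidates are generated
# in that order, so which.max's first-hit behaviour implements the rule.
step_best <- function(scores) which.max(scores)

#' Forward stepwise channel selection
#'
#' Greedy wrapper search: starting from the empty set, each step evaluates
#' every one-channel extension of the current subset with `scorer` and
#' keeps the highest-scoring one, until the full set is reached (or
#' `max_steps` subsets have been chosen).  For p channels the full search
#' makes exactly `p(p+1)/2` scorer calls.  Ties are broken toward the
#' candidate whose added channel comes first in canonical montage order.
#'
#' @param channels Character vector of candidate channels (canonical
#'   order).
#' @param scorer `function(channel_subset) -> numeric score` (higher is
#'   better); typically a classifier's mean f1, see
#'   [make_surrogate_scorer()] and [make_model_scorer()].
#' @param max_steps Stop after this many chosen subsets (default all p).
#' @return A `SelectionTrace`: per-step candidate log, the nested chain of
#'   chosen subsets, best subset per cardinality, and the evaluation
#'   count.
#' @export
forward_select <- function(channels, scorer, max_steps = length(channels)) {
  p <- length(channels)
  stopifnot(p >= 1L, max_steps >= 1L)
  current <- character(0)
  steps <- list(); chain <- list(); total <- 0L
  best_rows <- list()
  for (k in seq_len(min(max_steps, p))) {
    remaining <- setdiff(channels, current)
    cand <- lapply(remaining, function(ch) c(current, ch))
    scores <- vapply(cand, function(s) {
      sc <- scorer(s)
      if (!is.finite(sc)) stop("scorer failed on subset {",
                               paste(s, collapse = ", "), "}")
      sc
    }, numeric(1))
    total <- total + length(cand)
    pick <- step_best(scores)
    current <- cand[[pick]]
    steps[[k]] <- data.frame(step = k, candidate = I(cand),
                             added = remaining, score = scores,
                             chosen = seq_along(cand) == pick)
    chain[[k]] <- current
    best_rows[[k]] <- data.frame(
      size = k, subset = paste(current, collapse = "-"),
      score = scores[pick])
  }
  new_trace("forward", steps, chain, do.call(rbind, best_rows), total)
}

#' Backward stepwise channel selection
#'
#' Mirror image of [forward_select()]: the full set is evaluated once,
#' then each step evaluates every one-channel removal from the current
#' subset and keeps the highest-scoring remainder, down to a single
#' channel.  Including the initial full-set evaluation this is again
#' exactly `p(p+1)/2` scorer calls.  Ties prefer removing the channel that
#' comes first in canonical order.
#'
#' @inheritParams forward_select
#' @param min_size Stop once the subset reaches this size (default 1).
#' @return A `SelectionTrace` with `method = "backward"`.
#' @export
backward_select <- function(channels, scorer, min_size = 1L) {
  p <- length(channels)
  stopifnot(p >= 1L, min_size >= 1L)
  full_score <- scorer(channels)
  if (!is.finite(full_score)) stop("scorer failed on the full set")
  current <- channels
  total <- 1L
  steps <- list(data.frame(step = 0L, candidate = I(list(channels)),
                           removed = NA_character_, score = full_score,
                           chosen = TRUE))
  chain <- list(current)
  best_rows <- list(data.frame(size = p,
                               subset = paste(channels, collapse = "-"),
                               score = full_score))
  k <- 0L
  while (length(current) > min_size) {
    k <- k + 1L
    cand <- lapply(current, function(ch) setdiff(current, ch))
    scores <- vapply(cand, function(s) {
      sc <- scorer(s)
      if (!is.finite(sc)) stop("scorer failed on subset {",
                               paste(s, collapse = ", "), "}")
      sc
    }, numeric(1))
    total <- total + length(cand)
    pick <- step_best(scores)
    steps[[k + 1L]] <- data.frame(step = k, candidate = I(cand),
                                  removed = current,
                                  score = scores,
                                  chosen = seq_along(cand) == pick)
    current <- cand[[pick]]
    chain[[k + 1L]] <- current
    best_rows[[k + 1L]] <- data.frame(
      size = length(current), subset = paste(current, collapse = "-"),
      score = scores[pick])
  }
  new_trace("backward", steps, chain, do.call(rbind, best_rows), total)
}

#' Serialise / restore a selection trace
#'
#' One record per evaluated subset: step, subset bitmask over the
#' canonical channel order, and score — a compact structured-text form of
#' the full search history.
#'
#' @param trace A `SelectionTrace`.
#' @param path File path.
#' @param channels Canonical channel order the bitmask is defined over.
#' @return `write_selection_trace` returns `path` invisibly;
#'   `read_selection_trace` a data frame of the records.
#' @export
write_selection_trace <- function(trace, path,
                                  channels = standard_montage()$channels) {
  recs <- do.call(rbind, lapply(trace$steps, function(st) {
    data.frame(step = st$step,
               mask = vapply(st$candidate, function(s)
                 paste(as.integer(channels %in% s), collapse = ""),
                 character(1)),
               score = st$score, chosen = st$chosen)
  }))
  recs <- cbind(method = trace$method, recs)
  write.table(recs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection_trace
#' @export
read_selection_trace <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "integer", "character", "numeric",
                            "logical"))
}

#' Fast surrogate subset scorer from band-power features
#'
#' A desk-scale stand-in for the full classifier wrapper: per-window log
#' band powers (delta/theta/alpha/beta per channel) are fed to a ridge
#' logistic regression (glmnet, alpha = 0, fixed lambda), and a subset's
#' score is the mean f1 over a seeded subject-level k-fold
#' cross-validation (every subject is held out exactly once, so the score
#' is a low-variance cross-subject generalisation estimate).  It preserves
#' the wrapper structure — subset in, cross-subject f1 out — at a tiny
#' fraction of the network's cost, and is intended for selection-recovery
#' studies; it is a surrogate, not the classifier the full protocol uses.
#'
#' @param ws `WindowSet` over all candidate channels.
#' @param cv_folds Subject-level cross-validation folds (default 4).
#' @param lambda Ridge penalty (default 0.01).
#' @param seed Seed for the subject fold assignment.
#' @param bands Band definition, default [eeg_bands()].
#' @return `function(channel_subset) -> f1` for use with
#'   [forward_select()] / [backward_select()].
#' @export
make_surrogate_scorer <- function(ws, cv_folds = 4L, lambda = 0.01,
                                  seed = 1L, bands = eeg_bands()) {
  stopifnot(inherits(ws, "WindowSet"), cv_folds >= 2L)
  feats <- bandpower_features(ws, bands)
  y <- ws$labels
  subj <- unique(data.frame(id = ws$subject_ids, label = ws$labels))
  fold_ids <- with_seed(seed, {
    per_class <- lapply(split(subj$id, subj$label), function(ids)
      split(sample(ids), rep(seq_len(cv_folds), length.out = length(ids))))
    lapply(seq_len(cv_folds), function(i)
      unlist(lapply(per_class, `[[`, i), use.names = FALSE))
  })
  test_masks <- lapply(fold_ids, function(ids) ws$subject_ids %in% ids)
  chan_of_col <- rep(ws$channel_names, times = length(bands))

  function(subset_channels) {
    cols <- which(chan_of_col %in% subset_channels)
    f1s <- vapply(test_masks, function(is_test) {
      Xtr <- feats[!is_test, cols, drop = FALSE]
      Xte <- feats[is_test, cols, drop = FALSE]
      if (ncol(Xtr) < 2L) {     # glmnet needs >= 2 predictors
        Xtr <- cbind(Xtr, Xtr[, 1]^2); Xte <- cbind(Xte, Xte[, 1]^2)
      }
      fit <- glmnet::glmnet(Xtr, y[!is_test], family = "binomial",
                            alpha = 0, lambda = lambda, standardize = TRUE)
      pr <- as.numeric(predict(fit, Xte, type = "response"))
      confusion_metrics(y[is_test], as.integer(pr >= 0.5))$f1
    }, numeric(1))
    mean(f1s)
  }
}

#' Full-protocol subset scorer
#'
#' Wraps [evaluate_subset()] into the `function(subset) -> mean f1`
#' signature the stepwise searches expect: every candidate subset is
#' scored by training the convolutional classifier over `repeats` x k
#' runs.  This is the scorer the complete wrapper-selection protocol uses;
#' it is expensive (each call trains `repeats * k` networks).
#'
#' @param ws Full `WindowSet`.
#' @param plan A [make_folds()] plan.
#' @param repeats Repeats per fold (default 3).
#' @param config A [mhcnet_config()].
#' @return `function(channel_subset) -> mean f1`.
#' @export
make_model_scorer <- function(ws, plan, repeats = 3L,
                              config = mhcnet_config(sf = ws$sf)) {
  function(subset_channels) {
    evaluate_subset(ws, subset_channels, plan, repeats, config)$mean$f1
  }
}

#' Recovery rate of planted informative channels
#'
#' Instrumentation for selection-recovery studies on synthetic cohorts:
#' the fraction of seeded runs whose first `top_m` forward picks (or last
#' `top_m` backward survivors) all lie inside the planted informative set.
#'
#' @param traces List of `SelectionTrace`s from repeated seeded runs.
#' @param informative [channel_group()] or character vector of planted
#'   channels.
#' @param top_m How many leading picks / final survivors to check
#'   (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
recovery_rate <- function(traces, informative, top_m = 1L) {
  if (length(traces) == 0L) stop("no traces supplied")
  members <- if (inherits(informative, "ChannelGroup")) informative$members
             else as.character(informative)
  hits <- vapply(traces, function(tr) {
    picked <- if (tr$method == "forward") {
      if (length(tr$chain) < top_m) return(NA)
      tr$chain[[top_m]]
    } else {
      sizes <- vapply(tr$chain, length, integer(1))
      i <- which(sizes == top_m)
      if (!length(i)) return(NA)
      tr$chain[[i[1]]]
    }
    all(picked %in% members)
  }, logical(1))
  if (anyNA(hits)) stop("trace too short for top_m = ", top_m)
  mean(hits)
}

#' Seeded selection-recovery study on synthetic cohorts
#'
#' The package's parameter-recovery instrument: across `n_seeds`
#' independently generated synthetic cohorts with a band-power contrast
#' planted on known channels, run the full pipeline (filter chain,
#' z-score, 2-s windows, surrogate-scored forward selection) and measure
#' how often the first `top_m` picks land inside the planted set.  With a
#' strong contrast the rate should be high; with `effect = 0` it should
#' match the chance level `|informative| / n_channels` (for `top_m = 1`).
#'
#' @param n_seeds Number of seeded replicate cohorts (default 20).
#' @param effect Planted band-power contrast delta.
#' @param informative_channels Channels carrying the contrast.
#' @param n_per_class Subjects per class per cohort (default 12).
#' @param duration_s Per-subject duration range in seconds (default 60).
#' @param sf Sampling rate (default 128).
#' @param top_m Leading picks that must lie in the planted set (default 1).
#' @param seed Master seed; per-cohort seeds derive from it.
#' @param filter A [filter_spec()] for the preprocessing stage.
#' @param cv_folds,lambda Passed to [make_surrogate_scorer()].
#' @return List with `rate` (the recovery fraction), `picks` (first-pick
#'   channel per seed) and `traces` (the truncated `SelectionTrace`s).
#' @export
recovery_study <- function(n_seeds = 20L, effect = 1,
                           informative_channels = c("T7", "P3", "Pz"),
                           n_per_class = 12L, duration_s = c(60, 60),
                           sf = 128, top_m = 1L, seed = 1L,
                           filter = filter_spec(), cv_folds = 4L,
                           lambda = 0.01) {
  traces <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cseed <- derive_seed(seed, i)
    spec <- cohort_spec(n_per_class = n_per_class, sf = sf,
                        duration_s = duration_s,
                        informative_channels = informative_channels,
                        effect = effect, seed = cseed)
    cohort <- lapply(generate_cohort(spec), function(r)
      zscore_normalize(apply_filter_chain(r, filter)))
    ws <- segment_windows(cohort)
    scorer <- make_surrogate_scorer(ws, cv_folds = cv_folds,
                                    lambda = lambda, seed = cseed)
    traces[[i]] <- forward_select(ws$channel_names, scorer,
                                  max_steps = top_m)
  }
  list(rate = recovery_rate(traces, informative_channels, top_m),
       picks = vapply(traces, function(tr)
         paste(tr$chain[[min(top_m, length(tr$chain))]], collapse = "-"),
         character(1)),
       traces = traces)
}
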