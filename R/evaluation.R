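#' Seeded cross-subject fold plan
#'
#' Builds the subject-level partition used for k-fold cross-subject
#' validation: per class, a seeded permutation of the subjects is cut into
#' k test blocks (sizes differing by at most one when the class size is
#' not divisible by k; earlier folds take the remainder).  Within each
#' fold, `n_val_per_class` validation subjects are drawn — seeded per fold
#' — from that fold's non-test subjects, and the rest train.  With 60
#' subjects per class and k = 10 this yields per fold 6 test, 54 train
#' before the validation carve-out, and 49 effective-train subjects per
#' class.  Identical seeds give identical plans.
#'
#' @param subjects_by_class Named list `list("0" = ids, "1" = ids)` (or a
#'   list of two character vectors, class 0 first).
#' @param k Number of folds (default 10).
#' @param n_val_per_class Validation subjects per class per fold
#'   (default 5).
#' @param seed Integer seed.
#' @return A `FoldPlan`: list with `k`, `seed` and `folds`, each fold a
#'   list of per-class `test`, `val`, `train` id vectors.
#' @export
make_folds <- function(subjects_by_class, k = 10L, n_val_per_class = 5L,
                       seed = 1L) {
  stopifnot(length(subjects_by_class) == 2L, k >= 2L)
  subjects_by_class <- lapply(subjects_by_class, as.character)
  for (cl in 1:2) {
    n <- length(subjects_by_class[[cl]])
    if (n < k) stop("need at least k subjects per class (class ", cl - 1L,
                    " has ", n, ")")
    if (anyDuplicated(subjects_by_class[[cl]]))
      stop("duplicate subject ids in class ", cl - 1L)
    max_test <- n %/% k + as.integer(n %% k > 0L)
    if (n - max_test - n_val_per_class < 1L)
      stop("n_val_per_class too large for the class sizes")
  }
  perms <- with_seed(seed, lapply(subjects_by_class, sample))
  blocks <- lapply(perms, function(ids) {
    n <- length(ids)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(ids, rep(seq_len(k), sizes))
  })
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- list()
    for (cl in 1:2) {
      test <- blocks[[cl]][[f]]
      rest <- setdiff(perms[[cl]], test)
      val <- with_seed(derive_seed(seed, f, cl),
                       sample(rest, n_val_per_class))
      fold[[c("class0", "class1")[cl]]] <-
        list(test = test, val = val, train = setdiff(rest, val))
    }
    folds[[f]] <- fold
  }
  plan <- list(k = as.integer(k), seed = as.integer(seed),
               n_val_per_class = as.integer(n_val_per_class), folds = folds)
  class(plan) <- "FoldPlan"
  plan
}

#' @export
print.FoldPlan <- function(x, ...) {
  f1 <- x$folds[[1]]
  cat(sprintf(
    "FoldPlan: %d folds (seed %d); fold 1 sizes per class: %d test / %d val / %d train\n",
    x$k, x$seed, length(f1$class0$test), length(f1$class0$val),
    length(f1$class0$train)))
  invisible(x)
}

fold_subjects <- function(fold, part) {
  c(fold$class0[[part]], fold$class1[[part]])
}

ws_subset_subjects <- function(ws, ids) {
  keep <- ws$subject_ids %in% ids
  ws$windows <- ws$windows[keep, , , drop = FALSE]
  ws$subject_ids <- ws$subject_ids[keep]
  ws$labels <- ws$labels[keep]
  ws
}

#' Classification metrics from labels
#'
#' Precision, recall, f1 and accuracy of binary predictions, with class 1
#' as the positive class.  Zero-denominator conventions: precision is 0
#' when nothing is predicted positive, recall is 0 when no positives
#' exist, and f1 is 0 when `2tp + fp + fn = 0`.
#'
#' @param true_labels,pred_labels Equal-length binary vectors.
#' @return A `MetricSet`: named list `f1`, `accuracy`, `precision`,
#'   `recall`.
#' @examples
#' confusion_metrics(c(1,1,0,0,1,0), c(1,1,1,0,0,0))  # f1 = 2/3
#' @export
confusion_metrics <- function(true_labels, pred_labels) {
  if (length(true_labels) == 0L) stop("empty input")
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  y <- as.integer(true_labels); p <- as.integer(pred_labels)
  if (!all(c(y, p) %in% c(0L, 1L))) stop("labels must be binary")
  tp <- sum(y == 1L & p == 1L); fp <- sum(y == 0L & p == 1L)
  fn <- sum(y == 1L & p == 0L); tn <- sum(y == 0L & p == 0L)
  m <- list(
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    accuracy = (tp + tn) / length(y),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
  class(m) <- "MetricSet"
  m
}

#' Student-t confidence interval for a mean
#'
#' `mean(x) +/- t_{1-alpha/2, n-1} * sd(x) / sqrt(n)`.
#'
#' @param scores Numeric vector, length >= 2.
#' @param alpha Significance level (default 0.05 for a 95 % interval).
#' @return Named numeric `c(low, high)`.
#' @export
confidence_interval <- function(scores, alpha = 0.05) {
  n <- length(scores)
  if (n < 2L) stop("need at least two scores")
  m <- mean(scores)
  half <- qt(1 - alpha / 2, n - 1L) * sd(scores) / sqrt(n)
  c(low = m - half, high = m + half)
}

#' One-way ANOVA across score groups
#'
#' Fixed-effects one-way analysis of variance of (typically f1) scores
#' across channel subsets, as used to judge whether subsets differ
#' significantly.  Degenerate input — every score identical — returns
#' `F = 0, p = 1`.
#'
#' @param score_groups Named list of numeric vectors, each length >= 2.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_across_subsets <- function(score_groups) {
  if (length(score_groups) < 2L) stop("need at least two groups")
  if (any(vapply(score_groups, length, integer(1)) < 2L))
    stop("every group needs at least two scores")
  y <- unlist(score_groups, use.names = FALSE)
  g <- factor(rep(seq_along(score_groups),
                  vapply(score_groups, length, integer(1))))
  if (var(y) == 0)
    return(list(F = 0, p = 1, df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g)))
  fit <- summary(aov(y ~ g))[[1]]
  list(F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
       df_between = fit[["Df"]][1], df_within = fit[["Df"]][2])
}

#' Train and evaluate one channel subset across repeats and folds
#'
#' The evaluation protocol behind every reported score: for each of
#' `repeats` repetitions and each fold of the plan, a fresh classifier is
#' built on the group's channels, trained on the fold's training subjects'
#' windows with early stopping on the validation subjects' windows, and
#' scored on the held-out test subjects' windows.  With 3 repeats and 10
#' folds this gives 30 per-run metric sets, summarised by their mean and a
#' Student-t confidence interval on f1.  Per-run seeds derive
#' deterministically from `(config$seed, repeat, fold)`, so any single run
#' — and the whole summary — is reproducible.
#'
#' @param ws Full `WindowSet` (all channels, all subjects).
#' @param group [channel_group()] (or channel name vector) to evaluate.
#' @param plan A [make_folds()] plan whose subjects appear in `ws`.
#' @param repeats Repetitions per fold (default 3).
#' @param config A [mhcnet_config()]; its `seed` is the master seed.
#' @param scorer Optional custom scorer `function(train_ws, val_ws,
#'   test_ws, seed) -> MetricSet`, replacing the network classifier (used
#'   by the fast surrogate path).
#' @return An `EvalSummary`: data frame `runs` (repeat, fold, f1,
#'   accuracy, precision, recall), list `mean`, `ci` on f1, `alpha`.
#' @export
evaluate_subset <- function(ws, group, plan, repeats = 3L,
                            config = mhcnet_config(sf = ws$sf),
                            scorer = NULL) {
  stopifnot(inherits(ws, "WindowSet"), inherits(plan, "FoldPlan"))
  wsg <- select_channels(ws, group)
  plan_ids <- unique(unlist(lapply(plan$folds, fold_subjects, "test")))
  if (!all(plan_ids %in% ws$subject_ids))
    stop("fold plan contains subjects absent from the window set")

  rows <- vector("list", repeats * plan$k)
  i <- 0L
  for (r in seq_len(repeats)) {
    for (f in seq_len(plan$k)) {
      fold <- plan$folds[[f]]
      tr <- ws_subset_subjects(wsg, fold_subjects(fold, "train"))
      va <- ws_subset_subjects(wsg, fold_subjects(fold, "val"))
      te <- ws_subset_subjects(wsg, fold_subjects(fold, "test"))
      check_partition(tr, va, te)
      if (length(unique(te$labels)) < 2L)
        stop("protocol violation: fold ", f,
             " test windows contain a single class")
      run_seed <- derive_seed(config$seed, r, f)
      if (is.null(scorer)) {
        run_cfg <- config; run_cfg$seed <- run_seed
        mdl <- build_model(dim(tr$windows)[2], dim(tr$windows)[3], run_cfg)
        mdl <- train_model(mdl, tr, va, run_cfg)
        met <- confusion_metrics(te$labels, predict_labels(mdl, te))
      } else {
        met <- scorer(tr, va, te, run_seed)
      }
      i <- i + 1L
      rows[[i]] <- data.frame(rep = r, fold = f, f1 = met$f1,
                              accuracy = met$accuracy,
                              precision = met$precision,
                              recall = met$recall)
    }
  }
  runs <- do.call(rbind, rows)
  summ <- list(
    group = if (inherits(group, "ChannelGroup")) group$name
            else paste(group, collapse = "-"),
    runs = runs,
    mean = lapply(runs[c("f1", "accuracy", "precision", "recall")], mean),
    ci = confidence_interval(runs$f1),
    alpha = 0.05)
  class(summ) <- "EvalSummary"
  summ
}

check_partition <- function(tr, va, te) {
  a <- unique(tr$subject_ids); b <- unique(va$subject_ids)
  c_ <- unique(te$subject_ids)
  if (length(intersect(a, b)) || length(intersect(a, c_)) ||
      length(intersect(b, c_)))
    stop("protocol violation: subject appears in more than one partition")
  invisible(TRUE)
}

#' @export
print.EvalSummary <- function(x, ...) {
  cat(sprintf(
    "EvalSummary [%s]: %d runs; mean f1 %.4f (95%% CI %.4f-%.4f), acc %.4f, prec %.4f, rec %.4f\n",
    x$group, nrow(x$runs), x$mean$f1, x$ci["low"], x$ci["high"],
    x$mean$accuracy, x$mean$precision, x$mean$recall))
  invisible(x)
}

#' Tabulate evaluation summaries
#'
#' Collects a list of `EvalSummary` objects into the subset-by-metrics
#' layout used for reporting (one row per subset: f1, accuracy,
#' precision, recall), sorted by descending f1.
#'
#' @param summaries List of [evaluate_subset()] results.
#' @return A data frame.
#' @export
summary_table <- function(summaries) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(subset = s$group, f1 = s$mean$f1, accuracy = s$mean$accuracy,
               precision = s$mean$precision, recall = s$mean$recall)))
  df[order(-df$f1), , drop = FALSE]
}
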