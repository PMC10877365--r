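test_that("fold plans partition subjects as the protocol requires", {
  ids <- list(sprintf("td%02d", 1:60), sprintf("case%02d", 1:60))
  plan <- make_folds(ids, k = 10, n_val_per_class = 5, seed = 42)
  expect_equal(plan$k, 10L)
  for (fold in plan$folds) {
    for (cl in c("class0", "class1")) {
      expect_length(fold[[cl]]$test, 6L)
      expect_length(fold[[cl]]$val, 5L)
      expect_length(fold[[cl]]$train, 49L)
      # train + val = the 54 non-test subjects
      expect_length(union(fold[[cl]]$train, fold[[cl]]$val), 54L)
      expect_length(Reduce(intersect, fold[[cl]]), 0L)
    }
  }
  # every subject appears in exactly one fold's test set
  all_test <- unlist(lapply(plan$folds, function(f)
    c(f$class0$test, f$class1$test)))
  expect_setequal(all_test, unlist(ids))
  expect_equal(anyDuplicated(all_test), 0L)
  # determinism and seed sensitivity
  expect_identical(plan, make_folds(ids, k = 10, n_val_per_class = 5,
                                    seed = 42))
  expect_false(identical(plan,
                         make_folds(ids, k = 10, n_val_per_class = 5,
                                    seed = 43)))
})

test_that("fold construction handles remainders and rejects bad sizes", {
  ids <- list(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12))
  plan <- make_folds(ids, k = 10, n_val_per_class = 2, seed = 1)
  sizes <- vapply(plan$folds, function(f) length(f$class0$test), integer(1))
  expect_equal(sort(sizes, decreasing = TRUE), c(2L, 2L, rep(1L, 8)))
  expect_setequal(unlist(lapply(plan$folds, function(f) f$class0$test)),
                  ids[[1]])
  expect_error(make_folds(list(c("a", "b"), c("c", "d")), k = 10),
               "at least k subjects")
  expect_error(make_folds(ids, k = 10, n_val_per_class = 10),
               "n_val_per_class")
})

test_that("confusion metrics follow the standard formulas", {
  perfect <- confusion_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unlist(perfect[c("f1", "accuracy", "precision", "recall")]),
               c(f1 = 1, accuracy = 1, precision = 1, recall = 1))
  # tp=2 fp=1 fn=1 tn=2
  m <- confusion_metrics(c(1, 1, 0, 0, 1, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  # degenerate all-positive predictor on balanced labels
  deg <- confusion_metrics(c(0, 0, 1, 1), c(1, 1, 1, 1))
  expect_equal(deg$recall, 1)
  expect_equal(deg$accuracy, 0.5)
  # zero-denominator conventions return 0
  expect_equal(confusion_metrics(c(0, 0), c(0, 0))$precision, 0)
  expect_equal(confusion_metrics(c(0, 0), c(0, 0))$f1, 0)
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
  expect_error(confusion_metrics(c(0, 1), c(1)), "length")
  expect_error(confusion_metrics(c(0, 2), c(1, 0)), "binary")
})

test_that("confidence interval matches the Student-t closed form", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  ci <- confidence_interval(x)
  half <- qt(0.975, 3) * sd(x) / 2
  expect_equal(unname(ci), c(mean(x) - half, mean(x) + half))
  # constant scores: zero width at the constant
  expect_equal(unname(confidence_interval(rep(0.8, 10))), c(0.8, 0.8))
  # {0,1}: symmetric about 0.5
  ci01 <- confidence_interval(c(0, 1))
  expect_equal(mean(ci01), 0.5)
  expect_error(confidence_interval(0.5), "two scores")
})

test_that("t confidence intervals achieve nominal coverage", {
  # Monte-Carlo oracle: ~95 % of intervals over N(0,1) samples cover 0
  set.seed(123)
  n <- 30L
  hits <- vapply(1:2000, function(i) {
    x <- rnorm(n)
    ci <- confidence_interval(x)
    ci["low"] <= 0 && 0 <= ci["high"]
  }, logical(1))
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("one-way ANOVA matches its oracles", {
  # identical groups: F = 0, p = 1
  same <- anova_across_subsets(list(a = rep(0.5, 5), b = rep(0.5, 5)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(77)
  g1 <- rnorm(12, 0.8, 0.05); g2 <- rnorm(12, 0.82, 0.05)
  res <- anova_across_subsets(list(g1 = g1, g2 = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # one group shifted by 10 sd: overwhelming evidence
  far <- anova_across_subsets(list(a = rnorm(10, 0, 1), b = rnorm(10, 10, 1),
                                   c = rnorm(10, 0, 1)))
  expect_lt(far$p, 1e-6)
  expect_error(anova_across_subsets(list(a = 1:3)), "two groups")
  expect_error(anova_across_subsets(list(a = 1:3, b = 2)), "at least two")
})

test_that("evaluate_subset runs the full repeats-by-folds protocol", {
  ws <- tiny_cohort_ws(n_per_class = 4L, seed = 19L)
  plan <- make_folds(subjects_by_class(ws), k = 2, n_val_per_class = 1,
                     seed = 9)
  cfg <- mhcnet_config(sf = 32, scl_filters = 2L, max_epochs = 2L,
                       patience = 2L, batch_size = 64L, seed = 23L)
  es <- evaluate_subset(ws, c("T7", "T8"), plan, repeats = 2, config = cfg)
  expect_equal(nrow(es$runs), 4L)              # repeats x k
  expect_setequal(es$runs$fold, 1:2)
  for (col in c("f1", "accuracy", "precision", "recall")) {
    expect_true(all(es$runs[[col]] >= 0 & es$runs[[col]] <= 1))
    expect_equal(es$mean[[col]], mean(es$runs[[col]]))
  }
  expect_true(es$ci["low"] <= es$mean$f1 && es$mean$f1 <= es$ci["high"])
  # determinism of the whole summary under the same master seed
  es2 <- evaluate_subset(ws, c("T7", "T8"), plan, repeats = 2, config = cfg)
  expect_identical(es, es2)
  # unknown subjects in the plan are refused
  bad_plan <- make_folds(list(c("x1", "x2"), c("y1", "y2")), k = 2,
                         n_val_per_class = 0)
  expect_error(evaluate_subset(ws, c("T7"), bad_plan, 1, cfg), "absent")
})

test_that("summary tables collect one row per subset sorted by f1", {
  ws <- tiny_cohort_ws(n_per_class = 4L, seed = 19L)
  plan <- make_folds(subjects_by_class(ws), k = 2, n_val_per_class = 1,
                     seed = 9)
  fake_scorer <- function(tr, va, te, seed)
    confusion_metrics(te$labels, rep(1L, length(te$labels)))
  s1 <- evaluate_subset(ws, "T7", plan, repeats = 1, scorer = fake_scorer)
  s2 <- evaluate_subset(ws, "O1", plan, repeats = 1, scorer = fake_scorer)
  tab <- summary_table(list(s1, s2))
  expect_equal(nrow(tab), 2L)
  expect_true(all(diff(tab$f1) <= 0))
  expect_setequal(tab$subset, c("T7", "O1"))
})
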