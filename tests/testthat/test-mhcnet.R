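test_that("kernel schedule halves from sf/2 down to the minimum", {
  expect_equal(kernel_schedule(128), c(64L, 32L, 16L, 8L, 4L, 2L))
  expect_equal(kernel_schedule(8), c(4L, 2L))
  expect_equal(kernel_schedule(4), 2L)
  # truncation when sf/2 is not a power-of-two multiple of min_kernel
  expect_equal(kernel_schedule(24), c(12L, 6L, 3L))
  expect_error(kernel_schedule(3), "too low")
  # block count = log2(sf/2) - log2(min_kernel) + 1 for power-of-two sf
  for (sf in c(8, 16, 32, 64, 128, 256))
    expect_length(kernel_schedule(sf), log2(sf / 2) - log2(2) + 1)
})

test_that("parameter counts match direct weight enumeration", {
  # separable layer: depthwise C*K*D + pointwise C*D*F + F biases
  expect_equal(separable_conv_params(19, 64, 8), 19 * 64 + 19 * 8 + 8)
  expect_equal(separable_conv_params(4, 16, 8, d = 2),
               4 * 16 * 2 + 4 * 2 * 8 + 8)
  # fewer weights than the full convolution whenever 1/K + 1/F < 1
  for (ci in c(2, 7, 19)) for (k in c(4, 16, 64)) for (f in c(2, 8))
    expect_lt(separable_conv_params(ci, k, f), ci * k * f + f)

  cfg <- mhcnet_config(sf = 16, scl_filters = 3L, seed = 1L)
  S <- 32L; C <- 2L; F <- 3L; H <- 2L
  m <- build_model(C, S, cfg)
  per_block <- function(K)
    (C * K) + (C * F + F) +          # separable layer 1
    (F * K) + (F * F + F) +          # separable layer 2
    (S * F * H + H)                  # flattened softmax head
  expect_equal(m$parameter_count,
               sum(vapply(kernel_schedule(16), per_block, numeric(1))) +
                 H + 1)              # final sigmoid unit
})

test_that("model builds for one channel and rejects short windows", {
  cfg <- mhcnet_config(sf = 16, scl_filters = 2L)
  expect_s3_class(build_model(1L, 16L, cfg), "ModelHandle")
  expect_error(build_model(2L, 4L, cfg), "shorter than the largest kernel")
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- mhcnet_config(sf = 8, scl_filters = 3L, seed = 42L)
  m <- build_model(2L, 10L, cfg)
  set.seed(5)
  X <- array(rnorm(4 * 10 * 2), c(4, 10, 2))
  y <- c(0, 1, 1, 0)
  fw <- mhcnet:::mhc_forward(m$params, X, cfg, keep = TRUE)
  gr <- mhcnet:::mhc_backward(m$params, fw, y, cfg)
  fp <- mhcnet:::flatten_params(m$params)
  fg <- mhcnet:::flatten_params(gr)
  loss_at <- function(flat)
    mhcnet:::bce_loss(
      mhcnet:::mhc_forward(mhcnet:::unflatten_into(m$params, flat),
                           X, cfg)$prob, y)
  eps <- 1e-6
  set.seed(9)
  for (i in seq_along(fp)) {
    arr <- as.array(fp[[i]])
    for (j in sample(length(arr), min(4L, length(arr)))) {
      f2 <- fp
      a <- arr; a[j] <- arr[j] + eps; f2[[i]] <- a
      up <- loss_at(f2)
      a[j] <- arr[j] - eps; f2[[i]] <- a
      dn <- loss_at(f2)
      expect_equal(as.array(fg[[i]])[j], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("predictions are probabilities, order-invariant, and threshold as documented", {
  cfg <- mhcnet_config(sf = 16, scl_filters = 2L, seed = 3L)
  ws <- separable_window_set(n_subj_per_class = 2L, seed = 13L)
  m <- build_model(2L, 32L, cfg)
  p <- predict_prob(m, ws)
  expect_true(all(p >= 0 & p <= 1))
  # per-window prediction: permuting windows permutes outputs
  perm <- rev(seq_along(p))
  ws_perm <- ws
  ws_perm$windows <- ws$windows[perm, , , drop = FALSE]
  ws_perm$subject_ids <- ws$subject_ids[perm]
  ws_perm$labels <- ws$labels[perm]
  expect_equal(predict_prob(m, ws_perm), p[perm], tolerance = 1e-12)
  # thresholding: ties at the threshold go to class 1
  expect_equal(predict_labels(m, ws, threshold = 0),
               rep(1L, length(p)))
  expect_equal(predict_labels(m, ws, threshold = 1.0000001),
               rep(0L, length(p)))
  expect_equal(predict_labels(m, ws, threshold = p[1])[1], 1L)
  # channel mismatch is a shape error
  expect_error(predict_prob(m, select_channels(ws, "T7")), "channels")
})

test_that("training separates a separable cohort and is deterministic", {
  tr <- separable_window_set(n_subj_per_class = 5L, seed = 1L)
  va <- separable_window_set(n_subj_per_class = 2L, seed = 2L,
                             id_prefix = "v")
  cfg <- mhcnet_config(sf = 16, scl_filters = 4L, learning_rate = 5e-3,
                       max_epochs = 40L, patience = 10L, batch_size = 32L,
                       seed = 7L)
  m <- train_model(build_model(2L, 32L, cfg), tr, va, cfg)
  expect_true(m$fitted)
  f1_tr <- confusion_metrics(tr$labels, predict_labels(m, tr))$f1
  expect_gte(f1_tr, 0.95)
  # identical seed + identical data -> identical fit
  m2 <- train_model(build_model(2L, 32L, cfg), tr, va, cfg)
  expect_identical(m$best_val_loss, m2$best_val_loss)
  expect_identical(m$params, m2$params)
})

test_that("training refuses protocol violations", {
  tr <- separable_window_set(n_subj_per_class = 2L, seed = 1L)
  cfg <- mhcnet_config(sf = 16, scl_filters = 2L, max_epochs = 2L)
  m <- build_model(2L, 32L, cfg)
  expect_error(train_model(m, tr, tr, cfg), "protocol")
  one_class <- tr
  keep <- one_class$labels == 0L
  one_class$windows <- one_class$windows[keep, , , drop = FALSE]
  one_class$subject_ids <- one_class$subject_ids[keep]
  one_class$labels <- one_class$labels[keep]
  va <- separable_window_set(n_subj_per_class = 1L, seed = 3L,
                             id_prefix = "v")
  expect_error(train_model(m, one_class, va, cfg), "both classes")
})

test_that("label-shuffled training stays near chance accuracy", {
  cfg <- mhcnet_config(sf = 16, scl_filters = 3L, learning_rate = 5e-3,
                       max_epochs = 8L, patience = 4L, batch_size = 32L,
                       seed = 17L)
  accs <- vapply(1:3, function(s) {
    tr <- separable_window_set(n_subj_per_class = 4L, seed = s)
    va <- separable_window_set(n_subj_per_class = 2L, seed = s + 50L,
                               id_prefix = "v")
    # break the label-signal link: windows keep their subject structure
    # but subjects get random labels
    set.seed(s + 100L)
    relabel <- function(ws) {
      subj <- unique(ws$subject_ids)
      new_lab <- sample(rep(0:1, length.out = length(subj)))
      names(new_lab) <- subj
      ws$labels <- unname(new_lab[ws$subject_ids])
      ws
    }
    tr <- relabel(tr); va <- relabel(va)
    m <- train_model(build_model(2L, 32L, cfg), tr, va, cfg)
    confusion_metrics(va$labels, predict_labels(m, va))$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.8)
})

test_that("model checkpoints round-trip", {
  cfg <- mhcnet_config(sf = 16, scl_filters = 2L, seed = 5L)
  m <- build_model(3L, 32L, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$parameter_count, m2$parameter_count)
})
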