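#' Kernel schedule of the parallel blocks
#'
#' The multihead network extracts features at several temporal scales: the
#' first parallel block's kernel spans half the sampling rate (half a
#' second of signal), and each subsequent block halves the kernel length
#' until it reaches `min_kernel`.  At 128 Hz this gives kernels
#' 64, 32, 16, 8, 4, 2 — six parallel blocks.  If `sf/2` is not a
#' power-of-two multiple of `min_kernel` the schedule truncates at the
#' last value `>= min_kernel`.
#'
#' @param sf Sampling rate in Hz.
#' @param min_kernel Smallest kernel length (default 2).
#' @return Integer vector of kernel lengths, one per parallel block.
#' @examples
#' kernel_schedule(128)   # 64 32 16 8 4 2
#' @export
kernel_schedule <- function(sf, min_kernel = 2L) {
  if (sf < 2 * min_kernel)
    stop("sampling rate too low: need sf >= ", 2 * min_kernel)
  k <- floor(sf / 2)
  sched <- integer(0)
  while (k >= min_kernel) {
    sched <- c(sched, as.integer(k))
    k <- k %/% 2L
  }
  sched
}

#' Model configuration
#'
#' Architecture and training hyperparameters for the multihead
#' separable-convolution classifier.  The architecture shape (parallel
#' blocks of two cascading separable convolutions at halving kernel
#' lengths, per-block softmax heads averaged into a final sigmoid unit) is
#' fixed; the widths and the optimisation settings are configurable.
#'
#' @param sf Sampling rate the kernel schedule is derived from.
#' @param min_kernel Smallest block kernel (default 2).
#' @param scl_filters Pointwise output channels of each separable layer
#'   (default 8).
#' @param depth_multiplier Temporal kernels per input channel in the
#'   depthwise stage (default 1).
#' @param head_units Units of each block's softmax head (default 2, the
#'   number of classes).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Training epoch cap (default 50).
#' @param patience Early-stopping patience on validation loss (default 5).
#' @param dropout Dropout rate on the head inputs during training
#'   (default 0, i.e. off).
#' @param seed Seed governing initialisation and batch shuffling.
#' @return A `ModelConfig` object.
#' @export
mhcnet_config <- function(sf = 128, min_kernel = 2L, scl_filters = 8L,
                          depth_multiplier = 1L, head_units = 2L,
                          learning_rate = 1e-3, batch_size = 64L,
                          max_epochs = 50L, patience = 5L, dropout = 0,
                          seed = 1L) {
  stopifnot(scl_filters >= 1L, depth_multiplier >= 1L, head_units >= 1L,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L, dropout >= 0, dropout < 1)
  cfg <- list(sf = sf, min_kernel = as.integer(min_kernel),
              kernel_schedule = kernel_schedule(sf, min_kernel),
              scl_filters = as.integer(scl_filters),
              depth_multiplier = as.integer(depth_multiplier),
              head_units = as.integer(head_units),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              dropout = dropout, seed = as.integer(seed))
  class(cfg) <- "ModelConfig"
  cfg
}

#' Parameter count of one separable convolution layer
#'
#' A separable layer factorises a full convolution into a depthwise
#' temporal stage (`C_in * D` kernels of length `K`, no bias) and a
#' pointwise mixing stage (`C_in * D x F` weights plus `F` biases), so its
#' parameter count `C_in*K*D + C_in*D*F + F` is far below the
#' `C_in*K*F + F` of the equivalent full convolution whenever
#' `C_in, K, F > 1`.
#'
#' @param c_in Input channels.
#' @param k Kernel length.
#' @param f Pointwise output filters.
#' @param d Depth multiplier (default 1).
#' @return Integer parameter count.
#' @export
separable_conv_params <- function(c_in, k, f, d = 1L) {
  c_in * k * d + c_in * d * f + f
}

#' Build an untrained multihead separable-convolution classifier
#'
#' Constructs the network for windows of `n_channels x S` samples: one
#' parallel block per kernel-schedule entry, each block two cascading
#' separable 1-D convolutions ("same" padding, ReLU) at that block's
#' kernel length followed by a dense softmax head; the block heads are
#' element-wise averaged and a final one-unit dense sigmoid layer yields
#' the class-1 probability.  Weights are Glorot-uniform initialised from
#' `config$seed`.
#'
#' @param n_channels Number of input channels (>= 1; single-channel models
#'   are valid).
#' @param S Samples per window; must be at least the largest kernel.
#' @param config A [mhcnet_config()].
#' @return A `ModelHandle` with elements `params`, `config`, `n_channels`,
#'   `S`, `parameter_count`, `fitted`.
#' @export
build_model <- function(n_channels, S, config = mhcnet_config()) {
  stopifnot(inherits(config, "ModelConfig"), n_channels >= 1L)
  if (S < max(config$kernel_schedule))
    stop("window length S = ", S, " is shorter than the largest kernel (",
         max(config$kernel_schedule), ")")
  params <- with_seed(config$seed, init_params(n_channels, S, config))
  m <- list(params = params, config = config,
            n_channels = as.integer(n_channels), S = as.integer(S),
            parameter_count = sum(vapply(flatten_params(params),
                                         function(x) length(as.array(x)),
                                         numeric(1))),
            fitted = FALSE, history = NULL)
  class(m) <- "ModelHandle"
  m
}

#' @export
print.ModelHandle <- function(x, ...) {
  cat(sprintf(
    "ModelHandle: %d parallel blocks (kernels %s), %d ch x %d samples, %d parameters%s\n",
    length(x$config$kernel_schedule),
    paste(x$config$kernel_schedule, collapse = "/"),
    x$n_channels, x$S, x$parameter_count,
    if (x$fitted) " [fitted]" else " [untrained]"))
  invisible(x)
}

ws_tensor <- function(ws) aperm(ws$windows, c(1, 3, 2))  # [n,S,C] layout

#' Train the classifier on a window set
#'
#' Mini-batch Adam on binary cross-entropy, with early stopping on the
#' validation loss: training stops after `max_epochs` or when the
#' validation loss has not improved for `patience` consecutive epochs, and
#' the best-validation weights are restored.  Training and validation must
#' come from disjoint subjects (enforced), and all randomness (shuffling,
#' dropout) flows from `config$seed`, so identical seed and data give an
#' identical fitted model.
#'
#' @param model A [build_model()] handle.
#' @param train_ws,val_ws `WindowSet`s with disjoint subject ids; both
#'   classes must be present in `train_ws`.
#' @param config Optional [mhcnet_config()] overriding the model's.
#' @param verbose Print per-epoch losses.
#' @return The fitted `ModelHandle`, with a `history` data frame of
#'   train/validation loss per epoch.
#' @export
train_model <- function(model, train_ws, val_ws, config = model$config,
                        verbose = FALSE) {
  stopifnot(inherits(model, "ModelHandle"),
            inherits(train_ws, "WindowSet"), inherits(val_ws, "WindowSet"))
  if (length(intersect(unique(train_ws$subject_ids),
                       unique(val_ws$subject_ids))))
    stop("protocol violation: subjects shared between training and validation")
  if (length(unique(train_ws$labels)) < 2L)
    stop("training set must contain both classes")
  if (dim(train_ws$windows)[2] != model$n_channels)
    stop("channel count mismatch between model and training windows")

  Xtr <- ws_tensor(train_ws); ytr <- train_ws$labels
  Xval <- ws_tensor(val_ws);  yval <- val_ws$labels
  n <- dim(Xtr)[1]
  params <- model$params
  state <- NULL
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist_tr <- hist_val <- numeric(0)
  wait <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      for (s in seq.int(1L, n, by = config$batch_size)) {
        take <- idx[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xtr[take, , , drop = FALSE]
        fw <- mhc_forward(params, Xb, config, keep = TRUE,
                          dropout = config$dropout)
        gr <- mhc_backward(params, fw, ytr[take], config)
        up <- adam_step(params, gr, state, config$learning_rate)
        params <- up$params; state <- up$state
      }
      tr_loss <- bce_loss(mhc_forward(params, Xtr, config)$prob, ytr)
      val_loss <- bce_loss(mhc_forward(params, Xval, config)$prob, yval)
      hist_tr <- c(hist_tr, tr_loss); hist_val <- c(hist_val, val_loss)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch, tr_loss,
                        val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$fitted <- TRUE
  model$config <- config
  model$history <- data.frame(epoch = seq_along(hist_tr),
                              train_loss = hist_tr, val_loss = hist_val)
  model$best_val_loss <- best$loss
  model
}

#' Predict class-1 probabilities for a window set
#'
#' @param model A fitted (or untrained) `ModelHandle`.
#' @param ws A `WindowSet` with the model's channel count.
#' @return Numeric vector of probabilities in `[0, 1]`, one per window.
#' @export
predict_prob <- function(model, ws) {
  stopifnot(inherits(model, "ModelHandle"), inherits(ws, "WindowSet"))
  if (dim(ws$windows)[2] != model$n_channels)
    stop("window set has ", dim(ws$windows)[2],
         " channels; model expects ", model$n_channels)
  mhc_forward(model$params, ws_tensor(ws), model$config)$prob
}

#' Threshold probabilities into hard labels
#'
#' Label 1 is assigned when the probability is greater than or equal to
#' the threshold (ties at the threshold go to class 1).
#'
#' @param model A `ModelHandle`.
#' @param ws A `WindowSet`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels per window.
#' @export
predict_labels <- function(model, ws, threshold = 0.5) {
  as.integer(predict_prob(model, ws) >= threshold)
}

#' Save / load a model checkpoint
#'
#' @param model A `ModelHandle`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the
#'   restored handle.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ModelHandle"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  class(m) <- "ModelHandle"
  m
}
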