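# The recurrent sequence-labeling detector: initialization, fitting,
# prediction, persistence. The numerical core (forward, BPTT, Adam) lives
# in src/net.cpp; this file owns parameter initialization and the S3
# modelling interface.

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

orthogonal_block <- function(h) {
  qrd <- qr(matrix(rnorm(h * h), h))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), h)
}

lstm_init <- function(cin, h) {
  Wh <- do.call(cbind, lapply(1:4, function(i) orthogonal_block(h)))
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1                    # unit forget-gate bias
  list(Wx = glorot_uniform(cin, 4 * h, c(cin, 4 * h)), Wh = Wh, b = b)
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), mean = rep(0, c), var = rep(1, c))
}

#' Initialize an untrained ripple-detection network
#'
#' Builds the layer stack
#' noise -> conv1d -> dropout -> conv1d -> batchnorm -> relu -> dropout ->
#' (bi)LSTM -> batchnorm -> dropout -> (bi)LSTM -> dropout -> batchnorm ->
#' dropout -> time-distributed dense + sigmoid,
#' with Glorot-uniform kernels, orthogonal recurrent matrices and unit
#' forget-gate biases. Convolutions are length-preserving, so the network
#' accepts input sequences of any length N and returns an output of the
#' same length with values in (0, 1).
#'
#' The default unidirectional width (28 units vs 10 per direction) keeps
#' its trainable-parameter count about a factor two above the bidirectional
#' variant's.
#'
#' @param variant `"bidirectional"` (non-causal) or `"unidirectional"`
#'   (causal).
#' @param conv_filters numbers of filters of the two convolutional layers.
#' @param kernel_size convolution kernel length (odd).
#' @param lstm_units LSTM width (per direction for the bidirectional
#'   variant); default 10 (bidirectional) or 28 (unidirectional).
#' @param dropout dropout rate in `[0, 1)`, active only during training.
#' @param noise_sd SD of the Gaussian noise added to the input during
#'   training (mV).
#' @param bn_momentum momentum of the batch-normalization running
#'   statistics (default 0.9; inference-time normalization converges
#'   within a few hundred optimizer steps, matching desk-scale training
#'   schedules).
#' @param label_prior expected fraction of time steps labeled 1; the
#'   output bias is initialized to its logit (the standard rare-event
#'   initialization, which removes the early epochs otherwise spent
#'   learning the base rate). Default 0.05, the boxcar sparsity of 1 s
#'   samples. Set to 0.5 for a zero bias.
#' @param seed integer seed for weight initialization.
#' @return Object of class `swrnet` (untrained).
#' @export
swrnet_init <- function(variant = c("bidirectional", "unidirectional"),
                        conv_filters = c(20, 10), kernel_size = 11,
                        lstm_units = NULL, dropout = 0.2, noise_sd = 0.1,
                        bn_momentum = 0.9, label_prior = 0.05, seed = 1L) {
  variant <- match.arg(variant)
  if (length(conv_filters) != 2L || any(conv_filters < 1))
    stop_invalid("need two convolutional layers with >= 1 filter each")
  if (kernel_size %% 2 != 1) stop_invalid("kernel_size must be odd")
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must be in [0, 1)")
  if (is.null(lstm_units))
    lstm_units <- if (variant == "bidirectional") 10L else 28L
  if (lstm_units < 1) stop_invalid("need >= 1 LSTM unit")
  bidir <- variant == "bidirectional"
  ndir <- if (bidir) 2L else 1L
  c1 <- conv_filters[1L]; c2 <- conv_filters[2L]; h <- lstm_units
  k <- kernel_size
  set.seed(seed)
  p <- list(
    conv1_W = glorot_uniform(k * 1, k * c1, c(k, 1L, c1)),
    conv1_b = rep(0, c1),
    conv2_W = glorot_uniform(k * c1, k * c2, c(k, c1, c2)),
    conv2_b = rep(0, c2))
  for (nm in names(b <- bn_init(c2))) p[[paste0("bn1_", nm)]] <- b[[nm]]
  l <- lstm_init(c2, h)
  for (nm in names(l)) p[[paste0("lstm1_fwd_", nm)]] <- l[[nm]]
  if (bidir) {
    l <- lstm_init(c2, h)
    for (nm in names(l)) p[[paste0("lstm1_bwd_", nm)]] <- l[[nm]]
  }
  for (nm in names(b <- bn_init(ndir * h))) p[[paste0("bn2_", nm)]] <- b[[nm]]
  l <- lstm_init(ndir * h, h)
  for (nm in names(l)) p[[paste0("lstm2_fwd_", nm)]] <- l[[nm]]
  if (bidir) {
    l <- lstm_init(ndir * h, h)
    for (nm in names(l)) p[[paste0("lstm2_bwd_", nm)]] <- l[[nm]]
  }
  for (nm in names(b <- bn_init(ndir * h))) p[[paste0("bn3_", nm)]] <- b[[nm]]
  if (label_prior <= 0 || label_prior >= 1)
    stop_invalid("label_prior must be in (0, 1)")
  p$dense_W <- as.numeric(glorot_uniform(ndir * h, 1, c(ndir * h, 1)))
  p$dense_b <- stats::qlogis(label_prior)
  structure(list(params = p, variant = variant,
                 dims = list(conv_filters = conv_filters,
                             kernel_size = kernel_size,
                             lstm_units = lstm_units, ndir = ndir),
                 dropout = dropout, noise_sd = noise_sd,
                 bn_momentum = bn_momentum, seed = seed,
                 history = NULL, epochs_trained = 0L, fs = NULL),
            class = "swrnet")
}

#' Fit the ripple-detection network
#'
#' Initializes (see [swrnet_init()]) and trains the network on one-hot
#' labeled LFP segments by Adam optimization of the mean binary
#' cross-entropy, with mean squared error monitored alongside. Gaussian
#' input noise and dropout are active only during training; validation
#' metrics use inference mode. Training is deterministic for a fixed seed
#' on a fixed device.
#'
#' @param train a [sample_set()] with the training segments.
#' @param val optional [sample_set()] monitored each epoch.
#' @param variant,conv_filters,kernel_size,lstm_units,dropout,noise_sd,seed
#'   passed to [swrnet_init()].
#' @param learning_rate,beta1,beta2,epsilon Adam settings (defaults 0.005,
#'   0.9, 0.999, 1e-7).
#' @param batch_size mini-batch size (default 20).
#' @param epochs number of training epochs (default 50; >= 1).
#' @return A fitted object of class `swrnet` with a `history` data.frame
#'   (per-epoch `loss`, `mse`, `val_loss`, `val_mse`).
#' @seealso [predict.swrnet()], [find_events()], [predict_continuous()]
#' @export
swrnet <- function(train, val = NULL,
                   variant = c("bidirectional", "unidirectional"),
                   conv_filters = c(20, 10), kernel_size = 11,
                   lstm_units = NULL, dropout = 0.2, noise_sd = 0.1,
                   bn_momentum = 0.9, label_prior = 0.05,
                   learning_rate = 0.005, beta1 = 0.9,
                   beta2 = 0.999, epsilon = 1e-7, batch_size = 20,
                   epochs = 50, seed = 1L) {
  model <- swrnet_init(variant = variant, conv_filters = conv_filters,
                       kernel_size = kernel_size, lstm_units = lstm_units,
                       dropout = dropout, noise_sd = noise_sd,
                       bn_momentum = bn_momentum, label_prior = label_prior,
                       seed = seed)
  swrnet_train(model, train, val = val, learning_rate = learning_rate,
               beta1 = beta1, beta2 = beta2, epsilon = epsilon,
               batch_size = batch_size, epochs = epochs, seed = seed)
}

#' Train (or fine-tune) an existing network
#'
#' Continues optimization from the model's current weights, so a loaded
#' model can be trained further on new data.
#'
#' @param model a `swrnet` object.
#' @inheritParams swrnet
#' @export
swrnet_train <- function(model, train, val = NULL, learning_rate = 0.005,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         batch_size = 20, epochs = 50, seed = model$seed) {
  stopifnot(inherits(model, "swrnet"))
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  Xtr <- as_trace_matrix(train)
  ytr <- as_trace_matrix(if (inherits(train, "sample_set")) train$y else
    stop_invalid("train must be a sample_set"))
  if (nrow(Xtr) == 0L) stop_invalid("training set is empty")
  if (is.null(val)) {
    Xv <- matrix(numeric(0), 0L, ncol(Xtr)); yv <- Xv
  } else {
    stopifnot(inherits(val, "sample_set"))
    if (ncol(as_trace_matrix(val)) != ncol(Xtr))
      stop_invalid("train and val must share T")
    Xv <- as_trace_matrix(val); yv <- as_trace_matrix(val$y)
  }
  fit <- .net_train(model$params, Xtr, ytr, Xv, yv,
                    lr = learning_rate, beta1 = beta1, beta2 = beta2,
                    eps = epsilon, batch_size = as.integer(batch_size),
                    epochs = as.integer(epochs), noise_sd = model$noise_sd,
                    dropout = model$dropout, seed = as.integer(seed),
                    bn_momentum = if (is.null(model$bn_momentum)) 0.9 else
                      model$bn_momentum)
  if (any(!is.finite(fit$loss)))
    warning("training diverged: non-finite loss encountered")
  hist <- data.frame(epoch = model$epochs_trained + seq_len(epochs),
                     loss = fit$loss, mse = fit$mse,
                     val_loss = if (nrow(Xv)) fit$val_loss else NA_real_,
                     val_mse = if (nrow(Xv)) fit$val_mse else NA_real_)
  model$params <- fit$params
  model$history <- rbind(model$history, hist)
  model$epochs_trained <- model$epochs_trained + as.integer(epochs)
  model$fs <- if (inherits(train, "sample_set")) train$fs else model$fs
  model
}

#' Predict SPW-R probability traces
#'
#' Runs the network in inference mode (noise and dropout off). The output
#' has the same temporal shape as the input and values in (0, 1),
#' interpreted as the time-varying probability of a ripple event.
#'
#' @param object a fitted `swrnet`.
#' @param newdata a [sample_set()], an `(n, T, 1)` array, an `n x T`
#'   matrix, a numeric vector (single trace), or an [lfp_recording()]
#'   (delegated to [predict_continuous()]).
#' @param batch_size internal prediction batch size.
#' @param ... passed to [predict_continuous()] for recordings.
#' @return An `n x T` matrix of probabilities (a vector for vector input,
#'   or the [predict_continuous()] result for a recording).
#' @export
predict.swrnet <- function(object, newdata, batch_size = 128, ...) {
  if (inherits(newdata, "lfp_recording"))
    return(predict_continuous(object, newdata, ...))
  vec <- is.null(dim(newdata)) && !inherits(newdata, "sample_set")
  X <- as_trace_matrix(newdata)
  out <- .net_forward(object$params, X, batch_size = as.integer(batch_size))
  if (vec) as.numeric(out) else out
}

#' Number of parameters of a network
#' @param model a `swrnet` object.
#' @return Named vector with `trainable` and `total` counts (the difference
#'   being the batch-normalization running statistics).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "swrnet"))
  nm <- names(model$params)
  stat <- grepl("_(mean|var)$", nm)
  sizes <- vapply(model$params, length, 1)
  c(trainable = sum(sizes[!stat]), total = sum(sizes))
}

#' @export
coef.swrnet <- function(object, ...) object$params

#' @export
print.swrnet <- function(x, ...) {
  np <- n_parameters(x)
  cat(sprintf("<swrnet %s: conv(%s, k=%d) + 2x LSTM(%d%s), %d trainable parameters>\n",
              x$variant, paste(x$dims$conv_filters, collapse = ","),
              x$dims$kernel_size, x$dims$lstm_units,
              if (x$dims$ndir == 2L) "/dir" else "", np["trainable"]))
  if (x$epochs_trained > 0L) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f%s\n", x$epochs_trained,
                h$loss,
                if (is.finite(h$val_loss))
                  sprintf(", val loss %.4f", h$val_loss) else ""))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.swrnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Plot training and validation curves
#' @param x a fitted `swrnet`.
#' @param ... ignored.
#' @export
plot.swrnet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop_invalid("model has no training history")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  rng <- range(c(h$loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$loss, type = "l", ylim = rng, xlab = "epoch",
       ylab = "binary cross-entropy J", main = x$variant)
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  rng <- range(c(h$mse, h$val_mse), na.rm = TRUE)
  plot(h$epoch, h$mse, type = "l", ylim = rng, xlab = "epoch",
       ylab = "MSE")
  if (any(is.finite(h$val_mse)))
    graphics::lines(h$epoch, h$val_mse, lty = 2)
  invisible(x)
}

#' Save / load a fitted network
#'
#' Round-trips the full model object (weights, history, settings);
#' predictions after a load match those before the save, and a loaded model
#' can be trained further.
#'
#' @param model a `swrnet` object.
#' @param path file path.
#' @export
save_swrnet <- function(model, path) {
  stopifnot(inherits(model, "swrnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_swrnet
#' @export
load_swrnet <- function(path) {
  if (!file.exists(path)) stop_format("no such model file: ", path)
  model <- tryCatch(readRDS(path), error = function(e)
    stop_format("corrupt model file: ", conditionMessage(e)))
  if (!inherits(model, "swrnet") || is.null(model$params$conv1_W))
    stop_format("file does not contain a swrnet model")
  model
}

#' Mean binary cross-entropy
#'
#' `J = -(1/N) sum[y log yhat + (1 - y) log(1 - yhat)]` over all N time
#' steps. Predicted probabilities equal to exactly 0 or 1 are clipped to
#' `1e-7` away from the boundary (with a message).
#'
#' @param y binary labels.
#' @param yhat predicted probabilities in (0, 1).
#' @export
bce_loss <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (any(yhat <= 0 | yhat >= 1)) {
    message("clipping predicted probabilities to [1e-7, 1 - 1e-7]")
    yhat <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  }
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Mean squared error
#' @inheritParams bce_loss
#' @export
mse_metric <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean((y - yhat)^2)
}
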