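#' Network configuration
#'
#' Hyper-parameters of the beat-wise regression network: six residual 1-D
#' convolutional blocks (kernel length 16 throughout; 32 filters in blocks
#' 1--4 and 64 in blocks 5--6; the second convolution's stride and the
#' shortcut pooling size are 2 in blocks 1, 3 and 5, so the 1000-sample
#' input is downsampled to a 125-step feature sequence), a bidirectional
#' GRU with 32 units per direction (64-dimensional combined feature), and a
#' 4-cell dense output head. Training minimises mean squared error on the
#' scaled targets with a learning rate of 0.001 and batch size 64.
#'
#' @param input_length Window length in samples (1 s at 1 kHz).
#' @param input_channels Input channels (PCG, PPG).
#' @param channels Filters per residual block.
#' @param strides Second-convolution stride / shortcut pooling size per block.
#' @param kernel_length Convolution kernel length.
#' @param gru_units GRU units per direction.
#' @param dense_cells Output dimension (the four parameters).
#' @param dropout_rate Dropout between the two convolutions of each block.
#' @param leaky_slope Negative slope of the head's leaky ReLU.
#' @param batch_size Training mini-batch size.
#' @param learning_rate Optimiser step size.
#' @param epochs Default number of training epochs.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Integer seed driving weight initialisation, dropout and
#'   shuffling.
#' @return A `hemo_model_config` list.
#' @export
model_config <- function(input_length = 1000, input_channels = 2,
                         channels = c(32, 32, 32, 32, 64, 64),
                         strides = c(2, 1, 2, 1, 2, 1),
                         kernel_length = 16, gru_units = 32, dense_cells = 4,
                         dropout_rate = 0.2, leaky_slope = 0.01,
                         batch_size = 64, learning_rate = 0.001,
                         epochs = 200, optimizer = c("adam", "sgd"),
                         seed = 1) {
  optimizer <- match.arg(optimizer)
  if (length(channels) != length(strides))
    stop("`channels` and `strides` must have the same length", call. = FALSE)
  if (any(!strides %in% c(1, 2)))
    stop("strides must be 1 or 2 (shortcut pooling must match)", call. = FALSE)
  structure(list(
    input_length = as.integer(input_length),
    input_channels = as.integer(input_channels),
    channels = as.integer(channels), strides = as.integer(strides),
    kernel_length = as.integer(kernel_length),
    gru_units = as.integer(gru_units), dense_cells = as.integer(dense_cells),
    dropout_rate = as.numeric(dropout_rate),
    leaky_slope = as.numeric(leaky_slope),
    batch_size = as.integer(batch_size),
    learning_rate = as.numeric(learning_rate),
    epochs = as.integer(epochs), optimizer = optimizer,
    seed = as.integer(seed)), class = "hemo_model_config")
}

#' @export
print.hemo_model_config <- function(x, ...) {
  cat(sprintf(paste0("<hemo_model_config> %d x %d input, %d residual blocks ",
                     "(downsampling x%d), Bi-GRU %d/dir, %d outputs\n"),
              x$input_length, x$input_channels, length(x$channels),
              prod(x$strides), x$gru_units, x$dense_cells))
  invisible(x)
}

net_handle <- function(config) {
  .net_create(config[c("input_length", "input_channels", "channels", "strides",
                       "kernel_length", "gru_units", "dense_cells",
                       "dropout_rate", "leaky_slope", "seed")])
}

#' Build an untrained estimator
#'
#' Instantiates the network with seeded random weights.
#'
#' @param config A [model_config()].
#' @return A `hemo_estimator` holding the configuration and weights.
#' @export
build_estimator <- function(config = model_config()) {
  net <- net_handle(config)
  structure(list(config = config, weights = .net_get_weights(net)),
            class = "hemo_estimator")
}

restore_net <- function(estimator) {
  net <- net_handle(estimator$config)
  .net_set_weights(net, estimator$weights)
  net
}

#' Forward pass on scaled targets
#'
#' Runs the network in evaluation mode (deterministic: dropout off, batch
#' norm uses running statistics) and returns the scaled 4-vector per window.
#'
#' @param estimator A `hemo_estimator` or `hemo_trained`.
#' @param windows A `1000 x 2 x n` array ([windows_array()]) or cycle tibble.
#' @return An `n x 4` matrix of scaled outputs (columns sbp, dbp, mrr, mrd).
#' @export
forward_scaled <- function(estimator, windows) {
  if (is.data.frame(windows)) windows <- windows_array(windows)
  check_windows(windows, estimator$config)
  out <- .net_predict(restore_net(estimator), windows)
  colnames(out) <- names(target_divisors())
  out
}

check_windows <- function(arr, config) {
  d <- dim(arr)
  if (length(d) != 3 || d[1] != config$input_length || d[2] != config$input_channels)
    stop(sprintf("windows must be %d x %d x n; got %s",
                 config$input_length, config$input_channels,
                 paste(d, collapse = " x ")), call. = FALSE)
  invisible(arr)
}

#' Probe the network's internal shapes
#'
#' Runs a forward pass and reports the measured feature-sequence length
#' after the residual stack, the combined Bi-GRU feature dimension, and the
#' output dimension.
#'
#' @param estimator A `hemo_estimator` or `hemo_trained`.
#' @param windows Optional window array (defaults to a zero batch of 2).
#' @return A list with `res_seq_len`, `gru_feature_dim`, `output_dim`.
#' @export
probe_shapes <- function(estimator, windows = NULL) {
  cfg <- estimator$config
  if (is.null(windows))
    windows <- array(0, dim = c(cfg$input_length, cfg$input_channels, 2))
  .net_probe_shapes(restore_net(estimator), windows)[
    c("res_seq_len", "gru_feature_dim", "output_dim")]
}

#' Train the estimator
#'
#' Mini-batch gradient descent (Adam by default) on mean squared error over
#' scaled targets. The validation loss is evaluated after every epoch and
#' the returned model carries the weights of the epoch with the smallest
#' validation loss (checkpoint selection). Incomplete trailing mini-batches
#' are dropped so batch statistics stay well defined.
#'
#' @param estimator A `hemo_estimator` (or `hemo_trained` to continue).
#' @param train_windows,val_windows `1000 x 2 x n` arrays.
#' @param train_targets,val_targets `n x 4` matrices of scaled targets (or
#'   data frames with sbp/dbp/mrr/mrd columns, already scaled).
#' @param epochs Number of epochs; defaults to the configuration value.
#' @return A `hemo_trained` object: best-epoch weights, per-epoch history,
#'   `best_epoch`, and the configuration.
#' @export
train_estimator <- function(estimator, train_windows, train_targets,
                            val_windows, val_targets, epochs = NULL) {
  cfg <- estimator$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  train_targets <- as_target_matrix(train_targets)
  val_targets <- as_target_matrix(val_targets)
  if (dim(train_windows)[3] == 0 || nrow(train_targets) == 0)
    stop("empty training set", call. = FALSE)
  if (dim(val_windows)[3] == 0 || nrow(val_targets) == 0)
    stop("empty validation set", call. = FALSE)
  stopifnot(dim(train_windows)[3] == nrow(train_targets),
            dim(val_windows)[3] == nrow(val_targets))
  check_windows(train_windows, cfg); check_windows(val_windows, cfg)
  net <- restore_net(estimator)
  fit <- .net_train(net, train_windows, train_targets, val_windows, val_targets,
                    epochs, cfg$batch_size, cfg$learning_rate,
                    cfg$optimizer == "adam", TRUE)
  structure(list(
    config = cfg,
    weights = .net_get_weights(net), # best-epoch weights (restored in C++)
    history = tibble::tibble(epoch = seq_len(epochs),
                             train_loss = fit$train_loss,
                             val_loss = fit$val_loss),
    best_epoch = fit$best_epoch,
    best_val_loss = fit$best_val_loss), class = c("hemo_trained", "hemo_estimator"))
}

as_target_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(x[, names(target_divisors())])
}

#' @export
print.hemo_trained <- function(x, ...) {
  cat(sprintf("<hemo_trained> %d epochs, best epoch %d (val MSE %.4g)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict hemodynamic labels for cycles
#'
#' Forward pass followed by inverse target scaling, so predictions are in
#' physical units (mmHg, mmHg/s). Order matches the input order.
#'
#' @param object A `hemo_trained` estimator.
#' @param windows Window array or cycle tibble.
#' @param ... Unused.
#' @return A tibble with `sbp`, `dbp`, `mrr`, `mrd` per window.
#' @export
predict.hemo_trained <- function(object, windows, ...) {
  out <- forward_scaled(object, windows)
  inverse_scale(tibble::as_tibble(out))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history
#' @param x A `hemo_trained` model.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `dataset` (train/validation), `mse`.
#' @export
tidy.hemo_trained <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "dataset", values_to = "mse") |>
    dplyr::mutate(dataset = sub("_loss$", "", .data$dataset))
}

#' One-line model summary
#' @param x A `hemo_trained` model.
#' @param ... Unused.
#' @return One-row tibble with epoch counts and losses.
#' @export
glance.hemo_trained <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' Plot the training history
#' @param object A `hemo_trained` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemo_trained <- function(object, ...) {
  ggplot2::ggplot(tidy.hemo_trained(object),
                  ggplot2::aes(x = .data$epoch, y = .data$mse,
                               colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (scaled targets)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
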