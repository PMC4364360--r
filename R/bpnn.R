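#' Configuration of the backpropagation network
#'
#' The classifier is a single-hidden-layer perceptron: `n_hidden`
#' tangent-sigmoid units (default 25) feeding one linear output unit
#' that regresses the 0/1 class label. Training is full-batch gradient
#' descent on the mean squared error, stopping at `mse_goal` or
#' `max_epochs`.
#'
#' @param n_hidden Hidden units (default 25).
#' @param learning_rate Gradient-descent step size (default 0.05).
#' @param max_epochs Epoch budget (default 1000).
#' @param mse_goal Stop once training MSE falls to or below this
#'   (default 1e-3).
#' @param momentum Momentum coefficient in [0, 1) (default 0, plain
#'   gradient descent).
#' @param seed Integer seed for the uniform(-0.5, 0.5) weight
#'   initialization.
#' @return A list of class `bpnn_config`.
#' @export
bpnn_config <- function(n_hidden = 25L, learning_rate = 0.05,
                        max_epochs = 1000L, mse_goal = 1e-3,
                        momentum = 0, seed = 1L) {
  stopifnot(n_hidden >= 1L, learning_rate > 0, max_epochs >= 0L,
            mse_goal > 0, momentum >= 0, momentum < 1)
  structure(list(n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 mse_goal = mse_goal, momentum = momentum,
                 seed = as.integer(seed)),
            class = "bpnn_config")
}

#' Min-max normalization fitted on training data
#'
#' Scales each feature to [0, 1] using per-feature training bounds;
#' values outside the bounds (e.g. in a test fold) are clipped, and a
#' constant training feature maps to 0 everywhere.
#'
#' @param X Numeric training matrix (rows = samples).
#' @return A list of class `minmax_scaler` with `min` and `max` vectors.
#' @seealso [apply_scaler()]
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max)),
            class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `minmax_scaler`.
#' @param X Numeric matrix with the same columns as the training data.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (ncol(X) != length(scaler$min)) stop("feature count mismatch")
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2L, scaler$min, `-`)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], `/`)
  out[, !nz] <- 0
  pmin(pmax(out, 0), 1)
}

# forward pass; returns intermediates needed for backprop
bpnn_forward <- function(model, X) {
  Z <- X %*% model$W1 + matrix(model$b1, nrow(X), length(model$b1),
                               byrow = TRUE)
  H <- tanh(Z)
  yhat <- drop(H %*% model$W2 + model$b2)
  list(H = H, yhat = yhat)
}

# analytic gradient of MSE = mean((yhat - y)^2) over the batch
bpnn_gradient <- function(model, X, y) {
  fw <- bpnn_forward(model, X)
  n <- nrow(X)
  err <- fw$yhat - y                       # n
  d_out <- 2 * err / n                     # dMSE/dyhat
  gW2 <- crossprod(fw$H, d_out)            # h x 1
  gb2 <- sum(d_out)
  d_hidden <- (d_out %*% t(model$W2)) * (1 - fw$H^2)  # n x h
  gW1 <- crossprod(X, d_hidden)
  gb1 <- colSums(d_hidden)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       mse = mean(err^2))
}

bpnn_init <- function(n_inputs, config) {
  with_seed(config$seed, {
    h <- config$n_hidden
    list(W1 = matrix(stats::runif(n_inputs * h, -0.5, 0.5), n_inputs, h),
         b1 = stats::runif(h, -0.5, 0.5),
         W2 = matrix(stats::runif(h, -0.5, 0.5), h, 1L),
         b2 = stats::runif(1L, -0.5, 0.5))
  })
}

#' Train the backpropagation network
#'
#' Full-batch gradient descent on the mean squared error of the linear
#' output against 0/1 targets, with seeded uniform(-0.5, 0.5) weight
#' initialization. Features are min-max scaled to [0, 1] internally
#' (bounds fitted on the training data and stored in the model);
#' identical data, configuration and seed give identical weights.
#'
#' @param X Numeric feature matrix (rows = samples), e.g. integer-coded
#'   discretized attributes of a reduct projection.
#' @param y 0/1 class labels, one per row.
#' @param config A [bpnn_config()].
#' @param scale Fit-and-apply min-max scaling (default `TRUE`); set
#'   `FALSE` when features are already normalized.
#' @return A list of class `bpnn` with weights `W1`, `b1`, `W2`, `b2`,
#'   the stored `scaler`, `config`, and `record` (per-epoch MSE vector
#'   plus `stop_reason`, `"goal"` or `"max_epochs"`).
#' @examples
#' X <- cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1))
#' y <- c(0, 1, 1, 0)  # XOR
#' fit <- train_bpnn(X, y, bpnn_config(max_epochs = 200, seed = 1))
#' tail(fit$record$mse, 1)
#' @export
train_bpnn <- function(X, y, config = bpnn_config(), scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (length(y) != nrow(X)) stop("X and y length mismatch")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  y <- as.numeric(y)

  scaler <- if (scale) fit_scaler(X) else NULL
  Xs <- if (scale) apply_scaler(scaler, X) else X

  model <- bpnn_init(ncol(X), config)
  vel <- lapply(model, function(w) w * 0)
  mse_trace <- numeric(0)
  stop_reason <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    g <- bpnn_gradient(model, Xs, y)
    for (nm in c("W1", "b1", "W2", "b2")) {
      vel[[nm]] <- config$momentum * vel[[nm]] - config$learning_rate * g[[nm]]
      model[[nm]] <- model[[nm]] + vel[[nm]]
    }
    # MSE after the update
    mse <- mean((bpnn_forward(model, Xs)$yhat - y)^2)
    mse_trace <- c(mse_trace, mse)
    if (mse <= config$mse_goal) {
      stop_reason <- "goal"
      break
    }
  }
  structure(c(model,
              list(scaler = scaler, config = config,
                   feature_names = colnames(X),
                   record = list(mse = mse_trace, stop_reason = stop_reason))),
            class = "bpnn")
}

#' Predict with a trained backpropagation network
#'
#' @param object A `bpnn` model.
#' @param X Feature matrix with the model's columns.
#' @param ... Unused.
#' @return List with `scores` (linear outputs) and `labels` (1 when
#'   score >= 0.5).
#' @export
predict.bpnn <- function(object, X, ...) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(object$W1)) stop("feature count mismatch")
  Xs <- if (!is.null(object$scaler)) apply_scaler(object$scaler, X) else X
  scores <- bpnn_forward(object, Xs)$yhat
  list(scores = scores, labels = as.integer(scores >= 0.5))
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %d-%d-1 (tanh hidden, linear output)\n",
              nrow(x$W1), ncol(x$W1)))
  cat(sprintf("  trained %d epoch(s), final MSE %.4g, stopped at %s\n",
              length(x$record$mse),
              if (length(x$record$mse)) tail(x$record$mse, 1) else NA,
              x$record$stop_reason))
  invisible(x)
}

#' Serialize / restore a trained network as JSON
#'
#' @param model A `bpnn`.
#' @param path JSON file path.
#' @return `path` (write) or a `bpnn` (read).
#' @export
write_bpnn <- function(model, path) {
  stopifnot(inherits(model, "bpnn"))
  out <- list(W1 = model$W1, b1 = model$b1,
              W2 = as.numeric(model$W2), b2 = model$b2,
              scaler = if (!is.null(model$scaler)) {
                list(min = as.numeric(model$scaler$min),
                     max = as.numeric(model$scaler$max))
              },
              config = unclass(model$config),
              feature_names = model$feature_names,
              record = model$record)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_bpnn
#' @export
read_bpnn <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- as.matrix(raw$W1)
  storage.mode(W1) <- "double"
  model <- list(W1 = W1,
                b1 = as.numeric(raw$b1),
                W2 = matrix(as.numeric(raw$W2), ncol = 1L),
                b2 = as.numeric(raw$b2),
                scaler = if (!is.null(raw$scaler)) {
                  structure(list(min = as.numeric(raw$scaler$min),
                                 max = as.numeric(raw$scaler$max)),
                            class = "minmax_scaler")
                },
                config = do.call(bpnn_config, as.list(raw$config)),
                feature_names = raw$feature_names,
                record = list(mse = as.numeric(raw$record$mse),
                              stop_reason = raw$record$stop_reason))
  class(model) <- "bpnn"
  model
}
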