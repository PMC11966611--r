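# Reference regressor: a small fully connected network trained by minibatch
# Adam. Backpropagation is written out explicitly so that either loss (pooled
# MSE or MOORLE) plugs in through its gradient with respect to the batch
# predictions — the only point where the two objectives differ.

#' Model configuration for the reference fully connected regressor
#'
#' @param input_dim Number of input features (must match the assembled
#'   feature length).
#' @param hidden Integer vector of hidden layer widths.
#' @param activation Hidden activation; `"relu"` or `"tanh"`.
#' @param dropout Dropout rate on hidden activations, in \[0, 1).
#' @param seed Integer seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim, hidden = c(64, 32),
                         activation = c("relu", "tanh"),
                         dropout = 0.1, seed = 1) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, all(hidden >= 1), dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), activation = activation,
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs Number of passes over the training data (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Only `"adam"` is provided.
#' @param early_stop_patience Stop after this many epochs without
#'   improvement of the validation bulk MSE; `NULL` disables early stopping.
#' @param seed Integer seed scoping all training-time randomness (dropout
#'   masks; the sampler keeps its own seed).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 40, learning_rate = 1e-3,
                         optimizer = "adam", early_stop_patience = NULL,
                         seed = 1) {
  stopifnot(epochs >= 1, learning_rate > 0, identical(optimizer, "adam"))
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained fully connected regressor
#'
#' He-scaled Gaussian initialization, deterministic under the config seed.
#' The returned model predicts a single response per feature row.
#'
#' @param config A [model_config()].
#' @return An `fcnn` object.
#' @export
build_model <- function(config) {
  dims <- c(config$input_dim, config$hidden, 1L)
  params <- withr::with_seed(config$seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]
      list(W = matrix(stats::rnorm(fan_in * dims[l + 1], 0,
                                   sqrt(2 / fan_in)),
                      nrow = fan_in),
           b = numeric(dims[l + 1]))
    })
  })
  structure(list(params = params, config = config,
                 center = NULL, scale = NULL, history = NULL),
            class = "fcnn")
}

act_fun <- function(z, kind) {
  if (kind == "relu") pmax(z, 0) else tanh(z)
}
act_grad <- function(z, kind) {
  if (kind == "relu") (z > 0) * 1 else 1 - tanh(z)^2
}

# Forward pass. When training, applies inverted dropout to hidden
# activations (consumes RNG) and returns the cache needed for backprop.
fcnn_forward <- function(model, X, training = FALSE) {
  p <- model$params
  L <- length(p)
  kind <- model$config$activation
  drop <- if (training) model$config$dropout else 0
  zs <- vector("list", L); as <- vector("list", L)
  masks <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% p[[l]]$W, 2, p[[l]]$b, "+")
    zs[[l]] <- z
    if (l < L) {
      h <- act_fun(z, kind)
      if (drop > 0) {
        m <- matrix(stats::rbinom(length(h), 1, 1 - drop) / (1 - drop),
                    nrow = nrow(h))
        h <- h * m
        masks[[l]] <- m
      }
      as[[l]] <- h
      a <- h
    } else {
      as[[l]] <- z
    }
  }
  list(pred = as.numeric(as[[L]]), zs = zs, as = as, masks = masks, X = X)
}

# Backward pass: grad_pred is dLoss/dprediction (length = batch rows).
fcnn_backward <- function(model, cache, grad_pred) {
  p <- model$params
  L <- length(p)
  kind <- model$config$activation
  grads <- vector("list", L)
  delta <- matrix(grad_pred, ncol = 1)
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1) cache$X else cache$as[[l - 1]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(p[[l]]$W)
      if (!is.null(cache$masks[[l - 1]])) {
        delta <- delta * cache$masks[[l - 1]]
      }
      delta <- delta * act_grad(cache$zs[[l - 1]], kind)
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(pl) list(
    mW = pl$W * 0, vW = pl$W * 0,
    mb = pl$b * 0, vb = pl$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhatW <- s$mW / (1 - beta1^t); vhatW <- s$vW / (1 - beta2^t)
    mhatb <- s$mb / (1 - beta1^t); vhatb <- s$vb / (1 - beta2^t)
    params[[l]]$W <- params[[l]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

#' Train the reference regressor with a configurable sampler and loss
#'
#' Runs minibatch Adam over the training records. Features are standardized
#' to zero mean / unit variance using statistics of the training portion
#' only (stored in the model and re-applied at prediction time, so no test
#' information leaks into scaling). Each epoch's batches come from the
#' configured sampler; each batch's parameter update backpropagates the
#' gradient of the configured loss — pooled MSE or MOORLE — through the
#' network. Fully reproducible given the data, model, sampler and training
#' seeds.
#'
#' @param model An untrained (or partially trained) `fcnn` from
#'   [build_model()].
#' @param dataset A `drp_dataset` from [assemble_dataset()].
#' @param train_idx Integer indices of the training records.
#' @param sampler A [sampler_config()].
#' @param loss A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param val_idx Optional validation record indices for early stopping /
#'   monitoring (bulk MSE).
#' @return The trained `fcnn`, with `history`: a data frame of per-epoch
#'   mean training batch loss (and validation MSE if `val_idx` given).
#' @export
train_model <- function(model, dataset, train_idx, sampler, loss,
                        train_cfg, val_idx = NULL) {
  stopifnot(inherits(model, "fcnn"), length(train_idx) > 0)
  X <- dataset$features[train_idx, , drop = FALSE]
  if (ncol(X) != model$config$input_dim) {
    stop("train_model: dataset has ", ncol(X),
         " features but model expects ", model$config$input_dim)
  }
  y <- dataset$response[train_idx]
  groups <- dataset$drug_id[train_idx]

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  model$center <- center
  model$scale <- scale

  Xv <- NULL; yv <- NULL
  if (!is.null(val_idx) && length(val_idx) > 0) {
    Xv <- sweep(sweep(dataset$features[val_idx, , drop = FALSE],
                      2, center, "-"), 2, scale, "/")
    yv <- dataset$response[val_idx]
  }

  params <- model$params
  state <- adam_init(params)
  lr <- train_cfg$learning_rate
  t <- 0
  hist_loss <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_params <- params; stall <- 0
  patience <- train_cfg$early_stop_patience

  withr::with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      batches <- epoch_batches(groups, sampler, epoch)
      batch_losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        ix <- batches[[b]]
        model$params <- params
        cache <- fcnn_forward(model, Xs[ix, , drop = FALSE],
                              training = TRUE)
        lval <- batch_loss(cache$pred, y[ix], groups[ix], loss)
        if (!is.finite(lval)) {
          stop("non-finite loss at epoch ", epoch, ", batch ", b)
        }
        batch_losses[b] <- lval
        gpred <- batch_loss_gradient(cache$pred, y[ix], groups[ix], loss)
        grads <- fcnn_backward(model, cache, gpred)
        t <- t + 1
        upd <- adam_step(params, grads, state, lr, t)
        params <- upd$params
        state <- upd$state
      }
      hist_loss[epoch] <- mean(batch_losses)
      if (!is.null(Xv)) {
        model$params <- params
        pv <- fcnn_forward(model, Xv)$pred
        vmse <- mean((pv - yv)^2)
        hist_val[epoch] <- vmse
        if (vmse < best_val - 1e-12) {
          best_val <- vmse; best_params <- params; stall <- 0
        } else {
          stall <- stall + 1
          if (!is.null(patience) && stall >= patience) break
        }
      }
    }
  })

  if (!is.null(Xv) && !is.null(patience)) {
    model$params <- best_params
  } else {
    model$params <- params
  }
  h <- data.frame(epoch = seq_along(hist_loss), train_loss = hist_loss)
  if (length(hist_val) > 0) h$val_mse <- hist_val
  model$history <- h
  model
}

#' Predict responses for a feature matrix
#'
#' Applies the training-time standardization, then the forward pass with
#' dropout disabled.
#'
#' @param object A trained `fcnn`.
#' @param newdata Numeric matrix, one row per pair, width = `input_dim`.
#' @param ... Unused.
#' @return Numeric vector of predictions (length 0 for 0-row input).
#' @export
predict.fcnn <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$config$input_dim) {
    stop("predict.fcnn: input has ", ncol(newdata),
         " columns, expected ", object$config$input_dim)
  }
  if (nrow(newdata) == 0) return(numeric(0))
  X <- newdata
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  }
  fcnn_forward(object, X)$pred
}

#' @export
print.fcnn <- function(x, ...) {
  dims <- c(x$config$input_dim, x$config$hidden, 1L)
  cat("Fully connected regressor: ", paste(dims, collapse = "-"),
      " (", x$config$activation, ", dropout ", x$config$dropout, ")",
      if (is.null(x$history)) " [untrained]" else
        sprintf(" [trained %d epochs]", nrow(x$history)),
      "\n", sep = "")
  invisible(x)
}
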