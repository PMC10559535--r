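#' Training configuration of the feed-forward classifier
#'
#' The reference architecture is a 32-neuron input, a normalization layer
#' (per-feature z-score, statistics adapted on the training set only), three
#' rectifier hidden layers tapering 64-32-16, and a 2-neuron softmax output.
#' Optimisation is mini-batch stochastic gradient descent with momentum 0.9,
#' inverse-time learning-rate decay `lr_t = lr0 / (1 + decay * t)` (t counts
#' parameter updates), categorical cross-entropy loss, Glorot-uniform kernel
#' initialisation and zero biases. Per-sample losses are multiplied by
#' `class_weights[label]`; the weighting `c(1, 32)` trades precision for
#' recall on the cancer class.
#'
#' @param input_width number of input features (default 32).
#' @param hidden_widths widths of the rectifier hidden layers
#'   (default `c(64, 32, 16)`).
#' @param output_width number of classes (default 2).
#' @param learning_rate initial SGD learning rate (default 0.001).
#' @param decay inverse-time decay per update (default 1e-7).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param batch_size mini-batch size (default 32).
#' @param epochs training epochs, at least 1 (default 1280).
#' @param class_weights length-2 positive vector of loss multipliers for
#'   labels 0 and 1 (default `c(1, 1)`).
#' @param seed seed for initialisation and epoch shuffling.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(input_width = 32L, hidden_widths = c(64L, 32L, 16L),
                       output_width = 2L, learning_rate = 0.001,
                       decay = 1e-7, momentum = 0.9, batch_size = 32L,
                       epochs = 1280L, class_weights = c(1, 1), seed = 1L) {
  stopifnot(input_width >= 1L, all(hidden_widths >= 1L), output_width == 2L,
            learning_rate > 0, decay >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1L)
  if (!is.numeric(epochs) || epochs < 1L) {
    stop("epochs must be at least 1", call. = FALSE)
  }
  if (length(class_weights) != 2L || any(class_weights <= 0)) {
    stop("class_weights must be two positive values", call. = FALSE)
  }
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 output_width = as.integer(output_width),
                 learning_rate = learning_rate, decay = decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weights = as.numeric(class_weights),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

layer_widths <- function(config) {
  c(config$input_width, config$hidden_widths, config$output_width)
}

# Glorot-uniform weights, zero biases; consumes the RNG stream
init_layers <- function(config) {
  w <- layer_widths(config)
  lapply(seq_len(length(w) - 1L), function(l) {
    fan_in <- w[l]; fan_out <- w[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -limit, limit),
                    fan_in, fan_out),
         b = numeric(fan_out))
  })
}

# forward pass; returns hidden activations (post-ReLU) and softmax probs
mlp_forward <- function(layers, X) {
  L <- length(layers)
  acts <- vector("list", L)
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- pmax(sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+"), 0)
    acts[[l]] <- A
  }
  Z <- sweep(A %*% layers[[L]]$W, 2L, layers[[L]]$b, "+")
  Z <- Z - apply(Z, 1L, max)                  # log-sum-exp stabilisation
  E <- exp(Z)
  list(acts = acts, probs = E / rowSums(E))
}

#' Fit the class-weighted feed-forward classifier
#'
#' Builds the network of [mlp_config()] and trains it by seeded mini-batch
#' SGD with momentum on labeled feature instances. Normalization statistics
#' (per-feature mean and standard deviation) are computed from the training
#' instances only and stored with the model. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param x numeric matrix or data.frame of features, one row per instance,
#'   `input_width` columns (an instance table from [build_instances()] is
#'   accepted: the [feature_names()] columns are taken); or a formula.
#' @param y labels: 0 (benign hyperplasia) / 1 (prostate cancer), or a
#'   two-level factor.
#' @param config an [mlp_config()].
#' @param ... passed between methods.
#' @return an object of class `enose_mlp`: layer parameters, normalization
#'   statistics, the config snapshot and a per-epoch `history` data.frame
#'   (`epoch`, `loss`, `accuracy`).
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(200 * 32), 200, 32)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- enose_mlp(x, y, mlp_config(epochs = 30, seed = 7))
#' predict(fit, x[1:3, ])
#' @export
enose_mlp <- function(x, ...) UseMethod("enose_mlp")

#' @param formula a two-sided formula such as `label ~ .`, evaluated in
#'   `data`; the response is the label.
#' @param data a data.frame holding the formula's variables.
#' @rdname enose_mlp
#' @export
enose_mlp.formula <- function(formula, data, config = mlp_config(), ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as.matrix(mf[, -1L, drop = FALSE])
  out <- enose_mlp.default(x, y, config = config, ...)
  out$call <- match.call()
  out
}

#' @rdname enose_mlp
#' @export
enose_mlp.default <- function(x, y, config = mlp_config(), ...) {
  stopifnot(inherits(config, "mlp_config"))
  x <- resolve_features(x, config$input_width)
  y <- resolve_labels(y)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y lengths disagree", call. = FALSE)

  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2L, mu)^2))   # population s.d., train only
  sigma[sigma < 1e-8] <- 1                      # constant features pass through
  Xn <- sweep(sweep(x, 2L, mu), 2L, sigma, "/")
  Y <- cbind(y == 0L, y == 1L) * 1
  w_sample <- config$class_weights[y + 1L]

  n <- nrow(Xn)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  layers <- with_seed(config$seed, {
    layers <- init_layers(config)
    vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    L <- length(layers)
    iter <- 0L
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      loss_sum <- 0
      correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xn[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        wb <- w_sample[idx]
        fw <- mlp_forward(layers, Xb)
        P <- fw$probs
        batch_loss <- -sum(wb * log(pmax(rowSums(P * Yb), 1e-12)))
        if (!is.finite(batch_loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        loss_sum <- loss_sum + batch_loss
        correct <- correct + sum((P[, 1L] >= P[, 2L]) == (Yb[, 1L] == 1))
        lr <- config$learning_rate / (1 + config$decay * iter)
        iter <- iter + 1L
        # backprop: delta at softmax/cross-entropy is w*(p - y)/batch
        delta <- (P - Yb) * wb / length(idx)
        for (l in L:1) {
          A_prev <- if (l == 1L) Xb else fw$acts[[l - 1L]]
          gW <- crossprod(A_prev, delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l - 1L]] > 0)
          }
          vel[[l]]$W <- config$momentum * vel[[l]]$W - lr * gW
          vel[[l]]$b <- config$momentum * vel[[l]]$b - lr * gb
          layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
          layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
        }
      }
      history$loss[epoch] <- loss_sum / n
      history$accuracy[epoch] <- correct / n
    }
    layers
  })

  structure(list(layers = layers, norm = list(mean = mu, sd = sigma),
                 config = config, history = history,
                 n_train = n, call = match.call()),
            class = "enose_mlp")
}

resolve_features <- function(x, input_width) {
  if (is.data.frame(x)) {
    if (all(feature_names() %in% names(x)) && input_width == 32L) {
      x <- x[, feature_names(), drop = FALSE]
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  if (ncol(x) != input_width) {
    stop("expected ", input_width, " feature columns, got ", ncol(x),
         call. = FALSE)
  }
  dimnames(x) <- NULL
  x
}

resolve_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop("labels must be 0 (HBP) or 1 (CaP)", call. = FALSE)
  }
  y
}

#' Total number of trainable dense parameters
#' @param object an `enose_mlp` or `mlp_config`.
#' @return integer count of weights plus biases over the dense layers
#'   (normalization statistics are not trainable and are counted separately
#'   as `2 * input_width`).
#' @export
n_parameters <- function(object) {
  config <- if (inherits(object, "enose_mlp")) object$config else object
  w <- layer_widths(config)
  sum(w[-length(w)] * w[-1L] + w[-1L])
}

#' Predict class probabilities or labels
#'
#' Applies the stored normalization and the trained network. Probability rows
#' are nonnegative and sum to 1; hard labels are the argmax, ties resolved to
#' class 0.
#'
#' @param object a fitted [enose_mlp()].
#' @param newdata feature matrix or instance data.frame.
#' @param type `"prob"` for the n x 2 probability matrix (columns `"0"`,
#'   `"1"`), `"class"` for integer labels.
#' @param ... unused.
#' @export
predict.enose_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- resolve_features(newdata, object$config$input_width)
  Xn <- sweep(sweep(x, 2L, object$norm$mean), 2L, object$norm$sd, "/")
  P <- mlp_forward(object$layers, Xn)$probs
  colnames(P) <- c("0", "1")
  if (type == "prob") P else ifelse(P[, 1L] >= P[, 2L], 0L, 1L)
}

#' @export
print.enose_mlp <- function(x, ...) {
  w <- layer_widths(x$config)
  cat("Feed-forward e-nose classifier\n")
  cat("  architecture:", paste(w, collapse = " - "),
      "(ReLU hidden, softmax output, z-score input normalization)\n")
  cat(sprintf("  trained %d epochs on %d instances (batch %d, class weights %s)\n",
              x$config$epochs, x$n_train, x$config$batch_size,
              paste(format(x$config$class_weights, trim = TRUE),
                    collapse = "/")))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n", h$loss, h$accuracy))
  invisible(x)
}

#' @export
summary.enose_mlp <- function(object, ...) {
  w <- layer_widths(object$config)
  layers <- data.frame(
    layer = c(sprintf("dense_%d", seq_len(length(w) - 2L)), "output"),
    input = w[-length(w)], output = w[-1L],
    activation = c(rep("relu", length(w) - 2L), "softmax"),
    parameters = w[-length(w)] * w[-1L] + w[-1L])
  out <- list(layers = layers, n_parameters = n_parameters(object),
              config = object$config, n_train = object$n_train,
              final = object$history[nrow(object$history), ])
  class(out) <- "summary.enose_mlp"
  out
}

#' @export
print.summary.enose_mlp <- function(x, ...) {
  cat("Layers:\n")
  print(x$layers, row.names = FALSE)
  cat(sprintf("Trainable dense parameters: %d (+%d normalization statistics)\n",
              x$n_parameters, 2L * x$config$input_width))
  cat(sprintf("SGD: lr %g, decay %g, momentum %g, batch %d, epochs %d, seed %d\n",
              x$config$learning_rate, x$config$decay, x$config$momentum,
              x$config$batch_size, x$config$epochs, x$config$seed))
  cat(sprintf("Class weights: 0:%g, 1:%g\n", x$config$class_weights[1L],
              x$config$class_weights[2L]))
  cat(sprintf("Final epoch: loss %.4f, training accuracy %.3f\n",
              x$final$loss, x$final$accuracy))
  invisible(x)
}

#' @export
coef.enose_mlp <- function(object, ...) object$layers

#' Plot the training history
#' @param x a fitted [enose_mlp()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.enose_mlp <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "weighted cross-entropy", main = "Training loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = c(0, 1),
                 main = "Training accuracy", ...)
  invisible(x)
}
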