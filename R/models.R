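#' Configuration for the multilayer-perceptron classifier head
#'
#' Defaults follow the reference architecture this package implements: four
#' hidden layers of 1024, 512, 128 and 16 units with ReLU activations, a
#' single sigmoid output trained with binary cross-entropy for 40 epochs.
#' Optimizer settings (Adam, learning rate 1e-3, batch size 64) are
#' conventional choices surfaced here so they can be changed.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param epochs Number of passes over the training data.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param threshold Decision cutoff in (0, 1); scores `>= threshold` are
#'   classified as interactions.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(1024, 512, 128, 16),
                       epochs = 40,
                       learning_rate = 1e-3,
                       batch_size = 64,
                       threshold = 0.5,
                       seed = 1L) {
  if (length(hidden_sizes) == 0 || any(hidden_sizes < 1)) {
    abort("`hidden_sizes` must be a nonempty vector of positive integers.")
  }
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1).")
  }
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    abort("`epochs`, `batch_size` must be >= 1 and `learning_rate` > 0.")
  }
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes),
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      threshold = threshold,
      seed = as.integer(seed)
    ),
    class = "mlp_config"
  )
}

check_training_inputs <- function(x, y) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix of pair features.")
  }
  if (nrow(x) != length(y)) {
    abort("`x` and `y` must have matching lengths.")
  }
  if (!all(y %in% c(0, 1))) {
    abort("Labels must be 0/1.")
  }
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes.")
  }
  if (any(!is.finite(x))) {
    abort("Pair features must be finite.")
  }
  invisible(TRUE)
}

relu <- function(z) z * (z > 0)

# Numerically safe BCE on logits: softplus(z) - y*z, averaged.
bce_from_logits <- function(z, y) {
  sp <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  mean(sp - y * z)
}

#' Train the multilayer-perceptron head
#'
#' Fits a fully connected network with ReLU hidden activations and a single
#' sigmoid output on labeled pair-feature rows, minimizing binary
#' cross-entropy with Adam over shuffled minibatches. Training is fully
#' reproducible under `config$seed`.
#'
#' @param x Numeric matrix of pair features (rows = pairs).
#' @param y Binary labels (0/1), one per row of `x`.
#' @param config An [mlp_config()].
#' @return A `ppi_mlp` model object (also class `ppi_model`) carrying the
#'   learned weights, the input dimensionality, the per-epoch training-loss
#'   history, and the config snapshot.
#' @export
train_mlp <- function(x, y, config = mlp_config()) {
  check_training_inputs(x, y)
  y <- as.numeric(y)
  d <- ncol(x)
  sizes <- c(d, config$hidden_sizes, 1L)
  n_layers <- length(sizes) - 1L

  withr::with_seed(config$seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      # He-normal fan-in initialization for the ReLU stack
      W[[l]] <- matrix(
        rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
        sizes[l], sizes[l + 1]
      )
      b[[l]] <- rep(0, sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0)
    vW <- lapply(W, function(w) w * 0)
    mb <- lapply(b, function(bb) bb * 0)
    vb <- lapply(b, function(bb) bb * 0)
    beta1 <- 0.9
    beta2 <- 0.999
    eps <- 1e-8
    t_step <- 0
    n <- nrow(x)
    loss_history <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        # forward (bias add + ReLU fused in place on the fresh product)
        a <- vector("list", n_layers + 1L)
        a[[1]] <- xb
        for (l in seq_len(n_layers - 1L)) {
          z_l <- a[[l]] %*% W[[l]]
          bias_act_inplace(z_l, b[[l]], TRUE)
          a[[l + 1]] <- z_l
        }
        z <- drop(a[[n_layers]] %*% W[[n_layers]]) + b[[n_layers]]
        epoch_loss <- epoch_loss + bce_from_logits(z, yb) * length(idx)
        # backward
        delta <- matrix((plogis(z) - yb) / length(idx), ncol = 1)
        gW <- vector("list", n_layers)
        gb <- vector("list", n_layers)
        for (l in rev(seq_len(n_layers))) {
          gW[[l]] <- crossprod(a[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- tcrossprod(delta, W[[l]])
            relu_mask_inplace(delta, a[[l]])
          }
        }
        # Adam update, in place per parameter block
        t_step <- t_step + 1
        bc1 <- 1 - beta1^t_step
        bc2 <- 1 - beta2^t_step
        for (l in seq_len(n_layers)) {
          adam_step(
            W[[l]], mW[[l]], vW[[l]], gW[[l]],
            config$learning_rate, bc1, bc2, beta1, beta2, eps
          )
          adam_step(
            b[[l]], mb[[l]], vb[[l]], gb[[l]],
            config$learning_rate, bc1, bc2, beta1, beta2, eps
          )
        }
      }
      loss_history[epoch] <- epoch_loss / n
    }
  })

  structure(
    list(
      head = "mlp",
      weights = W,
      biases = b,
      input_dim = d,
      loss_history = loss_history,
      config = config
    ),
    class = c("ppi_mlp", "ppi_model")
  )
}

mlp_scores <- function(model, x) {
  a <- x
  n_layers <- length(model$weights)
  for (l in seq_len(n_layers - 1L)) {
    a <- relu(sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+"))
  }
  plogis(drop(a %*% model$weights[[n_layers]]) + model$biases[[n_layers]])
}

#' Train the random-forest head
#'
#' A random forest of 100 trees grown to unlimited depth (the reference
#' settings), via \pkg{randomForest}. Scores are class-1 vote fractions,
#' in \[0, 1\].
#'
#' @inheritParams train_mlp
#' @param seed Integer seed.
#' @param ntree Number of trees (default 100).
#' @param threshold Decision cutoff (default 0.5).
#' @return A `ppi_rf` model object (also class `ppi_model`).
#' @export
train_rf <- function(x, y, seed = 1L, ntree = 100, threshold = 0.5) {
  check_training_inputs(x, y)
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = x, y = factor(y, levels = c(0, 1)),
    ntree = ntree
  ))
  structure(
    list(
      head = "rf", fit = fit, input_dim = ncol(x),
      config = list(ntree = ntree, threshold = threshold, seed = seed)
    ),
    class = c("ppi_rf", "ppi_model")
  )
}

#' Train the support-vector-machine head
#'
#' An RBF-kernel SVM with regularization parameter `C = 1` and the
#' variance-scaled kernel coefficient `gamma = 1 / (d * Var(x))` (the
#' reference settings), via \pkg{e1071}. Probability calibration yields
#' scores in \[0, 1\].
#'
#' @inheritParams train_rf
#' @param cost Regularization parameter (default 1).
#' @return A `ppi_svm` model object (also class `ppi_model`).
#' @export
train_svm <- function(x, y, seed = 1L, cost = 1, threshold = 0.5) {
  check_training_inputs(x, y)
  v <- var(as.vector(x))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  # scale = FALSE: the variance-scaled gamma is defined on the raw feature
  # scale; letting svm() rescale internally would detune the kernel width
  fit <- withr::with_seed(seed, e1071::svm(
    x = x, y = factor(y, levels = c(0, 1)),
    kernel = "radial", cost = cost, gamma = gamma,
    probability = TRUE, scale = FALSE
  ))
  structure(
    list(
      head = "svm", fit = fit, input_dim = ncol(x),
      config = list(cost = cost, gamma = gamma, threshold = threshold, seed = seed)
    ),
    class = c("ppi_svm", "ppi_model")
  )
}

model_scores <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_dim) {
    abort(sprintf(
      "Feature dimension %d does not match the model's input dimension %d.",
      ncol(x), model$input_dim
    ))
  }
  if (nrow(x) == 0) {
    return(numeric(0))
  }
  switch(model$head,
    mlp = mlp_scores(model, x),
    rf = unname(predict(model$fit, x, type = "prob")[, "1"]),
    svm = {
      p <- predict(model$fit, x, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    }
  )
}

#' Threshold interaction scores into binary calls
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision cutoff; a score exactly at the threshold is
#'   called positive (the `>=` rule).
#' @return Integer vector of 0/1 labels.
#' @examples
#' classify_scores(c(0.5, 0.499, 1), threshold = 0.5) # 1 0 1
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}

#' Train a PPI classifier on labeled pairs
#'
#' High-level training interface: builds symmetric Hadamard pair features
#' from a labeled pair table and a per-protein feature source, then fits the
#' requested classifier head.
#'
#' @param pairs Labeled pair tibble (`id_a`, `id_b`, `label`).
#' @param features An `embedding_table` (from [load_embeddings()],
#'   [encode_proteins()], or a synthetic world).
#' @param head `"mlp"` (default), `"rf"`, or `"svm"`.
#' @param config An [mlp_config()] (MLP head only).
#' @param seed Seed for the RF / SVM heads (the MLP seed lives in `config`).
#' @return A `ppi_model` object.
#' @export
train_ppi_model <- function(pairs, features, head = c("mlp", "rf", "svm"),
                            config = mlp_config(), seed = 1L) {
  head <- match.arg(head)
  x <- pair_features(pairs, features)
  y <- pairs$label
  switch(head,
    mlp = train_mlp(x, y, config),
    rf = train_rf(x, y, seed = seed),
    svm = train_svm(x, y, seed = seed)
  )
}

#' Score protein pairs with a trained model
#'
#' @param object A `ppi_model`.
#' @param pairs Pair tibble (`id_a`, `id_b`, ...). A `label` column, if
#'   present, is carried through.
#' @param features The per-protein feature source (an `embedding_table`).
#' @param threshold Decision cutoff; defaults to the model's configured one.
#' @param ... Unused.
#' @return A tibble `id_a`, `id_b`, (`label`,) `score` in \[0, 1\],
#'   `predicted` in \{0, 1\}. Scores are invariant to pair-member order.
#' @export
predict.ppi_model <- function(object, pairs, features,
                              threshold = NULL, ...) {
  threshold <- threshold %||% object$config$threshold %||% 0.5
  x <- pair_features(pairs, features)
  s <- model_scores(object, x)
  out <- as_tibble(pairs[, intersect(c("id_a", "id_b", "label"), names(pairs))])
  out$score <- as.numeric(s)
  out$predicted <- classify_scores(out$score, threshold)
  out
}

#' @export
print.ppi_model <- function(x, ...) {
  cat(sprintf(
    "PPI classifier (head = %s, input dim = %d)\n", x$head, x$input_dim
  ))
  if (x$head == "mlp") {
    cat(sprintf(
      "  hidden layers: %s; epochs: %d; final training BCE: %.4f\n",
      paste(x$config$hidden_sizes, collapse = "-"),
      x$config$epochs, x$loss_history[length(x$loss_history)]
    ))
  }
  invisible(x)
}

#' @describeIn train_mlp one-row model summary (architecture, epochs, final
#'   training loss, parameter count).
#' @param x A `ppi_mlp` object.
#' @param ... Unused.
#' @export
glance.ppi_mlp <- function(x, ...) {
  tibble(
    head = "mlp",
    input_dim = x$input_dim,
    hidden = paste(x$config$hidden_sizes, collapse = "-"),
    epochs = x$config$epochs,
    n_parameters = sum(map_dbl(x$weights, length)) + sum(map_dbl(x$biases, length)),
    final_loss = x$loss_history[length(x$loss_history)]
  )
}

#' @describeIn train_mlp per-epoch training-loss history.
#' @export
tidy.ppi_mlp <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}
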