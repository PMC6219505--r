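# Feed-forward Cox risk network: full-batch RMSprop on the Breslow partial
# likelihood, inverted dropout on hidden activations, rectifier activations.

#' Training configuration for the neural risk model
#'
#' Defaults follow the genetic-protein risk model: three hidden layers of
#' 100 rectifier neurons, 25 epochs of full-batch RMSprop at learning rate
#' 1e-3, dropout 10%. The transcriptional model uses 500 neurons per layer
#' (`training_config(n_neurons = 500)`).
#'
#' @param n_layers number of hidden layers (0 gives a linear model).
#' @param n_neurons neurons per hidden layer.
#' @param epochs training epochs (one full-batch update each).
#' @param learning_rate RMSprop learning rate.
#' @param dropout_rate fraction of hidden units dropped per epoch.
#' @param activation `"relu"` or `"identity"`.
#' @param rmsprop_decay decay of the squared-gradient accumulator.
#' @param seed integer seed for weight initialization and dropout masks.
#' @return a `training_config` list.
#' @export
training_config <- function(n_layers = 3L, n_neurons = 100L, epochs = 25L,
                            learning_rate = 1e-3, dropout_rate = 0.10,
                            activation = c("relu", "identity"),
                            rmsprop_decay = 0.9, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(n_layers >= 0, epochs >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_neurons = as.integer(n_neurons),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 dropout_rate = dropout_rate,
                 activation = activation,
                 rmsprop_decay = rmsprop_decay,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train the neural Cox risk model
#'
#' Continuous inputs are z-scored with training-set statistics (binary 0/1
#' columns are left as-is); the network minimizes [cox_partial_loss()] by
#' full-batch RMSprop with fresh dropout masks each epoch. Training is
#' deterministic given the config seed.
#'
#' @param features a [feature_matrix()] (or numeric matrix) without missing
#'   values.
#' @param outcomes a [survival_outcome()] with at least two events.
#' @param config a [training_config()].
#' @return a `risk_model`: layer weights/biases, activation spec, input
#'   normalization parameters, the config snapshot and the per-epoch loss
#'   trace.
#' @export
train_risk_model <- function(features, outcomes, config = training_config()) {
  X <- unclass_matrix(features)
  if (nrow(X) != nrow(outcomes)) stop("features and outcomes are not aligned")
  if (anyNA(X)) stop("features contain missing values; prepare them upstream")
  if (sum(outcomes$event) < 2) stop("need at least two events to train")

  norm <- normalization_params(X)
  Z <- apply_normalization(X, norm)
  time <- outcomes$time; event <- outcomes$event
  n <- nrow(Z); p <- ncol(Z)
  dims <- c(p, rep(config$n_neurons, config$n_layers), 1L)
  L <- length(dims) - 1L

  with_seed(config$seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
             dims[l], dims[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
    vW <- lapply(W, function(w) w * 0)
    vb <- lapply(b, function(x) x * 0)
    rho <- config$rmsprop_decay; lr <- config$learning_rate
    drop_p <- config$dropout_rate
    trace <- numeric(config$epochs)

    for (ep in seq_len(config$epochs)) {
      A <- vector("list", L + 1L); A[[1L]] <- Z
      Mk <- vector("list", L)                 # backprop masks per hidden layer
      for (l in seq_len(L)) {
        pre <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        if (l < L) {
          act_mask <- if (config$activation == "relu") (pre > 0) * 1 else 1
          a <- if (config$activation == "relu") pre * act_mask else pre
          if (drop_p > 0) {
            keep <- matrix(rbinom(length(a), 1L, 1 - drop_p),
                           nrow(a)) / (1 - drop_p)
            a <- a * keep
            Mk[[l]] <- act_mask * keep
          } else Mk[[l]] <- act_mask
          A[[l + 1L]] <- a
        } else {
          A[[l + 1L]] <- pre
        }
      }
      cg <- cox_loss_grad(drop(A[[L + 1L]]), time, event)
      if (!is.finite(cg$loss)) {
        stop("non-finite loss at epoch ", ep, "; lower the learning rate")
      }
      trace[ep] <- cg$loss
      delta <- matrix(cg$grad / n, n, 1L)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        vW[[l]] <- rho * vW[[l]] + (1 - rho) * gW^2
        vb[[l]] <- rho * vb[[l]] + (1 - rho) * gb^2
        W[[l]] <- W[[l]] - lr * gW / (sqrt(vW[[l]]) + 1e-8)
        b[[l]] <- b[[l]] - lr * gb / (sqrt(vb[[l]]) + 1e-8)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * Mk[[l - 1L]]
      }
    }
    structure(list(weights = W, biases = b,
                   activation = config$activation,
                   normalization = norm,
                   feature_names = colnames(X),
                   config = config,
                   loss_trace = trace),
              class = "risk_model")
  })
}

unclass_matrix <- function(x) {
  x <- as.matrix(x)
  class(x) <- "matrix"
  attr(x, "kinds") <- NULL
  storage.mode(x) <- "double"
  x
}

# z-score continuous columns; leave binary 0/1 columns untouched.
normalization_params <- function(X) {
  is_bin <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  mu <- ifelse(is_bin, 0, colMeans(X))
  sdv <- ifelse(is_bin, 1, apply(X, 2, sd))
  sdv[sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_normalization <- function(X, norm) {
  sweep(sweep(X, 2, norm$center), 2, norm$scale, "/")
}

# Forward pass with dropout off; optionally keep pre-activations for
# gradient computation.
forward_pass <- function(model, Z, keep = FALSE) {
  L <- length(model$weights)
  pres <- if (keep) vector("list", L) else NULL
  A <- Z
  for (l in seq_len(L)) {
    pre <- sweep(A %*% model$weights[[l]], 2, model$biases[[l]], "+")
    if (keep) pres[[l]] <- pre
    A <- if (l < L && model$activation == "relu") pmax(pre, 0) else pre
  }
  list(risks = drop(A), pres = pres)
}

#' Predict risk scores from a trained model
#'
#' Dropout is disabled; the returned risks are translation-free scores whose
#' ordering is what the c-index evaluates.
#'
#' @param model a trained `risk_model`.
#' @param features a [feature_matrix()] whose columns match the model's
#'   training schema.
#' @return per-sample numeric risk scores.
#' @export
predict_risk <- function(model, features) {
  X <- unclass_matrix(features)
  if (!is.null(colnames(X)) && !identical(colnames(X), model$feature_names)) {
    stop("feature columns do not match the model's training schema")
  }
  if (ncol(X) != length(model$normalization$center)) {
    stop("feature dimension does not match the model's training schema")
  }
  Z <- apply_normalization(X, model$normalization)
  forward_pass(model, Z)$risks
}

#' Monte-Carlo cross-validation of the neural risk model
#'
#' For each of `n_splits` seeded partitions, 80% of samples train a model
#' and the held-out 20% are scored with Harrell's c-index. Test splits that
#' draw zero events are re-drawn (up to `retry_cap` attempts, logged on the
#' result).
#'
#' @param features,outcomes training data as in [train_risk_model()].
#' @param config a [training_config()]; each split trains with a sub-seed
#'   derived from `seed`.
#' @param n_splits number of random partitions (20 by default).
#' @param train_fraction fraction of samples assigned to training.
#' @param seed master seed for the partitions.
#' @param keep_models retain the per-split trained models (needed for
#'   [cv_prognostic_scores()]).
#' @param retry_cap maximum re-draws for event-free test splits.
#' @return a `cv_result`: per-split c-index values, their median and SD,
#'   split definitions, and optionally the models.
#' @export
monte_carlo_cv <- function(features, outcomes, config = training_config(),
                           n_splits = 20L, train_fraction = 0.8, seed = 1L,
                           keep_models = FALSE, retry_cap = 100L) {
  X <- unclass_matrix(features)
  n <- nrow(X)
  n_train <- floor(train_fraction * n)
  if (n_train < 2 || n_train >= n) stop("degenerate train fraction")
  seeds <- derive_seeds(seed, 2L * n_splits)
  part_seeds <- seeds[seq_len(n_splits)]
  train_seeds <- seeds[n_splits + seq_len(n_splits)]

  cindex <- numeric(n_splits)
  splits <- vector("list", n_splits)
  models <- if (keep_models) vector("list", n_splits) else NULL
  redraws <- 0L
  for (i in seq_len(n_splits)) {
    s <- part_seeds[i]
    for (attempt in seq_len(retry_cap)) {
      idx <- with_seed(s + attempt - 1L, sample.int(n, n_train))
      if (sum(outcomes$event[-idx]) >= 1 && sum(outcomes$event[idx]) >= 2) break
      redraws <- redraws + 1L
      if (attempt == retry_cap) stop("could not draw a test split with events")
    }
    cfg <- config; cfg$seed <- train_seeds[i]
    fit <- train_risk_model(X[idx, , drop = FALSE],
                            outcomes[idx, , drop = FALSE], cfg)
    risks <- predict_risk(fit, X[-idx, , drop = FALSE])
    cindex[i] <- concordance_index(risks, outcomes[-idx, , drop = FALSE])
    splits[[i]] <- list(train = rownames(X)[idx], test = rownames(X)[-idx],
                        seed = s)
    if (keep_models) models[[i]] <- fit
  }
  structure(list(cindex = cindex, median = median(cindex), sd = sd(cindex),
                 splits = splits, models = models, redraws = redraws,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d splits: median c-index %.3f (SD %.3f)\n",
              length(x$cindex), x$median, x$sd))
  invisible(x)
}
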