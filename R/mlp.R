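#' MLP configuration
#'
#' A fully-connected multilayer perceptron over texture features: sigmoid
#' activations in the hidden layers and at the three output units, trained
#' by full-batch gradient descent on a mean-squared-error loss against the
#' one-hot targets (classic backpropagation). Output triples are the three
#' sigmoid activations renormalized to sum to 1.
#'
#' @param input_dim number of input features.
#' @param hidden_layers integer vector of hidden-layer sizes (default
#'   `c(10, 10)`).
#' @param epochs training epochs (default 600).
#' @param learning_rate gradient-descent step size (default 0.8; features
#'   are z-scored internally, which this rate assumes).
#' @param seed RNG seed for the random weight initialization.
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(input_dim, hidden_layers = c(10L, 10L),
                       epochs = 600L, learning_rate = 0.8, seed = 1L) {
  input_dim <- as.integer(input_dim)
  if (is.na(input_dim) || input_dim < 1L)
    stop("`input_dim` must be >= 1", call. = FALSE)
  hidden_layers <- as.integer(hidden_layers)
  if (length(hidden_layers) < 1L || any(hidden_layers < 1L))
    stop("hidden layer sizes must be >= 1", call. = FALSE)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  structure(list(input_dim = input_dim, hidden_layers = hidden_layers,
                 epochs = epochs, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(config) {
  sizes <- c(config$input_dim, config$hidden_layers, 3L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    # Glorot-style uniform init
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; returns per-layer activations (a[[1]] = input)
mlp_forward <- function(params, x) {
  a <- list(x)
  nl <- length(params$W)
  for (l in seq_len(nl)) {
    z <- a[[l]] %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(x), length(params$b[[l]]), byrow = TRUE)
    a[[l + 1L]] <- sigmoid(z)
  }
  a
}

# mean squared error over all output units
mlp_loss <- function(params, x, y) {
  a <- mlp_forward(params, x)
  out <- a[[length(a)]]
  mean((out - y)^2)
}

# backprop gradients of mlp_loss
mlp_grad <- function(params, x, y) {
  a <- mlp_forward(params, x)
  nl <- length(params$W)
  n <- nrow(x)
  out <- a[[nl + 1L]]
  scale <- 2 / (n * ncol(y))          # d/d out of mean((out - y)^2)
  delta <- scale * (out - y) * out * (1 - out)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1L) {
    gW[[l]] <- crossprod(a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$W[[l]])) * a[[l]] * (1 - a[[l]])
  }
  list(W = gW, b = gb)
}

#' Train the texture MLP
#'
#' Features are z-scored with training-set statistics (stored in the model
#' and reapplied at prediction time). Training is deterministic given
#' `config$seed`; the per-epoch loss history is kept in the fitted object.
#'
#' @param features numeric matrix or data frame of training features (any
#'   `label` column is dropped).
#' @param labels class labels, one per row.
#' @param config an [mlp_config]; its `input_dim` must match the feature
#'   count.
#' @return an object of class `mlp_source` with a [predict_proba()] method.
#' @export
train_mlp <- function(features, labels, config) {
  if (is.data.frame(features)) {
    features <- features[setdiff(names(features), "label")]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  if (any(!is.finite(features)))
    stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training set is degenerate: a single class", call. = FALSE)
  if (ncol(features) != config$input_dim)
    stop(sprintf("config expects %d features, got %d", config$input_dim,
                 ncol(features)), call. = FALSE)
  y <- one_hot_encode(labels)

  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  x <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- mlp_init(config)
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    g <- mlp_grad(params, x, y)
    for (l in seq_along(params$W)) {
      params$W[[l]] <- params$W[[l]] - config$learning_rate * g$W[[l]]
      params$b[[l]] <- params$b[[l]] - config$learning_rate * g$b[[l]]
    }
    loss_history[ep] <- mlp_loss(params, x, y)
  }
  structure(list(params = params, config = config, feature_mean = mu,
                 feature_sd = sdv, feature_names = colnames(features),
                 loss_history = loss_history),
            class = c("mlp_source", "probability_source"))
}

#' Class-probability predictions from a trained source
#'
#' Both classifier types (texture MLP and image CNN) satisfy the same
#' contract: inputs of their modality in, one normalized probability triple
#' per input out, in the fixed class order [mass_classes()].
#'
#' @param source a trained `mlp_source` or `cnn_source`.
#' @param inputs feature matrix/data frame (MLP) or list of [gray_image]s
#'   (CNN).
#' @param ... unused.
#' @return an `n x 3` matrix of probabilities, rows summing to 1.
#' @export
predict_proba <- function(source, inputs, ...) UseMethod("predict_proba")

#' @export
predict_proba.mlp_source <- function(source, inputs, ...) {
  if (is.data.frame(inputs)) {
    inputs <- inputs[setdiff(names(inputs), "label")]
    inputs <- as.matrix(inputs)
  }
  storage.mode(inputs) <- "double"
  if (nrow(inputs) == 0L)
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, mass_classes())))
  x <- sweep(sweep(inputs, 2L, source$feature_mean), 2L,
             source$feature_sd, "/")
  a <- mlp_forward(source$params, x)
  out <- a[[length(a)]]
  out <- out / rowSums(out)
  colnames(out) <- mass_classes()
  out
}

#' @export
predict_proba.default <- function(source, inputs, ...)
  stop("`source` is not a trained probability source", call. = FALSE)
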