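# Lightweight dense neural network, trained by Adam with L2 weight decay.
#
# This is the model at the centre of the package: two small rectified-linear
# hidden layers (16 and 8 nodes by default) feeding a single output node —
# logistic-squashed with cross-entropy loss for case/control classification,
# linear with mean-square-error loss for covariate regression. The sample
# sizes this package targets (hundreds of samples, tens to hundreds of
# features) make plain R matrix arithmetic entirely adequate, and keeping the
# trainer self-contained makes every arithmetic step reproducible from the
# seed alone.

#' Specification of the dense neural network
#'
#' @param hidden_sizes integer vector of hidden-layer widths (default
#'   `c(16, 8)`).
#' @param activation hidden activation; only `"relu"` is implemented.
#' @param l2_lambda L2 penalty on the weights (not biases).
#' @param loss `"cross_entropy"` for binary classification (logistic output)
#'   or `"mse"` for regression (linear output, single node, no activation).
#' @param learning_rate Adam step size.
#' @param epochs,batch_size training schedule; mini-batches are reshuffled
#'   each epoch.
#' @param seed integer seed controlling weight initialization and batch
#'   order.
#' @return an `nn_spec` list.
#' @export
nn_spec <- function(hidden_sizes = c(16L, 8L), activation = "relu",
                    l2_lambda = 1e-4, loss = c("cross_entropy", "mse"),
                    learning_rate = 1e-3, epochs = 200L, batch_size = 16L,
                    seed = 1L) {
  loss <- match.arg(loss)
  if (!identical(activation, "relu")) {
    stop("only the rectified-linear activation is implemented", call. = FALSE)
  }
  if (!length(hidden_sizes) || any(hidden_sizes < 1)) {
    stop("hidden_sizes must be a non-empty vector of positive integers",
         call. = FALSE)
  }
  check_scalar_number(l2_lambda, "l2_lambda", min = 0)
  check_scalar_number(learning_rate, "learning_rate", min = 1e-12)
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, l2_lambda = l2_lambda, loss = loss,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "nn_spec")
}

# Train the network. X: numeric matrix (already standardized by the caller),
# target: 0/1 labels (cross_entropy) or numeric response (mse).
nn_train <- function(X, target, spec) {
  check_finite_matrix(X)
  n <- nrow(X)
  sizes <- c(ncol(X), spec$hidden_sizes, 1L)
  L <- length(sizes) - 1L
  lr <- spec$learning_rate; l2 <- spec$l2_lambda
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_seed(spec$seed, {
    W <- vector("list", L); b <- vector("list", L)
    mW <- vW <- vector("list", L); mb <- vb <- vector("list", L)
    for (l in seq_len(L)) {
      # He initialization, suited to rectified-linear units
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                             sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
      mW[[l]] <- vW[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
      mb[[l]] <- vb[[l]] <- numeric(sizes[l + 1L])
    }
    step <- 0L
    for (ep in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      for (s0 in seq(1L, n, by = spec$batch_size)) {
        bi <- idx[s0:min(s0 + spec$batch_size - 1L, n)]
        m <- length(bi)
        A <- vector("list", L + 1L)
        A[[1L]] <- X[bi, , drop = FALSE]
        for (l in seq_len(L)) {
          Z <- A[[l]] %*% W[[l]]
          Z <- Z + rep(b[[l]], rep.int(m, length(b[[l]])))
          A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
        }
        out <- A[[L + 1L]][, 1L]
        delta <- if (spec$loss == "cross_entropy") {
          p <- 1 / (1 + exp(-out))
          matrix((p - target[bi]) / m, m, 1L)
        } else {
          matrix(2 * (out - target[bi]) / m, m, 1L)
        }
        step <- step + 1L
        for (l in L:1L) {
          gW <- crossprod(A[[l]], delta) + l2 * W[[l]]
          gb <- colSums(delta)
          if (l > 1L) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^step)) /
            (sqrt(vW[[l]] / (1 - b2^step)) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - b1^step)) /
            (sqrt(vb[[l]] / (1 - b2^step)) + eps)
        }
      }
    }
    structure(list(W = W, b = b, spec = spec, n_inputs = ncol(X)),
              class = "micromark_nn")
  })
}

# Forward pass. Returns probabilities (cross_entropy) or raw outputs (mse).
nn_forward <- function(fit, X) {
  stopifnot(inherits(fit, "micromark_nn"))
  if (ncol(X) != fit$n_inputs) {
    stop("input has ", ncol(X), " features; network expects ", fit$n_inputs,
         call. = FALSE)
  }
  A <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    A <- A %*% fit$W[[l]]
    A <- A + rep(fit$b[[l]], rep.int(nrow(A), length(fit$b[[l]])))
    if (l < L) A <- pmax(A, 0)
  }
  out <- A[, 1L]
  if (fit$spec$loss == "cross_entropy") 1 / (1 + exp(-out)) else out
}
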