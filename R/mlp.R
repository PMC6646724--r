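## Compact multi-layer perceptron for binary classification: 1 or 2 hidden
## tanh layers, sigmoid output, cross-entropy loss with L2 weight decay,
## trained full-batch with either plain gradient descent or Adam. Kept
## deliberately small: the pipeline's perceptron techniques need exactly this
## and nothing more.

mlp_init <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(fan)),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  A <- list(X)
  L <- length(par$W)
  for (l in seq_len(L)) {
    Zl <- A[[l]] %*% par$W[[l]] + matrix(par$b[[l]], nrow(X), length(par$b[[l]]),
                                         byrow = TRUE)
    A[[l + 1]] <- if (l < L) tanh(Zl) else 1 / (1 + exp(-Zl))
  }
  A
}

mlp_grad <- function(par, A, y, l2) {
  L <- length(par$W)
  n <- length(y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (A[[L + 1]] - y) / n            # d(cross-entropy)/d(logit)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta) + l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(par$W[[l]])) * (1 - A[[l]]^2)
  }
  list(W = gW, b = gb)
}

## optimizer: "batch" = full-batch gradient descent, "adam" = Adam with the
## standard (0.9, 0.999) moment decays.
mlp_fit <- function(X, y, hidden, optimizer = c("batch", "adam"),
                    learning_rate = 0.1, l2 = 1e-4, epochs = 300) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X)
  y <- matrix(as.numeric(y), ncol = 1)
  sizes <- c(ncol(X), hidden, 1)
  par <- mlp_init(sizes)
  L <- length(par$W)
  if (optimizer == "adam") {
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  }
  for (t in seq_len(epochs)) {
    A <- mlp_forward(par, X)
    g <- mlp_grad(par, A, y, l2)
    for (l in seq_len(L)) {
      if (optimizer == "batch") {
        par$W[[l]] <- par$W[[l]] - learning_rate * g$W[[l]]
        par$b[[l]] <- par$b[[l]] - learning_rate * g$b[[l]]
      } else {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
        mhb <- mb[[l]] / (1 - b1^t); vhb <- vb[[l]] / (1 - b2^t)
        par$W[[l]] <- par$W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
        par$b[[l]] <- par$b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  structure(list(par = par), class = "mlp_model")
}

mlp_predict <- function(model, X) {
  A <- mlp_forward(model$par, as.matrix(X))
  as.numeric(A[[length(A)]])
}
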