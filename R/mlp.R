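# Minimal fully-connected network for the thickness regression: ReLU hidden
# layers, linear output, smooth-L1 loss, Adam with L2 weight decay, inverted
# dropout on hidden activations. Written in plain matrix algebra; the
# calibration sets are tiny (<= a few hundred rows) so full-batch training
# is fast and exactly reproducible under a fixed seed.

mlp_init <- function(n_in, widths, n_out) {
  sizes <- c(n_in, widths, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  a <- X
  acts <- vector("list", L)   # pre-activation inputs per layer
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    acts[[l]] <- a
    z <- a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a))
    if (l < L) {
      a <- pmax(z, 0)
      if (training && dropout > 0) {
        keep <- matrix(stats::runif(length(a)) >= dropout,
                       nrow(a), ncol(a))
        a <- a * keep / (1 - dropout)
        masks[[l]] <- keep
      }
    } else a <- z
  }
  list(out = a, acts = acts, masks = masks)
}

# smooth L1 (Huber-like) loss, elementwise mean; beta in scaled-target units
smooth_l1 <- function(r, beta = 1) {
  ifelse(abs(r) < beta, 0.5 * r^2 / beta, abs(r) - 0.5 * beta)
}

mlp_train <- function(X, Y, widths = c(128, 128), dropout = 0.01,
                      l2 = 1e-4, lr = 1e-3, epochs = 2000, beta = 1,
                      seed = 1, lr_decay = TRUE) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  net <- mlp_init(ncol(X), widths, ncol(Y))
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  loss_trace <- numeric(epochs)
  for (t in seq_len(epochs)) {
    # cosine annealing to ~0 stabilizes the final approach to the optimum
    # against dropout-induced gradient noise
    lr_t <- if (lr_decay) lr * 0.5 * (1 + cos(pi * (t - 1) / epochs)) else lr
    fw <- mlp_forward(net, X, dropout = dropout, training = TRUE)
    r <- fw$out - Y
    loss_trace[t] <- mean(smooth_l1(r, beta))
    if (!is.finite(loss_trace[t])) stop("non-finite training loss")
    # d loss / d out for elementwise-mean smooth L1
    g <- pmin(pmax(r / beta, -1), 1) / length(r)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(fw$acts[[l]], g) + l2 * net$W[[l]]
      gb <- colSums(g)
      if (l > 1) {
        g <- g %*% t(net$W[[l]])
        a_prev <- fw$acts[[l]]           # post-activation of layer l-1
        g <- g * (a_prev > 0)
        if (!is.null(fw$masks[[l - 1]]))
          g <- g * fw$masks[[l - 1]] / (1 - dropout)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
      mhb <- mb[[l]] / (1 - b1^t); vhb <- vb[[l]] / (1 - b2^t)
      net$W[[l]] <- net$W[[l]] - lr_t * mhW / (sqrt(vhW) + eps)
      net$b[[l]] <- net$b[[l]] - lr_t * mhb / (sqrt(vhb) + eps)
    }
  }
  list(net = net, loss_trace = loss_trace)
}

mlp_predict <- function(net, X) mlp_forward(net, X)$out

#' Trainable-parameter count of the thickness MLP
#'
#' Weights plus biases of a fully-connected network with `layers` hidden
#' layers of `width` neurons between `n_in` inputs and `n_out` outputs.
#'
#' @param n_in number of input features.
#' @param width hidden-layer width.
#' @param layers number of hidden layers.
#' @param n_out number of outputs.
#' @return integer parameter count.
#' @export
mlp_param_count <- function(n_in, width, layers = 2, n_out = 2) {
  sizes <- c(n_in, rep(width, layers), n_out)
  sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
}
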