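# Minimal multilayer perceptron with tanh hidden layers, used for both
# the Bernoulli excitation policy (sigmoid head) and the value function
# (linear head), trained with Adam. Parameters are plain matrices so the
# whole trainer is dependency-free and bit-reproducible under set.seed().

#' Create a multilayer perceptron
#'
#' Feed-forward network with tanh hidden activations. The policy uses a
#' sigmoid output head producing per-muscle excitation probabilities; the
#' value network a linear scalar head. Weights are initialized with
#' scaled Gaussians (output layer down-scaled so the initial policy is
#' near-uniform).
#'
#' @param sizes Integer vector of layer sizes, input first, output last.
#' @param head `"sigmoid"` or `"linear"`.
#' @param init_scale Multiplier on the output-layer initialization.
#' @return Object of class `mlp`.
#' @export
mlp <- function(sizes, head = c("sigmoid", "linear"), init_scale = 0.01) {
  head <- match.arg(head)
  stopifnot(length(sizes) >= 2)
  nl <- length(sizes) - 1
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    sd <- 1 / sqrt(sizes[l])
    if (l == nl) sd <- sd * init_scale
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes, head = head), class = "mlp")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; X is a matrix (one row per sample) or a vector.
# Returns list(out, cache) where cache holds the layer activations.
mlp_forward <- function(net, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$sizes[1]) {
    stop("input dimension ", ncol(X), " does not match network input ",
         net$sizes[1])
  }
  nl <- length(net$W)
  H <- vector("list", nl + 1)
  H[[1]] <- X
  for (l in seq_len(nl - 1)) {
    H[[l + 1]] <- tanh(sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`))
  }
  Z <- sweep(H[[nl]] %*% net$W[[nl]], 2, net$b[[nl]], `+`)
  out <- switch(net$head, sigmoid = sigmoid(Z), linear = Z)
  list(out = out, cache = H, z_out = Z)
}

# Backward pass: given dL/d(pre-activation output) `dZ`, return gradients.
mlp_backward <- function(net, cache, dZ) {
  nl <- length(net$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- dZ
  for (l in nl:1) {
    gW[[l]] <- crossprod(cache[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - cache[[l]]^2)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(net) {
  list(m = list(W = lapply(net$W, function(w) w * 0),
                b = lapply(net$b, function(x) x * 0)),
       v = list(W = lapply(net$W, function(w) w * 0),
                b = lapply(net$b, function(x) x * 0)),
       t = 0L)
}

adam_step <- function(net, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    for (p in c("W", "b")) {
      g <- grad[[p]][[l]]
      st$m[[p]][[l]] <- beta1 * st$m[[p]][[l]] + (1 - beta1) * g
      st$v[[p]][[l]] <- beta2 * st$v[[p]][[l]] + (1 - beta2) * g^2
      mhat <- st$m[[p]][[l]] / bc1
      vhat <- st$v[[p]][[l]] / bc2
      net[[p]][[l]] <- net[[p]][[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = st)
}
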