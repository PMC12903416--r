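# Minimal dense-network machinery with hand-written backpropagation.
# Layers are stored as named lists of matrices; all math is BLAS-backed
# base-R matrix algebra. No external deep-learning framework is used.

# GELU in its tanh approximation (cheap and smooth); the tanh values are
# cached in the forward pass and reused by the backward pass.
.gelu_k <- sqrt(2 / pi)
.gelu_forward <- function(x) {
  th <- tanh(.gelu_k * (x + 0.044715 * x^3))
  list(y = 0.5 * x * (1 + th), th = th)
}
.gelu_grad_cached <- function(x, th) {
  0.5 * (1 + th) + 0.5 * x * (1 - th^2) * .gelu_k * (1 + 3 * 0.044715 * x^2)
}

.softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-pmax(pmin(x, 700), -700)))

# Default (framework-style) fan-in uniform initialisation.
.init_linear <- function(fan_in, fan_out, init = c("default", "xavier")) {
  init <- match.arg(init)
  if (init == "xavier") {
    sd <- sqrt(2 / (fan_in + fan_out))
    list(W = matrix(stats::rnorm(fan_out * fan_in, sd = sd), fan_out, fan_in),
         b = numeric(fan_out))
  } else {
    bound <- 1 / sqrt(fan_in)
    list(W = matrix(stats::runif(fan_out * fan_in, -bound, bound), fan_out, fan_in),
         b = stats::runif(fan_out, -bound, bound))
  }
}

.add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Trunk of GELU-activated dense layers. `layers` is a list of list(W, b).
.trunk_forward <- function(X, layers) {
  L <- length(layers)
  H <- vector("list", L + 1L); A <- vector("list", L); TH <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A[[l]] <- .add_bias(tcrossprod(H[[l]], layers[[l]]$W), layers[[l]]$b)
    g <- .gelu_forward(A[[l]])
    H[[l + 1L]] <- g$y
    TH[[l]] <- g$th
  }
  list(out = H[[L + 1L]], H = H, A = A, TH = TH)
}

# Backward through the trunk; returns input gradient and per-layer grads.
.trunk_backward <- function(dOut, cache, layers) {
  L <- length(layers)
  grads <- vector("list", L)
  dH <- dOut
  for (l in rev(seq_len(L))) {
    dA <- dH * .gelu_grad_cached(cache$A[[l]], cache$TH[[l]])
    grads[[l]] <- list(W = crossprod(dA, cache$H[[l]]), b = colSums(dA))
    dH <- dA %*% layers[[l]]$W
  }
  list(dX = dH, grads = grads)
}

.linear_forward <- function(X, layer) {
  .add_bias(tcrossprod(X, layer$W), layer$b)
}

.linear_backward <- function(dOut, X, layer) {
  list(dX = dOut %*% layer$W,
       grads = list(W = crossprod(dOut, X), b = colSums(dOut)))
}

.softmax_rows <- function(logits) {
  m <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  e <- exp(logits - m)
  e / rowSums(e)
}

# ---- AdamW -----------------------------------------------------------------

# Parameters and gradients are flat named lists of numeric arrays with
# identical structure.
.adamw_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}

.adamw_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0.01,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Elementwise sum of two flat gradient lists (NULL treated as zero).
.grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
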