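# Minimal fully-connected network machinery: forward pass with inverted
# dropout, reverse-mode gradients (including gradients w.r.t. the input, so
# losses can be chained through downstream networks), and Adam / SGD-momentum
# updates. All randomness draws from R's global RNG so training is
# reproducible from a single seed; gradients are checked against finite
# differences in the test suite.

act_fun <- function(z, act, alpha = 0.2) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         lrelu = ifelse(z > 0, z, alpha * z),
         sigmoid = 1 / (1 + exp(-z)),
         stop("unknown activation: ", act))
}

act_grad <- function(z, a, act, alpha = 0.2) {
  # derivative w.r.t. z; `a` is act(z), reused where cheaper
  switch(act,
         linear = matrix(1, nrow(z), ncol(z)),
         relu = (z > 0) * 1,
         lrelu = ifelse(z > 0, 1, alpha),
         sigmoid = a * (1 - a),
         stop("unknown activation: ", act))
}

#' Create a fully connected network
#'
#' @param sizes Integer vector of layer widths, input first, output last.
#' @param acts Character vector of activations for each non-input layer
#'   (`"linear"`, `"relu"`, `"lrelu"`, `"sigmoid"`).
#' @param dropout Dropout rates applied to each non-input layer's output
#'   during training (0 disables).
#' @param alpha LeakyReLU negative slope.
#' @return An `mlp` object (list of weight matrices and biases).
#' @export
mlp_new <- function(sizes, acts, dropout = rep(0, length(acts)), alpha = 0.2) {
  stopifnot(length(sizes) >= 2, length(acts) == length(sizes) - 1,
            length(dropout) == length(acts))
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- sizes[l]
    sdw <- if (acts[l] %in% c("relu", "lrelu")) sqrt(2 / fan_in)
           else sqrt(1 / fan_in)
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1], 0, sdw), fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1]),
      act = acts[l], drop = dropout[l])
  }
  structure(list(layers = layers, sizes = sizes, alpha = alpha), class = "mlp")
}

#' Forward pass
#'
#' @param net An `mlp`.
#' @param X Input matrix (rows = examples).
#' @param training When `TRUE`, applies inverted dropout using the global
#'   RNG and stores the masks in the cache.
#' @return List with `out` (output activations) and `cache` for
#'   [mlp_backward()].
#' @export
mlp_forward <- function(net, X, training = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == net$sizes[1])
  L <- length(net$layers)
  Zs <- As <- masks <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    Z <- sweep(A %*% ly$W, 2, ly$b, `+`)
    A <- act_fun(Z, ly$act, net$alpha)
    if (training && ly$drop > 0) {
      m <- matrix((runif(length(A)) >= ly$drop) / (1 - ly$drop),
                  nrow(A), ncol(A))
      A <- A * m
      masks[[l]] <- m
    }
    Zs[[l]] <- Z
    As[[l]] <- A
  }
  list(out = A, cache = list(X = X, Zs = Zs, As = As, masks = masks))
}

#' Reverse-mode gradients
#'
#' Backpropagates either `dOut` (gradient of the loss w.r.t. the network
#' output, post-dropout) or `dZ_out` (gradient w.r.t. the output layer's
#' pre-activation, the numerically stable route for sigmoid +
#' cross-entropy).
#'
#' @param net An `mlp`.
#' @param cache Cache from [mlp_forward()].
#' @param dOut,dZ_out Upstream gradient; supply exactly one.
#' @return List with `grads` (per-layer `dW`, `db`) and `dX` (gradient
#'   w.r.t. the network input).
#' @export
mlp_backward <- function(net, cache, dOut = NULL, dZ_out = NULL) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    if (l == L && !is.null(dZ_out)) {
      dZ <- dZ_out
    } else {
      if (!is.null(cache$masks[[l]])) dA <- dA * cache$masks[[l]]
      pre_drop <- act_fun(cache$Zs[[l]], ly$act, net$alpha)
      dZ <- dA * act_grad(cache$Zs[[l]], pre_drop, ly$act, net$alpha)
    }
    A_prev <- if (l == 1) cache$X else cache$As[[l - 1]]
    grads[[l]] <- list(dW = crossprod(A_prev, dZ), db = colSums(dZ))
    dA <- tcrossprod(dZ, ly$W)
  }
  list(grads = grads, dX = dA)
}

sum_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (l in seq_along(g1)) {
    g1[[l]]$dW <- g1[[l]]$dW + g2[[l]]$dW
    g1[[l]]$db <- g1[[l]]$db + g2[[l]]$db
  }
  g1
}

#' Optimizer state constructors and update steps
#'
#' `opt_adam`/`opt_sgd_momentum` create state for a network; the matching
#' `*_step` functions apply one parameter update in place and return the
#' updated `(net, state)`.
#'
#' @param net An `mlp`.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param momentum SGD momentum coefficient.
#' @return Optimizer state (list), or for the `*_step` functions a list
#'   `(net, state)`.
#' @export
opt_adam <- function(net, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- lapply(net$layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
  list(kind = "adam", lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0, layers = st)
}

#' @rdname opt_adam
#' @param grads Gradients from [mlp_backward()].
#' @param state Optimizer state.
#' @export
opt_adam_step <- function(net, grads, state) {
  state$t <- state$t + 1
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (l in seq_along(net$layers)) {
    s <- state$layers[[l]]; g <- grads[[l]]
    s$mW <- state$beta1 * s$mW + (1 - state$beta1) * g$dW
    s$vW <- state$beta2 * s$vW + (1 - state$beta2) * g$dW^2
    s$mb <- state$beta1 * s$mb + (1 - state$beta1) * g$db
    s$vb <- state$beta2 * s$vb + (1 - state$beta2) * g$db^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      state$lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + state$eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      state$lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + state$eps)
    state$layers[[l]] <- s
  }
  list(net = net, state = state)
}

#' @rdname opt_adam
#' @export
opt_sgd_momentum <- function(net, lr = 1e-4, momentum = 0.9) {
  st <- lapply(net$layers, function(ly) list(vW = ly$W * 0, vb = ly$b * 0))
  list(kind = "sgd", lr = lr, momentum = momentum, layers = st)
}

#' @rdname opt_adam
#' @export
opt_sgd_step <- function(net, grads, state) {
  for (l in seq_along(net$layers)) {
    s <- state$layers[[l]]; g <- grads[[l]]
    s$vW <- state$momentum * s$vW - state$lr * g$dW
    s$vb <- state$momentum * s$vb - state$lr * g$db
    net$layers[[l]]$W <- net$layers[[l]]$W + s$vW
    net$layers[[l]]$b <- net$layers[[l]]$b + s$vb
    state$layers[[l]] <- s
  }
  list(net = net, state = state)
}

#' Binary cross-entropy loss
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Binary targets.
#' @return Mean BCE; finite for non-saturated `p` (predictions are clamped
#'   away from 0/1 by 1e-12 for the loss value).
#' @export
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradient of mean BCE w.r.t. the sigmoid pre-activation
bce_dz <- function(p, y) (p - y) / length(p)
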