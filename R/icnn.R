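#' Input-convex neural networks (dual potentials)
#'
#' An input-convex neural network (ICNN) is a feed-forward network
#' \deqn{h_{i+1} = \sigma_i(W_i^x x + W_i^z h_i + b_i), \qquad f(x) = h_L,}
#' whose output is convex in its input `x` provided every hidden-to-hidden
#' weight matrix \eqn{W_i^z} is elementwise non-negative and every activation
#' \eqn{\sigma_i} is convex and non-decreasing. The first hidden layer has no
#' \eqn{W^z} term; the final layer is linear. ICNNs parameterize the convex
#' Kantorovich dual potentials whose gradient is the transport map.
#'
#' @param input_dim Number of input features (d >= 1).
#' @param hidden_widths Integer vector of hidden-layer widths. The default,
#'   four hidden layers of width 64, is the reference architecture.
#' @param activation `"softplus"` (default) or `"leaky_relu"`. Both are convex
#'   and non-decreasing; the leaky rectifier uses `slope` on its negative part.
#'   Softplus is preferred where the gradient of the potential is the object
#'   of interest: a piecewise-linear potential has a piecewise-constant
#'   gradient, which approximates smooth transport maps poorly.
#' @param slope Negative-part slope of the leaky rectifier (must lie in
#'   `[0, 1]` so the activation stays convex and non-decreasing; 1 gives the
#'   identity activation).
#' @param seed Integer seed; construction is deterministic given the seed.
#'
#' @details Hidden-to-hidden weights are initialized to the absolute value of
#'   centred Gaussian draws scaled by fan-in, so a freshly built network is
#'   always convex; input weights are unconstrained Gaussian draws.
#'
#' @return An object of class `icnn`: a list with elements `input_dim`,
#'   `widths`, `Wx` (per-layer input weights, `d x width`), `Wz` (per-layer
#'   non-negative hidden weights, `NULL` for the first layer), `b` (biases),
#'   `activation`, `slope`, `seed`.
#' @examples
#' net <- icnn_init(2, seed = 1)
#' icnn_forward(net, matrix(rnorm(10), 5, 2))
#' @export
icnn_init <- function(input_dim, hidden_widths = rep(64L, 4L),
                      activation = c("softplus", "leaky_relu"),
                      slope = 0.2, seed = 0L) {
  activation <- match.arg(activation)
  if (length(input_dim) != 1L || is.na(input_dim) || input_dim < 1)
    stop("`input_dim` must be a positive integer.", call. = FALSE)
  if (length(hidden_widths) < 1L || any(hidden_widths < 1))
    stop("`hidden_widths` must be a non-empty vector of positive integers.",
         call. = FALSE)
  if (slope < 0 || slope > 1)
    stop("`slope` must lie in [0, 1].", call. = FALSE)
  input_dim <- as.integer(input_dim)
  widths <- c(as.integer(hidden_widths), 1L)
  n_layers <- length(widths)
  Wx <- vector("list", n_layers)
  Wz <- vector("list", n_layers)
  b <- vector("list", n_layers)
  with_seed(seed, {
    for (i in seq_len(n_layers)) {
      Wx[[i]] <- matrix(stats::rnorm(input_dim * widths[i], sd = 1 / sqrt(input_dim)),
                        input_dim, widths[i])
      if (i > 1L) {
        fan_in <- widths[i - 1L]
        Wz[[i]] <- abs(matrix(stats::rnorm(fan_in * widths[i], sd = 1 / sqrt(fan_in)),
                              fan_in, widths[i]))
      }
      b[[i]] <- rep(0, widths[i])
    }
  })
  structure(
    list(input_dim = input_dim, widths = widths, Wx = Wx, Wz = Wz, b = b,
         activation = activation, slope = slope, seed = as.integer(seed)),
    class = "icnn"
  )
}

#' @export
print.icnn <- function(x, ...) {
  cat(sprintf(
    "<icnn> %d -> [%s] -> 1, activation = %s, penalty(Wz<0) = %.3g\n",
    x$input_dim, paste(utils::head(x$widths, -1L), collapse = ", "),
    x$activation, negativity_penalty(x)))
  invisible(x)
}

act_fun <- function(net) {
  if (net$activation == "leaky_relu") {
    s <- net$slope
    list(
      f  = function(z) pmax(z, 0) + s * pmin(z, 0),
      d1 = function(z) ifelse(z > 0, 1, s),
      d2 = function(z) 0 * z
    )
  } else {
    list(
      f  = function(z) log1p(exp(-abs(z))) + pmax(z, 0),
      d1 = function(z) stats::plogis(z),
      d2 = function(z) { p <- stats::plogis(z); p * (1 - p) }
    )
  }
}

# Coerce a batch to an n x d matrix, checking the width.
as_icnn_batch <- function(net, x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = net$input_dim)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != net$input_dim)
    stop(sprintf("batch has width %d but the network expects %d features",
                 ncol(x), net$input_dim), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Full forward pass keeping pre-activations and activations for reuse by the
# gradient and training routines.
icnn_forward_cache <- function(net, X) {
  L <- length(net$widths)
  a <- act_fun(net)
  n <- nrow(X)
  Z <- vector("list", L)
  H <- vector("list", L)
  for (i in seq_len(L)) {
    Zi <- X %*% net$Wx[[i]]
    if (i > 1L) Zi <- Zi + H[[i - 1L]] %*% net$Wz[[i]]
    Zi <- Zi + rep(net$b[[i]], each = n)
    Z[[i]] <- Zi
    H[[i]] <- if (i < L) a$f(Zi) else Zi  # final layer linear
  }
  list(Z = Z, H = H, value = H[[L]][, 1L])
}

#' Evaluate an input-convex network
#'
#' @param net An [icnn_init()] object.
#' @param x A numeric matrix or data frame of shape `n x input_dim` (a bare
#'   vector is taken as one batch of `input_dim`-vectors).
#' @return `icnn_forward()`: a numeric vector of length `n` (the scalar
#'   potential per row). `icnn_gradient()`: an `n x input_dim` matrix with the
#'   exact gradient of the potential at each row; this gradient is the
#'   transport map when the network plays the role of the potential `g`.
#' @examples
#' net <- icnn_init(3, c(8, 8), seed = 2)
#' x <- matrix(rnorm(15), 5, 3)
#' icnn_forward(net, x)
#' icnn_gradient(net, x)
#' @export
icnn_forward <- function(net, x) {
  X <- as_icnn_batch(net, x)
  icnn_forward_cache(net, X)$value
}

# Reverse pass for the input-gradient given a forward cache.
icnn_gradient_cache <- function(net, X, cache) {
  L <- length(net$widths)
  a <- act_fun(net)
  n <- nrow(X)
  G <- matrix(1, n, 1L)        # seed on the scalar output
  grad <- G %*% t(net$Wx[[L]])
  for (i in seq(L - 1L, 1L)) {
    GH <- G %*% t(net$Wz[[i + 1L]])
    G <- a$d1(cache$Z[[i]]) * GH
    grad <- grad + G %*% t(net$Wx[[i]])
  }
  grad
}

#' @rdname icnn_forward
#' @export
icnn_gradient <- function(net, x) {
  X <- as_icnn_batch(net, x)
  icnn_gradient_cache(net, X, icnn_forward_cache(net, X))
}

#' Potential interface
#'
#' Generic accessors used wherever a scalar potential and its gradient map
#' are consumed (dual objectives, [transport()], diagnostics). The `icnn`
#' methods delegate to [icnn_forward()] / [icnn_gradient()]; other convex
#' potentials (e.g. closed-form quadratics in validation code) can plug in
#' by providing methods.
#'
#' @param potential A potential object (an `icnn`, or any class with
#'   methods).
#' @param x An `n x d` batch.
#' @return `potential_value()`: length-`n` numeric; `potential_gradient()`:
#'   `n x d` matrix.
#' @export
potential_value <- function(potential, x) UseMethod("potential_value")

#' @rdname potential_value
#' @export
potential_value.icnn <- function(potential, x) icnn_forward(potential, x)

#' @rdname potential_value
#' @export
potential_gradient <- function(potential, x) UseMethod("potential_gradient")

#' @rdname potential_value
#' @export
potential_gradient.icnn <- function(potential, x) icnn_gradient(potential, x)

#' Convexity-constraint penalty and projection
#'
#' Convexity of an ICNN requires non-negative hidden-to-hidden weights.
#' `negativity_penalty()` returns the soft relaxation used while training the
#' potential `g`: the sum over layers of the squared Frobenius norm of the
#' negative parts, \eqn{\sum_l \| \max(-W_l^z, 0) \|_F^2}.
#' `project_nonnegative()` enforces the constraint exactly (used for the
#' potential `f` after every update) by clamping negative entries to zero; it
#' is idempotent and leaves all other parameters untouched.
#'
#' @param net An `icnn` object.
#' @return `negativity_penalty()`: a non-negative scalar.
#'   `project_nonnegative()`: the projected `icnn`.
#' @examples
#' net <- icnn_init(2, c(4, 4), seed = 0)
#' negativity_penalty(net)          # 0: initialization is convex
#' net$Wz[[2]][1, 1] <- -2
#' negativity_penalty(net)          # 4
#' negativity_penalty(project_nonnegative(net))  # 0
#' @export
negativity_penalty <- function(net) UseMethod("negativity_penalty")

#' @rdname negativity_penalty
#' @export
negativity_penalty.icnn <- function(net) {
  tot <- 0
  for (W in net$Wz) if (!is.null(W)) tot <- tot + sum(pmin(W, 0)^2)
  tot
}

#' @rdname negativity_penalty
#' @export
project_nonnegative <- function(net) {
  for (i in seq_along(net$Wz))
    if (!is.null(net$Wz[[i]])) net$Wz[[i]][net$Wz[[i]] < 0] <- 0
  net
}

#' Empirically audit convexity of a network
#'
#' Samples random pairs in a box and counts violations of midpoint convexity
#' \eqn{f((x+y)/2) \le (f(x)+f(y))/2 + tol}. A network with non-negative
#' hidden weights and a convex non-decreasing activation must report zero
#' violations (up to floating-point tolerance).
#'
#' @param net An `icnn` object.
#' @param n_pairs Number of random pairs to draw (>= 1).
#' @param box Half-width of the sampling box, pairs are drawn uniformly in
#'   `[-box, box]^d`.
#' @param seed Integer seed for the pair draws.
#' @param tol Slack added to the right-hand side before counting a violation.
#' @return A list with `violations` (count) and `max_gap` (the largest value
#'   of \eqn{f((x+y)/2) - (f(x)+f(y))/2} observed; negative when convexity
#'   holds strictly).
#' @examples
#' check_convexity(icnn_init(2, c(8, 8), seed = 1), n_pairs = 100, seed = 9)
#' @export
check_convexity <- function(net, n_pairs = 1000L, box = 3, seed = 0L,
                            tol = 1e-8) {
  if (n_pairs < 1) stop("`n_pairs` must be >= 1.", call. = FALSE)
  d <- net$input_dim
  with_seed(seed, {
    X <- matrix(stats::runif(n_pairs * d, -box, box), n_pairs, d)
    Y <- matrix(stats::runif(n_pairs * d, -box, box), n_pairs, d)
  })
  gap <- icnn_forward(net, (X + Y) / 2) -
    (icnn_forward(net, X) + icnn_forward(net, Y)) / 2
  list(violations = sum(gap > tol), max_gap = max(gap))
}

## ---- parameter gradients (used by the dual training loop) -----------------

# Flat list view of the trainable arrays, in a fixed order shared with the
# Adam state. Names double as checkpoint keys.
icnn_param_list <- function(net) {
  L <- length(net$widths)
  out <- list()
  for (i in seq_len(L)) {
    out[[paste0("Wx", i)]] <- net$Wx[[i]]
    if (i > 1L) out[[paste0("Wz", i)]] <- net$Wz[[i]]
    out[[paste0("b", i)]] <- net$b[[i]]
  }
  out
}

icnn_set_params <- function(net, params) {
  L <- length(net$widths)
  for (i in seq_len(L)) {
    net$Wx[[i]] <- params[[paste0("Wx", i)]]
    if (i > 1L) net$Wz[[i]] <- params[[paste0("Wz", i)]]
    net$b[[i]] <- as.numeric(params[[paste0("b", i)]])
  }
  net
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# Gradients of sum_j c_j * f(x_j) with respect to all parameters.
# `cache` must come from icnn_forward_cache(net, X); `cvec` has length nrow(X).
icnn_value_param_grads <- function(net, X, cache, cvec) {
  L <- length(net$widths)
  a <- act_fun(net)
  g <- list()
  G <- matrix(cvec, ncol = 1L)
  for (i in seq(L, 1L)) {
    g[[paste0("Wx", i)]] <- crossprod(X, G)
    g[[paste0("b", i)]] <- colSums(G)
    if (i > 1L) {
      g[[paste0("Wz", i)]] <- crossprod(cache$H[[i - 1L]], G)
      GH <- G %*% t(net$Wz[[i]])
      G <- a$d1(cache$Z[[i - 1L]]) * GH
    }
  }
  g
}

# Gradients of sum_j u_j . grad_x f(x_j) with respect to all parameters
# (forward-over-reverse). U is n x d; fold any scaling (e.g. 1/n) into U.
# Needed because the dual objective differentiates through the gradient map:
# d/d(theta) of f_phi(grad g_theta(x)) and <x, grad g_theta(x)> are gradients
# of gradient-vector products of g.
icnn_gvp_param_grads <- function(net, X, cache, U) {
  L <- length(net$widths)
  a <- act_fun(net)
  n <- nrow(X)
  # tangent forward: directional derivative of each layer along U
  Zdot <- vector("list", L)
  Hdot <- vector("list", L)
  d1 <- vector("list", L)
  d2 <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    zd <- U %*% net$Wx[[i]]
    if (i > 1L) zd <- zd + Hdot[[i - 1L]] %*% net$Wz[[i]]
    Zdot[[i]] <- zd
    d1[[i]] <- a$d1(cache$Z[[i]])
    d2[[i]] <- a$d2(cache$Z[[i]])
    Hdot[[i]] <- d1[[i]] * zd
  }
  g <- list()
  # final (linear) layer: sdot = U Wx_L + Hdot_{L-1} Wz_L
  Gsd <- matrix(1, n, 1L)
  g[[paste0("Wx", L)]] <- crossprod(U, Gsd)
  g[[paste0("Wz", L)]] <- crossprod(Hdot[[L - 1L]], Gsd)
  g[[paste0("b", L)]] <- 0 * net$b[[L]]
  GHdot <- Gsd %*% t(net$Wz[[L]])
  GH <- NULL  # gradient w.r.t. the primal activation, appears once sigma'' does
  for (i in seq(L - 1L, 1L)) {
    GZdot <- d1[[i]] * GHdot
    GZ <- d2[[i]] * Zdot[[i]] * GHdot
    if (!is.null(GH)) GZ <- GZ + d1[[i]] * GH
    gWx <- crossprod(U, GZdot) + crossprod(X, GZ)
    gb <- colSums(GZ)
    if (i > 1L) {
      gWz <- crossprod(Hdot[[i - 1L]], GZdot) + crossprod(cache$H[[i - 1L]], GZ)
      GHdot <- GZdot %*% t(net$Wz[[i]])
      GH <- GZ %*% t(net$Wz[[i]])
      g[[paste0("Wz", i)]] <- gWz
    }
    g[[paste0("Wx", i)]] <- gWx
    g[[paste0("b", i)]] <- gb
  }
  g
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk * gk
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

## ---- misc -----------------------------------------------------------------

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
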