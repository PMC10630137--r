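#' Autoencoder configuration
#'
#' Describes a symmetric multilayer-perceptron autoencoder used to embed
#' high-dimensional expression profiles into a low-dimensional latent space
#' (default 50) in which the transport map is learned. The decoder mirrors
#' the encoder widths.
#'
#' @param latent_dim Latent dimensionality (must be below the feature count
#'   of the data it is trained on).
#' @param hidden_widths Encoder hidden widths (`c()` gives a linear
#'   encoder/decoder pair, whose optimum spans the top principal subspace).
#' @param activation `"leaky_relu"`, `"softplus"`, or `"linear"` for hidden
#'   layers; the latent and output layers are always linear.
#' @param slope Negative-part slope for the leaky rectifier.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of cells held out to report validation
#'   reconstruction error (and to select configurations).
#' @param seed Integer seed.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(latent_dim = 50L, hidden_widths = c(128L),
                      activation = c("leaky_relu", "softplus", "linear"),
                      slope = 0.2, lr = 1e-3, epochs = 50L, batch_size = 128L,
                      val_fraction = 0.1, seed = 0L) {
  activation <- match.arg(activation)
  stopifnot(latent_dim >= 1, lr > 0, epochs >= 1, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_widths = as.integer(hidden_widths),
                 activation = activation, slope = slope, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ae_config")
}

ae_act <- function(cfg) {
  switch(cfg$activation,
         linear = list(f = identity, d1 = function(z) 1 + 0 * z),
         leaky_relu = list(
           f = function(z) pmax(z, 0) + cfg$slope * pmin(z, 0),
           d1 = function(z) ifelse(z > 0, 1, cfg$slope)),
         softplus = list(
           f = function(z) log1p(exp(-abs(z))) + pmax(z, 0),
           d1 = function(z) stats::plogis(z)))
}

ae_widths <- function(cfg, d) {
  c(d, cfg$hidden_widths, cfg$latent_dim, rev(cfg$hidden_widths), d)
}

# layers whose output gets the nonlinearity: hidden widths only (latent and
# reconstruction layers stay linear so a linear AE can recover PCA exactly)
ae_act_layers <- function(cfg) {
  k <- length(cfg$hidden_widths)
  setdiff(seq_len(2 * k + 2), c(k + 1L, 2 * k + 2L))
}

ae_forward <- function(weights, cfg, X, upto = length(weights$W)) {
  a <- ae_act(cfg)
  act_on <- ae_act_layers(cfg)
  H <- X
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    Z <- H %*% weights$W[[i]] + rep(weights$b[[i]], each = nrow(H))
    caches[[i]] <- list(input = H, Z = Z)
    H <- if (i %in% act_on) a$f(Z) else Z
  }
  list(out = H, caches = caches)
}

#' Train an autoencoder on a cell population
#'
#' Minimizes the mean squared reconstruction error with Adam. Training is
#' deterministic given the config seed. All conditions' training cells
#' should be passed jointly, so that one shared embedding serves control and
#' perturbed populations alike.
#'
#' @param data A cell population, data frame, or matrix (cells by features).
#' @param config An [ae_config()].
#' @return An object of class `autoencoder`: weights, the config, feature
#'   names, and final `train_error` / `val_error` (mean squared error).
#' @export
fit_autoencoder <- function(data, config = ae_config()) {
  p <- as_pop_matrix(data)
  X <- p$X
  cfg <- config
  if (nrow(X) == 0) stop("`data` has no cells", call. = FALSE)
  if (cfg$latent_dim >= ncol(X))
    stop(sprintf("latent_dim = %d must be below the feature count (%d)",
                 cfg$latent_dim, ncol(X)), call. = FALSE)
  widths <- ae_widths(cfg, ncol(X))
  L <- length(widths) - 1L
  weights <- NULL
  with_seed(cfg$seed, {
    W <- lapply(seq_len(L), function(i)
      matrix(stats::rnorm(widths[i] * widths[i + 1], sd = 1 / sqrt(widths[i])),
             widths[i], widths[i + 1]))
    b <- lapply(seq_len(L), function(i) rep(0, widths[i + 1]))
    weights <- list(W = W, b = b)
    n_val <- floor(nrow(X) * cfg$val_fraction)
    val_idx <- if (n_val > 0) sample.int(nrow(X), n_val) else integer(0)
    Xtr <- if (length(val_idx)) X[-val_idx, , drop = FALSE] else X
    Xval <- X[val_idx, , drop = FALSE]
    params <- c(stats::setNames(weights$W, paste0("W", seq_len(L))),
                stats::setNames(weights$b, paste0("b", seq_len(L))))
    state <- adam_init(params)
    a <- ae_act(cfg)
    act_on <- ae_act_layers(cfg)
    bs <- min(cfg$batch_size, nrow(Xtr))
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(nrow(Xtr))
      for (start in seq(1, nrow(Xtr) - bs + 1, by = bs)) {
        Xb <- Xtr[perm[start:(start + bs - 1)], , drop = FALSE]
        fw <- ae_forward(weights, cfg, Xb)
        G <- 2 * (fw$out - Xb) / length(Xb)
        grads <- list()
        for (i in seq(L, 1)) {
          cache <- fw$caches[[i]]
          if (i %in% act_on) G <- G * a$d1(cache$Z)
          grads[[paste0("W", i)]] <- crossprod(cache$input, G)
          grads[[paste0("b", i)]] <- colSums(G)
          if (i > 1) G <- G %*% t(weights$W[[i]])
        }
        st <- adam_step(params, grads, state, cfg$lr, 0.9, 0.999)
        params <- st$params; state <- st$state
        weights$W <- unname(params[paste0("W", seq_len(L))])
        weights$b <- unname(params[paste0("b", seq_len(L))])
      }
    }
    train_error <- mean((ae_forward(weights, cfg, Xtr)$out - Xtr)^2)
    val_error <- if (length(val_idx))
      mean((ae_forward(weights, cfg, Xval)$out - Xval)^2) else NA_real_
  })
  structure(list(weights = weights, config = cfg,
                 feature_names = p$features %||% paste0("feature_", seq_len(ncol(X))),
                 input_dim = ncol(X),
                 train_error = train_error, val_error = val_error),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf(
    "<autoencoder> %d -> %d (hidden: %s), train mse %.4g, val mse %.4g\n",
    x$input_dim, x$config$latent_dim,
    paste(x$config$hidden_widths, collapse = ", "),
    x$train_error, x$val_error))
  invisible(x)
}

#' Encode and decode cell populations
#'
#' `encode()` maps cells into the autoencoder's latent space (annotations
#' preserved, latent features named `latent_1 ...`); `decode()` maps latent
#' populations back to the feature space, restoring the training feature
#' names.
#'
#' @param ae A fitted [fit_autoencoder()].
#' @param cells A population / data frame / matrix of the appropriate width.
#' @return A tibble (or matrix, matching the input container).
#' @export
encode <- function(ae, cells) {
  p <- as_pop_matrix(cells)
  if (ncol(p$X) != ae$input_dim)
    stop(sprintf("cells have width %d but the encoder expects %d",
                 ncol(p$X), ae$input_dim), call. = FALSE)
  k <- length(ae$config$hidden_widths) + 1L
  Zl <- ae_forward(ae$weights, ae$config, p$X, upto = k)$out
  colnames(Zl) <- paste0("latent_", seq_len(ncol(Zl)))
  if (is.data.frame(cells)) {
    out <- dplyr::bind_cols(pop_annotations(cells),
                            tibble::as_tibble(Zl, .name_repair = "minimal"))
    class(out) <- class(cells)
    out
  } else Zl
}

#' @rdname encode
#' @param latent A latent population from [encode()].
#' @export
decode <- function(ae, latent) {
  p <- as_pop_matrix(latent)
  if (ncol(p$X) != ae$config$latent_dim)
    stop(sprintf("latent cells have width %d but latent_dim is %d",
                 ncol(p$X), ae$config$latent_dim), call. = FALSE)
  k <- length(ae$config$hidden_widths) + 1L
  L <- length(ae$weights$W)
  a <- ae_act(ae$config)
  act_on <- ae_act_layers(ae$config)
  H <- p$X
  for (i in seq(k + 1L, L)) {
    Z <- H %*% ae$weights$W[[i]] + rep(ae$weights$b[[i]], each = nrow(H))
    H <- if (i %in% act_on) a$f(Z) else Z
  }
  colnames(H) <- ae$feature_names
  if (is.data.frame(latent)) {
    out <- dplyr::bind_cols(pop_annotations(latent),
                            tibble::as_tibble(H, .name_repair = "minimal"))
    class(out) <- class(latent)
    out
  } else H
}

#' Reconstruction error over non-zero entries
#'
#' Mean squared error between input and reconstruction computed only over
#' entries that are non-zero in the input. Zero entries of sparse expression
#' matrices mostly encode dropout, so configuration selection scores only
#' the observed signal.
#'
#' @param ae A fitted autoencoder.
#' @param cells Cells to reconstruct.
#' @return A scalar MSE.
#' @export
reconstruction_error_nonzero <- function(ae, cells) {
  p <- as_pop_matrix(cells)
  R <- ae_forward(ae$weights, ae$config, p$X)$out
  mask <- p$X != 0
  if (!any(mask))
    stop("input has no non-zero entries; the masked error is undefined",
         call. = FALSE)
  mean((R[mask] - p$X[mask])^2)
}

#' Grid-search autoencoder configurations
#'
#' Trains every configuration in the grid on `data` and returns the fitted
#' autoencoder with the smallest non-zero-masked reconstruction error on its
#' validation split; ties are broken by grid order.
#'
#' @param data Training cells.
#' @param grid A list of [ae_config()] objects.
#' @return The winning fitted `autoencoder`, with attribute `"scores"`
#'   (per-config validation errors).
#' @export
select_ae_config <- function(data, grid) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  p <- as_pop_matrix(data)
  scores <- numeric(length(grid))
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    fit <- fit_autoencoder(data, cfg)
    n_val <- floor(nrow(p$X) * cfg$val_fraction)
    val_idx <- if (n_val > 0) with_seed(cfg$seed, sample.int(nrow(p$X), n_val))
      else seq_len(nrow(p$X))
    scores[i] <- reconstruction_error_nonzero(fit, p$X[val_idx, , drop = FALSE])
    fits[[i]] <- fit
  }
  best <- which.min(scores)      # which.min takes the first on ties
  out <- fits[[best]]
  attr(out, "scores") <- scores
  out
}
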