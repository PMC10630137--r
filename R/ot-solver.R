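#' Training configuration for the dual-potential solver
#'
#' Collects the optimizer and schedule hyperparameters of the alternating
#' max-min training of the potential pair `(g, f)`. Defaults follow the
#' reference setting: Adam with learning rate 1e-4 and betas (0.5, 0.9),
#' batch size 256, convexity-penalty weight `lambda = 1`, and one `f` update
#' per ten inner `g` updates. `n_iter` counts outer `f` updates; the
#' desk-scale default is 10,000 (full-scale runs in the reference setting use
#' 250,000).
#'
#' @param batch_size Minibatch size (capped at the population size).
#' @param lr Adam learning rate for both potentials.
#' @param beta1,beta2 Adam moment decay rates.
#' @param lambda Weight of the negativity penalty on `g`'s hidden weights.
#' @param inner_g_steps Number of `g` minimization steps per outer iteration.
#' @param n_iter Number of outer iterations (one `f` update each).
#' @param hidden_widths ICNN hidden widths for both potentials.
#' @param activation,slope Activation spec passed to [icnn_init()].
#' @param warmstart_steps Iterations of the identity warm-start (fitting
#'   \eqn{\nabla g \approx \mathrm{id}} on source batches) before the
#'   alternation begins; 0 disables it.
#' @param warmstart_f Also warm-start `f` to the identity potential on
#'   target batches, so the alternation starts from the identity coupling on
#'   both sides (recommended; the projected `f` keeps its convexity
#'   constraint throughout).
#' @param checkpoint_every Evaluation cadence (in outer iterations) when
#'   `select_by_eval_mmd` is on.
#' @param select_by_eval_mmd If `TRUE`, hold out evaluation subsets, track
#'   the multiscale MMD of the pushforward every `checkpoint_every`
#'   iterations, and return the best checkpoint instead of the last iterate.
#' @param eval_holdout Number of cells per population held out for checkpoint
#'   selection (only used when `select_by_eval_mmd` is on).
#' @param log_every Cadence (outer iterations) of the training log.
#' @param seed Integer seed controlling initialization and minibatching.
#' @return A list of class `ot_train_config`.
#' @export
ot_train_config <- function(batch_size = 256L, lr = 1e-4, beta1 = 0.5,
                            beta2 = 0.9, lambda = 1, inner_g_steps = 10L,
                            n_iter = 10000L, hidden_widths = rep(64L, 4L),
                            activation = "softplus", slope = 0.2,
                            warmstart_steps = 1000L, warmstart_f = TRUE,
                            checkpoint_every = 500L,
                            select_by_eval_mmd = FALSE, eval_holdout = 500L,
                            log_every = 100L, seed = 0L) {
  stopifnot(batch_size >= 1, lr > 0, beta1 > 0, beta1 < 1, beta2 > 0,
            beta2 < 1, lambda >= 0, inner_g_steps >= 0, n_iter >= 0,
            warmstart_steps >= 0, checkpoint_every >= 1, log_every >= 1)
  structure(
    list(batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
         beta2 = beta2, lambda = lambda,
         inner_g_steps = as.integer(inner_g_steps),
         n_iter = as.integer(n_iter),
         hidden_widths = as.integer(hidden_widths),
         activation = activation, slope = slope,
         warmstart_steps = as.integer(warmstart_steps),
         warmstart_f = isTRUE(warmstart_f),
         checkpoint_every = as.integer(checkpoint_every),
         select_by_eval_mmd = isTRUE(select_by_eval_mmd),
         eval_holdout = as.integer(eval_holdout),
         log_every = as.integer(log_every), seed = as.integer(seed)),
    class = "ot_train_config")
}

#' Dual objective pieces
#'
#' The max-min training objective over the potential pair is
#' \deqn{\max_{\phi} \min_{\theta} \; f_\phi(\nabla g_\theta(x)) -
#'   \langle x, \nabla g_\theta(x)\rangle - f_\phi(y) + \lambda R(\theta),}
#' with expectations over source cells \eqn{x} and perturbed cells \eqn{y},
#' and \eqn{R} the negativity penalty of [negativity_penalty()].
#' `dual_loss_g()` returns the part minimized in `g`'s parameters:
#' mean over the batch of \eqn{f(\nabla g(x)) - \langle x, \nabla g(x)\rangle}
#' plus `lambda` times the penalty (the `-f(y)` term is constant in `g`).
#' `dual_loss_f()` returns mean \eqn{f(\nabla g(x))} minus mean \eqn{f(y)};
#' gradient ascent on this value in `f`'s parameters maximizes the objective.
#'
#' @param g,f `icnn` objects (the potential pair).
#' @param batch_c Matrix of source (control) cells, one row per cell.
#' @param batch_k Matrix of target (perturbed) cells.
#' @param lambda Penalty weight.
#' @return A scalar.
#' @export
dual_loss_g <- function(g, f, batch_c, lambda = 1) {
  X <- as_pop_matrix(batch_c)$X
  Tx <- potential_gradient(g, X)
  mean(potential_value(f, Tx) - rowSums(X * Tx)) +
    lambda * negativity_penalty(g)
}

#' @rdname dual_loss_g
#' @export
dual_loss_f <- function(g, f, batch_c, batch_k) {
  X <- as_pop_matrix(batch_c)$X
  Y <- as_pop_matrix(batch_k)$X
  if (ncol(X) != ncol(Y))
    stop("control and perturbed batches must share width", call. = FALSE)
  Tx <- potential_gradient(g, X)
  mean(potential_value(f, Tx)) - mean(potential_value(f, Y))
}

#' Fit a neural optimal transport map between two cell populations
#'
#' Learns the Kantorovich dual potential pair `(g, f)` as input-convex neural
#' networks by alternating optimization: each outer iteration performs one
#' Adam ascent step on `f` (whose hidden weights are projected non-negative
#' after every update) followed by `inner_g_steps` Adam descent steps on `g`
#' (whose convexity is relaxed into the `lambda`-weighted negativity
#' penalty). The learned transport map is the gradient \eqn{T = \nabla g};
#' applying it to control cells predicts their perturbed states.
#'
#' @param source A cell population (see [cell_population()]), data frame, or
#'   numeric matrix of control cells (rows) by features (columns).
#' @param target The perturbed population with the same feature width.
#' @param config An [ot_train_config()].
#' @return An object of class `transport_map` with elements `g`, `f`
#'   (the trained `icnn` potentials), `input_dim`, `feature_names`, `config`,
#'   and `log` (a tibble of objective values along training). Methods:
#'   [predict.transport_map()]/[transport()], [tidy.transport_map()],
#'   [glance.transport_map()], [autoplot.transport_map()].
#' @examples
#' \donttest{
#' src <- matrix(rnorm(400), 200, 2)
#' tgt <- matrix(rnorm(400), 200, 2) + 2
#' map <- fit_transport_map(src, tgt,
#'   ot_train_config(n_iter = 200, warmstart_steps = 100, seed = 1))
#' head(transport(map, src))
#' }
#' @export
fit_transport_map <- function(source, target, config = ot_train_config()) {
  Xs <- as_pop_matrix(source)
  Xt <- as_pop_matrix(target)
  if (ncol(Xs$X) != ncol(Xt$X))
    stop(sprintf("source has %d features but target has %d; widths must match",
                 ncol(Xs$X), ncol(Xt$X)), call. = FALSE)
  feats <- Xs$features
  X <- Xs$X
  Y <- Xt$X
  d <- ncol(X)
  cfg <- config
  eval_idx <- NULL
  if (cfg$select_by_eval_mmd) {
    with_seed(cfg$seed + 17L, {
      es <- sample.int(nrow(X), min(cfg$eval_holdout, floor(nrow(X) / 5)))
      et <- sample.int(nrow(Y), min(cfg$eval_holdout, floor(nrow(Y) / 5)))
    })
    Xe <- X[es, , drop = FALSE]; Ye <- Y[et, , drop = FALSE]
    X <- X[-es, , drop = FALSE]; Y <- Y[-et, , drop = FALSE]
  }
  g <- icnn_init(d, cfg$hidden_widths, cfg$activation, cfg$slope,
                 seed = cfg$seed + 1L)
  f <- icnn_init(d, cfg$hidden_widths, cfg$activation, cfg$slope,
                 seed = cfg$seed + 2L)
  meta <- list(widths = g$widths,
               act = if (cfg$activation == "leaky_relu") 0L else 1L,
               slope = cfg$slope)
  cpp_cfg <- list(n_iter = cfg$n_iter, inner_g_steps = cfg$inner_g_steps,
                  warmstart_steps = cfg$warmstart_steps,
                  warmstart_f = cfg$warmstart_f,
                  lr = cfg$lr, warm_lr = cfg$lr * 10,
                  beta1 = cfg$beta1, beta2 = cfg$beta2, lambda = cfg$lambda,
                  log_every = cfg$log_every,
                  checkpoint_every = cfg$checkpoint_every,
                  select_by_eval_mmd = cfg$select_by_eval_mmd,
                  batch_size = cfg$batch_size)
  if (!cfg$select_by_eval_mmd) {
    Xe <- matrix(0, 0, d); Ye <- matrix(0, 0, d)
  }
  res <- with_seed(cfg$seed,
    train_dual_cpp(X, Y, icnn_param_list(g), icnn_param_list(f),
                   meta, cpp_cfg, Xe, Ye, mmd_default_gammas()))
  g <- icnn_set_params(g, res$g)
  f <- icnn_set_params(f, res$f)
  log <- tibble::tibble(iteration = as.integer(res$log[, 1]),
                        loss_f = res$log[, 2], loss_g = res$log[, 3],
                        penalty = res$log[, 4])
  if (cfg$n_iter == 0L) log <- log[0, ]
  structure(
    list(g = g, f = f, input_dim = d, feature_names = feats,
         config = cfg, log = log,
         selected_iteration = as.integer(res$selected_iteration),
         eval_mmd = res$eval_mmd),
    class = "transport_map")
}

#' @export
print.transport_map <- function(x, ...) {
  cat(sprintf(
    "<transport_map> d = %d, %d outer iterations (selected %d), penalty(g) = %.3g\n",
    x$input_dim, x$config$n_iter, x$selected_iteration,
    negativity_penalty(x$g)))
  if (nrow(x$log))
    cat(sprintf("  final dual objectives: f-part %.4g, g-part %.4g\n",
                utils::tail(x$log$loss_f, 1), utils::tail(x$log$loss_g, 1)))
  invisible(x)
}

#' Apply a learned transport map
#'
#' `transport()` pushes cells through the learned map \eqn{T = \nabla g}:
#' the returned population holds the predicted perturbed state of each input
#' cell, with annotations preserved. `perturbation_effect()` returns the
#' per-cell displacement \eqn{T(x) - x} instead (same feature names), and
#' `predict()` is an alias for `transport()`.
#'
#' @param map A fitted [fit_transport_map()] object.
#' @param cells A cell population, data frame, or matrix with the map's
#'   feature width.
#' @return A tibble (cell population if the input was one) with the feature
#'   columns replaced by the mapped values.
#' @export
transport <- function(map, cells) {
  p <- as_pop_matrix(cells)
  if (ncol(p$X) != map$input_dim)
    stop(sprintf("cells have width %d but the map expects %d",
                 ncol(p$X), map$input_dim), call. = FALSE)
  rebuild_pop(cells, potential_gradient(map$g, p$X), p)
}

#' @rdname transport
#' @param object,... For the `predict` method: the map and `cells = `.
#' @export
predict.transport_map <- function(object, cells, ...) transport(object, cells)

#' @rdname transport
#' @export
perturbation_effect <- function(map, cells) {
  p <- as_pop_matrix(cells)
  if (ncol(p$X) != map$input_dim)
    stop(sprintf("cells have width %d but the map expects %d",
                 ncol(p$X), map$input_dim), call. = FALSE)
  rebuild_pop(cells, potential_gradient(map$g, p$X) - p$X, p)
}

#' Per-cell and per-group transport costs
#'
#' The transport cost of a cell is its squared displacement under the map,
#' \eqn{\|T(x) - x\|_2^2}; summed or averaged over groups it ranks how
#' strongly a perturbation remodels each group of cells. The coefficient of
#' variation (CV) is computed across the per-group mean costs and summarizes
#' how uniformly the perturbation acts across groups.
#'
#' @inheritParams transport
#' @param groups Optional per-cell grouping labels (defaults to the
#'   population's `cell_type` column when present). Empty groups are dropped
#'   with a warning.
#' @return A list with `per_cell` (tibble: `cell`, `cost`), `per_group`
#'   (tibble: `group`, `n`, `mean`, `sum`), `cv` (std/mean of the per-group
#'   mean costs; 0 when undefined) and `cv_defined` (FALSE when the mean cost
#'   is 0, e.g. under the identity map).
#' @export
transport_cost <- function(map, cells, groups = NULL) {
  p <- as_pop_matrix(cells)
  if (ncol(p$X) != map$input_dim)
    stop(sprintf("cells have width %d but the map expects %d",
                 ncol(p$X), map$input_dim), call. = FALSE)
  disp <- potential_gradient(map$g, p$X) - p$X
  cost <- unname(rowSums(disp^2))
  ids <- if (!is.null(p$meta$cell_id)) p$meta$cell_id else as.character(seq_along(cost))
  per_cell <- tibble::tibble(cell = ids, cost = cost)
  if (is.null(groups) && !is.null(p$meta$cell_type)) groups <- p$meta$cell_type
  if (is.null(groups)) groups <- rep("all", length(cost))
  if (is.factor(groups) && any(table(groups) == 0))
    warning("empty groups dropped from the transport-cost summary")
  groups <- as.character(groups)
  per_group <- tibble::tibble(group = groups, cost = cost) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$cost),
                     sum = sum(.data$cost), .groups = "drop")
  mu <- mean(per_group$mean)
  cv_defined <- is.finite(mu) && mu > 0 && nrow(per_group) > 1L
  cv <- if (cv_defined) stats::sd(per_group$mean) / mu else 0
  list(per_cell = per_cell, per_group = per_group, cv = cv,
       cv_defined = cv_defined)
}

#' Dual estimate of the squared Wasserstein-2 distance
#'
#' Diagnostic: evaluates the dual objective value implied by the trained
#' potentials on evaluation samples. The potential pair is trained under the
#' half-quadratic cost convention, whose dual value is
#' \eqn{\tfrac12 E[\|x\|^2 + \|y\|^2] -
#'  E[\langle x, \nabla g(x)\rangle - f(\nabla g(x))] - E[f(y)]};
#' the returned estimate is that value rescaled by 2, on the scale of the
#' squared Euclidean transport cost.
#'
#' @inheritParams transport
#' @param source,target Evaluation samples from the two populations.
#' @return A scalar estimate of the squared 2-Wasserstein distance.
#' @export
wasserstein_estimate <- function(map, source, target) {
  X <- as_pop_matrix(source)$X
  Y <- as_pop_matrix(target)$X
  Tx <- potential_gradient(map$g, X)
  C <- 0.5 * (mean(rowSums(X^2)) + mean(rowSums(Y^2)))
  V <- mean(rowSums(X * Tx) - potential_value(map$f, Tx)) +
    mean(potential_value(map$f, Y))
  2 * (C - V)   # half-quadratic dual value -> squared-Euclidean cost scale
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_transport_map
#' @param x A `transport_map`.
#' @export
tidy.transport_map <- function(x, ...) {
  tidyr::pivot_longer(x$log, -"iteration",
                      names_to = "objective", values_to = "value")
}

#' @rdname fit_transport_map
#' @export
glance.transport_map <- function(x, ...) {
  tibble::tibble(
    input_dim = x$input_dim,
    n_iter = x$config$n_iter,
    selected_iteration = x$selected_iteration,
    loss_f = if (nrow(x$log)) utils::tail(x$log$loss_f, 1) else NA_real_,
    loss_g = if (nrow(x$log)) utils::tail(x$log$loss_g, 1) else NA_real_,
    penalty_g = negativity_penalty(x$g),
    seed = x$config$seed)
}

#' @rdname fit_transport_map
#' @param object A `transport_map` (for `autoplot`).
#' @export
autoplot.transport_map <- function(object, ...) {
  ggplot2::ggplot(tidy.transport_map(object),
                  ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$objective, scales = "free_y") +
    ggplot2::labs(x = "outer iteration", y = "objective value",
                  title = "Dual-potential training trajectory") +
    ggplot2::theme_minimal()
}
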