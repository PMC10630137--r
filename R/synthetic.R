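#' Synthetic control/perturbed population pairs with known transport structure
#'
#' `gaussian_spec()` describes a pair of Gaussian populations (a "control"
#' source and a "perturbed" target) with known means and covariances, for
#' which the optimal transport map and cost have closed forms;
#' `sample_gaussian_pair()` draws the two populations. These fixtures let the
#' neural solver be validated against analytic oracles.
#'
#' @param mean_source,mean_target Mean vectors (equal length `d`).
#' @param cov_source,cov_target `d x d` symmetric positive-definite
#'   covariance matrices (scalars allowed for `d = 1`).
#' @param n_source,n_target Number of cells to draw per population.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return `gaussian_spec()`: a list of class `gaussian_spec`.
#'   `sample_gaussian_pair()`: a list with `source` and `target`, each a
#'   [cell_population()] (conditions `"control"` and `"perturbed"`).
#' @examples
#' sp <- gaussian_spec(0, 1, 2, 1, n_source = 100, n_target = 100, seed = 1)
#' pair <- sample_gaussian_pair(sp)
#' @export
gaussian_spec <- function(mean_source, cov_source, mean_target, cov_target,
                          n_source = 1000L, n_target = 1000L, seed = 0L) {
  ms <- as.numeric(mean_source); mt <- as.numeric(mean_target)
  d <- length(ms)
  if (length(mt) != d) stop("mean vectors must have equal length", call. = FALSE)
  Ss <- as_spd(cov_source, d, "cov_source")
  St <- as_spd(cov_target, d, "cov_target")
  structure(list(mean_source = ms, cov_source = Ss, mean_target = mt,
                 cov_target = St, n_source = as.integer(n_source),
                 n_target = as.integer(n_target), seed = as.integer(seed),
                 d = d),
            class = "gaussian_spec")
}

as_spd <- function(S, d, what) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(d, d)))
    stop(sprintf("`%s` must be %d x %d", what, d, d), call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8)
    stop(sprintf("`%s` must be symmetric", what), call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("`%s` is not positive definite (min eigenvalue %.3g)",
                 what, min(ev)), call. = FALSE)
  S
}

# Symmetric PSD square root via eigendecomposition, eigenvalues floored.
spd_sqrt <- function(S, inverse = FALSE, floor = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  v <- if (inverse) 1 / sqrt(lam) else sqrt(lam)
  e$vectors %*% (v * t(e$vectors))
}

rmvnorm_seeded <- function(n, mu, S) {
  d <- length(mu)
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% spd_sqrt(S), 2, mu, "+")
}

#' @rdname gaussian_spec
#' @param spec A `gaussian_spec`.
#' @export
sample_gaussian_pair <- function(spec) {
  stopifnot(inherits(spec, "gaussian_spec"))
  with_seed(spec$seed, {
    Xs <- rmvnorm_seeded(spec$n_source, spec$mean_source, spec$cov_source)
    Xt <- rmvnorm_seeded(spec$n_target, spec$mean_target, spec$cov_target)
  })
  colnames(Xs) <- colnames(Xt) <- paste0("feature_", seq_len(spec$d))
  list(source = cell_population(Xs, condition = "control"),
       target = cell_population(Xt, condition = "perturbed"))
}

#' Closed-form optimal transport between Gaussians
#'
#' For source \eqn{N(\mu_s, \Sigma_s)} and target \eqn{N(\mu_t, \Sigma_t)}
#' the squared-Euclidean optimal transport map is the affine map
#' \eqn{T(x) = A(x - \mu_s) + \mu_t} with
#' \eqn{A = \Sigma_s^{-1/2} (\Sigma_s^{1/2} \Sigma_t \Sigma_s^{1/2})^{1/2}
#' \Sigma_s^{-1/2}} (symmetric positive definite), and the squared
#' 2-Wasserstein distance is
#' \eqn{\|\mu_s - \mu_t\|^2 + \mathrm{tr}(\Sigma_s + \Sigma_t -
#' 2 (\Sigma_s^{1/2} \Sigma_t \Sigma_s^{1/2})^{1/2})}.
#' These are the analytic oracles against which learned maps are checked.
#'
#' @param mean_source,cov_source,mean_target,cov_target Gaussian parameters
#'   (covariances SPD; scalars allowed in 1-D).
#' @return `closed_form_gaussian_map()`: a list with the matrix `A`, the
#'   vector `offset` (so that `T(x) = A x + offset`), and `map`, a function
#'   applying `T` to a matrix of rows. `gaussian_w2()`: a non-negative
#'   scalar, zero iff the two Gaussians coincide.
#' @examples
#' closed_form_gaussian_map(0, 1, 2, 1)$map(matrix(0))  # pure shift: 2
#' gaussian_w2(0, 1, 2, 1)                              # 4
#' @export
closed_form_gaussian_map <- function(mean_source, cov_source,
                                     mean_target, cov_target) {
  ms <- as.numeric(mean_source); mt <- as.numeric(mean_target)
  d <- length(ms)
  Ss <- as_spd(cov_source, d, "cov_source")
  St <- as_spd(cov_target, d, "cov_target")
  Ss_h <- spd_sqrt(Ss)
  Ss_ih <- spd_sqrt(Ss, inverse = TRUE)
  M <- spd_sqrt(Ss_h %*% St %*% Ss_h)
  A <- Ss_ih %*% M %*% Ss_ih
  A <- (A + t(A)) / 2
  offset <- mt - A %*% ms
  list(A = A, offset = as.numeric(offset),
       map = function(x) {
         X <- if (is.matrix(x)) x else matrix(x, ncol = d)
         sweep(X %*% t(A), 2, as.numeric(offset), "+")
       })
}

#' @rdname closed_form_gaussian_map
#' @export
gaussian_w2 <- function(mean_source, cov_source, mean_target, cov_target) {
  ms <- as.numeric(mean_source); mt <- as.numeric(mean_target)
  d <- length(ms)
  Ss <- as_spd(cov_source, d, "cov_source")
  St <- as_spd(cov_target, d, "cov_target")
  Ss_h <- spd_sqrt(Ss)
  cross <- spd_sqrt(Ss_h %*% St %*% Ss_h)
  sum((ms - mt)^2) + sum(diag(Ss)) + sum(diag(St)) - 2 * sum(diag(cross))
}

#' Exact discrete optimal transport with barycentric projection
#'
#' Solves the exact linear program for squared-Euclidean cost between two
#' uniform-weighted point clouds and returns the coupling together with its
#' barycentric projection (the per-source-point average of target points
#' weighted by the coupling), which converts the coupling into a map. This
#' is the brute-force oracle the neural solver is compared against on small
#' problems.
#'
#' For `n == m` the optimal coupling is a permutation and is found by the
#' exact Hungarian assignment solver; in 1-D any `n, m` is solved exactly by
#' the monotone (sorted) coupling; for `d > 1` with `n != m` the problem is
#' lifted to an assignment on `lcm(n, m)` replicated points (guarded against
#' blow-up).
#'
#' @param source_pts,target_pts Numeric matrices (`n x d` and `m x d`).
#' @param max_lift Upper bound on `lcm(n, m)` for the replication lift.
#' @return A list with `coupling` (`n x m`, row sums `1/n`, column sums
#'   `1/m`), `projected` (`n x d` barycentric projection of each source
#'   point), and `cost` (the optimal total squared-Euclidean cost).
#' @examples
#' res <- discrete_ot_barycentric(matrix(c(0, 10)), matrix(c(1, 11)))
#' res$projected  # monotone matching: 1, 11
#' @export
discrete_ot_barycentric <- function(source_pts, target_pts, max_lift = 4000L) {
  X <- as_pop_matrix(source_pts)$X
  Y <- as_pop_matrix(target_pts)$X
  if (ncol(X) != ncol(Y))
    stop("point clouds must share dimension", call. = FALSE)
  n <- nrow(X); m <- nrow(Y)
  if (n < 1 || m < 1) stop("need at least one point per cloud", call. = FALSE)
  if (n == m) {
    P <- diag_coupling_assignment(X, Y) / n
  } else if (ncol(X) == 1L) {
    P <- north_west_coupling(order(X[, 1]), order(Y[, 1]), n, m)
  } else {
    l <- lcm_int(n, m)
    if (l > max_lift)
      stop(sprintf(
        "unequal cloud sizes need a lift to lcm(n, m) = %d points (> max_lift = %d)",
        l, max_lift), call. = FALSE)
    Xl <- X[rep(seq_len(n), each = l / n), , drop = FALSE]
    Yl <- Y[rep(seq_len(m), each = l / m), , drop = FALSE]
    Pl <- diag_coupling_assignment(Xl, Yl)
    P <- matrix(0, n, m)
    src_of <- rep(seq_len(n), each = l / n)
    tgt_of <- rep(seq_len(m), each = l / m)
    hit <- which(Pl > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(hit)))
      P[src_of[hit[r, 1]], tgt_of[hit[r, 2]]] <-
        P[src_of[hit[r, 1]], tgt_of[hit[r, 2]]] + 1 / l
  }
  projected <- (P %*% Y) * n   # rows of P carry mass 1/n
  cost_mat <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  list(coupling = P, projected = projected, cost = sum(P * cost_mat))
}

# 0/1 assignment matrix minimizing total squared cost (exact Hungarian).
diag_coupling_assignment <- function(X, Y) {
  C <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  C <- pmax(C, 0)
  sol <- clue::solve_LSAP(C)
  P <- matrix(0, nrow(X), nrow(Y))
  P[cbind(seq_len(nrow(X)), as.integer(sol))] <- 1
  P
}

# Exact 1-D coupling: monotone north-west corner rule on sorted points.
north_west_coupling <- function(ox, oy, n, m) {
  P <- matrix(0, n, m)
  i <- 1L; j <- 1L
  ri <- 1 / n; cj <- 1 / m
  while (i <= n && j <= m) {
    mass <- min(ri, cj)
    P[ox[i], oy[j]] <- P[ox[i], oy[j]] + mass
    ri <- ri - mass; cj <- cj - mass
    if (ri <= 1e-15) { i <- i + 1L; ri <- 1 / n }
    if (cj <= 1e-15) { j <- j + 1L; cj <- 1 / m }
  }
  P
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  as.integer(a / gcd(a, b) * b)
}

#' Gaussian-mixture population pairs with component-specific shifts
#'
#' `mixture_spec()` describes a source Gaussian mixture together with a
#' per-component ground-truth displacement; `sample_mixture_pair()` draws a
#' control population from the mixture and a perturbed population whose
#' components are the source components transformed by their own shifts.
#' Opposite-signed shifts emulate cell-type-specific perturbation responses
#' and produce bimodal perturbed marginals, the regime in which mean-shift
#' predictors fail and a transport map must be nonlinear.
#'
#' @param weights Component weights (must sum to 1).
#' @param means List of component mean vectors (source).
#' @param covs List of component covariances.
#' @param shifts List of per-component displacement vectors applied to the
#'   target draws.
#' @param n_source,n_target Cells per condition.
#' @param seed Integer seed.
#' @return `sample_mixture_pair()`: list with `source`, `target`
#'   ([cell_population()]s whose `cell_type` column carries the true
#'   component label).
#' @examples
#' sp <- mixture_spec(c(0.5, 0.5), list(-2, 2), list(0.3, 0.3),
#'                    shifts = list(3, -3), n_source = 200, n_target = 200)
#' pair <- sample_mixture_pair(sp)
#' @export
mixture_spec <- function(weights, means, covs, shifts,
                         n_source = 1000L, n_target = 1000L, seed = 0L) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop(sprintf("component weights must sum to 1 (got %.4g)", sum(weights)),
         call. = FALSE)
  k <- length(weights)
  stopifnot(length(means) == k, length(covs) == k, length(shifts) == k)
  d <- length(as.numeric(means[[1]]))
  covs <- lapply(seq_len(k), function(i) as_spd(covs[[i]], d,
                                                paste0("covs[[", i, "]]")))
  structure(list(weights = as.numeric(weights),
                 means = lapply(means, as.numeric), covs = covs,
                 shifts = lapply(shifts, as.numeric),
                 n_source = as.integer(n_source),
                 n_target = as.integer(n_target),
                 seed = as.integer(seed), d = d, k = k),
            class = "mixture_spec")
}

#' @rdname mixture_spec
#' @param spec A `mixture_spec`.
#' @export
sample_mixture_pair <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  draw <- function(n, shifted) {
    comp <- sample.int(spec$k, n, replace = TRUE, prob = spec$weights)
    X <- matrix(0, n, spec$d)
    for (j in seq_len(spec$k)) {
      idx <- which(comp == j)
      if (!length(idx)) next
      mu <- spec$means[[j]] + if (shifted) spec$shifts[[j]] else 0
      X[idx, ] <- rmvnorm_seeded(length(idx), mu, spec$covs[[j]])
    }
    colnames(X) <- paste0("feature_", seq_len(spec$d))
    list(X = X, comp = comp)
  }
  with_seed(spec$seed, {
    s <- draw(spec$n_source, shifted = FALSE)
    t <- draw(spec$n_target, shifted = TRUE)
  })
  list(source = cell_population(s$X, condition = "control",
                                cell_type = paste0("component_", s$comp)),
       target = cell_population(t$X, condition = "perturbed",
                                cell_type = paste0("component_", t$comp)))
}
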