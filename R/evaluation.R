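#' Unbiased maximum mean discrepancy
#'
#' Squared MMD between two samples under the Gaussian RBF kernel
#' \eqn{k(x, y) = \exp(-\gamma \|x - y\|^2)}:
#' \deqn{\mathrm{MMD}^2(p, q) = E[k(x, x')] + E[k(y, y')] - 2 E[k(x, y)].}
#' Within-sample expectations use the unbiased U-statistic (diagonal terms
#' excluded, sums divided by `n(n-1)` and `m(m-1)`); the cross term is the
#' plain mean over all `n * m` pairs. The estimate can be negative for close
#' distributions and is reported as-is.
#'
#' @param x,y Numeric matrices (or data frames / populations) with one row
#'   per observation and equal width; both need at least two rows.
#' @param gamma Kernel precision \eqn{\gamma}.
#' @return A scalar (possibly negative).
#' @examples
#' mmd_unbiased(matrix(rnorm(40), 20), matrix(rnorm(40), 20), gamma = 1)
#' @export
mmd_unbiased <- function(x, y, gamma = 1) {
  X <- as_pop_matrix(x)$X
  Y <- as_pop_matrix(y)$X
  if (ncol(X) != ncol(Y))
    stop("samples must have the same number of features", call. = FALSE)
  n <- nrow(X); m <- nrow(Y)
  if (n < 2 || m < 2)
    stop("the unbiased MMD needs at least two observations per sample",
         call. = FALSE)
  D <- mmd_distance_mats(X, Y)
  mmd_from_dists(D, gamma)
}

# Squared-distance matrices, computed once and reused across bandwidths.
mmd_distance_mats <- function(X, Y) {
  sx <- rowSums(X^2); sy <- rowSums(Y^2)
  Dxx <- pmax(outer(sx, sx, "+") - 2 * tcrossprod(X), 0)
  Dyy <- pmax(outer(sy, sy, "+") - 2 * tcrossprod(Y), 0)
  Dxy <- pmax(outer(sx, sy, "+") - 2 * tcrossprod(X, Y), 0)
  list(Dxx = Dxx, Dyy = Dyy, Dxy = Dxy, n = nrow(X), m = nrow(Y))
}

mmd_from_dists <- function(D, gamma) {
  n <- D$n; m <- D$m
  kxx <- exp(-gamma * D$Dxx); kyy <- exp(-gamma * D$Dyy)
  (sum(kxx) - n) / (n * (n - 1)) +
    (sum(kyy) - m) / (m * (m - 1)) -
    2 * mean(exp(-gamma * D$Dxy))
}

#' Default MMD bandwidth grid
#'
#' Fifty kernel precisions logarithmically spaced from 10^1 down to 10^-3
#' (the `logspace(1, -3)` convention).
#' @param n Number of scales.
#' @return Numeric vector of `gamma` values.
#' @export
mmd_default_gammas <- function(n = 50L) 10^seq(1, -3, length.out = n)

#' Multiscale MMD
#'
#' Evaluates [mmd_unbiased()] on a grid of kernel precisions and averages;
#' reporting the mean over length scales makes the metric robust to the
#' arbitrary choice of a single bandwidth. Distance matrices are computed
#' once and shared across scales.
#'
#' @inheritParams mmd_unbiased
#' @param gammas Vector of kernel precisions (default [mmd_default_gammas()]).
#' @return A list with `per_bandwidth` (tibble: `gamma`, `mmd`) and `mean`.
#' @export
mmd_multiscale <- function(x, y, gammas = mmd_default_gammas()) {
  if (length(gammas) < 1) stop("`gammas` must be non-empty", call. = FALSE)
  X <- as_pop_matrix(x)$X
  Y <- as_pop_matrix(y)$X
  if (ncol(X) != ncol(Y))
    stop("samples must have the same number of features", call. = FALSE)
  if (nrow(X) < 2 || nrow(Y) < 2)
    stop("the unbiased MMD needs at least two observations per sample",
         call. = FALSE)
  D <- mmd_distance_mats(X, Y)
  vals <- vapply(gammas, function(g) mmd_from_dists(D, g), numeric(1))
  list(per_bandwidth = tibble::tibble(gamma = gammas, mmd = vals),
       mean = mean(vals))
}

#' Feature-mean metrics
#'
#' `l2_feature_means()` is the Euclidean distance between the per-feature
#' mean vectors of the predicted and observed populations.
#' `r2_feature_means()` is the squared Pearson correlation between those two
#' mean vectors; it is undefined (returned as `NA` with attribute
#' `"undefined"`) when the observed means are constant.
#'
#' @param pred,obs Samples (matrix, data frame, or population) of equal
#'   feature width.
#' @return A scalar.
#' @export
l2_feature_means <- function(pred, obs) {
  P <- as_pop_matrix(pred)$X
  O <- as_pop_matrix(obs)$X
  if (ncol(P) != ncol(O))
    stop("samples must have the same number of features", call. = FALSE)
  sqrt(sum((colMeans(P) - colMeans(O))^2))
}

#' @rdname l2_feature_means
#' @export
r2_feature_means <- function(pred, obs) {
  P <- as_pop_matrix(pred)$X
  O <- as_pop_matrix(obs)$X
  if (ncol(P) != ncol(O))
    stop("samples must have the same number of features", call. = FALSE)
  if (ncol(P) < 2)
    stop("r2 of feature means needs at least two features", call. = FALSE)
  mp <- colMeans(P); mo <- colMeans(O)
  if (stats::sd(mo) == 0 || stats::sd(mp) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(mp, mo)^2
}

#' Rank marker genes of a perturbation
#'
#' Scores every shared feature by the absolute Welch t-statistic of treated
#' versus control cells and returns the top `n` feature names in decreasing
#' order of |t|. Features with zero variance in both groups get t = 0; ties
#' are broken by input feature order so the ranking is deterministic.
#'
#' @param control,treated Cell populations (or matrices) sharing feature
#'   names, each with at least two cells.
#' @param n Number of markers to return.
#' @return Character vector of `n` feature names.
#' @export
rank_marker_genes <- function(control, treated, n = 50L) {
  C <- as_pop_matrix(control)$X
  T_ <- as_pop_matrix(treated)$X
  if (ncol(C) != ncol(T_))
    stop("control and treated must share features", call. = FALSE)
  if (!is.null(colnames(C)) && !is.null(colnames(T_)) &&
      !identical(colnames(C), colnames(T_)))
    stop("control and treated feature names differ", call. = FALSE)
  if (nrow(C) < 2 || nrow(T_) < 2)
    stop("each group needs at least two cells", call. = FALSE)
  if (n > ncol(C))
    stop(sprintf("requested %d markers from %d features", n, ncol(C)),
         call. = FALSE)
  nc <- nrow(C); nt <- nrow(T_)
  mc <- colMeans(C); mt <- colMeans(T_)
  vc <- matrixStats_colVars(C); vt <- matrixStats_colVars(T_)
  se <- sqrt(vt / nt + vc / nc)
  t_stat <- ifelse(se == 0, 0, (mt - mc) / se)
  nm <- colnames(C)
  if (is.null(nm)) nm <- paste0("feature_", seq_len(ncol(C)))
  ord <- order(-abs(t_stat), seq_along(t_stat))
  nm[ord][seq_len(n)]
}

# Column variances without an extra dependency.
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Evaluate a predicted perturbed population
#'
#' Bundles the distribution-level metrics used to compare a predicted
#' perturbed population against held-out observed perturbed cells: the
#' multiscale unbiased MMD (optionally restricted to the top `k` marker
#' features, ranked on control vs. observed cells), and the l2 / r-squared of
#' the per-feature means computed on all features.
#'
#' @param pred Predicted perturbed cells.
#' @param obs Observed perturbed cells (the reference sample).
#' @param control Control cells; required for `feature_mode =
#'   "top_k_markers"` (marker ranking uses control vs. `obs`).
#' @param feature_mode `"all"` (MMD on every feature; typical for protein
#'   panels and latent spaces) or `"top_k_markers"` (MMD on the `k` strongest
#'   markers; typical for transcriptome-wide data).
#' @param k Number of marker features when restricting.
#' @param gammas Kernel precisions for the MMD.
#' @param baseline_tag Label recorded in the report (`"model"`,
#'   `"identity"`, or `"observed"`).
#' @return An `eval_report`: list with `mmd_per_bandwidth`, `mmd_mean`,
#'   `l2_means`, `r2_means`, `n_pred`, `n_obs`, `feature_subset`,
#'   `baseline_tag`. Methods: [tidy.eval_report()], [glance.eval_report()].
#' @export
evaluate_prediction <- function(pred, obs, control = NULL,
                                feature_mode = c("all", "top_k_markers"),
                                k = 50L, gammas = mmd_default_gammas(),
                                baseline_tag = "model") {
  feature_mode <- match.arg(feature_mode)
  P <- as_pop_matrix(pred)$X
  O <- as_pop_matrix(obs)$X
  if (ncol(P) != ncol(O))
    stop("pred and obs must share features", call. = FALSE)
  subset_used <- "all"
  Pm <- P; Om <- O
  if (feature_mode == "top_k_markers") {
    if (is.null(control))
      stop("`control` is required to rank marker features", call. = FALSE)
    markers <- rank_marker_genes(control, obs, n = k)
    nm <- colnames(P)
    if (is.null(nm)) nm <- paste0("feature_", seq_len(ncol(P)))
    idx <- match(markers, nm)
    Pm <- P[, idx, drop = FALSE]
    Om <- O[, idx, drop = FALSE]
    subset_used <- markers
  }
  mm <- mmd_multiscale(Pm, Om, gammas)
  structure(
    list(mmd_per_bandwidth = mm$per_bandwidth, mmd_mean = mm$mean,
         l2_means = l2_feature_means(P, O),
         r2_means = r2_feature_means(P, O),
         n_pred = nrow(P), n_obs = nrow(O),
         feature_subset = subset_used, baseline_tag = baseline_tag),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> [%s] mmd_mean = %.4g, l2_means = %.4g, r2_means = %s (n_pred = %d, n_obs = %d, features = %s)\n",
    x$baseline_tag, x$mmd_mean, x$l2_means,
    ifelse(is.na(x$r2_means), "NA", sprintf("%.4g", x$r2_means)),
    x$n_pred, x$n_obs,
    if (identical(x$feature_subset, "all")) "all"
    else sprintf("top %d markers", length(x$feature_subset))))
  invisible(x)
}

#' @rdname evaluate_prediction
#' @param x,object An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(baseline = x$baseline_tag, metric = "mmd",
                   gamma = x$mmd_per_bandwidth$gamma,
                   value = x$mmd_per_bandwidth$mmd),
    tibble::tibble(baseline = x$baseline_tag,
                   metric = c("mmd_mean", "l2_means", "r2_means"),
                   gamma = NA_real_,
                   value = c(x$mmd_mean, x$l2_means, x$r2_means)))
}

#' @rdname evaluate_prediction
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(baseline = x$baseline_tag, mmd_mean = x$mmd_mean,
                 l2_means = x$l2_means, r2_means = x$r2_means,
                 n_pred = x$n_pred, n_obs = x$n_obs,
                 n_features_mmd = if (identical(x$feature_subset, "all"))
                   NA_integer_ else length(x$feature_subset))
}

#' @rdname evaluate_prediction
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$mmd_per_bandwidth,
                  ggplot2::aes(x = .data$gamma, y = .data$mmd)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = object$mmd_mean, linetype = 2) +
    ggplot2::labs(x = "kernel precision (gamma)", y = "unbiased MMD",
                  title = sprintf("MMD across length scales [%s]",
                                  object$baseline_tag)) +
    ggplot2::theme_minimal()
}

#' Reference baselines for perturbation prediction
#'
#' `baseline_identity()` predicts the perturbed state as the unchanged
#' control state (the floor any useful model must beat).
#' `baseline_observed()` uses a disjoint sample of truly perturbed cells as
#' the prediction (the experimental-noise ceiling: no model can do better on
#' average). Both return their input tagged for [evaluate_prediction()].
#'
#' @param control_test Held-out control cells.
#' @return The input population, with attribute `baseline_tag`.
#' @export
baseline_identity <- function(control_test) {
  structure(control_test, baseline_tag = "identity")
}

#' @rdname baseline_identity
#' @param obs_eval Held-out observed perturbed cells.
#' @param test_obs The observed perturbed cells used as the evaluation
#'   reference; if supplied, `obs_eval` must be disjoint from them
#'   (checked via `cell_id`s when available).
#' @export
baseline_observed <- function(obs_eval, test_obs = NULL) {
  if (!is.null(test_obs) && is.data.frame(obs_eval) &&
      is.data.frame(test_obs) &&
      "cell_id" %in% names(obs_eval) && "cell_id" %in% names(test_obs) &&
      length(intersect(obs_eval$cell_id, test_obs$cell_id)) > 0)
    stop("the observed baseline must be disjoint from the test observations",
         call. = FALSE)
  structure(obs_eval, baseline_tag = "observed")
}
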