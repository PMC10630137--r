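#' Normalize a multiplexed-protein (4i) population
#'
#' Rescales every feature by its 75th percentile computed on control cells
#' only, then applies `log1p`. The same divisors are applied to all
#' conditions; features whose control 75th percentile is not positive carry
#' no control dynamic range and are dropped with a warning. Passing the
#' `percentiles` computed on a training population applies the training
#' normalizer to held-out cells without leakage.
#'
#' @param pop A cell population with a `condition` column.
#' @param control_label Condition label of the control cells.
#' @param percentiles Optional named vector of per-feature divisors (from a
#'   previous call's `"percentiles"` attribute); when supplied, the control
#'   cells of `pop` are not consulted at all.
#' @return The normalized population, with attribute `"percentiles"` (the
#'   divisors used, on the retained features).
#' @export
normalize_4i <- function(pop, control_label = "control", percentiles = NULL) {
  feats <- pop_feature_names(pop)
  if (is.null(percentiles)) {
    ctrl <- pop$condition == control_label
    if (!any(ctrl))
      stop(sprintf("no cells with condition `%s`", control_label),
           call. = FALSE)
    X_ctrl <- pop_matrix(pop[ctrl, ])
    percentiles <- apply(X_ctrl, 2, stats::quantile, probs = 0.75, names = FALSE)
    names(percentiles) <- feats
  }
  bad <- names(percentiles)[percentiles <= 0]
  if (length(bad)) {
    warning(sprintf(
      "dropping %d feature(s) with non-positive control 75th percentile: %s",
      length(bad), paste(bad, collapse = ", ")))
    percentiles <- percentiles[!names(percentiles) %in% bad]
  }
  keep <- intersect(feats, names(percentiles))
  out <- pop[c(intersect(pop_reserved, names(pop)), keep)]
  for (f in keep) out[[f]] <- log1p(out[[f]] / percentiles[[f]])
  class(out) <- class(pop)
  attr(out, "percentiles") <- percentiles[keep]
  out
}

#' Normalize a scRNA-seq count population
#'
#' The standard count pipeline: drop cells expressing fewer than `min_genes`
#' genes, drop genes expressed in fewer than `min_cells` cells, scale every
#' cell's counts to `target_sum`, and apply `log1p`.
#'
#' @param pop A cell population of raw non-negative counts.
#' @param target_sum Per-cell total after library-size scaling.
#' @param min_genes Minimum expressed genes per retained cell.
#' @param min_cells Minimum expressing cells per retained gene.
#' @return The normalized population (possibly fewer cells/genes).
#' @export
normalize_scrna <- function(pop, target_sum = 1e4, min_genes = 200L,
                            min_cells = 3L) {
  feats <- pop_feature_names(pop)
  X <- pop_matrix(pop)
  if (any(X < 0)) stop("counts must be non-negative", call. = FALSE)
  keep_cells <- rowSums(X > 0) >= min_genes
  X <- X[keep_cells, , drop = FALSE]
  keep_genes <- colSums(X > 0) >= min_cells
  X <- X[, keep_genes, drop = FALSE]
  if (nrow(X) == 0 || ncol(X) == 0)
    stop("no cells or genes left after filtering", call. = FALSE)
  totals <- rowSums(X)
  X <- log1p(X / totals * target_sum)
  out <- pop[keep_cells, c(intersect(pop_reserved, names(pop)))]
  out <- dplyr::bind_cols(out, tibble::as_tibble(X, .name_repair = "minimal"))
  class(out) <- class(pop)
  out
}

#' Select highly variable genes on training cells
#'
#' Ranks genes by normalized dispersion: the per-gene dispersion
#' (variance / mean) is z-scored within bins of genes of similar mean
#' expression, and the top `n_genes` are returned. Computing the selection
#' on training cells only, and then applying the returned index to held-out
#' cells, keeps preprocessing leakage-free.
#'
#' @param train_pop The training cells (already normalized).
#' @param n_genes Number of genes to select.
#' @param n_bins Number of mean-expression bins (collapsed automatically for
#'   small panels).
#' @return An integer vector of feature indices (named by feature), ordered
#'   by decreasing normalized dispersion.
#' @export
select_hvg <- function(train_pop, n_genes = 1000L, n_bins = 20L) {
  X <- pop_matrix(train_pop)
  if (n_genes > ncol(X))
    stop(sprintf("requested %d genes from %d features", n_genes, ncol(X)),
         call. = FALSE)
  mu <- colMeans(X)
  v <- matrixStats_colVars(X)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- max(1L, min(n_bins, floor(ncol(X) / 2)))
  bins <- if (nb == 1L) rep(1L, ncol(X)) else
    as.integer(cut(rank(mu, ties.method = "first"), breaks = nb))
  zdisp <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- stats::sd(disp[idx])
    m <- mean(disp[idx])
    zdisp[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  ord <- order(-zdisp, seq_along(zdisp))
  out <- ord[seq_len(n_genes)]
  names(out) <- colnames(X)[out]
  out
}

#' Split specification for train/test/evaluation protocols
#'
#' @param mode `"iid"` (random split within every condition), `"oos"`
#'   (hold out a sample/patient), or `"ood"` (hold out a distributionally
#'   distinct group, e.g. a species or lineage); `oos`/`ood` require
#'   `holdout`.
#' @param holdout The `sample_id` label to hold out.
#' @param test_size,eval_size Cells per condition in the test / evaluation
#'   sets.
#' @param seed Integer seed.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(mode = c("iid", "oos", "ood"), holdout = NULL,
                       test_size = 500L, eval_size = 500L, seed = 0L) {
  mode <- match.arg(mode)
  if (mode != "iid" && is.null(holdout))
    stop(sprintf("mode `%s` requires a `holdout` sample label", mode),
         call. = FALSE)
  stopifnot(test_size >= 1, eval_size >= 1)
  structure(list(mode = mode, holdout = holdout,
                 test_size = as.integer(test_size),
                 eval_size = as.integer(eval_size), seed = as.integer(seed)),
            class = "split_spec")
}

#' Assign cells to train/test/evaluation sets
#'
#' In `iid` mode every condition is split independently at random into
#' disjoint train/test/eval sets (test and eval of the requested sizes,
#' shrunk proportionally with a warning when a condition is small). In
#' `oos`/`ood` mode all cells of the holdout sample are excluded from the
#' training set; the test and eval sets are drawn from one half of the
#' holdout cells (per condition), and the other half is marked `heldback`:
#' it is the extra data an i.i.d.-counterpart model may train on so that
#' both models can be scored on identical test cells.
#'
#' @param pop A cell population (needs `sample_id` for `oos`/`ood`).
#' @param spec A [split_spec()].
#' @return A tibble with columns `cell_id`, `condition`, `split`
#'   (`"train"`, `"test"`, `"eval"`, or `"heldback"`) and `row` (row index
#'   into `pop`). The o.o.s./o.o.d. training set is `split == "train"`; its
#'   i.i.d. counterpart additionally includes `split == "heldback"`.
#' @export
make_splits <- function(pop, spec) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(pop)
  ids <- pop$cell_id %||% as.character(seq_len(n))
  cond <- pop$condition %||% rep("all", n)
  out <- tibble::tibble(cell_id = ids, condition = cond,
                        split = NA_character_, row = seq_len(n))
  if (spec$mode == "iid") {
    with_seed(spec$seed, {
      for (cc in unique(cond)) {
        rows <- which(cond == cc)
        sz <- shrink_sizes(length(rows), spec$test_size, spec$eval_size)
        pick <- sample(rows, sz$test + sz$eval)
        out$split[pick[seq_len(sz$test)]] <- "test"
        out$split[pick[sz$test + seq_len(sz$eval)]] <- "eval"
        out$split[setdiff(rows, pick)] <- "train"
      }
    })
    return(out)
  }
  if (!"sample_id" %in% names(pop))
    stop("oos/ood splits need a `sample_id` column", call. = FALSE)
  if (!spec$holdout %in% pop$sample_id)
    stop(sprintf("holdout sample `%s` not present in `sample_id`",
                 spec$holdout), call. = FALSE)
  hold <- pop$sample_id == spec$holdout
  out$split[!hold] <- "train"
  with_seed(spec$seed, {
    for (cc in unique(cond[hold])) {
      rows <- which(hold & cond == cc)
      rows <- sample(rows)                     # shuffle within condition
      half <- floor(length(rows) / 2)
      iid_extra <- rows[seq_len(half)]
      rest <- rows[-seq_len(half)]
      sz <- shrink_sizes(length(rest), spec$test_size, spec$eval_size)
      out$split[rest[seq_len(sz$test)]] <- "test"
      out$split[rest[sz$test + seq_len(sz$eval)]] <- "eval"
      out$split[setdiff(rest, rest[seq_len(sz$test + sz$eval)])] <- "heldback"
      out$split[iid_extra] <- "heldback"
    }
  })
  out
}

shrink_sizes <- function(n, test_size, eval_size) {
  need <- test_size + eval_size
  if (n > need) return(list(test = test_size, eval = eval_size))
  scale <- n / (2 * need)   # leave half the condition for training
  test <- max(1L, floor(test_size * scale))
  eval <- max(1L, floor(eval_size * scale))
  warning(sprintf(
    "condition has %d cells (< test + eval = %d); shrinking to test = %d, eval = %d",
    n, need, test, eval))
  list(test = test, eval = eval)
}

#' Size rule for test/eval sets
#'
#' Convenience rule scaling the split size with the condition: at least 500
#' cells, at most 1000, otherwise 10 percent of the condition.
#' @param n_condition Number of cells in the condition.
#' @return An integer size.
#' @export
split_size_rule <- function(n_condition) {
  as.integer(min(1000, max(500, round(0.1 * n_condition))))
}
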