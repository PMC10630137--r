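#' Annotated cell populations as tibbles
#'
#' A cell population is a tibble with one row per cell: a `cell_id` column,
#' per-cell annotation columns (`condition`, and optionally `sample_id` and
#' `cell_type`), and one numeric column per feature (gene, protein, or latent
#' coordinate). All package functions accept such tibbles, plain data frames,
#' or bare numeric matrices; feature columns are whatever numeric columns are
#' not reserved annotation names, so populations survive dplyr manipulation.
#'
#' @param x A cells-by-features numeric matrix or a data frame of feature
#'   columns.
#' @param condition Per-cell condition label (recycled if length 1), e.g.
#'   `"control"` or a perturbation name.
#' @param sample_id,cell_type Optional per-cell labels (patient / donor /
#'   species; cell state).
#' @param cell_id Cell identifiers; defaults to rownames or `cell_1 ...`.
#' @return A tibble of class `cell_pop`.
#' @examples
#' pop <- cell_population(matrix(rnorm(6), 3, 2), condition = "control")
#' pop_matrix(pop)
#' @export
cell_population <- function(x, condition = "control", sample_id = NULL,
                            cell_type = NULL, cell_id = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("feature names must be unique", call. = FALSE)
  if (is.null(cell_id))
    cell_id <- if (!is.null(rownames(x))) rownames(x) else
      paste0("cell_", seq_len(n))
  ann <- tibble::tibble(cell_id = as.character(cell_id),
                        condition = rep_len(as.character(condition), n))
  if (!is.null(sample_id)) ann$sample_id <- rep_len(as.character(sample_id), n)
  if (!is.null(cell_type)) ann$cell_type <- rep_len(as.character(cell_type), n)
  out <- dplyr::bind_cols(ann, tibble::as_tibble(x, .name_repair = "minimal"))
  class(out) <- c("cell_pop", class(out))
  out
}

pop_reserved <- c("cell_id", "condition", "sample_id", "cell_type")

#' @rdname cell_population
#' @param pop A cell population (or any data frame).
#' @export
pop_feature_names <- function(pop) {
  stopifnot(is.data.frame(pop))
  nm <- setdiff(names(pop), pop_reserved)
  nm[vapply(pop[nm], is.numeric, logical(1))]
}

#' @rdname cell_population
#' @export
pop_matrix <- function(pop) {
  feats <- pop_feature_names(pop)
  X <- as.matrix(pop[feats])
  storage.mode(X) <- "double"
  if ("cell_id" %in% names(pop)) rownames(X) <- pop$cell_id
  X
}

#' @rdname cell_population
#' @export
pop_annotations <- function(pop) {
  pop[intersect(pop_reserved, names(pop))]
}

# Uniform view of matrix / data.frame / cell_pop inputs.
as_pop_matrix <- function(x) {
  if (is.data.frame(x)) {
    feats <- pop_feature_names(x)
    list(X = pop_matrix(x), features = feats,
         meta = x[intersect(pop_reserved, names(x))])
  } else {
    X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
    storage.mode(X) <- "double"
    list(X = X, features = colnames(X), meta = NULL)
  }
}

# Replace the feature values of `orig` with matrix `M` (same row count),
# preserving annotations and class; matrices stay matrices.
rebuild_pop <- function(orig, M, parsed = as_pop_matrix(orig)) {
  if (is.data.frame(orig)) {
    feats <- parsed$features
    colnames(M) <- feats
    out <- orig
    out[feats] <- tibble::as_tibble(M, .name_repair = "minimal")
    out
  } else {
    colnames(M) <- colnames(orig)
    rownames(M) <- rownames(orig)
    M
  }
}

#' @export
print.cell_pop <- function(x, ...) {
  feats <- pop_feature_names(x)
  cat(sprintf("<cell_pop> %d cells x %d features; conditions: %s\n",
              nrow(x), length(feats),
              paste(unique(x$condition), collapse = ", ")))
  NextMethod()
}
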