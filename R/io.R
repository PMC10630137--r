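#' Read and write annotated cell populations
#'
#' Populations travel either as headered delimited text (CSV/TSV: first
#' column cell ids, one numeric column per feature, annotation columns named
#' by the `*_key` arguments) or as H5AD (the AnnData on-disk format: matrix
#' in `X`, per-cell annotations in `obs`, feature names in `var`). Delimited
#' round trips are exact (shortest round-trip decimal representation); H5AD
#' round trips are value-exact (doubles stored as IEEE 754).
#'
#' @param path File to read or write.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"h5ad"`.
#' @param condition_key Name of the per-cell condition annotation in the
#'   file (column of the delimited table / `obs`).
#' @param sample_key,cell_type_key Optional annotation names; mapped onto
#'   the population's `sample_id` / `cell_type` columns when given.
#' @return `read_population()`: a [cell_population()] tibble.
#' @export
read_population <- function(path, format = c("auto", "csv", "tsv", "h5ad"),
                            condition_key = "condition", sample_key = NULL,
                            cell_type_key = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "h5ad")
    return(read_population_h5ad(path, condition_key, sample_key, cell_type_key))
  delim <- if (format == "tsv") "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  id_col <- names(df)[1]
  ids <- as.character(df[[id_col]])
  df <- df[-1]
  keys <- c(condition = condition_key, sample_id = sample_key,
            cell_type = cell_type_key)
  for (k in names(keys)) {
    if (is.null(keys[[k]])) next
    if (!keys[[k]] %in% names(df))
      stop(sprintf("annotation column `%s` not found in %s", keys[[k]], path),
           call. = FALSE)
  }
  ann <- lapply(keys, function(key) if (is.null(key)) NULL
                else as.character(df[[key]]))
  feat_cols <- setdiff(names(df), unlist(keys))
  for (fc in feat_cols) {
    if (nrow(df) == 0) df[[fc]] <- numeric(0)
    if (!is.numeric(df[[fc]]))
      stop(sprintf("feature column `%s` in %s is not numeric", fc, path),
           call. = FALSE)
  }
  X <- as.matrix(df[feat_cols])
  cell_population(X, condition = ann$condition %||% "control",
                  sample_id = ann$sample_id, cell_type = ann$cell_type,
                  cell_id = ids)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, h5ad = "h5ad", tsv = "tsv", txt = "tsv", csv = "csv",
         stop(sprintf("cannot guess format from extension `%s`", ext),
              call. = FALSE))
}

#' @rdname read_population
#' @param pop A cell population tibble.
#' @export
write_population <- function(pop, path, format = c("auto", "csv", "tsv", "h5ad"),
                             condition_key = "condition", sample_key = NULL,
                             cell_type_key = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "h5ad")
    return(write_population_h5ad(pop, path, condition_key, sample_key,
                                 cell_type_key))
  feats <- pop_feature_names(pop)
  out <- tibble::tibble(cell_id = pop$cell_id %||%
                          paste0("cell_", seq_len(nrow(pop))))
  if ("condition" %in% names(pop)) out[[condition_key]] <- pop$condition
  if (!is.null(sample_key) && "sample_id" %in% names(pop))
    out[[sample_key]] <- pop$sample_id
  if (!is.null(cell_type_key) && "cell_type" %in% names(pop))
    out[[cell_type_key]] <- pop$cell_type
  out <- dplyr::bind_cols(out, pop[feats])
  delim <- if (format == "tsv") "\t" else ","
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- H5AD -----------------------------------------------------------------

h5_read_frame_column <- function(path, group, name) {
  obj <- rhdf5::h5read(path, paste0(group, "/", name), read.attributes = TRUE)
  if (is.list(obj) && all(c("codes", "categories") %in% names(obj))) {
    codes <- as.integer(obj$codes)
    out <- rep(NA_character_, length(codes))
    ok <- codes >= 0
    out[ok] <- as.character(obj$categories)[codes[ok] + 1L]
    return(out)
  }
  as.vector(obj)
}

read_population_h5ad <- function(path, condition_key, sample_key,
                                 cell_type_key) {
  contents <- rhdf5::h5ls(path)
  top <- contents$name[contents$group == "/"]
  obs_names <- as.character(rhdf5::h5read(path, "obs/_index"))
  var_names <- as.character(rhdf5::h5read(path, "var/_index"))
  n <- length(obs_names); d <- length(var_names)
  x_is_group <- contents$otype[contents$group == "/" &
                                 contents$name == "X"][1] == "H5I_GROUP"
  if (x_is_group) {
    enc <- rhdf5::h5readAttributes(path, "X")[["encoding-type"]]
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    X <- matrix(0, n, d)
    if (identical(enc, "csr_matrix")) {
      for (i in seq_len(n)) {
        rng <- seq.int(indptr[i] + 1L, indptr[i + 1L], length.out = indptr[i + 1L] - indptr[i])
        if (length(rng)) X[i, indices[rng] + 1L] <- data[rng]
      }
    } else if (identical(enc, "csc_matrix")) {
      for (j in seq_len(d)) {
        rng <- seq.int(indptr[j] + 1L, indptr[j + 1L], length.out = indptr[j + 1L] - indptr[j])
        if (length(rng)) X[indices[rng] + 1L, j] <- data[rng]
      }
    } else {
      stop(sprintf("unsupported X encoding `%s` in %s", enc, path),
           call. = FALSE)
    }
  } else {
    X <- rhdf5::h5read(path, "X")
    # on-disk layout is (n_obs, n_var) in C order; rhdf5 returns the
    # transposed view
    if (nrow(X) == d && ncol(X) == n) X <- t(X)
    if (!(nrow(X) == n && ncol(X) == d))
      stop("X dimensions do not match obs/var lengths", call. = FALSE)
  }
  storage.mode(X) <- "double"
  colnames(X) <- var_names
  obs_cols <- contents$name[contents$group == "/obs"]
  get_key <- function(key, required = FALSE) {
    if (is.null(key)) return(NULL)
    if (!key %in% obs_cols) {
      if (required)
        stop(sprintf("annotation `%s` not found in obs of %s", key, path),
             call. = FALSE)
      return(NULL)
    }
    h5_read_frame_column(path, "obs", key)
  }
  cond <- get_key(condition_key, required = TRUE)
  pop <- cell_population(X, condition = cond,
                         sample_id = get_key(sample_key),
                         cell_type = get_key(cell_type_key),
                         cell_id = obs_names)
  rhdf5::h5closeAll()
  pop
}

write_population_h5ad <- function(pop, path, condition_key, sample_key,
                                  cell_type_key) {
  feats <- pop_feature_names(pop)
  X <- pop_matrix(pop)
  ids <- pop$cell_id %||% paste0("cell_", seq_len(nrow(pop)))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # write transposed so that C-order readers see (n_obs, n_var)
  rhdf5::h5write(t(X), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(as.character(ids), path, "obs/_index")
  rhdf5::h5write(as.character(feats), path, "var/_index")
  cols <- character(0)
  if ("condition" %in% names(pop)) {
    rhdf5::h5write(as.character(pop$condition), path,
                   paste0("obs/", condition_key))
    cols <- c(cols, condition_key)
  }
  if (!is.null(sample_key) && "sample_id" %in% names(pop)) {
    rhdf5::h5write(as.character(pop$sample_id), path,
                   paste0("obs/", sample_key))
    cols <- c(cols, sample_key)
  }
  if (!is.null(cell_type_key) && "cell_type" %in% names(pop)) {
    rhdf5::h5write(as.character(pop$cell_type), path,
                   paste0("obs/", cell_type_key))
    cols <- c(cols, cell_type_key)
  }
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  write_attr <- function(obj, name, value, scalar = length(value) == 1) {
    if (length(value) == 0) return(invisible())   # rhdf5 rejects empty attrs
    if (identical(obj, ".")) {
      rhdf5::h5writeAttribute(value, fid, name, variableLengthString = TRUE,
                              asScalar = scalar)
      return(invisible())
    }
    h5obj <- rhdf5::H5Oopen(fid, obj)
    rhdf5::h5writeAttribute(value, h5obj, name,
                            variableLengthString = TRUE, asScalar = scalar)
    rhdf5::H5Oclose(h5obj)
  }
  write_attr(".", "encoding-type", "anndata")
  write_attr(".", "encoding-version", "0.1.0")
  write_attr("X", "encoding-type", "array")
  write_attr("X", "encoding-version", "0.2.0")
  for (grp in c("obs", "var")) {
    write_attr(grp, "encoding-type", "dataframe")
    write_attr(grp, "encoding-version", "0.2.0")
    write_attr(grp, "_index", "_index")
  }
  write_attr("obs", "column-order", cols, scalar = FALSE)
  # dataframe groups need a column-order attribute even when empty; rhdf5's
  # high-level writer cannot create empty attributes, so go low-level
  empty_attr <- function(group, name) {
    obj <- rhdf5::H5Oopen(fid, group)
    sid <- rhdf5::H5Screate_simple(0L)
    aid <- rhdf5::H5Acreate(obj, name, rhdf5::H5Tcopy("H5T_IEEE_F64LE"), sid)
    rhdf5::H5Aclose(aid); rhdf5::H5Sclose(sid); rhdf5::H5Oclose(obj)
  }
  if (length(cols) == 0) empty_attr("obs", "column-order")
  empty_attr("var", "column-order")
  for (ds in c("obs/_index", "var/_index",
               if (length(cols)) paste0("obs/", cols))) {
    write_attr(ds, "encoding-type", "string-array")
    write_attr(ds, "encoding-version", "0.2.0")
  }
  invisible(path)
}
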