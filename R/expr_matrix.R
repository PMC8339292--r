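#' Probe-by-sample expression matrix with dataset annotations
#'
#' Lightweight container for a non-negative intensity matrix (probes as rows,
#' samples as columns) together with the dataset (series) each sample came
#' from and the publication order of the datasets. The publication order is
#' what redundancy removal uses to decide which copy of a re-published array
#' is the original.
#'
#' @param values numeric matrix, probes x samples, with unique rownames
#'   (probe ids) and colnames (sample ids); all values must be non-negative.
#' @param dataset_id character vector of dataset ids, one per sample (in
#'   column order, or named by sample id).
#' @param dataset_order named integer vector giving the publication rank of
#'   each dataset (smaller = earlier). Defaults to order of first appearance.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, dataset_id, dataset_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("probe ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (!is.null(names(dataset_id))) {
    dataset_id <- dataset_id[colnames(values)]
  }
  if (length(dataset_id) != ncol(values))
    stop("`dataset_id` must give one dataset per sample")
  dataset_id <- as.character(dataset_id)
  names(dataset_id) <- colnames(values)
  if (is.null(dataset_order)) {
    ds <- unique(dataset_id)
    dataset_order <- setNames(seq_along(ds), ds)
  }
  if (!all(dataset_id %in% names(dataset_order)))
    stop("every dataset id needs an entry in `dataset_order`")
  structure(
    list(values = values, dataset_id = dataset_id,
         dataset_order = dataset_order),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples, %d dataset(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$dataset_id))))
  invisible(x)
}

#' Subset an expression matrix by samples and/or probes
#'
#' @param x an `expr_matrix`.
#' @param samples,probes character vectors of ids to keep (NULL = all).
#' @return an `expr_matrix`.
#' @export
em_subset <- function(x, samples = NULL, probes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(v))
    if (length(missing))
      stop("unknown probe id(s): ", paste(missing, collapse = ", "))
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expr_matrix(v, x$dataset_id[colnames(v)], x$dataset_order)
}

#' Write / read an expression matrix as tab-separated text
#'
#' The on-disk format is a TSV with probe ids in the first column
#' (`probe_id`) and one column per sample; dataset assignments travel in the
#' clinical table and are re-attached on read.
#'
#' @param x an `expr_matrix`.
#' @param path file path.
#' @export
write_expr_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_matrix
#' @param dataset_id,dataset_order as in [expr_matrix()].
#' @export
read_expr_matrix <- function(path, dataset_id, dataset_order = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  expr_matrix(v, dataset_id, dataset_order)
}
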