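#' Expression matrix with sample metadata
#'
#' The pipeline's central container: a genes x samples numeric matrix, the
#' unit the values are in (`"counts"`, `"tpm"`, or `"logtpm"`), per-sample
#' metadata, and an optional per-cell mask used by the outlier-masking stage
#' (`TRUE` = masked out).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique (gene and sample ids).
#' @param unit One of `"counts"`, `"tpm"`, `"logtpm"`.
#' @param sample_meta Data frame with one row per sample; must contain a
#'   `sample` column matching `colnames(values)` and typically `colony`,
#'   `batch`, `rna_conc`, `library`.
#' @param mask Optional logical matrix of the same dimension as `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `unit`, `sample_meta`, `mask`, and a `provenance` character vector that
#'   each pipeline stage appends to.
#' @export
expr_matrix <- function(values, unit = c("tpm", "counts", "logtpm"),
                        sample_meta = NULL, mask = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = colnames(values),
                              stringsAsFactors = FALSE)
  }
  if (!"sample" %in% names(sample_meta))
    stop("sample_meta must have a 'sample' column")
  if (!setequal(sample_meta$sample, colnames(values)))
    stop("sample_meta does not cover every sample")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(values)))
      stop("mask must be a logical matrix with the same dimensions as values")
  }
  if (unit == "tpm") {
    v <- values
    if (!is.null(mask)) v[mask] <- NA
    if (any(v < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  }
  structure(list(values = values, unit = unit, sample_meta = sample_meta,
                 mask = mask, provenance = character(0)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$mask))
    cat(sprintf("  masked cells: %d\n", sum(x$mask)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Extract the numeric matrix, with masked cells imputed or set NA
#'
#' @param x An `expr_matrix`.
#' @param impute How to treat masked cells: `"none"` (NA), or `"gene_mean"`
#'   (replace each masked cell by the mean of the gene's unmasked values).
#' @return A numeric matrix.
#' @export
expr_values <- function(x, impute = c("none", "gene_mean")) {
  impute <- match.arg(impute)
  v <- x$values
  if (!is.null(x$mask) && any(x$mask)) {
    v[x$mask] <- NA
    if (impute == "gene_mean") {
      gm <- rowMeans(v, na.rm = TRUE)
      idx <- which(is.na(v), arr.ind = TRUE)
      v[idx] <- gm[idx[, 1L]]
    }
  }
  v
}

stamp <- function(x, what) {
  x$provenance <- c(x$provenance, what)
  x
}

subset_expr <- function(x, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else genes
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else samples
  x$values <- x$values[gi, si, drop = FALSE]
  if (!is.null(x$mask)) x$mask <- x$mask[gi, si, drop = FALSE]
  x$sample_meta <- x$sample_meta[match(colnames(x$values),
                                       x$sample_meta$sample), , drop = FALSE]
  rownames(x$sample_meta) <- NULL
  x
}
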