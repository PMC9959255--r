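#' Expression dataset container
#'
#' A light-weight container in the spirit of limma's `EList`: a genes x
#' samples numeric matrix plus a sample-annotation data frame and a flag
#' recording whether values are on the log2 or the linear-intensity scale.
#'
#' @param exprs Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with one row per sample.  Must contain a
#'   `condition` column with exactly two levels (conventionally `"EA"` and
#'   `"NEA"`); any further columns are treated as covariates.
#' @param scale Either `"log2"` or `"intensity"`.
#'
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(exprs, samples, scale = c("log2", "intensity")) {
  scale <- match.arg(scale)
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    stopf("`exprs` must be a numeric matrix")
  }
  if (is.null(rownames(exprs))) {
    rownames(exprs) <- sprintf("g%05d", seq_len(nrow(exprs)))
  }
  if (anyDuplicated(rownames(exprs))) {
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(exprs)[duplicated(rownames(exprs))]), collapse = ", "))
  }
  if (!is.data.frame(samples) || nrow(samples) != ncol(exprs)) {
    stopf("`samples` must be a data frame with one row per column of `exprs`")
  }
  if (is.null(samples$condition)) stopf("`samples` must have a `condition` column")
  samples$condition <- as.factor(samples$condition)
  if (is.null(colnames(exprs))) colnames(exprs) <- rownames(samples)
  structure(list(exprs = exprs, samples = samples, scale = scale),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s scale)\n",
              nrow(x$exprs), ncol(x$exprs), x$scale))
  print(table(condition = x$samples$condition))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$exprs)

#' Subset an expression dataset to one condition
#'
#' @param dataset An [expression_dataset()].
#' @param condition Condition label to keep.
#' @return An `ExpressionDataset` with only the matching samples.
#' @export
subset_condition <- function(dataset, condition) {
  keep <- dataset$samples$condition == condition
  if (!any(keep)) stopf("no samples with condition '%s'", condition)
  expression_dataset(dataset$exprs[, keep, drop = FALSE],
                     droplevels(dataset$samples[keep, , drop = FALSE]),
                     scale = dataset$scale)
}

#' Convert a log2 dataset to the linear-intensity scale
#'
#' The inverse transform (`2^x`) feeds preprocessing steps that operate on
#' raw intensities, such as the coefficient-of-variation filter.
#'
#' @param dataset An [expression_dataset()] on the log2 scale.
#' @return An `ExpressionDataset` on the intensity scale.
#' @export
as_intensity <- function(dataset) {
  if (dataset$scale == "intensity") return(dataset)
  expression_dataset(2^dataset$exprs, dataset$samples, scale = "intensity")
}
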