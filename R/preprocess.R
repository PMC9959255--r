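# Expression preprocessing: background correction, quantile normalization,
# coefficient-of-variation filtering.  The pipeline order is background ->
# quantile -> CV filter; the CV band (default 0.3..10) is evaluated on the
# linear-intensity scale, where such a band is meaningful.

#' Preprocessing configuration
#'
#' @param bg_method `"subtract-floor"` (values at or below zero replaced by
#'   `floor`) or `"none"`.
#' @param floor Positive replacement value for non-positive intensities.
#' @param cv_low,cv_high Coefficient-of-variation retention band (sd/mean on
#'   the intensity scale), defaults 0.3 and 10.
#' @param log2_output Whether the pipeline returns log2 values.
#' @return A `PreprocConfig` list.
#' @export
preproc_config <- function(bg_method = c("subtract-floor", "none"), floor = 1,
                           cv_low = 0.3, cv_high = 10, log2_output = TRUE) {
  bg_method <- match.arg(bg_method)
  if (!is_number(floor) || floor <= 0) stopf("`floor` must be > 0")
  if (!(is_number(cv_low) && is_number(cv_high) && 0 < cv_low && cv_low < cv_high)) {
    stopf("need 0 < cv_low < cv_high")
  }
  structure(list(bg_method = bg_method, floor = floor, cv_low = cv_low,
                 cv_high = cv_high, log2_output = isTRUE(log2_output)),
            class = "PreprocConfig")
}

#' Background-correct a raw signal matrix
#'
#' Replaces non-positive (background-subtracted) signals by a small positive
#' floor, preserving the order of strictly positive values.
#'
#' @param raw_signal Numeric matrix of intensities (possibly negative after
#'   background subtraction).
#' @param config A [preproc_config()].
#' @return Corrected matrix on the intensity scale (log2 is applied by
#'   [preprocess_matrix()], not here).
#' @export
background_correct <- function(raw_signal, config = preproc_config()) {
  if (!all(is.finite(raw_signal))) stopf("`raw_signal` contains non-finite values")
  if (config$bg_method == "none") return(raw_signal)
  raw_signal[raw_signal <= 0] <- config$floor
  raw_signal
}

#' Quantile-normalize a matrix of intensities
#'
#' Each column's sorted values are replaced by the across-column means of
#' the order statistics, so all columns share an identical sorted value
#' multiset afterwards.  Ties within a column receive the mean of the
#' reference values they span (average-rank interpolation).
#'
#' @param x Numeric matrix (genes x samples), no missing values.
#' @return Normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  if (anyNA(x)) stopf("missing values are not supported")
  if (ncol(x) < 2L) {
    warnf("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  sorted <- apply(x, 2L, sort)
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- ref
    g <- x[o, j]
    # tied values share the mean of the reference quantiles they span
    if (anyDuplicated(g)) v <- stats::ave(ref, match(g, unique(g)))
    out[o, j] <- v
  }
  out
}

#' Filter genes by coefficient of variation
#'
#' Keeps genes whose sample coefficient of variation (sd/mean, denominator
#' n-1) lies within `[cv_low, cv_high]`.  CV must be computed on the
#' linear-intensity scale; genes with non-positive mean are excluded with a
#' recorded reason.
#'
#' @param x Numeric intensity matrix (genes x samples).
#' @param cv_low,cv_high Retention band.
#' @return List with `matrix` (kept rows), `kept` (gene ids) and `report`
#'   (data frame: gene, cv, kept, reason).
#' @export
cv_filter <- function(x, cv_low = 0.3, cv_high = 10) {
  if (!(cv_low < cv_high)) stopf("need cv_low < cv_high")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  reason <- rep("", nrow(x))
  keep <- !is.na(cv) & cv >= cv_low & cv <= cv_high
  reason[is.na(cv)] <- "non-positive mean"
  reason[!is.na(cv) & cv < cv_low] <- "cv below band"
  reason[!is.na(cv) & cv > cv_high] <- "cv above band"
  list(matrix = x[keep, , drop = FALSE], kept = ids[keep],
       report = data.frame(gene = ids, cv = cv, kept = keep, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Run the full preprocessing pipeline on an intensity dataset
#'
#' Background correction, quantile normalization and CV filtering, in that
#' order; optionally log2-transforms the output.
#'
#' @param dataset An [expression_dataset()] on the intensity scale (log2
#'   input is converted).
#' @param config A [preproc_config()].
#' @return List with `dataset` (preprocessed [expression_dataset()]) and
#'   `report` (the CV-filter report).
#' @export
preprocess_matrix <- function(dataset, config = preproc_config()) {
  stopifnot(inherits(dataset, "ExpressionDataset"), inherits(config, "PreprocConfig"))
  x <- as_intensity(dataset)$exprs
  x <- background_correct(x, config)
  x <- quantile_normalize(x)
  flt <- cv_filter(x, config$cv_low, config$cv_high)
  out <- flt$matrix
  scale <- "intensity"
  if (config$log2_output) {
    out <- log2(out)
    scale <- "log2"
  }
  list(dataset = expression_dataset(out, dataset$samples, scale = scale),
       report = flt$report)
}
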