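#' Reads-per-million normalization
#'
#' Scales each sample to reads per million (RPM/CPM). The library size is
#' the column sum over all genes, host and symbiont together, so host and
#' symbiont RPM values share a common scale within a sample. Optional TMM
#' factors multiply the library sizes (effective library sizes).
#'
#' @param cm A [count_matrix()].
#' @param tmm_factors Optional per-sample positive factors from
#'   [tmm_factors()], in column order or named by sample id.
#' @return An object of class `expression_matrix`: list with `values`
#'   (genes x samples), `design`, `organism`, `scale` (`"rpm"`),
#'   `pseudocount` (0) and `tmm_factors`.
#' @export
normalize_rpm <- function(cm, tmm_factors = NULL) {
  lib <- colSums(cm$counts)
  if (any(lib <= 0))
    stop("zero library size in sample: ",
         paste(colnames(cm$counts)[lib <= 0], collapse = ", "))
  if (!is.null(tmm_factors)) {
    if (!is.null(names(tmm_factors)))
      tmm_factors <- tmm_factors[colnames(cm$counts)]
    if (length(tmm_factors) != ncol(cm$counts) ||
        any(!is.finite(tmm_factors)) || any(tmm_factors <= 0))
      stop("tmm_factors must be one positive factor per sample")
    lib <- lib * tmm_factors
  }
  values <- sweep(cm$counts, 2, lib, "/") * 1e6
  structure(list(values = values, design = cm$design,
                 organism = cm$organism, scale = "rpm", pseudocount = 0,
                 tmm_factors = tmm_factors),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, scale = ", x$scale, sep = "")
  if (x$scale != "rpm") cat(", pseudocount = ", x$pseudocount, sep = "")
  cat("\n")
  invisible(x)
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values scaling factors between samples: a
#' precision-weighted mean of per-gene log count ratios to a reference
#' sample after trimming 30% on M (log ratio) and 5% on A (average log
#' abundance), renormalized to geometric mean 1. Computed by edgeR's
#' published TMM implementation; the reference defaults to the sample
#' whose upper-quartile count fraction is closest to the mean.
#'
#' @param cm A [count_matrix()].
#' @param reference Optional sample id used as reference.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(cm, reference = NULL) {
  if (ncol(cm$counts) < 2) stop("TMM needs at least 2 samples")
  ref_col <- NULL
  if (!is.null(reference)) {
    ref_col <- match(reference, colnames(cm$counts))
    if (is.na(ref_col)) stop("reference sample not found: ", reference)
  }
  if (!is.null(ref_col)) {
    shared <- (cm$counts[, ref_col] > 0) & (cm$counts > 0)
    if (any(colSums(shared) == 0))
      stop("a sample shares no nonzero gene with the reference")
  }
  f <- edgeR::calcNormFactors(cm$counts, method = "TMM",
                              refColumn = ref_col)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("TMM factors undefined; samples may share no nonzero genes")
  stats::setNames(f, colnames(cm$counts))
}

#' Log2 transformation with per-sample median centering
#'
#' Transforms RPM values to `log2(rpm + pseudocount)` and subtracts the
#' per-sample median of the transformed values, so every sample's median
#' is exactly zero. The transform is strictly increasing at fixed
#' pseudocount, so within-gene orderings (and hence monotone-trend calls)
#' are unchanged by this step.
#'
#' @param em An `expression_matrix` on the `rpm` scale.
#' @param pseudocount Non-negative value added before the log; with 0,
#'   zero RPM maps to `-Inf` (still ordered below every finite value).
#' @return An `expression_matrix` with scale `"log2_rpm_median_centered"`.
#' @export
log_median_center <- function(em, pseudocount = 1) {
  if (!inherits(em, "expression_matrix") || em$scale != "rpm")
    stop("log_median_center expects an expression_matrix on the rpm scale")
  if (!is.finite(pseudocount) || pseudocount < 0)
    stop("pseudocount must be >= 0")
  lv <- log2(em$values + pseudocount)
  med <- apply(lv, 2, stats::median)
  em$values <- sweep(lv, 2, med, "-")
  em$scale <- "log2_rpm_median_centered"
  em$pseudocount <- pseudocount
  em
}
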