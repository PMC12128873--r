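#' Normalise abundances per cell or per chromosomal content
#'
#' `per_cell` divides by a per-sample cell count (or protein proxy);
#' `per_ploidy` divides by the chromosomal content relative to the diploid
#' 46-chromosome baseline, i.e. by `chromosome_count / 46`, so a
#' tetraploid (92-chromosome) measurement is halved and a diploid one is
#' unchanged.
#'
#' @param values Numeric vector of abundances.
#' @param mode `"per_ploidy"` or `"per_cell"`.
#' @param chromosome_count Integer chromosome count(s), required for
#'   `per_ploidy` (recycled).
#' @param cell_count Cell counts (or protein), required for `per_cell`.
#' @return Numeric vector of normalised values.
#' @examples
#' normalize_abundance(10, "per_ploidy", chromosome_count = 92)  # 5
#' @export
normalize_abundance <- function(values, mode = c("per_ploidy", "per_cell"),
                                chromosome_count = NULL, cell_count = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_ploidy") {
    if (is.null(chromosome_count)) {
      stop("per_ploidy normalisation requires chromosome_count")
    }
    if (any(chromosome_count < 1)) stop("chromosome_count must be >= 1")
    values / (chromosome_count / 46)
  } else {
    if (is.null(cell_count)) stop("per_cell normalisation requires cell_count")
    if (any(cell_count <= 0)) stop("cell_count must be > 0")
    values / cell_count
  }
}

#' Simple abundance ratios (labeled::unlabeled, GSH::GSSG, ATP::AMP)
#'
#' Computes elementwise `numerator / denominator`. Nonpositive
#' denominators yield `NA` with a warning rather than a fabricated value.
#'
#' @param numerator,denominator Numeric vectors (recycled).
#' @return Numeric vector of ratios.
#' @export
ratio_metric <- function(numerator, denominator) {
  n <- max(length(numerator), length(denominator))
  numerator <- rep_len(numerator, n)
  denominator <- rep_len(denominator, n)
  bad <- !is.na(denominator) & denominator <= 0
  if (any(bad)) {
    warning(sum(bad), " ratio(s) undefined (nonpositive denominator); NA returned")
  }
  out <- numerator / denominator
  out[bad] <- NA_real_
  out
}

#' Associate features with aneuploidy burden by linear regression
#'
#' Fits, for every feature, the ordinary least squares model
#' `feature ~ burden` across samples (the `lm`-style analysis used for
#' metabolite levels and gene-effect scores versus net-gain aneuploidy)
#' and reports the slope per unit burden, the two-sided p-value, and
#' Benjamini-Hochberg FDR across all tested features. The slopes are
#' directly usable as a ranking metric for [preranked_gsea()].
#'
#' @param features Samples x features numeric matrix (rownames = sample
#'   ids); a features x samples matrix is auto-transposed when its
#'   colnames match the burden names and rownames do not.
#' @param burden Named numeric vector of per-sample burden scores.
#' @return A `data.frame` per feature: `feature`, `coefficient`, `p`,
#'   `fdr`, `n`.
#' @export
associate_with_burden <- function(features, burden) {
  features <- as.matrix(features)
  if (is.null(names(burden))) stop("burden must be named by sample")
  if (!all(rownames(features) %in% names(burden)) &&
      all(colnames(features) %in% names(burden))) {
    features <- t(features)
  }
  common <- intersect(rownames(features), names(burden))
  if (length(common) < 3) stop("need >= 3 samples with both feature and burden data")
  features <- features[common, , drop = FALSE]
  b <- burden[common]
  if (stats::sd(b) == 0) stop("burden has zero variance; slope unidentifiable")
  fits <- lapply(seq_len(ncol(features)), function(j) {
    y <- features[, j]
    ok <- !is.na(y)
    if (sum(ok) < 3) return(c(NA_real_, NA_real_, sum(ok)))
    sm <- summary(stats::lm(y[ok] ~ b[ok]))
    co <- stats::coef(sm)
    if (nrow(co) < 2) return(c(0, 1, sum(ok)))  # constant feature
    c(co[2, 1], co[2, 4], sum(ok))
  })
  m <- do.call(rbind, fits)
  res <- data.frame(
    feature = colnames(features) %||% as.character(seq_len(ncol(features))),
    coefficient = m[, 1], p = m[, 2],
    fdr = stats::p.adjust(m[, 2], "BH"), n = as.integer(m[, 3]),
    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Estimate mitochondrial DNA copies per cell from coverage
#'
#' From whole-genome sequencing coverage, mitochondrial genome copies per
#' cell are `nuclear_ploidy * mean_mt_coverage / mean_autosomal_coverage`
#' (each nuclear copy contributes one unit of autosomal coverage).
#'
#' @param mean_mt_coverage Mean read depth over the mitochondrial genome.
#' @param mean_autosomal_coverage Mean autosomal read depth.
#' @param nuclear_ploidy Nuclear genome copies per cell (default 2).
#' @return Estimated mtDNA copies per cell.
#' @examples
#' mito_copy_estimate(1000, 10)  # 200 copies in a diploid cell
#' @export
mito_copy_estimate <- function(mean_mt_coverage, mean_autosomal_coverage,
                               nuclear_ploidy = 2) {
  if (any(mean_mt_coverage <= 0) || any(mean_autosomal_coverage <= 0)) {
    stop("coverages must be positive")
  }
  nuclear_ploidy * mean_mt_coverage / mean_autosomal_coverage
}
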