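#' Infer copy-number alterations from bulk expression
#'
#' Estimates copy number along the genome from an expression matrix using a
#' reference cohort of non-tumor samples: each gene is normalised to its
#' reference mean, the normalised values are smoothed along each chromosome
#' with a centered moving average of `window` genes (odd-forced; shrunk,
#' with a warning, on chromosomes carrying fewer genes), and each tumor
#' sample is re-centered so its median modified expression equals 1. Genes
#' with modified expression above `expr_gain` (default 1.02) are called
#' gained and below `expr_loss` (default 0.98) lost; the per-sample burden
#' is gained minus lost genes (megabases if `length_bp` is provided in
#' `gene_info`).
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene ids).
#' @param gene_info `data.frame` with one row per gene: `gene`, `chrom`, and
#'   `pos` (bp midpoint used for ordering); optional `length_bp`.
#' @param reference Character vector of reference (normal) sample names;
#'   must be non-empty and disjoint from the tumor samples analysed.
#' @param window Moving-average width in genes (default 101; forced odd).
#' @param th Thresholds from [default_thresholds()].
#' @return A list: `modified_expr` (genes x tumor samples), `calls`
#'   (same shape, `"gain"`/`"loss"`/`"neutral"`), `burden` (per-sample
#'   `data.frame` with `gain`, `loss`, `net`, `class`, `unit`).
#' @export
infer_cna_from_expression <- function(expr, gene_info, reference,
                                      window = 101,
                                      th = default_thresholds()) {
  expr <- as.matrix(expr)
  if (length(reference) == 0) stop("reference sample set must be non-empty")
  if (!all(reference %in% colnames(expr))) {
    stop("reference sample(s) absent from expression matrix: ",
         paste(setdiff(reference, colnames(expr)), collapse = ", "))
  }
  tumors <- setdiff(colnames(expr), reference)
  if (length(tumors) == 0) stop("no tumor samples: all columns are reference")
  if (!all(rownames(expr) %in% gene_info$gene)) {
    stop("gene_info does not cover all expression rows")
  }
  info <- gene_info[match(rownames(expr), gene_info$gene), ]
  info$chrom <- normalize_chrom(info$chrom)
  ord <- order(match(info$chrom, unique(info$chrom)), info$pos)
  expr <- expr[ord, , drop = FALSE]
  info <- info[ord, , drop = FALSE]

  ref_mean <- rowMeans(expr[, reference, drop = FALSE])
  if (any(ref_mean <= 0)) stop("nonpositive reference mean expression for some genes")
  norm <- expr[, tumors, drop = FALSE] / ref_mean

  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (window %% 2 == 0) window <- window + 1L

  smoothed <- norm
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    w <- window
    if (w > length(idx)) {
      w <- length(idx) - (1 - length(idx) %% 2)  # largest odd <= n
      warning("window shrunk to ", w, " on chromosome ", ch,
              " (", length(idx), " genes)")
    }
    smoothed[idx, ] <- apply(norm[idx, , drop = FALSE], 2, running_mean, w = w)
  }

  med <- apply(smoothed, 2, stats::median)
  modified <- sweep(smoothed, 2, med, "/")

  calls <- matrix("neutral", nrow(modified), ncol(modified),
                  dimnames = dimnames(modified))
  calls[modified > th$expr_gain] <- "gain"
  calls[modified < th$expr_loss] <- "loss"

  w_mb <- if (!is.null(info$length_bp)) info$length_bp / 1e6 else rep(1, nrow(info))
  unit <- if (!is.null(info$length_bp)) "mb" else "genes"
  gain <- colSums((calls == "gain") * w_mb)
  loss <- colSums((calls == "loss") * w_mb)
  net <- gain - loss
  burden <- data.frame(
    sample = tumors, gain = unname(gain), loss = unname(loss), net = unname(net),
    class = ifelse(net > 0, "net_gain", ifelse(net < 0, "net_loss", "balanced")),
    unit = unit, stringsAsFactors = FALSE, row.names = NULL
  )
  list(modified_expr = modified, calls = calls, burden = burden)
}

# centered moving average with shrinking (partial) windows at the edges
running_mean <- function(x, w) {
  n <- length(x)
  if (w >= n) return(rep(mean(x), n))
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
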