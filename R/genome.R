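#' Toy chromosome-arm table
#'
#' A small 10-arm genome (five chromosomes, p and q each) used as the default
#' coordinate system for simulation and burden scoring. Real cytoband-derived
#' arm tables (hg19/hg38) can be supplied instead via [read_arm_table()].
#'
#' Coordinates are 1-based inclusive; megabases are computed as
#' `(end_bp - start_bp + 1) / 1e6`.
#'
#' @return A `data.frame` with columns `chrom`, `arm` (`"p"` or `"q"`),
#'   `arm_id` (e.g. `"1p"`), `start_bp`, `end_bp`, validated by
#'   [validate_genome()].
#' @examples
#' g <- toy_genome()
#' sum(arm_lengths_mb(g))  # total genome size in Mb
#' @export
toy_genome <- function() {
  g <- data.frame(
    chrom    = rep(as.character(1:5), each = 2),
    arm      = rep(c("p", "q"), 5),
    start_bp = c(1, 50e6 + 1, 1, 40e6 + 1, 1, 30e6 + 1, 1, 25e6 + 1, 1, 20e6 + 1),
    end_bp   = c(50e6, 120e6, 40e6, 100e6, 30e6, 90e6, 25e6, 70e6, 20e6, 60e6),
    stringsAsFactors = FALSE
  )
  g$arm_id <- paste0(g$chrom, g$arm)
  validate_genome(g)
}

#' Validate a chromosome-arm table
#'
#' Checks that arms are non-overlapping within each chromosome, that p
#' precedes q, and that every arm has positive length. Adds an `arm_id`
#' column (`chrom` + `arm`) if absent.
#'
#' @param genome A `data.frame` with columns `chrom`, `arm`, `start_bp`,
#'   `end_bp`.
#' @return The validated genome table (invisibly the same data, normalised).
#' @export
validate_genome <- function(genome) {
  stopifnot(is.data.frame(genome))
  req <- c("chrom", "arm", "start_bp", "end_bp")
  missing_cols <- setdiff(req, names(genome))
  if (length(missing_cols)) {
    stop("genome table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genome$chrom <- normalize_chrom(genome$chrom)
  if (!all(genome$arm %in% c("p", "q"))) {
    stop("arm must be 'p' or 'q'")
  }
  if (any(genome$end_bp <= genome$start_bp)) {
    stop("every arm must have end_bp > start_bp")
  }
  if (is.null(genome$arm_id)) genome$arm_id <- paste0(genome$chrom, genome$arm)
  if (anyDuplicated(genome$arm_id)) stop("duplicated arm ids")
  for (ch in unique(genome$chrom)) {
    sub <- genome[genome$chrom == ch, ]
    sub <- sub[order(sub$start_bp), ]
    if (nrow(sub) > 1) {
      if (any(sub$start_bp[-1] <= sub$end_bp[-nrow(sub)])) {
        stop("overlapping arms on chromosome ", ch)
      }
      pq <- sub$arm
      if (any(pq != sort(pq))) stop("p arm must precede q arm on chromosome ", ch)
    }
  }
  genome
}

#' Arm lengths in megabases
#'
#' @param genome An arm table as returned by [toy_genome()].
#' @return Named numeric vector of arm lengths (Mb), named by `arm_id`.
#' @export
arm_lengths_mb <- function(genome) {
  genome <- validate_genome(genome)
  stats::setNames((genome$end_bp - genome$start_bp + 1) / 1e6, genome$arm_id)
}

#' Normalise chromosome labels
#'
#' Strips any leading `"chr"` prefix so that `"chr1"` and `"1"` compare equal;
#' case-insensitive.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalised labels.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

#' Copy-number calling thresholds
#'
#' Bundles the calling cutoffs used throughout burden scoring. Defaults are
#' the values used for the three input modalities:
#' purity-corrected arm-level segment means are called lost below
#' `arm_loss_log2 = -0.41` and gained above `arm_gain_log2 = +0.32`, with at
#' least `min_arm_fraction = 0.5` of the arm affected; gene-level copy number
#' on the log2(copy ratio + 1) scale (diploid = 1) is called lost below
#' `gene_loss_l2cn1 = 0.8` and gained above `gene_gain_l2cn1 = 1.16`;
#' reference-normalised modified expression is called gained above
#' `expr_gain = 1.02` and lost below `expr_loss = 0.98`.
#'
#' @param arm_gain_log2,arm_loss_log2 Arm-level segment-mean cutoffs (log2
#'   copy ratio).
#' @param min_arm_fraction Minimum fraction of an arm that must pass a cutoff
#'   for the arm to be called.
#' @param gene_gain_l2cn1,gene_loss_l2cn1 Gene-level cutoffs on the
#'   log2(copy ratio + 1) scale.
#' @param expr_gain,expr_loss Modified-expression cutoffs.
#' @return An object of class `"aneu_thresholds"` (a named list).
#' @export
default_thresholds <- function(arm_gain_log2 = 0.32, arm_loss_log2 = -0.41,
                               min_arm_fraction = 0.5,
                               gene_gain_l2cn1 = 1.16, gene_loss_l2cn1 = 0.8,
                               expr_gain = 1.02, expr_loss = 0.98) {
  th <- list(
    arm_gain_log2 = arm_gain_log2, arm_loss_log2 = arm_loss_log2,
    min_arm_fraction = min_arm_fraction,
    gene_gain_l2cn1 = gene_gain_l2cn1, gene_loss_l2cn1 = gene_loss_l2cn1,
    expr_gain = expr_gain, expr_loss = expr_loss
  )
  if (th$arm_gain_log2 <= th$arm_loss_log2 ||
      th$gene_gain_l2cn1 <= th$gene_loss_l2cn1 ||
      th$expr_gain <= th$expr_loss) {
    stop("gain cutoff must exceed loss cutoff in each calling scheme")
  }
  if (th$min_arm_fraction < 0 || th$min_arm_fraction > 1) {
    stop("min_arm_fraction must be in [0, 1]")
  }
  structure(th, class = "aneu_thresholds")
}
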