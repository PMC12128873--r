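#' Correct segment log2 ratios for tumor purity
#'
#' De-mixes the observed tumor/normal copy ratio on the linear scale: with
#' tumor purity p, the observed ratio is `R_obs = p * R_tumor + (1 - p)`, so
#' `R_tumor = (R_obs - (1 - p)) / p` and the corrected value is
#' `log2(R_tumor)`. At purity 1 this is the identity; a neutral segment
#' (ratio 1) is invariant under mixing at any purity.
#'
#' Segments whose implied tumor ratio is nonpositive (observed ratio at or
#' below the normal-contamination floor `1 - p`) are uncorrectable; they are
#' returned as `NA` with a warning so callers can exclude them.
#'
#' @param log2_ratio Numeric vector of observed segment means (log2 copy
#'   ratio).
#' @param purity Numeric vector in (0, 1], recycled against `log2_ratio`.
#' @return Numeric vector of purity-corrected log2 ratios (`NA` where
#'   uncorrectable).
#' @examples
#' purity_correct(log2(1.25), 0.5)  # one extra copy seen at 50% purity -> log2(1.5)
#' @export
purity_correct <- function(log2_ratio, purity) {
  if (any(purity <= 0 | purity > 1, na.rm = TRUE)) {
    stop("purity must be in (0, 1]")
  }
  n <- max(length(log2_ratio), length(purity))
  log2_ratio <- rep_len(log2_ratio, n)
  purity <- rep_len(purity, n)
  tumor_ratio <- (2^log2_ratio - (1 - purity)) / purity
  bad <- !is.na(tumor_ratio) & tumor_ratio <= 0
  if (any(bad)) {
    warning(sum(bad), " segment(s) uncorrectable at given purity ",
            "(implied tumor ratio nonpositive); returned as NA")
    tumor_ratio[bad] <- NA_real_
  }
  log2(tumor_ratio)
}

#' Purity-correct a segment table
#'
#' Applies [purity_correct()] to the `log2_ratio` column of a segment table,
#' using a per-sample purity map (or a `purity` column already present).
#' Uncorrectable segments are dropped with a warning.
#'
#' @param segments Segment table: columns `sample`, `chrom`, `start_bp`,
#'   `end_bp`, `log2_ratio` and optionally `purity`.
#' @param purity Named numeric vector (names = sample ids) or single value;
#'   ignored if `segments$purity` exists. Default 1 (no correction).
#' @return The segment table with corrected `log2_ratio` (and the purity
#'   used in a `purity` column).
#' @export
correct_segments <- function(segments, purity = 1) {
  segments <- check_segment_table(segments)
  if (is.null(segments$purity)) {
    if (!is.null(names(purity))) {
      miss <- setdiff(unique(segments$sample), names(purity))
      if (length(miss)) stop("no purity for sample(s): ", paste(miss, collapse = ", "))
      segments$purity <- unname(purity[segments$sample])
    } else {
      segments$purity <- rep_len(purity, nrow(segments))
    }
  }
  segments$log2_ratio <- purity_correct(segments$log2_ratio, segments$purity)
  drop <- is.na(segments$log2_ratio)
  if (any(drop)) {
    warning("dropping ", sum(drop), " uncorrectable segment(s)")
    segments <- segments[!drop, , drop = FALSE]
  }
  segments
}

check_segment_table <- function(segments) {
  req <- c("sample", "chrom", "start_bp", "end_bp", "log2_ratio")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(segments$end_bp < segments$start_bp)) stop("segment end_bp < start_bp")
  segments$chrom <- normalize_chrom(segments$chrom)
  segments$sample <- as.character(segments$sample)
  segments
}

#' Call arm-level gain/loss events from purity-corrected segments
#'
#' For each sample and chromosome arm, sums the megabases covered by
#' segments whose (purity-corrected) log2 ratio exceeds the gain cutoff or
#' falls below the loss cutoff. The arm is called `gain` (resp. `loss`) when
#' the qualifying megabases reach at least `min_arm_fraction` of the arm
#' length; if both directions qualify, the direction with the larger
#' affected span wins, with an exact tie resolved to `neutral`.
#'
#' Segments overlapping no arm of the supplied genome are skipped with a
#' warning.
#'
#' @param segments Purity-corrected segment table (see [correct_segments()]).
#' @param genome Arm table (see [toy_genome()]).
#' @param th Thresholds from [default_thresholds()].
#' @return A `data.frame` with one row per sample x arm: `sample`, `arm_id`,
#'   `call` (`gain`/`loss`/`neutral`), `affected_mb` (megabases meeting the
#'   winning cutoff), `arm_fraction`, `arm_mb`.
#' @export
call_arm_events <- function(segments, genome = toy_genome(),
                            th = default_thresholds()) {
  segments <- check_segment_table(segments)
  genome <- validate_genome(genome)
  arm_mb <- arm_lengths_mb(genome)

  # intersect every segment with every arm on the same chromosome
  seg_arm <- merge(segments, genome, by = "chrom", suffixes = c("", ".arm"))
  ov_start <- pmax(seg_arm$start_bp, seg_arm$start_bp.arm)
  ov_end <- pmin(seg_arm$end_bp, seg_arm$end_bp.arm)
  keep <- ov_end >= ov_start
  # identify segments with no arm overlap at all
  seg_key <- paste(segments$sample, segments$chrom, segments$start_bp, segments$end_bp)
  hit_key <- unique(paste(seg_arm$sample, seg_arm$chrom, seg_arm$start_bp, seg_arm$end_bp)[keep])
  orphan <- !(seg_key %in% hit_key)
  if (any(orphan)) {
    warning("skipping ", sum(orphan), " segment(s) outside any arm")
  }

  seg_arm <- seg_arm[keep, , drop = FALSE]
  ov_mb <- (pmin(seg_arm$end_bp, seg_arm$end_bp.arm) -
              pmax(seg_arm$start_bp, seg_arm$start_bp.arm) + 1) / 1e6
  is_gain <- seg_arm$log2_ratio > th$arm_gain_log2
  is_loss <- seg_arm$log2_ratio < th$arm_loss_log2

  samples <- unique(segments$sample)
  grid <- expand.grid(sample = samples, arm_id = genome$arm_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(seg_arm$sample, seg_arm$arm_id)
  gkey <- paste(grid$sample, grid$arm_id)
  sum_by <- function(w) {
    v <- tapply(ov_mb[w], key[w], sum)
    out <- rep(0, nrow(grid))
    out[match(names(v), gkey)] <- v
    out
  }
  gain_mb <- sum_by(is_gain)
  loss_mb <- sum_by(is_loss)
  grid$arm_mb <- unname(arm_mb[grid$arm_id])

  call <- rep("neutral", nrow(grid))
  gain_ok <- gain_mb / grid$arm_mb >= th$min_arm_fraction
  loss_ok <- loss_mb / grid$arm_mb >= th$min_arm_fraction
  call[gain_ok & !loss_ok] <- "gain"
  call[loss_ok & !gain_ok] <- "loss"
  both <- gain_ok & loss_ok
  call[both & gain_mb > loss_mb] <- "gain"
  call[both & loss_mb > gain_mb] <- "loss"
  # both qualifying with equal span -> neutral (already default)

  grid$call <- call
  grid$affected_mb <- ifelse(call == "gain", gain_mb,
                             ifelse(call == "loss", loss_mb, pmax(gain_mb, loss_mb)))
  grid$arm_fraction <- grid$affected_mb / grid$arm_mb
  grid[order(grid$sample, grid$arm_id), c("sample", "arm_id", "call",
                                          "affected_mb", "arm_fraction", "arm_mb")]
}

#' Aneuploidy burden: gain minus loss megabases
#'
#' Sums, per sample, the genomic megabases affected by called chromosomal
#' gains and by called losses, and reports `net_mb = gain_mb - loss_mb`.
#' Samples with `net_mb > 0` are classed `net_gain`, `net_mb < 0`
#' `net_loss`, and exactly 0 `balanced`.
#'
#' Two weighting conventions are provided: `"segment"` (default) sums the
#' megabases actually meeting the cutoff on each called arm; `"arm"` counts
#' the full arm length for every called arm.
#'
#' @param calls Arm calls from [call_arm_events()].
#' @param weighting `"segment"` or `"arm"`.
#' @return A `data.frame` per sample: `sample`, `gain_mb`, `loss_mb`,
#'   `net_mb`, `class`.
#' @export
aneuploidy_burden <- function(calls, weighting = c("segment", "arm")) {
  weighting <- match.arg(weighting)
  if (nrow(calls) == 0) {
    warning("no arm calls supplied; returning empty burden table")
    return(data.frame(sample = character(), gain_mb = numeric(),
                      loss_mb = numeric(), net_mb = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  w <- if (weighting == "segment") calls$affected_mb else calls$arm_mb
  samples <- unique(calls$sample)
  agg <- function(dir) {
    v <- tapply(w[calls$call == dir], calls$sample[calls$call == dir], sum)
    out <- stats::setNames(rep(0, length(samples)), samples)
    out[names(v)] <- v
    out
  }
  gain_mb <- agg("gain")
  loss_mb <- agg("loss")
  net <- gain_mb - loss_mb
  data.frame(
    sample = samples,
    gain_mb = unname(gain_mb), loss_mb = unname(loss_mb), net_mb = unname(net),
    class = ifelse(net > 0, "net_gain", ifelse(net < 0, "net_loss", "balanced")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' End-to-end burden scoring from raw segments
#'
#' Convenience wrapper: purity-correct, call arms, score burden.
#'
#' @inheritParams correct_segments
#' @inheritParams call_arm_events
#' @inheritParams aneuploidy_burden
#' @return See [aneuploidy_burden()].
#' @export
score_segments <- function(segments, genome = toy_genome(),
                           th = default_thresholds(), purity = 1,
                           weighting = c("segment", "arm")) {
  seg <- correct_segments(segments, purity)
  calls <- call_arm_events(seg, genome, th)
  aneuploidy_burden(calls, match.arg(weighting))
}

#' Gene-level net-gain burden from a copy-number matrix
#'
#' Counts, per sample, genes gained minus genes lost on the
#' log2(copy ratio + 1) scale (diploid-neutral value 1.0): a gene is gained
#' above `gene_gain_l2cn1` (default 1.16) and lost below `gene_loss_l2cn1`
#' (default 0.8). If per-gene lengths (bp) are supplied the burden is
#' reported in megabases instead of gene counts.
#'
#' A median far from the diploid value (outside [0.5, 1.5]) triggers a
#' probable scale-mismatch warning.
#'
#' @param gene_cn Numeric matrix, genes x samples, on the log2(ratio + 1)
#'   scale.
#' @param th Thresholds from [default_thresholds()].
#' @param gene_lengths_bp Optional numeric vector (one per gene row) for
#'   megabase weighting.
#' @return A `data.frame` per sample: `sample`, `gain`, `loss`, `net`,
#'   `class`, `unit` (`"genes"` or `"mb"`).
#' @export
gene_level_burden <- function(gene_cn, th = default_thresholds(),
                              gene_lengths_bp = NULL) {
  gene_cn <- as.matrix(gene_cn)
  med <- stats::median(gene_cn, na.rm = TRUE)
  if (med < 0.5 || med > 1.5) {
    warning("matrix median ", signif(med, 3),
            " outside [0.5, 1.5]: values probably not on the log2(copy ratio + 1) scale")
  }
  w <- if (is.null(gene_lengths_bp)) rep(1, nrow(gene_cn)) else gene_lengths_bp / 1e6
  unit <- if (is.null(gene_lengths_bp)) "genes" else "mb"
  gained <- (gene_cn > th$gene_gain_l2cn1) * w
  lost <- (gene_cn < th$gene_loss_l2cn1) * w
  gain <- colSums(gained, na.rm = TRUE)
  loss <- colSums(lost, na.rm = TRUE)
  net <- gain - loss
  data.frame(
    sample = colnames(gene_cn) %||% as.character(seq_len(ncol(gene_cn))),
    gain = unname(gain), loss = unname(loss), net = unname(net),
    class = ifelse(net > 0, "net_gain", ifelse(net < 0, "net_loss", "balanced")),
    unit = unit, stringsAsFactors = FALSE, row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
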