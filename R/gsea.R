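#' Pre-ranked gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Scores each gene set against a ranked gene list with the weighted
#' Kolmogorov-Smirnov running sum: walking down the ranking, hitting a set
#' member increments the sum by `|score|^weight / sum(|score|^weight over
#' hits)` and missing decrements by `1 / (N - Nh)`; the enrichment score ES
#' is the maximum deviation from zero. Significance and NES come from
#' gene-label permutation: random sets of the same size are drawn from the
#' ranking, the p-value is the one-sided permutation tail on the matching
#' sign with the `(b + 1) / (n_perm + 1)` correction, and
#' `NES = ES / mean(|null ES| of the same sign)`. FDR is
#' Benjamini-Hochberg across tested sets.
#'
#' Sets are filtered to sizes within `[min_size, max_size]` after
#' intersection with the ranking; sets with empty intersection, or covering
#' the whole ranking (degenerate, `Nh = N`), are skipped and listed in the
#' `skipped` attribute.
#'
#' @param stats Named numeric vector of gene scores (ranking metric); no
#'   duplicate names.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param weight KS weight exponent p (default 1; 0 gives the unweighted
#'   statistic).
#' @param n_perm Permutations per set size (default 1000).
#' @param min_size,max_size Post-intersection set-size filter (default
#'   5-500).
#' @param seed Integer seed.
#' @return A `data.frame` per retained set: `set`, `size`, `es`, `nes`,
#'   `p`, `fdr`, `leading_edge` (semicolon-joined genes); attribute
#'   `skipped` names the sets not tested.
#' @examples
#' r <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
#' preranked_gsea(r, list(top = c("a", "b")), min_size = 2, n_perm = 200)
#' @export
preranked_gsea <- function(stats, gene_sets, weight = 1, n_perm = 1000,
                           min_size = 5, max_size = 500, seed = 1L) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be a named vector without duplicate gene names")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  ord <- order(stats, decreasing = TRUE)
  ranked <- stats[ord]
  genes <- names(ranked)
  N <- length(genes)
  aw <- abs(ranked)^weight

  sizes <- vapply(gene_sets, function(s) length(intersect(s, genes)), integer(1))
  skipped <- names(gene_sets)[sizes == 0 | sizes >= N |
                                sizes < min_size | sizes > max_size]
  keep <- setdiff(names(gene_sets), skipped)
  if (length(skipped)) {
    message(length(skipped), " gene set(s) skipped (empty intersection, ",
            "degenerate, or outside the size filter)")
  }
  if (length(keep) == 0) {
    res <- data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE)
    attr(res, "skipped") <- skipped
    return(res)
  }

  set.seed(as.integer(seed))
  null_cache <- new.env(parent = emptyenv())
  rows <- lapply(keep, function(nm) {
    hit <- genes %in% gene_sets[[nm]]
    es <- ks_running_es(hit, aw)
    s <- sum(hit)
    key <- as.character(s)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- vapply(seq_len(n_perm), function(i) {
        h <- logical(N)
        h[sample.int(N, s)] <- TRUE
        ks_running_es(h, aw)$es
      }, numeric(1))
    }
    null_es <- null_cache[[key]]
    same_sign <- if (es$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    b <- if (es$es >= 0) sum(same_sign >= es$es) else sum(same_sign <= es$es)
    p <- (b + 1) / (length(same_sign) + 1)
    nes <- if (length(same_sign)) es$es / mean(abs(same_sign)) else NA_real_
    le <- if (es$es >= 0) genes[seq_len(es$peak)][hit[seq_len(es$peak)]]
          else genes[es$peak:N][hit[es$peak:N]]
    data.frame(set = nm, size = s, es = es$es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, "BH")
  res <- res[, c("set", "size", "es", "nes", "p", "fdr", "leading_edge")]
  attr(res, "skipped") <- skipped
  res
}

# running-sum ES for a hit indicator over a ranked list; aw = |score|^weight
ks_running_es <- function(hit, aw) {
  N <- length(hit)
  nh <- sum(hit)
  denom_hit <- sum(aw[hit])
  step <- ifelse(hit,
                 if (denom_hit > 0) aw / denom_hit else 1 / nh,
                 -1 / (N - nh))
  run <- cumsum(step)
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak)
}
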