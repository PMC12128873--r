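#' Per-guide log2 fold changes from PD0/PD6 counts
#'
#' Normalises each column to its library size and computes, per clone, the
#' guide-level log2 fold change between the screen end point and start
#' point: `lfc = log2((c6 + pc) / N6) - log2((c0 + pc) / N0)`, where N is
#' the raw column sum. Columns are optionally median-centered so the bulk
#' of the library (non-essential genes) sits at LFC 0. Guides whose PD0
#' count falls below `min_pd0` (default 30) are flagged `excluded`; they
#' remain in the output but are dropped from downstream testing.
#'
#' @param counts Guide x column count matrix from [simulate_screen()] or
#'   [read_counts()].
#' @param design Column metadata (`column`, `clone`, `timepoint`).
#' @param pseudocount Added to counts before log (default 0.5), so a zero
#'   PD6 count yields a finite negative LFC.
#' @param min_pd0 Minimum PD0 count for a guide to be testable.
#' @param median_center Subtract each clone's median guide LFC (default
#'   TRUE).
#' @return A `data.frame`: `guide`, `clone`, `lfc`, `pd0`, `excluded`.
#' @export
normalize_and_lfc <- function(counts, design, pseudocount = 0.5,
                              min_pd0 = 30, median_center = TRUE) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("library size must be > 0 in every column")
  clones <- unique(design$clone)
  out <- vector("list", length(clones))
  for (k in seq_along(clones)) {
    cl <- clones[k]
    c0 <- design$column[design$clone == cl & design$timepoint == "PD0"]
    c6 <- design$column[design$clone == cl & design$timepoint == "PD6"]
    if (length(c0) < 1 || length(c6) < 1) {
      stop("clone ", cl, " lacks a PD0 or PD6 column")
    }
    # average replicates on the normalised-count scale
    f0 <- rowMeans(sweep(counts[, c0, drop = FALSE] + pseudocount, 2,
                         libsize[c0], "/"))
    f6 <- rowMeans(sweep(counts[, c6, drop = FALSE] + pseudocount, 2,
                         libsize[c6], "/"))
    lfc <- log2(f6) - log2(f0)
    if (median_center) lfc <- lfc - stats::median(lfc)
    pd0 <- rowMeans(counts[, c0, drop = FALSE])
    out[[k]] <- data.frame(
      guide = rownames(counts), clone = cl, lfc = lfc, pd0 = pd0,
      excluded = pd0 < min_pd0, stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  n_ex <- sum(res$excluded)
  if (n_ex > 0) {
    message(n_ex, " guide record(s) below PD0 count ", min_pd0,
            "; flagged excluded")
  }
  res
}

#' Correct guide LFCs for copy-number-driven chromosomal-location bias
#'
#' Guides targeting amplified or lost chromosome arms show a dropout or
#' enrichment shift unrelated to gene function (extra cut sites and dosage
#' effects). For every copy-number-altered arm of a clone, this subtracts
#' `(arm median guide LFC - genome median guide LFC)` from that arm's
#' guides, re-centering altered arms on the neutral-genome behaviour. The
#' reference median is computed over the clone's copy-neutral arms (a
#' genome-wide median would itself be dragged by a large biased arm).
#' Copy-neutral arms are untouched. Arms with fewer than `min_guides`
#' guides are skipped with a warning (the median would be unstable).
#'
#' @param guide_lfc Output of [normalize_and_lfc()].
#' @param map Guide map (`guide`, `gene`, `arm_id`, ...).
#' @param karyotype `data.frame` with per-clone arm status: `clone`,
#'   `arm_id`, `call` (`"gain"`/`"loss"`/`"neutral"`).
#' @param min_guides Minimum guides on an altered arm (default 20).
#' @return `guide_lfc` with corrected `lfc` and a logical `corrected`
#'   column.
#' @export
correct_cn_bias <- function(guide_lfc, map, karyotype, min_guides = 20) {
  guide_lfc$arm_id <- map$arm_id[match(guide_lfc$guide, map$guide)]
  if (anyNA(guide_lfc$arm_id)) stop("guide(s) missing from map")
  guide_lfc$corrected <- FALSE
  for (cl in unique(guide_lfc$clone)) {
    rows <- guide_lfc$clone == cl
    altered <- karyotype$arm_id[karyotype$clone == cl &
                                  karyotype$call != "neutral"]
    neutral_rows <- rows & !(guide_lfc$arm_id %in% altered)
    genome_med <- if (any(neutral_rows)) {
      stats::median(guide_lfc$lfc[neutral_rows])
    } else {
      stats::median(guide_lfc$lfc[rows])
    }
    for (a in altered) {
      on_arm <- rows & guide_lfc$arm_id == a
      if (sum(on_arm) < min_guides) {
        warning("clone ", cl, ", arm ", a, ": only ", sum(on_arm),
                " guide(s); bias correction skipped")
        next
      }
      shift <- stats::median(guide_lfc$lfc[on_arm]) - genome_med
      guide_lfc$lfc[on_arm] <- guide_lfc$lfc[on_arm] - shift
      guide_lfc$corrected[on_arm] <- TRUE
    }
  }
  guide_lfc
}

#' Permutation test of gene-level essentiality
#'
#' Aggregates guide LFCs to gene scores (mean by default) and tests each
#' gene against a null of pseudo-genes assembled from randomly drawn guide
#' sets of the same size out of the whole library. Two-sided p-values use
#' the standard permutation correction `p = (b + 1) / (n_perm + 1)`; FDR is
#' Benjamini-Hochberg across genes. Genes with no surviving (non-excluded)
#' guides are dropped and reported via a message.
#'
#' @param guide_lfc Output of [normalize_and_lfc()] (optionally after
#'   [correct_cn_bias()]), for one or more clones.
#' @param map Guide map (`guide`, `gene`).
#' @param n_perm Number of null draws per guide-set size (>= 1000 for
#'   reported FDRs; default 10000).
#' @param aggregate `"mean"` (default) or `"median"` guide aggregation.
#' @param seed Integer seed for the null draws.
#' @return A `data.frame` per (clone, gene): `clone`, `gene`, `lfc`, `p`,
#'   `fdr`, `n_guides`.
#' @export
gene_level_test <- function(guide_lfc, map, n_perm = 10000,
                            aggregate = c("mean", "median"), seed = 1L) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(as.integer(seed))
  out <- list()
  for (cl in unique(guide_lfc$clone)) {
    d <- guide_lfc[guide_lfc$clone == cl & !guide_lfc$excluded, , drop = FALSE]
    gene <- map$gene[match(d$guide, map$guide)]
    if (anyNA(gene)) stop("guide(s) missing from map")
    dropped <- setdiff(unique(map$gene), unique(gene))
    if (length(dropped)) {
      message("clone ", cl, ": ", length(dropped),
              " gene(s) with no surviving guides dropped")
    }
    score <- tapply(d$lfc, gene, agg_fun)
    size <- tapply(d$lfc, gene, length)
    pool <- d$lfc
    p <- rep(NA_real_, length(score))
    for (s in sort(unique(size))) {
      null_s <- if (s >= length(pool)) {
        rep(agg_fun(pool), n_perm)
      } else {
        vapply(seq_len(n_perm),
               function(i) agg_fun(pool[sample.int(length(pool), s)]),
               numeric(1))
      }
      idx <- which(size == s)
      for (i in idx) {
        b <- sum(abs(null_s) >= abs(score[i]))
        p[i] <- (b + 1) / (n_perm + 1)
      }
    }
    out[[cl]] <- data.frame(
      clone = cl, gene = names(score), lfc = unname(score), p = p,
      fdr = stats::p.adjust(p, "BH"), n_guides = unname(as.integer(size)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call essential genes from a screen result
#'
#' Applies the dropout cutoff used for essential-gene calling:
#' FDR < 0.05 and log2 fold change < -2 by default.
#'
#' @param result Output of [gene_level_test()].
#' @param lfc_cut,fdr_cut Calling cutoffs.
#' @return Logical vector aligned with `result` rows.
#' @export
call_essential <- function(result, lfc_cut = -2, fdr_cut = 0.05) {
  result$fdr < fdr_cut & result$lfc < lfc_cut
}

#' Aneuploidy epistasis profile from paired screens
#'
#' Compares screen end points between aneuploid and diploid clones:
#' `delta_lfc = mean aneuploid gene score - mean diploid gene score`, so
#' negative values mean a gene is more essential in the aneuploid
#' background. With at least two clones per group, p-values come from
#' permutation of clone labels (exhaustive when the number of group
#' reassignments is small, sampled otherwise); with a single clone per
#' group, from guide-level permutation per gene (guide LFCs must then be
#' supplied). Swapping the two groups negates `delta_lfc` exactly.
#'
#' @param aneuploid,diploid Gene x clone score matrices (rownames = genes);
#'   one-column matrices or named vectors accepted. Gene universes must
#'   overlap.
#' @param guide_lfc,map Optional guide-level data ([normalize_and_lfc()]
#'   output and guide map) used for the single-clone-per-group fallback.
#' @param n_perm Maximum permutations (default 10000).
#' @param seed Integer seed.
#' @return A `data.frame` per gene: `gene`, `delta_lfc`, `p`, `fdr`.
#' @export
epistasis_profile <- function(aneuploid, diploid, guide_lfc = NULL,
                              map = NULL, n_perm = 10000, seed = 1L) {
  aneuploid <- as_gene_matrix(aneuploid)
  diploid <- as_gene_matrix(diploid)
  genes <- intersect(rownames(aneuploid), rownames(diploid))
  if (length(genes) == 0) stop("aneuploid and diploid gene sets are disjoint")
  a <- aneuploid[genes, , drop = FALSE]
  d <- diploid[genes, , drop = FALSE]
  delta <- rowMeans(a) - rowMeans(d)
  na <- ncol(a); nd <- ncol(d)
  set.seed(as.integer(seed))
  if (na >= 2 && nd >= 2) {
    all_cols <- cbind(a, d)
    combos <- utils::combn(na + nd, na)
    if (ncol(combos) <= n_perm) {
      perm_delta <- apply(combos, 2, function(ix) {
        rowMeans(all_cols[, ix, drop = FALSE]) -
          rowMeans(all_cols[, -ix, drop = FALSE])
      })
      p <- rowMeans(abs(perm_delta) >= abs(delta))  # exhaustive: exact p
    } else {
      hits <- rep(1, length(genes))
      for (i in seq_len(n_perm)) {
        ix <- sample.int(na + nd, na)
        pd <- rowMeans(all_cols[, ix, drop = FALSE]) -
          rowMeans(all_cols[, -ix, drop = FALSE])
        hits <- hits + (abs(pd) >= abs(delta))
      }
      p <- hits / (n_perm + 1)
    }
  } else if (!is.null(guide_lfc) && !is.null(map)) {
    p <- guide_level_epistasis_p(genes, delta, guide_lfc, map,
                                 aneu_clones = colnames(a),
                                 dip_clones = colnames(d), n_perm = n_perm)
  } else {
    warning("fewer than 2 clones per group and no guide-level data; ",
            "p-values returned as NA")
    p <- rep(NA_real_, length(genes))
  }
  data.frame(gene = genes, delta_lfc = unname(delta), p = unname(p),
             fdr = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

as_gene_matrix <- function(x) {
  if (is.data.frame(x) && all(c("gene", "lfc") %in% names(x))) {
    cl <- if (!is.null(x$clone)) x$clone else rep("clone", nrow(x))
    genes <- sort(unique(x$gene))
    sp <- split(x, cl)
    m <- vapply(sp, function(d) d$lfc[match(genes, d$gene)],
                numeric(length(genes)))
    m <- matrix(m, nrow = length(genes), dimnames = list(genes, names(sp)))
    return(m)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), "clone"))
  as.matrix(x)
}

# two-sample guide permutation between single clones, per gene
guide_level_epistasis_p <- function(genes, delta, guide_lfc, map,
                                    aneu_clones, dip_clones, n_perm) {
  gl <- guide_lfc[!guide_lfc$excluded, , drop = FALSE]
  gl$gene <- map$gene[match(gl$guide, map$guide)]
  p <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    ga <- gl$lfc[gl$gene == genes[i] & gl$clone %in% aneu_clones]
    gd <- gl$lfc[gl$gene == genes[i] & gl$clone %in% dip_clones]
    if (length(ga) == 0 || length(gd) == 0) next
    pool <- c(ga, gd)
    k <- length(ga)
    n_comb <- choose(length(pool), k)
    if (n_comb <= n_perm) {
      combos <- utils::combn(length(pool), k)
      pd <- apply(combos, 2, function(ix) mean(pool[ix]) - mean(pool[-ix]))
      p[i] <- mean(abs(pd) >= abs(mean(ga) - mean(gd)))
    } else {
      b <- 0
      for (j in seq_len(n_perm)) {
        ix <- sample.int(length(pool), k)
        b <- b + (abs(mean(pool[ix]) - mean(pool[-ix])) >=
                    abs(mean(ga) - mean(gd)))
      }
      p[i] <- (b + 1) / (n_perm + 1)
    }
  }
  p
}
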