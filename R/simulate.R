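#' Simulate copy-number segment tables with planted arm events
#'
#' Emits a SEG-style segment table for a set of samples with arm-level
#' gains/losses planted as integer copy changes on a diploid background.
#' Mixing with normal contamination happens on the linear copy-ratio scale:
#' a single-copy gain observed at purity p has ratio
#' `p * 1.5 + (1 - p) * 1`, and the emitted segment mean is its log2 plus
#' Gaussian noise.
#'
#' @param genome Arm table (see [toy_genome()]).
#' @param events `data.frame` of planted events: `sample`, `arm_id`,
#'   `direction` (`"gain"`/`"loss"`) and optionally `copies` (integer copy
#'   change, default 1).
#' @param samples Character vector of sample ids to emit (defaults to the
#'   samples appearing in `events`). Samples without events get a fully
#'   neutral genome.
#' @param purity Per-sample tumor purity in (0, 1]; a named vector or a
#'   single value recycled to all samples.
#' @param noise_sd Gaussian noise SD added to segment means, log2 units.
#' @param event_fraction Fraction of each event arm covered by the altered
#'   segment (remainder emitted neutral); default 1 (whole arm).
#' @param seed Integer seed; identical seed + parameters give identical
#'   output.
#' @return A list with `segments` (columns `sample`, `chrom`, `start_bp`,
#'   `end_bp`, `log2_ratio`, `purity`) and `truth` (class `"sim_truth"`:
#'   the planted events and generator parameters).
#' @examples
#' ev <- data.frame(sample = "s1", arm_id = "1p", direction = "gain")
#' sim <- simulate_segments(toy_genome(), ev, purity = 1, noise_sd = 0, seed = 1)
#' subset(sim$segments, sample == "s1" & log2_ratio != 0)  # log2(1.5)
#' @export
simulate_segments <- function(genome = toy_genome(), events,
                              samples = NULL, purity = 1, noise_sd = 0,
                              event_fraction = 1, seed = 1L) {
  genome <- validate_genome(genome)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (event_fraction <= 0 || event_fraction > 1) {
    stop("event_fraction must be in (0, 1]")
  }
  if (missing(events) || is.null(events)) {
    events <- data.frame(sample = character(), arm_id = character(),
                         direction = character(), stringsAsFactors = FALSE)
  }
  if (nrow(events) > 0) {
    bad <- setdiff(events$arm_id, genome$arm_id)
    if (length(bad)) {
      stop("event references arm(s) absent from genome: ",
           paste(bad, collapse = ", "))
    }
    if (!all(events$direction %in% c("gain", "loss"))) {
      stop("event direction must be 'gain' or 'loss'")
    }
    if (is.null(events$copies)) events$copies <- 1L
  }
  if (is.null(samples)) samples <- unique(events$sample)
  if (length(samples) == 0) stop("no samples to simulate")
  pur <- resolve_per_sample(purity, samples, "purity")
  if (any(pur <= 0 | pur > 1)) stop("purity must be in (0, 1]")

  set.seed(as.integer(seed))
  rows <- list()
  for (s in samples) {
    ev <- events[events$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(genome))) {
      arm <- genome[i, ]
      e <- ev[ev$arm_id == arm$arm_id, , drop = FALSE]
      delta <- if (nrow(e)) sum(ifelse(e$direction == "gain", 1, -1) * e$copies) else 0
      len <- arm$end_bp - arm$start_bp + 1
      if (delta != 0 && event_fraction < 1) {
        cut <- arm$start_bp + round(len * event_fraction) - 1
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, chrom = arm$chrom,
          start_bp = c(arm$start_bp, cut + 1), end_bp = c(cut, arm$end_bp),
          copies = c(2 + delta, 2), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, chrom = arm$chrom,
          start_bp = arm$start_bp, end_bp = arm$end_bp,
          copies = 2 + delta, stringsAsFactors = FALSE)
      }
    }
  }
  seg <- do.call(rbind, rows)
  if (any(seg$copies < 0)) stop("planted events imply negative copy number")
  p <- pur[seg$sample]
  mixed <- p * (seg$copies / 2) + (1 - p) * 1
  seg$log2_ratio <- log2(mixed) + stats::rnorm(nrow(seg), 0, noise_sd)
  seg$purity <- unname(p)
  seg$copies <- NULL
  truth <- structure(
    list(events = events, purity = pur, noise_sd = noise_sd,
         event_fraction = event_fraction, seed = as.integer(seed)),
    class = "sim_truth")
  list(segments = seg, truth = truth)
}

resolve_per_sample <- function(x, samples, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(samples, names(x))
    if (length(miss)) stop("no ", what, " for sample(s): ", paste(miss, collapse = ", "))
    stats::setNames(unname(x[samples]), samples)
  } else {
    stats::setNames(rep_len(x, length(samples)), samples)
  }
}

#' Simulate a genome-wide CRISPR knockout screen
#'
#' Generates guide counts at PD0 and PD6 (zero and six population
#' doublings) for one or more clones, with planted essential genes and an
#' optional per-arm additive LFC shift emulating the dropout/enrichment
#' bias of guides targeting copy-number-altered chromosomes. Counts are
#' negative binomial with configurable dispersion (Poisson at
#' `dispersion = 0`); the PD6 mean of a guide with true log2 fold change
#' `l` is `depth * 2^l`.
#'
#' Genes are placed uniformly along the supplied genome (probability
#' proportional to arm length), so arm-level structure is available for
#' bias correction downstream.
#'
#' @param genome Arm table used to place genes.
#' @param n_genes,guides_per_gene Library design; the emitted library has
#'   `n_genes * guides_per_gene` reagent records.
#' @param depth Expected PD0 reads per guide (must be positive).
#' @param clones Character vector of clone names.
#' @param cn_bias Named list: per clone, a named numeric vector of additive
#'   LFC shifts by `arm_id` (e.g. `list(A1 = c("1q" = 0.5))`). Clones
#'   absent from the list are unbiased.
#' @param essential_fraction Fraction of genes planted as essential.
#' @param essential_lfc True LFC of essential genes (default -2, a 4-fold
#'   depletion by PD6).
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param seed Integer seed.
#' @return A list: `counts` (guides x columns `<clone>.PD0` /
#'   `<clone>.PD6`), `map` (`guide`, `gene`, `chrom`, `arm_id`, `pos`),
#'   `design` (column metadata), `truth` (`"sim_truth"`: essential gene
#'   ids, per-clone arm shifts, parameters).
#' @export
simulate_screen <- function(genome = toy_genome(), n_genes = 1000,
                            guides_per_gene = 5, depth = 500,
                            clones = "clone1", cn_bias = list(),
                            essential_fraction = 0.02, essential_lfc = -2,
                            dispersion = 0.1, seed = 1L) {
  genome <- validate_genome(genome)
  if (n_genes < 1 || guides_per_gene < 1) stop("n_genes and guides_per_gene must be >= 1")
  if (depth <= 0) stop("depth must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  bad_arms <- setdiff(unlist(lapply(cn_bias, names)), genome$arm_id)
  if (length(bad_arms)) {
    stop("cn_bias references arm(s) absent from genome: ",
         paste(bad_arms, collapse = ", "))
  }
  set.seed(as.integer(seed))

  arm_mb <- arm_lengths_mb(genome)
  gene_arm <- sample(genome$arm_id, n_genes, replace = TRUE, prob = arm_mb / sum(arm_mb))
  gi <- match(gene_arm, genome$arm_id)
  gene_pos <- genome$start_bp[gi] +
    floor(stats::runif(n_genes) * (genome$end_bp[gi] - genome$start_bp[gi]))
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_ess <- round(essential_fraction * n_genes)
  essential <- if (n_ess > 0) sample(genes, n_ess) else character()

  map <- data.frame(
    guide = paste0(rep(genes, each = guides_per_gene), "_sg",
                   rep(seq_len(guides_per_gene), n_genes)),
    gene = rep(genes, each = guides_per_gene),
    chrom = rep(genome$chrom[gi], each = guides_per_gene),
    arm_id = rep(gene_arm, each = guides_per_gene),
    pos = rep(gene_pos, each = guides_per_gene),
    stringsAsFactors = FALSE
  )
  n_guides <- nrow(map)

  rcounts <- function(mu) {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- matrix(0L, n_guides, 2 * length(clones),
                   dimnames = list(map$guide,
                                   paste(rep(clones, each = 2), c("PD0", "PD6"), sep = ".")))
  true_lfc_base <- ifelse(map$gene %in% essential, essential_lfc, 0)
  for (cl in clones) {
    shift <- rep(0, n_guides)
    b <- cn_bias[[cl]]
    if (!is.null(b)) shift <- shift + unname(ifelse(is.na(b[map$arm_id]), 0, b[map$arm_id]))
    lfc <- true_lfc_base + shift
    counts[, paste0(cl, ".PD0")] <- rcounts(rep(depth, n_guides))
    counts[, paste0(cl, ".PD6")] <- rcounts(depth * 2^lfc)
  }
  design <- data.frame(
    column = colnames(counts),
    clone = rep(clones, each = 2),
    timepoint = rep(c("PD0", "PD6"), length(clones)),
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(essential = sort(essential), essential_lfc = essential_lfc,
         cn_bias = cn_bias, depth = depth, dispersion = dispersion,
         seed = as.integer(seed)),
    class = "sim_truth")
  list(counts = counts, map = map, design = design, truth = truth)
}

#' Simulate a feature matrix linearly coupled to burden
#'
#' Each feature j is generated as `slope_j * burden + N(0, noise_sd)`,
#' emulating metabolite abundances (or gene-effect scores) whose levels
#' track net-gain aneuploidy across samples.
#'
#' @param burden Named numeric vector of per-sample burden scores
#'   (>= 3 samples).
#' @param slopes Named numeric vector of per-feature true slopes.
#' @param noise_sd Gaussian noise SD.
#' @param intercepts Optional per-feature intercepts (default 0).
#' @param seed Integer seed.
#' @return A list: `features` (samples x features matrix) and `truth`
#'   (`"sim_truth"` holding slopes/intercepts/parameters).
#' @export
simulate_feature_matrix <- function(burden, slopes, noise_sd = 0.1,
                                    intercepts = 0, seed = 1L) {
  if (length(burden) < 3) stop("need >= 3 samples")
  if (is.null(names(burden))) names(burden) <- paste0("s", seq_along(burden))
  if (is.null(names(slopes))) names(slopes) <- paste0("f", seq_along(slopes))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  intercepts <- rep_len(intercepts, length(slopes))
  set.seed(as.integer(seed))
  mat <- outer(burden, slopes) +
    matrix(rep(intercepts, each = length(burden)), length(burden)) +
    matrix(stats::rnorm(length(burden) * length(slopes), 0, noise_sd),
           length(burden))
  dimnames(mat) <- list(names(burden), names(slopes))
  truth <- structure(
    list(slopes = slopes, intercepts = stats::setNames(intercepts, names(slopes)),
         burden = burden, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_truth")
  list(features = mat, truth = truth)
}

#' Simulate a two-arm survival cohort with exponential event times
#'
#' Group 1 (`net_gain`) has constant hazard calibrated so its true 5-year
#' survival equals `baseline_5yr_survival`
#' (`lambda = -log(S(5)) / 5`); group 2 (`net_loss`) has hazard
#' `lambda * true_hr`. Follow-up is administratively censored at
#' `censor_horizon_years`; optionally a fraction of subjects is randomly
#' censored earlier (uniform censoring times on the horizon).
#'
#' @param n Cohort size (>= 2); split as evenly as possible between groups.
#' @param true_hr True hazard ratio of group 2 vs group 1 (> 0).
#' @param baseline_5yr_survival Group-1 survival probability at 5 years,
#'   in (0, 1).
#' @param censor_horizon_years Administrative censoring horizon (years).
#' @param dropout_rate Fraction of subjects given a random uniform
#'   censoring time before the horizon (default 0).
#' @param group_labels Two labels, first = baseline group.
#' @param seed Integer seed.
#' @return A list: `cohort` (`patient`, `time`, `event`, `group`) and
#'   `truth` (`"sim_truth"`).
#' @export
simulate_survival_cohort <- function(n, true_hr = 1,
                                     baseline_5yr_survival = 0.95,
                                     censor_horizon_years = 5,
                                     dropout_rate = 0,
                                     group_labels = c("net_gain", "net_loss"),
                                     seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (true_hr <= 0) stop("true_hr must be > 0")
  if (baseline_5yr_survival <= 0 || baseline_5yr_survival >= 1) {
    stop("baseline_5yr_survival must be in (0, 1)")
  }
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")
  set.seed(as.integer(seed))
  lambda1 <- -log(baseline_5yr_survival) / 5
  group <- rep(group_labels, length.out = n)
  lambda <- ifelse(group == group_labels[1], lambda1, lambda1 * true_hr)
  t_event <- stats::rexp(n, lambda)
  c_time <- rep(censor_horizon_years, n)
  if (dropout_rate > 0) {
    drop <- stats::runif(n) < dropout_rate
    c_time[drop] <- stats::runif(sum(drop), 0, censor_horizon_years)
  }
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  cohort <- data.frame(
    patient = sprintf("p%04d", seq_len(n)),
    time = time, event = event, group = group,
    stringsAsFactors = FALSE)
  truth <- structure(
    list(true_hr = true_hr, baseline_5yr_survival = baseline_5yr_survival,
         lambda1 = lambda1, censor_horizon_years = censor_horizon_years,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "sim_truth")
  list(cohort = cohort, truth = truth)
}

#' Simulate expression with dosage-coupled copy-number events
#'
#' Generates a genes x samples expression matrix where genes on arms with
#' planted gains have mean expression multiplied by `dosage_effect` (losses
#' divided by it) relative to a reference cohort, plus multiplicative
#' log-normal noise. The output feeds [infer_cna_from_expression()], which
#' should recover the planted arms.
#'
#' @param genome Arm table used to place genes.
#' @param events Planted events as in [simulate_segments()] (tumor samples
#'   only).
#' @param dosage_effect Expression scaling of a gained arm (> 0; 1 = no
#'   dosage coupling).
#' @param reference_n Number of reference (normal) samples to emit (>= 2).
#' @param genes_per_arm Genes per arm (uniformly spaced).
#' @param noise_sd Log-normal noise SD (log scale).
#' @param seed Integer seed.
#' @return A list: `expr` (genes x samples), `gene_info` (`gene`, `chrom`,
#'   `arm_id`, `pos`), `reference` (reference sample names), `truth`.
#' @export
simulate_expression_cna <- function(genome = toy_genome(), events,
                                    dosage_effect = 1.5, reference_n = 3,
                                    genes_per_arm = 60, noise_sd = 0.1,
                                    seed = 1L) {
  genome <- validate_genome(genome)
  if (dosage_effect <= 0) stop("dosage_effect must be > 0")
  if (reference_n < 2) stop("reference_n must be >= 2")
  if (nrow(events) > 0) {
    bad <- setdiff(events$arm_id, genome$arm_id)
    if (length(bad)) stop("event references arm(s) absent from genome: ",
                          paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  gene_info <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    pos <- round(seq(genome$start_bp[i], genome$end_bp[i],
                     length.out = genes_per_arm))
    data.frame(chrom = genome$chrom[i], arm_id = genome$arm_id[i], pos = pos,
               stringsAsFactors = FALSE)
  }))
  gene_info$gene <- sprintf("eg%04d", seq_len(nrow(gene_info)))
  gene_info <- gene_info[, c("gene", "chrom", "arm_id", "pos")]

  tumors <- unique(events$sample)
  refs <- paste0("ref", seq_len(reference_n))
  samples <- c(refs, tumors)
  n_genes <- nrow(gene_info)
  expr <- matrix(1, n_genes, length(samples),
                 dimnames = list(gene_info$gene, samples))
  for (s in tumors) {
    ev <- events[events$sample == s, , drop = FALSE]
    scale <- rep(1, n_genes)
    for (j in seq_len(nrow(ev))) {
      on_arm <- gene_info$arm_id == ev$arm_id[j]
      scale[on_arm] <- scale[on_arm] *
        if (ev$direction[j] == "gain") dosage_effect else 1 / dosage_effect
    }
    expr[, s] <- scale
  }
  if (noise_sd > 0) {
    expr <- expr * exp(matrix(stats::rnorm(length(expr), 0, noise_sd),
                              n_genes))
  }
  truth <- structure(
    list(events = events, dosage_effect = dosage_effect, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "sim_truth")
  list(expr = expr, gene_info = gene_info, reference = refs, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> seed", x$seed, "\n")
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}
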