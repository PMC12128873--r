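#' Pipeline configuration
#'
#' Builds the flat configuration driving [run_pipeline()]. Every calling
#' threshold defaults to the value used by the corresponding analysis
#' stage (see [default_thresholds()]); unknown keys are rejected so typos
#' fail loudly.
#'
#' @param ... Named overrides of the defaults.
#' @return Object of class `"pipeline_config"` (named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # copy-number calling
    arm_gain_log2 = 0.32, arm_loss_log2 = -0.41, min_arm_fraction = 0.5,
    gene_gain_l2cn1 = 1.16, gene_loss_l2cn1 = 0.8,
    expr_gain = 1.02, expr_loss = 0.98,
    weighting = "segment",
    # screen
    n_genes = 300, guides_per_gene = 5, depth = 500,
    essential_fraction = 0.05, essential_lfc = -2, dispersion = 0.1,
    n_perm = 1000,
    # simulation conditions
    n_samples = 12, purity = 0.8, noise_sd = 0.05,
    n_features = 20, feature_noise_sd = 0.5,
    cohort_n = 400, true_hr = 2.67, baseline_5yr_survival = 0.95,
    horizon = 5,
    # io
    seg_path = NULL, keywords = chemo_keywords()
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of flat key-value overrides.
#' @return A `"pipeline_config"` object.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(v) paste(format(v), collapse = ","),
                          character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-data pipeline
#'
#' Exercises every analysis stage end to end on data generated by the
#' synthetic-data module: (1) simulate arm-level segments, write/re-read
#' them as SEG and score aneuploidy burden; (2) simulate a paired
#' aneuploid/diploid screen, compute guide LFCs, correct the
#' chromosomal-location bias, run gene-level tests and the epistasis
#' profile; (3) simulate burden-coupled features and associate them with
#' the burden scores; (4) simulate a stratified survival cohort and
#' estimate per-treatment-class hazard ratios. Stage outputs are written
#' as CSV under `out_dir`, with a `summary.json` carrying the config hash,
#' seed and headline numbers; rerunning with the same config is
#' bit-identical.
#'
#' @param config A `"pipeline_config"` (or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (missing(out_dir)) stop("out_dir is required")
  if (!is.null(config$seg_path) && !file.exists(config$seg_path)) {
    stop("stage score-cn: SEG file not found: ", config$seg_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  th <- default_thresholds(
    arm_gain_log2 = config$arm_gain_log2, arm_loss_log2 = config$arm_loss_log2,
    min_arm_fraction = config$min_arm_fraction,
    gene_gain_l2cn1 = config$gene_gain_l2cn1,
    gene_loss_l2cn1 = config$gene_loss_l2cn1,
    expr_gain = config$expr_gain, expr_loss = config$expr_loss)
  genome <- toy_genome()
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  summary <- list(config_hash = config_hash(config), seed = seed)

  run_stage <- function(stage, expr) {
    logf(stage, "start")
    res <- tryCatch(expr, error = function(e) {
      logf(stage, paste("ERROR:", conditionMessage(e)))
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logf(stage, "done")
    res
  }

  # 1. segments -> burden
  burden <- run_stage("score-cn", {
    if (is.null(config$seg_path)) {
      samples <- sprintf("s%02d", seq_len(config$n_samples))
      set.seed(seed)
      ev <- do.call(rbind, lapply(samples, function(s) {
        k <- sample(0:3, 1)
        if (k == 0) return(NULL)
        data.frame(sample = s, arm_id = sample(genome$arm_id, k),
                   direction = sample(c("gain", "loss"), k, replace = TRUE),
                   stringsAsFactors = FALSE)
      }))
      sim <- simulate_segments(genome, ev, samples = samples,
                               purity = config$purity,
                               noise_sd = config$noise_sd, seed = seed)
      seg_path <- file.path(out_dir, "segments.seg")
      write_seg(sim$segments, seg_path)
      seg <- read_seg(seg_path)
      seg$purity <- config$purity
    } else {
      seg <- read_seg(config$seg_path)
      seg$purity <- config$purity
    }
    b <- score_segments(seg, genome, th, weighting = config$weighting)
    utils::write.csv(b, file.path(out_dir, "burden.csv"), row.names = FALSE)
    b
  })
  summary$score_cn <- list(n_samples = nrow(burden),
                           n_net_gain = sum(burden$class == "net_gain"))

  # 2. screen
  screen_out <- run_stage("screen", {
    scr <- simulate_screen(genome, n_genes = config$n_genes,
                           guides_per_gene = config$guides_per_gene,
                           depth = config$depth,
                           clones = c("aneuploid1", "diploid1"),
                           cn_bias = list(aneuploid1 = c("1q" = 0.4)),
                           essential_fraction = config$essential_fraction,
                           essential_lfc = config$essential_lfc,
                           dispersion = config$dispersion, seed = seed)
    lfc <- suppressMessages(normalize_and_lfc(scr$counts, scr$design))
    kar <- data.frame(clone = "aneuploid1", arm_id = "1q", call = "gain",
                      stringsAsFactors = FALSE)
    lfc <- correct_cn_bias(lfc, scr$map, kar)
    res <- suppressMessages(
      gene_level_test(lfc, scr$map, n_perm = config$n_perm, seed = seed))
    utils::write.csv(res, file.path(out_dir, "screen_genes.csv"),
                     row.names = FALSE)
    epi <- epistasis_profile(res[res$clone == "aneuploid1", ],
                             res[res$clone == "diploid1", ],
                             guide_lfc = lfc, map = scr$map,
                             n_perm = config$n_perm, seed = seed)
    utils::write.csv(epi, file.path(out_dir, "epistasis.csv"),
                     row.names = FALSE)
    list(result = res, epistasis = epi, truth = scr$truth)
  })
  ess_called <- with(screen_out$result,
                     tapply(call_essential(screen_out$result), clone, sum))
  summary$screen <- list(n_genes = config$n_genes,
                         n_essential_called = as.list(ess_called))

  # 3. feature association
  assoc <- run_stage("assoc", {
    b <- stats::setNames(burden$net_mb, burden$sample)
    slopes <- stats::setNames(
      seq(-1, 1, length.out = config$n_features) / 50,
      sprintf("f%02d", seq_len(config$n_features)))
    fm <- simulate_feature_matrix(b, slopes,
                                  noise_sd = config$feature_noise_sd,
                                  seed = seed)
    a <- associate_with_burden(fm$features, b)
    utils::write.csv(a, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    a
  })
  summary$assoc <- list(n_features = nrow(assoc),
                        n_fdr05 = sum(assoc$fdr < 0.05, na.rm = TRUE))

  # 4. survival
  surv <- run_stage("survival", {
    chemo <- simulate_survival_cohort(config$cohort_n, config$true_hr,
                                      config$baseline_5yr_survival,
                                      censor_horizon_years = config$horizon,
                                      seed = seed)$cohort
    nonchemo <- simulate_survival_cohort(config$cohort_n, 1,
                                         config$baseline_5yr_survival,
                                         censor_horizon_years = config$horizon,
                                         seed = seed + 1L)$cohort
    chemo$treatment_class <- "chemo"
    nonchemo$treatment_class <- "non_chemo"
    cohort <- rbind(chemo, nonchemo)
    names(cohort)[names(cohort) == "group"] <- "burden_class"
    res <- stratified_survival_analysis(cohort, horizon = config$horizon)
    utils::write.csv(res$km, file.path(out_dir, "survival_km.csv"),
                     row.names = FALSE)
    utils::write.csv(res$cox, file.path(out_dir, "survival_cox.csv"),
                     row.names = FALSE)
    res
  })
  summary$survival <- list(
    chemo_hr = surv$cox$hr[surv$cox$treatment_class == "chemo"],
    non_chemo_hr = surv$cox$hr[surv$cox$treatment_class == "non_chemo"])

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline", "complete")
  invisible(summary)
}
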