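# Shared fixtures: tiny genomes and segment builders used across test files.

# a 4-arm micro genome (100 bases total) where per-base brute force is cheap
micro_genome <- function() {
  validate_genome(data.frame(
    chrom = c("1", "1", "2", "2"),
    arm = c("p", "q", "p", "q"),
    start_bp = c(1, 31, 1, 21),
    end_bp = c(30, 70, 20, 50),
    stringsAsFactors = FALSE
  ))
}

# build a segment table from (sample, chrom, start, end, log2) rows
seg_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], chrom = r[[2]], start_bp = as.numeric(r[[3]]),
               end_bp = as.numeric(r[[4]]), log2_ratio = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

# independent per-base burden oracle: walk every base of every arm, find the
# covering segment, threshold, apply the >= 50% arm rule, sum qualifying bases
per_base_burden_oracle <- function(segments, genome, th,
                                   weighting = c("segment", "arm")) {
  weighting <- match.arg(weighting)
  out <- lapply(unique(segments$sample), function(s) {
    seg <- segments[segments$sample == s, ]
    gain_units <- 0; loss_units <- 0
    for (i in seq_len(nrow(genome))) {
      arm <- genome[i, ]
      bases <- arm$start_bp:arm$end_bp
      val <- rep(NA_real_, length(bases))
      for (j in seq_len(nrow(seg))) {
        if (seg$chrom[j] != arm$chrom) next
        hit <- bases >= seg$start_bp[j] & bases <= seg$end_bp[j]
        val[hit] <- seg$log2_ratio[j]
      }
      g <- sum(!is.na(val) & val > th$arm_gain_log2)
      l <- sum(!is.na(val) & val < th$arm_loss_log2)
      n <- length(bases)
      if (g / n >= th$min_arm_fraction && g > l) {
        gain_units <- gain_units + if (weighting == "segment") g else n
      } else if (l / n >= th$min_arm_fraction && l > g) {
        loss_units <- loss_units + if (weighting == "segment") l else n
      }
    }
    data.frame(sample = s, gain_mb = gain_units / 1e6,
               loss_mb = loss_units / 1e6,
               net_mb = (gain_units - loss_units) / 1e6,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# independent weighted-KS enrichment score (re-derived, loop form)
brute_es <- function(ranked, set, weight = 1) {
  genes <- names(ranked)
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  denom <- sum(abs(ranked[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(ranked[i])^weight / denom else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
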