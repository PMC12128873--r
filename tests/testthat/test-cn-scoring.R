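test_that("purity correction inverts linear-scale mixing", {
  expect_equal(purity_correct(0.7, 1), 0.7)          # identity at purity 1
  expect_equal(purity_correct(0, 0.5), 0)            # neutral invariant
  expect_equal(purity_correct(log2(1.25), 0.5), log2(1.5))
  expect_equal(purity_correct(log2(1.5), 0.5), 1)    # (1.5-0.5)/0.5 = 2
  expect_error(purity_correct(0, 0), "purity")
  # implied tumor ratio nonpositive -> NA with warning
  expect_warning(res <- purity_correct(-3, 0.5), "uncorrectable")
  expect_true(is.na(res))
})

test_that("arm calls follow the thresholds and the 50% arm rule", {
  g <- toy_genome()
  th <- default_thresholds()
  # full 1p at +0.5 -> gain (above +0.32)
  seg <- seg_table(list("s1", "1", 1, 50e6, 0.5))
  calls <- call_arm_events(seg, g, th)
  expect_equal(calls$call[calls$sample == "s1" & calls$arm_id == "1p"], "gain")

  # 40% of the arm at +0.5 -> neutral (below the 50% rule)
  seg2 <- seg_table(list("s1", "1", 1, 20e6, 0.5), list("s1", "1", 20e6 + 1, 50e6, 0))
  calls2 <- call_arm_events(seg2, g, th)
  expect_equal(calls2$call[calls2$arm_id == "1p"], "neutral")

  # full arm at 0 -> neutral
  seg3 <- seg_table(list("s1", "1", 1, 50e6, 0))
  expect_equal(call_arm_events(seg3, g, th)$call[1], "neutral")

  # full arm at -0.5 -> loss (below -0.41); at -0.40 -> neutral
  seg4 <- seg_table(list("s1", "1", 1, 50e6, -0.5))
  expect_equal(call_arm_events(seg4, g, th)$call[1], "loss")
  seg5 <- seg_table(list("s1", "1", 1, 50e6, -0.40))
  expect_equal(call_arm_events(seg5, g, th)$call[1], "neutral")

  # a segment outside any arm is skipped with a warning
  seg6 <- seg_table(list("s1", "9", 1, 1e6, 0.5))
  expect_warning(call_arm_events(seg6, g, th), "outside any arm")
})

test_that("burden arithmetic and class labels follow gain - loss", {
  g <- toy_genome()
  th <- default_thresholds()
  # gained 50 Mb 1p, lost 30 Mb 3p -> net +20 Mb under arm weighting
  seg <- seg_table(list("s1", "1", 1, 50e6, 0.6), list("s1", "3", 1, 30e6, -0.8))
  calls <- call_arm_events(seg, g, th)
  b <- aneuploidy_burden(calls, weighting = "arm")
  expect_equal(b$gain_mb, 50)
  expect_equal(b$loss_mb, 30)
  expect_equal(b$net_mb, 20)
  expect_equal(b$class, "net_gain")

  # no calls -> zeros, balanced
  segn <- seg_table(list("s1", "1", 1, 50e6, 0))
  bn <- aneuploidy_burden(call_arm_events(segn, g, th))
  expect_equal(bn$net_mb, 0)
  expect_equal(bn$class, "balanced")

  # empty input warns and returns empty
  expect_warning(b0 <- aneuploidy_burden(calls[0, ]), "no arm calls")
  expect_equal(nrow(b0), 0)
})

test_that("sign-flipping segments swaps gain and loss under symmetric cutoffs", {
  g <- toy_genome()
  th <- default_thresholds(arm_gain_log2 = 0.4, arm_loss_log2 = -0.4)
  seg <- seg_table(list("s1", "1", 1, 50e6, 0.6), list("s1", "2", 1, 40e6, -0.7),
                   list("s1", "5", 1, 20e6, 0.5))
  b <- aneuploidy_burden(call_arm_events(seg, g, th))
  seg_flip <- seg
  seg_flip$log2_ratio <- -seg_flip$log2_ratio
  b_flip <- aneuploidy_burden(call_arm_events(seg_flip, g, th))
  expect_equal(b$gain_mb, b_flip$loss_mb)
  expect_equal(b$loss_mb, b_flip$gain_mb)
  expect_equal(b$net_mb, -b_flip$net_mb)
})

test_that("raising a segment mean never demotes a gain call", {
  g <- toy_genome()
  th <- default_thresholds()
  for (v in c(0.33, 0.5, 1, 2, 5)) {
    seg <- seg_table(list("s1", "1", 1, 50e6, v))
    expect_equal(call_arm_events(seg, g, th)$call[1], "gain")
  }
})

test_that("burden matches per-base brute-force counting on a micro genome", {
  g <- micro_genome()
  th <- default_thresholds()
  set.seed(42)
  for (rep in 1:5) {
    # random segmentation: each arm split in two with random levels
    rows <- list()
    for (i in seq_len(nrow(g))) {
      cut <- sample(g$start_bp[i]:(g$end_bp[i] - 1), 1)
      rows <- c(rows, list(
        list("s1", g$chrom[i], g$start_bp[i], cut,
             sample(c(-0.8, -0.2, 0, 0.4, 0.9), 1)),
        list("s1", g$chrom[i], cut + 1, g$end_bp[i],
             sample(c(-0.8, -0.2, 0, 0.4, 0.9), 1))))
    }
    seg <- do.call(seg_table, rows)
    for (w in c("segment", "arm")) {
      got <- aneuploidy_burden(call_arm_events(seg, g, th), weighting = w)
      want <- per_base_burden_oracle(seg, g, th, weighting = w)
      expect_equal(got$net_mb, want$net_mb, tolerance = 1e-12)
      expect_equal(got$gain_mb, want$gain_mb, tolerance = 1e-12)
    }
  }
})

test_that("purity-corrected half-purity data scores like pure data", {
  g <- toy_genome()
  ev <- data.frame(sample = rep("s1", 2), arm_id = c("1q", "4p"),
                   direction = c("gain", "loss"))
  pure <- simulate_segments(g, ev, purity = 1, noise_sd = 0, seed = 1)
  mixed <- simulate_segments(g, ev, purity = 0.5, noise_sd = 0, seed = 1)
  b_pure <- score_segments(pure$segments, g)
  b_mixed <- score_segments(mixed$segments, g)  # purity column present
  expect_equal(b_pure, b_mixed)
})

test_that("planted net-gain samples are recovered under realistic conditions", {
  g <- toy_genome()
  ev <- do.call(rbind, lapply(sprintf("s%02d", 1:6), function(s) {
    data.frame(sample = s, arm_id = c("1q", "3p"),
               direction = c("gain", "gain"), stringsAsFactors = FALSE)
  }))
  sim <- simulate_segments(g, ev, purity = 0.6, noise_sd = 0.05, seed = 11)
  b <- score_segments(sim$segments, g)
  expect_true(all(b$class == "net_gain"))
})

test_that("gene-level burden counts genes past the log2(cn+1) cutoffs", {
  th <- default_thresholds()
  m <- matrix(1, nrow = 50, ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  m[1:10, 1] <- 1.3   # gained (> 1.16)
  m[11:14, 1] <- 0.5  # lost (< 0.8)
  b <- gene_level_burden(m, th)
  expect_equal(b$net[b$sample == "a"], 6)    # 10 - 4
  expect_equal(b$class[b$sample == "a"], "net_gain")
  expect_equal(b$net[b$sample == "b"], 0)    # all diploid-neutral at 1.0
  expect_equal(b$class[b$sample == "b"], "balanced")

  # boundary behaviour: 1.2 gained, 0.7 lost, 1.1 neutral
  m2 <- matrix(c(1.2, 0.7, 1.1, 1, 1, 1, 1, 1, 1, 1), ncol = 1)
  expect_equal(gene_level_burden(m2, th)$net, 0)

  # off-scale matrix triggers the scale-mismatch warning
  expect_warning(gene_level_burden(matrix(rnorm(20), ncol = 2), th),
                 "scale")
})
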