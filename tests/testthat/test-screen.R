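make_counts <- function(mat, clone = "c1") {
  colnames(mat) <- paste(clone, c("PD0", "PD6"), sep = ".")
  design <- data.frame(column = colnames(mat), clone = clone,
                       timepoint = c("PD0", "PD6"), stringsAsFactors = FALSE)
  list(counts = mat, design = design)
}

test_that("guide LFCs follow normalised count shares", {
  # identical normalised counts -> LFC 0 for every guide
  m <- matrix(c(100, 200, 300, 200, 400, 600), ncol = 2,
              dimnames = list(paste0("g", 1:3), NULL))
  x <- make_counts(m)
  lfc <- normalize_and_lfc(x$counts, x$design, pseudocount = 0,
                           min_pd0 = 0, median_center = FALSE)
  expect_equal(lfc$lfc, rep(0, 3))

  # a guide whose count share doubles gets LFC +1
  m2 <- matrix(c(100, 100, 100, 100, 200, 50, 50, 100), ncol = 2,
               dimnames = list(paste0("g", 1:4), NULL))
  # shares PD0: 0.25 each; PD6: 0.5, 0.125, 0.125, 0.25
  x2 <- make_counts(m2)
  lfc2 <- normalize_and_lfc(x2$counts, x2$design, pseudocount = 0,
                            min_pd0 = 0, median_center = FALSE)
  expect_equal(lfc2$lfc[1], 1)
  expect_equal(lfc2$lfc[4], 0)

  # zero PD6 count stays finite with a pseudocount
  m3 <- matrix(c(500, 500, 0, 1000), ncol = 2,
               dimnames = list(paste0("g", 1:2), NULL))
  x3 <- make_counts(m3)
  lfc3 <- normalize_and_lfc(x3$counts, x3$design, pseudocount = 0.5,
                            min_pd0 = 0, median_center = FALSE)
  expect_true(is.finite(lfc3$lfc[1]) && lfc3$lfc[1] < 0)

  # low PD0 guides are flagged excluded
  m4 <- matrix(c(5, 500, 100, 400), ncol = 2,
               dimnames = list(paste0("g", 1:2), NULL))
  x4 <- make_counts(m4)
  expect_message(lfc4 <- normalize_and_lfc(x4$counts, x4$design, min_pd0 = 30),
                 "excluded")
  expect_true(lfc4$excluded[1])
  expect_false(lfc4$excluded[2])
})

test_that("copy-number bias correction flattens planted arm shifts only", {
  g <- toy_genome()
  scr <- simulate_screen(g, n_genes = 800, clones = c("A", "D"),
                         cn_bias = list(A = c("1q" = 0.5)),
                         essential_fraction = 0, seed = 5)
  lfc <- normalize_and_lfc(scr$counts, scr$design)
  kar <- data.frame(clone = "A", arm_id = "1q", call = "gain",
                    stringsAsFactors = FALSE)
  cor <- correct_cn_bias(lfc, scr$map, kar)

  a_rows <- cor$clone == "A"
  on_arm <- cor$arm_id == "1q"
  # post-correction the biased arm's median equals the neutral-genome median
  expect_equal(median(cor$lfc[a_rows & on_arm]),
               median(cor$lfc[a_rows & !on_arm]))
  # the unbiased clone D is untouched
  expect_equal(cor$lfc[cor$clone == "D"], lfc$lfc[lfc$clone == "D"])

  # all-neutral karyotype: output identical to input
  kar0 <- data.frame(clone = "A", arm_id = "1q", call = "neutral")
  cor0 <- correct_cn_bias(lfc, scr$map, kar0)
  expect_equal(cor0$lfc, lfc$lfc)

  # a shift planted on an arm declared neutral is deliberately untouched
  kar_wrong <- data.frame(clone = "A", arm_id = "2p", call = "gain")
  cor_w <- correct_cn_bias(lfc, scr$map, kar_wrong)
  biased <- cor_w$clone == "A" & cor_w$arm_id == "1q"
  expect_gt(median(cor_w$lfc[biased]) - median(cor_w$lfc[cor_w$clone == "A"]),
            0.3)

  # sparse arms are skipped with a warning
  scr_small <- simulate_screen(g, n_genes = 20, clones = "A",
                               cn_bias = list(A = c("5q" = 0.5)),
                               essential_fraction = 0, seed = 6)
  lfc_s <- normalize_and_lfc(scr_small$counts, scr_small$design)
  kar_s <- data.frame(clone = "A", arm_id = "5q", call = "gain")
  expect_warning(correct_cn_bias(lfc_s, scr_small$map, kar_s, min_guides = 200),
                 "skipped")
})

test_that("gene-level permutation p-values behave at the null and the floor", {
  # all guide LFCs zero -> p = 1 for every gene
  guides <- paste0("g", 1:20)
  map <- data.frame(guide = guides, gene = rep(paste0("G", 1:4), each = 5))
  gl <- data.frame(guide = guides, clone = "c1", lfc = 0, pd0 = 100,
                   excluded = FALSE)
  res <- gene_level_test(gl, map, n_perm = 200, seed = 1)
  expect_true(all(res$p == 1))

  # a strongly depleted gene amid null guides attains the permutation floor
  set.seed(2)
  lfc_vals <- c(rep(-3, 5), rnorm(995, 0, 0.3))
  guides <- paste0("g", 1:1000)
  map2 <- data.frame(guide = guides, gene = rep(paste0("G", 1:200), each = 5))
  gl2 <- data.frame(guide = guides, clone = "c1", lfc = lfc_vals, pd0 = 100,
                    excluded = FALSE)
  res2 <- gene_level_test(gl2, map2, n_perm = 1000, seed = 3)
  expect_equal(res2$p[res2$gene == "G1"], 1 / 1001)
  expect_equal(res2$lfc[res2$gene == "G1"], -3)
})

test_that("sampled permutation p matches exhaustive enumeration on a toy", {
  # 6 guides, 2 genes of 3: enumerate all C(6,3) = 20 null means exactly
  lfc_vals <- c(-1.2, -0.9, -1.5, 0.3, -0.1, 0.2)
  guides <- paste0("g", 1:6)
  map <- data.frame(guide = guides, gene = rep(c("A", "B"), each = 3))
  gl <- data.frame(guide = guides, clone = "c1", lfc = lfc_vals, pd0 = 100,
                   excluded = FALSE)
  combos <- combn(6, 3)
  null_means <- apply(combos, 2, function(ix) mean(lfc_vals[ix]))
  exact_p <- vapply(c(mean(lfc_vals[1:3]), mean(lfc_vals[4:6])), function(obs) {
    mean(abs(null_means) >= abs(obs))
  }, numeric(1))
  res <- gene_level_test(gl, map, n_perm = 4000, seed = 4)
  expect_equal(res$p[res$gene == "A"], exact_p[1], tolerance = 0.03)
  expect_equal(res$p[res$gene == "B"], exact_p[2], tolerance = 0.03)
})

test_that("epistasis profiles are antisymmetric and recover planted deltas", {
  genes <- paste0("G", 1:50)
  set.seed(7)
  base <- rnorm(50, 0, 0.2)
  aneu <- cbind(c1 = base, c2 = base + rnorm(50, 0, 0.05))
  dip <- cbind(d1 = base + rnorm(50, 0, 0.05), d2 = base)
  rownames(aneu) <- rownames(dip) <- genes
  # identical groups -> delta ~ 0
  same <- epistasis_profile(aneu, aneu, n_perm = 100, seed = 1)
  expect_true(all(same$delta_lfc == 0))

  # plant a -2 depletion in aneuploid clones only
  aneu2 <- aneu
  aneu2["G1", ] <- aneu2["G1", ] - 2
  prof <- epistasis_profile(aneu2, dip, n_perm = 1000, seed = 2)
  expect_equal(prof$delta_lfc[prof$gene == "G1"],
               mean(aneu2["G1", ]) - mean(dip["G1", ]))
  expect_lt(prof$delta_lfc[prof$gene == "G1"], -1.5)

  # swapping the groups negates delta exactly
  swapped <- epistasis_profile(dip, aneu2, n_perm = 1000, seed = 2)
  expect_equal(swapped$delta_lfc, -prof$delta_lfc)

  # disjoint universes are rejected
  dip2 <- dip
  rownames(dip2) <- paste0("H", 1:50)
  expect_error(epistasis_profile(aneu, dip2), "disjoint")
})

test_that("single-clone epistasis falls back to guide-level permutation", {
  g <- toy_genome()
  scr <- simulate_screen(g, n_genes = 60, clones = c("A", "D"),
                         essential_fraction = 0, seed = 8)
  lfc <- normalize_and_lfc(scr$counts, scr$design)
  # plant a differential effect in clone A for one gene
  target <- scr$map$guide[scr$map$gene == "g00010"]
  lfc$lfc[lfc$clone == "A" & lfc$guide %in% target] <-
    lfc$lfc[lfc$clone == "A" & lfc$guide %in% target] - 2
  res <- gene_level_test(lfc, scr$map, n_perm = 500, seed = 9)
  prof <- epistasis_profile(res[res$clone == "A", ], res[res$clone == "D", ],
                            guide_lfc = lfc, map = scr$map,
                            n_perm = 500, seed = 10)
  row <- prof[prof$gene == "g00010", ]
  expect_lt(row$delta_lfc, -1.5)
  expect_lt(row$p, 0.05)
  expect_gt(median(prof$p[prof$gene != "g00010"]), 0.2)
})
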